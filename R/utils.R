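# Internal helpers shared across modules.

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single integer", call. = FALSE)
    }
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Binary Shannon entropy in bits; H2(0) = H2(1) = 0.
entropy2 <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- numeric(length(p))
  ok <- p > 0 & p < 1
  q <- p[ok]
  out[ok] <- -q * log2(q) - (1 - q) * log2(1 - q)
  out
}

# Shannon entropy (bits) of a discrete distribution given as counts or probs.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

read_tsv_ <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

write_tsv_ <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
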