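# Exact weighted-L1 simplex regression via a dense primal simplex method.
#
# minimise sum_i w_i |(A x - b)_i|  over  { x : x >= 0, sum(x) = 1 }
#
# LP reformulation with residual splits r = u - v, u, v >= 0:
#   minimise  w'u + w'v
#   s.t.      A x - u + v = b        (m rows)
#             1' x          = 1
#             x, u, v >= 0
# (x <= 1 is implied by x >= 0 and sum(x) = 1.)
#
# A basic feasible point needs no artificial variables: pivot x_1 into the
# simplex-sum row (x = e_1), then each residual row is made basic in u_i or
# v_i depending on the sign of its right-hand side.

wl1_simplex <- function(A, b, w, maxit = 50000L, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(w) == m, all(w > 0), n >= 1L)
  nv <- n + 2L * m

  Tb <- matrix(0, m + 1L, nv + 1L)
  Tb[seq_len(m), seq_len(n)] <- A
  Tb[cbind(seq_len(m), n + seq_len(m))] <- -1          # -u
  Tb[cbind(seq_len(m), n + m + seq_len(m))] <- 1       # +v
  Tb[seq_len(m), nv + 1L] <- b
  Tb[m + 1L, seq_len(n)] <- 1
  Tb[m + 1L, nv + 1L] <- 1
  cost <- c(rep(0, n), w, w)

  # initial pivot: x_1 enters on the simplex-sum row
  for (i in seq_len(m)) {
    if (Tb[i, 1L] != 0) Tb[i, ] <- Tb[i, ] - Tb[i, 1L] * Tb[m + 1L, ]
  }
  basis <- integer(m + 1L)
  basis[m + 1L] <- 1L
  for (i in seq_len(m)) {
    if (Tb[i, nv + 1L] < 0) {
      Tb[i, ] <- -Tb[i, ]
      basis[i] <- n + i                                # u_i basic
    } else {
      basis[i] <- n + m + i                            # v_i basic
    }
  }

  bland_after <- 5000L
  it <- 0L
  status <- "optimal"
  repeat {
    it <- it + 1L
    if (it > maxit) { status <- "iteration limit"; break }
    red <- cost - as.vector(cost[basis] %*% Tb[, seq_len(nv), drop = FALSE])
    red[basis] <- 0
    neg <- which(red < -tol)
    if (!length(neg)) break
    enter <- if (it > bland_after) neg[1L] else neg[which.min(red[neg])]
    col <- Tb[, enter]
    pos <- which(col > tol)
    if (!length(pos)) { status <- "unbounded"; break }
    ratio <- Tb[pos, nv + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    leave <- cand[which.min(basis[cand])]              # Bland-style tie-break
    piv <- Tb[leave, enter]
    Tb[leave, ] <- Tb[leave, ] / piv
    other <- setdiff(seq_len(m + 1L), leave)
    fac <- Tb[other, enter]
    nz <- other[fac != 0]
    if (length(nz)) {
      Tb[nz, ] <- Tb[nz, ] - outer(Tb[nz, enter], Tb[leave, ])
    }
    basis[leave] <- enter
  }

  z <- numeric(nv)
  z[basis] <- Tb[, nv + 1L]
  x <- z[seq_len(n)]

  # a zero reduced cost on ANY nonbasic column signals an alternative
  # optimum (a flat edge of the polytope), i.e. a non-unique solution
  degenerate <- FALSE
  if (status == "optimal") {
    red <- cost - as.vector(cost[basis] %*% Tb[, seq_len(nv), drop = FALSE])
    red[basis] <- 0
    nonbasic <- setdiff(seq_len(nv), basis)
    degenerate <- any(abs(red[nonbasic]) < 1e-7 * max(1, max(w)))
  }
  list(x = x, objective = sum(w * abs(as.vector(A %*% x) - b)),
       status = status, iterations = it, degenerate = degenerate)
}

# Euclidean projection onto the probability simplex.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (1 - css[rho]) / rho
  pmax(v + tau, 0)
}

# Smoothed-L1 solver: graduated sqrt(r^2 + eps) smoothing minimised by
# projected gradient descent with backtracking on the simplex.  The smoothed
# objective is convex in x, so the iteration converges to the global
# optimum; used as a cross-check of the exact LP.
wl1_smooth <- function(A, b, w, eps_schedule = 10^seq(-4, -12, by = -2),
                       maxit = 3000L) {
  n <- ncol(A)
  if (n == 1L) return(list(x = 1, objective = sum(w * abs(A[, 1L] - b)),
                           status = "optimal"))
  x <- rep(1 / n, n)
  scale <- sum(w) * max(rowSums(abs(A)))
  for (eps in eps_schedule) {
    f <- function(x) {
      r <- as.vector(A %*% x) - b
      sum(w * sqrt(r^2 + eps))
    }
    g <- function(x) {
      r <- as.vector(A %*% x) - b
      as.vector(crossprod(A, w * r / sqrt(r^2 + eps)))
    }
    step <- 1 / scale
    fx <- f(x)
    for (it in seq_len(maxit)) {
      xn <- project_simplex(x - step * g(x))
      fn <- f(xn)
      if (fn <= fx) {
        converged <- fx - fn < 1e-14 * max(1, abs(fx)) && it > 10L
        x <- xn
        fx <- fn
        if (converged) break
        step <- step * 1.2
      } else {
        step <- step / 2
      }
    }
  }
  list(x = x, objective = sum(w * abs(as.vector(A %*% x) - b)),
       status = "optimal")
}

# Weighted least squares on the simplex, solved exactly as a QP.
wl2_qp <- function(A, b, w) {
  n <- ncol(A)
  Aw <- A * w
  D <- 2 * crossprod(A, Aw)
  D <- D + diag(1e-10 * max(1, diag(D)), n)            # ridge for rank defects
  d <- 2 * as.vector(crossprod(Aw, b))
  Amat <- cbind(rep(1, n), diag(n))
  sol <- quadprog::solve.QP(D, d, Amat, c(1, rep(0, n)), meq = 1L)
  x <- sol$solution
  list(x = x, objective = sum(w * (as.vector(A %*% x) - b)^2),
       status = "optimal")
}
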