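# Perrin-type spherical spline interpolation on the unit sphere, shared by
# bad-channel repair and scalp topography.

# Legendre polynomials P_1..P_nmax evaluated at x (vector): nmax x length(x).
legendre_table <- function(x, nmax) {
  out <- matrix(0, nmax, length(x))
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  out[1, ] <- p_cur
  if (nmax > 1) {
    for (n in 2:nmax) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      out[n, ] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

# Spline kernel g_m(cos gamma) = (1/4pi) sum_n (2n+1)/(n(n+1))^m P_n(cos gamma).
# The series is truncated once terms fall below `tol` (the n-th term is
# bounded by (2n+1)/(n(n+1))^m), capped at nmax terms.
spline_g <- function(cosang, m = 4, tol = 1e-10, nmax = 64) {
  bound <- (2 * seq_len(nmax) + 1) / (seq_len(nmax) * (seq_len(nmax) + 1))^m
  n_use <- min(nmax, max(which(bound >= tol), 8L))
  coefs <- (2 * seq_len(n_use) + 1) / (seq_len(n_use) * (seq_len(n_use) + 1))^m
  P <- legendre_table(cosang, n_use)
  as.vector(crossprod(P, coefs)) / (4 * pi)
}

# Fit spline coefficients for electrode positions `pos` (k x 3, unit norm)
# and one or more value columns `V` (k x T). Returns a closure evaluating the
# interpolant at arbitrary unit-sphere points.
spherical_spline_fit <- function(pos, V, m = 4, lambda = 0) {
  pos <- as.matrix(pos)
  V <- as.matrix(V)
  k <- nrow(pos)
  if (k < 4) stop("spherical spline needs at least 4 electrodes")
  C <- tcrossprod(pos)                 # cos of inter-electrode angles
  C[C > 1] <- 1; C[C < -1] <- -1
  if (any(C[upper.tri(C)] > 1 - 1e-12)) {
    stop("degenerate montage: co-located electrodes")
  }
  G <- matrix(spline_g(as.vector(C), m = m), k, k)
  A <- rbind(cbind(G + diag(lambda, k), rep(1, k)),
             c(rep(1, k), 0))
  rhs <- rbind(V, rep(0, ncol(V)))
  sol <- solve(A, rhs)
  coef <- sol[seq_len(k), , drop = FALSE]
  c0 <- sol[k + 1, ]
  function(points) {
    points <- as.matrix(points)
    CA <- tcrossprod(points, pos)
    CA[CA > 1] <- 1; CA[CA < -1] <- -1
    Gp <- matrix(spline_g(as.vector(CA), m = m), nrow(points), k)
    sweep(Gp %*% coef, 2, c0, "+")
  }
}
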