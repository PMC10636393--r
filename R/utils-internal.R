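# Internal helpers shared across modules.

# Upper-triangle edge indices in column-major order (i < j), 1-based.
.edgeIndex <- function(P) {
  idx <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  list(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
}

# Extract upper-triangle vector of a square matrix in .edgeIndex order.
.upperVec <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix from an upper-triangle vector (diagonal = diag).
.symFromUpper <- function(v, P, diag = 0) {
  m <- matrix(0, P, P)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag
  m
}

# Truncated-normal draws by rejection (bounds far from the mean in all uses
# here, so rejection cost is negligible).
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- stats::rnorm(length(need), mean, sd)
    ok <- cand >= lower & cand <= upper
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

# Stationary unit-variance AR(1) filtering of each row of x with per-row
# coefficient phi: y_1 = x_1, y_t = phi*y_{t-1} + sqrt(1-phi^2)*x_t, so the
# marginal variance is preserved while lagged correlation is introduced.
.arFilterRows <- function(x, phi) {
  for (p in which(phi > 0)) {
    inp <- c(x[p, 1], sqrt(1 - phi[p]^2) * x[p, -1])
    x[p, ] <- stats::filter(inp, phi[p], method = "recursive")
  }
  x
}

# Least-squares residualization of the columns of y (T x P) against the
# columns of x (T x k), via QR.  Returns residuals of the same shape.
.residualize <- function(y, x) {
  qr.resid(qr(x), y)
}
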