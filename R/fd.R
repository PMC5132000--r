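# Central finite differences with one Richardson extrapolation step
# (error O(h^4)). Base steps scale with the magnitude of each
# coordinate unless an explicit step vector is supplied; when the
# curvature scale is known (e.g. standard errors), steps of about a
# tenth of that scale balance truncation against rounding.

fd_steps <- function(x, h0 = 1e-3) h0 * pmax(1, abs(x))

# gradient of a scalar function
fd_grad <- function(f, x, h0 = 1e-3, h = fd_steps(x, h0)) {
  p <- length(x)
  g <- numeric(p)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- 1
    d1 <- (f(x + h[i] * ei) - f(x - h[i] * ei)) / (2 * h[i])
    d2 <- (f(x + h[i] / 2 * ei) - f(x - h[i] / 2 * ei)) / h[i]
    g[i] <- (4 * d2 - d1) / 3
  }
  g
}

# Jacobian of a vector-valued function (rows: components of f's value,
# columns: coordinates of x)
fd_jacobian <- function(f, x, h0 = 1e-3, h = fd_steps(x, h0)) {
  p <- length(x)
  cols <- vector("list", p)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- 1
    d1 <- (f(x + h[i] * ei) - f(x - h[i] * ei)) / (2 * h[i])
    d2 <- (f(x + h[i] / 2 * ei) - f(x - h[i] / 2 * ei)) / h[i]
    cols[[i]] <- (4 * d2 - d1) / 3
  }
  do.call(cbind, cols)
}

# Hessian of a scalar function (Jacobian of the finite-difference
# gradient; symmetrized)
fd_hessian <- function(f, x, h0 = 1e-3, h = fd_steps(x, h0)) {
  H <- fd_jacobian(function(y) fd_grad(f, y, h = h), x, h = h)
  (H + t(H)) / 2
}
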