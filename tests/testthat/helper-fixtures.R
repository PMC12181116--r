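# Shared fixtures: small smooth fields, reference kernels, and independent
# numeric oracles used across the suite.

default_kernel <- function() connectivity_kernel(U = 0.1, R = 1)

# smooth low-wavenumber complex field on an nx x nx periodic grid
smooth_field <- function(nx = 32L, dx = 0.2, amp = 0.01, rotating = TRUE) {
  x <- (0:(nx - 1L)) * dx
  k1 <- 2 * pi / (nx * dx)
  phi <- amp * (outer(cos(k1 * x), rep(1, nx)) +
                  outer(rep(1, nx), sin(k1 * x))) + 0i
  v <- if (rotating) -1i * phi else matrix(0i, nx, nx)
  scalar_field(phi, dx, velocity = v)
}

plane_wave_field <- function(nx, dx, mode = 1L, standing = TRUE) {
  x <- (0:(nx - 1L)) * dx
  k <- 2 * pi * mode / (nx * dx)
  phi <- if (standing) outer(cos(k * x), rep(1, nx)) + 0i else
    outer(exp(1i * k * x), rep(1, nx))
  list(field = scalar_field(phi, dx), k = k)
}

# discrete plane-wave eigenvalue of the 5-point Laplacian
k_disc2 <- function(k, dx) 2 * (1 - cos(k * dx)) / dx^2

# complex matrix exponential through an eigendecomposition -- independent
# of the closed forms under test
expm_complex <- function(M) {
  e <- eigen(M)
  e$vectors %*% diag(exp(e$values), nrow(M)) %*% solve(e$vectors)
}

# integrate d2y/dt2 = f(y) for a complex vector y: independent ODE oracle
ode_oracle_2nd <- function(y0, v0, f, times, rtol = 1e-10) {
  n <- length(y0)
  rhs <- function(t, s, p) {
    y <- s[1:n] + 1i * s[(n + 1):(2 * n)]
    dy <- s[(2 * n + 1):(3 * n)] + 1i * s[(3 * n + 1):(4 * n)]
    dd <- f(y, t)
    list(c(Re(dy), Im(dy), Re(dd), Im(dd)))
  }
  sol <- deSolve::ode(
    y = c(Re(y0), Im(y0), Re(v0), Im(v0)), times = times, func = rhs,
    parms = NULL, method = "ode45", rtol = rtol, atol = rtol * 1e-2
  )
  t(sol[, 2:(n + 1), drop = FALSE] + 1i * sol[, (n + 2):(2 * n + 1), drop = FALSE])
}

# 2-sphere metric of radius rho in (theta, phi) coordinates
sphere_metric <- function(rho) {
  force(rho)
  function(p) diag(c(rho^2, rho^2 * sin(p[1])^2))
}

periodic_lap <- function(m, dx) {
  nx <- nrow(m); ny <- ncol(m)
  (m[c(2:nx, 1), ] + m[c(nx, 1:(nx - 1)), ] +
     m[, c(2:ny, 1)] + m[, c(ny, 1:(ny - 1))] - 4 * m) / dx^2
}
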