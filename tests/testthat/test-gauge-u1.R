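kern_par <- kg_params(connectivity_kernel(0.1, 1))

cgrad_ref <- function(m, dx) {
  nx <- nrow(m)
  (m[c(2:nx, 1), ] - m[c(nx, 1:(nx - 1)), ]) / (2 * dx)
}

test_that("gauge transformation: phase rotation, potential shift, modulus", {
  nx <- 32L; dx <- 0.2
  f <- smooth_field(nx, dx)
  A <- gauge_potential(0, 0.2, -0.1, epsilon = 0.05, dx = dx)
  # constant theta: pure global phase, A unchanged
  gt <- gauge_transform(f, A, matrix(0.7, nx, nx))
  expect_lt(max(Mod(gt$field$values - exp(0.7i) * f$values)), 1e-14)
  expect_lt(max(abs(gt$A$A_x - 0.2)), 1e-14)
  expect_lt(max(abs(gt$A$A_y + 0.1)), 1e-14)
  # theta = lambda x: A_x shifts by lambda / epsilon away from the seam
  lam <- 0.3
  x <- (0:(nx - 1L)) * dx
  gt2 <- gauge_transform(f, A, outer(lam * x, rep(1, nx)))
  interior <- 2:(nx - 2L)
  expect_lt(max(abs(gt2$A$A_x[interior, ] - (0.2 + lam / 0.05))), 1e-12)
  expect_lt(max(abs(gt2$A$A_y + 0.1)), 1e-14)
  # modulus pointwise unchanged; epsilon = 0 rejected
  expect_equal(Mod(gt2$field$values), Mod(f$values), tolerance = 1e-14)
  expect_error(
    gauge_transform(f, gauge_potential(epsilon = 0), matrix(0, nx, nx)),
    "epsilon"
  )
})

test_that("Lagrangian density is exactly gauge invariant on the lattice", {
  nx <- 32L; dx <- 0.2
  x <- (0:(nx - 1L)) * dx
  k1 <- 2 * pi / (nx * dx)
  f <- smooth_field(nx, dx)
  A <- gauge_potential(0, A_x = 0.1 * outer(sin(k1 * x), rep(1, nx)),
                       A_y = 0.05, epsilon = 0.01, dx = dx)
  theta <- 0.4 * outer(sin(k1 * x), cos(k1 * x))
  gt <- gauge_transform(f, A, theta)
  L1 <- lagrangian_density(f, A, kern_par)
  L2 <- lagrangian_density(gt$field, gt$A, kern_par)
  expect_lt(max(abs(L1 - L2)), 1e-10)
})

test_that("covariant derivative: free limit, plane-wave closed form, covariance", {
  nx <- 64L; dx <- 2 * pi / nx
  x <- (0:(nx - 1L)) * dx
  k <- 3
  phi <- outer(exp(1i * k * x), rep(1, nx))
  f <- scalar_field(phi, dx)
  A0 <- gauge_potential(0, 0, 0, epsilon = 0.05, dx = dx)
  expect_lt(
    max(Mod(covariant_derivative(f, A0, "x") - cgrad_ref(phi, dx))),
    1e-12
  )
  # constant A_x: D_x phi = i (k_disc - eps A_x) phi with k_disc = sin(k dx)/dx
  Ax <- 0.8
  A <- gauge_potential(0, Ax, 0, epsilon = 0.05, dx = dx)
  kd <- sin(k * dx) / dx
  D <- covariant_derivative(f, A, "x")
  expect_lt(max(Mod(D - 1i * (kd - 0.05 * Ax) * phi)), 1e-10)
  # covariance under a smooth small gauge transformation, second order in dx
  f2 <- smooth_field(32L, 0.2)
  A2 <- gauge_potential(0, 0.1, -0.2, epsilon = 0.01, dx = 0.2)
  k1 <- 2 * pi / (32 * 0.2)
  xx <- (0:31) * 0.2
  th <- 5e-5 * outer(sin(k1 * xx), cos(k1 * xx))
  gt <- gauge_transform(f2, A2, th)
  for (mu in c("x", "y")) {
    lhs <- covariant_derivative(gt$field, gt$A, mu)
    rhs <- exp(1i * th) * covariant_derivative(f2, A2, mu)
    expect_lt(max(Mod(lhs - rhs)), 1e-8)
  }
})

test_that("field strength: gradients are curl-free, uniform rotation has F = 2 lambda", {
  nx <- 48L; dx <- 0.15
  x <- (0:(nx - 1L)) * dx
  k1 <- 2 * pi / (nx * dx)
  # a pure gradient potential carries no solenoidal part: the centered curl
  # of a centered gradient cancels identically
  theta <- outer(sin(k1 * x), cos(k1 * x))
  Agrad <- gauge_potential(0, cgrad_ref(theta, dx), t(cgrad_ref(t(theta), dx)),
                           epsilon = 1, dx = dx)
  Fs <- field_strength(Agrad)
  expect_lt(max(abs(Fs$F_xy)), 1e-12)
  # rigid rotation potential A = (0, -lambda y, lambda x)
  lam <- 0.4
  y <- x
  A <- gauge_potential(0, A_x = outer(rep(1, nx), -lam * y),
                       A_y = outer(lam * x, rep(1, nx)),
                       epsilon = 1, dx = dx)
  Fs <- field_strength(A)
  interior <- 3:(nx - 3L)
  expect_lt(max(abs(Fs$F_xy[interior, interior] - 2 * lam)), 1e-10)
  # antisymmetry holds by construction: F_yx = -F_xy
  Fyx <- -Fs$F_xy
  expect_identical(Fyx + Fs$F_xy, matrix(0, nx, nx))
})

test_that("Noether current: phasor density, static field, free-current signs", {
  nx <- 16L
  phi <- matrix(0.3 + 0i, nx, nx)
  # phi = rho e^{-it}: velocity -i phi, J_t = -|phi|^2
  f <- scalar_field(phi, dx = 0.2, velocity = -1i * phi)
  J <- noether_current(f)
  expect_equal(J$J_t, -Mod(phi)^2, tolerance = 1e-14)
  # real static field: all spatial components vanish
  f2 <- scalar_field(matrix(seq(0, 1, length.out = nx^2), nx), dx = 0.2)
  J2 <- noether_current(f2)
  expect_true(all(J2$J_x == 0) && all(J2$J_y == 0) && all(J2$J_t == 0))
})

test_that("coupled evolution: decoupled limit is exact, field 0 leaves A free", {
  nx <- 24L; dx <- 0.2
  f0 <- smooth_field(nx, dx)
  Az <- gauge_potential(0, 0, 0, epsilon = 0.01, dx = dx)
  t1 <- evolve_coupled(f0, Az, kern_par, dt = 0.01, n_steps = 200,
                       evolve_A = FALSE, source_scale = 0)
  t2 <- evolve_kg(f0, kern_par, dt = 0.01, n_steps = 200)
  expect_identical(t1$field$values, t2$field$values)
  # zero field, solenoidal A: the potential evolves under its free wave
  # equation while the field stays identically zero
  x <- (0:(nx - 1L)) * dx
  k1 <- 2 * pi / (nx * dx)
  Asol <- gauge_potential(0, A_x = 0.1 * outer(rep(1, nx), sin(k1 * x)),
                          A_y = 0, epsilon = 0.01, dx = dx)
  fz <- scalar_field(matrix(0i, nx, nx), dx)
  tz <- evolve_coupled(fz, Asol, kern_par, dt = 0.01, n_steps = 300)
  expect_true(all(tz$field$values == 0))
  expect_gt(max(abs(tz$A$A_x - Asol$A_x)), 1e-4)
})

test_that("gauge-equivalent initial data give identical gauge-invariant observables", {
  nx <- 32L; dx <- 0.2
  x <- (0:(nx - 1L)) * dx
  k1 <- 2 * pi / (nx * dx)
  f0 <- smooth_field(nx, dx)
  A0 <- gauge_potential(0, A_x = 0.1 * outer(sin(k1 * x), rep(1, nx)),
                        A_y = 0.05 * outer(rep(1, nx), cos(k1 * x)),
                        epsilon = 0.01, dx = dx)
  theta <- 0.3 * outer(sin(k1 * x), cos(k1 * x))
  gt <- gauge_transform(f0, A0, theta)
  t1 <- evolve_coupled(f0, A0, kern_par, dt = 0.005, n_steps = 1500)
  t2 <- evolve_coupled(gt$field, gt$A, kern_par, dt = 0.005, n_steps = 1500)
  scale <- max(Mod(t1$field$values))
  expect_lt(max(abs(Mod(t1$field$values) - Mod(t2$field$values))) / scale,
            1e-6)
  # the potentials stay shifted by exactly the initial lattice gradient
  shift <- (theta[c(2:nx, 1), ] - theta) / dx / 0.01
  expect_lt(max(abs(t2$A$A_x - t1$A$A_x - shift)), 1e-9)
})

test_that("discrete charge and lattice continuity are conserved along coupled runs", {
  nx <- 32L; dx <- 0.2
  x <- (0:(nx - 1L)) * dx
  k1 <- 2 * pi / (nx * dx)
  f0 <- smooth_field(nx, dx)
  A0 <- gauge_potential(0, A_x = 0.1 * outer(sin(k1 * x), rep(1, nx)),
                        A_y = 0.05 * outer(rep(1, nx), cos(k1 * x)),
                        epsilon = 0.01, dx = dx)
  tr <- evolve_coupled(f0, A0, kern_par, dt = 0.005, n_steps = 10000,
                       track_conservation = TRUE)
  Q <- tr$charge
  expect_lt(max(abs(Q - Q[1])) / abs(Q[1]), 1e-6)
  ratios <- vapply(tr$continuity, function(z) z$rms_residual / z$rms_J, 0)
  expect_lt(max(ratios), 1e-6)
})

test_that("Gauss-law solve: Laplacian identity, log profile, superposition", {
  nx <- 48L; dx <- 0.1
  src <- matrix(0, nx, nx)
  q <- 1
  src[24, 24] <- q / dx^2   # unit point charge
  At <- gauss_solve(src, dx = dx)
  lap <- periodic_lap(At, dx)  # interior check avoids the pad seam
  interior <- 4:(nx - 3L)
  expect_lt(
    sqrt(mean((lap[interior, interior] + src[interior, interior])^2)),
    1e-6
  )
  # radial log profile: A(r1) - A(r2) = -(q / 2 pi) log(r1 / r2)
  prof <- At[24 + 3, 24] - At[24 + 8, 24]
  expect_equal(prof, -(q / (2 * pi)) * log(3 / 8), tolerance = 0.03)
  # the bare -log(r) normalization differs by exactly 2 pi
  At_p <- gauss_solve(src, dx = dx, normalization = "bare")
  expect_equal(At_p, 2 * pi * At, tolerance = 1e-12)
  # zero source -> zero field; superposition exact for the linear solve
  expect_identical(gauss_solve(matrix(0, 8, 8), dx = 1), matrix(0, 8, 8))
  s1 <- matrix(0, nx, nx); s1[16, 20] <- 2
  s2 <- matrix(0, nx, nx); s2[30, 28] <- 1
  expect_lt(
    max(abs(gauss_solve(s1 + s2, dx) -
              gauss_solve(s1, dx) - gauss_solve(s2, dx))),
    1e-10
  )
  expect_error(gauss_solve(-src, dx), "nonnegative")
})

test_that("Hebbian rate: zero activity, polynomial source scaling", {
  z <- hebbian_rate(matrix(0, 8, 8), dx = 0.2)
  expect_identical(z, matrix(0, 8, 8))
  # with a2 = 1 the quartic source term scales by 16 when |phi| doubles
  phi2 <- matrix(0.2, 4, 4)
  src1 <- phi2 + 1 * phi2^2
  phi2b <- 4 * phi2          # |phi| doubled => |phi|^2 quadrupled
  src2 <- phi2b + 1 * phi2b^2
  expect_equal(src2 - phi2b, 16 * (src1 - phi2), tolerance = 1e-12)
  # linear-Hebbian rate equals the plain Gauss solve of |phi|^2
  act <- matrix(0, 24, 24); act[12, 12] <- 1
  expect_equal(hebbian_rate(act, dx = 0.2),
               gauss_solve(act, dx = 0.2), tolerance = 1e-14)
  # higher-order terms add to the source monotonically
  r1 <- hebbian_rate(act, coeffs = numeric(0), dx = 0.2)
  r2 <- hebbian_rate(act, coeffs = c(1), dx = 0.2)
  expect_true(all(r2 >= r1 - 1e-12))
})
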