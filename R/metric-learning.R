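#' Stress-energy components of the neural field
#'
#' Diagonal stress-energy tensor of the scalar field on a diagonal sheet
#' metric, in the isotropic form appropriate when the field has no
#' preferred direction:
#' \deqn{T_{tt} = -\sqrt{|g|}\,g_{tt}\left(g^{ii}\partial_i\phi^*\partial_i\phi
#'   - m^2|\phi|^2\right) = g_{tt}\,A,}
#' \deqn{T_{ii} = -\sqrt{|g|}\,g_{ii}\left(g^{tt}|\partial_t\phi|^2
#'   + g^{jj}\partial_j\phi^*\partial_j\phi - m^2|\phi|^2\right) = -g_{ii}\,B,}
#' where `j` is the spatial index other than `i`.  The scalars `A` (density)
#' and `B` (pressure-like) drive the expansion dynamics of
#' [evolve_expansion()].
#'
#' @param field a [scalar_field()].
#' @param metric a [metric_flat()]-family metric.
#' @param mass2 squared mass coefficient `m^2` (i.e. `mass2c4` in flat
#'   model units).
#' @param boundary boundary handling for spatial gradients.
#' @return List of per-node matrices `T_tt`, `T_xx`, `T_yy` and the
#'   spatially averaged scalars `A` and `B`.
#' @export
stress_energy <- function(field, metric, mass2, boundary = "periodic") {
  phi <- field$values
  g <- metric_on_grid(metric, nrow(phi), ncol(phi))
  dpx <- cgrad(phi, field$dx, "x", boundary)
  dpy <- cgrad(phi, field$dx, "y", boundary)
  gradsq_x <- Mod(dpx)^2 / g$gxx  # g^{xx} |d_x phi|^2 (negative)
  gradsq_y <- Mod(dpy)^2 / g$gyy
  m2phi2 <- mass2 * Mod(phi)^2
  vt2 <- Mod(field$velocity)^2  # g^{tt} = 1
  A_field <- -g$sqrtg * (gradsq_x + gradsq_y - m2phi2)
  T_tt <- 1 * A_field  # g_tt = 1
  B_x <- g$sqrtg * (vt2 + gradsq_y - m2phi2)  # j != i
  B_y <- g$sqrtg * (vt2 + gradsq_x - m2phi2)
  list(
    T_tt = T_tt,
    T_xx = -g$gxx * B_x,
    T_yy = -g$gyy * B_y,
    A = mean(A_field),
    B = mean(0.5 * (B_x + B_y))
  )
}

#' Evolve the Robertson-Walker expansion factor
#'
#' Integrates the Friedmann-like first-order equation for the expansion
#' factor of the extrinsic-connectivity metric,
#' \deqn{\dot a^2 = A\,a^2 - k,}
#' (branch sign selectable) and checks it against the printed companion
#' acceleration equation \eqn{\ddot a / a = -B} and the conservation law
#' \eqn{d(a^2\rho)/dt + p\,d(a^2)/dt = 0} (with `rho = A`, `p = B`) along
#' the trajectory.  `A` and `B` may be constants or functions `(a, t)`;
#' the conserved-density family corresponds to `A = rho0 / a^2`.
#'
#' @param state initial [rw_state()] (uses `a` and `k_curv`).
#' @param A density term: constant or `function(a, t)`.
#' @param B pressure-like term: constant or `function(a, t)`.
#' @param dt output sampling interval.
#' @param n_steps number of intervals.
#' @param branch `+1` (growth, default) or `-1`.
#' @return Object of class `expansion_trajectory`: `times`, `a`, `adot`,
#'   maximum residuals `residual_accel` (of `addot + B a`) and
#'   `residual_conservation`.
#' @export
evolve_expansion <- function(state, A, B, dt, n_steps, branch = +1) {
  stopifnot(inherits(state, "rw_state"))
  k <- state$k_curv
  A_fun <- if (is.function(A)) A else function(a, t) A
  B_fun <- if (is.function(B)) B else function(a, t) B
  times <- dt * (0:n_steps)
  rhs <- function(t, y, parms) {
    a <- y[1L]
    val <- A_fun(a, t) * a^2 - k
    if (val < -1e-12) {
      stop(sprintf(
        "square-root domain violation at t = %g: A a^2 - k = %.3g < 0", t, val
      ))
    }
    list(branch * sqrt(max(val, 0)))
  }
  sol <- deSolve::ode(
    y = c(a = state$a), times = times, func = rhs, parms = NULL,
    method = "ode45", rtol = 1e-10, atol = 1e-12
  )
  a <- as.numeric(sol[, "a"])
  if (any(a <= 0)) stop("expansion factor reached a <= 0 along the trajectory")
  adot <- branch * sqrt(pmax(
    vapply(seq_along(a), function(i) A_fun(a[i], times[i]) * a[i]^2 - k, 0),
    0
  ))
  # consistency of the two printed equations and of the conservation law,
  # using the analytic time derivative of the first-order form:
  # addot = (Adot a^2 + 2 A a adot) / (2 adot), Adot by small-step
  # differentiation of A(a, t) along the trajectory
  res_accel <- NA_real_
  res_cons <- NA_real_
  interior <- which(abs(adot) > 1e-8)
  if (length(interior)) {
    h <- 1e-6
    Aval <- vapply(interior, function(i) A_fun(a[i], times[i]), 0)
    Adot <- vapply(interior, function(i) {
      da <- adot[i]
      (A_fun(a[i] + h * da, times[i] + h) -
         A_fun(a[i] - h * da, times[i] - h)) / (2 * h)
    }, 0)
    ai <- a[interior]; adi <- adot[interior]
    addot <- (Adot * ai^2 + 2 * Aval * ai * adi) / (2 * adi)
    Bval <- vapply(interior, function(i) B_fun(a[i], times[i]), 0)
    res_accel <- max(abs(addot + Bval * ai))
    # d(a^2 rho)/dt + p d(a^2)/dt with rho = A, p = B
    res_cons <- max(abs(2 * ai * adi * Aval + ai^2 * Adot +
                          Bval * 2 * ai * adi))
  }
  structure(
    list(times = times, a = a, adot = adot,
         residual_accel = res_accel, residual_conservation = res_cons,
         k_curv = k, branch = branch),
    class = "expansion_trajectory"
  )
}

#' @exportS3Method base::print
print.expansion_trajectory <- function(x, ...) {
  cat(sprintf(
    "<expansion_trajectory> %d samples, a: %.4g -> %.4g (max |addot + B a| = %.3g)\n",
    length(x$a), x$a[1L], x$a[length(x$a)], x$residual_accel
  ))
  invisible(x)
}

#' Refit expansion parameters from an observed trajectory
#'
#' Least-squares recovery of `(A, k)` of the constant-`A` family
#' `adot^2 = A a^2 - k` from a sampled `a(t)` trajectory (both parameters
#' are identifiable there; in the conserved-density family `A = rho0/a^2`
#' only the difference `rho0 - k` enters `a(t)` and a joint fit is
#' degenerate).
#'
#' @param times sample times.
#' @param a_traj observed expansion factors.
#' @param init named vector `c(A = ..., k = ...)` initial guess.
#' @param branch branch sign of the forward model.
#' @return Named vector `c(A, k)` of estimates with attribute `rss`.
#' @export
fit_expansion <- function(times, a_traj, init = c(A = 0.5, k = 0),
                          branch = +1) {
  dt <- diff(times)[1L]
  forward <- function(p) {
    st <- rw_state(a_traj[1L], k_curv = p[["k"]])
    tr <- evolve_expansion(st, A = p[["A"]], B = function(a, t) -p[["A"]],
                           dt = dt, n_steps = length(times) - 1L,
                           branch = branch)
    tr$a
  }
  fit <- minpack.lm::nls.lm(
    par = init,
    fn = function(p) forward(p) - a_traj,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  out <- stats::coef(fit)
  attr(out, "rss") <- fit$deviance
  out
}

#' High-mass Hebbian learning rate
#'
#' In the high-mass limit the gradient terms of the density drop out of the
#' Friedmann-like equation and the expansion rate reduces to
#' \deqn{\frac{da}{dt} \approx \pm m\,|\phi|,}
#' i.e. connection growth proportional to the local activity amplitude --
#' Hebbian change that is non-linear in the underlying pre/post unit pair.
#'
#' @param m mass coefficient, `m >= 0`.
#' @param phi_mod field modulus `|phi|` (scalar or matrix).
#' @param branch `+1` (default) or `-1`.
#' @return `branch * m * phi_mod`.
#' @examples
#' learning_rate(2, 0.3)  # 0.6
#' @export
learning_rate <- function(m, phi_mod, branch = +1) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0)
  stopifnot(all(phi_mod >= 0))
  branch * m * phi_mod
}

#' Default parameters of the delta-response learning experiment
#'
#' Reads the packaged parameter file for [delta_response_experiment()].
#' @return Named list of parameters.
#' @export
default_delta_params <- function() {
  load_config(
    system.file("extdata", "delta_response_defaults.yaml",
                package = "cortexgauge"),
    quiet = TRUE
  )
}

#' Delta response before and after metric learning
#'
#' Simulates the response of the curved-sheet Klein-Gordon field to a
#' spatially narrow impulse (a Gaussian of width `2 dx` added to the field
#' velocity at `t = 0`) under the Robertson-Walker spatial metric with
#' expansion factor `a_before` and again with `a_after`, and compares the
#' probe time series: learning that increases `a` slows lateral propagation
#' (effective speed `c / a`), concentrating the evoked energy near the
#' stimulus.
#'
#' @param params resolved parameter list as from [default_delta_params()]
#'   (uses `U`, `R`, `lapU`, `nx`, `ny`, `dx`, `dt`, `n_steps`).
#' @param a_before,a_after expansion factors; `a_after >= a_before`.
#' @param probe probe node, default the stimulus site (grid center).
#' @param amplitude impulse amplitude on the velocity.
#' @return List with `response_before`, `response_after` (complex probe
#'   series), `times`, `amplitude_ratio` and `area_ratio` (after / before,
#'   peak `|phi|` and integrated `|phi| dt`).
#' @export
delta_response_experiment <- function(params = default_delta_params(),
                                      a_before = 1, a_after = 1.5,
                                      probe = NULL, amplitude = 1) {
  if (a_after < a_before) {
    stop("'a_after' must be >= 'a_before' (learning increases the expansion)")
  }
  kern <- connectivity_kernel(params$U, params$R, params$lapU)
  kg <- kg_params(kern)
  nx <- params$nx; ny <- params$ny; dx <- params$dx
  cx <- nx %/% 2L; cy <- ny %/% 2L
  if (is.null(probe)) probe <- c(cx, cy)
  xg <- (seq_len(nx) - cx) * dx
  yg <- (seq_len(ny) - cy) * dx
  w <- 2 * dx  # narrow Gaussian standing in for the delta impulse
  kick <- amplitude * outer(xg, yg, function(x, y) exp(-(x^2 + y^2) / (2 * w^2)))
  run_one <- function(a) {
    f0 <- scalar_field(matrix(0i, nx, ny), dx, velocity = kick + 0i)
    traj <- evolve_kg(f0, kg, metric = metric_rw(a), dt = params$dt,
                      n_steps = params$n_steps, probe = probe)
    traj$probe_series
  }
  before <- run_one(a_before)
  after <- run_one(a_after)
  dtv <- params$dt
  list(
    times = dtv * (0:params$n_steps),
    response_before = before,
    response_after = after,
    amplitude_ratio = max(Mod(after)) / max(Mod(before)),
    area_ratio = sum(Mod(after)) / sum(Mod(before))
  )
}
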