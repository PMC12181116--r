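#' Klein-Gordon parameters from the connectivity kernel
#'
#' Maps local connectivity (gain `U`, disc moments `a`, `b`, gain Laplacian
#' `lapU`) to the coefficients of the wave equation
#' \deqn{\partial_t^2\phi - Ub\,\nabla^2\phi = -(1 - Ua - b\,\nabla^2 U)\,\phi,}
#' i.e. `mass2c4 = 1 - U a - b lapU` and `c2 = U b`.  A negative `mass2c4`
#' (supercritical gain) is representable and flagged with a warning, not
#' rejected; `c2 < 0` (negative gain) is flagged likewise since wave
#' evolution then loses hyperbolicity.
#'
#' @param kernel a [connectivity_kernel()].
#' @return Object of class `kg_params` with `mass2c4` and `c2`.
#' @examples
#' kg_params(connectivity_kernel(U = 0.1, R = 1))
#' # disconnected sheet: pure oscillator with unit frequency
#' kg_params(connectivity_kernel(U = 0, R = 1))
#' @export
kg_params <- function(kernel) {
  stopifnot(inherits(kernel, "connectivity_kernel"))
  mass2c4 <- 1 - kernel$U * kernel$a - kernel$b * kernel$lapU
  c2 <- kernel$U * kernel$b
  if (any(mass2c4 < 0)) {
    warning("mass2c4 < 0: supercritical connectivity gain (tachyonic mass)")
  }
  if (any(c2 < 0)) {
    warning("c2 < 0: negative connectivity gain, wave evolution not hyperbolic")
  }
  structure(list(mass2c4 = mass2c4, c2 = c2), class = "kg_params")
}

#' @exportS3Method base::print
print.kg_params <- function(x, ...) {
  cat(sprintf("<kg_params> mass2c4 = %.6g, c2 = %.6g\n",
              mean(x$mass2c4), mean(x$c2)))
  invisible(x)
}

cfl_check <- function(c2, metric, dx, dt, margin = 0.5) {
  cmax2 <- max(c2)
  if (inherits(metric, "metric2p1")) {
    gmin <- min(abs(c(metric$g_xx, metric$g_yy)))
    cmax2 <- cmax2 / gmin  # effective speed^2 = c2 * (-g^ii)
  }
  if (cmax2 <= 0) return(invisible(TRUE))
  limit <- margin * dx / sqrt(cmax2)
  if (dt > limit) {
    stop(sprintf(
      "CFL violation: dt = %g exceeds %g = %.2f * dx / sqrt(c2_eff)",
      dt, limit, margin
    ))
  }
  invisible(TRUE)
}

#' Discrete field energy of the Klein-Gordon system
#'
#' Energy functional matched to the conservative discretization used by
#' [evolve_kg()]:
#' \deqn{E = \sum_j \sqrt{|g|}\left(|\dot\phi|^2 + m^2c^4 |\phi|^2\right) dx^2
#'  + c^2 \sum_{\rm links} w\,|\Delta\phi/dx|^2 dx^2,}
#' with link weights `w` the half-node averages of
#' \eqn{\sqrt{|g|}(-g^{ii})}.  Conserved by the leapfrog integrator up to a
#' bounded \eqn{O(dt^2)} oscillation.
#'
#' @param field a [scalar_field()].
#' @param params a [kg_params()].
#' @param metric metric object, default flat.
#' @param boundary boundary handling, as in [laplace_beltrami()].
#' @return Scalar energy.
#' @export
kg_energy <- function(field, params, metric = metric_flat(),
                      boundary = "periodic") {
  phi <- field$values; v <- field$velocity; dx <- field$dx
  g <- metric_on_grid(metric, nrow(phi), ncol(phi))
  wx <- g$sqrtg / (-g$gxx)
  wy <- g$sqrtg / (-g$gyy)
  wxp <- 0.5 * (wx + shift_mat(wx, 1L, 0L))
  wyp <- 0.5 * (wy + shift_mat(wy, 0L, 1L))
  dpx <- (shift_mat(phi, 1L, 0L, boundary) - phi) / dx
  dpy <- (shift_mat(phi, 0L, 1L, boundary) - phi) / dx
  sum(g$sqrtg * (Mod(v)^2 + params$mass2c4 * Mod(phi)^2)) * dx^2 +
    mean(params$c2) * sum(wxp * Mod(dpx)^2 + wyp * Mod(dpy)^2) * dx^2
}

#' Evolve the Klein-Gordon neural field
#'
#' Second-order leapfrog (velocity Verlet) integration of
#' \deqn{\partial_t^2\phi = -m^2c^4\,\phi + c^2\,\Delta_g\phi,}
#' with \eqn{\Delta_g} the [laplace_beltrami()] operator of `metric`.
#' `mass2c4` and `c2` may be scalars or per-node matrices (spatially varying
#' gain).  The CFL-type stability bound `dt <= 0.5 dx / c_eff` is enforced,
#' and runaway growth of the field norm aborts with a diagnostic.
#'
#' @param field initial [scalar_field()].
#' @param params [kg_params()] coefficients.
#' @param metric sheet metric, default [metric_flat()].
#' @param dt time step.
#' @param n_steps number of steps.
#' @param probe optional `c(i, j)` node index whose complex amplitude is
#'   recorded every step.
#' @param save_every if not `NULL`, keep a field snapshot every that many
#'   steps.
#' @param boundary `"periodic"` or `"dirichlet"`.
#' @param energy_every if not `NULL`, record the discrete energy every that
#'   many steps.
#' @param accel_fn optional override of the acceleration operator
#'   `function(phi) -> matrix` (used internally by the gauge sector).
#' @return Object of class `kg_trajectory`: `times`, `probe_series`,
#'   `energies`, `energy_times`, `snapshots`, and the final `field`.
#' @examples
#' par <- kg_params(connectivity_kernel(U = 0.1, R = 1))
#' f0 <- scalar_field(matrix(0.1 + 0i, 16, 16), dx = 0.25)
#' traj <- evolve_kg(f0, par, dt = 0.05, n_steps = 100, probe = c(1, 1))
#' @export
evolve_kg <- function(field, params, metric = metric_flat(), dt, n_steps,
                      probe = NULL, save_every = NULL,
                      boundary = c("periodic", "dirichlet"),
                      energy_every = NULL, accel_fn = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(field, "scalar_field"))
  cfl_check(params$c2, metric, field$dx, dt)
  phi <- field$values
  v <- field$velocity
  dx <- field$dx
  m2 <- params$mass2c4
  c2 <- params$c2
  if (is.null(accel_fn)) {
    accel_fn <- function(p) {
      -m2 * p + c2 * laplace_beltrami(metric, p, dx = dx, boundary = boundary)
    }
  }
  probe_series <- if (!is.null(probe)) complex(n_steps + 1L) else NULL
  if (!is.null(probe)) probe_series[1L] <- phi[probe[1L], probe[2L]]
  snapshots <- list()
  energies <- NULL; energy_times <- NULL
  record_energy <- function(step, phi_c, v_c) {
    f <- scalar_field(phi_c, dx, velocity = v_c, time = field$time + step * dt)
    kg_energy(f, params, metric, boundary)
  }
  if (!is.null(energy_every)) {
    energies <- record_energy(0L, phi, v)
    energy_times <- field$time
  }
  norm0 <- max(sqrt(mean(Mod(phi)^2) + mean(Mod(v)^2)), 1e-12)
  acc <- accel_fn(phi)
  for (n in seq_len(n_steps)) {
    v_half <- v + 0.5 * dt * acc
    phi <- phi + dt * v_half
    acc <- accel_fn(phi)
    v <- v_half + 0.5 * dt * acc
    if (!is.null(probe)) probe_series[n + 1L] <- phi[probe[1L], probe[2L]]
    if (!is.null(save_every) && n %% save_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <- scalar_field(
        phi, dx, velocity = v, time = field$time + n * dt
      )
    }
    if (!is.null(energy_every) && n %% energy_every == 0L) {
      energies <- c(energies, record_energy(n, phi, v))
      energy_times <- c(energy_times, field$time + n * dt)
    }
    if (n %% 200L == 0L || n == n_steps) {
      nrm <- sqrt(mean(Mod(phi)^2) + mean(Mod(v)^2))
      if (!is.finite(nrm) || nrm > 1e6 * norm0 + 1e6) {
        stop(sprintf(
          "instability detected at step %d (t = %g): field norm %.3g exceeds bound; reduce dt",
          n, field$time + n * dt, nrm
        ))
      }
    }
  }
  structure(
    list(
      times = field$time + dt * (0:n_steps),
      probe_series = probe_series,
      energies = energies,
      energy_times = energy_times,
      snapshots = snapshots,
      field = scalar_field(phi, dx, velocity = v,
                           time = field$time + n_steps * dt),
      dt = dt
    ),
    class = "kg_trajectory"
  )
}

#' @exportS3Method base::print
print.kg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<kg_trajectory> %d steps, t in [%g, %g], %d snapshots\n",
    length(x$times) - 1L, min(x$times), max(x$times), length(x$snapshots)
  ))
  invisible(x)
}

#' Estimate the oscillation frequency of a sampled harmonic series
#'
#' For a uniformly sampled single-mode series `s[n] = A cos(w n dt + p)` the
#' three-term identity `s[n+1] + s[n-1] = 2 cos(w dt) s[n]` holds exactly;
#' the least-squares estimate of `cos(w dt)` over the whole series therefore
#' recovers `w` to machine precision for pure modes and degrades gracefully
#' under noise.
#'
#' @param series real numeric vector.
#' @param dt sampling interval.
#' @return Angular frequency estimate (rad per time unit).
#' @export
measure_frequency <- function(series, dt) {
  s <- as.numeric(series)
  n <- length(s)
  if (n < 5L) stop("series too short to estimate a frequency")
  mid <- s[2:(n - 1L)]
  num <- sum(mid * (s[3:n] + s[1:(n - 2L)]))
  den <- 2 * sum(mid^2)
  if (den == 0) stop("zero series: no oscillation to measure")
  r <- num / den
  if (abs(r) > 1) r <- sign(r)  # clip roundoff outside [-1, 1]
  acos(r) / dt
}

#' Non-weak-connectivity parameters
#'
#' Coefficients of the strong-intrinsic-connection branch, where the
#' point-like (Dirac) intrinsic term gives the local dynamics
#' \deqn{\partial_t\phi = -iW(1 - \alpha + a\gamma + \beta|\phi|^2)\phi
#'   + iW\gamma b \nabla^2\phi.}
#'
#' @param W connectivity magnitude, `W >= 0`.
#' @param alpha,beta,gamma sigmoid-expansion coefficients.
#' @return Object of class `nonweak_params`.
#' @export
nonweak_params <- function(W, alpha, beta, gamma) {
  stopifnot(is.numeric(W), length(W) == 1L, W >= 0)
  structure(
    list(W = W, alpha = alpha, beta = beta, gamma = gamma),
    class = "nonweak_params"
  )
}

#' Stationary moduli of the non-weak branch
#'
#' Returns all nonnegative stationary moduli `|phi0|` of the strong-coupling
#' dynamics: the trivial state 0 and, when the sign structure permits, the
#' root of \eqn{1 - \alpha + a\gamma + \beta|\phi_0|^2 = 0}, i.e.
#' \eqn{|\phi_0|^2 = (\alpha - 1 - a\gamma)/\beta}.
#'
#' @param params a [nonweak_params()].
#' @param kernel a [connectivity_kernel()] supplying the disc moment `a`.
#' @return Numeric vector of stationary moduli (always contains 0), with
#'   attribute `mod2` holding the squared moduli.
#' @examples
#' k <- connectivity_kernel(U = 0, R = 1)
#' stable_states(nonweak_params(1, alpha = 1.5, beta = 1, gamma = 0), k)
#' @export
stable_states <- function(params, kernel) {
  stopifnot(inherits(params, "nonweak_params"),
            inherits(kernel, "connectivity_kernel"))
  remainder <- 1 - params$alpha + kernel$a * params$gamma
  states <- 0
  if (params$beta == 0) {
    if (abs(remainder) > .Machine$double.eps^0.5) {
      # bracket 1 - alpha + a*gamma never vanishes: only the trivial state
      states <- 0
    } else {
      stop("beta = 0 with vanishing remainder: every modulus is stationary (degenerate)")
    }
  } else {
    mod2 <- -remainder / params$beta
    if (mod2 > 0) states <- c(0, sqrt(mod2))
  }
  attr(states, "mod2") <- states^2
  states
}

#' Perturbation wave speed of the non-weak branch
#'
#' Perturbations around a nontrivial stationary state propagate as a
#' massless wave with \eqn{c^2 = 2W\beta\gamma b\,|\phi_0|^2}.  Downstream
#' evolution uses `kg_params` with `mass2c4 = 0` and this `c2`.
#'
#' @inheritParams stable_states
#' @return Object of class `kg_params` with `mass2c4 = 0` and attribute
#'   `phi0_mod2`.
#' @export
perturbation_speed <- function(params, kernel) {
  states <- stable_states(params, kernel)
  nontrivial <- states[states > 0]
  if (length(nontrivial) == 0L) {
    stop("no nontrivial stationary state: perturbation speed undefined")
  }
  mod2 <- nontrivial[1L]^2
  c2 <- 2 * params$W * params$beta * params$gamma * kernel$b * mod2
  out <- structure(list(mass2c4 = 0, c2 = c2), class = "kg_params")
  attr(out, "phi0_mod2") <- mod2
  out
}
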