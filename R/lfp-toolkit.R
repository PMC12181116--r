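#' Laminar impulse (Green's function) response
#'
#' Closed-form response of a damped cortical oscillator layer to a Dirac
#' pulse, obtained by Laplace transform of
#' `(d2/dt2 + m^2 + iC) phi = delta(t)`:
#' \deqn{g(t) = H(t)\,\frac{1}{m}\,e^{imt}\,e^{-Ct/2},}
#' with `H` the Heaviside step.  The modulus decays as `e^{-Ct/2}/m`.
#'
#' @param m carrier frequency (mass term), `m > 0`.
#' @param C damping constant, `C >= 0`.
#' @param t time grid (values `< 0` give 0).
#' @return Complex vector of the response.
#' @export
delta_response <- function(m, C, t) {
  stopifnot(is.numeric(m), length(m) == 1L)
  if (m <= 0) stop("'m' must be positive")
  if (C < 0) stop("'C' must be nonnegative")
  ifelse(t < 0, 0i, (1 / m) * exp(1i * m * t) * exp(-C * t / 2))
}

rotation2 <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
}

#' Two-layer rotating-wave LFP response
#'
#' Impulse response of two coupled cortical layers: the scalar decaying
#' carrier of [delta_response()] multiplied by the amplitude-transfer
#' rotation `[[cos(at), -sin(at)], [sin(at), cos(at)]]` applied to a unit
#' impulse on `stim_layer` -- a decaying wave moving between the layers.
#' At `a t = pi/2 (mod pi)` the amplitude has fully transferred to the
#' other layer, and the layer power sum is `e^{-Ct}/m^2` for all `t >= 0`.
#'
#' @param m,C carrier frequency and damping, as [delta_response()].
#' @param alpha inter-layer rotation rate.
#' @param stim_layer stimulated layer (1 or 2).
#' @param t time grid.
#' @return An [lfp_record()] with 2 layers.
#' @export
two_layer_response <- function(m, C, alpha, stim_layer = 1, t) {
  stopifnot(stim_layer %in% c(1L, 2L))
  scal <- delta_response(m, C, t)
  e <- c(0, 0); e[stim_layer] <- 1
  traces <- vapply(seq_along(t), function(i) {
    (rotation2(alpha * t[i]) %*% e) * scal[i]
  }, complex(2L))
  lfp_record(t, traces, meta = list(
    model = "two_layer", m = m, C = C, alpha = alpha,
    stim_layer = stim_layer
  ))
}

# the three independent antisymmetric 3x3 rotation generators
# (1-2, 1-3 and 2-3 layer mixing)
rot3_generators <- function() {
  K12 <- matrix(0, 3, 3); K12[2, 1] <- 1; K12[1, 2] <- -1
  K13 <- matrix(0, 3, 3); K13[3, 1] <- 1; K13[1, 3] <- -1
  K23 <- matrix(0, 3, 3); K23[3, 2] <- 1; K23[2, 3] <- -1
  list(K12, K13, K23)
}

rot3 <- function(coeffs, t) {
  # exp(t * sum_c coeff_c K_c) via the Rodrigues closed form
  K <- rot3_generators()
  A <- coeffs[1] * K[[1]] + coeffs[2] * K[[2]] + coeffs[3] * K[[3]]
  w <- sqrt(sum(coeffs^2))
  if (w == 0) return(diag(3))
  th <- w * t
  diag(3) + sin(th) / w * A + (1 - cos(th)) / w^2 * (A %*% A)
}

#' Three-layer rotating-wave LFP response
#'
#' Minimal three-layer extension of [two_layer_response()]: the decaying
#' scalar carrier times an orthogonal rotation
#' `exp(t (c12 K12 + c13 K13 + c23 K23))` of the layer vector, where the
#' `K` are the three independent antisymmetric 3x3 generators of amplitude
#' transfer between layer pairs.  Orthogonality makes the layer power sum
#' exactly `e^{-Ct}/m^2`; zero coefficients confine the response to the
#' stimulated layer, and a single nonzero pair coefficient never excites
#' the third layer.
#'
#' @param m,C carrier frequency and damping.
#' @param generator_coeffs numeric length 3: rotation rates `c(c12, c13,
#'   c23)` for the layer pairs (1,2), (1,3), (2,3).
#' @param stim_layer stimulated layer (1, 2 or 3).
#' @param t time grid.
#' @return An [lfp_record()] with 3 layers.
#' @export
three_layer_response <- function(m, C, generator_coeffs, stim_layer = 1, t) {
  stopifnot(length(generator_coeffs) == 3L, stim_layer %in% 1:3)
  scal <- delta_response(m, C, t)
  e <- numeric(3L); e[stim_layer] <- 1
  traces <- vapply(seq_along(t), function(i) {
    as.complex(rot3(generator_coeffs, t[i]) %*% e) * scal[i]
  }, complex(3L))
  lfp_record(t, traces, meta = list(
    model = "three_layer", m = m, C = C,
    generator_coeffs = generator_coeffs, stim_layer = stim_layer
  ))
}

forward_lfp <- function(model, pars, stim_layer, t) {
  if (model == "two_layer") {
    two_layer_response(pars[["m"]], pars[["C"]], pars[["alpha"]],
                       stim_layer, t)
  } else {
    three_layer_response(
      pars[["m"]], pars[["C"]],
      c(pars[["c12"]], pars[["c13"]], pars[["c23"]]),
      stim_layer, t
    )
  }
}

#' Synthetic laminar LFP with observation noise
#'
#' Runs a forward model and adds independent Gaussian noise of standard
#' deviation `noise_sd` to the real and imaginary parts of every sample
#' (or to the real part only when `real_observations = TRUE`, matching
#' real-valued LFP channels).  Fully reproducible from `seed`; all
#' generating parameters are recorded in the metadata.
#'
#' @param model `"two_layer"` or `"three_layer"`.
#' @param pars named list/vector of forward parameters: `m`, `C` and
#'   `alpha` (two-layer) or `c12`, `c13`, `c23` (three-layer).
#' @param t time grid.
#' @param noise_sd nonnegative noise standard deviation (absolute units).
#' @param seed RNG seed.
#' @param stim_layer stimulated layer.
#' @param real_observations observe only the real part.
#' @return An [lfp_record()].
#' @export
make_synthetic_lfp <- function(model = c("two_layer", "three_layer"), pars, t,
                               noise_sd = 0, seed = 1L, stim_layer = 1L,
                               real_observations = FALSE) {
  model <- match.arg(model)
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  rec <- forward_lfp(model, pars, stim_layer, t)
  traces <- rec$traces
  if (real_observations) traces <- Re(traces) + 0i
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    n <- length(traces)
    noise_re <- stats::rnorm(n, sd = noise_sd)
    noise_im <- if (real_observations) 0 else stats::rnorm(n, sd = noise_sd)
    traces <- traces + matrix(noise_re + 1i * noise_im, nrow(traces))
  }
  meta <- c(rec$meta, list(
    noise_sd = noise_sd, seed = seed, real_observations = real_observations
  ))
  lfp_record(rec$times, traces, meta)
}

default_init_lfp <- function(record, model) {
  # spectral/envelope heuristics when no init is supplied: carrier frequency
  # from the FFT peak of the summed complex trace, damping from the early
  # decay of the total power envelope
  s <- colSums(record$traces)
  dt <- diff(record$times)[1L]
  n <- length(s)
  sp <- Mod(stats::fft(s))^2
  freqs <- 2 * pi * (0:(n - 1L)) / (n * dt)
  i_pk <- which.max(sp)
  m0 <- freqs[i_pk]
  if (m0 > pi / dt) m0 <- 2 * pi / dt - m0   # fold aliased band
  m0 <- max(m0, 0.1)
  env <- colSums(Mod(record$traces)^2)
  pos <- which(env > max(env) * 0.05)
  C0 <- if (length(pos) > 5) {
    slope <- stats::coef(stats::lm(
      log(env[pos]) ~ record$times[pos]
    ))[[2L]]
    max(-slope, 0.01)
  } else 0.1
  if (model == "two_layer") {
    c(m = m0, C = C0, alpha = 0.02)
  } else {
    c(m = m0, C = C0, c12 = 0.02, c13 = 0.02, c23 = 0.02)
  }
}

#' Invert a laminar LFP record for its generating parameters
#'
#' Levenberg-Marquardt least squares on the residual between the forward
#' rotating-wave model and the observed traces (real and imaginary parts
#' stacked; real part only for records flagged `real_observations`).
#' Five restarts from jittered initial values (fixed RNG stream per fit)
#' guard against carrier-phase local minima; optional Gaussian priors enter
#' as ridge residuals.  Standard errors come from the Gauss-Newton
#' approximation of the Hessian at the optimum.
#'
#' @param record an [lfp_record()] (stimulated layer read from metadata,
#'   default 1).
#' @param model `"two_layer"` or `"three_layer"`.
#' @param init optional named initial values (`m`, `C`, `alpha` or
#'   `c12`, `c13`, `c23`); heuristics otherwise.
#' @param priors optional list with named vectors `mean` and `sd` for a
#'   subset of parameters.
#' @param n_restarts number of jittered restarts (first start unjittered).
#' @param seed seed of the restart jitter stream.
#' @return An [inversion_result()].
#' @examples
#' t <- seq(0, 60, by = 0.1)
#' rec <- make_synthetic_lfp("two_layer",
#'   list(m = 1, C = 0.1, alpha = 0.05), t, noise_sd = 0)
#' fit_lfp(rec, "two_layer", init = c(m = 1.2, C = 0.08, alpha = 0.04))
#' @export
fit_lfp <- function(record, model = c("two_layer", "three_layer"),
                    init = NULL, priors = NULL, n_restarts = 5L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(record, "lfp_record"))
  stim <- record$meta$stim_layer %||% 1L
  realobs <- isTRUE(record$meta$real_observations)
  obs <- if (realobs) {
    as.vector(Re(record$traces))
  } else {
    c(as.vector(Re(record$traces)), as.vector(Im(record$traces)))
  }
  if (is.null(init)) init <- default_init_lfp(record, model)
  p_names <- names(init)
  n_par <- length(init)
  if (length(obs) < 10L * n_par) {
    stop("record too short: need at least 10 samples per estimated parameter")
  }
  resid_fn <- function(p) {
    p <- stats::setNames(as.numeric(p), p_names)
    p[["m"]] <- max(p[["m"]], 1e-3)   # keep the forward model defined
    p[["C"]] <- max(p[["C"]], 0)
    rec_hat <- forward_lfp(model, as.list(p), stim, record$times)
    pred <- if (realobs) {
      as.vector(Re(rec_hat$traces))
    } else {
      c(as.vector(Re(rec_hat$traces)), as.vector(Im(rec_hat$traces)))
    }
    r <- pred - obs
    if (!is.null(priors)) {
      keep <- intersect(names(priors$mean), p_names)
      r <- c(r, (p[keep] - priors$mean[keep]) / priors$sd[keep])
    }
    r
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    start <- if (r == 1L) init else init * (1 + 0.3 * stats::runif(n_par, -1, 1))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("all optimizer restarts failed")
  }
  est <- stats::setNames(as.numeric(stats::coef(best)), p_names)
  converged <- best$info %in% 1:3
  # Gauss-Newton standard errors from the Jacobian at the optimum
  J <- numeric_jacobian(resid_fn, est)
  rss <- best$deviance
  dof <- max(length(obs) - n_par, 1L)
  sigma2 <- rss / dof
  se <- rep(NA_real_, n_par)
  covm <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
  if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  inversion_result(
    estimates = est,
    standard_errors = stats::setNames(se, p_names),
    residual_norm = rss,
    converged = converged,
    n_iter = best$niter,
    info = list(model = model, message = best$message,
                stim_layer = stim, n_obs = length(obs))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

numeric_jacobian <- function(fn, p, h = 1e-6) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (k in seq_along(p)) {
    hp <- h * max(1, abs(p[k]))
    pp <- p; pp[k] <- pp[k] + hp
    pm <- p; pm[k] <- pm[k] - hp
    J[, k] <- (fn(pp) - fn(pm)) / (2 * hp)
  }
  J
}
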