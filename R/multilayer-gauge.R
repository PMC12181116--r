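#' SU(2) generator set for the two-bilayer cortex
#'
#' Returns the three generators of layer mixing exactly in their
#' unnormalized Pauli form,
#' `T1 = [[0,1],[1,0]]`, `T2 = [[0,-i],[i,0]]`, `T3 = [[1,0],[0,-1]]`,
#' together with the structure constants computed numerically from the
#' commutators `[Ta, Tb] = i f_abc Tc` (for these matrices `f_abc =
#' 2 eps_abc`, twice the value of the half-normalized convention).
#'
#' @param g coupling constant of the multilayer connectivity field.
#' @return Object of class `generator_set`: list `T` of Hermitian matrices,
#'   coupling `g` and structure-constant array `f`.
#' @export
su2_generators <- function(g = 1) {
  T1 <- matrix(c(0, 1, 1, 0), 2, 2)
  T2 <- matrix(c(0, 1i, -1i, 0), 2, 2)  # column-major: [[0,-i],[i,0]]
  T3 <- diag(c(1, -1))
  gens <- list(T1 + 0i, T2, T3 + 0i)
  f <- structure_constants(gens)
  structure(list(T = gens, g = g, f = f), class = "generator_set")
}

structure_constants <- function(gens) {
  n <- length(gens)
  f <- array(0, c(n, n, n))
  norm_c <- vapply(gens, function(Tc) Re(sum(diag(Tc %*% Tc))), 0)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      comm <- gens[[a]] %*% gens[[b]] - gens[[b]] %*% gens[[a]]
      for (cc in seq_len(n)) {
        # [Ta, Tb] = i f_abc Tc  =>  f_abc = tr([Ta,Tb] Tc) / (i tr(Tc Tc))
        f[a, b, cc] <- Re(sum(diag(comm %*% gens[[cc]])) / (1i * norm_c[cc]))
      }
    }
  }
  f
}

#' @exportS3Method base::print
print.generator_set <- function(x, ...) {
  cat(sprintf("<generator_set> %d generators, g = %g, f[1,2,3] = %g\n",
              length(x$T), x$g, x$f[1, 2, 3]))
  invisible(x)
}

#' Connectivity field estimated from the layered neural field
#'
#' Inverts the stationarity of the SU(2) Noether currents for the temporal
#' connectivity components:
#' \deqn{A^a_t = -\frac{\varphi^\dagger T^a \varphi}{g\,\varphi^\dagger\varphi},}
#' always real because each generator is Hermitian.
#'
#' @param phi complex vector of layer amplitudes (length = layer count), or
#'   a matrix with one column per node.
#' @param gens a [su2_generators()] set.
#' @return Numeric vector (or matrix, one row per generator) of `A^a_t`.
#' @examples
#' gens <- su2_generators(g = 1)
#' connectivity_from_current(c(1, 0), gens)  # (0, 0, -1)
#' @export
connectivity_from_current <- function(phi, gens) {
  stopifnot(inherits(gens, "generator_set"))
  phi_mat <- if (is.matrix(phi)) phi else matrix(phi, ncol = 1L)
  storage.mode(phi_mat) <- "complex"
  norms <- Re(colSums(Conj(phi_mat) * phi_mat))
  if (any(norms <= 0)) {
    stop(sprintf(
      "zero neural field at node(s) %s: connectivity undefined",
      paste(which(norms <= 0), collapse = ", ")
    ))
  }
  out <- vapply(gens$T, function(Ta) {
    Re(colSums(Conj(phi_mat) * (Ta %*% phi_mat))) / (gens$g * norms)
  }, numeric(ncol(phi_mat)))
  res <- -t(matrix(out, ncol = length(gens$T)))
  if (!is.matrix(phi)) as.numeric(res) else res
}

#' Connection-gain change rates between two bilayers
#'
#' The three intrinsic connection gains `f1, f2, f3` (one per generator:
#' in-phase mixing, quadrature mixing, differential gain) change at rates
#' set by the instantaneous layer amplitudes:
#' \deqn{\partial_t f_1 = \frac{2\,\mathrm{Re}(\varphi_1^*\varphi_2)}
#'   {g(|\varphi_1|^2 + |\varphi_2|^2)},\quad
#' \partial_t f_2 = \frac{2\,\mathrm{Im}(\varphi_1^*\varphi_2)}
#'   {g(|\varphi_1|^2 + |\varphi_2|^2)},\quad
#' \partial_t f_3 = \frac{|\varphi_1|^2 - |\varphi_2|^2}
#'   {g(|\varphi_1|^2 + |\varphi_2|^2)}.}
#' All three rates are real for arbitrary complex amplitudes.  In-phase
#' equal layers drive only `f1`, a single active layer only `f3`, and
#' quadrature layers only `f2`.
#'
#' @param phi1,phi2 complex amplitudes (vectorized).
#' @param g coupling constant.
#' @return List with numeric `f1`, `f2`, `f3` rate components.
#' @export
gain_rates <- function(phi1, phi2, g = 1) {
  denom <- g * (Mod(phi1)^2 + Mod(phi2)^2)
  if (any(denom == 0)) stop("zero total activity: gain rates undefined")
  cross <- Conj(phi1) * phi2
  list(
    f1 = 2 * Re(cross) / denom,
    f2 = 2 * Im(cross) / denom,
    f3 = (Mod(phi1)^2 - Mod(phi2)^2) / denom
  )
}

#' Closed-form generalized oscillation matrix
#'
#' Unitary layer rotation generated by a single SU(2) generator,
#' \deqn{e^{-i\alpha T^a t} = \cos(\alpha t)\,I - i\sin(\alpha t)\,T^a,}
#' exact for the involutory (unnormalized Pauli) generators; for `a = 3`
#' this is `diag(e^{-i alpha t}, e^{i alpha t})`, a pure inter-layer phase
#' precession, while `a = 2` transfers amplitude between the layers.
#'
#' @param alpha rotation rate.
#' @param a generator index 1, 2 or 3.
#' @param t time (scalar or vector).
#' @param gens generator set, default [su2_generators()].
#' @return For scalar `t` a 2x2 complex matrix; for vector `t` a
#'   `2 x 2 x length(t)` array.
#' @export
generalized_oscillation <- function(alpha, a, t, gens = su2_generators()) {
  stopifnot(a %in% seq_along(gens$T))
  Ta <- gens$T[[a]]
  one <- function(tt) {
    cos(alpha * tt) * diag(2) - 1i * sin(alpha * tt) * Ta
  }
  if (length(t) == 1L) return(one(t))
  out <- array(0i, c(2L, 2L, length(t)))
  for (i in seq_along(t)) out[, , i] <- one(t[i])
  out
}

#' Carrier-plus-rotation solution of the multilayer field
#'
#' Closed-form factorized solution of the multilayer dynamics in the
#' slow-rotation regime `|alpha| << m`: a fast scalar carrier `e^{i s m t}`
#' times the unitary generalized-oscillation factor,
#' \deqn{\vec\varphi(t) = e^{\pm imt}\, e^{\mp i(\alpha\cdot T)t}\,\vec\varphi_0,}
#' where the rotation rates `alpha_a = g\,\partial_t A^a_t / (2m)` are
#' supplied as inputs.  Because both factors are unitary the total layer
#' power `sum |phi_i|^2` is conserved exactly.
#'
#' @param phi0 complex length-2 initial layer vector.
#' @param m carrier (mass) frequency.
#' @param alphas numeric length-3 rotation rates, one per generator.
#' @param t time grid.
#' @param sign carrier branch, `+1` or `-1`.
#' @param gens generator set.
#' @return Complex matrix `2 x length(t)` of layer amplitudes, class
#'   `su2_trajectory` with attributes `times`.
#' @export
evolve_su2_approx <- function(phi0, m, alphas, t, sign = +1,
                              gens = su2_generators()) {
  stopifnot(length(phi0) == 2L, length(alphas) == length(gens$T))
  if (max(abs(alphas)) > 0.2 * abs(m)) {
    warning("|alpha| is not small compared to m: factorized solution degrades")
  }
  aT <- matrix(0i, 2, 2)
  for (k in seq_along(alphas)) aT <- aT + alphas[k] * gens$T[[k]]
  anorm <- sqrt(sum(alphas^2))  # (alpha.T)^2 = |alpha|^2 I for Pauli forms
  traces <- matrix(0i, 2L, length(t))
  for (i in seq_along(t)) {
    tt <- t[i]
    U <- if (anorm == 0) diag(2) + 0i else {
      cos(anorm * tt) * diag(2) - 1i * sin(anorm * tt) * (aT / anorm)
    }
    if (sign < 0) U <- Conj(t(U)) * 1  # e^{+i alpha.T t} for the - branch
    traces[, i] <- exp(sign * 1i * m * tt) * (U %*% phi0)
  }
  structure(traces, times = t, class = c("su2_trajectory", "matrix"))
}
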