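#' Abelian connectivity potential
#'
#' The U(1) connectivity field `A = (A_t, A_x, A_y)` encodes a space- and
#' time-dependent modulation of the intrinsic connection gain; the coupling
#' `epsilon` sets how strongly the phase of the neural field feels it.
#' Components may be scalars or per-node matrices on the field grid.
#'
#' @param A_t,A_x,A_y real components (scalar or matrix).
#' @param epsilon coupling constant, default 0.01 (weak coupling).
#' @param dx grid spacing the components live on.
#' @return Object of class `gauge_u1`.
#' @export
gauge_potential <- function(A_t = 0, A_x = 0, A_y = 0, epsilon = 0.01,
                            dx = NULL) {
  comp <- list(A_t = A_t, A_x = A_x, A_y = A_y)
  for (nm in names(comp)) {
    v <- comp[[nm]]
    if (!is.numeric(v) || !all(is.finite(v))) {
      stop(sprintf("'%s' must be real and finite", nm))
    }
  }
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  structure(
    list(A_t = A_t, A_x = A_x, A_y = A_y, epsilon = epsilon, dx = dx),
    class = "gauge_u1"
  )
}

#' @exportS3Method base::print
print.gauge_u1 <- function(x, ...) {
  f <- function(v) if (is.matrix(v)) "<per-node>" else format(v)
  cat(sprintf("<gauge_u1> epsilon = %g, A = (%s, %s, %s)\n",
              x$epsilon, f(x$A_t), f(x$A_x), f(x$A_y)))
  invisible(x)
}

expand_comp <- function(v, nx, ny) {
  if (is.matrix(v)) {
    stopifnot(all(dim(v) == c(nx, ny)))
    v
  } else {
    matrix(v, nx, ny)
  }
}

cgrad <- function(m, dx, dim = c("x", "y"), boundary = "periodic") {
  dim <- match.arg(dim)
  if (dim == "x") {
    (shift_mat(m, 1L, 0L, boundary) - shift_mat(m, -1L, 0L, boundary)) / (2 * dx)
  } else {
    (shift_mat(m, 0L, 1L, boundary) - shift_mat(m, 0L, -1L, boundary)) / (2 * dx)
  }
}

#' Local U(1) gauge transformation
#'
#' Applies the joint transformation that leaves the gauged dynamics
#' invariant: the field picks up a local phase, `phi -> e^{i theta} phi`,
#' and the connectivity potential shifts by the gradient of `theta`,
#' `A_mu -> A_mu + (d_mu theta) / epsilon`.  The sign of the shift is fixed
#' by requiring covariance of [covariant_derivative()] with the convention
#' `D_mu = d_mu - i epsilon A_mu` (the opposite sign bookkeeping from the
#' defining relation `-epsilon A = d theta` is absorbed into `theta`).
#'
#' On the lattice the spatial components of the potential are interpreted
#' as forward-link fields (`A_x[j]` lives on the link from node `j` to
#' `j + e_x`), and the shift uses the forward difference of `theta` on that
#' link.  With this convention the transformation is an exact symmetry of
#' the discrete dynamics of [evolve_coupled()] and of the link-based
#' [lagrangian_density()] -- not merely an order-`dx^2` one.  The pointwise
#' modulus of the field is unchanged exactly.
#'
#' @param field a [scalar_field()].
#' @param A a [gauge_potential()]; `epsilon` must be nonzero.
#' @param theta real matrix of phase angles on the grid.
#' @param theta_t optional real matrix of time derivatives of `theta`
#'   (shifts `A_t` and rotates the field velocity); default 0.
#' @param boundary boundary handling for the gradient.
#' @return List with transformed `field` and `A`.
#' @export
gauge_transform <- function(field, A, theta, theta_t = NULL,
                            boundary = "periodic") {
  stopifnot(inherits(field, "scalar_field"), inherits(A, "gauge_u1"))
  if (A$epsilon == 0) stop("gauge transformation undefined for epsilon = 0")
  nx <- nrow(field$values); ny <- ncol(field$values)
  theta <- expand_comp(theta, nx, ny)
  if (is.null(theta_t)) theta_t <- matrix(0, nx, ny)
  theta_t <- expand_comp(theta_t, nx, ny)
  phase <- exp(1i * theta)
  new_field <- scalar_field(
    phase * field$values,
    dx = field$dx,
    velocity = phase * (field$velocity + 1i * theta_t * field$values),
    time = field$time
  )
  fdiff_x <- (shift_mat(theta, 1L, 0L, boundary) - theta) / field$dx
  fdiff_y <- (shift_mat(theta, 0L, 1L, boundary) - theta) / field$dx
  new_A <- gauge_potential(
    A_t = expand_comp(A$A_t, nx, ny) + theta_t / A$epsilon,
    A_x = expand_comp(A$A_x, nx, ny) + fdiff_x / A$epsilon,
    A_y = expand_comp(A$A_y, nx, ny) + fdiff_y / A$epsilon,
    epsilon = A$epsilon, dx = field$dx
  )
  list(field = new_field, A = new_A)
}

#' Gauge-covariant derivative
#'
#' `D_mu phi = d_mu phi - i epsilon A_mu phi`, with centered spatial
#' differences; the temporal derivative uses the stored field velocity.
#' Spatial link components of the potential are averaged back to nodes, so
#' this node-centered operator is covariant under [gauge_transform()] to
#' second order in `dx` (the link operators inside [evolve_coupled()] and
#' [lagrangian_density()] are exactly covariant).
#'
#' @param field a [scalar_field()].
#' @param A a [gauge_potential()].
#' @param mu one of `"t"`, `"x"`, `"y"`.
#' @param boundary boundary handling.
#' @return Complex matrix.
#' @export
covariant_derivative <- function(field, A, mu = c("t", "x", "y"),
                                 boundary = "periodic") {
  mu <- match.arg(mu)
  nx <- nrow(field$values); ny <- ncol(field$values)
  eps <- A$epsilon
  link_to_node <- function(v, dim) {
    m <- expand_comp(v, nx, ny)
    if (dim == "x") 0.5 * (m + shift_mat(m, -1L, 0L, boundary)) else
      0.5 * (m + shift_mat(m, 0L, -1L, boundary))
  }
  switch(mu,
    t = field$velocity -
      1i * eps * expand_comp(A$A_t, nx, ny) * field$values,
    x = cgrad(field$values, field$dx, "x", boundary) -
      1i * eps * link_to_node(A$A_x, "x") * field$values,
    y = cgrad(field$values, field$dx, "y", boundary) -
      1i * eps * link_to_node(A$A_y, "y") * field$values
  )
}

#' Connectivity field strength
#'
#' Antisymmetric curl of the connectivity potential,
#' `F_munu = d_mu A_nu - d_nu A_mu`.  The purely spatial component `F_xy`
#' is always available; the temporal components need the time derivative of
#' the spatial potential (`Adot`, as produced along a coupled trajectory).
#'
#' @param A a [gauge_potential()] with `dx` set.
#' @param Adot optional list with matrices `A_x`, `A_y` of time derivatives.
#' @param boundary boundary handling.
#' @return List with `F_xy` and, when `Adot` is given, `F_tx`, `F_ty`.
#' @export
field_strength <- function(A, Adot = NULL, boundary = "periodic") {
  stopifnot(inherits(A, "gauge_u1"))
  if (is.null(A$dx)) stop("gauge potential has no grid spacing 'dx'")
  nx <- if (is.matrix(A$A_x)) nrow(A$A_x) else
    if (is.matrix(A$A_y)) nrow(A$A_y) else
      stop("field_strength needs at least one per-node component")
  ny <- if (is.matrix(A$A_x)) ncol(A$A_x) else ncol(A$A_y)
  Ax <- expand_comp(A$A_x, nx, ny)
  Ay <- expand_comp(A$A_y, nx, ny)
  At <- expand_comp(A$A_t, nx, ny)
  out <- list(
    F_xy = cgrad(Ay, A$dx, "x", boundary) - cgrad(Ax, A$dx, "y", boundary)
  )
  if (!is.null(Adot)) {
    out$F_tx <- expand_comp(Adot$A_x, nx, ny) - cgrad(At, A$dx, "x", boundary)
    out$F_ty <- expand_comp(Adot$A_y, nx, ny) - cgrad(At, A$dx, "y", boundary)
  }
  out
}

#' Gauged Lagrangian density of the neural field
#'
#' Matter part of the gauged Lagrangian on the flat connectivity metric,
#' \deqn{\mathcal{L} = |D_t\phi|^2 - c^2(|D_x\phi|^2 + |D_y\phi|^2)
#'   + m^2c^4 |\phi|^2,}
#' evaluated per node with forward-link covariant differences
#' `D_x phi = (e^{-i eps dx A_x} phi_{+x} - phi)/dx`, which makes the
#' density exactly invariant under [gauge_transform()] on the lattice.
#' The kinetic connectivity term `F_munu F^munu / 4` is added when `Adot`
#' is supplied.
#'
#' @param field a [scalar_field()].
#' @param A a [gauge_potential()].
#' @param params a [kg_params()].
#' @param Adot optional time derivative of the spatial potential.
#' @param boundary boundary handling.
#' @return Real matrix of the density per node.
#' @export
lagrangian_density <- function(field, A, params, Adot = NULL,
                               boundary = "periodic") {
  phi <- field$values
  nx <- nrow(phi); ny <- ncol(phi)
  dx <- field$dx
  eps <- A$epsilon
  Ax <- expand_comp(A$A_x, nx, ny)
  Ay <- expand_comp(A$A_y, nx, ny)
  Dt <- covariant_derivative(field, A, "t", boundary)
  Dx <- (exp(-1i * eps * dx * Ax) * shift_mat(phi, 1L, 0L, boundary) - phi) / dx
  Dy <- (exp(-1i * eps * dx * Ay) * shift_mat(phi, 0L, 1L, boundary) - phi) / dx
  L <- Mod(Dt)^2 - params$c2 * (Mod(Dx)^2 + Mod(Dy)^2) +
    params$mass2c4 * Mod(field$values)^2
  if (!is.null(Adot)) {
    Fs <- field_strength(A, Adot, boundary)
    # raise with diag(1, -c2, -c2): F^{tx} = -c2 F_tx etc, F^{xy} = c2^2 F_xy
    L <- L + 0.5 * (params$c2^2 * Fs$F_xy^2 -
                    params$c2 * (Fs$F_tx^2 + Fs$F_ty^2))
  }
  Re(L)
}

#' Noether current of the phase symmetry
#'
#' Conserved current of the global/local U(1) symmetry,
#' \deqn{J_\mu = \mathrm{Im}(\phi^* D_\mu\phi)
#'   = -\tfrac{i}{2}(\phi^*\partial_\mu\phi - \partial_\mu\phi^*\,\phi)
#'   - \epsilon A_\mu |\phi|^2,}
#' normalized so that a unit-frequency phasor `phi = rho e^{-it}` has
#' `J_t = -|phi|^2` (the activity density that sources Hebbian change).
#'
#' @param field a [scalar_field()].
#' @param A a [gauge_potential()] (use `epsilon = 0` for the free current).
#' @param boundary boundary handling.
#' @return List of real matrices `J_t`, `J_x`, `J_y`.
#' @export
noether_current <- function(field, A = gauge_potential(epsilon = 0),
                            boundary = "periodic") {
  list(
    J_t = Re(Im(Conj(field$values) * covariant_derivative(field, A, "t", boundary))),
    J_x = Re(Im(Conj(field$values) * covariant_derivative(field, A, "x", boundary))),
    J_y = Re(Im(Conj(field$values) * covariant_derivative(field, A, "y", boundary)))
  )
}

gauge_links <- function(A, nx, ny, dx) {
  eps <- A$epsilon
  if (eps == 0 || (!any(A$A_x != 0) && !any(A$A_y != 0))) {
    return(NULL)  # trivial links: covariant_laplacian falls back to the stencil
  }
  Ax <- expand_comp(A$A_x, nx, ny)
  Ay <- expand_comp(A$A_y, nx, ny)
  # A_i are forward-link fields; the hop factor on link j -> j+e_i is
  # exp(-i eps dx A_i[j]) so that (U phi_{+} - phi)/dx ~ (d - i eps A) phi
  list(
    Ux = exp(-1i * eps * dx * Ax),
    Uy = exp(-1i * eps * dx * Ay)
  )
}

covariant_laplacian <- function(phi, links, dx) {
  if (is.null(links)) {
    pxp <- shift_mat(phi, 1L, 0L)
    pxm <- shift_mat(phi, -1L, 0L)
    pyp <- shift_mat(phi, 0L, 1L)
    pym <- shift_mat(phi, 0L, -1L)
    return((pxp + pxm + pyp + pym - 4 * phi) / (1 * dx^2))
  }
  Ux <- links$Ux; Uy <- links$Uy
  (Ux * shift_mat(phi, 1L, 0L) +
     Conj(shift_mat(Ux, -1L, 0L)) * shift_mat(phi, -1L, 0L) +
     Uy * shift_mat(phi, 0L, 1L) +
     Conj(shift_mat(Uy, 0L, -1L)) * shift_mat(phi, 0L, -1L) -
     4 * phi) / dx^2
}

lattice_charge_density <- function(phi_new, phi_old, dt) {
  Im(Conj(phi_new) * phi_old) / dt
}

lattice_link_current <- function(phi, links, c2, dx) {
  Ux <- if (is.null(links)) 1 else links$Ux
  Uy <- if (is.null(links)) 1 else links$Uy
  list(
    J_x = c2 * Im(Conj(phi) * Ux * shift_mat(phi, 1L, 0L)) / dx,
    J_y = c2 * Im(Conj(phi) * Uy * shift_mat(phi, 0L, 1L)) / dx
  )
}

#' Coupled evolution of neural field and connectivity potential
#'
#' Leapfrog integration of the Euler-Lagrange system of the gauged
#' Lagrangian in the temporal gauge `A_t = 0`: the field obeys the
#' gauge-covariant Klein-Gordon equation
#' `d2phi/dt2 = -m2c4 phi + c2 D_i D_i phi` with a compact link-based
#' (Peierls) covariant Laplacian, and the spatial potential obeys sourced
#' wave equations `d2A_i/dt2 = c2 (lap A_i - grad_i div A) + J_i` with the
#' Noether current as source.  The link Laplacian is Hermitian at every
#' step, so the scheme carries an exactly conserved discrete charge and an
#' exact lattice continuity equation (see `track_conservation`); [gauss_solve()]
#' reconstructs the Gauss-law `A_t` diagnostically at snapshots.
#'
#' @param field initial [scalar_field()].
#' @param A initial [gauge_potential()]; any `A_t` component is ignored
#'   (temporal gauge) with a warning.
#' @param params [kg_params()].
#' @param dt,n_steps time step and step count (CFL bound as [evolve_kg()]).
#' @param Adot initial time derivative of `(A_x, A_y)` (list of matrices or
#'   scalars), default 0.
#' @param evolve_A logical: evolve the potential (otherwise frozen).
#' @param source_scale scale of the current source in the `A` equation
#'   (0 disables backreaction).
#' @param probe optional `c(i, j)` probe node.
#' @param save_every keep field/potential snapshots every that many steps.
#' @param track_conservation record the exactly-conserved discrete charge
#'   every step and the RMS lattice continuity residual at snapshot times.
#' @return Object of class `gauge_trajectory` with final `field`, `A`,
#'   `Adot`, per-step `charge` series, `continuity` diagnostics, probe
#'   series and snapshots.
#' @export
evolve_coupled <- function(field, A, params, dt, n_steps, Adot = NULL,
                           evolve_A = TRUE, source_scale = 1,
                           probe = NULL, save_every = NULL,
                           track_conservation = FALSE) {
  stopifnot(inherits(field, "scalar_field"), inherits(A, "gauge_u1"))
  cfl_check(max(params$c2, 1), NULL, field$dx, dt)
  nx <- nrow(field$values); ny <- ncol(field$values)
  dx <- field$dx
  if (is.matrix(A$A_t) && any(A$A_t != 0) ||
      (!is.matrix(A$A_t) && any(A$A_t != 0))) {
    warning("temporal gauge: input A_t ignored during evolution")
  }
  Ax <- expand_comp(A$A_x, nx, ny)
  Ay <- expand_comp(A$A_y, nx, ny)
  if (is.null(Adot)) Adot <- list(A_x = 0, A_y = 0)
  vAx <- expand_comp(Adot$A_x, nx, ny)
  vAy <- expand_comp(Adot$A_y, nx, ny)
  eps <- A$epsilon
  m2 <- params$mass2c4
  c2 <- params$c2
  phi <- field$values
  v <- field$velocity

  cur_A <- function(Ax, Ay) gauge_potential(0, Ax, Ay, epsilon = eps, dx = dx)
  accel_A <- function(Ax, Ay, phi) {
    if (!evolve_A) return(list(x = 0 * Ax, y = 0 * Ay))
    lapx <- flat_lap(Ax, dx)
    lapy <- flat_lap(Ay, dx)
    # backward-difference divergence at nodes, forward-difference gradient
    # back to links: (lap - grad div) then annihilates lattice gradients
    # exactly, which is what makes gauge-shifted runs identical
    divA <- (Ax - shift_mat(Ax, -1L, 0L) + Ay - shift_mat(Ay, 0L, -1L)) / dx
    gdx <- (shift_mat(divA, 1L, 0L) - divA) / dx
    gdy <- (shift_mat(divA, 0L, 1L) - divA) / dx
    src <- if (source_scale != 0) {
      lnk <- gauge_links(cur_A(Ax, Ay), nx, ny, dx)
      J <- lattice_link_current(phi, lnk, 1, dx)
      list(x = source_scale * J$J_x, y = source_scale * J$J_y)
    } else list(x = 0, y = 0)
    list(
      x = c2 * (lapx - gdx) + src$x,
      y = c2 * (lapy - gdy) + src$y
    )
  }

  links <- gauge_links(cur_A(Ax, Ay), nx, ny, dx)
  acc_phi <- -m2 * phi + c2 * covariant_laplacian(phi, links, dx)
  acc_A <- accel_A(Ax, Ay, phi)

  probe_series <- if (!is.null(probe)) complex(n_steps + 1L) else NULL
  if (!is.null(probe)) probe_series[1L] <- phi[probe[1L], probe[2L]]
  charge <- if (track_conservation) numeric(n_steps) else NULL
  continuity <- list()
  snapshots <- list()
  phi_prev <- NULL
  norm0 <- max(sqrt(mean(Mod(phi)^2) + mean(Mod(v)^2)), 1e-12)

  for (n in seq_len(n_steps)) {
    phi_old <- phi
    links_in <- links  # operator links of the middle step (exact continuity)
    v_half <- v + 0.5 * dt * acc_phi
    phi <- phi + dt * v_half
    if (evolve_A) {
      vAx_half <- vAx + 0.5 * dt * acc_A$x
      vAy_half <- vAy + 0.5 * dt * acc_A$y
      Ax <- Ax + dt * vAx_half
      Ay <- Ay + dt * vAy_half
    }
    links <- gauge_links(cur_A(Ax, Ay), nx, ny, dx)
    acc_phi <- -m2 * phi + c2 * covariant_laplacian(phi, links, dx)
    v <- v_half + 0.5 * dt * acc_phi
    if (evolve_A) {
      acc_A <- accel_A(Ax, Ay, phi)
      vAx <- vAx_half + 0.5 * dt * acc_A$x
      vAy <- vAy_half + 0.5 * dt * acc_A$y
    }
    if (!is.null(probe)) probe_series[n + 1L] <- phi[probe[1L], probe[2L]]
    if (track_conservation) {
      charge[n] <- sum(lattice_charge_density(phi, phi_old, dt)) * dx^2
      if (!is.null(phi_prev) && (n %% max(1L, n_steps %/% 20L) == 0L)) {
        # lattice continuity at the middle step: phi_{n-1}, phi_n, phi_{n+1}
        rho_new <- lattice_charge_density(phi, phi_old, dt)
        rho_old <- lattice_charge_density(phi_old, phi_prev, dt)
        J <- lattice_link_current(phi_old, links_in, c2, dx)
        divJ <- (J$J_x - shift_mat(J$J_x, -1L, 0L) +
                   J$J_y - shift_mat(J$J_y, 0L, -1L)) / dx
        res <- (rho_new - rho_old) / dt + divJ
        continuity[[length(continuity) + 1L]] <- list(
          step = n, rms_residual = sqrt(mean(res^2)),
          rms_J = sqrt(mean(J$J_x^2 + J$J_y^2 + rho_old^2))
        )
      }
      phi_prev <- phi_old
    }
    if (!is.null(save_every) && n %% save_every == 0L) {
      A_t_diag <- tryCatch(
        gauss_solve(Mod(phi)^2, dx = dx),
        error = function(e) NULL
      )
      snapshots[[length(snapshots) + 1L]] <- list(
        step = n,
        field = scalar_field(phi, dx, velocity = v, time = field$time + n * dt),
        A = gauge_potential(
          if (is.null(A_t_diag)) 0 else A_t_diag, Ax, Ay,
          epsilon = eps, dx = dx
        ),
        Adot = list(A_x = vAx, A_y = vAy)
      )
    }
    if (n %% 200L == 0L || n == n_steps) {
      nrm <- sqrt(mean(Mod(phi)^2) + mean(Mod(v)^2))
      if (!is.finite(nrm) || nrm > 1e6 * norm0 + 1e6) {
        stop(sprintf(
          "instability detected at step %d: field norm %.3g exceeds bound; reduce dt",
          n, nrm
        ))
      }
    }
  }
  structure(
    list(
      times = field$time + dt * (0:n_steps),
      field = scalar_field(phi, dx, velocity = v,
                           time = field$time + n_steps * dt),
      A = gauge_potential(0, Ax, Ay, epsilon = eps, dx = dx),
      Adot = list(A_x = vAx, A_y = vAy),
      probe_series = probe_series,
      charge = charge,
      continuity = continuity,
      snapshots = snapshots,
      dt = dt
    ),
    class = "gauge_trajectory"
  )
}

flat_lap <- function(m, dx) {
  (shift_mat(m, 1L, 0L) + shift_mat(m, -1L, 0L) +
     shift_mat(m, 0L, 1L) + shift_mat(m, 0L, -1L) - 4 * m) / dx^2
}

#' Gauss-law solution for the temporal connectivity component
#'
#' Solves the two-dimensional Poisson equation `lap A_t = -source` (the
#' Gauss-law constraint sourced by the activity density `|phi|^2`) with a
#' free-space-like setup: the grid is embedded centrally in a padded domain
#' with zero boundary values and the 5-point system is solved exactly by a
#' sparse direct factorization, so the discrete Laplacian identity holds to
#' solver precision on the returned region.  For a point source `q` the
#' profile behaves as `-(q / 2 pi) log(r)` up to an additive constant;
#' `normalization = "bare"` rescales by `2 pi` to reproduce the plain
#' `-log(r) q` convention.
#'
#' @param source nonnegative real matrix (activity density `|phi|^2`).
#' @param dx grid spacing.
#' @param pad_factor padded domain is `pad_factor` times the grid (>= 1).
#' @param normalization `"consistent"` (default; `lap A_t = -source` exact)
#'   or `"bare"` (`2 pi` times larger, the plain `-log(r)` convention).
#' @return Real matrix `A_t` of the same shape as `source`.
#' @export
gauss_solve <- function(source, dx, pad_factor = 2,
                        normalization = c("consistent", "bare")) {
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(source), all(is.finite(source)))
  if (any(source < 0)) stop("'source' must be nonnegative")
  nx <- nrow(source); ny <- ncol(source)
  if (all(source == 0)) return(matrix(0, nx, ny))
  npx <- max(nx + 2L, as.integer(ceiling(pad_factor * nx)))
  npy <- max(ny + 2L, as.integer(ceiling(pad_factor * ny)))
  src_pad <- matrix(0, npx, npy)
  i0 <- (npx - nx) %/% 2L
  j0 <- (npy - ny) %/% 2L
  src_pad[i0 + seq_len(nx), j0 + seq_len(ny)] <- source
  Tx <- Matrix::bandSparse(npx, k = c(-1, 0, 1),
                           diagonals = list(rep(1, npx - 1),
                                            rep(-2, npx),
                                            rep(1, npx - 1)))
  Ty <- Matrix::bandSparse(npy, k = c(-1, 0, 1),
                           diagonals = list(rep(1, npy - 1),
                                            rep(-2, npy),
                                            rep(1, npy - 1)))
  L <- (Matrix::kronecker(Matrix::Diagonal(npy), Tx) +
          Matrix::kronecker(Ty, Matrix::Diagonal(npx))) / dx^2
  sol <- Matrix::solve(L, -as.vector(src_pad))
  At <- matrix(as.numeric(sol), npx, npy)[i0 + seq_len(nx), j0 + seq_len(ny)]
  if (normalization == "bare") At <- 2 * pi * At
  At
}

#' Non-linear Hebbian learning rate of the intrinsic connection
#'
#' The temporal component of the conserved current sources the change of
#' the connection modulation `f`: Gauss's law gives
#' `d f / d t = A_t` with `lap A_t = -(|phi|^2 + a2 |phi|^4 + a3 |phi|^6 + ...)`.
#' With no higher coefficients this is the linear Hebbian case (rate set by
#' the product of co-active pre/post amplitudes); higher powers of the
#' activity density make the rule non-linear.
#'
#' @param phi_mod2 nonnegative real matrix of `|phi|^2`.
#' @param coeffs numeric vector `c(a2, a3, ...)` of higher-order
#'   coefficients (may be empty).
#' @param dx grid spacing.
#' @param ... passed to [gauss_solve()] (e.g. `normalization = "bare"`).
#' @return Real matrix: the learning rate field `d f / d t`.
#' @export
hebbian_rate <- function(phi_mod2, coeffs = numeric(0), dx, ...) {
  stopifnot(is.matrix(phi_mod2), all(phi_mod2 >= 0))
  src <- phi_mod2
  if (length(coeffs)) {
    for (k in seq_along(coeffs)) {
      src <- src + coeffs[k] * phi_mod2^(k + 1L)
    }
  }
  if (all(src == 0)) return(matrix(0, nrow(phi_mod2), ncol(phi_mod2)))
  gauss_solve(src, dx = dx, ...)
}
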