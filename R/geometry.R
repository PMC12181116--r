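#' Diagonal 2+1 pseudo-metric on the cortical sheet
#'
#' The sheet metric is diagonal with temporal component fixed at +1 and
#' negative spatial components (a pseudo-metric: the spatial entries carry
#' the connectivity-derived propagation factor).  Three tagged forms are
#' supported:
#'
#' * `metric_flat(scale)`: `g_xx = g_yy = -scale` (flat-scaled),
#' * `metric_rw(a, k_curv)`: Robertson-Walker with expansion factor `a(t)`;
#'   on the rectangular grid only the spatially flat `k_curv = 0` form is
#'   evaluable (`g_xx = g_yy = -a^2`),
#' * `metric_diag(g_xx, g_yy)`: general diagonal, constants or per-node
#'   matrices.
#'
#' @param scale positive scale of the flat spatial part.
#' @param a expansion factor, `a > 0`.
#' @param k_curv spatial curvature constant of the Robertson-Walker form.
#' @param g_xx,g_yy spatial diagonal entries (negative), scalars or matrices.
#' @return Object of class `metric2p1` with elements `g_tt = 1`, `g_xx`,
#'   `g_yy` and a `form` tag.
#' @examples
#' metric_flat()        # Minkowski-like sheet metric
#' metric_rw(a = 1.5)   # expanded sheet: waves propagate at c / 1.5
#' @export
metric_flat <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(
    list(g_tt = 1, g_xx = -scale, g_yy = -scale, form = "flat-scaled"),
    class = "metric2p1"
  )
}

#' @rdname metric_flat
#' @export
metric_rw <- function(a, k_curv = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  structure(
    list(g_tt = 1, g_xx = -a^2, g_yy = -a^2, form = "robertson-walker",
         a = a, k_curv = k_curv),
    class = "metric2p1"
  )
}

#' @rdname metric_flat
#' @export
metric_diag <- function(g_xx, g_yy) {
  check_neg <- function(g, nm) {
    if (!all(g < 0)) stop(sprintf("'%s' must be negative everywhere", nm))
  }
  check_neg(g_xx, "g_xx")
  check_neg(g_yy, "g_yy")
  structure(
    list(g_tt = 1, g_xx = g_xx, g_yy = g_yy, form = "general-diagonal"),
    class = "metric2p1"
  )
}

#' @exportS3Method base::print
print.metric2p1 <- function(x, ...) {
  gx <- if (is.matrix(x$g_xx)) "<per-node>" else format(x$g_xx)
  gy <- if (is.matrix(x$g_yy)) "<per-node>" else format(x$g_yy)
  cat(sprintf("<metric2p1> form = %s, g = diag(1, %s, %s)\n", x$form, gx, gy))
  invisible(x)
}

metric_on_grid <- function(metric, nx, ny) {
  expand <- function(g) {
    if (is.matrix(g)) {
      if (!identical(dim(g), c(nx, ny))) {
        stop("metric component shape does not match the field grid")
      }
      g
    } else {
      matrix(g, nx, ny)
    }
  }
  if (identical(metric$form, "robertson-walker") &&
      !isTRUE(all.equal(metric$k_curv, 0))) {
    stop("grid evaluation of the Robertson-Walker metric requires k_curv = 0")
  }
  gxx <- expand(metric$g_xx)
  gyy <- expand(metric$g_yy)
  detg <- abs(1 * gxx * gyy)
  if (any(detg < 1e-14)) {
    idx <- which(detg < 1e-14, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "singular metric: |g| ~ 0 at grid node (%d, %d)", idx[1L], idx[2L]
    ))
  }
  list(gxx = gxx, gyy = gyy, sqrtg = sqrt(detg))
}

shift_mat <- function(m, di, dj, boundary = "periodic") {
  nx <- nrow(m); ny <- ncol(m)
  if (boundary == "periodic") {
    i <- ((seq_len(nx) - 1L + di) %% nx) + 1L
    j <- ((seq_len(ny) - 1L + dj) %% ny) + 1L
    m[i, j, drop = FALSE]
  } else {
    out <- matrix(m[1L] * 0, nx, ny)  # typed zero padding
    isrc <- seq_len(nx) + di
    jsrc <- seq_len(ny) + dj
    iok <- isrc >= 1L & isrc <= nx
    jok <- jsrc >= 1L & jsrc <= ny
    out[iok, jok] <- m[isrc[iok], jsrc[jok], drop = FALSE]
    out
  }
}

#' Discrete spatial Laplace-Beltrami operator
#'
#' Applies the spatial part of the covariant wave operator,
#' \deqn{\Delta_g \phi = \frac{1}{\sqrt{|g|}}\,\partial_i\!\left(\sqrt{|g|}\,
#'   (-g^{ii})\,\partial_i \phi\right),}
#' in conservative (flux) form with half-node averaging of the metric
#' weights; second-order accurate in `dx`.  The sign convention is chosen so
#' that for the flat metric (`g_xx = g_yy = -1`) the operator reduces to the
#' ordinary 5-point Laplacian and the wave equation reads
#' `d2phi/dt2 = -m2c4 phi + c2 * laplace_beltrami(metric, phi)`.
#'
#' @param metric a [metric_flat()]-family metric.
#' @param field a [scalar_field()] (or a complex matrix plus `dx`).
#' @param dx grid spacing when `field` is a bare matrix.
#' @param boundary `"periodic"` (default) or `"dirichlet"` (zero outside).
#' @return Complex matrix of the same shape as the field values.
#' @examples
#' f <- scalar_field(matrix(rnorm(64 * 64), 64) + 0i, dx = 0.1)
#' lap <- laplace_beltrami(metric_flat(), f)
#' @export
laplace_beltrami <- function(metric, field, dx = NULL,
                             boundary = c("periodic", "dirichlet")) {
  boundary <- match.arg(boundary)
  if (inherits(field, "scalar_field")) {
    phi <- field$values
    dx <- field$dx
  } else {
    phi <- field
    if (is.null(dx)) stop("'dx' required when 'field' is a bare matrix")
  }
  nx <- nrow(phi); ny <- ncol(phi)
  if (identical(metric$form, "robertson-walker") &&
      !isTRUE(all.equal(metric$k_curv, 0))) {
    stop("grid evaluation of the Robertson-Walker metric requires k_curv = 0")
  }
  # constant isotropic metrics: the operator is the plain 5-point stencil
  # scaled by -1/g_xx, computed in stencil order (bit-identical to a direct
  # implementation, which the gauge sector relies on in its free limit)
  if (!is.matrix(metric$g_xx) && !is.matrix(metric$g_yy) &&
      identical(metric$g_xx, metric$g_yy)) {
    pxp <- shift_mat(phi, 1L, 0L, boundary)
    pxm <- shift_mat(phi, -1L, 0L, boundary)
    pyp <- shift_mat(phi, 0L, 1L, boundary)
    pym <- shift_mat(phi, 0L, -1L, boundary)
    return((pxp + pxm + pyp + pym - 4 * phi) / ((-metric$g_xx) * dx^2))
  }
  g <- metric_on_grid(metric, nx, ny)
  # positive weights sqrt|g| * (-g^ii) = sqrt|g| / (-g_ii)
  wx <- g$sqrtg / (-g$gxx)
  wy <- g$sqrtg / (-g$gyy)
  flux_div(phi, wx, wy, g$sqrtg, dx, boundary)
}

flux_div <- function(phi, wx, wy, sqrtg, dx, boundary) {
  wxp <- 0.5 * (wx + shift_mat(wx, 1L, 0L, boundary = "periodic"))
  wxm <- 0.5 * (wx + shift_mat(wx, -1L, 0L, boundary = "periodic"))
  wyp <- 0.5 * (wy + shift_mat(wy, 0L, 1L, boundary = "periodic"))
  wym <- 0.5 * (wy + shift_mat(wy, 0L, -1L, boundary = "periodic"))
  pxp <- shift_mat(phi, 1L, 0L, boundary)
  pxm <- shift_mat(phi, -1L, 0L, boundary)
  pyp <- shift_mat(phi, 0L, 1L, boundary)
  pym <- shift_mat(phi, 0L, -1L, boundary)
  (wxp * (pxp - phi) - wxm * (phi - pxm) +
   wyp * (pyp - phi) - wym * (phi - pym)) / (sqrtg * dx^2)
}

metric_as_function <- function(metric) {
  if (is.function(metric)) return(metric)
  if (inherits(metric, "metric2p1")) {
    if (is.matrix(metric$g_xx) || is.matrix(metric$g_yy)) {
      stop("christoffel/ricci need a functional or constant metric, not per-node arrays")
    }
    gxx <- metric$g_xx; gyy <- metric$g_yy
    return(function(p) diag(c(1, gxx, gyy)))
  }
  stop("metric must be a metric2p1 or a function(point) -> matrix")
}

metric_derivs <- function(gfun, point, h) {
  d <- length(point)
  g0 <- gfun(point)
  n <- nrow(g0)
  dg <- array(0, c(n, n, d))
  d2g <- array(0, c(n, n, d, d))
  gp <- vector("list", d)
  gm <- vector("list", d)
  for (s in seq_len(d)) {
    ep <- point; ep[s] <- ep[s] + h
    em <- point; em[s] <- em[s] - h
    gp[[s]] <- gfun(ep)
    gm[[s]] <- gfun(em)
    dg[, , s] <- (gp[[s]] - gm[[s]]) / (2 * h)
    d2g[, , s, s] <- (gp[[s]] - 2 * g0 + gm[[s]]) / h^2
  }
  if (d > 1L) {
    for (s in seq_len(d - 1L)) {
      for (t in (s + 1L):d) {
        epp <- point; epp[s] <- epp[s] + h; epp[t] <- epp[t] + h
        epm <- point; epm[s] <- epm[s] + h; epm[t] <- epm[t] - h
        emp <- point; emp[s] <- emp[s] - h; emp[t] <- emp[t] + h
        emm <- point; emm[s] <- emm[s] - h; emm[t] <- emm[t] - h
        mixed <- (gfun(epp) - gfun(epm) - gfun(emp) + gfun(emm)) / (4 * h^2)
        d2g[, , s, t] <- mixed
        d2g[, , t, s] <- mixed
      }
    }
  }
  list(g = g0, dg = dg, d2g = d2g)
}

christoffel_from_derivs <- function(g0, dg) {
  n <- nrow(g0)
  ginv <- solve(g0)
  gamma <- array(0, c(n, n, n))
  for (r in seq_len(n)) {
    for (m in seq_len(n)) {
      for (nu in seq_len(n)) {
        s <- 0
        for (l in seq_len(n)) {
          s <- s + ginv[r, l] *
            (dg[l, m, nu] + dg[l, nu, m] - dg[m, nu, l])
        }
        gamma[r, m, nu] <- 0.5 * s
      }
    }
  }
  gamma
}

#' Christoffel symbols of a diagonal metric
#'
#' Computes \eqn{\Gamma^\rho_{\mu\nu} = \tfrac12 g^{\rho\lambda}
#' (g_{\lambda\mu,\nu} + g_{\lambda\nu,\mu} - g_{\mu\nu,\lambda})} at a
#' point.  The metric may be a tagged [metric_flat()]-family object
#' (constant entries) or a `function(point) -> matrix` for analytic test
#' metrics of any dimension (e.g. the 2-sphere).  Derivatives are taken by
#' central finite differences of step `h`.
#'
#' @param metric `metric2p1` object or `function(point) -> matrix`.
#' @param point numeric coordinate vector.
#' @param h finite-difference step.
#' @return Array `G[rho, mu, nu]`, symmetric in the two lower indices.
#' @examples
#' sphere <- function(p) diag(c(1.3^2, 1.3^2 * sin(p[1])^2))
#' christoffel(sphere, c(0.7, 0.3))[1, 2, 2]  # -sin(theta) cos(theta)
#' @export
christoffel <- function(metric, point, h = 1e-3) {
  gfun <- metric_as_function(metric)
  md <- metric_derivs(gfun, point, h)
  if (abs(det(md$g)) < 1e-14) {
    stop("non-invertible metric at the requested point")
  }
  christoffel_from_derivs(md$g, md$dg)
}

#' Ricci scalar curvature
#'
#' Contracts the Riemann tensor built from the Christoffel symbols,
#' \eqn{R = g^{\sigma\nu} R^\lambda{}_{\sigma\lambda\nu}}, with the
#' derivative of \eqn{\Gamma} assembled analytically from first and second
#' metric derivatives (single-level finite differences, second-order in
#' `h`).
#'
#' @inheritParams christoffel
#' @return Scalar curvature at `point`.
#' @examples
#' rho <- 2
#' sphere <- function(p) diag(c(rho^2, rho^2 * sin(p[1])^2))
#' ricci_scalar(sphere, c(0.9, 0.4))  # ~ 2 / rho^2
#' @export
ricci_scalar <- function(metric, point, h = 1e-3) {
  gfun <- metric_as_function(metric)
  md <- metric_derivs(gfun, point, h)
  g0 <- md$g
  if (abs(det(g0)) < 1e-14) stop("non-invertible metric at the requested point")
  n <- nrow(g0)
  ginv <- solve(g0)
  dg <- md$dg; d2g <- md$d2g
  # d(ginv)/dx_s = -ginv %*% dg_s %*% ginv
  dginv <- array(0, c(n, n, n))
  for (s in seq_len(n)) {
    dginv[, , s] <- -ginv %*% dg[, , s] %*% ginv
  }
  gamma <- christoffel_from_derivs(g0, dg)
  # dGamma[s, r, m, nu] = d/dx_s Gamma^r_{m nu}
  dgamma <- array(0, c(n, n, n, n))
  for (s in seq_len(n)) {
    for (r in seq_len(n)) {
      for (m in seq_len(n)) {
        for (nu in seq_len(n)) {
          acc <- 0
          for (l in seq_len(n)) {
            br <- dg[l, m, nu] + dg[l, nu, m] - dg[m, nu, l]
            dbr <- d2g[l, m, nu, s] + d2g[l, nu, m, s] - d2g[m, nu, s, l]
            acc <- acc + dginv[r, l, s] * br + ginv[r, l] * dbr
          }
          dgamma[s, r, m, nu] <- 0.5 * acc
        }
      }
    }
  }
  # Ricci_{sig nu} = R^l_{sig l nu}
  ricci <- matrix(0, n, n)
  for (sig in seq_len(n)) {
    for (nu in seq_len(n)) {
      acc <- 0
      for (l in seq_len(n)) {
        acc <- acc + dgamma[l, l, nu, sig] - dgamma[nu, l, l, sig]
        for (m in seq_len(n)) {
          acc <- acc + gamma[l, l, m] * gamma[m, nu, sig] -
            gamma[l, nu, m] * gamma[m, l, sig]
        }
      }
      ricci[sig, nu] <- acc
    }
  }
  sum(ginv * ricci)
}

#' Robertson-Walker expansion state
#'
#' Bundles the expansion factor `a(t)` of the extrinsic-connectivity metric,
#' its time derivatives, the spatial curvature constant `k_curv` and the
#' conserved density parameter `rho0`.
#'
#' @param a expansion factor, `a > 0`.
#' @param adot first time derivative of `a`.
#' @param addot second time derivative of `a`.
#' @param k_curv spatial curvature constant.
#' @param rho0 conserved density parameter (optional).
#' @return Object of class `rw_state`.
#' @export
rw_state <- function(a, adot = 0, addot = 0, k_curv = 0, rho0 = NA_real_) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  structure(
    list(a = a, adot = adot, addot = addot, k_curv = k_curv, rho0 = rho0),
    class = "rw_state"
  )
}

#' Einstein tensor of the 2+1 Robertson-Walker metric
#'
#' Closed-form diagonal Einstein-tensor components of the polar-coordinate
#' Robertson-Walker line element
#' \eqn{ds^2 = dt^2 - a(t)^2\,(dr^2/(1-kr^2) + r^2 d\theta^2)}:
#' \deqn{G_{tt} = k/a^2 + \dot a^2/a^2,\quad
#'       G_{rr} = -a\ddot a/(1-kr^2),\quad
#'       G_{\theta\theta} = -r^2 a\ddot a.}
#'
#' @param state an [rw_state()] carrying `a`, `adot`, `addot`, `k_curv`.
#' @param r radial coordinate; requires `1 - k r^2 > 0`.
#' @return Named list `G_tt`, `G_rr`, `G_thth`.
#' @export
einstein_tensor_rw <- function(state, r) {
  stopifnot(inherits(state, "rw_state"))
  a <- state$a; adot <- state$adot; addot <- state$addot; k <- state$k_curv
  denom <- 1 - k * r^2
  if (any(denom <= 0)) {
    stop("coordinate singularity: 1 - k r^2 <= 0 at the requested radius")
  }
  list(
    G_tt = k / a^2 + adot^2 / a^2,
    G_rr = -a * addot / denom,
    G_thth = -r^2 * a * addot
  )
}
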