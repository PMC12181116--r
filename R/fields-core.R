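#' Complex neural field on a rectangular grid
#'
#' A `scalar_field` holds the complex field amplitude `phi` and its time
#' derivative on a uniform `nx` by `ny` grid with spacing `dx` (model length
#' units).  The field represents one excitatory-inhibitory bi-layer: balanced
#' excitation and inhibition lets cortical activity be written as a single
#' complex amplitude per surface position.
#'
#' @param values complex (or numeric) matrix of field amplitudes.
#' @param dx grid spacing, a single positive number.
#' @param velocity complex matrix of time derivatives, same shape as
#'   `values`; defaults to zero.
#' @param time current simulation time.
#' @return An object of class `scalar_field` with elements `values`,
#'   `velocity`, `dx`, `time`.
#' @examples
#' f <- scalar_field(matrix(0i, 16, 16), dx = 0.1)
#' dim(f$values)
#' @export
scalar_field <- function(values, dx, velocity = NULL, time = 0) {
  values <- as_complex_matrix(values, "values")
  if (is.null(velocity)) {
    velocity <- matrix(0i, nrow(values), ncol(values))
  }
  velocity <- as_complex_matrix(velocity, "velocity")
  if (!identical(dim(values), dim(velocity))) {
    stop("'values' and 'velocity' must have identical dimensions")
  }
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0) {
    stop("'dx' must be a single positive finite number")
  }
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("'values' contains non-finite entries")
  }
  if (!all(is.finite(Re(velocity))) || !all(is.finite(Im(velocity)))) {
    stop("'velocity' contains non-finite entries")
  }
  structure(
    list(values = values, velocity = velocity, dx = dx, time = time),
    class = "scalar_field"
  )
}

as_complex_matrix <- function(x, what) {
  if (!is.matrix(x)) stop(sprintf("'%s' must be a matrix", what))
  storage.mode(x) <- "complex"
  x
}

#' @exportS3Method base::print
print.scalar_field <- function(x, ...) {
  cat(sprintf(
    "<scalar_field> %d x %d grid, dx = %g, t = %g, max|phi| = %.4g\n",
    nrow(x$values), ncol(x$values), x$dx, x$time, max(Mod(x$values))
  ))
  invisible(x)
}

#' Disc moments of the local connectivity kernel
#'
#' Zeroth and second moments of the disc of radius `R` over which local
#' connections act: `a` is the disc area and `b` is half the second radial
#' moment,
#' \deqn{a = \pi R^2, \qquad b = \tfrac{1}{2}\int\!\!\int_A r^2\,dA = \pi R^4/4.}
#' These moments turn the connectivity integral into the mass and speed
#' coefficients of the Klein-Gordon reduction (see [kg_params()]).
#'
#' @param R disc radius (model length units), `R >= 0`.
#' @return Named list with `a` and `b`.
#' @examples
#' disc_moments(1)     # a = pi, b = pi/4
#' disc_moments(2)$b / disc_moments(2)$a  # always R^2 / 4
#' @export
disc_moments <- function(R) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R)) {
    stop("'R' must be a single finite number")
  }
  if (R < 0) stop("'R' must be nonnegative")
  list(a = pi * R^2, b = pi * R^4 / 4)
}

#' Local connectivity kernel
#'
#' Bundles the scalar connection gain `U`, the disc radius `R`, the derived
#' disc moments `a`, `b` and the (optional) Laplacian of the gain `lapU`
#' used when `U` varies slowly across the sheet.
#'
#' @param U connection gain (dimensionless).
#' @param R disc radius.
#' @param lapU Laplacian of `U` across the sheet; defaults to 0
#'   (spatially constant gain).
#' @return Object of class `connectivity_kernel` with elements
#'   `U`, `R`, `a`, `b`, `lapU`.
#' @examples
#' connectivity_kernel(U = 0.1, R = 1)
#' @export
connectivity_kernel <- function(U, R, lapU = 0) {
  stopifnot(is.numeric(U), length(U) == 1L, is.finite(U))
  m <- disc_moments(R)
  stopifnot(is.numeric(lapU), length(lapU) == 1L, is.finite(lapU))
  structure(
    list(U = U, R = R, a = m$a, b = m$b, lapU = lapU),
    class = "connectivity_kernel"
  )
}

#' @exportS3Method base::print
print.connectivity_kernel <- function(x, ...) {
  cat(sprintf(
    "<connectivity_kernel> U = %g, R = %g (a = %.6g, b = %.6g, lapU = %g)\n",
    x$U, x$R, x$a, x$b, x$lapU
  ))
  invisible(x)
}

#' Laminar LFP record
#'
#' Holds simulated laminar local field potential traces: one complex (or
#' real) amplitude trace per cortical layer, a common time axis and the
#' metadata that generated them.
#'
#' @param times numeric vector of sample times, strictly increasing.
#' @param traces complex matrix, `n_layers` rows by `length(times)` columns.
#' @param meta named list of generating parameters (model, m, C, rotation
#'   coefficients, stimulated layer, noise sd, seed, ...).
#' @return Object of class `lfp_record`.
#' @export
lfp_record <- function(times, traces, meta = list()) {
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1L)
  storage.mode(traces) <- "complex"
  times <- as.numeric(times)
  if (ncol(traces) != length(times)) {
    stop("'traces' must have one column per entry of 'times'")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing")
  }
  if (!is.list(meta)) stop("'meta' must be a list")
  structure(
    list(times = times, traces = traces, meta = meta),
    class = "lfp_record"
  )
}

#' @exportS3Method base::print
print.lfp_record <- function(x, ...) {
  cat(sprintf(
    "<lfp_record> %d layers x %d samples, t in [%g, %g]\n",
    nrow(x$traces), length(x$times), min(x$times), max(x$times)
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read laminar LFP traces as CSV
#'
#' The CSV layout is `time,layer_1_re,layer_1_im,...,layer_N_re,layer_N_im`
#' with full-precision scientific formatting so that identical records yield
#' byte-identical files.  Metadata round-trips through a JSON sidecar
#' `<path>.meta.json`.
#'
#' @param record an [lfp_record()].
#' @param path CSV file path.
#' @return `write_lfp` returns `path` invisibly; `read_lfp` returns the
#'   reconstructed [lfp_record()].
#' @export
write_lfp <- function(record, path) {
  stopifnot(inherits(record, "lfp_record"))
  n_layers <- nrow(record$traces)
  cols <- c("time", as.vector(rbind(
    sprintf("layer_%d_re", seq_len(n_layers)),
    sprintf("layer_%d_im", seq_len(n_layers))
  )))
  inter <- matrix(0, 2L * n_layers, length(record$times))
  inter[seq(1L, 2L * n_layers, by = 2L), ] <- Re(record$traces)
  inter[seq(2L, 2L * n_layers, by = 2L), ] <- Im(record$traces)
  body <- cbind(record$times, t(inter))
  lines <- c(
    paste(cols, collapse = ","),
    apply(body, 1L, function(row) paste(fmt_num(row), collapse = ","))
  )
  writeLines(lines, path)
  jsonlite::write_json(
    record$meta, paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path)
  if (length(raw) < 1L || !nzchar(raw[[1L]])) {
    stop(sprintf("empty trace file: %s (missing header with 'time' column)", path))
  }
  header <- strsplit(raw[[1L]], ",", fixed = TRUE)[[1L]]
  if (!"time" %in% header) {
    stop(sprintf("malformed trace file %s: missing 'time' column", path))
  }
  re_cols <- grep("^layer_[0-9]+_re$", header)
  im_cols <- grep("^layer_[0-9]+_im$", header)
  if (length(re_cols) == 0L || length(re_cols) != length(im_cols)) {
    stop(sprintf(
      "malformed trace file %s: missing layer_<k>_re/layer_<k>_im columns", path
    ))
  }
  rows <- lapply(seq_along(raw)[-1L], function(i) {
    vals <- strsplit(raw[[i]], ",", fixed = TRUE)[[1L]]
    if (length(vals) != length(header)) {
      stop(sprintf(
        "malformed trace file %s: row %d has %d fields, expected %d",
        path, i - 1L, length(vals), length(header)
      ))
    }
    as.numeric(vals)
  })
  if (length(rows) == 0L) {
    stop(sprintf("empty trace file: %s (no data rows)", path))
  }
  body <- do.call(rbind, rows)
  times <- body[, match("time", header)]
  n_layers <- length(re_cols)
  traces <- matrix(0i, n_layers, length(times))
  for (k in seq_len(n_layers)) {
    traces[k, ] <- body[, match(sprintf("layer_%d_re", k), header)] +
      1i * body[, match(sprintf("layer_%d_im", k), header)]
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  lfp_record(times, traces, meta)
}

#' Write / read a field snapshot as CSV
#'
#' Plain-text container for [scalar_field()] snapshots: four columns
#' `re,im,vel_re,vel_im` in column-major node order, with grid shape, `dx`
#' and `time` in a JSON sidecar `<path>.meta.json`.
#'
#' @param field a [scalar_field()].
#' @param path CSV file path.
#' @return `write_field` returns `path` invisibly; `read_field` the field.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  body <- cbind(
    as.vector(Re(field$values)), as.vector(Im(field$values)),
    as.vector(Re(field$velocity)), as.vector(Im(field$velocity))
  )
  lines <- c(
    "re,im,vel_re,vel_im",
    apply(body, 1L, function(row) paste(fmt_num(row), collapse = ","))
  )
  writeLines(lines, path)
  jsonlite::write_json(
    list(nx = nrow(field$values), ny = ncol(field$values),
         dx = field$dx, time = field$time),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  tab <- utils::read.csv(path)
  need <- c("re", "im", "vel_re", "vel_im")
  if (!all(need %in% names(tab))) {
    stop(sprintf(
      "malformed field file %s: missing columns %s",
      path, paste(setdiff(need, names(tab)), collapse = ", ")
    ))
  }
  vals <- matrix(tab$re + 1i * tab$im, meta$nx, meta$ny)
  vel <- matrix(tab$vel_re + 1i * tab$vel_im, meta$nx, meta$ny)
  scalar_field(vals, dx = meta$dx, velocity = vel, time = meta$time)
}

config_schema <- function() {
  list(
    U       = list(default = 0.1,  type = "numeric", min = 0),
    R       = list(default = 1.0,  type = "numeric", min = 0),
    lapU    = list(default = 0.0,  type = "numeric"),
    epsilon = list(default = 0.01, type = "numeric", min = 0),
    nx      = list(default = 64L,  type = "integer", min = 4),
    ny      = list(default = 64L,  type = "integer", min = 4),
    dx      = list(default = 0.1,  type = "numeric", min = 0, strict = TRUE),
    dt      = list(default = 0.01, type = "numeric", min = 0, strict = TRUE),
    n_steps = list(default = 1000L, type = "integer", min = 1),
    seed    = list(default = 1L,   type = "integer"),
    boundary = list(default = "periodic", type = "character",
                    choices = c("periodic", "dirichlet")),
    a_metric = list(default = 1.0, type = "numeric", min = 0, strict = TRUE),
    k_curv  = list(default = 0.0,  type = "numeric")
  )
}

#' Load and validate a simulation configuration
#'
#' Reads a JSON or YAML configuration (dispatched on file extension),
#' rejects unknown keys, fills defaults for absent ones, checks types and
#' ranges, and echoes the fully resolved configuration to the log via
#' `message()`.
#'
#' Recognised keys: `U`, `R`, `lapU`, `epsilon`, `nx`, `ny`, `dx`, `dt`,
#' `n_steps`, `seed`, `boundary`, `a_metric`, `k_curv`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @param quiet suppress the resolved-config log message.
#' @return Named list of resolved parameters.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop(sprintf("unsupported config extension '.%s' (use .json/.yaml/.yml)", ext))
  )
  if (is.null(raw)) raw <- list()
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  cfg <- list()
  errors <- character(0)
  for (key in names(schema)) {
    spec <- schema[[key]]
    val <- if (key %in% names(raw)) raw[[key]] else spec$default
    if (spec$type %in% c("numeric", "integer")) {
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
        errors <- c(errors, sprintf("'%s' must be a single finite number", key))
        next
      }
      if (spec$type == "integer") {
        if (abs(val - round(val)) > 1e-9) {
          errors <- c(errors, sprintf("'%s' must be an integer", key))
          next
        }
        val <- as.integer(round(val))
      }
      if (!is.null(spec$min)) {
        strict <- isTRUE(spec$strict)
        bad <- if (strict) val <= spec$min else val < spec$min
        if (bad) {
          errors <- c(errors, sprintf(
            "'%s' must be %s %g (got %g)", key,
            if (strict) ">" else ">=", spec$min, val
          ))
          next
        }
      }
    } else if (spec$type == "character") {
      if (!is.character(val) || length(val) != 1L) {
        errors <- c(errors, sprintf("'%s' must be a single string", key))
        next
      }
      if (!is.null(spec$choices) && !val %in% spec$choices) {
        errors <- c(errors, sprintf(
          "'%s' must be one of: %s", key, paste(spec$choices, collapse = ", ")
        ))
        next
      }
    }
    cfg[[key]] <- val
  }
  if (length(errors)) {
    stop(paste(c("invalid config:", errors), collapse = "\n  "))
  }
  if (!quiet) {
    message(
      "resolved config: ",
      paste(sprintf("%s=%s", names(cfg), vapply(cfg, format, "")),
            collapse = ", ")
    )
  }
  cfg
}

#' Parameter inversion result
#'
#' Container for fitted forward-model parameters: point estimates, standard
#' errors from the Gauss-Newton curvature at the optimum, the residual sum
#' of squares and convergence diagnostics.
#'
#' @param estimates named numeric vector of fitted parameters.
#' @param standard_errors named numeric vector, same names as `estimates`.
#' @param residual_norm residual sum of squares at the optimum.
#' @param converged logical success flag.
#' @param n_iter iterations used by the optimizer.
#' @param info free-form diagnostics list.
#' @return Object of class `inversion_result`.
#' @export
inversion_result <- function(estimates, standard_errors, residual_norm,
                             converged, n_iter, info = list()) {
  stopifnot(is.numeric(estimates), !is.null(names(estimates)))
  standard_errors <- standard_errors[names(estimates)]
  if (isTRUE(converged) && any(standard_errors < 0, na.rm = TRUE)) {
    stop("standard errors must be nonnegative when converged")
  }
  structure(
    list(estimates = estimates, standard_errors = standard_errors,
         residual_norm = residual_norm, converged = isTRUE(converged),
         n_iter = n_iter, info = info),
    class = "inversion_result"
  )
}

#' @exportS3Method base::print
print.inversion_result <- function(x, ...) {
  cat(sprintf(
    "<inversion_result> converged = %s, iterations = %d, RSS = %.6g\n",
    x$converged, x$n_iter, x$residual_norm
  ))
  tab <- data.frame(
    estimate = x$estimates,
    std_error = x$standard_errors
  )
  print(tab)
  invisible(x)
}
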