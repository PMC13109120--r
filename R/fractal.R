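#' Fractal dimension from SASA over a probe-radius grid
#'
#' The surface fractal dimension FD is defined through
#' \deqn{2 - FD = d\log(SASA) / d\log(PR),}
#' estimated as the slope of an ordinary least-squares fit of
#' \eqn{\log SASA} on \eqn{\log PR}. A perfectly smooth (planar-like)
#' surface gives slope 0 and FD = 2; rougher surfaces lose area faster
#' as the probe grows, giving slope < 0 and FD > 2 -- globular proteins
#' typically fall in 1.7-2.3. Natural logarithms are used internally;
#' the slope (hence FD) is base-invariant, only the intercept changes.
#'
#' @param radii probe radii in Angstrom, strictly increasing, >= 3 values
#' @param sasa_values matching total SASA values, Angstrom^2, all > 0
#' @return Object of class \code{fd_fit}: \code{radii},
#'   \code{sasa_values}, \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{fd} (= 2 - slope, identically).
#' @export
fit_fd <- function(radii, sasa_values) {
  radii <- as.numeric(radii); sasa_values <- as.numeric(sasa_values)
  if (length(radii) != length(sasa_values))
    stop("radii and sasa_values must have the same length")
  if (length(radii) < 3) stop("need at least 3 probe radii")
  if (any(radii <= 0)) stop("probe radii must be positive")
  if (any(sasa_values <= 0)) stop("SASA values must be positive")
  if (any(diff(radii) <= 0)) stop("probe radii must be strictly increasing")
  fit <- stats::lm(log(sasa_values) ~ log(radii))
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((log(sasa_values) - mean(log(sasa_values)))^2)
  ## constant SASA is a perfect flat fit, not an undefined one
  r2 <- if (sst < 1e-18) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  if (is.finite(r2) && r2 < 0.99)
    warning(sprintf("log-log fit is not near-linear (R^2 = %.4f)", r2))
  structure(list(radii = radii, sasa_values = sasa_values,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, fd = 2 - slope, lm = fit),
            class = "fd_fit")
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("FD = %.4f  (slope %.4f, R^2 %.5f, %d probe radii %.1f-%.1f A)\n",
              x$fd, x$slope, x$r_squared, length(x$radii),
              min(x$radii), max(x$radii)))
  invisible(x)
}

#' @export
coef.fd_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope, fd = object$fd)
}

#' Default probe-radius grid for fractal-dimension estimation
#'
#' 1.0 to 2.0 Angstrom in steps of 0.2 (6 points).
#' @return numeric vector of probe radii.
#' @export
fd_probe_grid <- function() seq(1.0, 2.0, by = 0.2)

#' Fractal dimension of one structure frame
#'
#' Computes [sasa()] at each grid radius, then [fit_fd()]. The caller
#' is expected to pass the component of interest only (e.g. the protein
#' isolated from the membrane).
#'
#' @param frame a \code{structure_frame} with radii assigned
#' @param radii probe-radius grid; default [fd_probe_grid()]
#' @param n_points sphere sample count per atom (see [sasa()])
#' @return An \code{fd_fit}.
#' @export
fd_of_frame <- function(frame, radii = fd_probe_grid(), n_points = 960) {
  vals <- vapply(radii, function(pr) sasa(frame, pr, n_points)$total, 0)
  fit_fd(radii, vals)
}

#' Fractal dimension along a trajectory
#'
#' One FD fit per frame, in time order.
#'
#' @param traj a \code{trajectory} (frames with radii assigned)
#' @param radii probe-radius grid
#' @param n_points sphere sample count per atom
#' @param component restrict each frame to this component class before
#'   the SASA computation (default \code{"protein"}; NULL = whole frame)
#' @return data.frame with \code{time}, \code{fd}, \code{slope},
#'   \code{r_squared}.
#' @export
fd_series <- function(traj, radii = fd_probe_grid(), n_points = 960,
                      component = "protein") {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) == 0L) stop("empty trajectory")
  rows <- lapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]
    if (!is.null(component)) f <- select_atoms(f, component = component)
    fit <- fd_of_frame(f, radii, n_points)
    data.frame(time = traj$times[i], fd = fit$fd, slope = fit$slope,
               r_squared = fit$r_squared)
  })
  do.call(rbind, rows)
}
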