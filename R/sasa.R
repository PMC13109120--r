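# Deterministic quasi-uniform point set on the unit sphere (golden-spiral
# / Fibonacci lattice). No RNG: identical input -> identical SASA.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area by deterministic sphere sampling
#'
#' Shrake-Rupley-style SASA: for every atom, \code{n_points}
#' quasi-uniform points are placed on the sphere of radius
#' \eqn{r_i + PR} (atom vdW radius plus probe radius); a point is
#' accessible iff it lies outside every other atom's equally expanded
#' sphere, and the atom's area is the accessible fraction of
#' \eqn{4\pi (r_i+PR)^2}. The point set is a fixed golden-spiral
#' lattice, so results are exactly reproducible for a given
#' \code{n_points} -- a property the downstream fractal-dimension
#' regression relies on.
#'
#' @param frame a \code{structure_frame} with radii assigned
#'   (see [assign_radii_masses()])
#' @param probe_radius probe sphere radius in Angstrom (water: 1.4)
#' @param n_points points per atom sphere (>= 32; default 960)
#' @return Object of class \code{sasa_result}: fields
#'   \code{probe_radius}, \code{per_atom} (Angstrom^2, file order),
#'   \code{total}, \code{n_points}.
#' @export
sasa <- function(frame, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(frame, "structure_frame"))
  if (nrow(frame) == 0L) stop("cannot compute SASA of an empty frame")
  if (anyNA(frame$radius)) stop("radii not assigned; call assign_radii_masses()")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_points < 32) stop("n_points must be >= 32")

  X <- coords(frame)
  R <- frame$radius + probe_radius    # expanded radii
  n <- nrow(X)
  unit <- fibonacci_sphere(n_points)
  per_atom <- numeric(n)

  # neighbour lists: j can occlude i iff |xi - xj| < Ri + Rj
  cut <- outer(R, R, "+")
  d2 <- as.matrix(stats::dist(X))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < cut[i, ]^2 & seq_len(n) != i)
    if (length(nb)) nb <- nb[order(d2[i, nb])]   # closest occluders first
    pts <- sweep(unit * R[i], 2, X[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      idx <- which(acc)
      if (!length(idx)) break
      dx <- pts[idx, 1] - X[j, 1]
      dy <- pts[idx, 2] - X[j, 2]
      dz <- pts[idx, 3] - X[j, 3]
      acc[idx[dx * dx + dy * dy + dz * dz < R[j]^2]] <- FALSE
    }
    per_atom[i] <- sum(acc) / n_points * 4 * pi * R[i]^2
  }
  structure(list(probe_radius = probe_radius, per_atom = per_atom,
                 total = sum(per_atom), n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.2f A^2 over %d atoms (probe %.2f A, %d points/atom)\n",
              x$total, length(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}

#' Aggregate per-atom SASA into per-residue areas
#'
#' @param frame the frame \code{sasa()} was computed on
#' @param result the matching \code{sasa_result}
#' @return data.frame with \code{chain}, \code{resno}, \code{resname},
#'   \code{area} (Angstrom^2).
#' @export
residue_sasa <- function(frame, result) {
  stopifnot(inherits(result, "sasa_result"),
            nrow(frame) == length(result$per_atom))
  key <- paste(frame$chain, frame$resno, sep = "/")
  first <- !duplicated(key)
  data.frame(chain = frame$chain[first], resno = frame$resno[first],
             resname = frame$resname[first],
             area = as.numeric(tapply(result$per_atom, factor(key, levels = key[first]),
                                      sum)),
             row.names = NULL)
}
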