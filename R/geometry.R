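#' Minimal interatomic distance between two atom sets
#'
#' Exact minimum over all atom pairs of the Euclidean centre-centre
#' distance (the xi observable of protein-membrane approach kinetics,
#' when called with the protein and lipid components).
#'
#' @param set_a,set_b non-empty \code{structure_frame}s
#' @return distance in Angstrom.
#' @export
min_distance <- function(set_a, set_b) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L)
    stop("min_distance needs two non-empty atom sets")
  A <- coords(set_a); B <- coords(set_b)
  ## block over the larger set to keep the cross matrix small
  best <- Inf
  step <- max(1L, floor(2e6 / nrow(B)))
  for (i0 in seq(1L, nrow(A), by = step)) {
    ii <- i0:min(i0 + step - 1L, nrow(A))
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[ii, , drop = FALSE] %*% t(B)
    best <- min(best, min(d2))
  }
  sqrt(max(0, best))
}

#' Mass-weighted centre-of-mass distance between two atom sets
#'
#' @param set_a,set_b \code{structure_frame}s with masses assigned
#' @return distance in Angstrom.
#' @export
com_distance <- function(set_a, set_b) {
  com <- function(f) {
    if (nrow(f) == 0L) stop("empty atom set")
    if (anyNA(f$mass)) stop("masses not assigned; call assign_radii_masses()")
    m <- f$mass
    if (sum(m) <= 0) stop("zero total mass")
    colSums(coords(f) * m) / sum(m)
  }
  sqrt(sum((com(set_a) - com(set_b))^2))
}

#' Distance between two named atoms of two residues
#'
#' Default atom is the alpha-carbon, giving inter-residue CA-CA
#' distances such as d(11-51).
#'
#' @param frame a \code{structure_frame}
#' @param res_a,res_b residue specs: \code{c(chain, resno)} or just a
#'   residue number (chain "A" assumed)
#' @param atom atom name (default \code{"CA"})
#' @return distance in Angstrom.
#' @export
residue_pair_distance <- function(frame, res_a, res_b, atom = "CA") {
  pick <- function(spec) {
    if (length(spec) == 1L) spec <- c("A", spec)
    hit <- frame$chain == spec[1] & frame$resno == as.integer(spec[2]) &
      frame$name == atom
    if (!any(hit))
      stop(sprintf("atom %s of residue %s/%s not found", atom,
                   spec[1], spec[2]))
    coords(frame)[which(hit)[1], ]
  }
  sqrt(sum((pick(res_a) - pick(res_b))^2))
}

#' Protein-membrane buried interface area, per cluster
#'
#' Buried ("contact") area is the SASA of the protein alone minus the
#' protein's SASA computed with the membrane atoms present as
#' occluders, at the same probe radius -- i.e. the protein surface in
#' contact with lipids. Per-atom buried areas are summed into residues
#' and, if a partition is given, into clusters. Contact residues are
#' those with any heavy atom within \code{contact_cutoff} of any
#' membrane atom.
#'
#' Both SASA evaluations use the same deterministic point lattice, so
#' per-atom buried areas are non-negative by construction.
#'
#' @param protein,membrane \code{structure_frame}s with radii assigned
#' @param partition optional \code{pcn_partition} of the protein's
#'   residues (from its CA network); enables per-cluster totals
#' @param probe probe radius, Angstrom (default 1.4)
#' @param n_points SASA sphere sample count
#' @param contact_cutoff heavy-atom contact distance, Angstrom
#' @return Object of class \code{interface_report}: \code{total_buried}
#'   (Angstrom^2), \code{per_cluster_buried}, \code{per_residue}
#'   (data.frame), \code{contact_residues} (data.frame resno /
#'   min_dist).
#' @export
buried_interface <- function(protein, membrane, partition = NULL,
                             probe = 1.4, n_points = 960,
                             contact_cutoff = 4) {
  alone <- sasa(protein, probe, n_points)
  both <- rbind_frames(protein, membrane)
  complexed <- sasa(both, probe, n_points)
  buried_atom <- alone$per_atom - complexed$per_atom[seq_len(nrow(protein))]
  key <- paste(protein$chain, protein$resno, sep = "/")
  first <- !duplicated(key)
  per_res <- data.frame(
    chain = protein$chain[first], resno = protein$resno[first],
    buried = as.numeric(tapply(buried_atom, factor(key, levels = key[first]),
                               sum)), row.names = NULL)
  per_cluster <- NULL
  if (!is.null(partition)) {
    lab <- partition$labels[match(paste0(per_res$chain, per_res$resno),
                                  names(partition$labels))]
    per_res$cluster <- as.integer(lab)
    per_cluster <- tapply(per_res$buried, per_res$cluster, sum)
  }
  ## heavy-atom contact residues
  heavy <- select_atoms(protein, heavy_only = TRUE)
  mind <- rep(Inf, nrow(per_res))
  if (nrow(heavy) && nrow(membrane)) {
    M <- coords(membrane)
    hk <- paste(heavy$chain, heavy$resno, sep = "/")
    d2 <- outer(rowSums(coords(heavy)^2), rowSums(M^2), "+") -
      2 * coords(heavy) %*% t(M)
    dmin_atom <- sqrt(pmax(0, apply(d2, 1, min)))
    agg <- tapply(dmin_atom, factor(hk, levels = key[first]), min)
    mind <- as.numeric(agg)
  }
  contact <- per_res[!is.na(mind) & mind <= contact_cutoff, , drop = FALSE]
  contact$min_dist <- mind[!is.na(mind) & mind <= contact_cutoff]
  structure(list(total_buried = sum(buried_atom),
                 per_cluster_buried = per_cluster,
                 per_residue = per_res,
                 contact_residues = contact,
                 probe = probe, contact_cutoff = contact_cutoff),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: %.1f A^2 buried (probe %.2f A)\n",
              x$total_buried, x$probe))
  if (!is.null(x$per_cluster_buried)) {
    cc <- x$per_cluster_buried
    cat("  per cluster:",
        paste(sprintf("CL%s=%.1f", names(cc), cc), collapse = ", "), "\n")
  }
  cat(sprintf("  %d contact residue(s) within %.1f A\n",
              nrow(x$contact_residues), x$contact_cutoff))
  invisible(x)
}

# Concatenate two frames (atom tables), keeping the first frame's time.
rbind_frames <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  rownames(out) <- NULL
  attr(out, "time_label") <- attr(a, "time_label")
  class(out) <- c("structure_frame", "data.frame")
  out
}

#' Orientation of the heme (porphyrin) plane relative to the membrane
#'
#' Fits the best plane through the selected ring heavy atoms (direction
#' of least variance via singular-value decomposition) and reports the
#' angle between that plane and the membrane plane, folded into
#' [0, 90] degrees: 0 = rings parallel, 90 = orthogonal.
#'
#' @param frame a \code{structure_frame}
#' @param selection logical/integer index of the heme atoms within
#'   \code{frame}; default: heavy atoms of the \code{cofactor}
#'   component
#' @param membrane_normal unit normal of the membrane plane (default
#'   z-axis; pre-rotate frames from arbitrary simulations)
#' @return Object of class \code{heme_orientation}: \code{plane_normal}
#'   (unit 3-vector), \code{angle_to_membrane} (degrees).
#' @export
heme_orientation <- function(frame, selection = NULL,
                             membrane_normal = c(0, 0, 1)) {
  if (is.null(selection)) {
    sel <- frame$component == "cofactor" & frame$element != "H"
  } else sel <- selection
  X <- coords(frame)[sel, , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 heme atoms to fit a plane")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("heme atoms are (near-)collinear; plane undefined")
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  m <- membrane_normal / sqrt(sum(membrane_normal^2))
  cosang <- min(1, abs(sum(normal * m)))
  structure(list(plane_normal = normal,
                 angle_to_membrane = acos(cosang) * 180 / pi),
            class = "heme_orientation")
}

#' @export
print.heme_orientation <- function(x, ...) {
  cat(sprintf("heme plane at %.1f deg to the membrane plane\n",
              x$angle_to_membrane))
  invisible(x)
}

#' Minimal-distance and centre-of-mass kinetics along a trajectory
#'
#' Per frame: minimal interatomic distance xi between two components
#' (default protein vs lipid) and their centre-of-mass separation.
#'
#' @param traj a \code{trajectory} (masses assigned for COM)
#' @param sel_a,sel_b component classes of the two sets
#' @param heavy_only use heavy atoms only for the minimal distance
#' @return data.frame: \code{time}, \code{xi}, \code{com_distance}.
#' @export
kinetics_series <- function(traj, sel_a = "protein", sel_b = "lipid",
                            heavy_only = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  rows <- lapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]
    a <- select_atoms(f, component = sel_a, heavy_only = heavy_only)
    b <- select_atoms(f, component = sel_b, heavy_only = heavy_only)
    data.frame(time = traj$times[i],
               xi = min_distance(a, b),
               com_distance = if (anyNA(a$mass) || anyNA(b$mass))
                 NA_real_ else com_distance(a, b))
  })
  do.call(rbind, rows)
}
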