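#' Validated run configuration for the full per-frame pipeline
#'
#' @param input path to a (multi-model) PDB file, or a
#'   \code{trajectory} object
#' @param outdir output directory (created if missing)
#' @param probe_grid probe radii for the fractal-dimension fit
#' @param sasa_points sphere sample count per atom
#' @param d_min,d_max contact-network distance window, Angstrom
#' @param heavy_only restrict SASA/kinetics to heavy atoms
#' @param probe probe radius for the interface analysis, Angstrom
#' @param contact_cutoff heavy-atom membrane-contact distance, Angstrom
#' @param d_pairs list of residue-number pairs whose CA-CA distance is
#'   tracked per frame (e.g. \code{list(c(11, 51))})
#' @param p_min participation threshold for the "significant P" counts
#' @param p_windows named list of residue windows for participation
#'   counts; defaults to the three omega-loops of cytochrome c
#' @param interface_frames \code{"last"} or \code{"all"}: frames on
#'   which the buried-interface analysis runs (it is the expensive step)
#' @param radii_table,component_map overrides passed to the reader
#' @return Object of class \code{run_config} (a validated list).
#' @export
run_config <- function(input, outdir,
                       probe_grid = fd_probe_grid(), sasa_points = 960,
                       d_min = 4, d_max = 8, heavy_only = FALSE,
                       probe = 1.4, contact_cutoff = 4,
                       d_pairs = list(), p_min = 0.05,
                       p_windows = list(omega_20_30 = c(20, 30),
                                        omega_40_57 = c(40, 57),
                                        omega_71_85 = c(71, 85)),
                       interface_frames = c("last", "all"),
                       radii_table = default_vdw_radii(),
                       component_map = default_component_map()) {
  interface_frames <- match.arg(interface_frames)
  if (!inherits(input, "trajectory") &&
      !(is.character(input) && file.exists(input)))
    stop("input must be an existing PDB path or a trajectory object")
  stopifnot(length(probe_grid) >= 3, all(probe_grid > 0),
            d_min >= 0, d_max > d_min, sasa_points >= 32)
  structure(list(input = input, outdir = outdir, probe_grid = probe_grid,
                 sasa_points = sasa_points, d_min = d_min, d_max = d_max,
                 heavy_only = heavy_only, probe = probe,
                 contact_cutoff = contact_cutoff, d_pairs = d_pairs,
                 p_min = p_min, p_windows = p_windows,
                 interface_frames = interface_frames,
                 radii_table = radii_table, component_map = component_map),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full per-frame analysis pipeline
#'
#' For every frame of the input trajectory: fractal dimension of the
#' protein surface (fd.tsv), contact-network partition / betweenness /
#' participation (partition.tsv, metrics.tsv), protein-membrane
#' minimal-distance kinetics when a lipid component is present
#' (xi.tsv), requested inter-residue distances, buried-interface report
#' (interface.tsv) and a per-frame summary (summary.tsv: mean BC, FD,
#' xi, d-pairs, significant-P counts per window). All outputs are TSV
#' with a header row; a plain-text run log and the configuration are
#' written alongside for provenance. Deterministic: identical config
#' and input give byte-identical tables.
#'
#' @param config a [run_config()]
#' @return (invisibly) a list with the tables and output paths.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "run.log")
  logcon <- file(logfile, "w")
  on.exit(close(logcon))
  say <- function(...) writeLines(sprintf(...), logcon)
  say("pcnsurf run_full")

  traj <- if (inherits(config$input, "trajectory")) config$input else
    read_pdb(config$input, "all", component_map = config$component_map)
  traj$frames <- lapply(traj$frames, function(f) {
    if (anyNA(f$radius) || anyNA(f$mass))
      assign_radii_masses(f, radii = config$radii_table) else f
  })
  say("frames: %d", length(traj$frames))

  has_lipid <- any(traj$frames[[1]]$component == "lipid")

  ## stage: fractal dimension of the isolated protein
  fd_tab <- fd_series(traj, radii = config$probe_grid,
                      n_points = config$sasa_points, component = "protein")
  write_tsv(fd_tab, file.path(config$outdir, "fd.tsv"))
  say("fd.tsv: %d rows", nrow(fd_tab))

  ## stage: contact-network series
  pcn <- pcn_series(traj, config$d_min, config$d_max)
  write_tsv(pcn$metrics, file.path(config$outdir, "metrics.tsv"))
  part_tab <- pcn$metrics[, c("time", "chain", "resno", "cluster")]
  write_tsv(part_tab, file.path(config$outdir, "partition.tsv"))
  say("metrics.tsv: %d rows (%d frame(s) skipped)", nrow(pcn$metrics),
      length(pcn$skipped))

  ## stage: kinetics
  xi_tab <- NULL
  if (has_lipid) {
    xi_tab <- kinetics_series(traj, heavy_only = config$heavy_only)
    write_tsv(xi_tab, file.path(config$outdir, "xi.tsv"))
    say("xi.tsv: %d rows", nrow(xi_tab))
  } else say("no lipid component; kinetics skipped")

  ## stage: inter-residue distances
  dpair_tab <- NULL
  if (length(config$d_pairs)) {
    rows <- lapply(seq_along(traj$frames), function(i) {
      f <- traj$frames[[i]]
      vals <- vapply(config$d_pairs, function(pr)
        residue_pair_distance(f, pr[1], pr[2]), 0)
      stats::setNames(data.frame(traj$times[i], t(vals)),
                      c("time", vapply(config$d_pairs, function(pr)
                        sprintf("d_%s_%s", pr[1], pr[2]), "")))
    })
    dpair_tab <- do.call(rbind, rows)
    write_tsv(dpair_tab, file.path(config$outdir, "dpairs.tsv"))
  }

  ## stage: buried interface (last frame by default)
  iface_tab <- NULL
  if (has_lipid) {
    idx <- if (config$interface_frames == "all") seq_along(traj$frames)
           else length(traj$frames)
    rows <- lapply(idx, function(i) {
      f <- traj$frames[[i]]
      prot <- select_atoms(f, component = "protein")
      memb <- select_atoms(f, component = "lipid")
      part <- pcn$partitions[[match(traj$times[i], pcn$summary$time)]]
      ir <- buried_interface(prot, memb, partition = part,
                             probe = config$probe,
                             n_points = config$sasa_points,
                             contact_cutoff = config$contact_cutoff)
      pc <- ir$per_cluster_buried
      data.frame(time = traj$times[i], total_buried = ir$total_buried,
                 cl1_buried = if (!is.null(pc)) pc[["1"]] else NA_real_,
                 cl2_buried = if (!is.null(pc) && "2" %in% names(pc))
                   pc[["2"]] else 0,
                 n_contact_residues = nrow(ir$contact_residues))
    })
    iface_tab <- do.call(rbind, rows)
    write_tsv(iface_tab, file.path(config$outdir, "interface.tsv"))
    say("interface.tsv: %d rows", nrow(iface_tab))
  }

  summary_tab <- report_summary(pcn$metrics, fd_tab = fd_tab,
                                xi_tab = xi_tab, dpair_tab = dpair_tab,
                                p_min = config$p_min,
                                windows = config$p_windows)
  write_tsv(summary_tab, file.path(config$outdir, "summary.tsv"))
  say("summary.tsv: %d rows", nrow(summary_tab))

  ## provenance: the effective configuration
  cfg <- config; cfg$input <- if (is.character(config$input))
    config$input else "<trajectory object>"
  writeLines(utils::capture.output(utils::str(unclass(cfg))),
             file.path(config$outdir, "config.txt"))

  invisible(list(fd = fd_tab, metrics = pcn$metrics, partition = part_tab,
                 xi = xi_tab, dpairs = dpair_tab, interface = iface_tab,
                 summary = summary_tab, skipped = pcn$skipped,
                 outdir = config$outdir))
}

#' Per-frame summary: mean betweenness, FD, xi and significant-P counts
#'
#' Aggregates the per-residue metrics table into one row per frame:
#' mean betweenness over all residues, the frame's FD and minimal
#' distance (when supplied), tracked inter-residue distances, and the
#' count of residues with participation above \code{p_min} inside each
#' residue window (defaults: the three omega-loops).
#'
#' @param metrics long per-residue table (columns time, resno, bc, p)
#' @param fd_tab,xi_tab,dpair_tab optional per-frame tables merged in
#' @param p_min participation threshold
#' @param windows named list of \code{c(from, to)} residue windows
#' @return data.frame, one row per frame.
#' @export
report_summary <- function(metrics, fd_tab = NULL, xi_tab = NULL,
                           dpair_tab = NULL, p_min = 0.05,
                           windows = list(omega_20_30 = c(20, 30),
                                          omega_40_57 = c(40, 57),
                                          omega_71_85 = c(71, 85))) {
  need <- c("time", "resno", "bc", "p")
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop("metrics table is missing column(s): ", paste(miss, collapse = ", "))
  times <- unique(metrics$time)
  rows <- lapply(times, function(t) {
    m <- metrics[metrics$time == t, ]
    out <- data.frame(time = t, mean_bc = mean(m$bc))
    for (w in names(windows)) {
      inw <- m$resno >= windows[[w]][1] & m$resno <= windows[[w]][2]
      out[[paste0("n_p_", w)]] <- sum(m$p[inw] > p_min)
    }
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(fd_tab)) out <- merge(out, fd_tab[, c("time", "fd")],
                                     by = "time", all.x = TRUE, sort = TRUE)
  if (!is.null(xi_tab)) out <- merge(out, xi_tab[, c("time", "xi")],
                                     by = "time", all.x = TRUE, sort = TRUE)
  if (!is.null(dpair_tab)) out <- merge(out, dpair_tab, by = "time",
                                        all.x = TRUE, sort = TRUE)
  out[order(out$time), , drop = FALSE]
}
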