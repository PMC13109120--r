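# Standard amino-acid residue names used for component classification.
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "HSD", "HSE", "HSP")

#' Default van der Waals radii (Angstrom), keyed by element symbol
#'
#' Element-based radii used for solvent-accessible surface area unless the
#' caller supplies an alternative table. Values are the common vdW set
#' (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20, Fe 1.80).
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    FE = 1.80, NA. = 2.27, CL = 1.75, K = 2.75, MG = 1.73, CA = 2.31,
    ZN = 1.39, SE = 1.90)
}

#' Default atomic masses (Dalton), keyed by element symbol
#'
#' @return Named numeric vector of masses in Dalton.
#' @export
default_atomic_masses <- function() {
  c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    H = 1.008, FE = 55.845, NA. = 22.990, CL = 35.45, K = 39.098,
    MG = 24.305, CA = 40.078, ZN = 65.38, SE = 78.971)
}

#' Default residue-name to component-class map
#'
#' Maps PDB residue names onto the component classes used throughout the
#' package: \code{protein}, \code{lipid}, \code{water}, \code{ion},
#' \code{cofactor} or \code{other}. Lipid names cover the common
#' CHARMM-GUI dialect (POPC; cardiolipin as POCL/TOCL/CDL) plus the
#' \code{LIP} name used by the synthetic membrane-slab generator.
#'
#' @return Named character vector mapping residue name to class.
#' @export
default_component_map <- function() {
  m <- c(
    stats::setNames(rep("protein", length(.AA3)), .AA3),
    POPC = "lipid", POCL = "lipid", TOCL = "lipid", POCL2 = "lipid",
    TOCL2 = "lipid", CDL = "lipid", CDL1 = "lipid", CDL2 = "lipid",
    LIP = "lipid", POPE = "lipid", POPS = "lipid",
    HOH = "water", TIP3 = "water", TIP = "water", SOL = "water",
    WAT = "water",
    "NA" = "ion", CL = "ion", SOD = "ion", CLA = "ion", POT = "ion",
    K = "ion", MG = "ion", ZN = "ion", CAL = "ion",
    HEM = "cofactor", HEC = "cofactor", HEB = "cofactor", HEME = "cofactor")
  m
}

.frame_cols <- c("serial", "name", "resname", "chain", "resno",
                 "x", "y", "z", "element", "is_hetero", "component",
                 "radius", "mass")

#' Construct a structure frame from an atom table
#'
#' A structure frame is the package's unit of input: the atoms of one
#' 3-D structure (one PDB model / one trajectory time point) as an
#' ordered table with one row per atom. Coordinates are in Angstrom.
#'
#' @param atoms data.frame with at least columns \code{serial},
#'   \code{name}, \code{resname}, \code{chain}, \code{resno}, \code{x},
#'   \code{y}, \code{z}. Optional: \code{element}, \code{is_hetero},
#'   \code{radius}, \code{mass}.
#' @param time_label frame identifier (e.g. time in ns); stored as an
#'   attribute.
#' @param component_map named character vector mapping residue names to
#'   component classes; see [default_component_map()].
#' @return Object of class \code{structure_frame} (a data.frame).
#' @export
structure_frame <- function(atoms, time_label = 0,
                            component_map = default_component_map()) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "resname", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1L) stop("a structure frame needs at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  atoms$element <- toupper(atoms$element)
  if (any(!nzchar(atoms$element)))
    stop("empty element symbol for atom(s): ",
         paste(utils::head(atoms$serial[!nzchar(atoms$element)], 5),
               collapse = ", "))
  if (is.null(atoms$is_hetero)) atoms$is_hetero <- FALSE
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (is.null(atoms$mass)) atoms$mass <- NA_real_
  cls <- unname(component_map[toupper(atoms$resname)])
  cls[is.na(cls)] <- "other"
  atoms$component <- cls
  out <- atoms[, .frame_cols]
  rownames(out) <- NULL
  attr(out, "time_label") <- time_label
  class(out) <- c("structure_frame", "data.frame")
  out
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("structure_frame: %d atoms, %d residues, t = %s\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              format(attr(x, "time_label"))))
  tab <- table(x$component)
  cat("  components:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Frame time label
#' @param frame a \code{structure_frame}
#' @return the frame's time label
#' @export
time_label <- function(frame) attr(frame, "time_label")

# Derive an element symbol from a PDB atom name, following the usual
# column-13/14 convention (e.g. " CA " -> C, "FE" -> FE, "1HB" -> H).
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9']+", "", nm)
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  known2 <- c("FE", "CL", "NA", "MG", "ZN", "SE", "BR", "MN", "CU")
  ifelse(two %in% known2, two, one)
}

#' Build a trajectory from structure frames
#'
#' @param frames list of \code{structure_frame}s
#' @param times optional numeric labels; default taken from the frames
#' @return Object of class \code{trajectory}.
#' @export
trajectory <- function(frames, times = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  ok <- vapply(frames, inherits, logical(1), "structure_frame")
  if (!all(ok)) stop("all elements must be structure_frames")
  if (is.null(times))
    times <- vapply(frames, function(f) as.numeric(time_label(f)), 0)
  if (length(times) != length(frames))
    stop("times must match the number of frames")
  if (any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  frames <- Map(function(f, t) { attr(f, "time_label") <- t; f },
                frames, times)
  structure(list(frames = frames, times = times), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, t = %s .. %s\n",
              length(x$frames), format(x$times[1]),
              format(x$times[length(x$times)])))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Read a (multi-model) PDB file into a trajectory
#'
#' Parses ATOM/HETATM/MODEL records via \code{bio3d::read.pdb}. Each
#' MODEL becomes one \code{structure_frame}; a file without MODEL
#' records yields a single frame. HETATM records are retained and
#' flagged. Insertion codes are rejected: residue identity in this
#' package is (chain, residue number) only.
#'
#' @param path PDB file path.
#' @param model integer model number, or \code{"all"} (default) for
#'   every model.
#' @param component_map residue-name to class map.
#' @return A \code{trajectory} (even for a single model; index with
#'   \code{$frames[[1]]}).
#' @export
read_pdb <- function(path, model = "all",
                     component_map = default_component_map()) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  if (any(nzchar(trimws(at$insert)) & !is.na(at$insert)))
    stop("insertion codes present in ", path,
         "; renumber residues before analysis")
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  want <- if (identical(model, "all")) seq_len(n_models) else as.integer(model)
  if (any(want < 1L | want > n_models))
    stop("requested model ", paste(setdiff(want, seq_len(n_models)),
                                   collapse = ", "),
         " absent: file has ", n_models, " model(s)")
  element <- at$elesy
  if (is.null(element) || all(!nzchar(trimws(element))))
    element <- guess_element(at$elety)
  element <- toupper(trimws(element))
  blank <- !nzchar(element) | is.na(element)
  element[blank] <- guess_element(at$elety[blank])
  frames <- lapply(want, function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    structure_frame(data.frame(
      serial = at$eleno, name = trimws(at$elety),
      resname = trimws(at$resid), chain = ifelse(is.na(at$chain), "A", at$chain),
      resno = at$resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = element, is_hetero = at$type == "HETATM",
      stringsAsFactors = FALSE),
      time_label = m, component_map = component_map)
  })
  trajectory(frames, times = as.numeric(want))
}

#' Write frames to a (multi-model) PDB file
#'
#' Fixed-width PDB formatter (coordinates printed at the format's
#' 3-decimal precision). Multiple frames are written as MODEL/ENDMDL
#' blocks, the trajectory interchange format used by this package.
#'
#' @param x a \code{structure_frame} or \code{trajectory}
#' @param path output file path
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(x, path) {
  frames <- if (inherits(x, "trajectory")) x$frames else list(x)
  multi <- length(frames) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (multi) writeLines(sprintf("MODEL %8d", i), con)
    rec <- ifelse(f$is_hetero, "HETATM", "ATOM  ")
    # atom-name column convention: 1-3 character names start in col 14
    nm <- ifelse(nchar(f$name) >= 4, substr(f$name, 1, 4),
                 sprintf(" %-3s", f$name))
    lines <- sprintf("%s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, f$serial %% 100000L, nm, substr(f$resname, 1, 4),
                     substr(f$chain, 1, 1), f$resno %% 10000L,
                     f$x, f$y, f$z, 1, 0, substr(f$element, 1, 2))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Assign van der Waals radii and atomic masses to a frame
#'
#' Idempotent: reassigning with the same tables leaves the frame
#' unchanged. Elements absent from a table raise an error naming them
#' unless a \code{fallback} radius/mass pair is given.
#'
#' @param frame a \code{structure_frame}
#' @param radii named vector, element to radius (Angstrom)
#' @param masses named vector, element to mass (Dalton)
#' @param fallback optional \code{c(radius=, mass=)} used for unknown
#'   elements instead of erroring
#' @return The frame with \code{radius} and \code{mass} filled in.
#' @export
assign_radii_masses <- function(frame, radii = default_vdw_radii(),
                                masses = default_atomic_masses(),
                                fallback = NULL) {
  stopifnot(inherits(frame, "structure_frame"))
  key <- frame$element
  key[key == "NA"] <- "NA."   # sodium; avoid the NA name clash
  r <- unname(radii[key]); m <- unname(masses[key])
  unk <- unique(frame$element[is.na(r) | is.na(m)])
  if (length(unk)) {
    if (is.null(fallback))
      stop("no radius/mass for element(s): ", paste(unk, collapse = ", "))
    r[is.na(r)] <- fallback[["radius"]]
    m[is.na(m)] <- fallback[["mass"]]
  }
  if (any(r <= 0) || any(m <= 0)) stop("radii and masses must be positive")
  frame$radius <- r
  frame$mass <- m
  frame
}

#' Select an atom subset from a frame
#'
#' Criteria combine with AND; order is preserved, so selection is a
#' projection (selecting twice with the same criteria is a no-op).
#' An empty result is returned as a zero-row frame together with a
#' warning of class \code{pcnsurf_empty_selection}, leaving the caller
#' to decide whether that is an error.
#'
#' @param frame a \code{structure_frame}
#' @param component component class(es) to keep (e.g. \code{"protein"},
#'   \code{"lipid"})
#' @param name atom name(s) to keep (e.g. \code{"CA"})
#' @param resno residue-number range or vector to keep
#' @param heavy_only drop hydrogens if TRUE
#' @param hetero keep only HETATM (TRUE) / only ATOM (FALSE) records
#' @return The subset \code{structure_frame} (possibly zero rows).
#' @export
select_atoms <- function(frame, component = NULL, name = NULL,
                         resno = NULL, heavy_only = FALSE, hetero = NULL) {
  stopifnot(inherits(frame, "structure_frame"))
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(component)) keep <- keep & frame$component %in% component
  if (!is.null(name)) keep <- keep & frame$name %in% name
  if (!is.null(resno)) keep <- keep & frame$resno %in% resno
  if (isTRUE(heavy_only)) keep <- keep & frame$element != "H"
  if (!is.null(hetero)) keep <- keep & frame$is_hetero == hetero
  out <- frame[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "time_label") <- attr(frame, "time_label")
  class(out) <- class(frame)
  if (nrow(out) == 0L)
    warning(warningCondition("selection matched no atoms",
                             class = c("pcnsurf_empty_selection", "warning")))
  out
}

#' Extract the C-alpha trace of the protein component
#'
#' One atom per standard protein residue, in file order.
#'
#' @param frame a \code{structure_frame}
#' @return \code{structure_frame} of CA atoms.
#' @export
ca_trace <- function(frame) {
  select_atoms(frame, component = "protein", name = "CA")
}

coords <- function(frame) {
  cbind(frame$x, frame$y, frame$z)
}

#' Write an atom table as TSV
#' @param frame a \code{structure_frame}
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
write_atoms_tsv <- function(frame, path) {
  utils::write.table(as.data.frame(frame), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
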