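# Seeded generators producing every fixture the pipeline needs, with
# planted ground truth emitted alongside the structure. All randomness
# comes from the single integer `seed` argument via a local RNG state;
# identical arguments give bit-identical output.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

make_frame <- function(xyz, element = "C", radius = NA_real_, mass = NA_real_,
                       resname = "GLY", name = element, chain = "A",
                       resno = NULL, is_hetero = FALSE, time_label = 0) {
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  f <- structure_frame(data.frame(
    serial = seq_len(n), name = rep_len(name, n),
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resno = rep_len(resno, n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep_len(element, n), is_hetero = rep_len(is_hetero, n),
    stringsAsFactors = FALSE), time_label = time_label)
  f$radius <- rep_len(radius, n)
  f$mass <- rep_len(mass, n)
  f
}

# n points of the integer lattice (scaled by `spacing`), closest to the
# origin first, jittered by +/- `jitter` per coordinate.
lattice_blob <- function(n, spacing = 6, jitter = 0.3) {
  k <- 0L
  repeat {
    k <- k + 1L
    g <- as.matrix(expand.grid(-k:k, -k:k, -k:k))
    if (nrow(g) >= n) {
      g <- g[order(rowSums(g^2)), , drop = FALSE][seq_len(n), , drop = FALSE]
      break
    }
  }
  g * spacing + matrix(stats::runif(3 * n, -jitter, jitter), ncol = 3)
}

#' Synthetic sphere clusters with known analytic SASA
#'
#' Arrangements: \code{"single"} (one sphere: SASA exactly
#' \eqn{4\pi(r+PR)^2}); \code{"pair"} (two spheres at \code{distance});
#' \code{"cage"} (a centre atom enclosed by an overlapping shell, fully
#' buried); \code{"ball"} (a solid ball of touching pseudo-atoms of
#' overall radius \code{ball_radius}).
#'
#' @param n_atoms atom count (single: forced 1; pair: 2; cage: shell
#'   size; ball: ignored, filled from \code{ball_radius})
#' @param radius_each vdW radius given to every pseudo-atom, Angstrom
#' @param arrangement one of single/pair/cage/ball
#' @param distance pair separation (pair), or shell radius (cage)
#' @param ball_radius overall ball radius (ball)
#' @param seed integer seed (used only by arrangements with jitter;
#'   kept for the uniform generator contract)
#' @return a \code{structure_frame} with radii and masses set.
#' @export
make_sphere_cluster <- function(n_atoms = 1, radius_each = 1.9,
                                arrangement = c("single", "pair", "cage", "ball"),
                                distance = NULL, ball_radius = NULL,
                                seed = 1) {
  arrangement <- match.arg(arrangement)
  xyz <- switch(arrangement,
    single = matrix(0, 1, 3),
    pair = {
      if (is.null(distance)) distance <- 10
      rbind(c(0, 0, 0), c(distance, 0, 0))
    },
    cage = {
      if (is.null(distance)) distance <- 2 * radius_each * 0.9
      n_shell <- max(n_atoms - 1L, 60L)
      rbind(c(0, 0, 0), fibonacci_sphere(n_shell) * distance)
    },
    ball = {
      if (is.null(ball_radius)) ball_radius <- 10
      s <- 2 * radius_each * 0.95          # slightly overlapping packing
      k <- ceiling(ball_radius / s)
      g <- as.matrix(expand.grid(-k:k, -k:k, -k:k)) * s
      g[rowSums(g^2) <= ball_radius^2, , drop = FALSE]
    })
  if (nrow(xyz) < 1) stop("arrangement produced no atoms")
  make_frame(xyz, element = "C", radius = radius_each, mass = 12.011)
}

#' Synthetic two-domain C-alpha body with planted module labels
#'
#' Two compact jittered-lattice blobs of \code{n1} and \code{n2}
#' C-alphas (intra-blob nearest-neighbour spacing ~6 Angstrom, inside
#' the 4-8 contact window) joined only by a straight linker of
#' \code{linker_len} extra C-alphas; every other inter-blob distance
#' exceeds the 8 Angstrom contact ceiling, so the minimal cut of the
#' contact network is a single linker edge. Planted labels: blob 1 plus
#' the first half of the linker = module 1. With \code{gap <= 0} the
#' second blob is laid on top of the first (a documented degenerate
#' case: coincident geometry gives a (near-)degenerate Fiedler gap).
#'
#' @param n1,n2 blob sizes (>= 8)
#' @param linker_len linker C-alpha count (even; default 2)
#' @param gap minimal blob-blob surface separation, Angstrom
#' @param seed integer seed
#' @return list: \code{frame} (CA \code{structure_frame}),
#'   \code{labels} (planted module id per residue).
#' @export
make_two_domain <- function(n1 = 20, n2 = 20, linker_len = 2, gap = 15,
                            seed = 1) {
  if (n1 < 8 || n2 < 8) stop("blobs need at least 8 residues each")
  if (linker_len < 0 || linker_len %% 2 != 0)
    stop("linker_len must be a non-negative even number")
  with_seed(seed, {
    b1 <- lattice_blob(n1)
    b2 <- lattice_blob(n2)
    if (gap <= 0) {
      xyz <- rbind(b1, b2)
      labels <- rep(c(1L, 2L), c(n1, n2))
    } else {
      ## anchors: extreme +x point of blob 1, extreme -x point of blob 2.
      ## blob 2 is aligned so its anchor faces blob 1's anchor head-on at
      ## separation span = 6 * (linker_len + 1) >= gap, giving a linker
      ## chain with 6 A spacing as the only inter-module connection
      ## (every direct blob-blob pair is separated by > 8 A in x alone).
      span <- max(6 * (linker_len + 1), gap)
      if (span <= 8)
        stop("infeasible geometry: gap and linker too short to separate ",
             "the modules; increase gap or linker_len")
      a1 <- b1[which.max(b1[, 1]), ]
      j2 <- which.min(b2[, 1])
      b2s <- sweep(b2, 2, c(a1[1] + span - b2[j2, 1],
                            a1[2] - b2[j2, 2],
                            a1[3] - b2[j2, 3]), "+")
      a2 <- b2s[j2, ]
      lin <- if (linker_len > 0)
        t(vapply(seq_len(linker_len),
                 function(k) a1 + (a2 - a1) * k / (linker_len + 1),
                 numeric(3)))
      else matrix(numeric(0), 0, 3)
      xyz <- rbind(b1, lin, b2s)
      labels <- c(rep(1L, n1), rep(1L, linker_len / 2),
                  rep(2L, linker_len / 2), rep(2L, n2))
    }
    list(frame = make_frame(xyz, element = "C", name = "CA",
                            resname = "GLY", radius = 1.70, mass = 12.011),
         labels = labels)
  })
}

#' Synthetic flat membrane slab of pseudo-lipid particles
#'
#' A regular nx-by-ny grid of particles in the plane z = z0 (plane
#' normal +z by construction), residue name \code{LIP}, classified as
#' the \code{lipid} component.
#'
#' @param nx,ny grid size (>= 2 each)
#' @param spacing grid spacing, Angstrom (default 8, the order of a
#'   lipid headgroup spacing)
#' @param z0 slab plane height, Angstrom
#' @return a \code{structure_frame} of lipid particles.
#' @export
make_membrane_slab <- function(nx = 10, ny = 10, spacing = 8, z0 = 0) {
  if (nx < 2 || ny < 2) stop("slab needs nx, ny >= 2")
  g <- as.matrix(expand.grid(seq_len(nx) - 1, seq_len(ny) - 1))
  xyz <- cbind(g * spacing, z0)
  make_frame(xyz, element = "P", name = "P", resname = "LIP", chain = "M",
             radius = 1.80, mass = 30.974, is_hetero = TRUE)
}

#' Synthetic approach trajectory with a known minimal-distance schedule
#'
#' The rigid \code{body} is translated toward the \code{slab} along z:
#' the minimal body-slab distance xi follows a linear descent from
#' \code{start_gap} to \code{contact_gap} over the first half of the
#' frames, then stays at \code{contact_gap}. The body's lowest atom is
#' placed exactly above a slab particle, so the realized minimal
#' interatomic distance equals the schedule exactly. The schedule is
#' attached as attribute \code{"xi_schedule"}.
#'
#' @param body a \code{structure_frame} (e.g. a sphere cluster)
#' @param slab a \code{structure_frame} from [make_membrane_slab()]
#' @param start_gap initial minimal distance, Angstrom
#' @param n_frames number of frames (>= 2)
#' @param contact_gap plateau minimal distance, Angstrom
#' @return a \code{trajectory}; frames contain body + slab atoms.
#' @export
make_approach_trajectory <- function(body, slab, start_gap = 30,
                                     n_frames = 20, contact_gap = 3) {
  if (!(start_gap > contact_gap && contact_gap >= 0))
    stop("need start_gap > contact_gap >= 0")
  if (n_frames < 2) stop("need at least 2 frames")
  z0 <- max(slab$z)
  ## align the body's lowest atom over the first slab particle
  i0 <- which.min(body$z)
  shift_xy <- c(slab$x[1] - body$x[i0], slab$y[1] - body$y[i0])
  k <- max(1L, floor(n_frames / 2))
  step <- (start_gap - contact_gap) / k
  xi <- pmax(contact_gap, start_gap - (seq_len(n_frames) - 1) * step)
  frames <- lapply(seq_len(n_frames), function(t) {
    b <- body
    b$x <- b$x + shift_xy[1]
    b$y <- b$y + shift_xy[2]
    b$z <- b$z - body$z[i0] + z0 + xi[t]
    f <- rbind_frames(b, slab)
    attr(f, "time_label") <- t
    f
  })
  traj <- trajectory(frames, times = seq_len(n_frames))
  attr(traj, "xi_schedule") <- xi
  traj
}

#' Planted two-block graph (stochastic block model) adjacency
#'
#' Within-block edges with probability \code{p_in}, between-block with
#' \code{p_out}; \code{bridges} inter-block edges are always forced so
#' the planted cut exists even as p_out -> 0. Resampled until connected
#' (bounded retries).
#'
#' @param n node count
#' @param blocks number of blocks (default 2; balanced)
#' @param p_in,p_out edge probabilities, \code{p_in > p_out}
#' @param seed integer seed
#' @param bridges forced inter-block edges (default 1)
#' @param max_retries connectivity retry budget
#' @return list: \code{adjacency}, \code{labels}.
#' @export
make_planted_graph <- function(n = 20, blocks = 2, p_in = 0.6, p_out = 0.02,
                               seed = 1, bridges = 1, max_retries = 50) {
  if (p_in <= p_out) stop("need p_in > p_out")
  labels <- sort(rep(seq_len(blocks), length.out = n))
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      A <- matrix(0L, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        p <- if (labels[i] == labels[j]) p_in else p_out
        A[i, j] <- A[j, i] <- as.integer(stats::runif(1) < p)
      }
      if (bridges > 0 && blocks == 2) {
        i1 <- which(labels == 1L)[seq_len(bridges)]
        i2 <- which(labels == 2L)[seq_len(bridges)]
        A[cbind(i1, i2)] <- 1L; A[cbind(i2, i1)] <- 1L
      }
      if (max(graph_components(A)) == 1L)
        return(list(adjacency = A, labels = labels))
    }
    stop("could not generate a connected graph within the retry budget")
  })
}

#' Synthetic surface-roughening trajectory
#'
#' A solid ball of pseudo-atoms whose surface is deformed by a smooth
#' angular corrugation of linearly increasing amplitude across frames
#' (frame 1 is the undeformed ball). Growing corrugation makes SASA
#' fall faster with probe radius, so the fitted fractal dimension is
#' non-decreasing along the trajectory -- the planted ground truth for
#' FD-trend tests.
#'
#' @param n_frames frames (>= 2)
#' @param ball_radius undeformed ball radius, Angstrom
#' @param atom_radius pseudo-atom vdW radius, Angstrom
#' @param amplitude_step corrugation amplitude increment per frame,
#'   Angstrom
#' @return a \code{trajectory}.
#' @export
make_roughening_trajectory <- function(n_frames = 3, ball_radius = 12,
                                       atom_radius = 1.7,
                                       amplitude_step = 0.8) {
  if (n_frames < 2) stop("need at least 2 frames")
  base <- make_sphere_cluster(radius_each = atom_radius, arrangement = "ball",
                              ball_radius = ball_radius)
  X <- coords(base)
  r <- sqrt(rowSums(X^2))
  theta <- acos(ifelse(r > 0, X[, 3] / pmax(r, 1e-12), 1))
  phi <- atan2(X[, 2], X[, 1])
  bump <- sin(4 * theta) * cos(4 * phi)       # smooth angular corrugation
  frames <- lapply(seq_len(n_frames), function(t) {
    a <- (t - 1) * amplitude_step
    scale <- ifelse(r > 0, 1 + a * bump * (r / ball_radius)^2 / ball_radius, 1)
    f <- base
    f$x <- X[, 1] * scale; f$y <- X[, 2] * scale; f$z <- X[, 3] * scale
    attr(f, "time_label") <- t
    f
  })
  trajectory(frames, times = seq_len(n_frames))
}

#' Synthetic cytochrome-c-like structure (labelled synthetic stand-in)
#'
#' A 104-residue all-atom pseudo-protein that emulates the topological
#' architecture of cytochrome c for pipeline tests: two compact
#' modules, module 1 = residues 1-34 and 86-104 (the N/C-terminal
#' segments folded together, containing His18), module 2 = residues
#' 35-85 (the long-loop half, containing Met80), joined only through
#' the two sequence bridges 34-35 and 85-86; a planar heme-like HETATM
#' ring sits between the modules. Each residue carries a C-alpha plus
#' seven pseudo side-chain/backbone heavy atoms packed at protein-like
#' density, so surface (SASA/FD) analyses see a compact globular body.
#' This is a synthetic construction with planted ground truth, not a
#' deposited structure.
#'
#' @param seed integer seed
#' @return list: \code{frame} (all-atom \code{structure_frame}),
#'   \code{labels} (planted module per residue, named by residue
#'   number).
#' @export
make_cytc_like <- function(seed = 1) {
  mod1 <- c(1:34, 86:104)          # planted module 1 (with His18)
  mod2 <- 35:85                    # planted module 2 (with Met80)
  with_seed(seed, {
    ## blob positions for the non-bridge residues of each module
    n1 <- length(mod1) - 2L        # residues 34 and 86 are placed manually
    n2 <- length(mod2) - 2L        # residues 35 and 85 likewise
    b1 <- lattice_blob(n1)
    b2 <- lattice_blob(n2)
    ## separate the blobs along x so only the bridges connect them
    span <- 18.5                    # anchor-anchor distance fitting CA-6 / 6.5 / CA-6
    shift <- max(b1[, 1]) + span - min(b2[, 1])
    b2 <- sweep(b2, 2, c(shift, 0, 0), "+")
    ## bridge 1 (y > 0): module-1 residue 34 -- module-2 residue 35
    pA1 <- b1[which.max(b1[, 1] + 0.5 * b1[, 2]), ]
    pB1 <- b2[which.min(b2[, 1] - 0.5 * b2[, 2]), ]
    u1 <- (pB1 - pA1) / sqrt(sum((pB1 - pA1)^2))
    r34 <- pA1 + u1 * 6
    r35 <- r34 + u1 * 6.5
    ## bridge 2 (y < 0): module-2 residue 85 -- module-1 residue 86
    pA2 <- b1[which.max(b1[, 1] - 0.5 * b1[, 2]), ]
    pB2 <- b2[which.min(b2[, 1] + 0.5 * b2[, 2]), ]
    u2 <- (pB2 - pA2) / sqrt(sum((pB2 - pA2)^2))
    r86 <- pA2 + u2 * 6
    r85 <- r86 + u2 * 6.5
    ## assemble CA coordinates per residue number
    ca <- matrix(NA_real_, 104, 3)
    ca[setdiff(mod1, c(34, 86)), ] <- b1
    ca[setdiff(mod2, c(35, 85)), ] <- b2
    ca[34, ] <- r34; ca[35, ] <- r35; ca[85, ] <- r85; ca[86, ] <- r86
    ## residue names: cycle of common residues with the named positions
    resnames <- rep(c("ALA", "GLY", "LEU", "SER", "VAL", "THR", "GLU", "LYS"),
                    length.out = 104)
    resnames[c(11, 18, 51, 52, 72, 80, 88)] <-
      c("ILE", "HIS", "ALA", "ASN", "LYS", "MET", "LYS")
    ## all-atom build: CA + 7 pseudo heavy atoms filling the 6 A cell
    offs <- rbind(c(1.8, 1.8, 1.8), c(-1.8, 1.8, -1.8), c(1.8, -1.8, -1.8),
                  c(-1.8, -1.8, 1.8), c(2.6, 0, 0), c(0, 2.6, 0),
                  c(0, 0, 2.6))
    elems <- c("N", "C", "O", "C", "C", "C", "N")
    rows <- vector("list", 104)
    for (i in 1:104) {
      jit <- matrix(stats::runif(21, -0.25, 0.25), ncol = 3)
      xyz <- rbind(ca[i, ], sweep(offs + jit, 2, ca[i, ], "+"))
      rows[[i]] <- data.frame(
        serial = 0L, name = c("CA", "N", "CB", "O", "CG", "CD", "CE", "ND"),
        resname = resnames[i], chain = "A", resno = i,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        element = c("C", elems), is_hetero = FALSE,
        stringsAsFactors = FALSE)
    }
    ## heme-like planar ring between the modules, plane normal along y
    ctr <- (r34 + r35 + r85 + r86) / 4
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    ring <- cbind(ctr[1] + 3.4 * cos(ang), ctr[2], ctr[3] + 3.4 * sin(ang))
    ring_elem <- rep(c("C", "C", "N"), 4)   # 12 ring atoms, 4 pyrrole-like N
    heme <- data.frame(
      serial = 0L,
      name = c(paste0(ring_elem, 1:12), "FE"),
      resname = "HEM", chain = "A", resno = 201L,
      x = c(ring[, 1], ctr[1]), y = c(ring[, 2], ctr[2]),
      z = c(ring[, 3], ctr[3]),
      element = c(ring_elem, "FE"),
      is_hetero = TRUE, stringsAsFactors = FALSE)
    at <- do.call(rbind, c(rows, list(heme)))
    at$serial <- seq_len(nrow(at))
    f <- structure_frame(at, time_label = 0)
    f <- assign_radii_masses(f)
    list(frame = f,
         labels = stats::setNames(ifelse(1:104 %in% mod1, 1L, 2L), 1:104))
  })
}
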