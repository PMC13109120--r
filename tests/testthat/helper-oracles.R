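# Independent oracles and small fixture builders shared across tests.

# Frame from bare coordinates with explicit radii/masses.
frame_from_xyz <- function(xyz, radius = 1.7, mass = 12.011,
                           resname = "GLY", name = "C", chain = "A",
                           element = "C", resno = NULL, hetero = FALSE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  f <- structure_frame(data.frame(
    serial = seq_len(n), name = rep_len(name, n),
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resno = resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep_len(element, n), is_hetero = rep_len(hetero, n)))
  f$radius <- rep_len(radius, n)
  f$mass <- rep_len(mass, n)
  f
}

# Ordinary least-squares slope by the explicit textbook formula,
# independent of lm().
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Brute-force betweenness centrality by exhaustive shortest-path
# counting: all-pairs BFS distances, then path counts via the
# composition rule sigma_uv(i) = sigma_ui * sigma_iv when i lies on a
# shortest u-v path. Unordered-pair convention. Independent of the
# package's Brandes accumulation.
brute_bc <- function(A) {
  n <- nrow(A)
  INF <- n + 1L
  dist <- matrix(INF, n, n); diag(dist) <- 0L
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- integer(0)
      for (v in frontier) for (w in which(A[v, ] == 1)) {
        if (dist[s, w] >= d) {
          if (dist[s, w] > d) { dist[s, w] <- d; nxt <- union(nxt, w) }
          sigma[s, w] <- sigma[s, w] + sigma[s, v]
        }
      }
      frontier <- nxt
    }
  }
  bc <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (u in seq_len(n - 1)) for (v in (u + 1):n) {
      if (u == i || v == i || dist[u, v] >= INF) next
      if (dist[u, i] + dist[i, v] == dist[u, v])
        acc <- acc + sigma[u, i] * sigma[i, v] / sigma[u, v]
    }
    bc[i] <- acc
  }
  bc
}

# Random connected graph on n nodes (resampled until connected).
random_connected_adjacency <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(stats::runif(length(up)) < p)
    A <- A + t(A)
    comp <- pcnsurf:::graph_components(A)
    if (max(comp) == 1L) return(A)
  }
}

# Analytic accessible area of a sphere (radius r1, probe P) occluded by
# one neighbouring sphere (radius r2) at centre distance d: full area
# minus the spherical cap cut off by the expanded neighbour.
lens_accessible_area <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * R1^2)
  cap <- 2 * pi * R1 * (R1 - (d^2 + R1^2 - R2^2) / (2 * d))
  4 * pi * R1^2 - cap
}

# Minimal multi-model PDB text fixture written to a temp file.
write_fixture_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}
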