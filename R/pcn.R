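#' Build a protein contact network from a C-alpha trace
#'
#' Residues are nodes; an undirected link joins residues i and j
#' (i != j) iff their C-alpha distance lies in the closed interval
#' [\code{d_min}, \code{d_max}] Angstrom (default 4-8). The lower bound
#' excludes the trivial backbone contacts of sequence neighbours
#' (canonical CA-CA spacing ~3.8 A), so links reflect tertiary
#' structure.
#'
#' @param ca_frame \code{structure_frame} holding exactly the CA atoms,
#'   one per residue, in sequence order (see [ca_trace()])
#' @param d_min,d_max distance window in Angstrom (closed interval)
#' @return Object of class \code{contact_network}: \code{nodes}
#'   (data.frame chain/resno/resname), \code{adjacency} (binary,
#'   symmetric, zero diagonal), \code{degree}, \code{laplacian}
#'   (degree matrix minus adjacency).
#' @export
build_pcn <- function(ca_frame, d_min = 4, d_max = 8) {
  stopifnot(inherits(ca_frame, "structure_frame"))
  n <- nrow(ca_frame)
  if (n < 2) stop("need at least 2 residues to build a contact network")
  key <- paste(ca_frame$chain, ca_frame$resno, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate residue id(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  D <- as.matrix(stats::dist(coords(ca_frame)))
  A <- (D >= d_min & D <= d_max) * 1L
  diag(A) <- 0L
  lab <- paste0(ca_frame$chain, ca_frame$resno)
  dimnames(A) <- list(lab, lab)
  deg <- unname(rowSums(A))
  L <- diag(deg) - A
  structure(list(
    nodes = data.frame(chain = ca_frame$chain, resno = ca_frame$resno,
                       resname = ca_frame$resname, row.names = NULL),
    adjacency = A, degree = deg, laplacian = L,
    d_min = d_min, d_max = d_max), class = "contact_network")
}

#' Construct a contact network directly from an adjacency matrix
#'
#' Used for graph fixtures (e.g. planted-partition benchmarks) that do
#' not come from coordinates.
#'
#' @param adjacency symmetric binary matrix, zero diagonal
#' @param resno optional node identifiers (default 1..n)
#' @return A \code{contact_network}.
#' @export
pcn_from_adjacency <- function(adjacency, resno = seq_len(nrow(adjacency))) {
  A <- as.matrix(adjacency)
  if (!isSymmetric(unname(A)) || any(diag(A) != 0) || !all(A %in% c(0, 1)))
    stop("adjacency must be binary, symmetric, with zero diagonal")
  storage.mode(A) <- "integer"
  deg <- unname(rowSums(A))
  structure(list(
    nodes = data.frame(chain = "A", resno = resno,
                       resname = rep("GLY", nrow(A)), row.names = NULL),
    adjacency = A, degree = deg, laplacian = diag(deg) - A,
    d_min = NA_real_, d_max = NA_real_), class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("contact_network: %d residues, %d links (window [%s, %s] A)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2,
              format(x$d_min), format(x$d_max)))
  invisible(x)
}

# Connected components by breadth-first search on the adjacency matrix.
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Betweenness centrality of every residue
#'
#' BC(i) sums, over pairs of other nodes u, v, the fraction of shortest
#' paths between u and v that pass through i
#' (\eqn{\sigma_{uv}(i)/\sigma_{uv}}), on the unweighted graph;
#' unreachable pairs contribute 0. Computed by Brandes' dependency
#' accumulation (one BFS per source). By default each unordered pair is
#' counted once; \code{ordered_pairs = TRUE} counts the literal double
#' sum over ordered (u, v), exactly doubling every value -- a uniform
#' rescaling that leaves rankings and comparisons unchanged.
#'
#' @param network a \code{contact_network}
#' @param ordered_pairs count ordered pairs (doubles all values)
#' @param normalized divide by the number of pairs
#'   \eqn{(n-1)(n-2)/2} (unordered convention)
#' @return Named numeric vector of BC values, node order.
#' @export
betweenness <- function(network, ordered_pairs = FALSE, normalized = FALSE) {
  stopifnot(inherits(network, "contact_network"))
  A <- network$adjacency
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2                       # each unordered pair counted from both ends
  if (ordered_pairs) bc <- bc * 2
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  stats::setNames(bc, rownames(A))
}

#' Spectral bipartition by the Fiedler vector
#'
#' Eigendecomposes the graph Laplacian and takes the eigenvector of the
#' second-smallest eigenvalue (the Fiedler vector). Nodes whose
#' component is <= the mean of the components form cluster 1, the rest
#' cluster 2; on a connected graph the Fiedler vector is orthogonal to
#' the constant vector, so the mean threshold is (numerically) a sign
#' split. Labels are canonicalized so that cluster 1 contains the
#' first node (lowest residue index), removing the eigenvector's sign
#' ambiguity.
#'
#' @param network a \code{contact_network}; must be connected
#' @return Object of class \code{pcn_partition}: \code{labels} (1/2 per
#'   node), \code{fiedler_vector}, \code{fiedler_value},
#'   \code{threshold} (mean component), \code{degenerate} (TRUE when
#'   the gap to the next eigenvalue is < 1e-9, flagged with a warning).
#' @export
fiedler_partition <- function(network) {
  stopifnot(inherits(network, "contact_network"))
  A <- network$adjacency
  n <- nrow(A)
  comp <- graph_components(A)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("graph is disconnected (", max(comp), " components of sizes ",
         paste(sizes, collapse = ", "), "); spectral bipartition needs ",
         "a connected network")
  }
  eig <- eigen(network$laplacian, symmetric = TRUE)
  vals <- rev(eig$values)            # ascending
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  fvec <- vecs[, 2]
  fval <- vals[2]
  degenerate <- n >= 3 && abs(vals[3] - vals[2]) < 1e-9
  if (degenerate)
    warning("near-degenerate Fiedler eigenvalue; bipartition may be unstable")
  thr <- mean(fvec)
  labels <- ifelse(fvec <= thr, 1L, 2L)
  if (labels[1] != 1L) {             # canonical: first node in cluster 1
    labels <- 3L - labels
    fvec <- -fvec
    thr <- -thr
  }
  structure(list(labels = stats::setNames(labels, rownames(A)),
                 fiedler_vector = fvec, fiedler_value = fval,
                 threshold = thr, degenerate = degenerate),
            class = "pcn_partition")
}

#' @export
print.pcn_partition <- function(x, ...) {
  cat(sprintf("pcn_partition: %d | %d nodes (lambda_2 = %.4g%s)\n",
              sum(x$labels == 1L), sum(x$labels == 2L), x$fiedler_value,
              if (x$degenerate) ", DEGENERATE gap" else ""))
  invisible(x)
}

#' Contiguous residue segments of one cluster
#'
#' Helper for reporting a partition as sequence segments (e.g.
#' "residues 1-34 and 86-104").
#'
#' @param partition a \code{pcn_partition}
#' @param network the matching \code{contact_network}
#' @param cluster which cluster label
#' @return data.frame with \code{from}, \code{to} residue numbers.
#' @export
cluster_segments <- function(partition, network, cluster = 1L) {
  res <- network$nodes$resno[partition$labels == cluster]
  res <- sort(res)
  if (!length(res)) return(data.frame(from = integer(0), to = integer(0)))
  brk <- c(0, which(diff(res) > 1), length(res))
  data.frame(from = res[utils::head(brk, -1) + 1], to = res[brk[-1]])
}

#' Participation coefficient of every residue
#'
#' \eqn{P_i = 1 - (k_{si}/k_i)^2} where \eqn{k_i} is the node degree
#' and \eqn{k_{si}} the number of links node i shares with its own
#' cluster. P = 0 for nodes linked only within their cluster; P close
#' to 1 marks inter-cluster bridges. Isolated nodes (k = 0) get P = 0
#' with a warning.
#'
#' @param network a \code{contact_network}
#' @param partition a \code{pcn_partition} covering all nodes
#' @return Named numeric vector of P values in [0, 1].
#' @export
participation <- function(network, partition) {
  stopifnot(inherits(network, "contact_network"),
            inherits(partition, "pcn_partition"))
  A <- network$adjacency
  if (length(partition$labels) != nrow(A))
    stop("partition does not cover all nodes")
  same <- outer(partition$labels, partition$labels, "==")
  k_si <- rowSums(A * same)
  k <- network$degree
  p <- numeric(length(k))
  if (any(k == 0)) warning("isolated node(s): participation set to 0")
  nz <- k > 0
  p[nz] <- 1 - (k_si[nz] / k[nz])^2
  stats::setNames(p, rownames(A))
}

#' Per-frame contact-network analysis of a trajectory
#'
#' For each frame: extract the CA trace, build the contact network,
#' bipartition it, and compute betweenness and participation. Cluster
#' labels are kept stable across frames by maximal overlap with the
#' previous frame's clusters (absorbing Fiedler-vector sign flips and
#' label permutations). Frames whose network is disconnected are
#' skipped and reported.
#'
#' @param traj a \code{trajectory}
#' @param d_min,d_max contact window, Angstrom
#' @return List: \code{metrics} (long data.frame: time, chain, resno,
#'   cluster, degree, bc, p), \code{summary} (per-frame: time, n_links,
#'   mean_bc, fiedler_value), \code{partitions} (list of
#'   \code{pcn_partition}), \code{skipped} (times of skipped frames).
#' @export
pcn_series <- function(traj, d_min = 4, d_max = 8) {
  stopifnot(inherits(traj, "trajectory"))
  metrics <- list(); summ <- list(); parts <- list(); skipped <- numeric(0)
  prev_labels <- NULL; prev_key <- NULL
  for (i in seq_along(traj$frames)) {
    t <- traj$times[i]
    ca <- ca_trace(traj$frames[[i]])
    net <- build_pcn(ca, d_min, d_max)
    part <- tryCatch(suppressWarnings(fiedler_partition(net)),
                     error = function(e) e)
    if (inherits(part, "error")) {
      message(sprintf("frame t=%s skipped: %s", format(t),
                      conditionMessage(part)))
      skipped <- c(skipped, t)
      next
    }
    key <- paste(net$nodes$chain, net$nodes$resno, sep = "/")
    if (!is.null(prev_labels)) {
      common <- intersect(key, prev_key)
      cur <- part$labels[match(common, key)]
      prv <- prev_labels[match(common, prev_key)]
      if (sum(cur == prv) < sum((3L - cur) == prv)) {
        part$labels <- stats::setNames(3L - part$labels, names(part$labels))
        part$fiedler_vector <- -part$fiedler_vector
        part$threshold <- -part$threshold
      }
    }
    prev_labels <- part$labels; prev_key <- key
    bc <- betweenness(net)
    p <- suppressWarnings(participation(net, part))
    metrics[[length(metrics) + 1L]] <- data.frame(
      time = t, chain = net$nodes$chain, resno = net$nodes$resno,
      cluster = as.integer(part$labels), degree = net$degree,
      bc = as.numeric(bc), p = as.numeric(p), row.names = NULL)
    summ[[length(summ) + 1L]] <- data.frame(
      time = t, n_links = sum(net$adjacency) / 2, mean_bc = mean(bc),
      fiedler_value = part$fiedler_value, row.names = NULL)
    parts[[length(parts) + 1L]] <- part
  }
  if (!length(metrics)) stop("no frame yielded a connected contact network")
  list(metrics = do.call(rbind, metrics),
       summary = do.call(rbind, summ),
       partitions = parts, skipped = skipped)
}
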