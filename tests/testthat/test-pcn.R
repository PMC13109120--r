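path_graph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

test_that("the contact rule applies the closed 4-8 Angstrom window", {
  f <- frame_from_xyz(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)), name = "CA")
  net <- build_pcn(f)
  expect_equal(net$degree, c(1, 2, 1))        # 1-3 at 10 A exceeds the ceiling
  expect_equal(net$adjacency[1, 3], 0L)

  ## canonical backbone spacing 3.8 A is below the floor: no link
  f2 <- frame_from_xyz(rbind(c(0, 0, 0), c(3.8, 0, 0)), name = "CA")
  expect_equal(sum(build_pcn(f2)$adjacency), 0L)
  ## boundary is closed: exactly 4.0 links, exactly 8.0 links
  f3 <- frame_from_xyz(rbind(c(0, 0, 0), c(4, 0, 0), c(-8, 0, 0)), name = "CA")
  A <- build_pcn(f3)$adjacency
  expect_equal(A[1, 2], 1L)
  expect_equal(A[1, 3], 1L)
  expect_equal(A[2, 3], 0L)                   # 12 A apart
})

test_that("contact-network invariants hold on a synthetic protein", {
  cc <- make_cytc_like(seed = 5)
  net <- build_pcn(ca_trace(cc$frame))
  A <- net$adjacency
  expect_true(isSymmetric(unname(A)))
  expect_true(all(diag(A) == 0))
  expect_equal(net$degree, unname(rowSums(A)))
  expect_equal(unname(rowSums(net$laplacian)), rep(0, nrow(A)))
  expect_error(build_pcn(f <- frame_from_xyz(c(0, 0, 0), name = "CA")), "2")
  dup <- frame_from_xyz(rbind(c(0, 0, 0), c(5, 0, 0)), name = "CA",
                        resno = c(1, 1))
  expect_error(build_pcn(dup), "duplicate")
})

test_that("betweenness matches closed forms on path and star graphs", {
  expect_equal(unname(betweenness(pcn_from_adjacency(path_graph(3)))),
               c(0, 1, 0))
  star <- matrix(0L, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1L
  bc <- betweenness(pcn_from_adjacency(star))
  expect_equal(unname(bc), c(6, 0, 0, 0, 0))   # C(4,2) pairs via the hub
  ## ordered-pair convention doubles every value
  expect_equal(unname(betweenness(pcn_from_adjacency(star),
                                  ordered_pairs = TRUE)),
               c(12, 0, 0, 0, 0))
  ## path graph BC sum: interior node i of an n-path intermediates
  ## (i-1)(n-i) pairs; closed form cross-check on n = 6
  p6 <- betweenness(pcn_from_adjacency(path_graph(6)))
  expect_equal(unname(p6), sapply(1:6, function(i) (i - 1) * (6 - i)))
})

test_that("betweenness equals the exhaustive shortest-path oracle", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    A <- random_connected_adjacency(n, p = stats::runif(1, 0.3, 0.6))
    got <- unname(betweenness(pcn_from_adjacency(A)))
    expect_equal(got, brute_bc(A), tolerance = 1e-12)
  }
})

test_that("betweenness agrees with an independent library implementation", {
  skip_if_not_installed("igraph")
  cc <- make_cytc_like(seed = 1)
  net <- build_pcn(ca_trace(cc$frame))
  got <- unname(betweenness(net))
  ref <- unname(igraph::betweenness(
    igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("Fiedler bipartition separates two bridged triangles", {
  A <- matrix(0L, 6, 6)
  link <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  A[link] <- 1L; A <- A + t(A) - diag(diag(A))
  A[A > 1] <- 1L
  part <- fiedler_partition(pcn_from_adjacency(A))
  expect_equal(unname(part$labels), c(1, 1, 1, 2, 2, 2))
  expect_lt(abs(mean(part$fiedler_vector)), 1e-9)
  ## oracle: among all 2^6 bipartitions with both sides non-empty, the
  ## minimum cut with balanced sides is {1,2,3} | {4,5,6}
  best <- NULL; best_score <- Inf
  for (m in 1:(2^6 - 2)) {
    s <- as.logical(bitwAnd(m, 2^(0:5)))
    cut <- sum(A[s, !s])
    score <- cut / (sum(s) * sum(!s))   # ratio-cut objective
    if (score < best_score) { best_score <- score; best <- s }
  }
  if (!best[1]) best <- !best           # orient: side containing node 1
  expect_equal(which(best), which(unname(part$labels) == part$labels[[1]]))
})

test_that("path-graph Fiedler vector matches the cosine closed form", {
  n <- 4
  part <- fiedler_partition(pcn_from_adjacency(path_graph(n)))
  ## Laplacian eigenvectors of a path: v_k(i) = cos(pi k (2i-1) / (2n))
  cosv <- cos(pi * 1 * (2 * (1:n) - 1) / (2 * n))
  got <- part$fiedler_vector
  expect_equal(got / sqrt(sum(got^2)),
               sign(sum(got * cosv)) * cosv / sqrt(sum(cosv^2)),
               tolerance = 1e-9)
  expect_equal(unname(part$labels), c(1, 1, 2, 2))
})

test_that("disconnected graphs are rejected; exact degeneracy is flagged", {
  A <- matrix(0L, 4, 4); A[1, 2] <- A[2, 1] <- 1L; A[3, 4] <- A[4, 3] <- 1L
  expect_error(fiedler_partition(pcn_from_adjacency(A)), "disconnected")
  ## cycle C4 has Laplacian spectrum {0, 2, 2, 4}: exactly degenerate
  C4 <- matrix(0L, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; C4[i, j] <- C4[j, i] <- 1L }
  expect_warning(p <- fiedler_partition(pcn_from_adjacency(C4)),
                 "degenerate")
  expect_true(p$degenerate)
})

test_that("participation coefficient follows 1 - (k_si/k_i)^2", {
  ## hub with 4 links, 2 inside its own cluster -> P = 0.75
  A <- matrix(0L, 5, 5); A[1, 2:5] <- A[2:5, 1] <- 1L
  net <- pcn_from_adjacency(A)
  part <- structure(list(labels = stats::setNames(c(1L, 1L, 1L, 2L, 2L),
                                                  rownames(A))),
                    class = "pcn_partition")
  p <- participation(net, part)
  expect_equal(unname(p[1]), 0.75)
  ## leaves in cluster 1 link only to the hub (cluster 1): all-intra, P = 0
  expect_equal(unname(p[2]), 0)
  ## leaves in cluster 2 link only across: P = 1
  expect_equal(unname(p[4]), 1)
  ## invariance under label swap
  part2 <- structure(list(labels = stats::setNames(3L - part$labels,
                                                   names(part$labels))),
                     class = "pcn_partition")
  expect_equal(participation(net, part2), p)
  ## isolated node: P defined as 0 with a warning
  B <- matrix(0L, 3, 3); B[1, 2] <- B[2, 1] <- 1L
  netB <- pcn_from_adjacency(B)
  partB <- structure(list(labels = stats::setNames(c(1L, 1L, 2L), rownames(B))),
                     class = "pcn_partition")
  expect_warning(pB <- participation(netB, partB), "isolated")
  expect_equal(unname(pB[3]), 0)
})

test_that("Fiedler mean is ~0 and P >= 0 on random connected graphs", {
  set.seed(7)
  for (rep in 1:25) {
    A <- random_connected_adjacency(sample(5:12, 1), p = 0.45)
    part <- suppressWarnings(fiedler_partition(pcn_from_adjacency(A)))
    expect_lt(abs(mean(part$fiedler_vector)), 1e-9)
    p <- suppressWarnings(participation(pcn_from_adjacency(A), part))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("planted two-domain bodies are recovered exactly across seeds", {
  for (seed in c(1, 7, 23)) {
    td <- make_two_domain(20, 20, linker_len = 2, gap = 15, seed = seed)
    part <- fiedler_partition(build_pcn(td$frame))
    expect_true(all(unname(part$labels) == td$labels) ||
                  all(unname(part$labels) == 3 - td$labels))
  }
})

test_that("pcn_series keeps labels stable across frames", {
  cc <- make_cytc_like(seed = 1)
  f1 <- cc$frame
  f2 <- cc$frame                # identical geometry, later time
  attr(f2, "time_label") <- 2
  tr <- trajectory(list(f1, f2), times = c(1, 2))
  out <- pcn_series(tr)
  m1 <- out$metrics[out$metrics$time == 1, ]
  m2 <- out$metrics[out$metrics$time == 2, ]
  expect_equal(m1$cluster, m2$cluster)
  expect_equal(m1$bc, m2$bc)
  ## forcing a sign flip on frame 2's partition is undone by overlap
  ## matching: labels of identical frames always agree
  expect_equal(out$summary$mean_bc[1], out$summary$mean_bc[2])
  expect_length(out$skipped, 0L)
})
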