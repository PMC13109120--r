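test_that("generators are deterministic given the same seed", {
  expect_identical(make_two_domain(10, 10, seed = 9),
                   make_two_domain(10, 10, seed = 9))
  expect_identical(make_planted_graph(16, seed = 5),
                   make_planted_graph(16, seed = 5))
  expect_identical(make_cytc_like(seed = 2), make_cytc_like(seed = 2))
  ## different seeds move the jitter
  expect_false(identical(make_two_domain(10, 10, seed = 1)$frame$x,
                         make_two_domain(10, 10, seed = 2)$frame$x))
  ## generators do not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(make_cytc_like(seed = 7)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("sphere-cluster arrangements have their stated geometry", {
  one <- make_sphere_cluster(radius_each = 1.9)
  expect_equal(nrow(one), 1L)
  expect_equal(one$radius, 1.9)
  pair <- make_sphere_cluster(2, 1.5, "pair", distance = 100)
  expect_equal(sqrt(sum((pair[2, c("x", "y", "z")] -
                           pair[1, c("x", "y", "z")])^2)), 100)
  ball <- make_sphere_cluster(arrangement = "ball", ball_radius = 10,
                              radius_each = 1.7)
  expect_true(all(rowSums(pcnsurf:::coords(ball)^2) <= 10^2 + 1e-9))
  expect_error(make_sphere_cluster(arrangement = "torus"))
})

test_that("two-domain bodies respect the planted contact structure", {
  td <- make_two_domain(15, 12, linker_len = 2, gap = 15, seed = 3)
  expect_equal(length(td$labels), 15 + 12 + 2)
  X <- pcnsurf:::coords(td$frame)
  D <- as.matrix(dist(X))
  blob1 <- which(td$labels == 1)[1:15]
  blob2 <- utils::tail(which(td$labels == 2), 12)
  ## all direct blob-blob distances exceed the 8 A contact ceiling
  expect_gt(min(D[blob1, blob2]), 8)
  ## intra-blob nearest neighbours sit inside the contact window
  nn1 <- apply(D[blob1, blob1] + diag(Inf, 15), 1, min)
  expect_true(all(nn1 >= 4.5 & nn1 <= 7.5))
  expect_error(make_two_domain(4, 20), "at least 8")
  expect_error(make_two_domain(10, 10, linker_len = 3), "even")
})

test_that("membrane slab is a flat lipid grid with plane normal z", {
  slab <- make_membrane_slab(10, 10, spacing = 8, z0 = -5)
  expect_equal(nrow(slab), 100L)
  expect_true(all(slab$z == -5))
  expect_true(all(slab$component == "lipid"))
  probe <- frame_from_xyz(c(slab$x[1], slab$y[1], 2))
  expect_equal(min_distance(probe, slab), 7)
  expect_error(make_membrane_slab(1, 5), "nx")
})

test_that("planted graphs are connected with forced bridges as p_out -> 0", {
  g <- make_planted_graph(20, p_in = 0.7, p_out = 0, seed = 8, bridges = 1)
  expect_equal(max(pcnsurf:::graph_components(g$adjacency)), 1L)
  ## exactly one inter-block edge: the forced bridge
  inter <- g$adjacency[g$labels == 1, g$labels == 2]
  expect_equal(sum(inter), 1L)
  part <- fiedler_partition(pcn_from_adjacency(g$adjacency))
  expect_true(all(unname(part$labels) == g$labels) ||
                all(unname(part$labels) == 3 - g$labels))
  expect_error(make_planted_graph(10, p_in = 0.1, p_out = 0.1), "p_in")
})

test_that("the synthetic cytochrome-c stand-in carries its planted truth", {
  cc <- make_cytc_like(seed = 1)
  expect_equal(nrow(ca_trace(cc$frame)), 104L)
  expect_equal(unname(cc$labels[c("18", "80")]), c(1L, 2L))
  expect_equal(cc$frame$resname[cc$frame$resno == 18][1], "HIS")
  expect_equal(cc$frame$resname[cc$frame$resno == 80][1], "MET")
  expect_true(any(cc$frame$component == "cofactor"))    # heme-like ring
  ## the heme ring is planar by construction (normal along y)
  h <- heme_orientation(cc$frame, membrane_normal = c(0, 1, 0))
  expect_equal(h$angle_to_membrane, 0, tolerance = 1e-6)
})
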