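test_that("minimal distance is the exact symmetric pairwise minimum", {
  a <- frame_from_xyz(c(0, 0, 0))
  b <- frame_from_xyz(c(0, 0, 5))
  expect_equal(min_distance(a, b), 5)
  expect_equal(min_distance(b, a), 5)
  expect_equal(min_distance(a, a), 0)
  expect_error(min_distance(a, a[0, ]), "non-empty")
})

test_that("centre-of-mass distance is mass-weighted and rigid-motion invariant", {
  a <- frame_from_xyz(rbind(c(0, 0, 0), c(0, 0, 10)), mass = 1)
  ref <- frame_from_xyz(c(0, 0, 0), mass = 1)
  expect_equal(com_distance(a, ref), 5)
  ## lever rule: masses 1 and 3 across a 4 A pair put the COM 3 A from
  ## the unit mass
  lever <- frame_from_xyz(rbind(c(0, 0, 0), c(4, 0, 0)), mass = c(1, 3))
  expect_equal(com_distance(lever, ref), 3)
  shift <- function(f, v) { f$x <- f$x + v[1]; f$y <- f$y + v[2]; f$z <- f$z + v[3]; f }
  expect_equal(com_distance(shift(lever, c(5, -2, 7)), shift(ref, c(5, -2, 7))),
               3)
  bad <- lever; bad$mass <- NA_real_
  expect_error(com_distance(bad, ref), "mass")
})

test_that("inter-residue CA distances resolve named atoms", {
  f <- frame_from_xyz(rbind(c(0, 0, 0), c(0, 0, 20)), name = "CA",
                      resno = c(11, 51))
  expect_equal(residue_pair_distance(f, 11, 51), 20)
  expect_equal(residue_pair_distance(f, 11, 11), 0)
  expect_error(residue_pair_distance(f, 11, 99), "99")
  ## planted open-vs-closed pair differing by a 12 A extension
  open <- f; open$z[2] <- 32
  d_closed <- residue_pair_distance(f, 11, 51)
  d_open <- residue_pair_distance(open, 11, 51)
  expect_equal(d_open - d_closed, 12)
})

test_that("buried interface equals the spherical-cap closed form for one occluder", {
  r1 <- 1.9; r2 <- 1.7; probe <- 1.4; d <- 4.0
  prot <- frame_from_xyz(c(0, 0, 0), radius = r1)
  memb <- frame_from_xyz(c(d, 0, 0), radius = r2, resname = "LIP")
  rep <- buried_interface(prot, memb, probe = probe, n_points = 4000)
  R1 <- r1 + probe; R2 <- r2 + probe
  cap <- 2 * pi * R1 * (R1 - (d^2 + R1^2 - R2^2) / (2 * d))
  expect_lt(abs(rep$total_buried - cap) / cap, 0.01)
  expect_equal(rep$total_buried, sum(rep$per_residue$buried))
  expect_equal(rep$contact_residues$resno, 1L)   # centres 4 A apart
})

test_that("a distant membrane buries nothing and touches no residue", {
  cc <- make_cytc_like(seed = 1)
  prot <- select_atoms(cc$frame, component = "protein", resno = 1:12)
  slab <- make_membrane_slab(4, 4, z0 = min(prot$z) - 100)
  rep <- buried_interface(prot, slab, probe = 1.4, n_points = 240)
  expect_equal(rep$total_buried, 0)
  expect_equal(nrow(rep$contact_residues), 0L)
})

test_that("per-cluster buried area lands on the cluster facing the slab", {
  td <- make_two_domain(12, 12, linker_len = 2, gap = 15, seed = 4)
  net <- build_pcn(td$frame)
  part <- fiedler_partition(net)
  ## slab placed just below the module-2 blob only
  m2 <- td$frame[td$labels == 2, ]
  class(m2) <- class(td$frame); attr(m2, "time_label") <- 0
  slab <- make_membrane_slab(6, 6, spacing = 6, z0 = min(m2$z) - 4)
  slab$x <- slab$x + mean(m2$x) - 15
  slab$y <- slab$y + mean(m2$y) - 15
  rep <- buried_interface(td$frame, slab, partition = part,
                          probe = 1.4, n_points = 240)
  expect_gt(rep$total_buried, 0)
  expect_equal(sum(rep$per_cluster_buried), rep$total_buried)
  expect_gt(rep$per_cluster_buried[["2"]] + 1e-9,
            10 * max(rep$per_cluster_buried[["1"]], 1e-9))
})

test_that("heme-plane orientation recovers planted angles", {
  ring <- cbind(3 * cos(seq_len(12)), 3 * sin(seq_len(12)), 0)
  f <- frame_from_xyz(ring)
  f$component <- "cofactor"
  expect_equal(heme_orientation(f)$angle_to_membrane, 0)
  ## same ring stood up in the xz-plane: orthogonal
  g <- frame_from_xyz(ring[, c(1, 3, 2)])
  g$component <- "cofactor"
  expect_equal(heme_orientation(g)$angle_to_membrane, 90)
  ## in-plane rotation leaves the angle unchanged
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  h <- frame_from_xyz(ring %*% t(R)); h$component <- "cofactor"
  expect_equal(heme_orientation(h)$angle_to_membrane, 0, tolerance = 1e-9)
  ## noisy planar ring (sigma = 0.1 A out of plane): plane recovered
  ## within 2 degrees; oracle = principal axes of the generated points
  set.seed(11)
  noisy <- ring + cbind(0, 0, stats::rnorm(12, 0, 0.1))
  nf <- frame_from_xyz(noisy); nf$component <- "cofactor"
  got <- heme_orientation(nf)
  ev <- eigen(stats::cov(noisy), symmetric = TRUE)
  oracle_normal <- ev$vectors[, 3]
  expect_lt(got$angle_to_membrane, 2)
  expect_gt(abs(sum(got$plane_normal * oracle_normal)), cos(1e-6))
  ## collinear atoms: plane undefined
  line <- frame_from_xyz(cbind(1:5, 0, 0)); line$component <- "cofactor"
  expect_error(heme_orientation(line), "collinear")
})

test_that("approach-trajectory kinetics reproduce the construction exactly", {
  body <- make_sphere_cluster(arrangement = "ball", ball_radius = 5,
                              radius_each = 1.7)
  slab <- make_membrane_slab(6, 6)
  tr <- make_approach_trajectory(body, slab, start_gap = 24, n_frames = 9,
                                 contact_gap = 3)
  k <- kinetics_series(tr)
  sched <- attr(tr, "xi_schedule")
  expect_equal(k$xi, sched, tolerance = 1e-9)
  ## strictly decreasing until contact, then a plateau at contact_gap
  drop <- which(k$xi > 3)
  expect_true(all(diff(k$xi[c(drop, max(drop) + 1)]) < 0))
  expect_true(all(k$xi[-drop] == 3))
  ## xi <= COM separation (the protein COM sits above its lowest atom)
  expect_true(all(k$xi <= k$com_distance))
})
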