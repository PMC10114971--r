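hb_topo <- function() {
  topology(data.frame(
    serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_name = c("ALA", "ALA", "GLY"), residue_number = c(1L, 1L, 2L),
    chain = "A", stringsAsFactors = FALSE))
}

triad <- function(d_na, h = c(1, 0, 0)) {
  rbind(c(0, 0, 0), h, c(d_na, 0, 0))
}

test_that("hydrogen bonds respect the strict distance and angle thresholds", {
  topo <- hb_topo()
  hit <- detect_hbonds(triad(2.9), topo)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 2.9)
  expect_gt(hit$angle, 120)
  expect_equal(hit$key, "A1-N-H..G2-O")
  # 3.6 A fails on distance regardless of angle
  expect_equal(nrow(detect_hbonds(triad(3.6), topo)), 0)
  # exactly 3.5 A fails (strict <)
  expect_equal(nrow(detect_hbonds(triad(3.5), topo)), 0)
  # an angle exactly at the threshold fails (strict >): perpendicular
  # geometry evaluates to exactly 90 degrees, so test against min_angle = 90
  perp <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1.8, 0))
  expect_equal(nrow(detect_hbonds(perp, topo, hbond_criteria(3.5, 90))), 0)
  expect_equal(nrow(detect_hbonds(perp, topo, hbond_criteria(3.5, 89))), 1)
  # just below / above the default 120-degree threshold
  place <- function(theta) rbind(c(0, 0, 0), c(1, 0, 0),
                                 c(1, 0, 0) + 1.8 * c(cos(pi - theta), sin(pi - theta), 0))
  expect_equal(nrow(detect_hbonds(place(119 * pi / 180), topo)), 0)
  expect_equal(nrow(detect_hbonds(place(121 * pi / 180), topo)), 1)
})

test_that("missing donor hydrogens error unless the heavy fallback is enabled", {
  topo <- topology(data.frame(
    serial = 1:2, name = c("N", "O"), element = c("N", "O"),
    residue_name = c("ALA", "GLY"), residue_number = c(1L, 2L),
    chain = "A", stringsAsFactors = FALSE))
  coords <- rbind(c(0, 0, 0), c(2.9, 0, 0))
  expect_error(detect_hbonds(coords, topo), "hydrogens")
  rec <- detect_hbonds(coords, topo, heavy_fallback = TRUE)
  expect_equal(nrow(rec), 1)
  expect_true(rec$no_angle)
})

test_that("detection equals a brute-force all-triples scan on random toys", {
  topo <- hb_topo()
  set.seed(40)
  for (rep in 1:20) {
    coords <- rbind(c(0, 0, 0), c(1, 0, 0) + rnorm(3, 0, 0.05),
                    rnorm(3, 0, 2.5))
    got <- nrow(detect_hbonds(coords, topo))
    oracle <- length(brute_force_hbonds(coords, donors = cbind(1, 2),
                                        acceptors = 3))
    expect_equal(got, oracle)
  }
})

test_that("tightening cutoffs only removes detections (monotonicity)", {
  topo <- hb_topo()
  set.seed(41)
  coords_list <- lapply(1:30, function(i)
    rbind(c(0, 0, 0), c(1, 0, 0), rnorm(3, 0, 2)))
  for (dmax in list(c(3.5, 3.0), c(4.5, 3.5))) {
    n_loose <- sum(vapply(coords_list, function(co)
      nrow(detect_hbonds(co, topo, hbond_criteria(dmax[1], 120))), numeric(1)))
    n_tight <- sum(vapply(coords_list, function(co)
      nrow(detect_hbonds(co, topo, hbond_criteria(dmax[2], 120))), numeric(1)))
    expect_lte(n_tight, n_loose)
  }
  for (amin in list(c(120, 150), c(100, 120))) {
    n_loose <- sum(vapply(coords_list, function(co)
      nrow(detect_hbonds(co, topo, hbond_criteria(3.5, amin[1]))), numeric(1)))
    n_tight <- sum(vapply(coords_list, function(co)
      nrow(detect_hbonds(co, topo, hbond_criteria(3.5, amin[2]))), numeric(1)))
    expect_lte(n_tight, n_loose)
  }
})

test_that("the occupancy fixture yields its constructed percentage exactly", {
  tr <- make_hbond_fixture(10, 0.7, seed = 3)
  occ <- occupancy(tr, "hbond")
  expect_equal(nrow(occ), 1)
  expect_identical(occ$occupancy, 70)
  expect_equal(occ$n_present, 7L)
  # doubling the trajectory leaves occupancy unchanged
  tr2 <- concatenate_trajectories(tr, tr)
  expect_identical(occupancy(tr2, "hbond")$occupancy, 70)
  # occupancy 0: empty table (absent keys are not zero-filled)
  expect_equal(nrow(occupancy(make_hbond_fixture(5, 0, 1), "hbond")), 0)
  expect_identical(occupancy(make_hbond_fixture(5, 1, 1), "hbond")$occupancy, 100)
})

test_that("occupancy is invariant to frame order", {
  tr <- make_hbond_fixture(10, 0.3, seed = 4)
  perm <- c(7, 2, 9, 1, 10, 3, 8, 5, 4, 6)
  tr_perm <- trajectory(tr$topology, tr$xyz[perm, ])
  expect_identical(occupancy(tr, "hbond")$occupancy,
                   occupancy(tr_perm, "hbond")$occupancy)
})

test_that("salt bridges pair charged-group centroids within the cutoff", {
  topo <- topology(data.frame(
    serial = 1:3, name = c("NZ", "OD1", "OD2"),
    element = c("N", "O", "O"),
    residue_name = c("LYS", "ASP", "ASP"),
    residue_number = c(26L, 129L, 129L), chain = "A",
    stringsAsFactors = FALSE))
  near <- rbind(c(0, 0, 0), c(3.8, 0.5, 0), c(3.8, -0.5, 0))
  rec <- detect_salt_bridges(near, topo)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$key, "K26+..D129-")
  expect_equal(rec$distance, 3.8, tolerance = 1e-9)
  far <- rbind(c(0, 0, 0), c(6.0, 0.5, 0), c(6.0, -0.5, 0))
  expect_equal(nrow(detect_salt_bridges(far, topo)), 0)
  # neutral groups at 2 A are not bridged (charge gating)
  neutral <- topology(data.frame(
    serial = 1:2, name = c("CA", "CB"), element = c("C", "C"),
    residue_name = c("ALA", "GLY"), residue_number = 1:2, chain = "A",
    stringsAsFactors = FALSE))
  expect_equal(nrow(detect_salt_bridges(rbind(c(0, 0, 0), c(2, 0, 0)),
                                        neutral)), 0)
})

test_that("pi stacking classifies parallel and rejects skew or distant rings", {
  hexagon <- function(z, tilt = 0) {
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
    if (tilt != 0) {
      Ry <- rbind(c(cos(tilt), 0, sin(tilt)), c(0, 1, 0),
                  c(-sin(tilt), 0, cos(tilt)))
      ring <- ring %*% t(Ry)
    }
    sweep(ring, 2, c(0, 0, z), "+")
  }
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  topo <- topology(data.frame(
    serial = 1:12, name = rep(ring_names, 2), element = "C",
    residue_name = "PHE", residue_number = rep(c(38L, 42L), each = 6),
    chain = "A", stringsAsFactors = FALSE))
  stacked <- rbind(hexagon(0), hexagon(3.8))
  rec <- detect_pi_pi(stacked, topo)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$geometry, "parallel")
  expect_equal(rec$distance, 3.8, tolerance = 1e-9)
  # centroids 7 A apart: not detected
  expect_equal(nrow(detect_pi_pi(rbind(hexagon(0), hexagon(7)), topo)), 0)
  # normals at 45 degrees fall in the gap between classes
  skew <- rbind(hexagon(0), hexagon(3.8, tilt = pi / 4))
  expect_equal(nrow(detect_pi_pi(skew, topo)), 0)
  # T-shaped (90 degrees) is classified
  tsh <- rbind(hexagon(0), hexagon(4.5, tilt = pi / 2))
  rec_t <- detect_pi_pi(tsh, topo)
  expect_equal(rec_t$geometry, "t_shaped")
  # non-planar ring is skipped with a warning
  bent <- rbind(hexagon(0), hexagon(3.8))
  bent[12, 3] <- bent[12, 3] + 1.2
  expect_warning(none <- detect_pi_pi(bent, topo), "non-planar")
  expect_equal(nrow(none), 0)
})

test_that("metal coordination gates on element and distance", {
  topo <- topology(data.frame(
    serial = 1:4, name = c("MG", "OG", "O1", "C1"),
    element = c("MG", "O", "O", "C"),
    residue_name = c("MG", "SER", "GTP", "GTP"),
    residue_number = c(201L, 27L, 180L, 180L), chain = "A",
    stringsAsFactors = FALSE))
  coords <- rbind(c(0, 0, 0), c(2.10, 0, 0), c(0, 4.1, 0), c(2.0, 0, 1))
  rec <- detect_metal_coordination(coords, topo)
  expect_equal(nrow(rec), 1)           # only the 2.10 A oxygen
  expect_equal(rec$distance, 2.10)
  expect_match(rec$key, "S27-OG")
  # carbon at 2.0 A is ignored; oxygen at 4.1 A is beyond the cutoff
  no_metal <- topology(data.frame(
    serial = 1:2, name = c("OG", "O"), element = c("O", "O"),
    residue_name = c("SER", "GTP"), residue_number = c(27L, 180L),
    chain = "A", stringsAsFactors = FALSE))
  expect_warning(empty <- detect_metal_coordination(coords[2:3, ], no_metal),
                 "no MG")
  expect_equal(nrow(empty), 0)
})

test_that("network diffs are order-stable set differences", {
  a <- data.frame(key = c("k1", "k2", "k3"))
  b <- data.frame(key = c("k2", "k3", "k4"))
  d <- network_diff(a, b)
  expect_equal(d$appeared, "k4")
  expect_equal(d$disappeared, "k1")
  expect_equal(d$shared, c("k2", "k3"))
  same <- network_diff(a, a)
  expect_length(same$appeared, 0)
  expect_length(same$disappeared, 0)
  # antisymmetry
  rev <- network_diff(b, a)
  expect_equal(rev$appeared, d$disappeared)
  expect_equal(rev$disappeared, d$appeared)
})
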