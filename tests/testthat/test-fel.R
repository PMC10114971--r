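# helper: wrap a G matrix into a pmf object with uniform counts
pmf_from_grid <- function(G, counts = NULL) {
  nx <- nrow(G); ny <- ncol(G)
  if (is.null(counts)) counts <- array(100L, dim = c(nx, ny))
  structure(list(
    breaks = list(seq(0, nx), seq(0, ny)),
    centers = list(seq(0.5, nx - 0.5), seq(0.5, ny - 0.5)),
    dim = 2L, G = G, counts = counts,
    probability = exp(-G) / sum(exp(-G)),
    artificial = array(FALSE, dim = c(nx, ny)),
    temperature = 300, method = "none", n_total = sum(counts)),
    class = "pmf")
}

test_that("an analytic double-well grid yields two valleys, deeper first", {
  xs <- seq(-3, 3, length.out = 20)
  ys <- seq(-1, 1, length.out = 5)
  G <- outer(xs, ys, function(x, y) 2 * ((x^2 - 4) / 4)^2 + 0.5 * y^2 + 0.3 * x)
  G <- G - min(G)
  v <- find_valleys(pmf_from_grid(G), depth_cutoff = 1, min_count = 1)
  expect_length(v, 2)
  expect_equal(v[[1]]$valley_id, "EV1")
  expect_lt(v[[1]]$G_min, v[[2]]$G_min)
  # the deeper valley sits on the negative-x side (the +0.3x tilt)
  expect_lt(xs[v[[1]]$minimum_bin[1]], 0)
  expect_gt(xs[v[[2]]$minimum_bin[1]], 0)
})

test_that("a single-basin quadratic grid yields exactly one valley", {
  xs <- seq(-2, 2, length.out = 15)
  G <- outer(xs, xs, function(x, y) x^2 + y^2)
  v <- find_valleys(pmf_from_grid(G), depth_cutoff = 1, min_count = 1)
  expect_length(v, 1)
  expect_equal(v[[1]]$G_min, 0)
})

test_that("valley membership partitions sub-cutoff bins", {
  set.seed(30)
  raw <- matrix(rnorm(100), 10, 10)
  G <- 0.25 * (raw + raw[c(2:10, 10), ] + raw[, c(2:10, 10)] + raw[c(1, 1:9), ])
  G <- G - min(G)
  v <- find_valleys(pmf_from_grid(G), depth_cutoff = 1.5, min_count = 1)
  all_members <- do.call(rbind, lapply(v, `[[`, "member_bins"))
  keys <- paste(all_members[, 1], all_members[, 2])
  expect_equal(anyDuplicated(keys), 0)
})

test_that("detected minima match an exhaustive local-minimum scan", {
  set.seed(31)
  for (rep in 1:5) {
    raw <- matrix(rnorm(64), 8, 8)
    G <- raw
    for (i in 1:8) for (j in 1:8) {
      ni <- max(1, i - 1):min(8, i + 1)
      nj <- max(1, j - 1):min(8, j + 1)
      G[i, j] <- mean(raw[ni, nj])
    }
    G <- G - min(G)
    # brute force: all strict-or-equal local minima (plateau-free by construction)
    brute <- NULL
    for (i in 1:8) for (j in 1:8) {
      ni <- max(1, i - 1):min(8, i + 1)
      nj <- max(1, j - 1):min(8, j + 1)
      if (G[i, j] <= min(G[ni, nj])) brute <- rbind(brute, c(i, j))
    }
    v <- find_valleys(pmf_from_grid(G), depth_cutoff = 0.01,
                      min_separation = 1, min_count = 1)
    got <- do.call(rbind, lapply(v, `[[`, "minimum_bin"))
    expect_equal(nrow(got), nrow(brute))
    expect_setequal(paste(got[, 1], got[, 2]), paste(brute[, 1], brute[, 2]))
  }
})

test_that("barrier heights follow the hand-enumerable 1D example", {
  # three bins G = (0, 2, 0.5): a -> b crosses 2.0; b -> a crosses 1.5
  x <- c(rep(0.5, 100), rep(1.5, 100), rep(2.5, 100))
  b <- assign_bins(x, c(0, 1, 2, 3))
  pmf <- reweight_pmf(b, 300, "none")
  pmf$G[] <- c(0, 2, 0.5)  # impose the quoted levels exactly
  v <- find_valleys(pmf, depth_cutoff = 0.4, min_separation = 1, min_count = 1)
  expect_length(v, 2)
  bh <- barrier_height(pmf, v[[1]], v[[2]])
  expect_equal(bh$a_to_b, 2.0)
  expect_equal(bh$b_to_a, 1.5)
  same <- barrier_height(pmf, v[[1]], v[[1]])
  expect_equal(same$a_to_b, 0)
})

test_that("minimax barriers equal exhaustive path enumeration on small grids", {
  set.seed(32)
  for (rep in 1:4) {
    G <- matrix(runif(36, 0, 5), 6, 6)
    G[2, 2] <- 0
    G[5, 5] <- 0.2
    p <- pmf_from_grid(G)
    va <- list(minimum_bin = c(2, 2), G_min = G[2, 2])
    vb <- list(minimum_bin = c(5, 5), G_min = G[5, 5])
    bh <- barrier_height(p, va, vb)
    oracle <- brute_force_minimax(G, c(2, 2), c(5, 5))
    expect_equal(bh$saddle, oracle, tolerance = 1e-12)
    expect_gte(bh$a_to_b, 0)
    expect_gte(bh$b_to_a, 0)
  }
})

test_that("valleys disconnected through populated bins return Inf", {
  G <- matrix(0, 5, 5)
  art <- array(FALSE, dim = c(5, 5))
  art[3, ] <- TRUE  # an artificial wall across the grid
  p <- pmf_from_grid(G)
  p$artificial <- art
  va <- list(minimum_bin = c(1, 1), G_min = 0)
  vb <- list(minimum_bin = c(5, 5), G_min = 0)
  expect_warning(bh <- barrier_height(p, va, vb), "disconnected")
  expect_identical(bh$a_to_b, Inf)
})

test_that("identical frames collapse to a single populated bin at G = 0", {
  topo <- toy_topology(4)
  traj <- traj_from_frames(topo, rep(list(tetra_coords()), 10))
  fel <- build_fel(traj, rc1 = rep(1.0, 10), rc2 = rep(2.0, 10), breaks = 5)
  expect_equal(sum(fel$counts > 0), 1)
  expect_equal(min(fel$G), 0)
  expect_true(all(fel$artificial[fel$counts == 0]))
  expect_true(all(fel$G[fel$counts == 0] == max(fel$G[fel$counts > 0])))
})

test_that("unbiased landscapes are identical under none and cumulant2", {
  set.seed(33)
  topo <- toy_topology(4)
  frames <- lapply(1:200, function(i) tetra_coords() + matrix(rnorm(12, 0, 0.3), 4, 3))
  traj <- traj_from_frames(topo, frames)
  rc1 <- rnorm(200)
  rc2 <- rnorm(200)
  records <- data.frame(step = 1:200, V = rnorm(200), dV = 0, E = Inf, k = 0)
  f1 <- build_fel(traj, rc1, rc2, records = records, method = "none", breaks = 8)
  f2 <- build_fel(traj, rc1, rc2, records = records, method = "cumulant2", breaks = 8)
  expect_equal(f1$G, f2$G, tolerance = 1e-12)
})

test_that("representative frames sit inside the minimum bin, ties to lowest index", {
  topo <- toy_topology(4)
  traj <- traj_from_frames(topo, rep(list(tetra_coords()), 6))
  rc1 <- c(0.10, 0.90, 0.52, 0.48, 0.50, 2.6)
  rc2 <- rep(0.5, 6)
  fel <- build_fel(traj, rc1, rc2, breaks = list(c(0, 1, 2, 3), c(0, 1)))
  v <- find_valleys(fel, depth_cutoff = 3, min_count = 1)
  rep_f <- representative_frame(fel, v[[1]])
  # bin 1 holds frames 1:5 with centre 0.5; frames 4 and 5 are equidistant
  # (0.48, 0.52 after frame 3) -> frame 3 is closest (exactly 0.52? no: 0.50)
  expect_equal(rep_f, 5)  # frame 5 at rc1 = 0.50 is exactly central
  # containment
  expect_true(rc1[rep_f] >= 0 && rc1[rep_f] < 1)
  # tie rule: remove the exact-centre frame; 0.48 and 0.52 tie -> lower index
  rc1b <- c(0.10, 0.90, 0.52, 0.48, 0.70, 2.6)
  felb <- build_fel(traj, rc1b, rc2, breaks = list(c(0, 1, 2, 3), c(0, 1)))
  vb <- find_valleys(felb, depth_cutoff = 3, min_count = 1)
  expect_equal(representative_frame(felb, vb[[1]]), 3)
})

test_that("a single-member valley returns its only frame", {
  topo <- toy_topology(4)
  traj <- traj_from_frames(topo, rep(list(tetra_coords()), 4))
  rc1 <- c(0.5, 0.5, 0.5, 2.5)
  fel <- build_fel(traj, rc1, rep(0.5, 4), breaks = list(c(0, 1, 2, 3), c(0, 1)))
  v <- find_valleys(fel, depth_cutoff = 0.3, min_count = 1)
  solo <- Filter(function(x) x$population == 1, v)
  expect_length(solo, 1)
  expect_equal(representative_frame(fel, solo[[1]]), 4)
})

test_that("an unbiased switch-chain ensemble shows two valleys at the wells", {
  sc <- make_switch_chain(switch_chain_spec())
  trajs <- lapply(1:2, function(r) {
    cfg <- langevin_config(n_steps = 3e5, seed = 7 + 10L * r, stride = 20,
                           timestep = 0.01)
    run_trajectory(run_langevin(sc$system, cfg), sc$topology)
  })
  traj <- concatenate_trajectories(trajs)
  d <- distance_series(traj, distance_definition("sw", 1, 10))
  fel <- build_fel(traj,
                   rc1 = list(kind = "rmsd", reference = 1,
                              selection = selection("heavy")),
                   rc2 = d, breaks = 24, method = "none")
  v <- find_valleys(fel, depth_cutoff = 1.0, min_count = 10)
  expect_equal(length(v), 2)
  wells <- sort(vapply(v, function(vv) fel$centers[[2]][vv$minimum_bin[2]], 0))
  expect_lt(abs(wells[1] - 11.1), 1.5)
  expect_lt(abs(wells[2] - 26.9), 1.5)
})
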