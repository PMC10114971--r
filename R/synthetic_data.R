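# Generators for every input the pipeline needs: analytic toy potentials,
# two-state bead-chain "switch" systems, prescribed-covariance ensembles and
# interaction-geometry fixtures.  All are seeded and reproducible.

bead_topology <- function(n_beads, residue_name = "BEA", atom_name = "CA",
                          element = "C") {
  topology(data.frame(
    serial = seq_len(n_beads), name = atom_name, element = element,
    residue_name = residue_name, residue_number = seq_len(n_beads),
    chain = "A", het = FALSE, stringsAsFactors = FALSE
  ))
}

#' Construct an analytic toy potential
#'
#' Low-dimensional model systems whose Boltzmann potential of mean force is
#' known in closed form, used to validate the boosted sampler and the
#' reweighting estimators against truth.
#'
#' * `harmonic`: \eqn{U = k/2 \sum (x_i - c_i)^2} with force constant
#'   `spring_k` and centre `center`
#' * `double_well_1d`: \eqn{U(x) = h ((x^2-b^2)/b^2)^2}; minima at
#'   \eqn{\pm b}, barrier height `h` at `x = 0`.  Defaults `h = 5` kcal/mol,
#'   `b = 2` A give a barrier of about 8.4 kT at 300 K, high enough that
#'   unboosted Langevin sampling rarely crosses on short runs.
#' * `triple_well_2d`: harmonic confinement minus three Gaussian wells.
#'
#' @param kind one of `"harmonic"`, `"double_well_1d"`, `"triple_well_2d"`
#' @param ... kind-specific parameters (see Details above); `mass` (amu, per
#'   degree of freedom) defaults to 12.
#' @return object of class `toy_system` with `energy`/`gradient` closures,
#'   an `analytic_pmf` callable, and the integer `kind_code`/`params` pair
#'   consumed by the compiled integrator.
#' @export
toy_potential <- function(kind = c("harmonic", "double_well_1d", "triple_well_2d"),
                          ...) {
  kind <- match.arg(kind)
  args <- list(...)
  mass <- if (is.null(args$mass)) 12 else args$mass
  if (kind == "harmonic") {
    k <- if (is.null(args$spring_k)) 1 else args$spring_k
    center <- if (is.null(args$center)) 0 else args$center
    n_dof <- length(center)
    params <- c(k, center)
    kind_code <- 0L
    pmf <- function(x) 0.5 * k * sum((x - center)^2)
    x0 <- center
  } else if (kind == "double_well_1d") {
    h <- if (is.null(args$h)) 5 else args$h
    b <- if (is.null(args$b)) 2 else args$b
    stopifnot(h > 0, b > 0)
    n_dof <- 1L
    params <- c(h, b)
    kind_code <- 1L
    pmf <- function(x) h * ((x^2 - b^2) / b^2)^2
    x0 <- -b
  } else {
    kc <- if (is.null(args$kc)) 0.3 else args$kc
    wells <- if (is.null(args$wells)) {
      # (cx, cy, depth, width) per well
      rbind(c(-2, 0, 4, 1), c(2, 0, 4, 1), c(0, 2.5, 3, 1))
    } else args$wells
    stopifnot(ncol(wells) == 4, nrow(wells) == 3)
    n_dof <- 2L
    params <- c(kc, as.vector(t(wells)))
    kind_code <- 2L
    pmf <- function(x) {
      0.5 * kc * sum(x^2) - sum(wells[, 3] *
        exp(-((x[1] - wells[, 1])^2 + (x[2] - wells[, 2])^2) / (2 * wells[, 4]^2)))
    }
    x0 <- wells[1, 1:2]
  }
  sys <- structure(list(
    kind = kind, kind_code = kind_code, params = params, n_dof = n_dof,
    masses = rep(mass, n_dof), x0 = x0, analytic_pmf = pmf
  ), class = "toy_system")
  sys$energy <- function(x) ff_eval_cpp(sys$kind_code, sys$params, x)$energy
  sys$gradient <- function(x) ff_eval_cpp(sys$kind_code, sys$params, x)$gradient
  sys
}

#' Specification of a two-state bead-chain switch system
#'
#' A coarse bead chain with harmonic bonds and angles plus a two-state pair
#' potential on one bead pair, emulating the open/closed transition of a
#' switch-domain distance.  The default well separations (11.1 and 26.9 A)
#' match the compact/incompact switch-domain distances characteristic of
#' RAS-family energy-valley analyses.
#'
#' @param n_beads chain length (>= 8)
#' @param bond_length equilibrium bond length (A)
#' @param bond_k bond force constant (kcal/mol/A^2)
#' @param angle_k angle force constant (kcal/mol/rad^2); equilibrium angle
#'   is extended (pi)
#' @param switch_pair indices of the two beads carrying the pair potential
#' @param well_distances `c(compact, incompact)` pair separations (A)
#' @param well_depths `c(compact, incompact)` well depths (kcal/mol, > 0)
#' @param barrier height of the Gaussian barrier bump between the wells
#'   (kcal/mol, > 0)
#' @param mutation_bias energy added to the compact well (kcal/mol;
#'   negative deepens it — the "mutant" condition)
#' @param well_width Gaussian width of each well (A)
#' @export
switch_chain_spec <- function(n_beads = 10, bond_length = 3.8, bond_k = 100,
                              angle_k = 0.5, switch_pair = c(1, 10),
                              well_distances = c(11.1, 26.9),
                              well_depths = c(2, 2.8), barrier = 1.5,
                              mutation_bias = 0, well_width = 1.2) {
  stopifnot(n_beads >= 8, bond_length > 0, bond_k > 0, angle_k >= 0,
            length(switch_pair) == 2, length(well_distances) == 2,
            length(well_depths) == 2, barrier > 0, well_width > 0)
  switch_pair <- as.integer(switch_pair)
  if (switch_pair[1] == switch_pair[2] || any(switch_pair < 1) ||
      any(switch_pair > n_beads)) {
    stop("switch_pair indices must be distinct and within 1..n_beads")
  }
  if (well_distances[1] >= well_distances[2]) {
    stop("compact well distance must be smaller than the incompact one")
  }
  structure(list(n_beads = as.integer(n_beads), bond_length = bond_length,
                 bond_k = bond_k, angle_k = angle_k, switch_pair = switch_pair,
                 well_distances = well_distances, well_depths = well_depths,
                 barrier = barrier, mutation_bias = mutation_bias,
                 well_width = well_width),
            class = "switch_chain_spec")
}

#' Build the bead topology and force field of a switch-chain system
#'
#' @param spec a [switch_chain_spec()]
#' @param mass bead mass (amu)
#' @return list with `topology` (one pseudo-residue per bead) and `system`
#'   (a `toy_system` whose `x0` is the extended conformation and whose pair
#'   potential has minima at the specified well distances)
#' @export
make_switch_chain <- function(spec, mass = 50) {
  stopifnot(inherits(spec, "switch_chain_spec"))
  nb <- spec$n_beads
  r1 <- spec$well_distances[1]
  r2 <- spec$well_distances[2]
  params <- c(nb, spec$bond_k, spec$bond_length, spec$angle_k, pi,
              spec$switch_pair, r1, r2, spec$well_depths, spec$mutation_bias,
              spec$barrier, spec$well_width, spec$well_width,
              10, r1 - 2.5 * spec$well_width, r2 + 2.5 * spec$well_width)
  x0 <- as.vector(t(cbind((seq_len(nb) - 1) * spec$bond_length, 0, 0)))
  sys <- structure(list(
    kind = "switch_chain", kind_code = 3L, params = params,
    n_dof = 3L * nb, masses = rep(mass, 3L * nb), x0 = x0,
    spec = spec, analytic_pmf = NULL
  ), class = "toy_system")
  sys$energy <- function(x) ff_eval_cpp(sys$kind_code, sys$params, x)$energy
  sys$gradient <- function(x) ff_eval_cpp(sys$kind_code, sys$params, x)$gradient
  sys$pair_potential <- function(r) {
    (spec$mutation_bias - spec$well_depths[1]) *
      exp(-(r - r1)^2 / (2 * spec$well_width^2)) -
      spec$well_depths[2] * exp(-(r - r2)^2 / (2 * spec$well_width^2)) +
      spec$barrier * exp(-(r - (r1 + r2) / 2)^2 / (2 * spec$well_width^2)) +
      ifelse(r < r1 - 2.5 * spec$well_width,
             5 * (r - (r1 - 2.5 * spec$well_width))^2,
             ifelse(r > r2 + 2.5 * spec$well_width,
                    5 * (r - (r2 + 2.5 * spec$well_width))^2, 0))
  }
  list(topology = bead_topology(nb), system = sys)
}

#' Sample a Gaussian ensemble with prescribed coordinate covariance
#'
#' Frames are i.i.d. zero-mean Gaussian displacements about a fixed base
#' structure, with the requested `3n x 3n` covariance — the analytic oracle
#' for cross-correlation and covariance-eigenvector analyses.
#'
#' @param n_particles number of particles
#' @param covariance symmetric PSD `3 * n_particles` square matrix (A^2)
#' @param n_frames frames to draw
#' @param seed RNG seed
#' @param base optional `n_particles x 3` base structure; default spreads
#'   particles 10 A apart along x
#' @return a [trajectory()]
#' @export
sample_correlated_ensemble <- function(n_particles, covariance, n_frames, seed,
                                       base = NULL) {
  d <- 3L * n_particles
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == d, ncol(covariance) == d)
  if (max(abs(covariance - t(covariance))) > 1e-8) {
    stop("covariance must be symmetric")
  }
  e <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (any(e$values < -tol)) {
    stop("covariance is not positive semi-definite (eigenvalue ",
         format(min(e$values)), ")")
  }
  lam <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(lam), d)
  if (is.null(base)) base <- cbind((seq_len(n_particles) - 1) * 10, 0, 0)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_frames * d), n_frames, d)
  xyz <- Z %*% t(L)
  xyz <- sweep(xyz, 2, as.vector(t(base)), "+")
  trajectory(bead_topology(n_particles), xyz)
}

#' Hydrogen-bond occupancy fixture with an exact qualifying-frame count
#'
#' A donor-H-acceptor triad in which exactly `round(occupancy * n_frames)`
#' frames satisfy the detection criteria (D-A distance 2.9 A, angle 165
#' degrees) and the remainder violate the distance criterion (4.5 A).
#' Frame order is shuffled by `seed`; the attribute `"manifest"` records
#' which frames qualify.
#'
#' @param n_frames number of frames; `occupancy * n_frames` must be integral
#' @param occupancy target fraction in `[0, 1]`
#' @param seed RNG seed for the shuffle
#' @return a [trajectory()] of a 3-atom system (residue 1: N, H; residue 2: O)
#' @export
make_hbond_fixture <- function(n_frames, occupancy, seed) {
  stopifnot(n_frames >= 1, occupancy >= 0, occupancy <= 1)
  expected <- occupancy * n_frames
  if (abs(expected - round(expected)) > 1e-9) {
    stop("occupancy * n_frames must be an integer for exact counting")
  }
  n_yes <- as.integer(round(expected))
  topo <- topology(data.frame(
    serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_name = c("ALA", "ALA", "GLY"), residue_number = c(1L, 1L, 2L),
    chain = "A", het = FALSE, stringsAsFactors = FALSE
  ))
  # donor N at origin, H along +x; acceptor on the x axis
  yes <- c(0, 0, 0, 1, 0, 0, 2.9, 0, 0)  # d(N-O) = 2.9, angle at H = 180
  no <- c(0, 0, 0, 1, 0, 0, 4.5, 0, 0)   # d(N-O) = 4.5 fails the cutoff
  qualifies <- c(rep(TRUE, n_yes), rep(FALSE, n_frames - n_yes))
  set.seed(seed)
  qualifies <- sample(qualifies)
  xyz <- t(vapply(qualifies, function(q) if (q) yes else no, numeric(9)))
  traj <- trajectory(topo, xyz)
  attr(traj, "manifest") <- data.frame(frame = seq_len(n_frames),
                                       qualifies = qualifies)
  traj
}

#' Rigid-body trajectory: the base structure under random rotations and
#' translations
#'
#' Internal geometry is identical across frames, so every superposition-based
#' fluctuation measure must vanish — the null oracle for RMSD and RMSF.
#'
#' @param topology a [topology()]
#' @param base `n_atoms x 3` base coordinates
#' @param n_frames number of frames
#' @param seed RNG seed
#' @export
make_rigid_body_trajectory <- function(topology, base, n_frames, seed) {
  base <- as.matrix(base)
  stopifnot(nrow(base) == n_atoms(topology), ncol(base) == 3)
  if (nrow(base) >= 3) {
    centered <- sweep(base, 2, colMeans(base))
    if (qr(centered)$rank < 2) {
      warning("base structure is collinear; superposition is degenerate")
    }
  }
  set.seed(seed)
  xyz <- matrix(0, n_frames, 3 * nrow(base))
  for (f in seq_len(n_frames)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    R <- rbind(
      c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
        2 * (q[2] * q[4] + q[3] * q[1])),
      c(2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
        2 * (q[3] * q[4] - q[2] * q[1])),
      c(2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
        1 - 2 * (q[2]^2 + q[3]^2))
    )
    tr <- stats::runif(3, -10, 10)
    xyz[f, ] <- as.vector(t(base %*% t(R) + matrix(tr, nrow(base), 3, byrow = TRUE)))
  }
  trajectory(topology, xyz)
}
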