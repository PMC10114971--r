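# Per-structure and per-ensemble descriptors: least-squares superposition,
# RMSD/RMSF/delta-RMSF, radius of gyration, numerical solvent-accessible
# surface area, named distances and frequency distributions.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `reference`
#' over the selected atoms, with the reflection excluded (det = +1).
#'
#' @param mobile,reference `N x 3` coordinate matrices
#' @param sel optional atom indices to fit on (default: all)
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (post-fit, over the fit selection) and `coords` (all mobile atoms
#'   transformed).  The transform maps a row vector p to
#'   `(p - center_mobile) %*% rotation + center_reference`.
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  if (length(sel) < 3) stop("superposition needs at least 3 atoms")
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2 || qr(Qc)$rank < 2) {
    stop("degenerate (collinear) selection: superposition is ill-defined")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted_sel <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted_sel - Qc)^2)))
  coords <- sweep(sweep(mobile, 2, cp) %*% R, 2, cq, "+")
  list(rotation = R, translation = cq - as.vector(cp %*% R), rmsd = rmsd,
       coords = coords)
}

# fit every frame of an xyz matrix (rows = frames) onto a reference frame
# using the given atom selection; returns the fitted xyz matrix
fit_frames <- function(xyz, reference, sel_idx) {
  ref <- matrix(reference, ncol = 3, byrow = TRUE)
  out <- xyz
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    out[f, ] <- as.vector(t(superpose(m, ref, sel_idx)$coords))
  }
  out
}

# iterated mean structure: fit to the running mean, recompute, repeat
iterated_mean_fit <- function(xyz, sel_idx, n_iter = 2) {
  ref <- xyz[1, ]
  fitted <- xyz
  for (it in seq_len(n_iter)) {
    fitted <- fit_frames(fitted, ref, sel_idx)
    ref <- colMeans(fitted)
  }
  list(xyz = fitted, mean = ref)
}

#' Per-frame RMSD against a reference structure
#'
#' Each frame is optimally superposed onto the reference over the selection
#' before the deviation is measured.
#'
#' @param traj a [trajectory()]
#' @param reference `N x 3` reference coordinates, or a frame index into
#'   `traj`
#' @param sel a [selection()] (default: all atoms)
#' @return numeric vector of per-frame RMSD (A)
#' @export
rmsd_series <- function(traj, reference = 1, sel = NULL) {
  idx <- resolve_selection(traj$topology, sel)
  ref <- if (length(reference) == 1) frame_coords(traj, reference) else as.matrix(reference)
  vapply(seq_len(n_frames(traj)), function(f) {
    superpose(frame_coords(traj, f), ref, idx)$rmsd
  }, numeric(1))
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed onto the iterated ensemble-average structure
#' (2 iterations by default), then
#' \eqn{RMSF_i = \sqrt{\langle |r_i - \langle r_i \rangle|^2 \rangle}} per
#' selected atom.
#'
#' @param traj a [trajectory()]
#' @param sel a [selection()] (default: all atoms)
#' @param fit_sel selection used for the superposition (default: same as
#'   `sel`)
#' @param n_iter mean-structure iterations
#' @return named numeric vector (A) with residue numbers as names
#' @export
rmsf <- function(traj, sel = NULL, fit_sel = sel, n_iter = 2) {
  stopifnot(n_frames(traj) >= 2)
  idx <- resolve_selection(traj$topology, sel)
  fidx <- resolve_selection(traj$topology, fit_sel)
  fitted <- iterated_mean_fit(traj$xyz, fidx, n_iter)
  cols <- xyz_cols(idx)
  dev <- sweep(fitted$xyz[, cols, drop = FALSE], 2,
               fitted$mean[cols])
  per_atom <- matrix(colMeans(dev^2), ncol = 3, byrow = TRUE)
  out <- sqrt(rowSums(per_atom))
  names(out) <- traj$topology$atoms$residue_number[idx]
  out
}

#' Difference in per-atom RMSF between a variant and a reference ensemble
#'
#' Positive entries mean the variant is more flexible at that atom.
#'
#' @param rmsf_variant,rmsf_reference equal-length per-atom RMSF vectors
#'   over the same selection
#' @export
delta_rmsf <- function(rmsf_variant, rmsf_reference) {
  if (length(rmsf_variant) != length(rmsf_reference)) {
    stop("RMSF vectors have different lengths; selections do not match")
  }
  rmsf_variant - rmsf_reference
}

#' Radius of gyration of one frame
#'
#' \eqn{R_g = \sqrt{\sum w_i |r_i - r_{cm}|^2 / \sum w_i}} with mass or
#' unit weights.
#'
#' @param coords `N x 3` coordinates
#' @param masses per-atom masses (used when `mass_weighted`)
#' @param mass_weighted logical
#' @export
radius_of_gyration <- function(coords, masses = NULL, mass_weighted = TRUE) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  w <- if (mass_weighted && !is.null(masses)) masses else rep(1, nrow(coords))
  cm <- colSums(coords * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(coords, 2, cm)^2)) / sum(w))
}

#' Per-frame radius of gyration of a trajectory
#' @param traj a [trajectory()]
#' @param sel a [selection()]
#' @param mass_weighted logical (default TRUE)
#' @export
rg_series <- function(traj, sel = NULL, mass_weighted = TRUE) {
  idx <- resolve_selection(traj$topology, sel)
  m <- traj$topology$atoms$mass[idx]
  vapply(seq_len(n_frames(traj)), function(f) {
    radius_of_gyration(frame_coords(traj, f)[idx, , drop = FALSE], m,
                       mass_weighted)
  }, numeric(1))
}

# deterministic near-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom's solvent-accessible sphere
#' (radius = vdW + probe) is covered with a deterministic golden-spiral
#' point set and the fraction of points not buried inside any neighbour's
#' sphere is converted to area.
#'
#' @param coords `N x 3` coordinates
#' @param topology matching [topology()] (elements give Bondi radii)
#' @param probe_radius probe radius (A), 1.4 by default (water)
#' @param n_points test points per atom
#' @return list with `total` (A^2) and `per_atom` (A^2 vector)
#' @export
sasa <- function(coords, topology, probe_radius = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  el <- toupper(topology$atoms$element)
  unknown <- setdiff(unique(el), names(.bondi_radii))
  if (length(unknown) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  r <- .bondi_radii[el] + probe_radius
  n <- nrow(coords)
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      # points exactly on a neighbour's surface are assigned to the
      # lower-index atom, so coincident spheres are counted once
      tol <- 1e-9 * r[j]^2
      buried <- dj2 < r[j]^2 - tol | (abs(dj2 - r[j]^2) <= tol & j < i)
      exposed <- exposed & !buried
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_points
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Define a labelled distance between two atoms or group centroids
#'
#' @param label name used in output tables
#' @param end_a,end_b each either a [selection()] or an integer vector of
#'   atom indices; multi-atom ends are reduced to their centroid
#' @param mass_weighted use mass-weighted centroids (default: unweighted
#'   mean, which coincides with the mass centre for identical-element
#'   groups)
#' @export
distance_definition <- function(label, end_a, end_b, mass_weighted = FALSE) {
  structure(list(label = label, end_a = end_a, end_b = end_b,
                 mass_weighted = mass_weighted),
            class = "distance_definition")
}

resolve_end <- function(topology, end) {
  idx <- if (inherits(end, "selection")) resolve_selection(topology, end)
         else as.integer(end)
  if (length(idx) < 1 || any(idx < 1) || any(idx > n_atoms(topology))) {
    stop("distance end does not resolve to atoms in the topology")
  }
  idx
}

#' Per-frame distance series for a distance definition
#' @param traj a [trajectory()]
#' @param definition a [distance_definition()]
#' @export
distance_series <- function(traj, definition) {
  stopifnot(inherits(definition, "distance_definition"))
  ia <- resolve_end(traj$topology, definition$end_a)
  ib <- resolve_end(traj$topology, definition$end_b)
  wa <- if (definition$mass_weighted) traj$topology$atoms$mass[ia] else rep(1, length(ia))
  wb <- if (definition$mass_weighted) traj$topology$atoms$mass[ib] else rep(1, length(ib))
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    ca <- colSums(m[ia, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(m[ib, , drop = FALSE] * wb) / sum(wb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
}

#' Density-normalised frequency distribution of a series
#'
#' Histogram with fixed bin width, normalised to unit area; the reported
#' peak is the centre of the modal bin (ties broken toward the lower
#' value, with a note).
#'
#' @param series numeric values
#' @param bin_width bin width in the series' units
#' @return list with `centers`, `density`, `peak`
#' @export
frequency_distribution <- function(series, bin_width) {
  stopifnot(length(series) >= 1, bin_width > 0)
  lo <- floor(min(series) / bin_width) * bin_width
  hi <- ceiling(max(series) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < max(series)) breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  h <- graphics::hist(series, breaks = breaks, plot = FALSE)
  modal <- which(h$counts == max(h$counts))
  if (length(modal) > 1) {
    message("frequency_distribution: modal-bin tie; reporting the lower value")
  }
  list(centers = h$mids, density = h$density, peak = h$mids[modal[1]])
}
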