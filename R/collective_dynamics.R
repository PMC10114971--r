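# Dynamic cross-correlation maps and Cartesian principal component
# analysis over a selected atom set, with variance-fraction reporting and
# mode-vector export for porcupine-style rendering.

# centered, optionally superposed coordinate block for a selection
prepare_ensemble <- function(traj, sel, fit, n_iter = 2) {
  idx <- resolve_selection(traj$topology, sel)
  xyz <- traj$xyz
  if (fit) {
    xyz <- iterated_mean_fit(xyz, idx, n_iter)$xyz
  }
  block <- xyz[, xyz_cols(idx), drop = FALSE]
  list(idx = idx, block = block, mean = colMeans(block))
}

#' Dynamic cross-correlation map
#'
#' \eqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#' (\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle)^{1/2}} with
#' \eqn{\Delta r} the full 3-vector displacement from the mean position.
#' Entries are in `[-1, 1]`: positive for in-phase (correlated) motion,
#' negative for anti-phase (anticorrelated) motion.  Frames are superposed
#' onto the iterated mean structure first (disable with `fit = FALSE` when
#' the ensemble is already in a common frame).
#'
#' @param traj a [trajectory()]
#' @param sel a [selection()] (conventionally the C-alpha set)
#' @param fit superpose frames before analysis (default TRUE)
#' @return object of class `dccm_result`: the correlation matrix with
#'   residue numbers as dimnames, plus `n_frames` attribute.  Rows/columns
#'   of zero-variance atoms are `NA` with a warning.
#' @export
dccm <- function(traj, sel = NULL, fit = TRUE) {
  stopifnot(n_frames(traj) >= 2)
  prep <- prepare_ensemble(traj, sel, fit)
  A <- sweep(prep$block, 2, prep$mean)
  nf <- nrow(A)
  na <- length(prep$idx)
  Ax <- A[, seq(1, 3 * na, 3), drop = FALSE]
  Ay <- A[, seq(2, 3 * na, 3), drop = FALSE]
  Az <- A[, seq(3, 3 * na, 3), drop = FALSE]
  S <- (crossprod(Ax) + crossprod(Ay) + crossprod(Az)) / nf
  v <- diag(S)
  dead <- v < 1e-20
  if (any(dead)) {
    warning(sum(dead), " zero-variance atom(s): correlation undefined",
            call. = FALSE)
  }
  denom <- sqrt(pmax(v, 1e-300))
  C <- S / outer(denom, denom)
  C[dead, ] <- NA
  C[, dead] <- NA
  diag(C)[!dead] <- 1
  C <- pmin(pmax(C, -1), 1)
  resno <- traj$topology$atoms$residue_number[prep$idx]
  dimnames(C) <- list(resno, resno)
  structure(C, class = c("dccm_result", "matrix"), n_frames = nf)
}

#' Cartesian principal component analysis
#'
#' Eigendecomposition of the `3n x 3n` covariance matrix of the selected
#' coordinates (population normalisation, 1/N).  Eigenvectors describe
#' concerted motions; eigenvalues (A^2) the fluctuation amplitude along
#' each mode.  Modes are sorted by decreasing eigenvalue and each
#' eigenvector's sign is fixed by making its largest-magnitude component
#' positive.
#'
#' @param traj a [trajectory()]
#' @param sel a [selection()]
#' @param fit superpose frames onto the iterated mean first (default TRUE)
#' @return object of class `pca_result` with `values`, `vectors`
#'   (orthonormal columns), `mean` (mean structure coordinates),
#'   `fraction`, `cumulative`, `sel_idx`
#' @export
pca <- function(traj, sel = NULL, fit = TRUE) {
  if (n_frames(traj) < 2) stop("PCA needs at least 2 frames")
  prep <- prepare_ensemble(traj, sel, fit)
  d <- ncol(prep$block)
  if (n_frames(traj) < d + 1) {
    warning("fewer frames (", n_frames(traj), ") than recommended (", d + 1,
            ") for a ", d, "-dof covariance", call. = FALSE)
  }
  A <- sweep(prep$block, 2, prep$mean)
  covm <- crossprod(A) / nrow(A)
  e <- eigen(covm, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  frac <- vals / sum(vals)
  structure(list(values = vals, vectors = vecs, mean = prep$mean,
                 fraction = frac, cumulative = cumsum(frac),
                 sel_idx = prep$idx, n_frames = nrow(A), fit = fit),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  n <- min(5, length(x$values))
  cat(sprintf("pca_result: %d modes over %d frames\n", length(x$values),
              x$n_frames))
  cat(sprintf("first %d eigenvectors account for %.1f%% of the total movements\n",
              n, 100 * x$cumulative[n]))
  invisible(x)
}

#' Project a trajectory onto principal modes
#'
#' Frames are superposed and mean-centred consistently with the PCA, then
#' dotted with the selected eigenvectors.  The variance of the projection
#' onto mode k equals the k-th eigenvalue (spectral identity).
#'
#' @param traj a [trajectory()] over the same topology
#' @param pca_res a [pca()] result
#' @param modes integer vector of mode indices
#' @return matrix `n_frames x length(modes)` (A)
#' @export
project_modes <- function(traj, pca_res, modes = 1:2) {
  stopifnot(inherits(pca_res, "pca_result"))
  if (any(modes < 1 | modes > length(pca_res$values))) {
    stop("mode index out of range")
  }
  xyz <- traj$xyz
  if (pca_res$fit) {
    ref <- pca_res$mean
    full_ref <- traj$xyz[1, ]
    full_ref[xyz_cols(pca_res$sel_idx)] <- ref
    xyz <- fit_frames(xyz, full_ref, pca_res$sel_idx)
  }
  A <- sweep(xyz[, xyz_cols(pca_res$sel_idx), drop = FALSE], 2, pca_res$mean)
  A %*% pca_res$vectors[, modes, drop = FALSE]
}

# subset a topology to selected atom indices
subtopology <- function(topology, idx) {
  topology(topology$atoms[idx, , drop = FALSE])
}

#' Export a principal mode as a paired-structure PDB
#'
#' Writes two MODELs — the mean structure and the mean displaced by
#' `scale` times the mode's per-atom 3-vectors — so standard viewers can
#' render porcupine-style arrows between them.
#'
#' @param pca_res a [pca()] result
#' @param mode mode index
#' @param scale displacement scale (A; eigenvectors have unit norm, so no
#'   atom moves by more than `scale`)
#' @param topology the full [topology()] the PCA selection refers to
#' @param path output PDB path
#' @export
export_mode_arrows <- function(pca_res, mode, scale, topology, path) {
  stopifnot(inherits(pca_res, "pca_result"))
  if (mode < 1 || mode > length(pca_res$values)) stop("mode index out of range")
  sub <- subtopology(topology, pca_res$sel_idx)
  displaced <- pca_res$mean + scale * pca_res$vectors[, mode]
  write_pdb(sub, rbind(pca_res$mean, displaced), path)
}
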