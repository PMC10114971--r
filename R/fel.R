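# 2D free-energy landscapes on reaction-coordinate pairs, energy-valley
# detection, representative-structure extraction and minimax barrier
# heights.

# evaluate an RC specification against a trajectory -> numeric series
eval_rc <- function(traj, rc) {
  if (is.numeric(rc)) {
    stopifnot(length(rc) == n_frames(traj))
    return(list(values = rc, label = "rc"))
  }
  stopifnot(is.list(rc), !is.null(rc$kind))
  if (rc$kind == "distance") {
    list(values = distance_series(traj, rc$definition),
         label = rc$definition$label)
  } else if (rc$kind == "rmsd") {
    ref <- if (is.null(rc$reference)) 1 else rc$reference
    sel <- if (is.null(rc$selection)) selection("heavy") else rc$selection
    list(values = rmsd_series(traj, ref, sel), label = "rmsd")
  } else {
    stop("unknown reaction-coordinate kind: ", rc$kind)
  }
}

default_breaks <- function(x, n) {
  r <- range(x)
  pad <- 0.05 * max(diff(r), 1e-6)
  seq(r[1] - pad, r[2] + pad, length.out = n + 1)
}

#' Build a free-energy landscape over one or two reaction coordinates
#'
#' Composes RC extraction, binning, reweighting and the empty-bin fill:
#' the standard pipeline behind landscape figures on (heavy-atom RMSD,
#' inter-residue distance) coordinate pairs.
#'
#' @param traj a [trajectory()]
#' @param rc1,rc2 reaction-coordinate specs: a numeric per-frame series, or
#'   `list(kind = "distance", definition = )` /
#'   `list(kind = "rmsd", reference = , selection = )`; `rc2 = NULL` gives
#'   a 1D profile
#' @param records optional boost-record table (per stored frame) whose
#'   `dV` column drives the reweighting
#' @param method reweighting estimator (see [reweight_pmf()])
#' @param breaks bins per axis (scalar, default 60 for 2D / 100 for 1D) or
#'   explicit edge vectors
#' @param temperature K
#' @param retain retain per-bin boost samples
#' @return a `pmf` (see [reweight_pmf()]) carrying the per-frame RC matrix
#'   (`$rc`) and per-frame bin assignment (`$frame_bins`)
#' @export
build_fel <- function(traj, rc1, rc2 = NULL, records = NULL,
                      method = "cumulant2", breaks = NULL, temperature = 300,
                      retain = identical(method, "exponential")) {
  r1 <- eval_rc(traj, rc1)
  rc <- matrix(r1$values, ncol = 1)
  labels <- r1$label
  if (!is.null(rc2)) {
    r2 <- eval_rc(traj, rc2)
    rc <- cbind(rc, r2$values)
    labels <- c(labels, r2$label)
  }
  ndim <- ncol(rc)
  if (is.null(breaks)) breaks <- if (ndim == 1) 100 else 60
  if (!is.list(breaks)) {
    breaks <- if (length(breaks) == 1) {
      lapply(seq_len(ndim), function(d) default_breaks(rc[, d], breaks))
    } else list(breaks)
  }
  dv <- if (is.null(records)) NULL else records$dV
  if (!is.null(dv) && length(dv) != nrow(rc)) {
    stop("boost records (", length(dv), ") do not align with frames (",
         nrow(rc), ")")
  }
  bins <- assign_bins(rc, breaks, delta_v = dv, retain = retain)
  pmf <- fill_empty_bins(reweight_pmf(bins, temperature, method))
  pmf$rc <- rc
  pmf$rc_labels <- labels
  pmf$frame_bins <- bins$frame_bins
  pmf
}

# G as a matrix (nx x ny; ny = 1 for 1D grids)
g_matrix <- function(pmf) {
  if (pmf$dim == 1) matrix(pmf$G, ncol = 1) else pmf$G
}

neighbors8 <- function(i, j, nx, ny) {
  di <- rep(-1:1, times = 3)
  dj <- rep(-1:1, each = 3)
  keep <- !(di == 0 & dj == 0)
  ii <- i + di[keep]; jj <- j + dj[keep]
  ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
  cbind(ii[ok], jj[ok])
}

#' Detect energy valleys on a free-energy grid
#'
#' Local minima over 8-connected neighbourhoods among populated,
#' non-artificial bins; minima closer than `min_separation` bins
#' (Chebyshev) are merged keeping the deeper.  Each surviving valley's
#' member set is grown over connected bins with
#' `G < G_min + depth_cutoff` not claimed by a deeper valley, and valleys
#' are labelled EV1, EV2, ... in order of increasing minimum energy.
#'
#' @param pmf a `pmf` (1D or 2D)
#' @param depth_cutoff valley depth cutoff (kcal/mol, > 0)
#' @param min_separation minimum separation between distinct minima (bins)
#' @param min_count minimum frame count for a bin to seed a valley
#'   (noise floor: sparse single-frame bins cannot nucleate minima; they
#'   can still be members of a deeper valley's basin)
#' @return list of valleys: `valley_id`, `minimum_bin` (grid index pair),
#'   `G_min`, `member_bins` (2-column matrix), `population` (frame count),
#'   `fraction` (of all binned frames)
#' @export
find_valleys <- function(pmf, depth_cutoff = 1.0, min_separation = 2,
                         min_count = 5) {
  stopifnot(inherits(pmf, "pmf"), depth_cutoff > 0)
  G <- g_matrix(pmf)
  counts <- if (pmf$dim == 1) matrix(pmf$counts, ncol = 1) else pmf$counts
  art <- if (pmf$dim == 1) matrix(pmf$artificial, ncol = 1) else pmf$artificial
  nx <- nrow(G); ny <- ncol(G)
  eligible <- counts > 0 & !art
  if (!any(eligible)) {
    warning("no populated bins: no valleys")
    return(list())
  }
  # local minima
  minima <- NULL
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!eligible[i, j] || counts[i, j] < min_count) next
    nb <- neighbors8(i, j, nx, ny)
    gn <- G[nb]
    if (all(G[i, j] <= gn)) minima <- rbind(minima, c(i, j))
  }
  if (is.null(minima)) {
    # every local minimum is below the count floor: keep the deepest bin
    cand <- which(eligible, arr.ind = TRUE)
    minima <- cand[which.min(G[cand]), , drop = FALSE]
  }
  g_at <- G[minima, drop = FALSE]
  ord <- order(g_at, minima[, 1], minima[, 2])
  minima <- minima[ord, , drop = FALSE]
  # merge minima closer than min_separation (deeper kept; sorted ascending)
  keep <- rep(TRUE, nrow(minima))
  for (a in seq_len(nrow(minima))) {
    if (!keep[a]) next
    for (b in seq_len(nrow(minima))) {
      if (b <= a || !keep[b]) next
      if (max(abs(minima[a, ] - minima[b, ])) < min_separation) keep[b] <- FALSE
    }
  }
  minima <- minima[keep, , drop = FALSE]
  # grow member regions, deeper valleys first
  claimed <- matrix(FALSE, nx, ny)
  valleys <- list()
  for (a in seq_len(nrow(minima))) {
    i0 <- minima[a, 1]; j0 <- minima[a, 2]
    if (claimed[i0, j0]) next  # absorbed into a deeper valley's basin
    gmin <- G[i0, j0]
    members <- matrix(c(i0, j0), 1, 2)
    claimed[i0, j0] <- TRUE
    queue <- list(c(i0, j0))
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- neighbors8(cur[1], cur[2], nx, ny)
      for (q in seq_len(nrow(nb))) {
        ii <- nb[q, 1]; jj <- nb[q, 2]
        if (claimed[ii, jj] || !eligible[ii, jj]) next
        if (G[ii, jj] < gmin + depth_cutoff) {
          claimed[ii, jj] <- TRUE
          members <- rbind(members, c(ii, jj))
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
    valleys[[length(valleys) + 1]] <- list(
      minimum_bin = c(i0, j0), G_min = gmin, member_bins = members,
      population = sum(counts[members]),
      fraction = sum(counts[members]) / sum(counts))
  }
  for (a in seq_along(valleys)) valleys[[a]]$valley_id <- paste0("EV", a)
  valleys
}

flat_bin <- function(ij, nx) ij[, 1] + nx * (ij[, 2] - 1L)

#' Representative frame of an energy valley
#'
#' The frame falling in the valley's minimum bin whose reaction-coordinate
#' point is nearest the bin centre (ties: lowest frame index).  If the
#' minimum bin holds no frames, the most populated member bin is used with
#' a warning.
#'
#' @param pmf a `pmf` built by [build_fel()] (carries per-frame RCs)
#' @param valley one element of [find_valleys()]
#' @return frame index into the trajectory the landscape was built from
#' @export
representative_frame <- function(pmf, valley) {
  if (is.null(pmf$frame_bins)) stop("pmf carries no per-frame bin assignment")
  counts <- if (pmf$dim == 1) matrix(pmf$counts, ncol = 1) else pmf$counts
  nx <- nrow(counts)
  target <- matrix(valley$minimum_bin, 1, 2)
  if (counts[target] == 0) {
    warning("minimum bin is empty; falling back to the most populated member bin")
    mem <- valley$member_bins
    target <- mem[which.max(counts[mem]), , drop = FALSE]
  }
  tflat <- flat_bin(target, nx)
  frames <- which(pmf$frame_bins == tflat)
  if (length(frames) == 0) stop("no frames in the representative bin")
  ctr <- c(pmf$centers[[1]][target[1, 1]],
           if (pmf$dim == 2) pmf$centers[[2]][target[1, 2]] else NULL)
  rc <- pmf$rc[frames, , drop = FALSE]
  d2 <- rowSums(sweep(rc, 2, ctr)^2)
  frames[which.min(d2)]  # which.min takes the first (lowest index) on ties
}

#' Minimax barrier height between two valleys
#'
#' The lowest possible maximum energy along any 8-connected path between
#' the two minima (the watershed saddle), minus each valley's minimum:
#' reported from a to b and from b to a.  Paths may not traverse
#' artificial (unpopulated) bins; if the valleys are disconnected, `Inf`
#' is returned with a warning.
#'
#' @param pmf a `pmf`
#' @param valley_a,valley_b elements of [find_valleys()]
#' @return list with `a_to_b`, `b_to_a` (kcal/mol) and `saddle` (the
#'   minimax energy level)
#' @export
barrier_height <- function(pmf, valley_a, valley_b) {
  G <- g_matrix(pmf)
  art <- if (pmf$dim == 1) matrix(pmf$artificial, ncol = 1) else pmf$artificial
  nx <- nrow(G); ny <- ncol(G)
  a <- valley_a$minimum_bin; b <- valley_b$minimum_bin
  if (all(a == b)) {
    return(list(a_to_b = 0, b_to_a = 0, saddle = valley_a$G_min))
  }
  eligible <- is.finite(G) & !art
  ord <- order(G[eligible])
  cells <- which(eligible)  # flat indices, column-major
  cells <- cells[ord]
  parent <- seq_len(nx * ny)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  added <- rep(FALSE, nx * ny)
  af <- a[1] + nx * (a[2] - 1L)
  bf <- b[1] + nx * (b[2] - 1L)
  saddle <- NA_real_
  for (cf in cells) {
    i <- ((cf - 1L) %% nx) + 1L
    j <- ((cf - 1L) %/% nx) + 1L
    added[cf] <- TRUE
    nb <- neighbors8(i, j, nx, ny)
    for (q in seq_len(nrow(nb))) {
      nf <- nb[q, 1] + nx * (nb[q, 2] - 1L)
      if (added[nf]) {
        ra <- find(cf); rb <- find(nf)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (added[af] && added[bf] && find(af) == find(bf)) {
      saddle <- G[cf]
      break
    }
  }
  if (is.na(saddle)) {
    warning("valleys are disconnected through populated bins")
    return(list(a_to_b = Inf, b_to_a = Inf, saddle = Inf))
  }
  list(a_to_b = saddle - valley_a$G_min, b_to_a = saddle - valley_b$G_min,
       saddle = saddle)
}
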