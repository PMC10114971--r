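# Recovery of unbiased free-energy profiles from boosted trajectories:
# reaction-coordinate binning with per-bin boost statistics, then
# exponential / Maclaurin / second-order-cumulant reweighting and the
# empty-bin fill rule.

#' Bin reaction-coordinate values and accumulate per-bin boost statistics
#'
#' Each frame goes to exactly one bin (half-open intervals, last bin
#' closed); per-bin boost-energy mean and variance are accumulated with a
#' one-pass Welford scheme.  Values outside the grid are counted in an
#' overflow register, excluded, and flagged with a warning.
#'
#' @param rc numeric vector (1D) or two-column matrix (2D) of per-frame
#'   reaction-coordinate values
#' @param breaks bin-edge vector (1D) or list of two edge vectors (2D);
#'   edges must be strictly increasing
#' @param delta_v optional per-frame boost energies (kcal/mol)
#' @param retain keep the per-bin boost samples (required by the
#'   exponential estimator)
#' @return object of class `bin_stats`
#' @export
assign_bins <- function(rc, breaks, delta_v = NULL, retain = FALSE) {
  rc <- if (is.matrix(rc) || is.data.frame(rc)) as.matrix(rc) else matrix(rc, ncol = 1)
  ndim <- ncol(rc)
  if (!ndim %in% 1:2) stop("reaction coordinate must be 1- or 2-dimensional")
  if (!is.list(breaks)) breaks <- list(breaks)
  if (length(breaks) != ndim) stop("need one break vector per rc dimension")
  for (b in breaks) {
    if (length(b) < 2 || any(diff(b) <= 0)) stop("bin edges must be strictly increasing")
  }
  n <- nrow(rc)
  if (is.null(delta_v)) delta_v <- numeric(n)
  stopifnot(length(delta_v) == n)
  nb <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  idx <- matrix(0L, n, ndim)
  for (d in seq_len(ndim)) {
    i <- findInterval(rc[, d], breaks[[d]], rightmost.closed = TRUE)
    i[rc[, d] < breaks[[d]][1] | rc[, d] > breaks[[d]][length(breaks[[d]])]] <- 0L
    idx[, d] <- i
  }
  ok <- apply(idx >= 1L, 1, all)
  overflow <- sum(!ok)
  if (overflow > 0) {
    warning(overflow, " frame(s) outside the grid were excluded", call. = FALSE)
  }
  flat <- rep(NA_integer_, n)
  flat[ok] <- if (ndim == 1) idx[ok, 1] else idx[ok, 1] + nb[1] * (idx[ok, 2] - 1L)
  counts <- array(0L, dim = nb)
  dv_mean <- array(0, dim = nb)
  dv_m2 <- array(0, dim = nb)
  samples <- if (retain) vector("list", prod(nb)) else NULL
  for (f in which(ok)) {
    j <- flat[f]
    counts[j] <- counts[j] + 1L
    d <- delta_v[f] - dv_mean[j]
    dv_mean[j] <- dv_mean[j] + d / counts[j]
    dv_m2[j] <- dv_m2[j] + d * (delta_v[f] - dv_mean[j])
    if (retain) samples[[j]] <- c(samples[[j]], delta_v[f])
  }
  structure(list(breaks = breaks, dim = ndim, counts = counts,
                 dv_mean = dv_mean, dv_m2 = dv_m2, samples = samples,
                 overflow = overflow, n_total = sum(counts),
                 frame_bins = flat),
            class = "bin_stats")
}

bin_centers <- function(breaks) lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Reweight binned populations to an unbiased free-energy grid
#'
#' The unbiased probability of bin i is proportional to `N_i * W_i`, where
#' the weight depends on the estimator:
#' \itemize{
#'   \item `none`: `W = 1` (raw boosted populations);
#'   \item `exponential`: \eqn{W = \langle e^{\beta \Delta V} \rangle} over
#'     the retained per-bin samples (exact but noisy);
#'   \item `maclaurin`: \eqn{W = \sum_{j=0}^{K} \beta^j \langle \Delta V^j \rangle / j!};
#'   \item `cumulant2`: \eqn{\ln W = \beta \langle \Delta V \rangle +
#'     \beta^2 \sigma^2_{\Delta V} / 2} — accurate when the per-bin boost
#'     distribution is near-Gaussian (the regime the `sigma_0` cap enforces).
#' }
#' Probabilities are renormalised and converted to
#' \eqn{G_i = -k_B T \ln(p_i / p_{max})}, so the modal bin has G = 0.
#' Empty bins get `G = Inf` until [fill_empty_bins()] is applied.
#'
#' @param bins a [assign_bins()] result
#' @param temperature simulation temperature (K)
#' @param method estimator name
#' @param order Maclaurin truncation order (moments beyond 2 need retained
#'   samples)
#' @return object of class `pmf`
#' @export
reweight_pmf <- function(bins, temperature = 300,
                         method = c("cumulant2", "none", "exponential", "maclaurin"),
                         order = 2) {
  stopifnot(inherits(bins, "bin_stats"))
  method <- match.arg(method)
  if (sum(bins$counts) < 1) stop("no populated bins to reweight")
  beta <- 1 / (KB_KCAL * temperature)
  nb <- dim(bins$counts)
  pop <- bins$counts > 0
  dv_var <- array(0, dim = nb)
  dv_var[pop] <- bins$dv_m2[pop] / bins$counts[pop]

  logw <- array(0, dim = nb)
  if (method == "exponential") {
    if (is.null(bins$samples)) {
      stop("exponential estimator needs retained samples (assign_bins(retain = TRUE))")
    }
    for (j in which(pop)) {
      s <- bins$samples[[j]]
      logw[j] <- log_sum_exp(beta * s) - log(length(s))
    }
  } else if (method == "cumulant2") {
    if (!is.null(bins$samples)) {
      all_dv <- unlist(bins$samples)
      if (length(all_dv) >= 100 && stats::sd(all_dv) > 1e-12) {
        gam <- anharmonicity(all_dv)
        if (gam > 0.1) {
          warning("boost-energy anharmonicity gamma = ", round(gam, 3),
                  " > 0.1: cumulant reweighting may be inaccurate",
                  call. = FALSE)
        }
      }
    }
    logw[pop] <- beta * bins$dv_mean[pop] + beta^2 * dv_var[pop] / 2
  } else if (method == "maclaurin") {
    if (order > 2 && is.null(bins$samples)) {
      stop("maclaurin order > 2 needs retained samples")
    }
    for (j in which(pop)) {
      mom <- if (!is.null(bins$samples)) {
        vapply(0:order, function(p) mean(bins$samples[[j]]^p), numeric(1))
      } else {
        c(1, bins$dv_mean[j], dv_var[j] + bins$dv_mean[j]^2)[1:(order + 1)]
      }
      logw[j] <- log(sum(beta^(0:order) * mom / factorial(0:order)))
    }
  }
  logp <- array(-Inf, dim = nb)
  logp[pop] <- log(bins$counts[pop]) + logw[pop]
  logp <- logp - log_sum_exp(logp[pop])  # normalise over populated bins
  G <- array(Inf, dim = nb)
  G[pop] <- -KB_KCAL * temperature * (logp[pop] - max(logp[pop]))
  structure(list(breaks = bins$breaks, centers = bin_centers(bins$breaks),
                 dim = bins$dim, G = G, counts = bins$counts,
                 probability = exp(logp),
                 artificial = array(FALSE, dim = nb),
                 temperature = temperature, method = method,
                 n_total = bins$n_total),
            class = "pmf")
}

#' Fill unpopulated bins with an artificial barrier
#'
#' Empty bins are set to the level of the least-probable populated bin (the
#' maximum finite G) and flagged `artificial`, so that landscape plots and
#' valley detection see a barrier rather than a hole.  Populated bins are
#' unchanged.
#'
#' @param pmf a [reweight_pmf()] result
#' @export
fill_empty_bins <- function(pmf) {
  stopifnot(inherits(pmf, "pmf"))
  empty <- pmf$counts == 0
  if (!any(empty)) return(pmf)
  g_fill <- max(pmf$G[!empty])
  pmf$G[empty] <- g_fill
  pmf$artificial[empty] <- TRUE
  pmf
}

#' @export
print.pmf <- function(x, ...) {
  cat(sprintf("pmf: %s grid, %d frames, method = %s, T = %g K\n",
              paste(dim(x$G), collapse = " x "), x$n_total, x$method,
              x$temperature))
  invisible(x)
}

#' Long-format table of a PMF grid
#' @param x a `pmf`
#' @param ... unused
#' @export
as.data.frame.pmf <- function(x, ...) {
  if (x$dim == 1) {
    data.frame(rc1_center = x$centers[[1]], G = as.vector(x$G),
               count = as.vector(x$counts),
               artificial = as.vector(x$artificial))
  } else {
    grid <- expand.grid(rc1_center = x$centers[[1]], rc2_center = x$centers[[2]])
    data.frame(grid, G = as.vector(x$G), count = as.vector(x$counts),
               artificial = as.vector(x$artificial))
  }
}
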