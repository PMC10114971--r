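# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute force, direct summation, enumeration.

# central-difference gradient of a scalar function of a vector
numerical_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

euler_rotation <- function(a, b, c) {
  Rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))
  Ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# brute-force best-fit RMSD: coarse Euler-angle grid plus Nelder-Mead
# refinement; translation handled by centering
brute_force_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 7)[-7]
  best <- NULL
  for (a in grid) for (b in seq(0, pi, length.out = 4)) for (c in grid) {
    v <- obj(c(a, b, c))
    if (is.null(best) || v < best$value) best <- list(par = c(a, b, c), value = v)
  }
  for (i in 1:3) {
    best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 5000))
  }
  best$value
}

# two-pass per-bin variance (plain textbook formula)
two_pass_bin_stats <- function(x, bin_idx, nb) {
  out <- data.frame(count = integer(nb), mean = NA_real_, var = NA_real_)
  for (j in seq_len(nb)) {
    v <- x[bin_idx == j]
    out$count[j] <- length(v)
    if (length(v) >= 1) {
      out$mean[j] <- mean(v)
      out$var[j] <- mean((v - mean(v))^2)
    }
  }
  out
}

# exhaustive minimax path value between two cells of a small grid
# (depth-first enumeration over simple paths, 8-connected)
brute_force_minimax <- function(G, from, to) {
  nx <- nrow(G); ny <- ncol(G)
  best <- Inf
  visited <- matrix(FALSE, nx, ny)
  rec <- function(i, j, cur) {
    cur <- max(cur, G[i, j])
    if (cur >= best) return()
    if (i == to[1] && j == to[2]) {
      best <<- min(best, cur)
      return()
    }
    visited[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
      if (visited[ii, jj] || !is.finite(G[ii, jj])) next
      rec(ii, jj, cur)
    }
    visited[i, j] <<- FALSE
  }
  rec(from[1], from[2], -Inf)
  best
}

# brute-force hydrogen-bond scan over all donor/acceptor pairs using only
# base R, mirroring the strict distance/angle thresholds
brute_force_hbonds <- function(coords, donors, acceptors, max_d = 3.5,
                               min_ang = 120) {
  hits <- character(0)
  for (r in seq_len(nrow(donors))) {
    di <- donors[r, 1]; hi <- donors[r, 2]
    for (ai in acceptors) {
      if (ai %in% c(di, hi)) next
      dda <- sqrt(sum((coords[di, ] - coords[ai, ])^2))
      if (!(dda < max_d)) next
      v1 <- coords[di, ] - coords[hi, ]
      v2 <- coords[ai, ] - coords[hi, ]
      ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (ang > min_ang) hits <- c(hits, paste(di, hi, ai))
    }
  }
  hits
}

# analytic bin-integrated Boltzmann PMF for a 1D potential
analytic_bin_pmf <- function(U, edges, temperature = 300) {
  beta <- 1 / (boostmd::KB_KCAL * temperature)
  g <- vapply(seq_len(length(edges) - 1), function(i) {
    -log(stats::integrate(function(z) exp(-beta * U(z)),
                          edges[i], edges[i + 1])$value) / beta
  }, numeric(1))
  g - min(g)
}
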