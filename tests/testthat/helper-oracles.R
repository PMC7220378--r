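# Independent brute-force oracles used across tests. These deliberately use
# naive loops / full enumeration, separate from the package's code paths.

# exact two-tailed Wilcoxon signed-rank p by enumerating all 2^n sign patterns
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p_ge <- mean(vs >= v_obs)
  p_le <- mean(vs <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Pearson r by direct summation
direct_pearson_r <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# percentile by explicit order statistics and index (n-1)*q/100
sort_index_percentile <- function(v, q) {
  s <- sort(v)
  h <- (length(v) - 1) * q / 100
  lo <- floor(h); hi <- ceiling(h)
  s[lo + 1] + (h - lo) * (s[hi + 1] - s[lo + 1])
}

# point-to-polygon-boundary distance by looping over every segment
loop_segment_distance <- function(px, py, poly) {
  n <- nrow(poly)
  best <- Inf
  for (s in seq_len(n)) {
    x1 <- poly$x_nm[s]; y1 <- poly$y_nm[s]
    s2 <- if (s == n) 1 else s + 1
    x2 <- poly$x_nm[s2]; y2 <- poly$y_nm[s2]
    L2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (L2 == 0) 0 else
      max(0, min(1, ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / L2))
    d <- sqrt((px - (x1 + t * (x2 - x1)))^2 + (py - (y1 + t * (y2 - y1)))^2)
    best <- min(best, d)
  }
  best
}

# profile fit over a dense grid of decay constants C with a linear solve for
# (A, B) at each C
grid_decay_fit <- function(l, j, n_grid = 2000) {
  profile_best <- function(cs) {
    best_rss <- Inf; best <- NULL
    for (C in cs) {
      e <- exp(-j / C)
      fit <- lm(l ~ e)
      rss <- sum(resid(fit)^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- list(A = unname(coef(fit)[1]), B = unname(coef(fit)[2]),
                     C = C)
      }
    }
    best
  }
  # coarse log-spaced pass, then a fine linear pass around the optimum
  best <- profile_best(exp(seq(log(0.05), log(100), length.out = n_grid)))
  lo <- best$C / 1.1; hi <- best$C * 1.1
  best <- profile_best(seq(lo, hi, length.out = n_grid))
  best$fitted <- best$A + best$B * exp(-j / best$C)
  best
}

# small manual session block with given per-recording encoder free speeds
make_manual_block <- function(free_cm_s, n_rois = 2, n_frames = 300,
                              frame_rate = 30) {
  recordings <- lapply(seq_along(free_cm_s), function(jj) {
    t <- (seq_len(n_frames) - 1) / frame_rate
    list(index = jj,
         condition = if (jj <= length(free_cm_s) / 2) "pre_drug" else
           "post_drug",
         wavelength = 910,
         soma = matrix(100, n_rois, n_frames),
         neuropil = matrix(10, n_rois, n_frames),
         encoder = data.frame(time_s = t,
                              position_cm = free_cm_s[jj] * t))
  })
  structure(list(recordings = recordings, frame_rate = frame_rate,
                 roi_ids = seq_len(n_rois)),
            class = "session_block")
}
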