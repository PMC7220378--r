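#' Generate the deterministic treadmill speed trace
#'
#' Samples the piecewise-linear motorized-treadmill speed profile at the
#' imaging frame rate and returns it together with the exact (closed-form)
#' position integral. Speed is zero during the free-walking segments
#' (the motor is disengaged there; self-paced walking is added separately by
#' the session generator).
#'
#' @param protocol A \code{\link{protocol_params}} object.
#' @return A data frame of class \code{speed_trace} with columns
#'   \code{time_s}, \code{speed_cmps}, \code{position_cm}, one row per frame.
#' @examples
#' tr <- gen_speed_trace(protocol_params())
#' tr$speed_cmps[tr$time_s == 15]   # 10 cm/s plateau
#' @export
gen_speed_trace <- function(protocol = protocol_params()) {
  stopifnot(inherits(protocol, "protocol_params"))
  p <- protocol
  n <- round(p$t_total * p$frame_rate)
  t <- (seq_len(n) - 1) / p$frame_rate
  t_ramp <- p$v_max / p$accel
  t_vmax <- p$t_accel_start + t_ramp
  t_dec_end <- p$t_const_end + t_ramp

  speed <- numeric(n)
  ramp_up <- t >= p$t_accel_start & t < t_vmax
  plateau <- t >= t_vmax & t < p$t_const_end
  ramp_dn <- t >= p$t_const_end & t < t_dec_end
  speed[ramp_up] <- p$accel * (t[ramp_up] - p$t_accel_start)
  speed[plateau] <- p$v_max
  speed[ramp_dn] <- p$v_max - p$accel * (t[ramp_dn] - p$t_const_end)

  # closed-form running integral of the speed profile
  d_ramp <- 0.5 * p$accel * t_ramp^2
  pos <- numeric(n)
  pos[ramp_up] <- 0.5 * p$accel * (t[ramp_up] - p$t_accel_start)^2
  pos[plateau] <- d_ramp + p$v_max * (t[plateau] - t_vmax)
  pos[ramp_dn] <- d_ramp + p$v_max * (p$t_const_end - t_vmax) +
    p$v_max * (t[ramp_dn] - p$t_const_end) -
    0.5 * p$accel * (t[ramp_dn] - p$t_const_end)^2
  after <- t >= t_dec_end
  pos[after] <- 2 * d_ramp + p$v_max * (p$t_const_end - t_vmax)

  out <- data.frame(time_s = t, speed_cmps = speed, position_cm = pos)
  class(out) <- c("speed_trace", "data.frame")
  attr(out, "protocol") <- p
  out
}

#' Generate a synthetic forced-locomotion session block with ground truth
#'
#' Builds raw soma and neuropil fluorescence traces (plus rotary-encoder
#' traces) for \code{n_pre} pre-drug and \code{n_post} post-drug recordings
#' such that, after neuropil correction and rest normalization, each
#' recording's 75th-percentile locomotion fluorescence equals the designed
#' value: pre-drug \code{b_i + f_j}, post-drug \code{b_i + d_i + f_j}, with
#' \code{f_j = decay_A + decay_B * exp(-j / decay_C)} the shared session
#' decay and \code{d_i = effect_slope * (b_i - baseline_mean) + eps_i} the
#' planted drug effect.
#'
#' Neuropil contamination follows \code{soma_observed = soma_true +
#' neuropil_scale * neuropil_observed}, so the standard scaled subtraction
#' with the same factor recovers \code{soma_true} exactly.
#'
#' @param params A \code{\link{loco_gen_params}} object.
#' @param protocol A \code{\link{protocol_params}} object.
#' @param motor_window Maximal-speed analysis window (s, half-open).
#' @return A list with elements \code{block} (a \code{session_block}) and
#'   \code{truth} (designed per-ROI baselines \code{b}, changes \code{d},
#'   designed locomotion-fluorescence matrix \code{L}, resting levels,
#'   decay parameters and the planted frame shift).
#' @export
gen_locomotion_block <- function(params = loco_gen_params(),
                                 protocol = protocol_params(),
                                 motor_window = c(10, 25)) {
  stopifnot(inherits(params, "loco_gen_params"))
  set.seed(params$seed)
  n_rec <- params$n_pre + params$n_post
  n_frames <- round(protocol$t_total * protocol$frame_rate)
  motor_idx <- window_frames(motor_window, protocol$frame_rate, n_frames)

  b <- stats::rnorm(params$n_rois, params$baseline_mean, params$baseline_sd)
  eps <- stats::rnorm(params$n_rois, 0, params$effect_noise_sd)
  d <- params$effect_slope * (b - params$baseline_mean) + eps
  f_rest <- pmax(stats::rnorm(params$n_rois, params$f_rest_mean,
                              params$f_rest_sd), 1)
  j <- seq_len(n_rec)
  decay <- params$decay_A + params$decay_B * exp(-j / params$decay_C)
  condition <- rep(c("pre_drug", "post_drug"),
                   c(params$n_pre, params$n_post))
  L <- outer(b, decay, "+") +
    outer(d, as.numeric(condition == "post_drug"), "*")

  # neuropil baseline and locomotion-locked amplitude per ROI
  npl_base <- 0.5 * f_rest * stats::runif(params$n_rois, 0.8, 1.2)
  npl_amp <- 0.3 * npl_base
  speed <- gen_speed_trace(protocol)
  motor_profile <- speed$speed_cmps / max(speed$speed_cmps)

  # self-paced walking speed during the free segments, constant per recording
  free_speed <- stats::runif(n_rec, 0, 2)
  t_s <- speed$time_s
  free_mask <- t_s < protocol$t_free_end | t_s >= protocol$t_stop

  recordings <- vector("list", n_rec)
  for (jj in j) {
    nr <- params$n_rois
    dff <- if (params$jitter_sd > 0)
      matrix(stats::rnorm(nr * n_frames, 0, params$jitter_sd), nr, n_frames)
    else matrix(0, nr, n_frames)
    jm <- dff[, motor_idx, drop = FALSE]
    if (params$jitter_sd > 0) {
      # re-center each ROI's motorized jitter at its own 75th percentile so
      # the window percentile equals the designed value exactly
      q75 <- apply(jm, 1, stats::quantile, probs = 0.75, names = FALSE)
      jm <- jm - q75
    }
    dff[, motor_idx] <- jm + L[, jj]
    soma_true <- f_rest * (1 + dff)
    neuropil <- npl_base +
      npl_amp %o% motor_profile +
      (params$jitter_sd * npl_base) *
        matrix(stats::rnorm(nr * n_frames), nr, n_frames)
    soma_obs <- soma_true + params$neuropil_scale * neuropil
    vel <- speed$speed_cmps
    vel[free_mask] <- free_speed[jj]
    encoder <- data.frame(time_s = t_s,
                          position_cm = cumsum(vel) / protocol$frame_rate)
    recordings[[jj]] <- list(index = jj, condition = condition[jj],
                             wavelength = 910, soma = soma_obs,
                             neuropil = neuropil, encoder = encoder)
  }

  block <- structure(list(recordings = recordings,
                          frame_rate = protocol$frame_rate,
                          roi_ids = seq_len(params$n_rois)),
                     class = "session_block")
  truth <- list(b = b, d = d, L = L, f_rest = f_rest,
                decay = c(A = params$decay_A, B = params$decay_B,
                          C = params$decay_C),
                shift_px = params$shift_px, condition = condition)
  list(block = block, truth = truth)
}

#' @export
print.session_block <- function(x, ...) {
  n_pre <- sum(vapply(x$recordings, function(r) r$condition == "pre_drug",
                      logical(1)))
  cat("session_block:", length(x$roi_ids), "ROIs,",
      length(x$recordings), "recordings (", n_pre, "pre-drug ),",
      x$frame_rate, "Hz\n")
  invisible(x)
}

#' Generate a pair of ROI label images with a planted rigid translation
#'
#' Places \code{n_rois} non-overlapping rectangular ROIs in image A, then
#' builds image B by translating the whole set by \code{shift_px} and
#' additionally offsetting each ROI along x by \code{perturb_px[i]} pixels,
#' which yields an exactly known overlap-over-union fraction
#' \code{(w - |p|) * h / (2 w h - (w - |p|) * h)} per ROI.
#'
#' @param n_rois Number of ROIs.
#' @param field_px Image dimensions \code{c(nx, ny)} in pixels.
#' @param roi_px ROI rectangle size \code{c(w, h)} in pixels.
#' @param shift_px Planted global translation \code{c(dx, dy)} (image B
#'   content is image A moved by +dx columns, +dy rows).
#' @param perturb_px Integer vector (recycled) of per-ROI extra x offsets in
#'   image B; 0 keeps the ROI shape/overlap identical.
#' @param overlap_threshold Threshold used to mark which truth pairs should
#'   match.
#' @param seed Integer seed (ROI placement jitter).
#' @return A list with \code{image_a}, \code{image_b} (integer label
#'   matrices, rows = y), \code{shift_px} and \code{truth} (per-label
#'   designed overlap ratio and match flag).
#' @export
gen_roi_scene <- function(n_rois, field_px = c(128L, 128L),
                          roi_px = c(8L, 8L), shift_px = c(4L, -3L),
                          perturb_px = 0L, overlap_threshold = 0.3,
                          seed = 1L) {
  set.seed(seed)
  nx <- field_px[1]; ny <- field_px[2]
  w <- roi_px[1]; h <- roi_px[2]
  perturb_px <- as.integer(rep_len(perturb_px, n_rois))
  margin <- max(abs(shift_px)) + max(abs(perturb_px)) + 1L

  # jittered grid placement; cell large enough that perturbed ROIs stay disjoint
  cell <- max(w, h) + 2L * max(abs(perturb_px)) + 3L
  ncol_g <- (nx - 2L * margin) %/% cell
  nrow_g <- (ny - 2L * margin) %/% cell
  if (ncol_g * nrow_g < n_rois)
    stop("field too small for ", n_rois, " ROIs: ROIs would leave the field ",
         "or overlap", call. = FALSE)
  slots <- sample(ncol_g * nrow_g, n_rois)
  gx <- (slots - 1L) %% ncol_g
  gy <- (slots - 1L) %/% ncol_g
  x0 <- margin + gx * cell + sample(0:1, n_rois, replace = TRUE)
  y0 <- margin + gy * cell + sample(0:1, n_rois, replace = TRUE)

  a <- matrix(0L, nrow = ny, ncol = nx)
  b <- matrix(0L, nrow = ny, ncol = nx)
  for (i in seq_len(n_rois)) {
    a[y0[i]:(y0[i] + h - 1L), x0[i]:(x0[i] + w - 1L)] <- i
    xb <- x0[i] + shift_px[1] + perturb_px[i]
    yb <- y0[i] + shift_px[2]
    if (xb < 1L || yb < 1L || xb + w - 1L > nx || yb + h - 1L > ny)
      stop("ROI ", i, " leaves the field after translation", call. = FALSE)
    b[yb:(yb + h - 1L), xb:(xb + w - 1L)] <- i
  }
  ov <- pmax(w - abs(perturb_px), 0L) * h
  ratio <- ov / (2L * w * h - ov)
  truth <- data.frame(label = seq_len(n_rois), ratio = ratio,
                      should_match = ratio >= overlap_threshold)
  list(image_a = a, image_b = b, shift_px = as.integer(shift_px),
       truth = truth)
}

#' Generate a synthetic beam-stimulation peak table with known drug ratio
#'
#' @param params A \code{\link{stim_gen_params}} object.
#' @param frequency_hz,duration_s,compartment Protocol labels attached to
#'   every row.
#' @param control_label,drug_label Condition labels.
#' @return A list with \code{table} (long data frame: cell, condition,
#'   frequency_hz, duration_s, compartment, peak_dff) and \code{truth}
#'   (the exact mean ratio \code{1 / (1 + m)} and the per-cell
#'   drug-insensitive components).
#' @export
gen_stim_dataset <- function(params = stim_gen_params(), frequency_hz = 100,
                             duration_s = 1, compartment = "soma",
                             control_label = "control",
                             drug_label = "drug") {
  stopifnot(inherits(params, "stim_gen_params"))
  set.seed(params$seed)
  mean_a <- params$control_peak_mean / (1 + params$m)
  if (params$control_peak_cv > 0) {
    shape <- 1 / params$control_peak_cv^2
    a <- stats::rgamma(params$n_cells, shape = shape, rate = shape / mean_a)
  } else {
    a <- rep(mean_a, params$n_cells)
  }
  drug <- a
  if (params$peak_noise_sd > 0)
    drug <- drug + stats::rnorm(params$n_cells, 0, params$peak_noise_sd)
  tab <- data.frame(
    cell = rep(seq_len(params$n_cells), 2),
    condition = rep(c(control_label, drug_label), each = params$n_cells),
    frequency_hz = frequency_hz, duration_s = duration_s,
    compartment = compartment,
    peak_dff = c(a * (1 + params$m), drug))
  list(table = tab,
       truth = list(true_ratio = 1 / (1 + params$m), a = a))
}

#' Generate a synthetic immunogold sample around a PSD outline
#'
#' Places gold particles outside the PSD polygon so that the particle counts
#' per 50 nm distance band follow \code{radial_profile} (relative densities
#' per band, converted to expected counts via the exact band areas), or
#' homogeneously over the square field for the \code{"uniform"} profile.
#' Placement within a band is by rejection sampling of the boundary-distance
#' field, i.e. spatially uniform within the band.
#'
#' @param params An \code{\link{em_gen_params}} object.
#' @return A list with \code{sample} (a \code{psd_sample}: polygon +
#'   particle coordinates in nm) and \code{truth} (designed per-band counts,
#'   areas and densities in particles/um^2).
#' @export
gen_em_sample <- function(params = em_gen_params()) {
  stopifnot(inherits(params, "em_gen_params"))
  set.seed(params$seed)
  poly <- params$psd_polygon
  cx <- mean(poly$x_nm); cy <- mean(poly$y_nm)
  E <- params$field_extent
  n <- params$particle_count

  if (identical(params$radial_profile, "uniform")) {
    pts <- data.frame(x_nm = stats::runif(n, cx - E, cx + E),
                      y_nm = stats::runif(n, cy - E, cy + E))
    truth <- list(profile = "uniform",
                  intensity_per_um2 = n / (2 * E / 1000)^2)
  } else {
    dens <- params$radial_profile
    nb <- length(dens)
    edges <- seq(0, by = params$band_width, length.out = nb + 1)
    areas <- vapply(seq_len(nb), function(bidx)
      buffer_area(poly, edges[bidx + 1]) - buffer_area(poly, edges[bidx]),
      numeric(1))
    probs <- dens * areas
    counts <- if (n > 0) as.integer(stats::rmultinom(1, n, probs)) else
      integer(nb)
    pts_list <- vector("list", nb)
    for (bidx in seq_len(nb)) {
      k <- counts[bidx]
      acc_x <- numeric(0); acc_y <- numeric(0)
      while (length(acc_x) < k) {
        m <- max(4L * (k - length(acc_x)), 64L)
        xs <- stats::runif(m, cx - E, cx + E)
        ys <- stats::runif(m, cy - E, cy + E)
        dd <- edge_distance(data.frame(x_nm = xs, y_nm = ys), poly)
        keep <- !dd$inside & dd$distance_nm >= edges[bidx] &
          dd$distance_nm < edges[bidx + 1]
        acc_x <- c(acc_x, xs[keep]); acc_y <- c(acc_y, ys[keep])
      }
      pts_list[[bidx]] <- data.frame(x_nm = acc_x[seq_len(k)],
                                     y_nm = acc_y[seq_len(k)])
    }
    pts <- do.call(rbind, pts_list)
    if (is.null(pts)) pts <- data.frame(x_nm = numeric(0), y_nm = numeric(0))
    truth <- list(profile = dens, counts = counts, areas_nm2 = areas,
                  density_per_um2 = 1e6 * counts / areas, edges_nm = edges)
  }
  sample <- structure(list(psd_polygon = poly, particles = pts),
                      class = "psd_sample")
  list(sample = sample, truth = truth)
}
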