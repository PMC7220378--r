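#' Forced-locomotion treadmill protocol parameters
#'
#' The motorized-treadmill protocol used during awake imaging: the mouse walks
#' freely, then a servo linearly accelerates the treadmill at \code{accel}
#' (10/3 cm/s^2, printed as 3.33) from \code{t_accel_start} until the maximal
#' speed \code{v_max} is reached, holds it constant until \code{t_const_end},
#' decelerates symmetrically to standstill at \code{t_stop}, and releases the
#' wheel for self-paced walking until \code{t_total}.
#'
#' The acceleration is stored exactly as \code{v_max / 3} so that kinematic
#' identities (e.g. the 160 cm motorized distance at defaults) are exact.
#'
#' @param t_free_end End of the initial free-walking baseline (s).
#' @param t_accel_start Motor engagement / acceleration onset (s).
#' @param accel Linear acceleration magnitude (cm/s^2).
#' @param v_max Maximal imposed speed (cm/s).
#' @param t_const_end End of the constant-speed plateau (s).
#' @param t_stop Time of standstill after linear deceleration (s).
#' @param t_total Recording length (s).
#' @param frame_rate Imaging frame rate (Hz).
#' @return An object of class \code{protocol_params}.
#' @export
protocol_params <- function(t_free_end = 6, t_accel_start = 7,
                            accel = 10 / 3, v_max = 10,
                            t_const_end = 23, t_stop = 26, t_total = 40,
                            frame_rate = 30) {
  p <- list(t_free_end = t_free_end, t_accel_start = t_accel_start,
            accel = accel, v_max = v_max, t_const_end = t_const_end,
            t_stop = t_stop, t_total = t_total, frame_rate = frame_rate)
  if (!(t_free_end < t_accel_start && t_accel_start < t_const_end &&
        t_const_end < t_stop && t_stop <= t_total))
    stop("inconsistent protocol times: require t_free_end < t_accel_start < ",
         "t_const_end < t_stop <= t_total", call. = FALSE)
  if (accel <= 0 || v_max <= 0 || frame_rate <= 0)
    stop("accel, v_max and frame_rate must be positive", call. = FALSE)
  t_ramp <- v_max / accel
  if (t_accel_start + t_ramp > t_const_end)
    stop("acceleration ramp does not fit before the constant-speed plateau",
         call. = FALSE)
  if (t_const_end + t_ramp > t_stop + 1e-9)
    stop("deceleration ramp does not fit before t_stop", call. = FALSE)
  structure(p, class = "protocol_params")
}

#' Parameters of the synthetic forced-locomotion session generator
#'
#' Defines the ground truth planted into a synthetic session block: per-ROI
#' pre-drug locomotion fluorescence \code{b_i ~ Normal(baseline_mean,
#' baseline_sd)} (dF/F_rest units), a post-drug change
#' \code{d_i = effect_slope * (b_i - baseline_mean) + eps_i} with
#' \code{eps_i ~ Normal(0, effect_noise_sd)}, and a decay offset
#' \code{decay_A + decay_B * exp(-j / decay_C)} shared across ROIs added to
#' every recording \code{j} (1-based acquisition index across pre and post).
#'
#' @param n_rois Number of ROIs (somata).
#' @param n_pre,n_post Numbers of pre- and post-drug recordings
#'   (\code{n_pre >= 2}, \code{n_post >= 4} so at least one post-drug
#'   recording survives the exclude-first-3 wash-in rule).
#' @param baseline_mean,baseline_sd Mean and SD of the designed pre-drug
#'   locomotion fluorescence (dF/F_rest units); \code{baseline_sd > 0}.
#' @param effect_slope Slope coupling the drug-induced change to the pre-drug
#'   baseline (dimensionless; negative means large responders lose more).
#' @param effect_noise_sd SD of the ROI-level change noise (dF/F_rest units).
#' @param decay_A,decay_B,decay_C Parameters of the shared session decay
#'   \code{A + B exp(-j/C)} in recording-index units; \code{decay_C > 0}.
#' @param neuropil_scale Neuropil contamination factor r: the observed soma
#'   trace is \code{soma_true + r * neuropil_observed}, so the standard
#'   correction with the same r inverts the contamination exactly.
#' @param jitter_sd SD of within-trace noise (dF/F_rest units). The motorized
#'   window noise is re-centered so each recording's 75th percentile equals
#'   its designed value exactly.
#' @param shift_px Integer \code{c(dx, dy)} rigid translation planted between
#'   the pre- and post-drug imaging frames.
#' @param f_rest_mean,f_rest_sd Per-ROI resting fluorescence level (a.u.)
#'   used to map dF/F_rest traces back to raw fluorescence.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class \code{loco_gen_params}.
#' @export
loco_gen_params <- function(n_rois = 313, n_pre = 6, n_post = 11,
                            baseline_mean = 1.28, baseline_sd = 0.60,
                            effect_slope = -0.65, effect_noise_sd = 0.597,
                            decay_A = 0.1, decay_B = 0.5, decay_C = 4,
                            neuropil_scale = 0.7, jitter_sd = 0.05,
                            shift_px = c(4L, -3L),
                            f_rest_mean = 200, f_rest_sd = 30,
                            seed = 1L) {
  if (baseline_sd <= 0) stop("baseline_sd must be > 0", call. = FALSE)
  if (n_pre < 2) stop("n_pre must be >= 2", call. = FALSE)
  if (n_post < 4) stop("n_post must be >= 4 (exclude-first-3 rule)",
                       call. = FALSE)
  if (decay_C <= 0) stop("decay_C must be > 0", call. = FALSE)
  if (neuropil_scale < 0 || neuropil_scale >= 1)
    stop("neuropil_scale must be in [0, 1)", call. = FALSE)
  if (length(shift_px) != 2) stop("shift_px must be length 2", call. = FALSE)
  structure(list(n_rois = n_rois, n_pre = n_pre, n_post = n_post,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 effect_slope = effect_slope,
                 effect_noise_sd = effect_noise_sd,
                 decay_A = decay_A, decay_B = decay_B, decay_C = decay_C,
                 neuropil_scale = neuropil_scale, jitter_sd = jitter_sd,
                 shift_px = as.integer(shift_px),
                 f_rest_mean = f_rest_mean, f_rest_sd = f_rest_sd,
                 seed = as.integer(seed)),
            class = "loco_gen_params")
}

#' Parameters of the synthetic beam-stimulation dataset generator
#'
#' Each cell has a drug-insensitive peak component \code{a_i} drawn from a
#' Gamma distribution with mean \code{control_peak_mean / (1 + m)} and
#' coefficient of variation \code{control_peak_cv}; the control peak is
#' \code{a_i * (1 + m)} and the drug-condition peak is \code{a_i} (plus
#' optional noise), so the true mean drug/control ratio is \code{1 / (1 + m)}.
#'
#' @param n_cells Number of cells.
#' @param control_peak_mean Mean control peak dF/Fo (e.g. 3.47 for the 347%
#'   somatic peaks seen with 1 s, 100 Hz trains).
#' @param control_peak_cv Coefficient of variation of the cell-level peaks.
#' @param m Drug-sensitive component multiplier: drug-sensitive component =
#'   \code{m} times the drug-insensitive one; \code{m >= 0}.
#' @param peak_noise_sd SD of additive noise on the drug-condition peak.
#' @param seed Integer seed.
#' @return An object of class \code{stim_gen_params}.
#' @export
stim_gen_params <- function(n_cells = 20, control_peak_mean = 3.47,
                            control_peak_cv = 0.5, m = 1,
                            peak_noise_sd = 0, seed = 1L) {
  if (m < 0) stop("m must be >= 0", call. = FALSE)
  if (control_peak_mean <= 0)
    stop("control_peak_mean must be > 0", call. = FALSE)
  structure(list(n_cells = n_cells, control_peak_mean = control_peak_mean,
                 control_peak_cv = control_peak_cv, m = m,
                 peak_noise_sd = peak_noise_sd, seed = as.integer(seed)),
            class = "stim_gen_params")
}

#' Parameters of the synthetic immunogold EM sample generator
#'
#' @param psd_polygon Data frame with columns \code{x_nm}, \code{y_nm}: the
#'   closed PSD outline (last vertex need not repeat the first). Defaults to
#'   a 64-gon approximating a circle of radius 100 nm.
#' @param particle_count Total number of gold particles to place.
#' @param radial_profile Either \code{"uniform"} (homogeneous points over the
#'   whole field) or a numeric vector of relative densities (particles per
#'   unit area) for the 50 nm bands covering [0, 250) nm from the PSD edge.
#' @param band_width Width of each distance band (nm).
#' @param field_extent Half-width of the square field around the polygon
#'   centroid (nm).
#' @param seed Integer seed.
#' @return An object of class \code{em_gen_params}.
#' @export
em_gen_params <- function(psd_polygon = circle_polygon(100), particle_count = 400,
                          radial_profile = c(8, 4, 2, 1, 0.5),
                          band_width = 50, field_extent = 500, seed = 1L) {
  if (particle_count < 0) stop("particle_count must be >= 0", call. = FALSE)
  if (!identical(radial_profile, "uniform")) {
    radial_profile <- as.numeric(radial_profile)
    if (any(radial_profile < 0) || all(radial_profile == 0))
      stop("radial_profile densities must be >= 0 with at least one > 0",
           call. = FALSE)
    if (length(radial_profile) * band_width < 250)
      stop("radial_profile bands must cover [0, 250] nm", call. = FALSE)
  }
  structure(list(psd_polygon = as.data.frame(psd_polygon),
                 particle_count = as.integer(particle_count),
                 radial_profile = radial_profile, band_width = band_width,
                 field_extent = field_extent, seed = as.integer(seed)),
            class = "em_gen_params")
}

#' Cross-session ROI matching parameters
#'
#' @param overlap_threshold Minimum overlap-over-union fraction for two ROIs
#'   to be considered the same soma; the comparison is inclusive (at least
#'   30% at the default 0.3).
#' @param max_shift Maximum rigid-translation search radius (px).
#' @return An object of class \code{match_params}.
#' @export
match_params <- function(overlap_threshold = 0.3, max_shift = 10L) {
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    stop("overlap_threshold must be in (0, 1]", call. = FALSE)
  structure(list(overlap_threshold = overlap_threshold,
                 max_shift = as.integer(max_shift)),
            class = "match_params")
}

#' Per-ROI drug-effect test parameters
#'
#' @param exclude_first Number of initial post-drug recordings excluded to
#'   account for drug wash-in (default 3, motivated by a wash-in time
#'   constant of about 5.5 min with recordings every 2-4 min).
#' @param alpha Two-sided significance level for the increase/decrease call.
#' @param test_kind \code{"welch"} (unequal-variance two-sample t-test,
#'   default: pre and post recording counts differ so pairing is undefined)
#'   or \code{"pooled"} for the classical equal-variance variant.
#' @return An object of class \code{drug_test_params}.
#' @export
drug_test_params <- function(exclude_first = 3L, alpha = 0.01,
                             test_kind = c("welch", "pooled")) {
  test_kind <- match.arg(test_kind)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (exclude_first < 0) stop("exclude_first must be >= 0", call. = FALSE)
  structure(list(exclude_first = as.integer(exclude_first), alpha = alpha,
                 test_kind = test_kind),
            class = "drug_test_params")
}

# Half-open time window [start, end) in seconds -> 1-based frame indices.
# Frame f (0-based) covers time f/rate, so the window maps to 0-based frames
# floor(start*rate) .. floor(end*rate)-1.
window_frames <- function(window, frame_rate, n_frames) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(start, end) with end > start", call. = FALSE)
  i0 <- floor(window[1] * frame_rate) + 1L
  i1 <- floor(window[2] * frame_rate)
  i1 <- min(i1, n_frames)
  if (i0 > i1) stop("window maps to no frames", call. = FALSE)
  seq.int(i0, i1)
}
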