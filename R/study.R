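#' Run the full synthetic forced-locomotion study for one seed
#'
#' Generates a session block with a planted drug-effect model plus a matched
#' pre/post ROI mask pair, then runs the complete pipeline: rigid-translation
#' registration, 30%-overlap ROI matching, neuropil correction, rest
#' normalization, 75th-percentile locomotion fluorescence, per-ROI
#' exponential detrending, drug-effect classification, and the
#' change-vs-baseline regression.
#'
#' @param seed Integer seed driving all randomness of this run.
#' @param params A \code{\link{loco_gen_params}} object (its \code{seed}
#'   field is overwritten by \code{seed}).
#' @param field_px Mask image dimensions (512 px at 0.78 um/px spans the
#'   400 x 400 um field of view).
#' @param max_shift Registration search radius (px).
#' @return List with \code{regression} (a \code{regression_result}),
#'   \code{effects}, \code{truth}, the estimated \code{shift} and
#'   \code{n_matched}.
#' @export
synthetic_locomotion_run <- function(seed, params = loco_gen_params(),
                                     field_px = c(512L, 512L),
                                     max_shift = 6L) {
  params$seed <- as.integer(seed)
  gen <- gen_locomotion_block(params)
  scene <- gen_roi_scene(params$n_rois, field_px = field_px,
                         shift_px = params$shift_px,
                         seed = as.integer(seed) + 500000L)
  shift <- estimate_translation(scene$image_a, scene$image_b, max_shift)
  m <- match_rois(scene$image_a, scene$image_b, shift)
  rois <- m$pairs$label_a[m$pairs$matched]
  dffm <- normalize_to_rest(gen$block, select_least_active(gen$block))
  res <- analyze_locomotion(dffm, rois = rois)
  list(regression = res$regression, effects = res$effects,
       truth = gen$truth, shift = shift, n_matched = length(rois))
}

#' Empirical false-positive rate of the per-ROI drug-effect test
#'
#' Null simulation: per ROI, pre- and post-drug locomotion fluorescence
#' values are i.i.d. Normal with no drug effect and no decay; the fraction of
#' ROIs flagged as changed (either direction) at the test's alpha estimates
#' the type-I error of the classification.
#'
#' @param seed Integer seed.
#' @param n_rois Number of simulated ROIs.
#' @param n_pre,n_post Numbers of pre-/post-drug values per ROI.
#' @param sd Common SD of the values.
#' @param test A \code{\link{drug_test_params}} object.
#' @return Fraction of ROIs with a label other than "none".
#' @export
null_classification_rate <- function(seed, n_rois = 1000, n_pre = 8,
                                     n_post = 11, sd = 0.3,
                                     test = drug_test_params()) {
  set.seed(as.integer(seed))
  flagged <- vapply(seq_len(n_rois), function(i) {
    cls <- classify_drug_effect(stats::rnorm(n_pre, 0, sd),
                                stats::rnorm(n_post, 0, sd), test)
    cls$label != "none"
  }, logical(1))
  mean(flagged)
}
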