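#' Locomotion fluorescence of a trace
#'
#' The q-th percentile (linear interpolation between order statistics, index
#' (n-1)q/100) of a dF/F_rest trace within the maximal-speed motorized
#' window. The default 75th percentile emphasizes the high-fluorescence
#' episodes while ignoring transient drops during locomotion.
#'
#' @param trace Numeric dF/F_rest trace.
#' @param window Half-open analysis window in seconds (default [10, 25)).
#' @param q Percentile in (0, 100).
#' @param frame_rate Frames per second.
#' @return Scalar locomotion fluorescence.
#' @export
locomotion_fluorescence <- function(trace, window = c(10, 25), q = 75,
                                    frame_rate = 30) {
  if (q <= 0 || q >= 100) stop("q must be in (0, 100)", call. = FALSE)
  idx <- window_frames(window, frame_rate, length(trace))
  if (length(idx) < 2) stop("window maps to fewer than 2 frames",
                            call. = FALSE)
  stats::quantile(trace[idx], q / 100, names = FALSE, type = 7)
}

#' Fit the shared session decay of locomotion fluorescence
#'
#' Least-squares fit of the single-exponential decay
#' \code{f_j = A + B * exp(-j / C)} to one ROI's pre-drug locomotion
#' fluorescence values, with \code{j} the 1-based recording index in
#' acquisition order (the decay tracks the number of recordings, not wall
#' clock time). If the nonlinear fit fails or fewer than 3 points are
#' available, the fit falls back to a straight line in \code{j} and is
#' flagged.
#'
#' @param l Pre-drug locomotion fluorescence values.
#' @param j Recording indices (default \code{seq_along(l)}).
#' @return An object of class \code{decay_fit} with elements \code{A},
#'   \code{B}, \code{C} (exponential branch), \code{coef} (linear branch),
#'   \code{kind} ("exp", "linear" or "constant") and \code{flag}.
#' @export
fit_decay <- function(l, j = seq_along(l)) {
  if (length(l) < 2) stop("need at least 2 points to fit a decay",
                          call. = FALSE)
  if (stats::var(l) == 0) {
    return(structure(list(A = l[1], B = 0, C = 1, kind = "constant",
                          flag = "degenerate_constant"),
                     class = "decay_fit"))
  }
  fit <- NULL
  if (length(l) >= 3) {
    c0 <- max(diff(range(j)) / 3, 0.5)
    start <- list(A = l[length(l)], B = l[1] - l[length(l)], C = c0)
    fit <- tryCatch(
      minpack.lm::nlsLM(l ~ A + B * exp(-j / C), start = start,
                        lower = c(-Inf, -Inf, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(structure(list(A = unname(cf["A"]), B = unname(cf["B"]),
                          C = unname(cf["C"]), kind = "exp", flag = NULL),
                     class = "decay_fit"))
  }
  lin <- stats::lm(l ~ j)
  structure(list(coef = stats::coef(lin), kind = "linear",
                 flag = "linear_fallback"),
            class = "decay_fit")
}

#' Evaluate a fitted decay at recording indices
#' @param object A \code{decay_fit}.
#' @param j Recording indices.
#' @param ... Unused.
#' @return Fitted decay values f_j.
#' @export
predict.decay_fit <- function(object, j, ...) {
  switch(object$kind,
         exp = object$A + object$B * exp(-j / object$C),
         constant = rep(object$A, length(j)),
         linear = unname(object$coef[1] + object$coef[2] * j))
}

#' Subtract a fitted pre-drug decay from all recordings
#'
#' \code{L'_j = L_j - f_j} for every recording, pre- AND post-drug: this
#' normalizes the pre-drug locomotion fluorescence to about zero and exposes
#' drug-induced change beyond the shared session decay.
#'
#' @param l Locomotion fluorescence values.
#' @param j Recording indices corresponding to \code{l}.
#' @param fit A \code{decay_fit} from the same ROI's pre-drug points.
#' @return Detrended values.
#' @export
detrend_values <- function(l, j, fit) {
  l - predict(fit, j)
}

#' Classify a per-ROI drug effect
#'
#' Two-sided two-sample t-test (Welch by default) comparing detrended
#' pre-drug locomotion fluorescence against detrended post-drug values after
#' dropping the first \code{exclude_first} post-drug recordings (drug
#' wash-in). Labels: \code{increase}/\code{decrease} if p < alpha with the
#' corresponding sign of the mean difference, else \code{none}.
#'
#' @param pre_values Detrended pre-drug values.
#' @param post_values Detrended post-drug values in acquisition order
#'   (the wash-in exclusion is applied here).
#' @param params A \code{\link{drug_test_params}} object.
#' @return List with \code{p}, \code{label}, \code{mean_pre},
#'   \code{mean_post} and \code{flag} (NULL, "too_few_recordings" or
#'   "zero_variance").
#' @export
classify_drug_effect <- function(pre_values, post_values,
                                 params = drug_test_params()) {
  post <- post_values[-seq_len(min(params$exclude_first,
                                   length(post_values)))]
  if (params$exclude_first == 0) post <- post_values
  if (length(pre_values) < 2 || length(post) < 2)
    return(list(p = NA_real_, label = "none",
                mean_pre = mean(pre_values), mean_post = mean(post),
                flag = "too_few_recordings"))
  m_pre <- mean(pre_values); m_post <- mean(post)
  p <- tryCatch({
    flag <- NULL
    stats::t.test(post, pre_values,
                  var.equal = params$test_kind == "pooled")$p.value
  }, error = function(e) {
    # variance (essentially) zero on both sides: decide by the means alone
    flag <<- "zero_variance"
    if (isTRUE(all.equal(m_pre, m_post))) 1 else 0
  })
  label <- if (!is.na(p) && p < params$alpha) {
    if (m_post > m_pre) "increase" else "decrease"
  } else "none"
  list(p = p, label = label, mean_pre = m_pre, mean_post = m_post,
       flag = flag)
}

#' Linear regression of drug-induced change on pre-drug baseline
#'
#' Ordinary least squares of the per-ROI change in locomotion fluorescence
#' (mean detrended post-drug value) on the pre-drug baseline (mean raw
#' pre-drug locomotion fluorescence), with the Pearson correlation, the
#' variance explained R^2 = r^2 and the two-sided p-value for r.
#'
#' @param table Data frame with columns \code{baseline} and \code{change}
#'   (one row per ROI), e.g. the \code{effects} table from
#'   \code{\link{analyze_locomotion}}.
#' @return List of class \code{regression_result}: \code{slope},
#'   \code{intercept}, \code{r}, \code{r_squared}, \code{p}, \code{n}.
#' @export
regress_change_vs_baseline <- function(table) {
  x <- table$baseline; y <- table$change
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 ROIs for the regression",
                          call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in the baseline: regression undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p = ct$p.value, n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "change vs baseline: r = %.3f (R^2 = %.3f, p = %.3g, n = %d)\n",
    x$r, x$r_squared, x$p, x$n))
  cat(sprintf("  slope = %.3f, intercept = %.3f\n", x$slope, x$intercept))
  invisible(x)
}

#' Movement-artifact ratios between 820 nm and 910 nm runs
#'
#' GCaMP fluorescence at 820 nm excitation is calcium-insensitive, so the
#' ratio of a locomotion-window statistic (SD or 75th percentile of
#' dF/F_rest) between matched 820 nm and 910 nm runs bounds the fraction of
#' the signal attributable to movement artifacts.
#'
#' @param metric_820,metric_910 Per-ROI statistics from the 820 nm and
#'   910 nm runs, aligned by ROI matching.
#' @return List with \code{ratio} (per ROI; NA where the 910 nm metric is 0,
#'   flagged), \code{mean}, \code{sem}, \code{n}, \code{flagged} (indices of
#'   undefined ratios).
#' @export
artifact_ratio <- function(metric_820, metric_910) {
  if (length(metric_820) != length(metric_910))
    stop("metric vectors differ in length", call. = FALSE)
  undef <- metric_910 == 0
  ratio <- ifelse(undef, NA_real_, metric_820 / metric_910)
  if (any(undef)) warning("zero 910 nm metric for ", sum(undef),
                          " ROI(s): ratio undefined")
  ok <- ratio[!is.na(ratio)]
  list(ratio = ratio, mean = mean(ok),
       sem = stats::sd(ok) / sqrt(length(ok)), n = length(ok),
       flagged = which(undef))
}

#' Run the locomotion drug-effect analysis on a normalized session block
#'
#' Computes per-ROI, per-recording locomotion fluorescence, fits and
#' subtracts the per-ROI pre-drug exponential decay, classifies each ROI's
#' drug effect, and regresses the change on the pre-drug baseline.
#'
#' @param dffm A \code{dff_matrix} from \code{\link{normalize_to_rest}}.
#' @param rois Optional integer vector restricting analysis to a subset of
#'   ROIs (e.g. those matched across sessions); defaults to all
#'   non-degenerate ROIs.
#' @param window,q Locomotion window (s) and percentile.
#' @param test A \code{\link{drug_test_params}} object.
#' @return List with \code{summary} (long data frame: roi, recording,
#'   condition, L, L_detrended), \code{effects} (per ROI: baseline, change,
#'   p, label, fit_flag, test_flag) and \code{regression}
#'   (a \code{regression_result}).
#' @export
analyze_locomotion <- function(dffm, rois = NULL, window = c(10, 25),
                               q = 75, test = drug_test_params()) {
  stopifnot(inherits(dffm, "dff_matrix"))
  if (is.null(rois)) rois <- which(!dffm$degenerate)
  n_rec <- length(dffm$dff)
  pre <- which(dffm$condition == "pre_drug")
  post <- which(dffm$condition == "post_drug")
  j <- dffm$index

  L <- vapply(dffm$dff, function(m)
    apply(m[rois, , drop = FALSE], 1, locomotion_fluorescence,
          window = window, q = q, frame_rate = dffm$frame_rate),
    numeric(length(rois)))
  L <- matrix(L, nrow = length(rois))

  Ld <- matrix(NA_real_, nrow(L), ncol(L))
  eff <- data.frame(roi = dffm$roi_ids[rois], baseline = NA_real_,
                    change = NA_real_, p = NA_real_, label = "none",
                    fit_flag = NA_character_, test_flag = NA_character_,
                    stringsAsFactors = FALSE)
  keep_post <- post[-seq_len(min(test$exclude_first, length(post)))]
  if (test$exclude_first == 0) keep_post <- post
  for (i in seq_len(nrow(L))) {
    fit <- fit_decay(L[i, pre], j[pre])
    Ld[i, ] <- detrend_values(L[i, ], j, fit)
    cls <- classify_drug_effect(Ld[i, pre], Ld[i, post], test)
    eff$baseline[i] <- mean(L[i, pre])
    eff$change[i] <- mean(Ld[i, keep_post])
    eff$p[i] <- cls$p
    eff$label[i] <- cls$label
    eff$fit_flag[i] <- if (is.null(fit$flag)) NA_character_ else fit$flag
    eff$test_flag[i] <- if (is.null(cls$flag)) NA_character_ else cls$flag
  }

  summary <- data.frame(
    roi = rep(dffm$roi_ids[rois], n_rec),
    recording = rep(j, each = length(rois)),
    condition = rep(dffm$condition, each = length(rois)),
    L = as.vector(L), L_detrended = as.vector(Ld))
  list(summary = summary, effects = eff,
       regression = regress_change_vs_baseline(eff))
}
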