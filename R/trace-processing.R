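#' Estimate the background fluorescence trace from a frame stack
#'
#' Background Fb(t) is the per-frame mean over the \code{n_low} pixels with
#' the lowest value on the time-averaged image (typically 20-30 pixels).
#' Selecting on the time average rather than frame-by-frame keeps the pixel
#' set fixed across the sequence.
#'
#' @param frame_stack 3-D numeric array (y, x, frame).
#' @param n_low Number of darkest pixels to average (default 25).
#' @return Numeric vector Fb(t), one value per frame.
#' @export
estimate_background <- function(frame_stack, n_low = 25L) {
  if (!is.array(frame_stack) || length(dim(frame_stack)) != 3 ||
      any(dim(frame_stack) == 0))
    stop("frame_stack must be a non-empty 3-D array (y, x, frame)",
         call. = FALSE)
  n_px <- prod(dim(frame_stack)[1:2])
  if (n_low > n_px) stop("n_low exceeds pixel count", call. = FALSE)
  avg <- rowMeans(matrix(frame_stack, nrow = n_px))
  sel <- order(avg)[seq_len(n_low)]
  colMeans(matrix(frame_stack, nrow = n_px)[sel, , drop = FALSE])
}

#' Compute a dF/Fo trace
#'
#' \code{(F(t) - Fo) / (Fo - FB)} where Fo and FB are the means of the ROI
#' trace and the background trace over the pre-stimulus window. A value of
#' 1.0 corresponds to a 100% fluorescence change over baseline.
#'
#' @param f Numeric ROI fluorescence trace F(t) (a.u.).
#' @param prestim_window Half-open pre-stimulus window \code{c(start, end)}
#'   in seconds.
#' @param fb Background trace Fb(t), same length as \code{f} (or a scalar).
#' @param frame_rate Frames per second.
#' @return Numeric dF/Fo trace with attributes \code{Fo} and \code{FB}.
#' @export
compute_dff <- function(f, prestim_window, fb, frame_rate) {
  if (length(fb) == 1) fb <- rep(fb, length(f))
  if (length(fb) != length(f))
    stop("F and Fb traces must have equal length", call. = FALSE)
  idx <- window_frames(prestim_window, frame_rate, length(f))
  fo <- mean(f[idx]); fbb <- mean(fb[idx])
  if (fo <= fbb)
    stop("degenerate baseline: Fo (", signif(fo, 6), ") <= FB (",
         signif(fbb, 6), ")", call. = FALSE)
  out <- (f - fo) / (fo - fbb)
  attr(out, "Fo") <- fo
  attr(out, "FB") <- fbb
  out
}

#' Neuropil compensation by scaled subtraction
#'
#' \code{F = F_MLI - r * F_Neuropil}, elementwise, with the standard
#' contamination factor r = 0.7.
#'
#' @param f_mli Somatic ROI trace (vector) or ROI-by-frame matrix.
#' @param f_neuropil Surrounding-neuropil trace, same shape.
#' @param r Contamination scale in [0, 1).
#' @return Corrected trace(s), same shape as the input.
#' @export
neuropil_correct <- function(f_mli, f_neuropil, r = 0.7) {
  if (!identical(dim(f_mli), dim(f_neuropil)) ||
      length(f_mli) != length(f_neuropil))
    stop("soma and neuropil traces differ in shape", call. = FALSE)
  if (r < 0 || r >= 1) stop("r must be in [0, 1)", call. = FALSE)
  f_mli - r * f_neuropil
}

#' Select the recording with the least active baseline period
#'
#' Scans the rotary-encoder traces of a session block and returns the index
#' of the recording with the smallest total absolute distance traveled in
#' the baseline window (ties broken by the lowest recording index). Its
#' quiet baseline defines F_rest for the whole block.
#'
#' @param block A \code{session_block}.
#' @param window Baseline window in seconds, half-open (default [0, 5)).
#' @return Integer recording index k.
#' @export
select_least_active <- function(block, window = c(0, 5)) {
  stopifnot(inherits(block, "session_block"))
  dist <- vapply(block$recordings, function(rec) {
    if (is.null(rec$encoder))
      stop("recording ", rec$index, " has no encoder trace", call. = FALSE)
    enc <- rec$encoder
    keep <- enc$time_s >= window[1] & enc$time_s < window[2]
    sum(abs(diff(enc$position_cm[keep])))
  }, numeric(1))
  which.min(dist) # which.min returns the first (lowest-index) minimum
}

#' Normalize a session block to resting fluorescence
#'
#' Per ROI, F_rest is the mean of the neuropil-corrected soma trace of the
#' least-active recording \code{k} over the baseline window; every recording
#' (pre- and post-drug) is then normalized as
#' \code{dF/F_rest = (F - F_rest) / F_rest} with that single F_rest.
#'
#' @param block A \code{session_block} with raw soma + neuropil traces.
#' @param k Index of the least-active recording (see
#'   \code{\link{select_least_active}}).
#' @param window Baseline window in seconds (half-open).
#' @param r Neuropil contamination scale (default 0.7).
#' @return A \code{dff_matrix}: list with \code{dff} (list of ROI-by-frame
#'   matrices per recording), per-recording \code{condition} and
#'   \code{index}, \code{f_rest} per ROI, \code{frame_rate}, and a logical
#'   \code{degenerate} flag per ROI (F_rest <= 0; such ROIs get NA traces
#'   rather than being silently dropped).
#' @export
normalize_to_rest <- function(block, k = select_least_active(block),
                              window = c(0, 5), r = 0.7) {
  stopifnot(inherits(block, "session_block"))
  if (k < 1 || k > length(block$recordings))
    stop("invalid recording index k", call. = FALSE)
  corrected <- lapply(block$recordings, function(rec)
    neuropil_correct(rec$soma, rec$neuropil, r))
  n_frames <- ncol(corrected[[k]])
  idx <- window_frames(window, block$frame_rate, n_frames)
  f_rest <- rowMeans(corrected[[k]][, idx, drop = FALSE])
  degenerate <- f_rest <= 0
  if (any(degenerate))
    warning("degenerate baseline (F_rest <= 0) for ROI(s) ",
            paste(block$roi_ids[degenerate], collapse = ", "))
  dff <- lapply(corrected, function(m) {
    out <- (m - f_rest) / f_rest
    out[degenerate, ] <- NA_real_
    out
  })
  structure(list(dff = dff,
                 condition = vapply(block$recordings, `[[`, "", "condition"),
                 index = vapply(block$recordings, function(rec)
                   as.integer(rec$index), integer(1)),
                 f_rest = f_rest, degenerate = degenerate,
                 roi_ids = block$roi_ids, frame_rate = block$frame_rate),
            class = "dff_matrix")
}

#' @export
print.dff_matrix <- function(x, ...) {
  cat("dff_matrix:", length(x$f_rest), "ROIs,", length(x$dff),
      "recordings (", sum(x$condition == "pre_drug"), "pre-drug ),",
      sum(x$degenerate), "degenerate\n")
  invisible(x)
}
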