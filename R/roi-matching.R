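#' Estimate a rigid integer-pixel translation between two images
#'
#' Exhaustive search over shifts within \code{max_shift} for the shift
#' maximizing the zero-mean cross-correlation over the overlapping region
#' (both images are centered by their overlap means before the product).
#' Ties are broken by the smallest |dx| + |dy|, then lexicographically by
#' (dx, dy). Needed because drug application requires removing the objective,
#' which moves the stage between the pre- and post-drug sessions.
#'
#' @param image_a,image_b Numeric matrices of equal dimensions
#'   (rows = y, columns = x); label images are binarized internally.
#' @param max_shift Search radius in pixels.
#' @param binarize If \code{TRUE} (default) compare \code{image > 0} masks,
#'   appropriate for label images.
#' @return Integer vector \code{c(dx, dy)} such that image B content equals
#'   image A content moved by +dx columns and +dy rows.
#' @export
estimate_translation <- function(image_a, image_b, max_shift = 10L,
                                 binarize = TRUE) {
  if (!identical(dim(image_a), dim(image_b)))
    stop("images differ in dimensions", call. = FALSE)
  a <- if (binarize) (image_a > 0) * 1 else image_a * 1
  b <- if (binarize) (image_b > 0) * 1 else image_b * 1
  if (stats::var(as.vector(a)) == 0 || stats::var(as.vector(b)) == 0)
    stop("flat (zero-variance) image: translation cannot be estimated",
         call. = FALSE)
  ny <- nrow(a); nx <- ncol(a)
  shifts <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  score <- numeric(nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    dx <- shifts$dx[s]; dy <- shifts$dy[s]
    ax <- max(1, 1 + dx):min(nx, nx + dx)   # columns of A visible in B
    ay <- max(1, 1 + dy):min(ny, ny + dy)
    sub_a <- a[ay - dy, ax - dx, drop = FALSE]
    sub_b <- b[ay, ax, drop = FALSE]
    score[s] <- sum((sub_a - mean(sub_a)) * (sub_b - mean(sub_b)))
  }
  best <- max(score)
  cand <- which(score >= best - 1e-12 * abs(best))
  l1 <- abs(shifts$dx[cand]) + abs(shifts$dy[cand])
  cand <- cand[order(l1, shifts$dx[cand], shifts$dy[cand])]
  c(dx = shifts$dx[cand[1]], dy = shifts$dy[cand[1]])
}

#' Overlap-over-union of two binary masks
#'
#' \code{|a intersect b| / |a union b|}: 0 for disjoint masks, 1 for
#' identical masks. Two cross-session ROIs are considered the same soma if
#' this fraction is at least the matching threshold (0.3 by default).
#'
#' @param mask_a,mask_b Logical matrices in a common frame (apply any shift
#'   before calling).
#' @return Overlap fraction in [0, 1]; 0 with a warning if a mask is empty.
#' @export
overlap_ratio <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks differ in dimensions", call. = FALSE)
  if (!any(mask_a) || !any(mask_b)) {
    warning("empty mask: overlap ratio defined as 0")
    return(0)
  }
  sum(mask_a & mask_b) / sum(mask_a | mask_b)
}

#' Translate a label image by an integer shift
#'
#' Content moves by +dx columns and +dy rows; pixels shifted in from outside
#' are background (0).
#'
#' @param labels Integer label matrix (rows = y).
#' @param shift Integer \code{c(dx, dy)}.
#' @return Shifted label matrix, same dimensions.
#' @export
shift_labels <- function(labels, shift) {
  dx <- as.integer(shift[1]); dy <- as.integer(shift[2])
  ny <- nrow(labels); nx <- ncol(labels)
  out <- matrix(0L, ny, nx)
  sx <- max(1, 1 + dx):min(nx, nx + dx)
  sy <- max(1, 1 + dy):min(ny, ny + dy)
  out[sy, sx] <- labels[sy - dy, sx - dx]
  out
}

#' Match ROIs across sessions by the overlap criterion
#'
#' Aligns session B's label image to session A's frame using the supplied
#' rigid translation, computes overlap-over-union for every touching label
#' pair, and greedily accepts pairs in descending ratio (ties by the smaller
#' label pair), each ROI appearing in at most one accepted pair. A pair is
#' accepted if its ratio is at least \code{params$overlap_threshold}
#' (inclusive: "at least 30%").
#'
#' @param set_a,set_b Integer label matrices (0 = background).
#' @param shift Integer \code{c(dx, dy)} mapping A's frame onto B's (as
#'   returned by \code{\link{estimate_translation}}); B is shifted by
#'   \code{-shift} before comparison.
#' @param params A \code{\link{match_params}} object.
#' @return A list with \code{pairs} (data frame: label_a, label_b, ratio,
#'   matched logical — candidates above threshold that lost the one-to-one
#'   assignment are kept with \code{matched = FALSE}) and
#'   \code{unmatched_a}, \code{unmatched_b} (label vectors).
#' @export
match_rois <- function(set_a, set_b, shift = c(0L, 0L),
                       params = match_params()) {
  b_aligned <- shift_labels(set_b, -as.integer(shift))
  labs_a <- sort(unique(set_a[set_a > 0]))
  labs_b <- sort(unique(set_b[set_b > 0]))
  area_a <- table(factor(set_a[set_a > 0], levels = labs_a))
  area_b <- table(factor(b_aligned[b_aligned > 0], levels = labs_b))

  both <- set_a > 0 & b_aligned > 0
  if (!any(both)) {
    pairs <- data.frame(label_a = integer(0), label_b = integer(0),
                        ratio = numeric(0), matched = logical(0))
    return(list(pairs = pairs, unmatched_a = labs_a, unmatched_b = labs_b))
  }
  inter <- table(a = factor(set_a[both], levels = labs_a),
                 b = factor(b_aligned[both], levels = labs_b))
  idx <- which(inter > 0, arr.ind = TRUE)
  la <- labs_a[idx[, 1]]; lb <- labs_b[idx[, 2]]
  ov <- inter[idx]
  ratio <- as.numeric(ov) /
    (as.numeric(area_a[idx[, 1]]) + as.numeric(area_b[idx[, 2]]) -
       as.numeric(ov))
  cand <- data.frame(label_a = la, label_b = lb, ratio = ratio)
  cand <- cand[cand$ratio >= params$overlap_threshold, , drop = FALSE]
  cand <- cand[order(-cand$ratio, cand$label_a, cand$label_b), , drop = FALSE]

  used_a <- integer(0); used_b <- integer(0); matched <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$label_a[i] %in% used_a) && !(cand$label_b[i] %in% used_b)) {
      matched[i] <- TRUE
      used_a <- c(used_a, cand$label_a[i])
      used_b <- c(used_b, cand$label_b[i])
    }
  }
  cand$matched <- matched
  rownames(cand) <- NULL
  list(pairs = cand,
       unmatched_a = setdiff(labs_a, cand$label_a[matched]),
       unmatched_b = setdiff(labs_b, cand$label_b[matched]))
}
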