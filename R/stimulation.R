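#' Peak dF/Fo response in a window
#'
#' Maximum of the dF/Fo trace within the half-open response window starting
#' at stimulus onset. The peak is taken on the raw trace; set
#' \code{smooth_frames > 1} for an optional moving-average before the max.
#'
#' @param trace Numeric dF/Fo trace.
#' @param response_window Half-open window in seconds.
#' @param frame_rate Frames per second.
#' @param smooth_frames Moving-average width in frames (1 = off, default).
#' @return Peak dF/Fo.
#' @export
peak_response <- function(trace, response_window, frame_rate,
                          smooth_frames = 1L) {
  idx <- window_frames(response_window, frame_rate, length(trace))
  x <- trace
  if (smooth_frames > 1)
    x <- stats::filter(x, rep(1 / smooth_frames, smooth_frames),
                       sides = 2)
  max(x[idx], na.rm = TRUE)
}

#' Two-tailed Wilcoxon signed-rank p-value
#'
#' Exact signed-rank distribution for n <= 25 non-zero untied differences;
#' normal approximation with tie correction otherwise. Zero differences are
#' dropped before ranking (standard signed-rank convention) and reported in
#' the \code{n_zero} attribute; if all differences are zero the p-value is 1
#' with a flag.
#'
#' @param differences Numeric paired differences.
#' @return p-value with attributes \code{n_used}, \code{n_zero} and
#'   \code{flag} (NULL or "all_zero").
#' @export
wilcoxon_signed_p <- function(differences) {
  d <- differences[!is.na(differences)]
  nz <- d[d != 0]
  n_zero <- length(d) - length(nz)
  if (length(nz) == 0) {
    p <- 1
    attr(p, "n_used") <- 0L
    attr(p, "n_zero") <- n_zero
    attr(p, "flag") <- "all_zero"
    return(p)
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  p <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = exact,
                       correct = !exact)$p.value)
  attr(p, "n_used") <- length(nz)
  attr(p, "n_zero") <- n_zero
  attr(p, "flag") <- NULL
  p
}

#' Drug/control ratio summary of peak responses
#'
#' Per cell, the ratio of the drug-condition peak to the control peak;
#' summarized per protocol group (duration, frequency, compartment) as
#' mean +/- sem with a two-tailed Wilcoxon signed-rank test of the paired
#' peaks (drug minus control).
#'
#' @param table Long data frame with columns \code{cell}, \code{condition},
#'   \code{frequency_hz}, \code{duration_s}, \code{compartment},
#'   \code{peak_dff}.
#' @param drug_cond,control_cond Condition labels to pair.
#' @param group_by Grouping columns (defaults to the protocol grid).
#' @return Data frame with one row per group: group key columns,
#'   \code{mean_ratio}, \code{sem}, \code{n}, \code{p_wilcoxon},
#'   \code{n_zero_control} (cells flagged for a zero control peak). Cells
#'   missing either condition are dropped with a warning.
#' @export
drug_ratio_summary <- function(table, drug_cond, control_cond,
                               group_by = c("duration_s", "frequency_hz",
                                            "compartment")) {
  need <- c("cell", "condition", "peak_dff", group_by)
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  drug <- table[table$condition == drug_cond, ]
  ctrl <- table[table$condition == control_cond, ]
  key <- function(df) do.call(paste, c(df[c("cell", group_by)], sep = "\r"))
  merged <- merge(ctrl, drug, by = c("cell", group_by),
                  suffixes = c("_control", "_drug"))
  dropped <- length(unique(key(ctrl))) + length(unique(key(drug))) -
    2 * nrow(merged)
  if (dropped > 0)
    warning(dropped, " cell/condition entr", if (dropped == 1) "y" else "ies",
            " without a matching pair dropped")

  zero_ctrl <- merged$peak_dff_control == 0
  if (any(zero_ctrl))
    warning(sum(zero_ctrl), " cell(s) with zero control peak flagged")
  merged$ratio <- ifelse(zero_ctrl, NA_real_,
                         merged$peak_dff_drug / merged$peak_dff_control)

  groups <- unique(merged[group_by])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- rep(TRUE, nrow(merged))
    for (col in group_by) sel <- sel & merged[[col]] == groups[[col]][g]
    r <- merged$ratio[sel & !is.na(merged$ratio)]
    diffs <- merged$peak_dff_drug[sel] - merged$peak_dff_control[sel]
    out <- groups[g, , drop = FALSE]
    out$mean_ratio <- mean(r)
    out$sem <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
    out$n <- length(r)
    out$p_wilcoxon <- as.numeric(wilcoxon_signed_p(diffs))
    out$n_zero_control <- sum(zero_ctrl[sel])
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
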