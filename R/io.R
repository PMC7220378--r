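#' Write a session block to a directory (long CSV + encoder CSV + meta JSON)
#'
#' Long-format CSV is the canonical interchange: \code{traces.csv} has one
#' row per ROI, recording and frame (columns roi, recording, condition,
#' wavelength, frame, soma, neuropil), \code{encoder.csv} one row per
#' recording and sample (recording, time_s, position_cm), and
#' \code{meta.json} carries the frame rate and ROI ids.
#'
#' @param block A \code{session_block}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_traces <- function(block, dir) {
  stopifnot(inherits(block, "session_block"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(block$recordings, function(rec) {
    n_frames <- ncol(rec$soma)
    data.frame(roi = rep(block$roi_ids, n_frames),
               recording = rec$index, condition = rec$condition,
               wavelength = rec$wavelength,
               frame = rep(seq_len(n_frames) - 1L, each = nrow(rec$soma)),
               soma = as.vector(rec$soma),
               neuropil = as.vector(rec$neuropil))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "traces.csv"),
                   row.names = FALSE)
  enc <- lapply(block$recordings, function(rec)
    cbind(recording = rec$index, rec$encoder))
  utils::write.csv(do.call(rbind, enc), file.path(dir, "encoder.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(frame_rate = block$frame_rate,
                            roi_ids = block$roi_ids),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a session block written by \code{\link{write_traces}}
#'
#' @param dir Directory containing \code{traces.csv}, \code{encoder.csv}
#'   and \code{meta.json}.
#' @return A \code{session_block}; write-then-read is the identity on values
#'   and metadata.
#' @export
read_traces <- function(dir) {
  tr_path <- file.path(dir, "traces.csv")
  if (!file.exists(tr_path)) stop("missing ", tr_path, call. = FALSE)
  tr <- utils::read.csv(tr_path)
  need <- c("roi", "recording", "condition", "wavelength", "frame",
            "soma", "neuropil")
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols))
    stop("traces.csv is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  enc <- utils::read.csv(file.path(dir, "encoder.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  roi_ids <- meta$roi_ids
  recs <- sort(unique(tr$recording))
  recordings <- lapply(recs, function(jj) {
    sub <- tr[tr$recording == jj, ]
    sub <- sub[order(sub$frame, match(sub$roi, roi_ids)), ]
    n_frames <- length(unique(sub$frame))
    e <- enc[enc$recording == jj, c("time_s", "position_cm")]
    rownames(e) <- NULL
    list(index = jj, condition = sub$condition[1],
         wavelength = sub$wavelength[1],
         soma = matrix(sub$soma, nrow = length(roi_ids), ncol = n_frames),
         neuropil = matrix(sub$neuropil, nrow = length(roi_ids),
                           ncol = n_frames),
         encoder = e)
  })
  structure(list(recordings = recordings, frame_rate = meta$frame_rate,
                 roi_ids = roi_ids),
            class = "session_block")
}

#' Write a label image as a 16-bit PNG
#'
#' The 16-bit label value is split across the red (high byte) and green
#' (low byte) channels so the file is lossless with any 8-bit PNG codec.
#'
#' @param labels Integer label matrix (rows = y), labels < 65536.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mask_png <- function(labels, path) {
  if (max(labels) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  img <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  img[, , 1] <- (labels %/% 256L) / 255
  img[, , 2] <- (labels %% 256L) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Read a label image written by \code{\link{write_mask_png}}
#' @param path PNG path.
#' @return Integer label matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 3 || dim(img)[3] < 2)
    stop("not a label mask PNG (needs red/green byte channels)", call. = FALSE)
  hi <- round(img[, , 1] * 255)
  lo <- round(img[, , 2] * 255)
  matrix(as.integer(hi * 256 + lo), dim(img)[1], dim(img)[2])
}

#' Read an immunogold sample from particle and polygon CSVs
#'
#' @param particle_csv CSV with columns \code{x_nm}, \code{y_nm}.
#' @param polygon_csv CSV with columns \code{vertex_x_nm},
#'   \code{vertex_y_nm} (PSD outline vertices in order).
#' @return A \code{psd_sample}.
#' @export
read_em_sample <- function(particle_csv, polygon_csv) {
  pts <- utils::read.csv(particle_csv)
  if (!all(c("x_nm", "y_nm") %in% names(pts)))
    stop("particle CSV needs columns x_nm, y_nm", call. = FALSE)
  pol <- utils::read.csv(polygon_csv)
  if (!all(c("vertex_x_nm", "vertex_y_nm") %in% names(pol)))
    stop("polygon CSV needs columns vertex_x_nm, vertex_y_nm", call. = FALSE)
  structure(list(psd_polygon = data.frame(x_nm = pol$vertex_x_nm,
                                          y_nm = pol$vertex_y_nm),
                 particles = pts[c("x_nm", "y_nm")]),
            class = "psd_sample")
}

#' Write an immunogold sample to particle and polygon CSVs
#' @param sample A \code{psd_sample}.
#' @param particle_csv,polygon_csv Output paths.
#' @return Invisibly, the particle path.
#' @export
write_em_sample <- function(sample, particle_csv, polygon_csv) {
  utils::write.csv(sample$particles, particle_csv, row.names = FALSE)
  utils::write.csv(data.frame(vertex_x_nm = sample$psd_polygon$x_nm,
                              vertex_y_nm = sample$psd_polygon$y_nm),
                   polygon_csv, row.names = FALSE)
  invisible(particle_csv)
}
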