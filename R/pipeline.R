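.pipeline_keys <- c("pipeline", "seed", "output_dir", "inputs", "params")

.known_param_keys <- function() {
  list(loco_gen = names(formals(loco_gen_params)),
       protocol = names(formals(protocol_params)),
       stim_gen = names(formals(stim_gen_params)),
       em_gen = names(formals(em_gen_params)),
       match = names(formals(match_params)),
       drug_test = names(formals(drug_test_params)),
       locomotion = c("window", "q", "neuropil_scale", "baseline_window"),
       stim = c("drug_cond", "control_cond", "group_by"),
       em = c("band_width", "n_bands", "grid_res_nm"))
}

#' Validate a pipeline run configuration
#'
#' Rejects unknown keys (naming the offender), checks the pipeline name,
#' and verifies that referenced input files exist — all before any
#' computation.
#'
#' @param config A named list, or a path to a YAML file with the same
#'   structure. Keys: \code{pipeline} (one of "simulate", "stim",
#'   "locomotion", "em"), \code{seed}, \code{output_dir}, \code{inputs}
#'   (named file/directory paths), \code{params} (named sub-lists keyed by
#'   parameter-set name, e.g. \code{loco_gen}, \code{drug_test}).
#' @return The validated config list, invisibly on error-free input.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$pipeline) ||
      !config$pipeline %in% c("simulate", "stim", "locomotion", "em"))
    stop("config$pipeline must be one of simulate, stim, locomotion, em",
         call. = FALSE)
  if (is.null(config$output_dir))
    stop("config$output_dir is required", call. = FALSE)
  known <- .known_param_keys()
  for (set in names(config$params)) {
    if (!set %in% names(known))
      stop("unknown config key: params$", set, call. = FALSE)
    bad <- setdiff(names(config$params[[set]]), known[[set]])
    if (length(bad))
      stop("unknown config key: params$", set, "$", bad[1], call. = FALSE)
  }
  for (nm in names(config$inputs)) {
    path <- config$inputs[[nm]]
    if (!file.exists(path))
      stop("input '", nm, "' does not exist: ", path, call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.build_params <- function(constructor, overrides) {
  do.call(constructor, if (is.null(overrides)) list() else overrides)
}

.write_provenance <- function(dir, config, extra = list()) {
  prov <- c(list(package = "mlipharm",
                 version = as.character(utils::packageVersion("mlipharm")),
                 config = config), extra)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run one of the analysis pipelines end to end
#'
#' Dispatches on \code{config$pipeline}:
#' \describe{
#'   \item{simulate}{Generates a synthetic locomotion session block plus a
#'     matched pre/post ROI mask pair and writes them (traces/encoder CSV,
#'     meta JSON, mask PNGs, ground-truth JSON) to \code{output_dir}.}
#'   \item{locomotion}{Reads a session block (and optionally the mask pair),
#'     registers and matches ROIs, normalizes to rest, runs the decay
#'     detrending, per-ROI classification and the change-vs-baseline
#'     regression; writes locomotion_summary.csv, drug_effects.csv and
#'     regression.json.}
#'   \item{stim}{Reads a stimulation peak table CSV and writes the grouped
#'     drug/control ratio summary with Wilcoxon p-values.}
#'   \item{em}{Reads particle and PSD-polygon CSVs and writes the annulus
#'     density profile.}
#' }
#' All randomness flows from \code{config$seed}; outputs are deterministic
#' given config + seed (a provenance JSON records parameters and versions).
#'
#' @param config Config list or YAML path (see \code{\link{validate_config}}).
#' @return The pipeline's result object, invisibly (also written to disk).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(config$pipeline,
                simulate = .run_simulate(config),
                locomotion = .run_locomotion(config),
                stim = .run_stim(config),
                em = .run_em(config))
  .write_provenance(config$output_dir, config)
  invisible(out)
}

.run_simulate <- function(config) {
  gp <- config$params$loco_gen
  gp$seed <- config$seed
  params <- .build_params(loco_gen_params, gp)
  protocol <- .build_params(protocol_params, config$params$protocol)
  gen <- gen_locomotion_block(params, protocol)
  write_traces(gen$block, config$output_dir)
  scene <- gen_roi_scene(params$n_rois, field_px = c(512L, 512L),
                         shift_px = params$shift_px,
                         seed = config$seed + 1L)
  write_mask_png(scene$image_a, file.path(config$output_dir, "masks_pre.png"))
  write_mask_png(scene$image_b, file.path(config$output_dir, "masks_post.png"))
  jsonlite::write_json(
    list(b = gen$truth$b, d = gen$truth$d, f_rest = gen$truth$f_rest,
         decay = as.list(gen$truth$decay), shift_px = gen$truth$shift_px),
    file.path(config$output_dir, "truth.json"), digits = NA,
    auto_unbox = TRUE)
  gen
}

.run_locomotion <- function(config) {
  if (is.null(config$inputs$traces))
    stop("locomotion pipeline requires inputs$traces (directory)",
         call. = FALSE)
  block <- read_traces(config$inputs$traces)
  lp <- config$params$locomotion
  window <- if (is.null(lp$window)) c(10, 25) else unlist(lp$window)
  q <- if (is.null(lp$q)) 75 else lp$q
  r <- if (is.null(lp$neuropil_scale)) 0.7 else lp$neuropil_scale
  bw <- if (is.null(lp$baseline_window)) c(0, 5) else
    unlist(lp$baseline_window)
  mp <- .build_params(match_params, config$params$match)
  tp <- .build_params(drug_test_params, config$params$drug_test)

  rois <- NULL
  shift <- NULL
  if (!is.null(config$inputs$masks_pre) &&
      !is.null(config$inputs$masks_post)) {
    a <- read_mask_png(config$inputs$masks_pre)
    b <- read_mask_png(config$inputs$masks_post)
    shift <- estimate_translation(a, b, mp$max_shift)
    match <- match_rois(a, b, shift, mp)
    utils::write.csv(match$pairs, file.path(config$output_dir,
                                            "roi_matches.csv"),
                     row.names = FALSE)
    rois <- match$pairs$label_a[match$pairs$matched]
    rois <- rois[rois %in% block$roi_ids]
  }
  k <- select_least_active(block, bw)
  dffm <- normalize_to_rest(block, k, bw, r)
  res <- analyze_locomotion(dffm, rois = rois, window = window, q = q,
                            test = tp)
  utils::write.csv(res$summary,
                   file.path(config$output_dir, "locomotion_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$effects,
                   file.path(config$output_dir, "drug_effects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(unclass(res$regression),
                         list(least_active_recording = k,
                              shift_px = shift)),
                       file.path(config$output_dir, "regression.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}

.run_stim <- function(config) {
  if (is.null(config$inputs$peaks))
    stop("stim pipeline requires inputs$peaks (CSV)", call. = FALSE)
  tab <- utils::read.csv(config$inputs$peaks)
  sp <- config$params$stim
  if (is.null(sp$drug_cond) || is.null(sp$control_cond))
    stop("stim pipeline requires params$stim$drug_cond and $control_cond",
         call. = FALSE)
  gb <- if (is.null(sp$group_by))
    c("duration_s", "frequency_hz", "compartment") else unlist(sp$group_by)
  res <- drug_ratio_summary(tab, sp$drug_cond, sp$control_cond, gb)
  utils::write.csv(res, file.path(config$output_dir, "ratio_summary.csv"),
                   row.names = FALSE)
  res
}

.run_em <- function(config) {
  if (is.null(config$inputs$particles) || is.null(config$inputs$polygon))
    stop("em pipeline requires inputs$particles and inputs$polygon (CSVs)",
         call. = FALSE)
  sample <- read_em_sample(config$inputs$particles, config$inputs$polygon)
  ep <- config$params$em
  bw <- if (is.null(ep$band_width)) 50 else ep$band_width
  nb <- if (is.null(ep$n_bands)) 5 else ep$n_bands
  prof <- annulus_density_profile(sample, band_width = bw, n_bands = nb)
  utils::write.csv(prof$bands,
                   file.path(config$output_dir, "annulus_profile.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(inside_count = prof$inside_count,
                            beyond_count = prof$beyond_count,
                            total = prof$total),
                       file.path(config$output_dir, "annulus_counts.json"),
                       auto_unbox = TRUE, digits = NA)
  prof
}
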