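#' Configuration of the end-to-end analysis pipeline
#'
#' One top-level seed drives every stage through [derive_seed()], so adding
#' stages never perturbs the draws seen by existing ones.
#'
#' @param out_dir directory for the pipeline artifacts (created if needed).
#' @param seed top-level integer seed.
#' @param synth a [synth_config()] (its own seed is overridden by a child of
#'   `seed`).
#' @param fit a [fit_config()] (seed overridden likewise).
#' @param thresholds a [thresholds()] used for classification.
#' @param subsample_every analyze every k-th frame (default 1).
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            synth = synth_config(),
                            fit = fit_config(),
                            thresholds = smcflex::thresholds(),
                            subsample_every = 1) {
  stopifnot(inherits(synth, "synth_config"), inherits(fit, "fit_config"),
            inherits(thresholds, "thresholds"))
  synth$seed <- derive_seed(seed, 11)
  fit$seed <- derive_seed(seed, 12)
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 fit = fit, thresholds = thresholds,
                 subsample_every = as.integer(subsample_every)),
            class = "pipeline_config")
}

#' Run the full synthetic-movie analysis pipeline
#'
#' Stages: generate a synthetic movie, write and re-read its landmark table,
#' classify the frames, extract the head-hinge distances of V-shaped frames
#' (both arms), and fit worm-like-chain parameters to them.  Progress counts
#' go to standard error; artifacts (`landmarks.tsv`, `traces.jsonl`,
#' `truth.tsv`, `labels.tsv`, `distances.csv`, `report.json`) are written
#' under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `movie`, `annotation`, `distances`, `fit`
#'   and `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)

  message("stage synth: generating ", config$synth$n_frames, " frames")
  movie <- generate_movie(config$synth)
  write_landmarks(movie$frames, p("landmarks.tsv"))
  write_traces(movie$traces, movie$frames$frame_id, p("traces.jsonl"))
  write.table(movie$truth[, c("frame_id", "true_state")], p("truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  frames <- read_landmarks(p("landmarks.tsv"))
  message("stage classify: ", nrow(frames), " frames read")
  ann <- annotate_movie(frames, config$thresholds, config$subsample_every)
  write_labels(ann, p("labels.tsv"))
  freq <- ann$class_frequencies
  message("  class counts: ",
          paste(sprintf("%s %.0f", names(freq),
                        freq * attr(freq, "n_classified")), collapse = ", "))

  v_rows <- frames$frame_id %in%
    ann$labels$frame_id[ann$labels$label == "V"]
  g <- head_hinge_distances(frames[v_rows, , drop = FALSE])
  distances <- as.numeric(t(g))
  write_distances(distances, p("distances.csv"))
  message("stage fit: ", length(distances), " V-arm distances")
  fit <- fit_wlc(distances, config$fit)

  report <- list(
    config = list(seed = config$seed,
                  n_frames = config$synth$n_frames,
                  subsample_every = config$subsample_every,
                  head_head_engaged_nm = config$thresholds$head_head_engaged,
                  head_hinge_engaged_nm = config$thresholds$head_hinge_engaged),
    classification = list(
      n_analyzed = length(ann$analyzed_frame_ids),
      class_frequencies = as.list(freq),
      unclassified_fraction = attr(freq, "unclassified_fraction"),
      transition_counts = ann$transition_counts),
    fit = list(lp_hat_nm = fit$lp_hat, lc_hat_nm = fit$lc_hat,
               lp_sd_nm = fit$lp_sd, lc_sd_nm = fit$lc_sd,
               n_data = fit$n_data,
               boundary_warning = fit$boundary_warning))
  write_report(report, p("report.json"), seed = config$seed)
  message(sprintf("fit: L_p = %.2f nm, L_c = %.1f nm", fit$lp_hat, fit$lc_hat))
  invisible(list(movie = movie, annotation = ann, distances = distances,
                 fit = fit, report = report))
}
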