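#' Read a per-frame landmark table
#'
#' Tab-separated with header columns exactly `frame_id, time_s, head1_x_nm,
#' head1_y_nm, head2_x_nm, head2_y_nm, hinge_x_nm, hinge_y_nm`.  Empty cells
#' become `NA` (missing landmark); any other non-numeric cell is reported
#' with its line number.
#'
#' @param path file path.
#' @return landmark data.frame (see [dimer_frames()]).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop(sprintf("landmark file not found: %s", path), call. = FALSE)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  missing_cols <- setdiff(LANDMARK_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("landmark file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[, LANDMARK_COLUMNS, drop = FALSE]
  out <- raw
  for (col in LANDMARK_COLUMNS) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("malformed numeric value '%s' in column %s at line %d",
                   v[bad[1L]], col, bad[1L] + 1L), call. = FALSE)
    out[[col]] <- num
  }
  out$frame_id <- as.integer(out$frame_id)
  out
}

#' Write a per-frame landmark table
#'
#' @param frames landmark data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(frames, path) {
  check_frames(frames)
  write.table(frames[, LANDMARK_COLUMNS], path, sep = "\t", na = "",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write end-to-end distance samples
#'
#' Single-column CSV with header `distance_nm`.
#'
#' @param path file path.
#' @return `read_distances`: numeric vector (nm).
#' @export
read_distances <- function(path) {
  if (!file.exists(path))
    stop(sprintf("distance file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  if (!"distance_nm" %in% names(df))
    stop("distance file lacks required column: distance_nm", call. = FALSE)
  as.numeric(df$distance_nm)
}

#' @rdname read_distances
#' @param distances numeric vector (nm).
#' @export
write_distances <- function(distances, path) {
  utils::write.csv(data.frame(distance_nm = distances), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-frame arm traces as JSON lines
#'
#' One JSON object per line: `{"frame_id": int, "arm": 1|2,
#' "x_nm": [...], "y_nm": [...]}`.
#'
#' @param path file path.
#' @return `read_traces`: a named list keyed by frame_id, each element a
#'   list with `arm1` and/or `arm2` polyline matrices.
#' @export
read_traces <- function(path) {
  if (!file.exists(path))
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  out <- list()
  for (line in readLines(path)) {
    if (!nzchar(line)) next
    o <- jsonlite::fromJSON(line)
    key <- as.character(o$frame_id)
    m <- cbind(x = as.numeric(o$x_nm), y = as.numeric(o$y_nm))
    if (is.null(out[[key]])) out[[key]] <- list()
    out[[key]][[paste0("arm", o$arm)]] <- m
  }
  out
}

#' @rdname read_traces
#' @param traces per-frame list as produced by [generate_movie()]
#'   (`traces[[i]]$arm1`, `traces[[i]]$arm2`), with frame ids taken from
#'   `frame_ids`.
#' @param frame_ids integer vector, one id per element of `traces`.
#' @export
write_traces <- function(traces, frame_ids, path) {
  stopifnot(length(traces) == length(frame_ids))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(traces)) {
    for (a in 1:2) {
      m <- traces[[i]][[paste0("arm", a)]]
      if (is.null(m)) next
      writeLines(jsonlite::toJSON(list(frame_id = frame_ids[i], arm = a,
                                       x_nm = unname(m[, 1]),
                                       y_nm = unname(m[, 2])),
                                  auto_unbox = TRUE, digits = 6), con)
    }
  }
  invisible(path)
}

#' Write simulated chain traces as JSON lines
#'
#' One object per chain: `{"chain_id": int, "x_nm": [...], "y_nm": [...]}`.
#'
#' @param chains list of `"chain_trace"` matrices.
#' @param path output path.
#' @export
write_chain_traces <- function(chains, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(chains)) {
    writeLines(jsonlite::toJSON(list(chain_id = i,
                                     x_nm = unname(chains[[i]][, 1]),
                                     y_nm = unname(chains[[i]][, 2])),
                                auto_unbox = TRUE, digits = 6), con)
  }
  invisible(path)
}

#' Write a per-frame label table
#'
#' TSV with columns `frame_id`, `time_s`, `label`.
#'
#' @param annotation a `"movie_annotation"`.
#' @param path output path.
#' @export
write_labels <- function(annotation, path) {
  stopifnot(inherits(annotation, "movie_annotation"))
  write.table(annotation$labels, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a structured JSON report
#'
#' Adds a schema version and echoes the seed; keys keep the construction
#' order, so identical inputs yield byte-identical files.
#'
#' @param results named list of stage outputs (may be empty).
#' @param path output path.
#' @param seed seed to record.
#' @export
write_report <- function(results, path, seed = NULL) {
  report <- c(list(schema_version = "1.0",
                   seed = if (is.null(seed)) NA else seed),
              results)
  txt <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                          pretty = TRUE, na = "null", force = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' Read a fit configuration from YAML
#'
#' Recognized keys: `lp_min, lp_max, lc_min, lc_max, grid_points,
#' refinement_rounds, chains_per_eval, bin_width_nm, hist_max_nm,
#' ci_replicates, seed`.  Missing keys keep the [fit_config()] defaults.
#'
#' @param path YAML file path.
#' @return a [fit_config()].
#' @export
read_fit_config <- function(path) {
  y <- yaml::read_yaml(path)
  d <- fit_config()
  pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  fit_config(
    lp_range = c(pick("lp_min", d$lp_range[1]), pick("lp_max", d$lp_range[2])),
    lc_range = c(pick("lc_min", d$lc_range[1]), pick("lc_max", d$lc_range[2])),
    grid_points = pick("grid_points", d$grid_points),
    refinement_rounds = pick("refinement_rounds", d$refinement_rounds),
    chains_per_eval = pick("chains_per_eval", d$chains_per_eval),
    bin_width = pick("bin_width_nm", d$bin_width),
    hist_max = pick("hist_max_nm", d$hist_max),
    ci_replicates = pick("ci_replicates", d$ci_replicates),
    seed = pick("seed", d$seed))
}
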