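#' Engagement thresholds for conformational classification
#'
#' Two globular domains are called "engaged" when their centre-to-centre
#' distance is at or below the threshold.  The 7-nm default sits in the dip
#' between the engaged peak (~2.4 nm) and the open population of head-hinge
#' distances.  `tangent_arc` is the arc length (nm) along each arm at which
#' the hinge-angle chord is taken; single-segment tangents are dominated by
#' bending noise, so a chord of about one persistence length is used instead.
#'
#' @param head_head_engaged head-head engagement threshold (nm), default 7.
#' @param head_hinge_engaged head-hinge engagement threshold (nm), default 7.
#' @param tangent_arc chord arc length for [hinge_angle()] (nm), default 5.
#' @return an object of class `"thresholds"`.
#' @export
thresholds <- function(head_head_engaged = 7, head_hinge_engaged = 7,
                       tangent_arc = 5) {
  if (head_head_engaged <= 0) stop_param("head_head_engaged", "must be > 0")
  if (head_hinge_engaged <= 0) stop_param("head_hinge_engaged", "must be > 0")
  if (tangent_arc <= 0) stop_param("tangent_arc", "must be > 0")
  structure(list(head_head_engaged = head_head_engaged,
                 head_hinge_engaged = head_hinge_engaged,
                 tangent_arc = tangent_arc),
            class = "thresholds")
}

LANDMARK_COLUMNS <- c("frame_id", "time_s",
                      "head1_x_nm", "head1_y_nm",
                      "head2_x_nm", "head2_y_nm",
                      "hinge_x_nm", "hinge_y_nm")

#' Build a per-frame landmark table
#'
#' Frames are kept as a plain data.frame with one row per movie frame and
#' the columns `frame_id`, `time_s`, `head1_x_nm`, `head1_y_nm`,
#' `head2_x_nm`, `head2_y_nm`, `hinge_x_nm`, `hinge_y_nm` (all coordinates
#' in nm; `NA` marks a missing landmark).
#'
#' @param frame_id integer frame identifiers.
#' @param time_s frame times in seconds.
#' @param head1,head2,hinge two-column matrices (or length-2 vectors for a
#'   single frame) of landmark coordinates in nm.
#' @return a landmark data.frame.
#' @export
dimer_frames <- function(frame_id, time_s, head1, head2, hinge) {
  as_xy <- function(m) {
    if (is.null(dim(m))) m <- matrix(m, ncol = 2, byrow = TRUE)
    m
  }
  head1 <- as_xy(head1); head2 <- as_xy(head2); hinge <- as_xy(hinge)
  data.frame(frame_id = frame_id, time_s = time_s,
             head1_x_nm = head1[, 1], head1_y_nm = head1[, 2],
             head2_x_nm = head2[, 1], head2_y_nm = head2[, 2],
             hinge_x_nm = hinge[, 1], hinge_y_nm = hinge[, 2])
}

check_frames <- function(frames) {
  missing_cols <- setdiff(LANDMARK_COLUMNS, names(frames))
  if (length(missing_cols))
    stop("landmark table lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  frames
}

#' Head-head distance of each frame
#'
#' Euclidean distance between the two ATPase head centres, invariant under
#' rigid motions of the frame.  `NA` where either head is missing.
#'
#' @param frames landmark data.frame (see [dimer_frames()]).
#' @return numeric vector of distances (nm).
#' @export
head_head_distance <- function(frames) {
  check_frames(frames)
  sqrt((frames$head1_x_nm - frames$head2_x_nm)^2 +
       (frames$head1_y_nm - frames$head2_y_nm)^2)
}

#' Head-hinge distances of each frame
#'
#' @inheritParams head_head_distance
#' @return two-column matrix (`arm1`, `arm2`) of hinge-to-head distances (nm).
#' @export
head_hinge_distances <- function(frames) {
  check_frames(frames)
  g1 <- sqrt((frames$head1_x_nm - frames$hinge_x_nm)^2 +
             (frames$head1_y_nm - frames$hinge_y_nm)^2)
  g2 <- sqrt((frames$head2_x_nm - frames$hinge_x_nm)^2 +
             (frames$head2_y_nm - frames$hinge_y_nm)^2)
  cbind(arm1 = g1, arm2 = g2)
}

CONFORMATION_LEVELS <- c("V", "O", "B", "P", "UNCLASSIFIED")

#' Classify frames into the V / O / B / P conformational classes
#'
#' With `hh` the head-head distance and `g1`, `g2` the head-hinge distances:
#' * **B** (butterfly): both heads engaged with the hinge
#'   (`g1 <= t` and `g2 <= t`);
#' * **O**: not B, heads engaged with each other (`hh <= t_hh`);
#' * **P**: not B or O, exactly one head engaged with the hinge;
#' * **V**: everything else — connected at the hinge only, no engagement.
#'
#' The precedence B > O > P > V makes the classes exhaustive and mutually
#' exclusive for any positive thresholds; when all three domains co-locate
#' the frame counts as B.  Distances exactly at a threshold classify as
#' engaged.  Frames with any missing landmark are `UNCLASSIFIED`.
#'
#' @param frames landmark data.frame.
#' @param t a [thresholds()] object.
#' @return factor with levels `V, O, B, P, UNCLASSIFIED`.
#' @export
classify_frames <- function(frames, t = thresholds()) {
  stopifnot(inherits(t, "thresholds"))
  hh <- head_head_distance(frames)
  g <- head_hinge_distances(frames)
  g1 <- g[, 1L]
  g2 <- g[, 2L]
  ok <- is.finite(hh) & is.finite(g1) & is.finite(g2)
  lab <- rep("UNCLASSIFIED", nrow(frames))
  e1 <- g1 <= t$head_hinge_engaged
  e2 <- g2 <= t$head_hinge_engaged
  ehh <- hh <= t$head_head_engaged
  lab[ok & e1 & e2] <- "B"
  lab[ok & !(e1 & e2) & ehh] <- "O"
  lab[ok & !(e1 & e2) & !ehh & xor(e1, e2)] <- "P"
  lab[ok & !e1 & !e2 & !ehh] <- "V"
  factor(lab, levels = CONFORMATION_LEVELS)
}

#' Classify a single frame
#'
#' @param frame one-row landmark data.frame.
#' @inheritParams classify_frames
#' @return a single-label factor.
#' @export
classify_frame <- function(frame, t = thresholds()) {
  stopifnot(nrow(frame) == 1L)
  classify_frames(frame, t)
}

# point at arc length s along a polyline (n x 2 matrix), by linear
# interpolation between vertices
chord_point <- function(trace, s) {
  seg <- sqrt(diff(trace[, 1L])^2 + diff(trace[, 2L])^2)
  cum <- c(0, cumsum(seg))
  if (s > cum[length(cum)] + 1e-9)
    stop_param("tangent_arc", sprintf(
      "arc length %g nm exceeds trace length %g nm", s, cum[length(cum)]))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  f <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
  trace[i, ] + f * (trace[i + 1L, ] - trace[i, ])
}

#' Opening angle between the two coiled-coil arms at the hinge
#'
#' The angle (degrees, in `[0, 180]`) between the chord vectors from the
#' hinge (the first vertex of each trace) to the point at arc length
#' `t$tangent_arc` along each arm.  Symmetric under swapping the arms and
#' invariant under rigid motions.
#'
#' @param arm1_trace,arm2_trace polylines (n x 2 matrices, nm) running from
#'   the hinge to the head; each must be at least `t$tangent_arc` long.
#' @param t a [thresholds()] object (only `tangent_arc` is used).
#' @return angle in degrees.
#' @export
hinge_angle <- function(arm1_trace, arm2_trace, t = thresholds()) {
  if (is.null(arm1_trace) || is.null(arm2_trace))
    stop("hinge angle requires both arm traces", call. = FALSE)
  arm1_trace <- as.matrix(arm1_trace)
  arm2_trace <- as.matrix(arm2_trace)
  v1 <- chord_point(arm1_trace, t$tangent_arc) - arm1_trace[1L, ]
  v2 <- chord_point(arm2_trace, t$tangent_arc) - arm2_trace[1L, ]
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Least-squares Gaussian fit to a windowed distance histogram
#'
#' Bins the sample on `[window[1], window[2]]` and fits
#' `A * exp(-(x - mu)^2 / (2 sigma^2))` to the bin densities by
#' Levenberg-Marquardt least squares.  Windowing isolates one mode of a
#' bimodal distance distribution (e.g. the engaged peak below ~10 nm versus
#' the open population above it).  Degenerate histograms with fewer than
#' three occupied bins fall back to the moment estimates of the binned
#' density.
#'
#' @param distances numeric sample (nm).
#' @param window numeric `(lo, hi)` fitting window (nm).
#' @param bin_width histogram bin width (nm), default 0.5.
#' @return named numeric `c(mean =, sd =)` in nm.
#' @export
gaussian_peak <- function(distances, window, bin_width = 0.5) {
  inside <- distances >= window[1] & distances <= window[2]
  if (sum(inside) < 20L)
    stop(sprintf("only %d data points inside the window [%g, %g] nm: too few",
                 sum(inside), window[1], window[2]), call. = FALSE)
  n_bins <- ceiling((window[2] - window[1]) / bin_width - 1e-9)
  h <- histogram_density(distances, bin_width,
                         c(window[1], window[1] + n_bins * bin_width))
  x <- h$mids
  y <- h$density
  w_mean <- sum(x * y) / sum(y)
  w_sd <- sqrt(max(sum((x - w_mean)^2 * y) / sum(y), 1e-12))
  if (sum(y > 0) < 3L)
    return(c(mean = w_mean, sd = w_sd))
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
    start = list(A = max(y), mu = w_mean, sigma = w_sd),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  c(mean = unname(cf["mu"]), sd = abs(unname(cf["sigma"])))
}

#' Fractions of classified frames per conformational class
#'
#' @param labels factor or character vector of conformational labels.
#' @return named numeric of fractions over `V, O, B, P` (summing to 1 over
#'   classified frames) with attributes `n_classified` and
#'   `unclassified_fraction`.
#' @export
class_frequencies <- function(labels) {
  labels <- as.character(labels)
  classes <- setdiff(CONFORMATION_LEVELS, "UNCLASSIFIED")
  classified <- labels %in% classes
  if (!any(classified))
    stop("no classified frames", call. = FALSE)
  tab <- table(factor(labels[classified], levels = classes))
  out <- as.numeric(tab) / sum(tab)
  names(out) <- classes
  attr(out, "n_classified") <- sum(classified)
  attr(out, "unclassified_fraction") <- mean(!classified)
  out
}

#' Annotate a movie with conformational states and transition counts
#'
#' Classifies every `subsample_every`-th frame (starting from the first) and
#' counts state transitions between consecutive *analyzed* frames.  An
#' `UNCLASSIFIED` frame breaks the transition chain: no transition is
#' counted into or out of it.
#'
#' @param frames time-ordered landmark data.frame.
#' @param t a [thresholds()] object.
#' @param subsample_every analyze every k-th frame (default 1 = all).
#' @return an object of class `"movie_annotation"`: `labels` (data.frame of
#'   `frame_id`, `time_s`, `label` for analyzed frames), `class_frequencies`,
#'   `transition_counts` (4 x 4 matrix from-row to-column),
#'   `analyzed_frame_ids`, `subsample_every`.
#' @export
annotate_movie <- function(frames, t = thresholds(), subsample_every = 1) {
  check_frames(frames)
  if (nrow(frames) == 0L) stop("empty movie", call. = FALSE)
  if (subsample_every < 1) stop_param("subsample_every", "must be >= 1")
  idx <- seq(1L, nrow(frames), by = as.integer(subsample_every))
  sub <- frames[idx, , drop = FALSE]
  lab <- classify_frames(sub, t)
  classes <- setdiff(CONFORMATION_LEVELS, "UNCLASSIFIED")
  trans <- matrix(0L, 4, 4, dimnames = list(from = classes, to = classes))
  lc <- as.character(lab)
  if (length(lc) > 1L) {
    from <- lc[-length(lc)]
    to <- lc[-1L]
    ok <- from != "UNCLASSIFIED" & to != "UNCLASSIFIED"
    for (k in which(ok)) trans[from[k], to[k]] <- trans[from[k], to[k]] + 1L
  }
  structure(list(labels = data.frame(frame_id = sub$frame_id,
                                     time_s = sub$time_s,
                                     label = lab),
                 class_frequencies = class_frequencies(lab),
                 transition_counts = trans,
                 analyzed_frame_ids = sub$frame_id,
                 subsample_every = as.integer(subsample_every)),
            class = "movie_annotation")
}

#' @export
print.movie_annotation <- function(x, ...) {
  cat(sprintf("movie annotation: %d analyzed frames (every %d)\n",
              nrow(x$labels), x$subsample_every))
  f <- x$class_frequencies
  cat("  class frequencies:",
      paste(sprintf("%s %.1f%%", names(f), 100 * f), collapse = ", "), "\n")
  uf <- attr(f, "unclassified_fraction")
  if (uf > 0) cat(sprintf("  unclassified: %.1f%%\n", 100 * uf))
  cat(sprintf("  transitions counted: %d\n", sum(x$transition_counts)))
  invisible(x)
}
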