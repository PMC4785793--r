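#' Parameters of a discretized 2D worm-like chain
#'
#' A worm-like chain of contour length `contour_length` is discretized into
#' `N = round(contour_length / segment_length)` straight segments.  Successive
#' segments are deflected by independent zero-mean Gaussian angles with
#' variance `segment_length / persistence_length`, the convention for which a
#' surface-equilibrated (2D) chain has tangent correlation
#' `<cos theta(s)> = exp(-s / (2 L_p))`.  Any residual contour shorter than
#' half a segment is dropped by the rounding.
#'
#' @param persistence_length persistence length L_p in nm; must be > 0.
#' @param contour_length contour length L_c in nm; must be > 0.
#' @param segment_length discretization segment length L_s in nm
#'   (default 0.2); must satisfy `0 < segment_length <= contour_length`.
#' @param n_chains number of chains for ensemble operations (default 1e5).
#' @param seed optional integer seed used by the simulation operations.
#' @return an object of class `"wlc_params"`.
#' @examples
#' p <- wlc_params(3.8, 46)
#' p$n_segments
#' @export
wlc_params <- function(persistence_length, contour_length,
                       segment_length = 0.2, n_chains = 1e5, seed = NULL) {
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop_param(nm, "must be a single positive finite number")
  }
  chk(persistence_length, "persistence_length")
  chk(contour_length, "contour_length")
  chk(segment_length, "segment_length")
  if (segment_length > contour_length)
    stop_param("segment_length", "must not exceed contour_length")
  if (!is.numeric(n_chains) || length(n_chains) != 1L || n_chains < 1)
    stop_param("n_chains", "must be a positive count")
  n_seg <- as.integer(round(contour_length / segment_length))
  if (n_seg < 1L)
    stop_param("segment_length", "yields fewer than one segment")
  structure(list(persistence_length = persistence_length,
                 contour_length = contour_length,
                 segment_length = segment_length,
                 n_segments = n_seg,
                 n_chains = as.integer(n_chains),
                 seed = seed),
            class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf(
    "2D worm-like chain: L_p = %g nm, L_c = %g nm, L_s = %g nm (%d segments)\n",
    x$persistence_length, x$contour_length, x$segment_length, x$n_segments))
  invisible(x)
}

deflection_sd <- function(params) {
  sqrt(params$segment_length / params$persistence_length)
}

#' Simulate a single worm-like chain trace
#'
#' The first vertex is at the origin and the first segment points along +x;
#' end-to-end statistics are rotation invariant so this choice is free.
#'
#' @param params a [wlc_params()] object.
#' @param seed optional seed overriding `params$seed`.
#' @return a `"chain_trace"`: an `(N + 1) x 2` matrix of vertex coordinates
#'   (nm) with columns `x`, `y` and attribute `segment_length`.
#' @examples
#' tr <- simulate_chain(wlc_params(3.8, 46), seed = 1)
#' nrow(tr)  # 231 vertices
#' @export
simulate_chain <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "wlc_params"))
  m <- with_seed(seed, cpp_wlc_chain(params$n_segments,
                                     params$segment_length,
                                     deflection_sd(params), 0))
  colnames(m) <- c("x", "y")
  structure(m, segment_length = params$segment_length,
            class = c("chain_trace", class(m)))
}

#' Simulate an ensemble of end-to-end distances
#'
#' Simulates `params$n_chains` independent chains and returns only their
#' end-to-end (first-to-last vertex) distances.
#'
#' @inheritParams simulate_chain
#' @param n_chains optional override of `params$n_chains`.
#' @return numeric vector of distances (nm) with attribute `params`.
#' @export
simulate_end_to_end <- function(params, seed = params$seed,
                                n_chains = params$n_chains) {
  stopifnot(inherits(params, "wlc_params"))
  if (!is.numeric(n_chains) || length(n_chains) != 1L || n_chains < 1)
    stop_param("n_chains", "must be a positive count")
  d <- with_seed(seed, cpp_wlc_end_to_end(as.integer(n_chains),
                                          params$n_segments,
                                          params$segment_length,
                                          deflection_sd(params)))
  attr(d, "params") <- params
  d
}

#' Closed-form mean squared end-to-end distance of a 2D worm-like chain
#'
#' For a surface-equilibrated chain,
#' `<R^2> = 4 L_p L_c (1 - (2 L_p / L_c) (1 - exp(-L_c / (2 L_p))))`,
#' the double integral of the tangent correlation
#' `exp(-|s - s'| / (2 L_p))` over the square `[0, L_c]^2`.
#' In the stiff limit (`L_p >> L_c`) this tends to `L_c^2`; in the flexible
#' limit it tends to `4 L_p L_c`.
#'
#' @param persistence_length L_p in nm (> 0); vectorized.
#' @param contour_length L_c in nm (> 0); vectorized.
#' @return mean squared end-to-end distance in nm^2.
#' @examples
#' msd_closed_form(3.8, 46)  # ~ 584 nm^2
#' @export
msd_closed_form <- function(persistence_length, contour_length) {
  if (!is.numeric(persistence_length) || any(!is.finite(persistence_length)) ||
      any(persistence_length <= 0))
    stop_param("persistence_length", "must be positive and finite")
  if (!is.numeric(contour_length) || any(!is.finite(contour_length)) ||
      any(contour_length <= 0))
    stop_param("contour_length", "must be positive and finite")
  lp <- persistence_length
  lc <- contour_length
  4 * lp * lc * (1 - (2 * lp / lc) * (1 - exp(-lc / (2 * lp))))
}

#' Moment-based persistence-length estimate from end-to-end distances
#'
#' Inverts the closed-form 2D mean squared end-to-end distance at a known
#' contour length: returns the `L_p` whose predicted `<R^2>` equals the
#' empirical mean square of the sample.  The inversion is a bracketed
#' monotone root search on `L_p` in `[1e-3, 1e6]` nm (relative tolerance
#' 1e-6).  Note that this estimator uses only the second moment; samples in
#' which small distances are under-represented (e.g. head-hinge engagement
#' removing near-zero separations) bias it upward.
#'
#' @param distances numeric vector of end-to-end distances (nm), non-empty.
#' @param contour_length known contour length (nm).
#' @return estimated persistence length (nm).
#' @export
rivetti_estimator <- function(distances, contour_length) {
  if (length(distances) == 0L)
    stop("cannot estimate persistence length from an empty sample",
         call. = FALSE)
  if (!is.numeric(contour_length) || length(contour_length) != 1L ||
      contour_length <= 0)
    stop_param("contour_length", "must be a single positive number")
  msq <- mean(distances^2)
  if (msq >= contour_length^2)
    stop(sprintf(paste0("mean squared distance (%.4g nm^2) reaches the ",
                        "rigid-rod limit L_c^2 = %.4g nm^2: ",
                        "no finite persistence length"),
                 msq, contour_length^2), call. = FALSE)
  lo <- 1e-3
  hi <- 1e6
  f <- function(u) msd_closed_form(10^u, contour_length) - msq
  if (f(log10(lo)) > 0)
    stop("mean squared distance below the reachable range of the model",
         call. = FALSE)
  r <- uniroot(f, c(log10(lo), log10(hi)), tol = 1e-8)
  10^r$root
}

#' Tangent-tangent correlation of an ensemble of chain traces
#'
#' Mean cosine of the angle between tangents separated by arc length `s`,
#' averaged over all positions along each chain and over chains.  For the 2D
#' worm-like chain the expectation is `exp(-s / (2 L_p))`.
#'
#' @param traces a single `"chain_trace"` or a list of them, all sharing the
#'   same segment length.
#' @param s arc-length separation (nm), `0 <= s <= L_c`.
#' @return the mean tangent correlation (dimensionless).
#' @export
tangent_correlation <- function(traces, s) {
  if (inherits(traces, "chain_trace")) traces <- list(traces)
  stopifnot(length(traces) > 0L, inherits(traces[[1L]], "chain_trace"))
  ls <- attr(traces[[1L]], "segment_length")
  n_seg <- nrow(traces[[1L]]) - 1L
  lc <- n_seg * ls
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > lc + 1e-9)
    stop_param("s", sprintf("must lie in [0, %g] nm", lc))
  k <- as.integer(round(s / ls))
  if (k == 0L) return(1.0)
  vals <- vapply(traces, function(tr) {
    if (!identical(attr(tr, "segment_length"), ls) || nrow(tr) != n_seg + 1L)
      stop("all traces must share the same discretization", call. = FALSE)
    dx <- diff(tr[, 1L])
    dy <- diff(tr[, 2L])
    th <- atan2(dy, dx)
    mean(cos(th[(1L + k):n_seg] - th[1L:(n_seg - k)]))
  }, numeric(1))
  mean(vals)
}
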