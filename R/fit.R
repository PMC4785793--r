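#' Configuration of the histogram least-squares WLC fit
#'
#' Defaults: `L_p` grid on `[1, 20]` nm, `L_c` grid on `[20, 80]` nm, 15
#' points per axis, three refinement rounds (each halving the search window
#' around the running minimum), 2e4 simulated chains per grid evaluation,
#' 2-nm histogram bins over `[0, 60]` nm, 50 parametric replicates for the
#' one-SD confidence intervals.
#'
#' @param lp_range,lc_range numeric length-2 search ranges (nm), ordered.
#' @param grid_points points per axis of the search grid (>= 3).
#' @param refinement_rounds number of grid-shrinkage rounds (>= 0).
#' @param chains_per_eval Monte-Carlo chains per grid evaluation.
#' @param bin_width histogram bin width (nm).
#' @param hist_max upper edge of the histogram range `[0, hist_max]` (nm);
#'   must be an integer multiple of `bin_width`.
#' @param ci_replicates parametric replicates used by [confidence_sd()].
#' @param segment_length WLC discretization (nm).
#' @param seed integer seed controlling every simulation in the fit.
#' @return an object of class `"fit_config"`.
#' @export
fit_config <- function(lp_range = c(1, 20), lc_range = c(20, 80),
                       grid_points = 15, refinement_rounds = 3,
                       chains_per_eval = 2e4, bin_width = 2, hist_max = 60,
                       ci_replicates = 50, segment_length = 0.2, seed = 1) {
  chk_range <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 2L || any(r <= 0) || r[1] >= r[2])
      stop_param(nm, "must be a positive ordered (min, max) pair")
  }
  chk_range(lp_range, "lp_range")
  chk_range(lc_range, "lc_range")
  if (grid_points < 3) stop_param("grid_points", "must be >= 3")
  if (refinement_rounds < 0) stop_param("refinement_rounds", "must be >= 0")
  if (chains_per_eval < 1) stop_param("chains_per_eval", "must be >= 1")
  if (bin_width <= 0) stop_param("bin_width", "must be > 0")
  if (hist_max <= 0) stop_param("hist_max", "must be > 0")
  structure(list(lp_range = as.numeric(lp_range),
                 lc_range = as.numeric(lc_range),
                 grid_points = as.integer(grid_points),
                 refinement_rounds = as.integer(refinement_rounds),
                 chains_per_eval = as.integer(chains_per_eval),
                 bin_width = bin_width, hist_max = hist_max,
                 ci_replicates = as.integer(ci_replicates),
                 segment_length = segment_length,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Binned probability density of a distance sample
#'
#' Bins are half-open `[lo, hi)` with equal width covering `range` exactly.
#' The density is normalized by the *total* sample size, so it integrates to
#' the in-range fraction of the data (1 when the range covers all of it).
#'
#' @param distances numeric vector (nm), non-empty.
#' @param bin_width bin width (nm).
#' @param range numeric length-2 `(lo, hi)`; `(hi - lo)` must be an integer
#'   multiple of `bin_width`.
#' @return an object of class `"binned_density"` with fields `breaks`,
#'   `mids`, `density`, `n` and `n_in_range`.
#' @export
histogram_density <- function(distances, bin_width, range = c(0, 60)) {
  if (length(distances) == 0L)
    stop("cannot bin an empty sample", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop_param("bin_width", "must be > 0")
  width <- range[2] - range[1]
  n_bins <- width / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8)
    stop_param("range", "must be an integer number of bins wide")
  n_bins <- as.integer(round(n_bins))
  breaks <- range[1] + bin_width * (0:n_bins)
  idx <- floor((distances - range[1]) / bin_width) + 1
  keep <- idx >= 1 & idx <= n_bins
  counts <- tabulate(idx[keep], nbins = n_bins)
  structure(list(breaks = breaks,
                 mids = breaks[-1L] - bin_width / 2,
                 density = counts / (length(distances) * bin_width),
                 n = length(distances),
                 n_in_range = sum(keep)),
            class = "binned_density")
}

#' Least-squares distance between two binned densities
#'
#' The goodness-of-fit score of the histogram fit: the sum over bins of the
#' squared difference between the two densities.  Zero iff identical.
#'
#' @param empirical,simulated `"binned_density"` objects on identical bins.
#' @return non-negative score.
#' @export
gof_least_squares <- function(empirical, simulated) {
  stopifnot(inherits(empirical, "binned_density"),
            inherits(simulated, "binned_density"))
  if (length(empirical$breaks) != length(simulated$breaks) ||
      any(abs(empirical$breaks - simulated$breaks) > 1e-9))
    stop("histograms have mismatched bin edges", call. = FALSE)
  sum((empirical$density - simulated$density)^2)
}

wlc_sim_density <- function(lp, lc, config, seed) {
  n_seg <- max(1L, as.integer(round(lc / config$segment_length)))
  d <- with_seed(seed,
                 cpp_wlc_end_to_end(config$chains_per_eval, n_seg,
                                    config$segment_length,
                                    sqrt(config$segment_length / lp)))
  histogram_density(d, config$bin_width, c(0, config$hist_max))
}

#' Fit worm-like-chain parameters to an end-to-end distance sample
#'
#' Grid search over `(L_p, L_c)`: each candidate is scored by simulating
#' `chains_per_eval` chains, binning their end-to-end distances on the same
#' bins as the data, and computing the least-squares score
#' ([gof_least_squares()]).  The grid is then refined `refinement_rounds`
#' times, halving the search window around the running minimum (clipped to
#' the initial ranges).  Every evaluation reuses the same derived seed
#' (common random numbers), so the score surface is deterministic given
#' `config$seed` and simulation jitter largely cancels in the argmin.
#'
#' @param distances numeric end-to-end distance sample (nm).  Samples with
#'   fewer than 50 values trigger a warning.
#' @param config a [fit_config()].
#' @return an object of class `"wlc_fit"`: fields `lp_hat`, `lc_hat`
#'   (best-fit values, nm), `lp_sd`, `lc_sd` (NA until [confidence_sd()] is
#'   run), `gof_surface` (data.frame of every evaluated `lp`, `lc`, `score`,
#'   `round`), `n_data`, `boundary_warning`, `config`.
#' @export
fit_wlc <- function(distances, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  if (length(distances) == 0L)
    stop("cannot fit an empty sample", call. = FALSE)
  if (length(distances) < 50L)
    warning(sprintf("only %d distances: fit will be poorly constrained",
                    length(distances)), call. = FALSE)
  emp <- histogram_density(distances, config$bin_width, c(0, config$hist_max))
  eval_seed <- derive_seed(config$seed, 7)

  lp_win <- config$lp_range
  lc_win <- config$lc_range
  surface <- vector("list", config$refinement_rounds + 1L)
  best <- list(score = Inf, lp = NA_real_, lc = NA_real_)
  for (round_i in 0:config$refinement_rounds) {
    lp_grid <- seq(lp_win[1], lp_win[2], length.out = config$grid_points)
    lc_grid <- seq(lc_win[1], lc_win[2], length.out = config$grid_points)
    g <- expand.grid(lp = lp_grid, lc = lc_grid)
    g$score <- mapply(function(lp, lc) {
      gof_least_squares(emp, wlc_sim_density(lp, lc, config, eval_seed))
    }, g$lp, g$lc)
    g$round <- round_i
    surface[[round_i + 1L]] <- g
    i <- which.min(g$score)
    if (g$score[i] < best$score)
      best <- list(score = g$score[i], lp = g$lp[i], lc = g$lc[i])
    # shrink the window by half, centred on the running minimum
    shrink <- function(win, centre, full) {
      hw <- (win[2] - win[1]) / 4
      c(max(full[1], centre - hw), min(full[2], centre + hw))
    }
    lp_win <- shrink(lp_win, best$lp, config$lp_range)
    lc_win <- shrink(lc_win, best$lc, config$lc_range)
  }
  surface <- do.call(rbind, surface)
  final_spacing_lp <- (lp_win[2] - lp_win[1]) / (config$grid_points - 1)
  final_spacing_lc <- (lc_win[2] - lc_win[1]) / (config$grid_points - 1)
  boundary <- (best$lp <= config$lp_range[1] + final_spacing_lp ||
               best$lp >= config$lp_range[2] - final_spacing_lp ||
               best$lc <= config$lc_range[1] + final_spacing_lc ||
               best$lc >= config$lc_range[2] - final_spacing_lc)
  if (boundary)
    warning("goodness-of-fit minimum lies on the search boundary",
            call. = FALSE)
  structure(list(lp_hat = best$lp, lc_hat = best$lc,
                 lp_sd = NA_real_, lc_sd = NA_real_,
                 gof = best$score, gof_surface = surface,
                 n_data = length(distances),
                 boundary_warning = boundary,
                 config = config),
            class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("WLC histogram fit (n = %d distances)\n", x$n_data))
  cat(sprintf("  L_p = %.2f %s nm\n", x$lp_hat,
              if (is.na(x$lp_sd)) "(sd not computed)"
              else sprintf("+/- %.2f", x$lp_sd)))
  cat(sprintf("  L_c = %.1f %s nm\n", x$lc_hat,
              if (is.na(x$lc_sd)) "(sd not computed)"
              else sprintf("+/- %.1f", x$lc_sd)))
  if (x$boundary_warning)
    cat("  warning: minimum on search boundary\n")
  invisible(x)
}

#' Parametric Monte-Carlo one-SD confidence intervals for a WLC fit
#'
#' Simulates `n_replicates` synthetic datasets of the fitted sample size at
#' the best-fit `(L_p, L_c)`, refits each with the same configuration, and
#' returns the standard deviations of the refitted parameters — the
#' Monte-Carlo analogue of a one-SD confidence interval.
#'
#' @param fit a `"wlc_fit"` without boundary warning.
#' @param config fit configuration (defaults to the one stored in `fit`).
#' @param n_replicates number of parametric replicates (>= 10).
#' @return named numeric `c(lp_sd =, lc_sd =)` with attribute `replicates`
#'   (matrix of the refitted parameters).
#' @export
confidence_sd <- function(fit, config = fit$config,
                          n_replicates = config$ci_replicates) {
  stopifnot(inherits(fit, "wlc_fit"))
  if (fit$boundary_warning)
    stop("fit minimum lies on the search boundary; confidence SD undefined",
         call. = FALSE)
  if (n_replicates < 10)
    stop("need at least 10 replicates for a usable SD", call. = FALSE)
  gen <- wlc_params(fit$lp_hat, fit$lc_hat, config$segment_length,
                    n_chains = fit$n_data)
  est <- vapply(seq_len(n_replicates), function(r) {
    rep_seed <- derive_seed(config$seed, 1000 + r)
    d <- simulate_end_to_end(gen, seed = rep_seed)
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, 5000 + r)
    f <- suppressWarnings(fit_wlc(d, cfg_r))
    c(f$lp_hat, f$lc_hat)
  }, numeric(2))
  out <- c(lp_sd = sd(est[1L, ]), lc_sd = sd(est[2L, ]))
  attr(out, "replicates") <- t(est)
  out
}
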