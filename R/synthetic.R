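#' Default conformational-state transition matrix
#'
#' Row-stochastic 4 x 4 matrix over the states `V, O, B, P` with stay
#' probability `stay` and the remaining mass distributed in proportion to
#' the target stationary distribution, which is therefore the exact
#' stationary distribution of the chain.  The default stationary weights
#' put a quarter of the frames in V and make O the most abundant class,
#' so O<->B switching dominates the off-diagonal traffic.
#'
#' @param stationary named stationary probabilities over `V, O, B, P`.
#' @param stay per-frame probability of remaining in the current state.
#' @return a 4 x 4 row-stochastic matrix.
#' @export
default_transition_matrix <- function(stationary = c(V = 0.25, O = 0.40,
                                                     B = 0.20, P = 0.15),
                                      stay = 0.9) {
  stopifnot(abs(sum(stationary) - 1) < 1e-9, stay >= 0, stay < 1)
  states <- c("V", "O", "B", "P")
  pi0 <- stationary[states]
  m <- stay * diag(4) + (1 - stay) * matrix(pi0, 4, 4, byrow = TRUE)
  dimnames(m) <- list(from = states, to = states)
  m
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param transition_matrix square row-stochastic matrix.
#' @return named stationary probability vector.
#' @export
stationary_distribution <- function(transition_matrix) {
  e <- eigen(t(transition_matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  setNames(v, colnames(transition_matrix))
}

#' Configuration of the synthetic dimer-movie generator
#'
#' Each frame places the hinge at the origin and grows two independent
#' worm-like-chain arms with uniformly random initial directions; the arm
#' endpoints are the heads.  The conformational state dictates acceptance
#' constraints imposed by rejection sampling, which preserves the exact
#' conditional WLC ensemble:
#' * **V** — both head-hinge distances and the head-head distance exceed the
#'   engagement thresholds;
#' * **O** — the head-head distance matches a draw from the engaged
#'   head-head distribution within `engagement_tol`, both arms open;
#' * **B** — each head-hinge distance matches an independent draw from the
#'   engaged head-hinge distribution within `engagement_tol`;
#' * **P** — one randomly chosen arm is hinge-engaged as in B, the other is
#'   open with head-head distance above threshold.
#'
#' Engaged-distance draws come from Gaussians truncated at zero.  Isotropic
#' Gaussian localization noise is added to the emitted landmarks only; the
#' ground truth and arm traces stay noiseless.
#'
#' @param arm [wlc_params()] of one coiled-coil arm (defaults
#'   `L_p = 3.8` nm, `L_c = 46` nm, `L_s = 0.2` nm).
#' @param transition_matrix row-stochastic 4 x 4 over `V, O, B, P`.
#' @param initial_state `"stationary"` or one of `V, O, B, P`.
#' @param n_frames number of movie frames.
#' @param frame_interval seconds between frames (default 0.1).
#' @param engaged_head_head `(mean, sd)` nm of the engaged head-head
#'   distance distribution (default 2.5, 1.3).
#' @param engaged_head_hinge `(mean, sd)` nm of the engaged head-hinge
#'   distance distribution (default 2.4, 1.9).
#' @param localization_noise_sd isotropic landmark noise SD (nm).
#' @param engagement_tol half-width (nm) within which a sampled arm must
#'   match its engaged-distance draw.
#' @param thresholds [thresholds()] shared with the classifier, so ground
#'   truth and classification agree by construction.
#' @param rejection_cap maximum chains simulated per frame before erroring.
#' @param seed integer seed.
#' @return an object of class `"synth_config"`.
#' @export
synth_config <- function(arm = wlc_params(3.8, 46, 0.2),
                         transition_matrix = default_transition_matrix(),
                         initial_state = "stationary",
                         n_frames = 500,
                         frame_interval = 0.1,
                         engaged_head_head = c(mean = 2.5, sd = 1.3),
                         engaged_head_hinge = c(mean = 2.4, sd = 1.9),
                         localization_noise_sd = 0.5,
                         engagement_tol = 0.5,
                         thresholds = smcflex::thresholds(),
                         rejection_cap = 1e5,
                         seed = NULL) {
  stopifnot(inherits(arm, "wlc_params"), inherits(thresholds, "thresholds"))
  if (!all(dim(transition_matrix) == c(4, 4)) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9) ||
      any(transition_matrix < 0))
    stop_param("transition_matrix", "must be 4x4 row-stochastic")
  if (is.null(dimnames(transition_matrix)))
    dimnames(transition_matrix) <- list(from = c("V", "O", "B", "P"),
                                        to = c("V", "O", "B", "P"))
  if (!initial_state %in% c("stationary", "V", "O", "B", "P"))
    stop_param("initial_state", "must be 'stationary' or one of V, O, B, P")
  if (n_frames < 1) stop_param("n_frames", "must be >= 1")
  if (frame_interval <= 0) stop_param("frame_interval", "must be > 0")
  chk_dist <- function(d, nm) {
    if (length(d) != 2L || any(d <= 0)) stop_param(nm, "needs positive (mean, sd)")
  }
  chk_dist(engaged_head_head, "engaged_head_head")
  chk_dist(engaged_head_hinge, "engaged_head_hinge")
  if (localization_noise_sd < 0) stop_param("localization_noise_sd", "must be >= 0")
  if (engagement_tol <= 0) stop_param("engagement_tol", "must be > 0")
  if (rejection_cap < 1) stop_param("rejection_cap", "must be >= 1")
  structure(list(arm = arm, transition_matrix = transition_matrix,
                 initial_state = initial_state,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 engaged_head_head = unname(engaged_head_head),
                 engaged_head_hinge = unname(engaged_head_hinge),
                 localization_noise_sd = localization_noise_sd,
                 engagement_tol = engagement_tol,
                 thresholds = thresholds,
                 rejection_cap = as.integer(rejection_cap),
                 seed = seed),
            class = "synth_config")
}

#' Draw from a Gaussian truncated at zero
#'
#' Rejection sampling of `N(mean, sd^2)` conditioned on non-negative values;
#' used for the engaged-distance distributions.
#'
#' @param n number of draws.
#' @param mean,sd Gaussian location and scale (nm).
#' @param seed optional seed.
#' @return numeric vector of non-negative draws.
#' @export
sample_engaged_distance <- function(n, mean, sd, seed = NULL) {
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n - length(out) + ceiling(0.2 * n) + 8L, mean, sd)
      out <- c(out, x[x >= 0])
    }
    out[seq_len(n)]
  })
}

#' Sample a conformational-state sequence from a Markov chain
#'
#' @param transition_matrix row-stochastic 4 x 4 over `V, O, B, P`.
#' @param n_frames sequence length.
#' @param initial_state `"stationary"` or a state label.
#' @param seed optional seed.
#' @return character vector of states.
#' @export
sample_state_sequence <- function(transition_matrix, n_frames,
                                  initial_state = "stationary",
                                  seed = NULL) {
  states <- colnames(transition_matrix)
  if (is.null(states)) {
    states <- c("V", "O", "B", "P")
    dimnames(transition_matrix) <- list(states, states)
  }
  with_seed(seed, {
    s <- character(n_frames)
    if (identical(initial_state, "stationary")) {
      p0 <- stationary_distribution(transition_matrix)
      s[1L] <- sample(states, 1L, prob = p0)
    } else {
      s[1L] <- initial_state
    }
    for (i in seq_len(n_frames - 1L)) {
      s[i + 1L] <- sample(states, 1L,
                          prob = transition_matrix[s[i], ])
    }
    s
  })
}

# state -> constraint ranges for the arm-pair rejection sampler
state_constraints <- function(state, config) {
  thr_hh <- config$thresholds$head_head_engaged
  thr_hg <- config$thresholds$head_hinge_engaged
  tol <- config$engagement_tol
  inf <- .Machine$double.xmax
  band <- function(target) c(max(0, target - tol), target + tol)
  open_g <- c(thr_hg, inf)
  switch(state,
    V = list(g1 = open_g, g2 = open_g, hh = c(thr_hh, inf)),
    O = {
      t <- sample_engaged_distance(1L, config$engaged_head_head[1],
                                   config$engaged_head_head[2])
      list(g1 = open_g, g2 = open_g, hh = band(t))
    },
    B = {
      t1 <- sample_engaged_distance(1L, config$engaged_head_hinge[1],
                                    config$engaged_head_hinge[2])
      t2 <- sample_engaged_distance(1L, config$engaged_head_hinge[1],
                                    config$engaged_head_hinge[2])
      list(g1 = band(t1), g2 = band(t2), hh = c(-1, inf))
    },
    P = {
      t <- sample_engaged_distance(1L, config$engaged_head_hinge[1],
                                   config$engaged_head_hinge[2])
      eng <- band(t)
      if (runif(1L) < 0.5) list(g1 = eng, g2 = open_g, hh = c(thr_hh, inf))
      else list(g1 = open_g, g2 = eng, hh = c(thr_hh, inf))
    },
    stop_param("state", "must be one of V, O, B, P"))
}

#' Sample one dimer conformation in a given state
#'
#' Draws the current random-number stream (use [with_seed()] or
#' [generate_movie()] for reproducibility).
#'
#' @param state one of `"V", "O", "B", "P"`.
#' @param config a [synth_config()].
#' @param frame_id,time_s identifiers stored in the emitted frame.
#' @return a list with elements `frame` (one-row noisy landmark data.frame),
#'   `truth` (noiseless landmark row plus `true_state`), `arm1_trace`,
#'   `arm2_trace` (noiseless polylines from hinge to head), and `tries`
#'   (chains simulated by the rejection sampler).
#' @export
sample_dimer_conformation <- function(state, config, frame_id = 0L,
                                      time_s = 0) {
  stopifnot(inherits(config, "synth_config"))
  con <- state_constraints(state, config)
  arm <- config$arm
  res <- cpp_sample_dimer_arms(arm$n_segments, arm$segment_length,
                               deflection_sd(arm),
                               con$g1[1], con$g1[2],
                               con$g2[1], con$g2[2],
                               con$hh[1], con$hh[2],
                               config$rejection_cap)
  if (!isTRUE(res$success))
    stop(sprintf(paste0("rejection cap (%d chains) exceeded while sampling ",
                        "state %s at L_p = %g, L_c = %g"),
                 config$rejection_cap, state, arm$persistence_length,
                 arm$contour_length), call. = FALSE)
  n <- nrow(res$arm1)
  head1 <- res$arm1[n, ]
  head2 <- res$arm2[n, ]
  hinge <- c(0, 0)
  noise <- function(p) p + rnorm(2L, 0, config$localization_noise_sd)
  truth <- dimer_frames(frame_id, time_s, head1, head2, hinge)
  truth$true_state <- state
  list(frame = dimer_frames(frame_id, time_s,
                            noise(head1), noise(head2), noise(hinge)),
       truth = truth,
       arm1_trace = res$arm1, arm2_trace = res$arm2,
       tries = res$tries)
}

#' Generate a synthetic dimer movie with ground truth
#'
#' States evolve by the configured Markov chain, one step per frame; each
#' frame's geometry is drawn by [sample_dimer_conformation()].  Frame times
#' are `frame_id * frame_interval` with `frame_id` starting at 0.
#'
#' @param config a [synth_config()].
#' @return an object of class `"synthetic_movie"`: `frames` (noisy landmark
#'   data.frame), `truth` (noiseless landmarks plus `true_state`), `traces`
#'   (per-frame list of `arm1`/`arm2` polylines), `total_tries`, `config`.
#' @export
generate_movie <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    states <- sample_state_sequence(config$transition_matrix,
                                    config$n_frames, config$initial_state)
    frames <- vector("list", config$n_frames)
    truth <- vector("list", config$n_frames)
    traces <- vector("list", config$n_frames)
    total_tries <- 0
    for (i in seq_len(config$n_frames)) {
      sm <- sample_dimer_conformation(states[i], config,
                                      frame_id = i - 1L,
                                      time_s = (i - 1L) * config$frame_interval)
      frames[[i]] <- sm$frame
      truth[[i]] <- sm$truth
      traces[[i]] <- list(arm1 = sm$arm1_trace, arm2 = sm$arm2_trace)
      total_tries <- total_tries + sm$tries
    }
    structure(list(frames = do.call(rbind, frames),
                   truth = do.call(rbind, truth),
                   traces = traces,
                   total_tries = total_tries,
                   config = config),
              class = "synthetic_movie")
  })
}

#' @export
print.synthetic_movie <- function(x, ...) {
  cat(sprintf("synthetic dimer movie: %d frames at %g s intervals\n",
              nrow(x$frames), x$config$frame_interval))
  tab <- table(factor(x$truth$true_state, levels = c("V", "O", "B", "P")))
  cat("  true states:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  rejection efficiency: %.3g accepted arms per simulated chain\n",
              2 * nrow(x$frames) / x$total_tries))
  invisible(x)
}

#' Generate an end-to-end distance dataset from V-state frames
#'
#' Emulates the sample used for persistence-length fitting: both head-hinge
#' distances of `n` V-state frames (open arms only, noiseless), giving `2n`
#' distances.
#'
#' @param config a [synth_config()].
#' @param n number of V-state frames.
#' @return numeric vector of `2n` distances (nm).
#' @export
generate_end_to_end_dataset <- function(config = synth_config(), n = 1000) {
  stopifnot(inherits(config, "synth_config"))
  if (n < 1) stop_param("n", "must be >= 1")
  with_seed(config$seed, {
    out <- numeric(2 * n)
    for (i in seq_len(n)) {
      con <- state_constraints("V", config)
      arm <- config$arm
      res <- cpp_sample_dimer_arms(arm$n_segments, arm$segment_length,
                                   deflection_sd(arm),
                                   con$g1[1], con$g1[2],
                                   con$g2[1], con$g2[2],
                                   con$hh[1], con$hh[2],
                                   config$rejection_cap)
      if (!isTRUE(res$success))
        stop("rejection cap exceeded while sampling V frames", call. = FALSE)
      out[2 * i - 1L] <- res$g1
      out[2 * i] <- res$g2
    }
    out
  })
}
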