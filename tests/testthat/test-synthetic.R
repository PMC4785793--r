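test_that("synth config validates its transition matrix and scales", {
  bad <- default_transition_matrix()
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(synth_config(transition_matrix = bad), "row-stochastic")
  expect_error(synth_config(localization_noise_sd = -1), "noise")
  expect_error(synth_config(n_frames = 0), "n_frames")
  expect_error(sample_dimer_conformation("X", synth_config()), "state")
})

test_that("default transition matrix has the configured stationary law", {
  m <- default_transition_matrix()
  expect_equal(rowSums(m), setNames(rep(1, 4), c("V", "O", "B", "P")))
  expect_equal(stationary_distribution(m),
               c(V = 0.25, O = 0.40, B = 0.20, P = 0.15), tolerance = 1e-9)
})

test_that("state sequences follow the transition matrix", {
  m <- default_transition_matrix()
  s <- sample_state_sequence(m, 5000, seed = 71)
  # chi-squared goodness of fit of empirical transition counts, pooled
  from <- s[-length(s)]
  to <- s[-1]
  states <- c("V", "O", "B", "P")
  obs <- table(factor(from, states), factor(to, states))
  expected <- rowSums(obs) * m
  stat <- sum((obs - expected)^2 / expected)
  p_val <- pchisq(stat, df = 4 * 3, lower.tail = FALSE)
  expect_gt(p_val, 0.01)
  # identity matrix freezes the chain
  s_id <- sample_state_sequence(diag(4), 50, initial_state = "V", seed = 1)
  expect_true(all(s_id == "V"))
})

test_that("V-state frames satisfy the open predicate exactly", {
  cfg <- synth_config(n_frames = 150, seed = 81,
                      transition_matrix = diag(4),
                      initial_state = "V")
  mov <- generate_movie(cfg)
  g <- head_hinge_distances(mov$truth)
  hh <- head_head_distance(mov$truth)
  expect_true(all(g > 7))
  expect_true(all(hh > 7))
  expect_true(all(as.character(classify_frames(mov$truth)) == "V"))
})

test_that("B-state head-hinge distances match the engaged distribution", {
  cfg <- synth_config(n_frames = 600, seed = 82,
                      transition_matrix = diag(4),
                      initial_state = "B", localization_noise_sd = 0)
  mov <- generate_movie(cfg)
  g <- as.numeric(head_hinge_distances(mov$truth))
  target <- truncnorm0_moments(2.4, 1.9)
  expect_equal(mean(g), unname(target["mean"]), tolerance = 0.2 / 2.78)
  # rejection efficiency: on the order of the single-arm return mass
  rate <- (2 * cfg$n_frames) / mov$total_tries
  expect_gt(rate, 1e-4)
  expect_lt(rate, 1e-1)
})

test_that("O-state head-head distances match the engaged distribution", {
  cfg <- synth_config(n_frames = 300, seed = 83,
                      transition_matrix = diag(4),
                      initial_state = "O", localization_noise_sd = 0)
  mov <- generate_movie(cfg)
  hh <- head_head_distance(mov$truth)
  target <- truncnorm0_moments(2.5, 1.3)
  expect_equal(mean(hh), unname(target["mean"]), tolerance = 0.25 / 2.6)
  # engaged draws land above the 7-nm threshold only ~0.1% of the time
  expect_gte(mean(as.character(classify_frames(mov$truth)) == "O"), 0.99)
})

test_that("truncated-Gaussian sampler reproduces the requested moments", {
  for (par in list(c(2.5, 1.3), c(2.4, 1.9))) {
    x <- sample_engaged_distance(2e4, par[1], par[2], seed = 84)
    expect_true(all(x >= 0))
    m <- truncnorm0_moments(par[1], par[2])
    expect_equal(mean(x), unname(m["mean"]),
                 tolerance = 3 * m["sd"] / sqrt(2e4) / m["mean"])
    expect_equal(sd(x), unname(m["sd"]), tolerance = 0.05)
  }
})

test_that("movies are reproducible and carry consistent ground truth", {
  cfg <- synth_config(n_frames = 60, seed = 85)
  m1 <- generate_movie(cfg)
  m2 <- generate_movie(cfg)
  expect_identical(m1$frames, m2$frames)
  expect_identical(m1$truth$true_state, m2$truth$true_state)
  expect_equal(nrow(m1$frames), 60L)
  expect_equal(m1$frames$time_s, (0:59) * 0.1)
  # arm traces run from the hinge to the head
  tr <- m1$traces[[1]]
  expect_equal(unname(tr$arm1[1, ]), c(0, 0))
  n <- nrow(tr$arm1)
  expect_equal(unname(tr$arm1[n, ]),
               unname(as.numeric(m1$truth[1, c("head1_x_nm", "head1_y_nm")])),
               tolerance = 1e-9)
})

test_that("classifier recovers ground-truth states from noisy landmarks", {
  cfg <- synth_config(n_frames = 400, seed = 86)   # default 0.5 nm noise
  mov <- generate_movie(cfg)
  acc <- mean(as.character(classify_frames(mov$frames)) ==
                mov$truth$true_state)
  expect_gte(acc, 0.95)
  cfg1 <- synth_config(n_frames = 300, localization_noise_sd = 1, seed = 87)
  mov1 <- generate_movie(cfg1)
  acc1 <- mean(as.character(classify_frames(mov1$frames)) ==
                 mov1$truth$true_state)
  expect_gte(acc1, 0.90)
})

test_that("V-conditioned end-to-end sample matches brute-force rejection", {
  d <- generate_end_to_end_dataset(synth_config(seed = 88), n = 1500)
  expect_length(d, 3000)
  expect_true(all(d > 7))
  # identical seeds give identical datasets
  expect_identical(d, generate_end_to_end_dataset(synth_config(seed = 88),
                                                  n = 1500))
  # oracle: plain unconditioned chains, V predicate applied by brute force
  p <- wlc_params(3.8, 46)
  set.seed(880)
  keep <- c()
  for (k in 1:4000) {
    a1 <- simulate_chain(p, seed = NULL)
    a2 <- simulate_chain(p, seed = NULL)
    phi <- runif(1, 0, 2 * pi)
    e1 <- a1[nrow(a1), ]
    e2r <- c(cos(phi) * a2[nrow(a2), 1] - sin(phi) * a2[nrow(a2), 2],
             sin(phi) * a2[nrow(a2), 1] + cos(phi) * a2[nrow(a2), 2])
    g1 <- sqrt(sum(e1^2))
    g2 <- sqrt(sum(e2r^2))
    hh <- sqrt(sum((e1 - e2r)^2))
    if (g1 > 7 && g2 > 7 && hh > 7) keep <- c(keep, g1, g2)
  }
  se <- sqrt(var(keep^2) / length(keep) + var(d^2) / length(d))
  expect_lt(abs(mean(keep^2) - mean(d^2)), 3 * se)
  # rigid arms degenerate to the contour length
  rigid <- synth_config(arm = wlc_params(1e6, 46), seed = 89)
  expect_equal(generate_end_to_end_dataset(rigid, n = 20), rep(46, 40),
               tolerance = 1e-4)
})
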