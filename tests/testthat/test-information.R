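test_that("uniform-count binning equipopulates with stable tie-breaking", {
  set.seed(1)
  x <- runif(120)
  b <- uniform_count_bins(x, 12)
  expect_true(all(tabulate(b, 12) == 10))
  ## ties broken by frame order (stable ranking)
  b2 <- uniform_count_bins(c(2, 1, 1, 3), 2)
  expect_equal(b2, c(2L, 1L, 1L, 2L))
  expect_error(uniform_count_bins(rep(1, 10), 2), "distinct")
})

test_that("equal-width bins match the analytic edges", {
  x <- c(0, 0.9, 1, 2.5, 3.999, 4)
  b <- equal_width_bins(x, 4, lo = 0, hi = 4)
  expect_equal(b, c(1L, 1L, 2L, 3L, 4L, 4L))
})

test_that("session discretization binarizes neurons and bins astrocytes", {
  pos <- runif(240)
  resp <- cbind(astro = rnorm(240), neuron = c(rep(0, 120), rep(0.5, 120)))
  d <- discretize_session(pos, resp, c("astro-soma", "neuron"), n_s = 12)
  expect_true(all(tabulate(d$s, 12) == 20))
  expect_equal(sort(unique(d$r[, "astro"])), 1:4)
  expect_equal(unname(d$r[, "neuron"]), c(rep(1L, 120), rep(2L, 120)))
})

test_that("plug-in MI equals brute-force summation and is relabel-invariant", {
  set.seed(2)
  for (i in 1:300) {
    ns <- sample(2:8, 1); nr <- sample(2:8, 1); n <- sample(30:150, 1)
    s <- sample(ns, n, replace = TRUE)
    r <- sample(nr, n, replace = TRUE)
    expect_lt(abs(plugin_mi(s, r) - brute_force_mi(s, r)), 1e-12)
  }
  s <- sample(4, 500, replace = TRUE)
  r <- sample(3, 500, replace = TRUE)
  perm_s <- sample(4); perm_r <- sample(3)
  expect_equal(plugin_mi(perm_s[s], perm_r[r]), plugin_mi(s, r),
               tolerance = 1e-12)
  ## deterministic uniform bijection: I = H(S) = 2 bits
  s <- rep(1:4, 100)
  expect_equal(plugin_mi(s, s), 2)
  ## exact product table: zero information
  d <- exact_cond_indep_pair(n_s = 1)
  expect_lt(plugin_mi(d$r1, d$r2), 1e-12)
})

test_that("permutation significance detects dependence and rejects tiny nulls", {
  set.seed(3)
  s <- sample(6, 600, replace = TRUE)
  res <- permutation_significance(s, s, n_perm = 500, seed = 4)
  expect_true(res$significant)
  expect_lt(res$p_value, 0.01)
  expect_error(permutation_significance(s, s, n_perm = 10), ">= 100")
})

test_that("independent responses are declared significant at the nominal rate", {
  set.seed(5)
  hits <- vapply(1:100, function(i) {
    s <- sample(8, 150, replace = TRUE)
    r <- sample(3, 150, replace = TRUE)
    permutation_significance(s, r, n_perm = 200, seed = i)$significant
  }, logical(1))
  ## binomial 99.9% envelope around 5%
  expect_lt(mean(hits), 0.14)
})

test_that("Panzeri-Treves penalty matches the closed form on a full table", {
  n <- 6000
  s <- rep(1:12, each = 500)
  r <- rep(rep(1:4, each = 125), 12)
  res <- bias_corrected_mi(s, r, "pt")
  expect_equal(res$mi_plugin - res$mi_corrected, (12 * 3 - 3) / (2 * n * log(2)),
               tolerance = 1e-12)
})

test_that("corrections barely move a strongly informative deterministic code", {
  s <- rep(1:4, 250)
  r <- s
  for (m in c("bootstrap", "pt", "qe")) {
    res <- bias_corrected_mi(s, r, m, n_perm = 100, qe_iterations = 30,
                             seed = 6)
    expect_lt(abs(res$mi_corrected - res$mi_plugin), 0.05)
    expect_gt(res$mi_corrected, 1.9)
  }
  expect_error(bias_corrected_mi(rep(1:2, 8), rep(1:2, 8), "qe"), "too few")
})

test_that("shuffled estimator corrects multi-ROI arrays and is near-unbiased", {
  set.seed(7)
  vals <- vapply(1:25, function(i) {
    s <- sample(8, 800, replace = TRUE)
    r <- cbind(sample(2, 800, TRUE), sample(2, 800, TRUE))
    bias_corrected_mi(s, r, "shuffled", n_perm = 40, seed = i)$mi_corrected
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.03)
})

test_that("information breakdown satisfies the exact plug-in identity", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(200:500, 1)
    s <- sample(sample(3:8, 1), n, replace = TRUE)
    r1 <- sample(sample(2:4, 1), n, replace = TRUE)
    r2 <- (r1 + s + sample(3, n, replace = TRUE)) %% 3 + 1
    b <- pair_breakdown(s, r1, r2, bias = "none")
    expect_lt(abs(b$I_LIN + b$I_SS + b$I_CI + b$I_CD - b$I), 1e-10)
    expect_lte(b$I_SS, 1e-12)
    expect_gte(b$I_CD, -1e-12)
  }
})

test_that("conditional independence zeroes the stimulus-dependent term", {
  d <- exact_cond_indep_pair()
  b <- pair_breakdown(d$s, d$r1, d$r2, bias = "none")
  expect_lt(abs(b$I_CD), 1e-10)
})

test_that("a duplicated ROI is fully redundant", {
  set.seed(9)
  s <- sample(6, 900, replace = TRUE)
  r1 <- rbinom(900, 1, c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2)[s]) + 1
  b <- pair_breakdown(s, r1, r1, bias = "none")
  expect_equal(b$I, plugin_mi(s, r1), tolerance = 1e-12)
  expect_lt(b$I_SS, 0)
  expect_equal(b$I_LIN, 2 * plugin_mi(s, r1), tolerance = 1e-12)
})

test_that("quadratic-extrapolation-corrected breakdown keeps the identity", {
  set.seed(10)
  s <- sample(6, 600, replace = TRUE)
  r1 <- rbinom(600, 1, 0.2 + 0.1 * s) + 1
  r2 <- rbinom(600, 1, 0.8 - 0.1 * s) + 1
  b <- pair_breakdown(s, r1, r2, bias = "qe", qe_iterations = 30, seed = 11)
  expect_lt(abs(b$I_LIN + b$I_SS + b$I_CI + b$I_CD - b$I), 1e-10)
})

test_that("trial-shuffle pair test flags planted within-stimulus correlation", {
  set.seed(12)
  n_s <- 8
  s <- sample(rep(1:n_s, each = 80))
  r1 <- rbinom(length(s), 1, 0.2 + 0.07 * s) + 1
  r2 <- rbinom(length(s), 1, 0.75 - 0.07 * s) + 1
  k <- which(s == 4)
  r2[k] <- r1[k]
  res <- trial_shuffle_pair_test(s, r1, r2, n_shuffle = 60, bias = "qe",
                                 qe_iterations = 10, seed = 13)
  expect_true(res$correlation_enhanced)
  expect_length(res$null, 60)
  expect_error(trial_shuffle_pair_test(s, r1, r2, n_shuffle = 0), "positive")
})

test_that("cue-constrained shuffle separates zone identity from position", {
  set.seed(14)
  n <- 2400
  pos <- runif(n, 0, 180)
  zone <- as.integer(pos %/% 60)
  ## zone-identity response: no information beyond the cue
  r_cue <- c(1L, 3L, 2L)[zone + 1L]
  res_cue <- cue_constrained_shuffle_info(pos, r_cue, zone, n_s = 12,
                                          n_perm = 60, seed = 15)
  expect_false(res_cue$genuine)
  ## place-tuned response: flagged
  p <- exp(-(pos - 90)^2 / (2 * 15^2))
  r_place <- rbinom(n, 1, 0.1 + 0.8 * p) + 1L
  res_place <- cue_constrained_shuffle_info(pos, r_place, zone, n_s = 12,
                                            n_perm = 60, seed = 16)
  expect_true(res_place$genuine)
  expect_error(cue_constrained_shuffle_info(pos, r_place, zone, n_s = 10),
               "divisible")
})

test_that("a single zone reduces the cue shuffle to the unrestricted null", {
  set.seed(17)
  n <- 1200
  pos <- runif(n, 0, 180)
  p <- exp(-(pos - 60)^2 / (2 * 12^2))
  r <- rbinom(n, 1, 0.1 + 0.8 * p) + 1L
  one_zone <- rep(0L, n)
  res <- cue_constrained_shuffle_info(pos, r, one_zone, n_s = 12,
                                      n_perm = 80, seed = 18)
  expect_true(res$genuine)    # full shuffle destroys all information
  ## the constrained null matches an unrestricted permutation null
  full <- vapply(1:80, function(i) {
    set.seed(1000 + i)
    s2 <- equal_width_bins(pos[sample(n)], 12, lo = 0, hi = 180)
    enc <- astroplace:::encode_response(r)
    astroplace:::mi_from_counts(
      astroplace:::joint_counts(s2, enc$code, 12, enc$n_levels)) -
      astroplace:::pt_penalty(s2, enc$code, enc$n_levels)
  }, numeric(1))
  expect_lt(abs(mean(res$I_V) - mean(full)), 3 * stats::sd(full))
})
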