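test_that("suffix scoring matches closed forms", {
  # uniform model: perplexity equals the vocabulary size exactly
  uni <- make_tabular_model(list(matrix(1 / 16, 1, 16),
                                 matrix(1 / 16, 16, 16)))
  rep16 <- score_suffix(uni, token_sequence(c(1L, 5L, 9L, 2L), 1L))
  expect_equal(rep16$perplexity, 16, tolerance = 1e-9)
  expect_equal(rep16$nll, log(16), tolerance = 1e-9)
  expect_equal(rep16$n_scored, 3L)
  # deterministic chain: perplexity 1
  det <- make_tabular_model(list(
    matrix(c(1, 0, 0), 1, 3),
    matrix(c(0, 1, 0,  0, 0, 1,  1, 0, 0), 3, 3, byrow = TRUE)))
  rep1 <- score_suffix(det, token_sequence(c(1L, 2L, 3L, 1L), 1L))
  expect_equal(rep1$perplexity, 1, tolerance = 1e-12)
  # hand chain rule on explicit rows: P(2|1) = 0.2? no: suffix [1,2] after [1]
  m <- fix_hand_tabular()
  rep2 <- score_suffix(m, token_sequence(c(1L, 1L, 2L), 1L))
  expect_equal(rep2$mean_logprob, (log(0.7) + log(0.2)) / 2,
               tolerance = 1e-12)
  expect_equal(rep2$perplexity, exp(rep2$nll), tolerance = 1e-12)
  expect_error(score_suffix(m, token_sequence(c(1L, 2L), 2L)), "suffix")
})

test_that("the single-step marginal identity holds algebraically", {
  expect_equal(exact_step_marginal(c(0.5, 0.3, 0.2), c(0.2, 0.5, 0.3)),
               c(0.5, 0.3, 0.2), tolerance = 1e-12)
  pt <- c(0.4, 0.6)
  expect_equal(exact_step_marginal(pt, pt), pt, tolerance = 1e-15)
  expect_error(exact_step_marginal(c(1, 0), c(0.5, 0.25, 0.25)),
               "vocabulary")
})

test_that("acceptance rate is the drafted-token fraction", {
  rounds <- list(n_proposed = c(3L, 3L, 3L), n_accepted = c(2L, 3L, 0L),
                 used_residual = c(TRUE, FALSE, TRUE),
                 used_bonus = c(FALSE, TRUE, FALSE))
  expect_equal(acceptance_rate(rounds), 5 / 9)
  expect_error(acceptance_rate(list(n_proposed = 0L, n_accepted = 0L)),
               "undefined")
})

test_that("run summaries and speedups match direct arithmetic", {
  mk <- function(tps) {
    r <- list(sequence = token_sequence(1:3, 1L),
              rounds = list(n_proposed = 2L, n_accepted = 1L,
                            used_residual = TRUE, used_bonus = FALSE),
              decode_seconds = 2 / tps, n_generated = 2L, config = NULL)
    class(r) <- "decode_result"
    r
  }
  runs <- lapply(c(100, 120, 110, 130, 140), mk)
  s <- summarize_runs(runs, 5L)
  expect_equal(s$mean_tps, 120, tolerance = 1e-9)
  expect_equal(s$sd_tps, sd(c(100, 120, 110, 130, 140)), tolerance = 1e-9)
  expect_equal(s$mean_acceptance_rate, 0.5)
  one <- summarize_runs(runs[1], 1L)
  expect_equal(one$sd_tps, 0)
  expect_equal(compute_speedup(list(mean_tps = 130), list(mean_tps = 100)),
               1.3)
  expect_equal(compute_speedup(s, s), 1)
  expect_error(compute_speedup(s, list(mean_tps = 0)), "positive")
  bad <- mk(100); bad$decode_seconds <- 0
  expect_error(summarize_runs(list(bad), 1L), "zero decode time")
})

test_that("exact suffix enumeration reproduces hand chain products", {
  m <- fix_hand_tabular()
  pol <- sampling_policy()
  ex <- enumerate_suffix_distribution(m, 1L, 2, pol)
  tab <- next_token_table(m)
  hand <- numeric(9)  # P(x1 | prompt = 1) * P(x2 | x1)
  for (x1 in 1:3) for (x2 in 1:3)
    hand[(x1 - 1) * 3 + x2] <- tab[1, x1] * tab[x1, x2]
  expect_equal(ex, hand, tolerance = 1e-12)
  expect_equal(sum(ex), 1, tolerance = 1e-12)
  expect_error(enumerate_suffix_distribution(m, 1L, 12, pol), "too large")
})

test_that("the distribution check accepts a faithful decoder on a small run", {
  pair <- fix_tabular_pair(seed_t = 71, seed_d = 72)
  cfg <- speculative_config(L = 2, max_new_tokens = 2)
  chk <- distribution_equivalence_check(pair$target, pair$draft, cfg,
                                        horizon = 2, n_samples = 20000,
                                        seed = 5, engine = "reference")
  expect_gt(chk$p_value, 0.001)
  expect_lt(chk$tv_distance, 0.05)
})
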