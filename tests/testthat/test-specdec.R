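test_that("span proposal records the distributions it sampled from", {
  pair <- fix_tabular_pair()
  pol <- sampling_policy()
  # L = 1: one token, one probability vector
  set.seed(21)
  out <- propose_span(pair$draft, 1L, init_cache(pair$draft), 1L, pol)
  expect_length(out$span, 1)
  expect_length(out$p_draft, 1)
  expect_equal(cache_covered_len(out$cache), 2L)
  # replay with the same seed reproduces the span; every drafted token has
  # nonzero warped probability
  set.seed(21)
  out2 <- propose_span(pair$draft, 1L, init_cache(pair$draft), 1L, pol)
  expect_identical(out$span, out2$span)
  set.seed(33)
  out <- propose_span(pair$draft, 1L, init_cache(pair$draft), 5L, pol)
  for (j in seq_along(out$span))
    expect_gt(out$p_draft[[j]][out$span[j]], 0)
  # greedy proposal equals an independent greedy rollout of the draft
  g <- propose_span(pair$draft, 1L, init_cache(pair$draft), 4L,
                    sampling_policy(greedy = TRUE))
  expect_equal(g$span, oracle_greedy_rollout(pair$draft, 1L, 4)[-1])
})

test_that("verification matches table rows and is cache-invariant", {
  pair <- fix_tabular_pair()
  pol <- sampling_policy()
  tgt <- pair$target
  span <- c(2L, 1L, 3L)
  ver <- verify_span(tgt, 1L, span, init_cache(tgt), pol)
  tab <- next_token_table(tgt)
  prefix <- c(1L, span)
  for (i in 1:3)
    expect_equal(ver$p_target[[i]], tab[prefix[i], ], tolerance = 1e-12)
  expect_equal(ver$p_post, tab[3L, ], tolerance = 1e-12)
  # warm cache (covering the prefix) gives identical results
  warm <- forward_incremental(tgt, 1L, init_cache(tgt))$cache
  ver2 <- verify_span(tgt, 1L, span, warm, pol)
  expect_equal(ver2$p_target, ver$p_target, tolerance = 1e-12)
  expect_equal(ver2$p_post, ver$p_post, tolerance = 1e-12)
})

test_that("verification distributions equal draft records when models coincide", {
  tt <- fix_transformer(3, seed = 6)
  pol <- sampling_policy(temperature = 0.9)
  set.seed(5)
  prop <- propose_span(tt, c(1L, 2L), init_cache(tt), 4L, pol)
  ver <- verify_span(tt, c(1L, 2L), prop$span, init_cache(tt), pol)
  for (i in seq_along(prop$span))
    expect_equal(ver$p_target[[i]], prop$p_draft[[i]], tolerance = 1e-6)
})

test_that("the accept/reject scan follows the min(1, pt/pd) rule", {
  pt <- list(c(0.5, 0.3, 0.2))
  pd <- list(c(0.2, 0.5, 0.3))
  # token 2: acceptance probability min(1, 0.3/0.5) = 0.6
  set.seed(77)
  acc <- 0L
  for (i in 1:100000) {
    r <- accept_reject_span(2L, pd, pt)
    acc <- acc + (r$n_accepted == 1L)
  }
  expect_lt(abs(acc / 100000 - 0.6), 0.01)
  # zero target probability: always rejected, replacement from residual
  r <- accept_reject_span(1L, list(c(0.5, 0.5, 0)), list(c(0, 0.5, 0.5)))
  expect_equal(r$n_accepted, 0L)
  expect_true(r$replacement %in% c(2L, 3L))
  # identical distributions: everything accepted
  p <- list(c(0.4, 0.6), c(0.7, 0.3))
  r <- accept_reject_span(c(1L, 2L), p, p)
  expect_equal(r$n_accepted, 2L)
  expect_null(r$replacement)
})

test_that("draft == target accepts everything and emits L + 1 per round", {
  m <- make_tabular_toy(1, 4, 12)
  cfg <- speculative_config(L = 3, max_new_tokens = 15, seed = 8)
  res <- speculative_generate(m, m, 1L, cfg)
  expect_equal(acceptance_rate(res), 1.0)
  rounds <- as.data.frame(res$rounds)
  expect_true(all(rounds$n_accepted == rounds$n_proposed))
  # budget 15, L 3: three full L+1 rounds, then a final budget-truncated
  # span with no room for a bonus
  expect_equal(rounds$n_proposed + rounds$used_bonus, c(4, 4, 4, 3))
  expect_equal(res$n_generated, 15L)
})

test_that("greedy speculative output is token-identical to the target rollout", {
  pair <- fix_tabular_pair(vocab = 4, seed_t = 3, seed_d = 19)
  cfg <- speculative_config(L = 3, policy = sampling_policy(greedy = TRUE),
                            max_new_tokens = 12, seed = 1)
  res <- speculative_generate(pair$target, pair$draft, c(2L, 1L), cfg)
  expect_equal(res$sequence$ids,
               oracle_greedy_rollout(pair$target, c(2L, 1L), 12))
})

test_that("KV-cached and cache-free decoding are identical under one seed", {
  for (trial in 1:20) {
    pair <- fix_tabular_pair(vocab = 3 + trial %% 3,
                             seed_t = 100 + trial, seed_d = 200 + trial)
    L <- 1L + trial %% 4
    cfg_kv <- speculative_config(L = L, max_new_tokens = 8,
                                 seed = 300 + trial)
    cfg_no <- cfg_kv
    cfg_no$use_kv_cache <- FALSE
    a <- speculative_generate(pair$target, pair$draft, 1L, cfg_kv)
    b <- speculative_generate(pair$target, pair$draft, 1L, cfg_no)
    expect_identical(a$sequence$ids, b$sequence$ids)
    expect_identical(a$rounds[c("n_proposed", "n_accepted")],
                     b$rounds[c("n_proposed", "n_accepted")])
  }
})

test_that("each round issues exactly one target forward and emits 1..L+1 tokens", {
  pair <- fix_tabular_pair(seed_t = 51, seed_d = 52)
  w <- instrumented_model(pair$target)
  cfg <- speculative_config(L = 3, max_new_tokens = 30, seed = 4)
  res <- speculative_generate(w, pair$draft, 1L, cfg)
  n_rounds <- length(res$rounds$n_proposed)
  # one incremental call per round plus the prompt prefill
  expect_equal(forward_counts(w)$incremental, n_rounds + 1L)
  rounds <- as.data.frame(res$rounds)
  emitted <- rounds$n_accepted + rounds$used_residual + rounds$used_bonus
  expect_true(all(emitted >= 1 & emitted <= cfg$L + 1))
  expect_equal(sum(emitted), res$n_generated)
})

test_that("stop tokens cut the span and terminate generation", {
  tgt <- make_tabular_toy(1, 4, 31, stop_token_ids = 4L)
  drf <- make_tabular_toy(1, 4, 32, stop_token_ids = 4L)
  cfg <- speculative_config(L = 4, max_new_tokens = 200, seed = 0)
  hit_stop <- FALSE
  for (s in 1:10) {
    cfg$seed <- s
    res <- speculative_generate(tgt, drf, 1L, cfg)
    suffix <- res$sequence$ids[-1]
    if (4L %in% suffix) {
      hit_stop <- TRUE
      expect_equal(which(suffix == 4L)[1], length(suffix))
    }
    expect_lte(res$n_generated, 200L)
  }
  expect_true(hit_stop)
  expect_error(speculative_generate(tgt, make_tabular_toy(1, 4, 32), 1L, cfg),
               "stop-token")
})

test_that("the token budget pre-truncates the final span", {
  pair <- fix_tabular_pair(seed_t = 61, seed_d = 62)
  cfg <- speculative_config(L = 5, max_new_tokens = 7, seed = 13)
  res <- speculative_generate(pair$target, pair$draft, 1L, cfg)
  expect_equal(res$n_generated, 7L)
  expect_true(all(res$rounds$n_proposed <= 5))
})

test_that("baseline sampling is budgeted, greedy-consistent and reproducible", {
  m <- make_tabular_toy(1, 4, 25)
  res <- baseline_generate(m, 2L, sampling_policy(), 20, seed = 6)
  expect_equal(res$n_generated, 20L)
  g <- baseline_generate(m, 2L, sampling_policy(greedy = TRUE), 10, seed = 1)
  expect_equal(g$sequence$ids, oracle_greedy_rollout(m, 2L, 10))
  r2 <- baseline_generate(m, 2L, sampling_policy(), 20, seed = 6)
  expect_identical(res$sequence$ids, r2$sequence$ids)
  expect_error(speculative_generate(m, make_tabular_toy(1, 3, 1), 1L,
                                    speculative_config(L = 2, max_new_tokens = 2)),
               "vocabulary")
})
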