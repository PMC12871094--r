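test_that("tabular toy construction is seeded, normalized and order-aware", {
  m <- make_tabular_toy(1, 3, 7)
  expect_equal(nrow(next_token_table(m)), 3)
  expect_equal(unname(rowSums(next_token_table(m))), rep(1, 3),
               tolerance = 1e-12)
  expect_true(all(next_token_table(m) > 0))
  expect_identical(make_tabular_toy(1, 3, 7)$tables, m$tables)
  # order 0: one fixed distribution regardless of context
  m0 <- make_tabular_toy(0, 4, 5)
  r <- forward_full(m0, c(1, 3, 2, 4))
  for (i in 2:4) expect_equal(r[i, ], r[1, ])
  expect_error(make_tabular_toy(3, 3, 1), "order")
  expect_error(make_tabular_toy(1, 12, 1), "vocab_size")
})

test_that("tabular forward reproduces its own tables", {
  m <- fix_hand_tabular()
  # softmax of returned logits is exactly the table row for the context
  r <- forward_full(m, 1L)
  expect_equal(exp(r[1, ]), c(0.7, 0.2, 0.1), tolerance = 1e-9)
  r <- forward_full(m, c(1L, 2L, 3L))
  expect_equal(exp(r[2, ]), c(0.3, 0.4, 0.3), tolerance = 1e-9)
  expect_equal(exp(r[3, ]), c(0.25, 0.25, 0.5), tolerance = 1e-9)
  # uniform rows stay uniform after softmax for any prefix
  mu <- make_tabular_model(list(matrix(0.25, 1, 4), matrix(0.25, 4, 4)))
  ru <- forward_full(mu, c(2L, 4L, 1L))
  expect_equal(exp(ru), matrix(0.25, 3, 4), tolerance = 1e-12)
  expect_error(forward_full(m, c(1L, 9L)), "invalid token id")
})

test_that("incremental and full forwards agree token by token", {
  tt <- fix_transformer()
  set.seed(2)
  ids <- sample.int(16, 8, replace = TRUE)
  full <- forward_full(tt, ids)
  cache <- init_cache(tt)
  inc <- matrix(NA_real_, 8, 16)
  for (i in seq_along(ids)) {
    step <- forward_incremental(tt, ids[i], cache)
    inc[i, ] <- step$logits
    cache <- step$cache
  }
  expect_lt(max(abs(inc - full)), 1e-5)
  expect_equal(cache_covered_len(cache), 8L)
  # tabular models agree exactly
  m <- make_tabular_toy(2, 4, 11)
  ids2 <- c(3L, 1L, 4L, 2L, 2L)
  cache2 <- init_cache(m)
  for (i in seq_along(ids2))
    cache2 <- forward_incremental(m, ids2[i], cache2)$cache
  expect_equal(cache2$head_logits,
               forward_full(m, ids2)[5, ], tolerance = 1e-12)
})

test_that("empty incremental calls are no-ops", {
  tt <- fix_transformer(2)
  cache <- forward_incremental(tt, c(1L, 2L), init_cache(tt))$cache
  out <- forward_incremental(tt, integer(0), cache)
  expect_identical(out$cache, cache)
  expect_equal(nrow(out$logits), 0L)
})

test_that("cache truncation behaves like a fresh cache on the shorter prefix", {
  tt <- fix_transformer()
  set.seed(3)
  ids10 <- sample.int(16, 10, replace = TRUE)
  fresh4 <- sample.int(16, 4, replace = TRUE)
  cache <- forward_incremental(tt, ids10, init_cache(tt))$cache
  expect_equal(cache_covered_len(truncate_cache(cache, 10L)), 10L)
  cut <- truncate_cache(cache, 6L)
  expect_equal(cache_covered_len(cut), 6L)
  adv <- forward_incremental(tt, fresh4, cut)
  hybrid <- c(ids10[1:6], fresh4)
  expect_lt(max(abs(adv$logits - forward_full(tt, hybrid)[7:10, ])), 1e-5)
  # truncation to zero equals no cache at all
  zero <- truncate_cache(cache, 0L)
  out0 <- forward_incremental(tt, hybrid, zero)
  expect_lt(max(abs(out0$logits - forward_full(tt, hybrid))), 1e-10)
  expect_error(truncate_cache(cache, 11L), "covered_len")
})

test_that("transformer construction is deterministic and yields finite logits", {
  a <- fix_transformer(3, seed = 9)
  b <- fix_transformer(3, seed = 9)
  expect_identical(a, b)
  set.seed(4)
  for (len in c(1, 7, 33, 64)) {
    ids <- sample.int(16, len, replace = TRUE)
    expect_true(all(is.finite(forward_full(a, ids))))
  }
  expect_error(
    forward_incremental(a, rep(1L, 10), init_cache(fix_transformer(2))),
    "mismatch")
})

test_that("token sequences validate their prompt boundary", {
  ts <- token_sequence(c(5L, 2L, 9L), prompt_len = 2)
  expect_equal(ts$prompt_len, 2L)
  expect_error(token_sequence(c(1L, 2L), prompt_len = 3), "prompt_len")
  expect_error(token_sequence(c(0L, 1L)), ">= 1")
})

test_that("instrumented wrapper counts forward calls transparently", {
  m <- make_tabular_toy(1, 3, 1)
  w <- instrumented_model(m)
  expect_equal(vocabulary(w)$size, 3L)
  cache <- forward_incremental(w, c(1L, 2L), init_cache(w))$cache
  forward_incremental(w, integer(0), cache)   # not counted
  forward_full(w, c(1L, 2L, 3L))
  expect_equal(forward_counts(w), list(full = 1L, incremental = 1L))
})
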