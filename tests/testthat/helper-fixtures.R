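# Shared fixtures: built fresh in code, never stored.

fix_tabular_pair <- function(vocab = 3L, order = 1L,
                             seed_t = 42L, seed_d = 43L, ...) {
  list(target = make_tabular_toy(order, vocab, seed_t, ...),
       draft = make_tabular_toy(order, vocab, seed_d, ...))
}

fix_transformer <- function(n_layers = 4L, seed = 1L, vocab = 16L,
                            width = 16L, ...) {
  make_tiny_transformer(n_layers, width = width, vocab_size = vocab,
                        seed = seed, ...)
}

# explicit order-1 tabular model with hand-chosen rows over vocab 3
fix_hand_tabular <- function() {
  make_tabular_model(list(
    matrix(c(0.7, 0.2, 0.1), 1, 3, byrow = TRUE),
    matrix(c(0.7, 0.2, 0.1,
             0.3, 0.4, 0.3,
             0.25, 0.25, 0.5), 3, 3, byrow = TRUE)
  ))
}

# Independent transformer forward oracle: per-position loops with direct
# attention formulas, structured differently from the package's batched
# incremental path.
oracle_forward <- function(model, ids) {
  d <- model$width; nh <- model$n_heads; dh <- d %/% nh
  n <- length(ids)
  ln1 <- function(v, g, b) {
    m <- mean(v); s <- sqrt(mean((v - m)^2) + 1e-5)
    (v - m) / s * g + b
  }
  X <- model$tok_emb[ids, , drop = FALSE] +
    model$pos_emb[seq_len(n), , drop = FALSE]
  for (blk in model$blocks) {
    H <- t(apply(X, 1, ln1, g = blk$ln1_g, b = blk$ln1_b))
    Q <- H %*% blk$Wq; K <- H %*% blk$Wk; Vm <- H %*% blk$Wv
    O <- matrix(0, n, d)
    for (i in seq_len(n)) {
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        sc <- drop(K[seq_len(i), cols, drop = FALSE] %*% Q[i, cols]) /
          sqrt(dh)
        w <- exp(sc - max(sc)); w <- w / sum(w)
        O[i, cols] <- drop(t(w) %*% Vm[seq_len(i), cols, drop = FALSE])
      }
    }
    X <- X + O %*% blk$Wo
    U <- t(apply(X, 1, ln1, g = blk$ln2_g, b = blk$ln2_b))
    A <- U %*% blk$W1 + rep(blk$b1, each = n)
    A <- A * pnorm(A)
    X <- X + A %*% blk$W2 + rep(blk$b2, each = n)
  }
  X <- t(apply(X, 1, ln1, g = model$ln_f$g, b = model$ln_f$b))
  X %*% model$head
}

# target-only greedy rollout, written independently of the decoders
oracle_greedy_rollout <- function(model, prompt_ids, n_new) {
  ids <- as.integer(prompt_ids)
  for (i in seq_len(n_new)) {
    rows <- forward_full(model, ids)
    ids <- c(ids, which.max(rows[length(ids), ]))
  }
  ids
}
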