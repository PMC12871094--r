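#' Token sequences with a prompt boundary
#'
#' A thin container for an ordered vector of 1-based token ids together
#' with the number of leading tokens that form the prompt. Decoders append
#' generated tokens after the prompt; scoring functions only score the
#' suffix.
#'
#' @param ids Integer vector of token ids (all `>= 1`).
#' @param prompt_len Number of leading prompt tokens, in `0:length(ids)`.
#' @return An object of class `token_sequence` with fields `ids` and
#'   `prompt_len`.
#' @export
token_sequence <- function(ids, prompt_len = length(ids)) {
  ids <- as.integer(ids)
  prompt_len <- as.integer(prompt_len)
  if (length(ids) && any(ids < 1L)) stop("token ids must be >= 1")
  if (prompt_len < 0L || prompt_len > length(ids))
    stop("prompt_len must lie in [0, length(ids)]")
  structure(list(ids = ids, prompt_len = prompt_len),
            class = "token_sequence")
}

as_token_ids <- function(tokens) {
  if (inherits(tokens, "token_sequence")) tokens$ids else as.integer(tokens)
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence: %d tokens (%d prompt + %d suffix)>\n",
              length(x$ids), x$prompt_len, length(x$ids) - x$prompt_len))
  invisible(x)
}

#' Vocabulary of a causal language model
#'
#' Every model used by the decoding loop exposes its vocabulary size and
#' the set of stop-token ids that terminate generation. A draft/target
#' pair must have equal sizes and identical stop sets.
#'
#' @param model A causal language model object.
#' @return A list with `size` (positive integer) and `stop_token_ids`
#'   (integer vector, possibly empty).
#' @export
vocabulary <- function(model) UseMethod("vocabulary")

#' @export
vocabulary.causal_lm <- function(model) model$vocab

#' Full forward pass: logits for every position of a prefix
#'
#' Runs the model over an entire token prefix and returns one logit vector
#' per position, where row `i` scores the token at position `i + 1`. No
#' cache is created or mutated. This is the reference path against which
#' the incremental (KV-cached) path is validated.
#'
#' @param model A causal language model.
#' @param tokens A [token_sequence()] or plain integer vector of token ids
#'   (nonempty, all ids within the vocabulary).
#' @return A numeric matrix with `length(tokens)` rows and `vocab size`
#'   columns.
#' @export
forward_full <- function(model, tokens) UseMethod("forward_full")

#' @export
forward_full.causal_lm <- function(model, tokens) {
  ids <- as_token_ids(tokens)
  if (!length(ids)) stop("tokens must be nonempty")
  forward_incremental(model, ids, init_cache(model))$logits
}

#' Incremental forward pass against a KV cache
#'
#' Advances the model over `new_tokens`, reusing the cached keys/values for
#' the prefix the cache covers. Returns the logits for the new positions
#' and the updated cache (covering `covered_len + length(new_tokens)`
#' positions). Within floating-point tolerance the logits equal the
#' corresponding tail rows of [forward_full()] on the concatenated prefix.
#'
#' @param model A causal language model.
#' @param new_tokens Integer vector of token ids to append (may be empty,
#'   in which case nothing happens).
#' @param cache A cache created by [init_cache()] for this model (or
#'   returned by a previous incremental call).
#' @return A list with `logits` (matrix, one row per new token) and
#'   `cache` (the updated cache).
#' @export
forward_incremental <- function(model, new_tokens, cache) {
  UseMethod("forward_incremental")
}

#' Create an empty cache for a model
#'
#' @param model A causal language model.
#' @return A cache object with `covered_len == 0`.
#' @export
init_cache <- function(model) UseMethod("init_cache")

#' Truncate a KV cache to a shorter prefix
#'
#' After a rejection the accepted prefix is shorter than the span the
#' models were advanced over; the caches are cut back so that
#' `covered_len == new_len` and subsequent incremental calls behave as if
#' the cache had been built on the truncated prefix from scratch.
#'
#' @param cache A cache object.
#' @param new_len Target covered length, in `0:cache$covered_len`.
#' @return The truncated cache.
#' @export
truncate_cache <- function(cache, new_len) UseMethod("truncate_cache")

#' Number of prefix positions a cache covers
#'
#' @param cache A cache object.
#' @return Integer covered length.
#' @export
cache_covered_len <- function(cache) cache$covered_len

check_token_ids <- function(ids, vocab_size) {
  if (length(ids) && (any(ids < 1L) || any(ids > vocab_size)))
    stop(sprintf("invalid token id (outside 1..%d)", vocab_size))
}

# ---------------------------------------------------------------------------
# Tabular toy models: bounded-order Markov chains with explicit probability
# tables. Their full sequence distribution is exactly enumerable, which is
# what lets the distribution-preservation guarantee be certified exactly —
# something real checkpoints cannot provide.
# ---------------------------------------------------------------------------

#' Tabular toy model: an order-m Markov chain with explicit tables
#'
#' Builds a small causal LM whose next-token distribution is an explicit
#' conditional probability table over the last `order` tokens (with
#' separate tables for shorter initial contexts). Rows are strictly
#' positive Dirichlet-like draws, normalized exactly, and reproducible from
#' `seed`. Because the induced sequence distribution can be enumerated in
#' closed form, these models are the exact oracles behind the
#' distribution-preservation tests.
#'
#' @param order Markov order, one of 0, 1, 2.
#' @param vocab_size Vocabulary size, at most 8.
#' @param seed Integer seed; the same seed yields identical tables.
#' @param stop_token_ids Optional integer vector of stop-token ids.
#' @param concentration Positive scalar controlling row skew: values below
#'   1 yield peaky rows (models that disagree more), large values approach
#'   uniform rows.
#' @return A `tabular_lm` (also `causal_lm`) object.
#' @examples
#' m <- make_tabular_toy(order = 1, vocab_size = 3, seed = 7)
#' rowSums(next_token_table(m))  # each row sums to 1
#' @export
make_tabular_toy <- function(order, vocab_size, seed,
                             stop_token_ids = integer(0),
                             concentration = 1.0) {
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  if (vocab_size < 2 || vocab_size > 8) stop("vocab_size must be in 2..8")
  order <- as.integer(order)
  vocab_size <- as.integer(vocab_size)
  tables <- with_seed(seed, {
    lapply(0:order, function(j) {
      n_ctx <- vocab_size^j
      t <- matrix(stats::rgamma(n_ctx * vocab_size, shape = concentration),
                  nrow = n_ctx)
      t / rowSums(t)
    })
  })
  structure(
    list(
      vocab = list(size = vocab_size,
                   stop_token_ids = as.integer(stop_token_ids)),
      order = order,
      tables = tables,
      log_tables = lapply(tables, log)
    ),
    class = c("tabular_lm", "causal_lm")
  )
}

#' Tabular model from explicit probability tables
#'
#' Builds a tabular causal LM directly from user-supplied conditional
#' tables, one per context length `0..order` (a matrix of `vocab^j` rows).
#' Unlike [make_tabular_toy()], rows may be degenerate (one-hot) and the
#' vocabulary may exceed 8; every row must still sum to 1 within 1e-12.
#' Useful for closed-form oracles: a uniform model has perplexity equal to
#' its vocabulary size, a one-hot model perplexity 1.
#'
#' @param tables List of probability matrices, element `j` conditioning on
#'   contexts of length `j - 1`; all with the same number of columns
#'   (the vocabulary size). Row order follows [next_token_table()].
#' @param stop_token_ids Optional stop-token ids.
#' @return A `tabular_lm` object.
#' @export
make_tabular_model <- function(tables, stop_token_ids = integer(0)) {
  V <- ncol(tables[[1]])
  order <- length(tables) - 1L
  for (j in seq_along(tables)) {
    if (ncol(tables[[j]]) != V || nrow(tables[[j]]) != V^(j - 1L))
      stop(sprintf("table %d must be %d x %d", j, V^(j - 1L), V))
    if (any(abs(rowSums(tables[[j]]) - 1) > 1e-12))
      stop("every table row must sum to 1 within 1e-12")
    if (any(tables[[j]] < 0)) stop("probabilities must be nonnegative")
  }
  structure(
    list(vocab = list(size = as.integer(V),
                      stop_token_ids = as.integer(stop_token_ids)),
         order = order, tables = tables,
         log_tables = lapply(tables, log)),
    class = c("tabular_lm", "causal_lm")
  )
}

#' Conditional probability table of a tabular toy model
#'
#' @param model A `tabular_lm`.
#' @param context_len Context length of the requested table (default: the
#'   model's order). Row `r` of the returned matrix is the next-token
#'   distribution after the context whose tokens `t_1..t_j` satisfy
#'   `r = 1 + sum((t_i - 1) * V^(j - i))`.
#' @return A probability matrix.
#' @export
next_token_table <- function(model, context_len = model$order) {
  stopifnot(inherits(model, "tabular_lm"),
            context_len %in% 0:model$order)
  model$tables[[context_len + 1L]]
}

tabular_context_row <- function(model, ids, pos) {
  # row index of the table conditioning the token at position pos + 1,
  # given ids[1..pos]
  j <- min(pos, model$order)
  if (j == 0L) return(1L)
  ctx <- ids[(pos - j + 1L):pos]
  r <- 0L
  for (t in ctx) r <- r * model$vocab$size + (t - 1L)
  r + 1L
}

# Caches also carry `head_logits`: the logits predicting the position after
# the covered prefix, produced by the last incremental call. Truncation
# invalidates it; the decoding loop then re-derives it by feeding the
# not-yet-cached committed tokens in its next incremental call.

#' @export
init_cache.tabular_lm <- function(model) {
  structure(list(covered_len = 0L, ids = integer(0), head_logits = NULL),
            class = c("tabular_cache", "kv_state"))
}

#' @export
forward_incremental.tabular_lm <- function(model, new_tokens, cache) {
  m <- length(new_tokens)
  if (m == 0L) return(list(logits = matrix(numeric(0), 0, model$vocab$size),
                           cache = cache))
  new_tokens <- as.integer(new_tokens)
  check_token_ids(new_tokens, model$vocab$size)
  ids <- c(cache$ids, new_tokens)
  off <- cache$covered_len
  out <- matrix(0, m, model$vocab$size)
  for (i in seq_len(m)) {
    j <- min(off + i, model$order)
    row <- tabular_context_row(model, ids, off + i)
    out[i, ] <- model$log_tables[[j + 1L]][row, ]
  }
  cache$ids <- ids
  cache$covered_len <- off + m
  cache$head_logits <- out[m, ]
  list(logits = out, cache = cache)
}

#' @export
truncate_cache.tabular_cache <- function(cache, new_len) {
  new_len <- as.integer(new_len)
  if (new_len < 0L || new_len > cache$covered_len)
    stop("new_len must lie in [0, covered_len]")
  cache$ids <- cache$ids[seq_len(new_len)]
  cache$covered_len <- new_len
  cache$head_logits <- NULL
  cache
}

# ---------------------------------------------------------------------------
# Tiny GPT-style transformer: embeddings + positional embeddings, a stack of
# pre-norm blocks (causal multi-head attention + GELU MLP), final layer norm
# and a linear head. Small enough to run on a CPU in milliseconds, but
# structurally faithful to the checkpoints the decoder targets: it exposes
# its block list so layer-truncated drafts can be carved out of it, and it
# supports the same KV-cache contract.
# ---------------------------------------------------------------------------

#' Tiny GPT-style transformer fixture
#'
#' A desk-scale decoder-only transformer with deterministic random
#' initialization. It exposes its components separately (`tok_emb`,
#' `pos_emb`, the ordered `blocks` list, `ln_f`, `head`) so that
#' [build_truncated_draft()] can retain a subset of blocks while reusing
#' the embeddings, final normalization and head — mirroring how truncated
#' drafts are carved out of GPT-2-style checkpoints.
#'
#' @param n_layers Number of transformer blocks (>= 1).
#' @param width Model width; must be divisible by `n_heads`.
#' @param vocab_size Vocabulary size.
#' @param seed Integer seed; the same seed gives bitwise-identical
#'   parameters.
#' @param n_heads Number of attention heads.
#' @param max_len Maximum sequence length (size of the positional table).
#' @param stop_token_ids Optional stop-token ids.
#' @return A `tiny_transformer` (also `causal_lm`) object.
#' @export
make_tiny_transformer <- function(n_layers, width = 16L, vocab_size = 16L,
                                  seed = 1L, n_heads = 2L, max_len = 256L,
                                  stop_token_ids = integer(0)) {
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (width %% n_heads != 0L) stop("width must be divisible by n_heads")
  d <- as.integer(width)
  V <- as.integer(vocab_size)
  mats <- function(n, m) matrix(stats::rnorm(n * m, sd = 0.02), n, m)
  params <- with_seed(seed, {
    list(
      tok_emb = mats(V, d),
      pos_emb = mats(max_len, d),
      blocks = lapply(seq_len(n_layers), function(l) list(
        ln1_g = rep(1, d), ln1_b = rep(0, d),
        Wq = mats(d, d), Wk = mats(d, d), Wv = mats(d, d), Wo = mats(d, d),
        ln2_g = rep(1, d), ln2_b = rep(0, d),
        W1 = mats(d, 4L * d), b1 = rep(0, 4L * d),
        W2 = mats(4L * d, d), b2 = rep(0, d)
      )),
      ln_f = list(g = rep(1, d), b = rep(0, d)),
      head = mats(d, V)
    )
  })
  structure(
    c(params,
      list(vocab = list(size = V, stop_token_ids = as.integer(stop_token_ids)),
           width = d, n_heads = as.integer(n_heads),
           max_len = as.integer(max_len))),
    class = c("tiny_transformer", "causal_lm")
  )
}

layer_norm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  sweep(xc / sd, 2L, g, "*") + rep(b, each = nrow(x))
}

gelu <- function(x) x * stats::pnorm(x)

#' @export
init_cache.tiny_transformer <- function(model) {
  empty <- matrix(numeric(0), 0L, model$width)
  structure(
    list(covered_len = 0L,
         K = rep(list(empty), length(model$blocks)),
         V = rep(list(empty), length(model$blocks)),
         head_logits = NULL),
    class = c("transformer_cache", "kv_state")
  )
}

#' @export
forward_incremental.tiny_transformer <- function(model, new_tokens, cache) {
  m <- length(new_tokens)
  if (m == 0L)
    return(list(logits = matrix(numeric(0), 0L, model$vocab$size),
                cache = cache))
  new_tokens <- as.integer(new_tokens)
  check_token_ids(new_tokens, model$vocab$size)
  if (length(cache$K) != length(model$blocks))
    stop("cache/model mismatch: different number of layers")
  off <- cache$covered_len
  if (off + m > model$max_len) stop("prefix exceeds model context length")
  d <- model$width
  nh <- model$n_heads
  dh <- d %/% nh
  x <- model$tok_emb[new_tokens, , drop = FALSE] +
    model$pos_emb[off + seq_len(m), , drop = FALSE]
  for (l in seq_along(model$blocks)) {
    blk <- model$blocks[[l]]
    h <- layer_norm(x, blk$ln1_g, blk$ln1_b)
    q <- h %*% blk$Wq
    k <- h %*% blk$Wk
    v <- h %*% blk$Wv
    K_all <- rbind(cache$K[[l]], k)
    V_all <- rbind(cache$V[[l]], v)
    n_all <- off + m
    att_out <- matrix(0, m, d)
    for (hd in seq_len(nh)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      sc <- q[, cols, drop = FALSE] %*% t(K_all[, cols, drop = FALSE]) /
        sqrt(dh)
      for (i in seq_len(m)) {                       # causal mask
        lim <- off + i
        if (lim < n_all) sc[i, (lim + 1L):n_all] <- -Inf
      }
      sc <- sc - apply(sc, 1L, max)
      w <- exp(sc)
      w <- w / rowSums(w)
      att_out[, cols] <- w %*% V_all[, cols, drop = FALSE]
    }
    x <- x + att_out %*% blk$Wo
    u <- layer_norm(x, blk$ln2_g, blk$ln2_b)
    x <- x + gelu(u %*% blk$W1 + rep(blk$b1, each = m)) %*% blk$W2 +
      rep(blk$b2, each = m)
    cache$K[[l]] <- K_all
    cache$V[[l]] <- V_all
  }
  x <- layer_norm(x, model$ln_f$g, model$ln_f$b)
  cache$covered_len <- off + m
  logits <- x %*% model$head
  cache$head_logits <- logits[m, ]
  list(logits = logits, cache = cache)
}

#' @export
truncate_cache.transformer_cache <- function(cache, new_len) {
  new_len <- as.integer(new_len)
  if (new_len < 0L || new_len > cache$covered_len)
    stop("new_len must lie in [0, covered_len]")
  keep <- seq_len(new_len)
  cache$K <- lapply(cache$K, function(k) k[keep, , drop = FALSE])
  cache$V <- lapply(cache$V, function(v) v[keep, , drop = FALSE])
  cache$covered_len <- new_len
  cache$head_logits <- NULL
  cache
}

# ---------------------------------------------------------------------------
# Instrumented wrapper: counts forward calls. The speculative loop's speedup
# rests on issuing exactly one target forward per round, which tests verify
# through this wrapper.
# ---------------------------------------------------------------------------

#' Wrap a model to count its forward calls
#'
#' Returns a model that behaves identically but records how many
#' [forward_full()] and [forward_incremental()] calls it served (empty
#' incremental calls are not counted). Used to verify that speculative
#' decoding issues exactly one target forward per round.
#'
#' @param model A causal language model.
#' @return An `instrumented_lm` wrapping `model`.
#' @seealso [forward_counts()]
#' @export
instrumented_model <- function(model) {
  counts <- new.env(parent = emptyenv())
  counts$full <- 0L
  counts$incremental <- 0L
  structure(list(inner = model, counts = counts),
            class = c("instrumented_lm", "causal_lm"))
}

#' @rdname instrumented_model
#' @export
forward_counts <- function(model) {
  list(full = model$counts$full, incremental = model$counts$incremental)
}

#' @export
vocabulary.instrumented_lm <- function(model) vocabulary(model$inner)

#' @export
init_cache.instrumented_lm <- function(model) init_cache(model$inner)

#' @export
forward_full.instrumented_lm <- function(model, tokens) {
  model$counts$full <- model$counts$full + 1L
  forward_full(model$inner, tokens)
}

#' @export
forward_incremental.instrumented_lm <- function(model, new_tokens, cache) {
  if (length(new_tokens))
    model$counts$incremental <- model$counts$incremental + 1L
  forward_incremental(model$inner, new_tokens, cache)
}

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}
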