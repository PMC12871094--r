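#' Configuration of a speculative decoding run
#'
#' @param L Speculation window: the number of tokens the draft proposes per
#'   round before the target verifies them in a single forward pass. Small
#'   values (2-7) are typical; long windows depress the acceptance rate
#'   because draft and target must agree on longer spans.
#' @param policy A [sampling_policy()] shared by draft and target.
#' @param bonus_enabled When every drafted token in a round is accepted,
#'   draw one extra token directly from the target's post-span
#'   distribution (default `TRUE`), so a round can emit up to `L + 1`
#'   tokens.
#' @param max_new_tokens Token budget for the generated suffix.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used (callers doing bulk Monte Carlo seed once outside the loop).
#' @param use_kv_cache If `TRUE` (default) both models keep KV caches that
#'   are advanced incrementally and truncated on rejection; if `FALSE`
#'   every round recomputes the full prefix from scratch. The two modes
#'   produce identical output for identical seeds.
#' @return A `speculative_config` object.
#' @export
speculative_config <- function(L, policy = sampling_policy(),
                               bonus_enabled = TRUE, max_new_tokens,
                               seed = NULL, use_kv_cache = TRUE) {
  L <- as.integer(L)
  if (L < 1L || L > 16L) stop("L must lie in [1, 16]")
  max_new_tokens <- as.integer(max_new_tokens)
  if (max_new_tokens < 1L) stop("max_new_tokens must be >= 1")
  structure(
    list(L = L, policy = policy, bonus_enabled = isTRUE(bonus_enabled),
         max_new_tokens = max_new_tokens, seed = seed,
         use_kv_cache = isTRUE(use_kv_cache)),
    class = "speculative_config"
  )
}

# feed any committed tokens the cache has not absorbed yet, so that
# covered_len == length(ids) and head_logits predicts the next position
sync_cache <- function(model, ids, cache) {
  if (cache$covered_len < length(ids)) {
    cache <- forward_incremental(
      model, ids[(cache$covered_len + 1L):length(ids)], cache)$cache
  }
  if (is.null(cache$head_logits))
    stop("cache desynchronized: no head logits for the covered prefix")
  cache
}

#' Draft a span of proposed tokens
#'
#' Runs the draft model autoregressively for up to `L` steps, sampling each
#' token from its warped next-token distribution and advancing its cache
#' incrementally. The warped distribution each token was drawn from is
#' recorded: the accept/reject rule needs exactly these probabilities. The
#' span is cut short if a stop token is drafted.
#'
#' @param draft A causal language model.
#' @param prefix A [token_sequence()] (or id vector): the accepted prefix.
#' @param draft_cache Cache covering (a leading part of) the prefix;
#'   uncached prefix tokens are absorbed in one incremental call.
#' @param L Maximum span length.
#' @param policy A [sampling_policy()].
#' @return A list with `span` (integer vector, length <= L), `p_draft`
#'   (list of warped probability vectors, one per span token) and `cache`
#'   (updated, covering prefix + span).
#' @export
propose_span <- function(draft, prefix, draft_cache, L, policy) {
  ids <- as_token_ids(prefix)
  cache <- sync_cache(draft, ids, draft_cache)
  stops <- draft$vocab$stop_token_ids %||% vocabulary(draft)$stop_token_ids
  span <- integer(L)
  p_draft <- vector("list", L)
  s <- 0L
  for (j in seq_len(L)) {
    p <- warp_logits(cache$head_logits, policy)
    x <- sample_categorical(p)
    s <- j
    span[j] <- x
    p_draft[[j]] <- p
    cache <- forward_incremental(draft, x, cache)$cache
    if (x %in% stops) break
  }
  list(span = span[seq_len(s)], p_draft = p_draft[seq_len(s)], cache = cache)
}

#' Verify a drafted span with one target forward pass
#'
#' Evaluates the target on the span in a single forward call (reusing its
#' cache for the prefix) and returns the warped target distribution for
#' every span position plus the distribution at the position after the
#' span, from which a bonus token can be drawn on full acceptance.
#'
#' @param target A causal language model.
#' @param prefix The accepted prefix ([token_sequence()] or id vector).
#' @param span Integer vector of drafted token ids.
#' @param target_cache Cache covering (a leading part of) the prefix.
#' @param policy A [sampling_policy()].
#' @return A list with `p_target` (list of warped probability vectors, one
#'   per span position), `p_post` (warped distribution after the span) and
#'   `cache` (updated, covering prefix + span).
#' @export
verify_span <- function(target, prefix, span, target_cache, policy) {
  ids <- as_token_ids(prefix)
  s <- length(span)
  cache <- target_cache
  pending <- if (cache$covered_len < length(ids))
    ids[(cache$covered_len + 1L):length(ids)] else integer(0)
  if (length(pending) == 0L && is.null(cache$head_logits))
    stop("cache desynchronized: no head logits for the covered prefix")
  out <- forward_incremental(target, c(pending, span), cache)
  rows <- out$logits
  cache <- out$cache
  np <- length(pending)
  # row for fed position q predicts position q + 1; we need predictions for
  # span positions and the post-span position
  logit_rows <- vector("list", s + 1L)
  if (np > 0L) {
    for (i in 0:s) logit_rows[[i + 1L]] <- rows[np + i, ]
  } else {
    logit_rows[[1L]] <- target_cache$head_logits
    for (i in seq_len(s)) logit_rows[[i + 1L]] <- rows[i, ]
  }
  p_all <- lapply(logit_rows, warp_logits, policy = policy)
  list(p_target = p_all[seq_len(s)], p_post = p_all[[s + 1L]], cache = cache)
}

#' Probabilistic accept/reject scan over a drafted span
#'
#' Scans the span left to right. The token at position `i` is accepted
#' with probability `min(1, p_target(x_i) / p_draft(x_i))`. On the first
#' rejection a replacement is drawn from
#' [residual_distribution()]`(p_target_i, p_draft_i)` and all later
#' drafted tokens are discarded. This rule makes each emitted token
#' exactly target-distributed (see [exact_step_marginal()]).
#'
#' @param span Integer vector of drafted token ids.
#' @param p_draft,p_target Lists of warped probability vectors, one per
#'   span position.
#' @return A list with `n_accepted` (0..length(span)) and `replacement`
#'   (token id drawn from the residual, or `NULL` if all were accepted).
#' @export
accept_reject_span <- function(span, p_draft, p_target) {
  s <- length(span)
  if (length(p_draft) != s || length(p_target) != s)
    stop("span and probability lists must have equal length")
  for (i in seq_len(s)) {
    x <- span[i]
    a <- p_target[[i]][x] / p_draft[[i]][x]
    if (stats::runif(1) >= a) {
      r <- residual_distribution(p_target[[i]], p_draft[[i]])
      return(list(n_accepted = i - 1L,
                  replacement = sample_categorical(r)))
    }
  }
  list(n_accepted = s, replacement = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_round_log <- function(n) {
  list(n_proposed = integer(n), n_accepted = integer(n),
       used_residual = logical(n), used_bonus = logical(n))
}

finish_round_log <- function(log, n) {
  structure(lapply(log, function(v) v[seq_len(n)]), class = "round_log")
}

#' @export
as.data.frame.round_log <- function(x, ...) {
  data.frame(n_proposed = x$n_proposed, n_accepted = x$n_accepted,
             used_residual = x$used_residual, used_bonus = x$used_bonus)
}

new_decode_result <- function(ids, prompt_len, rounds, decode_seconds,
                              config = NULL) {
  structure(
    list(sequence = token_sequence(ids, prompt_len), rounds = rounds,
         decode_seconds = decode_seconds,
         n_generated = length(ids) - prompt_len, config = config),
    class = "decode_result"
  )
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "<decode_result: %d generated tokens, %d rounds, %.4f s decode>\n",
    x$n_generated, length(x$rounds$n_proposed %||% x$rounds), x$decode_seconds))
  invisible(x)
}

check_compatible <- function(target, draft) {
  vt <- vocabulary(target)
  vd <- vocabulary(draft)
  if (vt$size != vd$size ||
      !setequal(vt$stop_token_ids, vd$stop_token_ids))
    stop("draft and target must share vocabulary size and stop-token set")
  vt
}

#' Speculative generation
#'
#' The full speculative decoding loop: the draft proposes a span of up to
#' `L` tokens, the target verifies the whole span in one forward pass, the
#' probabilistic accept/reject rule with residual resampling decides how
#' much of the span survives, and on full acceptance an optional bonus
#' token is drawn directly from the target. Both models' KV caches are
#' advanced as tokens are accepted and truncated back on rejection. The
#' generated sequence is distributed exactly as if it had been sampled one
#' token at a time from the target with the same [sampling_policy()].
#'
#' Every round emits between 1 and `L + 1` tokens (the residual replacement
#' guarantees progress). Generation ends at the token budget or at the
#' first emitted stop token. Timing covers only the decoding loop; prompt
#' prefill and model construction are excluded.
#'
#' The random stream is consumed in a fixed order — draft draws in position
#' order, acceptance uniforms in position order, then the residual draw,
#' then the bonus draw — so runs with and without KV caching are
#' reproducible and identical under a shared seed.
#'
#' @param target,draft Causal language models with identical vocabularies.
#' @param prompt A nonempty [token_sequence()] (or id vector).
#' @param config A [speculative_config()].
#' @param .always_accept Internal diagnostic switch that disables the
#'   accept/reject rule (every drafted token is kept). Only used as the
#'   negative control of [distribution_equivalence_check()]; never a
#'   user-facing decoding mode.
#' @return A `decode_result`: the sequence, per-round acceptance records,
#'   decode time and generated-token count.
#' @seealso [baseline_generate()], [distribution_equivalence_check()]
#' @export
speculative_generate <- function(target, draft, prompt, config,
                                 .always_accept = FALSE) {
  vt <- check_compatible(target, draft)
  ids <- as_token_ids(prompt)
  if (!length(ids)) stop("prompt must be nonempty")
  P0 <- length(ids)
  stops <- vt$stop_token_ids
  if (!is.null(config$seed)) set.seed(config$seed)
  budget <- config$max_new_tokens
  policy <- config$policy
  use_kv <- config$use_kv_cache

  # prompt prefill (excluded from decode timing)
  cache_d <- forward_incremental(draft, ids, init_cache(draft))$cache
  cache_t <- forward_incremental(target, ids, init_cache(target))$cache

  log <- new_round_log(budget)
  n_rounds <- 0L
  n_gen <- 0L
  done <- FALSE
  t0 <- proc.time()[[3L]]
  while (!done && n_gen < budget) {
    if (!use_kv) {                      # recompute-from-scratch variant
      cache_d <- init_cache(draft)
      cache_t <- init_cache(target)
    }
    Lr <- min(config$L, budget - n_gen)
    P <- length(ids)
    prop <- propose_span(draft, ids, cache_d, Lr, policy)
    cache_d <- prop$cache
    ver <- verify_span(target, ids, prop$span, cache_t, policy)
    cache_t <- ver$cache
    s <- length(prop$span)

    if (.always_accept) {
      ar <- list(n_accepted = s, replacement = NULL)
    } else {
      ar <- accept_reject_span(prop$span, prop$p_draft, ver$p_target)
    }

    used_bonus <- FALSE
    used_residual <- FALSE
    if (is.null(ar$replacement)) {      # full acceptance
      ids <- c(ids, prop$span)
      n_gen <- n_gen + s
      if (s > 0L && prop$span[s] %in% stops) done <- TRUE
      if (!done && config$bonus_enabled && n_gen < budget) {
        xb <- sample_categorical(ver$p_post)
        ids <- c(ids, xb)
        n_gen <- n_gen + 1L
        used_bonus <- TRUE
        if (xb %in% stops) done <- TRUE
      }
    } else {                            # rejection at position n_accepted+1
      k <- ar$n_accepted
      ids <- c(ids, if (k > 0L) prop$span[seq_len(k)], ar$replacement)
      n_gen <- n_gen + k + 1L
      used_residual <- TRUE
      if (use_kv) {
        cache_d <- truncate_cache(cache_d, P + k)
        cache_t <- truncate_cache(cache_t, P + k)
      }
      if (ar$replacement %in% stops) done <- TRUE
    }
    n_rounds <- n_rounds + 1L
    log$n_proposed[n_rounds] <- s
    log$n_accepted[n_rounds] <- ar$n_accepted
    log$used_residual[n_rounds] <- used_residual
    log$used_bonus[n_rounds] <- used_bonus
  }
  dt <- proc.time()[[3L]] - t0
  new_decode_result(ids, P0, finish_round_log(log, n_rounds), dt, config)
}

#' KV-cached autoregressive baseline
#'
#' Standard one-token-per-forward sampling from the target model with an
#' incremental cache, under the same warping, stop-token and budget
#' semantics as [speculative_generate()]. This is the decoder whose output
#' distribution speculative decoding provably reproduces, and the
#' denominator of every speedup ratio.
#'
#' @param target A causal language model.
#' @param prompt A nonempty [token_sequence()] (or id vector).
#' @param policy A [sampling_policy()].
#' @param max_new_tokens Token budget.
#' @param seed Optional integer seed (`NULL`: use the current RNG state).
#' @return A `decode_result` (its `rounds` log is empty: no tokens are
#'   drafted).
#' @export
baseline_generate <- function(target, prompt, policy, max_new_tokens,
                              seed = NULL) {
  ids <- as_token_ids(prompt)
  if (!length(ids)) stop("prompt must be nonempty")
  P0 <- length(ids)
  stops <- vocabulary(target)$stop_token_ids
  if (!is.null(seed)) set.seed(seed)
  cache <- forward_incremental(target, ids, init_cache(target))$cache
  n_gen <- 0L
  t0 <- proc.time()[[3L]]
  while (n_gen < max_new_tokens) {
    p <- warp_logits(cache$head_logits, policy)
    x <- sample_categorical(p)
    ids <- c(ids, x)
    n_gen <- n_gen + 1L
    if (x %in% stops || n_gen >= max_new_tokens) break
    cache <- forward_incremental(target, x, cache)$cache
  }
  dt <- proc.time()[[3L]] - t0
  new_decode_result(ids, P0, finish_round_log(new_round_log(0L), 0L), dt,
                    NULL)
}
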