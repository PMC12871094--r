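#' Batch speculative sampling on tabular toy models
#'
#' Draws many independent speculative generations in one call through a
#' compiled kernel that replays the reference decoding loop
#' ([speculative_generate()]) step for step: identical algorithm,
#' identical random-stream consumption order, so under a shared seed the
#' two paths produce token-identical output (a property the test suite
#' asserts). This is what makes goodness-of-fit certification with
#' hundreds of thousands of generations affordable; it is restricted to
#' tabular models without stop tokens, which is exactly the setting the
#' certification runs in.
#'
#' @param target,draft Tabular toy models ([make_tabular_toy()]) with a
#'   shared vocabulary and no stop tokens.
#' @param prompt Prompt ids ([token_sequence()] or integer vector).
#' @param config A [speculative_config()]; `max_new_tokens` is the fixed
#'   suffix length of every generation.
#' @param n_reps Number of independent generations.
#' @param seed Optional seed applied once before the whole batch (`NULL`:
#'   continue the current stream).
#' @param .always_accept Negative-control switch, as in
#'   [speculative_generate()].
#' @return A list: `suffixes` (n_reps x max_new_tokens integer matrix),
#'   `n_proposed` and `n_accepted` (per-rep drafted/accepted counts).
#' @export
speculative_generate_batch <- function(target, draft, prompt, config,
                                       n_reps, seed = NULL,
                                       .always_accept = FALSE) {
  check_compatible(target, draft)
  check_batchable(target)
  check_batchable(draft)
  if (!is.null(seed)) set.seed(seed)
  pol <- config$policy
  cpp_tabular_speculative_batch(
    target$log_tables, target$order, draft$log_tables, draft$order,
    vocabulary(target)$size, as_token_ids(prompt), as.integer(n_reps),
    config$max_new_tokens, config$L,
    pol$temperature, pol$top_k %||% 0L, pol$top_p %||% 0,
    pol$greedy, config$bonus_enabled, isTRUE(.always_accept))
}

#' Batch baseline sampling on tabular toy models
#'
#' Compiled counterpart of repeated [baseline_generate()] calls, with the
#' same token-identity guarantee as [speculative_generate_batch()].
#'
#' @param target A tabular toy model without stop tokens.
#' @param prompt Prompt ids.
#' @param policy A [sampling_policy()].
#' @param max_new_tokens Suffix length of every generation.
#' @param n_reps Number of generations.
#' @param seed Optional seed applied once before the batch.
#' @return An n_reps x max_new_tokens integer matrix of suffixes.
#' @export
baseline_generate_batch <- function(target, prompt, policy, max_new_tokens,
                                    n_reps, seed = NULL) {
  check_batchable(target)
  if (!is.null(seed)) set.seed(seed)
  cpp_tabular_baseline_batch(
    target$log_tables, target$order, vocabulary(target)$size,
    as_token_ids(prompt), as.integer(n_reps), as.integer(max_new_tokens),
    policy$temperature, policy$top_k %||% 0L, policy$top_p %||% 0,
    policy$greedy)
}

check_batchable <- function(model) {
  if (!inherits(model, "tabular_lm"))
    stop("batch kernels support tabular toy models only")
  if (length(vocabulary(model)$stop_token_ids))
    stop("batch kernels require models without stop tokens")
  invisible(model)
}
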