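#' Rescore a generated suffix under a model
#'
#' Runs the model over the whole sequence and accumulates the
#' log-probability of each suffix token under the model's *canonical*
#' distribution — plain softmax of the logits at temperature 1, with no
#' top-k/top-p truncation — regardless of the policy the sequence was
#' generated with. Averaging gives the mean log-probability (nats per
#' token); its negative is the empirical NLL and `exp(NLL)` the
#' perplexity. Only positions after the prompt are scored ("suffix
#' perplexity"): absolute values are cross-entropy estimates, and the
#' informative quantity is the *difference* between decoding schemes — a
#' faithful speculative decoder matches the baseline's scores.
#'
#' @param model A causal language model.
#' @param tokens A [token_sequence()] with `prompt_len >= 1` and at least
#'   one suffix token.
#' @return A `scoring_report`: `mean_logprob`, `nll`, `perplexity`,
#'   `n_scored`.
#' @export
score_suffix <- function(model, tokens) {
  stopifnot(inherits(tokens, "token_sequence"))
  ids <- tokens$ids
  pl <- tokens$prompt_len
  if (pl >= length(ids)) stop("empty suffix: nothing to score")
  if (pl < 1L) stop("scoring requires at least one leading context token")
  rows <- forward_full(model, ids)
  total <- 0
  for (t in (pl + 1L):length(ids)) {
    r <- rows[t - 1L, ]
    total <- total + r[ids[t]] - log(sum(exp(r - max(r)))) - max(r)
  }
  n <- length(ids) - pl
  mean_lp <- total / n
  structure(
    list(mean_logprob = mean_lp, nll = -mean_lp,
         perplexity = exp(-mean_lp), n_scored = n),
    class = "scoring_report"
  )
}

#' Exact single-step marginal of the accept/reject + residual mechanism
#'
#' Closed-form distribution of the token emitted at one position by the
#' speculative rule: draft a token from `p_draft`, accept with probability
#' `min(1, p_target/p_draft)`, otherwise redraw from the residual. The
#' algebraic identity
#' \deqn{m(x) = p_d(x) \min(1, p_t(x)/p_d(x)) +
#'   \left(1 - \sum_y p_d(y)\min(1, p_t(y)/p_d(y))\right) r(x) = p_t(x)}
#' is the mathematical core of the distribution-preservation guarantee;
#' this function computes the left-hand side so tests can confirm it
#' equals `p_target` for arbitrary distribution pairs.
#'
#' @param p_target,p_draft Probability vectors over the same vocabulary.
#' @return A probability vector (equal to `p_target` up to round-off).
#' @export
exact_step_marginal <- function(p_target, p_draft) {
  if (length(p_target) != length(p_draft))
    stop("p_target and p_draft must cover the same vocabulary")
  acc <- pmin(p_draft, p_target)      # p_d(x) * min(1, p_t(x)/p_d(x))
  rejection_mass <- 1 - sum(acc)
  r <- residual_distribution(p_target, p_draft)
  acc + rejection_mass * r
}

#' Acceptance rate of a decoding run
#'
#' Fraction of *drafted* tokens accepted by the probabilistic rule. Bonus
#' tokens and residual replacements are excluded from both numerator and
#' denominator.
#'
#' @param rounds A `decode_result`, or its `rounds` log (anything with
#'   `n_proposed` and `n_accepted` fields).
#' @return A number in `[0, 1]`.
#' @export
acceptance_rate <- function(rounds) {
  if (inherits(rounds, "decode_result")) rounds <- rounds$rounds
  prop <- sum(rounds$n_proposed)
  if (prop == 0L) stop("acceptance rate undefined: no tokens were proposed")
  sum(rounds$n_accepted) / prop
}

#' Summarize repeated decoding runs
#'
#' Computes per-run throughput (`n_generated / decode_seconds`), its mean
#' and sample standard deviation across repeats, and the mean acceptance
#' rate (NA for baseline runs, which draft nothing).
#'
#' @param results List of `decode_result`s, one per repeat.
#' @param reps Expected number of repeats (defaults to `length(results)`).
#' @return A `run_summary` with `mean_tps`, `sd_tps`,
#'   `mean_acceptance_rate`, `n_runs` and a `config` echo.
#' @export
summarize_runs <- function(results, reps = length(results)) {
  if (reps < 1L || length(results) != reps)
    stop("expected one decode_result per repeat")
  secs <- vapply(results, function(r) r$decode_seconds, numeric(1))
  if (any(secs <= 0))
    stop("zero decode time recorded; run is too short to time")
  tps <- vapply(results, function(r) r$n_generated, numeric(1)) / secs
  acc <- vapply(results, function(r) {
    if (sum(r$rounds$n_proposed) > 0L) acceptance_rate(r) else NA_real_
  }, numeric(1))
  structure(
    list(mean_tps = mean(tps), sd_tps = if (reps > 1L) stats::sd(tps) else 0,
         tps = tps,
         mean_acceptance_rate = if (all(is.na(acc))) NA_real_ else
           mean(acc, na.rm = TRUE),
         n_runs = reps, config = results[[1]]$config),
    class = "run_summary"
  )
}

#' Speedup of speculative over baseline decoding
#'
#' @param spec,base `run_summary` objects for the speculative and baseline
#'   decoders on the same task.
#' @return Ratio of mean throughputs (`> 1` means speculative is faster).
#' @export
compute_speedup <- function(spec, base) {
  if (!is.finite(base$mean_tps) || base$mean_tps <= 0)
    stop("baseline throughput must be positive")
  spec$mean_tps / base$mean_tps
}

suffix_index <- function(suffix, vocab_size) {
  r <- 0L
  for (t in suffix) r <- r * vocab_size + (t - 1L)
  r + 1L
}

#' Exact suffix distribution of a model under a sampling policy
#'
#' Enumerates, by chain-rule recursion over warped next-token
#' distributions, the exact probability of every possible length-`horizon`
#' suffix following `prompt`. Feasible only for small vocabularies
#' (`vocab^horizon <= 10000`); this is the closed-form reference the
#' goodness-of-fit certification compares decoders against.
#'
#' @param model A causal language model (in practice a tabular toy).
#' @param prompt Prompt ids ([token_sequence()] or integer vector).
#' @param horizon Suffix length to enumerate.
#' @param policy A [sampling_policy()].
#' @return Numeric vector of length `vocab_size^horizon`; entry
#'   `suffix_index` corresponds to the suffix `(t_1, ..., t_h)` via
#'   `1 + sum((t_i - 1) * V^(h - i))`.
#' @export
enumerate_suffix_distribution <- function(model, prompt, horizon, policy) {
  V <- vocabulary(model)$size
  if (V^horizon > 10000)
    stop("enumeration too large: vocab^horizon must be <= 10000")
  ids0 <- as_token_ids(prompt)
  out <- numeric(V^horizon)
  recurse <- function(ids, depth, prob, idx) {
    if (depth == horizon) {
      out[idx] <<- prob
      return(invisible())
    }
    rows <- forward_full(model, ids)
    p <- warp_logits(rows[length(ids), ], policy)
    for (x in seq_len(V)) {
      if (p[x] > 0)
        recurse(c(ids, x), depth + 1L, prob * p[x], (idx - 1L) * V + x)
    }
  }
  recurse(ids0, 0L, 1, 1L)
  out
}

#' Certify that a decoder reproduces the target's sequence distribution
#'
#' Samples many generations from a decoder on exactly enumerable tabular
#' toy models and tests the empirical suffix distribution against the
#' closed-form target chain distribution with a chi-square goodness-of-fit
#' test (cells restricted to suffixes with positive exact probability;
#' cells with expected count below 5 are pooled per the usual validity
#' rule; any observation in a zero-probability cell is itself a failure
#' and forces p = 0). Also reports the total-variation distance. With a
#' correct implementation the test statistic follows its null
#' distribution, so p-values are uniform and rarely small; the
#' `always_accept` mode deliberately breaks the acceptance rule and serves
#' as a negative control that the test has power to reject.
#'
#' @param target,draft Tabular toy models sharing a vocabulary.
#' @param config A [speculative_config()]; `max_new_tokens` is overridden
#'   by `horizon` and `seed` by the `seed` argument.
#' @param horizon Suffix length (with `vocab^horizon <= 10000`).
#' @param n_samples Number of generations to draw.
#' @param seed Integer seed for the whole Monte Carlo batch.
#' @param prompt Prompt ids (default: single token 1).
#' @param mode `"speculative"` (default), `"baseline"` (target-only
#'   sampler), or `"always_accept"` (broken-rule negative control).
#' @param engine `"batch"` (default) draws the generations through the
#'   compiled batch kernels, which are property-tested to be
#'   token-identical to the reference loop under shared seeds;
#'   `"reference"` calls [speculative_generate()] /
#'   [baseline_generate()] once per sample.
#' @return A `distribution_check` with `statistic`, `df`, `p_value`,
#'   `tv_distance`, `n_samples`, `mode`, plus observed counts and exact
#'   probabilities.
#' @export
distribution_equivalence_check <- function(target, draft, config, horizon,
                                           n_samples, seed,
                                           prompt = 1L,
                                           mode = c("speculative", "baseline",
                                                    "always_accept"),
                                           engine = c("batch", "reference")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  V <- vocabulary(target)$size
  exact <- enumerate_suffix_distribution(target, prompt, horizon,
                                         config$policy)
  prompt_ids <- as_token_ids(prompt)
  pl <- length(prompt_ids)
  cfg <- config
  cfg$max_new_tokens <- as.integer(horizon)
  cfg$seed <- NULL
  counts <- integer(length(exact))
  set.seed(seed)
  if (engine == "batch") {
    suff <- switch(mode,
      speculative = speculative_generate_batch(target, draft, prompt_ids,
                                               cfg, n_samples)$suffixes,
      always_accept = speculative_generate_batch(target, draft, prompt_ids,
                                                 cfg, n_samples,
                                                 .always_accept = TRUE)$suffixes,
      baseline = baseline_generate_batch(target, prompt_ids, cfg$policy,
                                         horizon, n_samples)
    )
    pw <- V^((horizon - 1L):0L)
    ks <- as.integer(drop((suff - 1L) %*% pw) + 1L)
    tab <- tabulate(ks, nbins = length(exact))
    counts <- counts + tab
  } else {
    for (i in seq_len(n_samples)) {
      res <- switch(mode,
        speculative = speculative_generate(target, draft, prompt_ids, cfg),
        always_accept = speculative_generate(target, draft, prompt_ids, cfg,
                                             .always_accept = TRUE),
        baseline = baseline_generate(target, prompt_ids, cfg$policy,
                                     cfg$max_new_tokens)
      )
      sfx <- res$sequence$ids[(pl + 1L):(pl + horizon)]
      k <- suffix_index(sfx, V)
      counts[k] <- counts[k] + 1L
    }
  }
  live <- exact > 0
  leaked <- sum(counts[!live])
  expected <- exact[live] * n_samples
  obs <- counts[live]
  # Cochran validity rule: the chi-square approximation needs adequate
  # expected counts, so cells expecting fewer than 5 observations are
  # pooled into one. Without pooling a single occurrence of a
  # probability ~1e-7 suffix would dominate the statistic.
  small <- expected < 5
  if (any(small)) {
    obs <- c(obs[!small], sum(obs[small]))
    expected <- c(expected[!small], sum(expected[small]))
  }
  stat <- sum((obs - expected)^2 / expected)
  df <- length(expected) - 1L
  p <- if (leaked > 0L) 0 else
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(
    list(statistic = stat, df = df, p_value = p,
         tv_distance = 0.5 * sum(abs(counts / n_samples - exact)),
         n_samples = n_samples, mode = mode, counts = counts,
         exact = exact, leaked = leaked),
    class = "distribution_check"
  )
}

#' @export
print.distribution_check <- function(x, ...) {
  cat(sprintf(
    "<distribution_check [%s]: X2 = %.2f (df %d), p = %.3g, TV = %.4f, n = %d>\n",
    x$mode, x$statistic, x$df, x$p_value, x$tv_distance, x$n_samples))
  invisible(x)
}
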