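#' Parse a toy-model specification string
#'
#' Command-line entry points describe models as compact strings:
#' `"tabular:order=1,vocab=3,seed=7"` builds a [make_tabular_toy()] and
#' `"tiny:layers=4,width=16,vocab=16,seed=1,heads=2"` a
#' [make_tiny_transformer()]. Externally hosted checkpoints are wrapped
#' behind the same causal-LM contract by user-supplied adapters instead.
#'
#' @param spec Model specification string.
#' @return A causal language model.
#' @export
parse_model_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop(sprintf("malformed model spec '%s' (expected kind:key=val,...)",
                 spec))
  kv <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], "=",
                 fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed key=value list in model spec")
  args <- stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                          vapply(kv, `[`, "", 1L))
  get_arg <- function(name, default = NULL) {
    if (name %in% names(args)) args[[name]] else
      default %||% stop(sprintf("model spec missing '%s'", name))
  }
  switch(parts[1],
    tabular = make_tabular_toy(order = get_arg("order", 1L),
                               vocab_size = get_arg("vocab"),
                               seed = get_arg("seed")),
    tiny = make_tiny_transformer(n_layers = get_arg("layers"),
                                 width = get_arg("width", 16L),
                                 vocab_size = get_arg("vocab", 16L),
                                 seed = get_arg("seed"),
                                 n_heads = get_arg("heads", 2L)),
    stop(sprintf("unknown model kind '%s'", parts[1]))
  )
}

#' Resolve a draft specification against a target
#'
#' Layer-selector specs (`"first:3"`, `"last:2"`, `"indices:..."`) build a
#' truncated draft from the target; anything else is parsed as an
#' independent toy-model spec via [parse_model_spec()].
#'
#' @param spec Draft specification string.
#' @param target The target model.
#' @return A causal language model usable as a draft.
#' @export
default_draft_factory <- function(spec, target) {
  if (grepl("^(first|last|indices):", spec))
    build_truncated_draft(target, spec)
  else
    parse_model_spec(spec)
}

#' Benchmark sweep configuration
#'
#' Defines the grid of decoding configurations a benchmark runs: one cell
#' per combination of speculation window, temperature, prompt length and
#' draft specification, each repeated `reps` times with seeds
#' `base_seed + 0:(reps-1)`.
#'
#' @param L_values Integer vector of speculation windows (typical range
#'   2-7).
#' @param temperatures Numeric vector (typical range 0.8-1.2).
#' @param prompt_lengths Integer vector of prompt lengths in tokens.
#' @param draft_specs Character vector of draft specifications (see
#'   [default_draft_factory()]).
#' @param reps Repeats per cell (default 5).
#' @param base_seed First seed of the per-rep seed schedule.
#' @param max_new_tokens Tokens generated per run.
#' @param top_k,top_p Optional shared warping settings.
#' @param bonus_enabled Draw the bonus token on full acceptance.
#' @return A `sweep_config`.
#' @export
sweep_config <- function(L_values = 2:7,
                         temperatures = seq(0.8, 1.2, by = 0.1),
                         prompt_lengths = 32L,
                         draft_specs,
                         reps = 5L, base_seed = 1L, max_new_tokens = 64L,
                         top_k = NULL, top_p = NULL, bonus_enabled = TRUE) {
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1")
  if (any(L_values < 1L | L_values > 16L)) stop("L values must lie in [1, 16]")
  if (any(temperatures <= 0)) stop("temperatures must be positive")
  structure(
    list(L_values = as.integer(L_values),
         temperatures = as.numeric(temperatures),
         prompt_lengths = as.integer(prompt_lengths),
         draft_specs = as.character(draft_specs),
         reps = reps, base_seed = as.integer(base_seed),
         max_new_tokens = as.integer(max_new_tokens),
         top_k = top_k, top_p = top_p, bonus_enabled = isTRUE(bonus_enabled)),
    class = "sweep_config"
  )
}

#' Read a sweep configuration from JSON
#'
#' The JSON file mirrors [sweep_config()] field for field.
#'
#' @param path Path to a JSON file.
#' @return A `sweep_config`.
#' @export
read_sweep_config <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(sweep_config, j)
}

default_prompt_factory <- function(target) {
  V <- vocabulary(target)$size
  core <- setdiff(seq_len(V), vocabulary(target)$stop_token_ids)
  function(len) rep_len(core, len)     # deterministic, shared by all runs
}

#' Run a benchmark sweep over decoding configurations
#'
#' For every cell of the grid, runs the KV-cached baseline and the
#' speculative decoder `reps` times each (seeds `base_seed + rep - 1`,
#' identical prompts for both decoders), summarizes throughput and
#' acceptance rate with [summarize_runs()] and the speedup ratio with
#' [compute_speedup()]. Cells are visited in a deterministic order
#' (draft, prompt length, temperature, L varying fastest). A failing cell
#' is recorded with its error message and skipped.
#'
#' @param config A [sweep_config()].
#' @param target The target model.
#' @param draft_factory `function(spec, target)` building the draft for a
#'   cell (default [default_draft_factory()]).
#' @param prompt_factory `function(len)` returning prompt token ids
#'   (default: a deterministic cycle over non-stop vocabulary ids).
#' @return A list of per-cell records (see [emit_results()] for the
#'   serialized schema), with attribute `n_failed`.
#' @export
run_benchmark_sweep <- function(config, target,
                                draft_factory = default_draft_factory,
                                prompt_factory = default_prompt_factory(target)) {
  grid <- expand.grid(L = config$L_values, temperature = config$temperatures,
                      prompt_len = config$prompt_lengths,
                      draft_spec = config$draft_specs,
                      stringsAsFactors = FALSE)
  records <- vector("list", nrow(grid))
  n_failed <- 0L
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    rec <- tryCatch({
      draft <- draft_factory(cell$draft_spec, target)
      policy <- sampling_policy(temperature = cell$temperature,
                                top_k = config$top_k, top_p = config$top_p)
      prompt <- as.integer(prompt_factory(cell$prompt_len))
      spec_runs <- vector("list", config$reps)
      base_runs <- vector("list", config$reps)
      for (r in seq_len(config$reps)) {
        seed <- config$base_seed + r - 1L
        cfg <- speculative_config(L = cell$L, policy = policy,
                                  bonus_enabled = config$bonus_enabled,
                                  max_new_tokens = config$max_new_tokens,
                                  seed = seed)
        base_runs[[r]] <- baseline_generate(target, prompt, policy,
                                            config$max_new_tokens, seed)
        spec_runs[[r]] <- speculative_generate(target, draft, prompt, cfg)
      }
      spec_sum <- summarize_runs(spec_runs, config$reps)
      base_sum <- summarize_runs(base_runs, config$reps)
      pl <- length(prompt)
      list(
        L = cell$L, temperature = cell$temperature,
        prompt_len = cell$prompt_len, draft_spec = cell$draft_spec,
        reps = config$reps, base_seed = config$base_seed,
        max_new_tokens = config$max_new_tokens,
        spec_mean_tps = spec_sum$mean_tps, spec_sd_tps = spec_sum$sd_tps,
        base_mean_tps = base_sum$mean_tps, base_sd_tps = base_sum$sd_tps,
        speedup = compute_speedup(spec_sum, base_sum),
        mean_acceptance_rate = spec_sum$mean_acceptance_rate,
        spec_suffixes = lapply(spec_runs, function(x)
          x$sequence$ids[-seq_len(pl)]),
        base_suffixes = lapply(base_runs, function(x)
          x$sequence$ids[-seq_len(pl)])
      )
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      list(L = cell$L, temperature = cell$temperature,
           prompt_len = cell$prompt_len, draft_spec = cell$draft_spec,
           error = conditionMessage(e))
    })
    records[[g]] <- rec
  }
  attr(records, "n_failed") <- n_failed
  records
}

#' Write sweep records as JSON Lines
#'
#' One JSON object per configuration cell, with the full configuration
#' echoed for reproducibility plus the package version and a timestamp
#' (the timestamp is informational and excluded from any equality
#' comparison).
#'
#' @param records List of records from [run_benchmark_sweep()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_results <- function(records, path) {
  ver <- as.character(utils::packageVersion("specdec"))
  ts <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  lines <- vapply(records, function(r) {
    r$package_version <- ver
    r$timestamp <- ts
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read back JSON Lines records
#'
#' @param path Path written by [emit_results()].
#' @return List of records.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = TRUE)
}
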