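#' Parse a layer-selector specification
#'
#' Layer selectors describe which transformer blocks of a target model a
#' truncated draft retains: `"first:k"` keeps the first k blocks (the
#' default recommendation — early contiguous layers give the best
#' acceptance rates), `"last:k"` keeps the final k, and
#' `"indices:i1,i2,..."` keeps an explicit set of 1-based block indices.
#' Selected blocks always stay in their original stack order.
#'
#' @param spec Character such as `"first:3"`, `"last:2"` or
#'   `"indices:1,3,5"`.
#' @return A `layer_selector` with fields `mode` and `k` or `indices`.
#' @examples
#' parse_layer_selector("first:3")
#' @export
parse_layer_selector <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec))
    stop("selector spec must be a single nonempty string")
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop(sprintf("malformed layer selector '%s' (expected mode:value)", spec))
  mode <- parts[1]
  if (mode %in% c("first", "last")) {
    k <- suppressWarnings(as.integer(parts[2]))
    if (is.na(k) || k < 1L)
      stop(sprintf("'%s' requires a positive block count", mode))
    sel <- list(mode = mode, k = k)
  } else if (mode == "indices") {
    idx <- suppressWarnings(as.integer(strsplit(parts[2], ",")[[1]]))
    if (!length(idx) || anyNA(idx) || any(idx < 1L))
      stop("'indices' requires a comma-separated list of positive integers")
    if (anyDuplicated(idx))
      stop("duplicate block indices in layer selector")
    sel <- list(mode = mode, indices = sort(idx))
  } else {
    stop(sprintf("unknown layer-selector mode '%s'", mode))
  }
  structure(sel, class = "layer_selector")
}

resolve_layer_indices <- function(selector, n_blocks) {
  idx <- switch(selector$mode,
    first = {
      if (selector$k > n_blocks)
        stop(sprintf("first:%d exceeds the %d-block stack", selector$k,
                     n_blocks))
      seq_len(selector$k)
    },
    last = {
      if (selector$k > n_blocks)
        stop(sprintf("last:%d exceeds the %d-block stack", selector$k,
                     n_blocks))
      (n_blocks - selector$k + 1L):n_blocks
    },
    indices = {
      if (any(selector$indices > n_blocks))
        stop(sprintf("block index out of range (stack has %d blocks)",
                     n_blocks))
      selector$indices
    }
  )
  as.integer(idx)
}

#' Build a training-free truncated draft from a target model
#'
#' Constructs a draft by retaining a subset of the target's transformer
#' blocks while reusing — by reference, with no copying and no training —
#' its token embeddings, positional embeddings, final layer normalization
#' and language-modeling head. The draft therefore shares the target's
#' vocabulary, tokenizer and input/output spaces and supports the same
#' cache contract; its per-token cost scales with the number of retained
#' blocks. This is structural distillation: a shallow approximation of the
#' target obtained for free, usable as a speculative-decoding draft when no
#' separately pretrained small model exists.
#'
#' Any layer normalization inside discarded blocks is dropped with them;
#' the end-of-stack normalization is applied directly after the last
#' retained block.
#'
#' @param target A model exposing an ordered `blocks` list (the
#'   tiny-transformer fixture does; GPT-2-style checkpoints do through an
#'   adapter).
#' @param selector A [parse_layer_selector()] result or selector string.
#' @return A causal language model of the same class as the target with
#'   `length(selector)` blocks. Selecting every block reproduces the
#'   target's logits exactly.
#' @examples
#' tgt <- make_tiny_transformer(n_layers = 4, seed = 1)
#' drf <- build_truncated_draft(tgt, "first:2")
#' length(drf$blocks)  # 2
#' @export
build_truncated_draft <- function(target, selector) {
  if (is.character(selector)) selector <- parse_layer_selector(selector)
  if (is.null(target$blocks))
    stop("unsupported architecture: target does not expose a block stack")
  idx <- resolve_layer_indices(selector, length(target$blocks))
  draft <- target
  draft$blocks <- target$blocks[idx]
  attr(draft, "layer_selection") <- idx
  draft
}

#' Describe a truncated-draft selection as a manifest
#'
#' Produces a small list (serializable as JSON) recording which blocks a
#' selector retains on a given target — no weights are rewritten.
#'
#' @param target A model exposing a block stack.
#' @param selector Selector string or `layer_selector`.
#' @return A list with the selector, resolved indices and depths.
#' @export
truncation_manifest <- function(target, selector) {
  spec <- if (is.character(selector)) selector else
    paste0(selector$mode, ":", if (selector$mode == "indices")
      paste(selector$indices, collapse = ",") else selector$k)
  if (is.character(selector)) selector <- parse_layer_selector(selector)
  idx <- resolve_layer_indices(selector, length(target$blocks))
  list(selector = spec, retained_blocks = idx,
       target_depth = length(target$blocks), draft_depth = length(idx),
       vocab_size = vocabulary(target)$size)
}
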