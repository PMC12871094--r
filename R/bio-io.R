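#' Non-overlapping 6-mer DNA tokenizer
#'
#' Builds the k-mer vocabulary used by genomic language models of the
#' DNAGPT family: every one of the 4^6 = 4096 DNA 6-mers over {A,C,G,T}
#' maps bijectively to a core token id (lexicographic order, so
#' `"AAAAAA"` is id 1), and tag tokens such as the human-reference tag
#' `"<R>"` occupy ids after the core block. DNA is encoded as consecutive
#' disjoint 6-character chunks; ambiguity codes (N, IUPAC) are rejected
#' because the vocabulary is defined over ACGT only.
#'
#' @param tags Character vector of tag-token texts (default `"<R>"`).
#' @return A `dna_tokenizer` with fields `k`, `kmers`, `core_size`,
#'   `tag_ids` (named integer vector) and `vocab_size`.
#' @export
dna_tokenizer <- function(tags = "<R>") {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(rep(list(bases), 6), stringsAsFactors = FALSE)
  kmers <- do.call(paste0, rev(g))    # first character most significant
  tag_ids <- if (length(tags))
    stats::setNames(4096L + seq_along(tags), tags) else
    stats::setNames(integer(0), character(0))
  structure(
    list(k = 6L, kmers = kmers, core_size = 4096L, tag_ids = tag_ids,
         vocab_size = 4096L + length(tags)),
    class = "dna_tokenizer"
  )
}

#' Tokenize DNA into non-overlapping 6-mers
#'
#' @param tokenizer A [dna_tokenizer()].
#' @param sequence DNA text over A/C/G/T (lowercase accepted).
#' @param on_remainder What to do when the length is not a multiple of 6:
#'   `"error"` (default) or `"drop"` the trailing partial chunk.
#' @return Integer vector of core token ids (empty for the empty string).
#' @examples
#' tok <- dna_tokenizer()
#' tokenize_dna_6mer(tok, "ACGTACGGTTAA")
#' @export
tokenize_dna_6mer <- function(tokenizer, sequence,
                              on_remainder = c("error", "drop")) {
  on_remainder <- match.arg(on_remainder)
  s <- toupper(sequence)
  if (!nzchar(s)) return(integer(0))
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0)
    stop(sprintf("invalid character '%s' at position %d (only A/C/G/T allowed)",
                 substr(s, bad, bad), bad))
  n <- nchar(s)
  rem <- n %% 6L
  if (rem != 0L) {
    if (on_remainder == "error")
      stop(sprintf("sequence length %d is not a multiple of 6", n))
    n <- n - rem
    if (n == 0L) return(integer(0))
  }
  starts <- seq.int(1L, n, by = 6L)
  chunks <- substring(s, starts, starts + 5L)
  match(chunks, tokenizer$kmers)
}

#' Decode 6-mer token ids back to DNA
#'
#' Exact inverse of [tokenize_dna_6mer()] on core ids;
#' `detokenize(tokenize(s)) == s` for every valid sequence.
#'
#' @param tokenizer A [dna_tokenizer()].
#' @param ids Integer vector of core 6-mer ids.
#' @return DNA text.
#' @export
detokenize_dna_6mer <- function(tokenizer, ids) {
  if (!length(ids)) return("")
  if (any(ids < 1L | ids > tokenizer$core_size))
    stop("ids contain special/tag tokens or are out of the core 6-mer range")
  paste0(tokenizer$kmers[ids], collapse = "")
}

#' Character-level protein tokenizer for toy models
#'
#' A minimal amino-acid tokenizer mirroring the ProGen-style conventions:
#' a begin-of-sequence token `"1"`, a termination token `"2"` (the stop
#' id exposed to decoders), and one token per standard amino-acid letter.
#' Real checkpoints use their own (BPE) tokenizers through an adapter;
#' this one exists so protein prompts can be exercised end to end at toy
#' scale.
#'
#' @return A `protein_tokenizer` with `tokens`, `vocab_size`,
#'   `stop_token_ids`.
#' @export
protein_tokenizer <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tokens <- c("1", "2", aa)
  structure(
    list(tokens = tokens, vocab_size = length(tokens),
         stop_token_ids = 2L),
    class = "protein_tokenizer"
  )
}

tokenize_protein <- function(tokenizer, sequence) {
  if (!nzchar(sequence)) return(integer(0))
  chars <- strsplit(toupper(sequence), "")[[1]]
  ids <- match(chars, tokenizer$tokens)
  if (anyNA(ids))
    stop(sprintf("invalid amino-acid character '%s' at position %d",
                 chars[which(is.na(ids))[1]], which(is.na(ids))[1]))
  ids
}

#' Prompt specification
#'
#' Describes how a raw biological sequence prefix is turned into the model
#' prompt: which family (DNA or protein), which tag tokens to prepend
#' (e.g. the human-reference tag `"<R>"` for genomic models), an optional
#' start-token text (e.g. `"1M"` for ProGen-style protein generation), and
#' the raw prefix itself.
#'
#' @param family `"dna"` or `"protein"`.
#' @param sequence Raw sequence prefix (may be empty).
#' @param tags Character vector of tag-token texts (DNA family).
#' @param start_token Start-token text prepended before the sequence
#'   (protein family), tokenized with the family tokenizer.
#' @return A `prompt_spec`.
#' @export
prompt_spec <- function(family = c("dna", "protein"), sequence = "",
                        tags = if (family[1] == "dna") "<R>" else character(0),
                        start_token = NULL) {
  family <- match.arg(family)
  structure(list(family = family, sequence = sequence, tags = tags,
                 start_token = start_token),
            class = "prompt_spec")
}

#' Build a prompt token sequence
#'
#' Deterministically resolves a [prompt_spec()] against a tokenizer: tag
#' tokens first, then the start token (protein), then the tokenized
#' sequence prefix; `prompt_len` is set to the total so generation appends
#' after it. Baseline and speculative runs must share the identical prompt
#' for their comparison to be controlled, which determinism guarantees.
#'
#' @param spec A [prompt_spec()].
#' @param tokenizer A [dna_tokenizer()] or [protein_tokenizer()] matching
#'   the family.
#' @return A [token_sequence()].
#' @export
build_prompt <- function(spec, tokenizer) {
  stopifnot(inherits(spec, "prompt_spec"))
  if (spec$family == "dna") {
    stopifnot(inherits(tokenizer, "dna_tokenizer"))
    tag_ids <- integer(0)
    if (length(spec$tags)) {
      unknown <- setdiff(spec$tags, names(tokenizer$tag_ids))
      if (length(unknown))
        stop(sprintf("unknown tag token '%s' for this vocabulary",
                     unknown[1]))
      tag_ids <- unname(tokenizer$tag_ids[spec$tags])
    }
    ids <- c(tag_ids, tokenize_dna_6mer(tokenizer, spec$sequence))
  } else {
    stopifnot(inherits(tokenizer, "protein_tokenizer"))
    start_ids <- if (!is.null(spec$start_token))
      tokenize_protein(tokenizer, spec$start_token) else integer(0)
    tag_ids <- if (length(spec$tags))
      tokenize_protein(tokenizer, paste(spec$tags, collapse = "")) else
      integer(0)
    ids <- c(tag_ids, start_ids, tokenize_protein(tokenizer, spec$sequence))
  }
  token_sequence(ids, prompt_len = length(ids))
}

#' Read a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet()` returning a plain
#' data frame, with a pre-scan that reports malformed files (sequence
#' data before any header) by line number.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `header` (verbatim, without the
#'   leading `>`) and `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  meaningful <- which(nzchar(trimws(lines)))
  if (!length(meaningful))
    return(data.frame(header = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  first <- meaningful[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA: sequence data before any header at line %d",
                 first))
  set <- Biostrings::readBStringSet(path)
  data.frame(header = names(set), sequence = as.character(set),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' Wraps `Biostrings::writeXStringSet()`; sequences are wrapped at
#' `width` characters per line and headers are written verbatim.
#'
#' @param records Data frame with columns `header` and `sequence` (the
#'   shape [read_fasta()] returns).
#' @param path Output path.
#' @param width Line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(
    stats::setNames(as.character(records$sequence),
                    as.character(records$header)))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Header for a generated FASTA record
#'
#' Encodes the generation provenance (model, seed, speculation window,
#' temperature) in the header of emitted records.
#'
#' @param model_name Character label of the target model.
#' @param seed,L,temperature Generation settings.
#' @return A single header string.
#' @export
fasta_header <- function(model_name, seed, L, temperature) {
  sprintf("%s seed=%d L=%d T=%g", model_name, seed, L, temperature)
}
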