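test_that("6-mer tokenization chunks, validates and inverts exactly", {
  tok <- dna_tokenizer()
  expect_equal(tokenize_dna_6mer(tok, ""), integer(0))
  ids <- tokenize_dna_6mer(tok, "ACGTACGGTTAA")
  expect_equal(tok$kmers[ids], c("ACGTAC", "GGTTAA"))
  expect_equal(tokenize_dna_6mer(tok, "acgtac"),
               tokenize_dna_6mer(tok, "ACGTAC"))
  # lexicographic core ids: AAAAAA is 1, TTTTTT is 4096
  expect_equal(tokenize_dna_6mer(tok, "AAAAAA"), 1L)
  expect_equal(tokenize_dna_6mer(tok, "TTTTTT"), 4096L)
  expect_error(tokenize_dna_6mer(tok, "ACGTANT"), "'N' at position 6")
  expect_error(tokenize_dna_6mer(tok, "ACGTACG"), "multiple of 6")
  expect_equal(tokenize_dna_6mer(tok, "ACGTACG", on_remainder = "drop"),
               tokenize_dna_6mer(tok, "ACGTAC"))
})

test_that("detokenization round-trips and rejects tag ids", {
  tok <- dna_tokenizer()
  expect_equal(detokenize_dna_6mer(tok, integer(0)), "")
  set.seed(30)
  for (i in 1:200) {
    m <- sample(1:50, 1)
    s <- paste(sample(c("A", "C", "G", "T"), 6 * m, replace = TRUE),
               collapse = "")
    expect_equal(detokenize_dna_6mer(tok, tokenize_dna_6mer(tok, s)), s)
  }
  expect_error(detokenize_dna_6mer(tok, tok$tag_ids[["<R>"]]), "tag")
})

test_that("prompt construction is deterministic with tags and start tokens", {
  tok <- dna_tokenizer()
  spec <- prompt_spec("dna", sequence = "ACGTACGGTTAA")
  a <- build_prompt(spec, tok)
  expect_equal(a$ids[1], tok$tag_ids[["<R>"]])
  expect_equal(a$prompt_len, 3L)
  expect_identical(build_prompt(spec, tok), a)
  # empty prefix: the prompt is the tag token only
  empty <- build_prompt(prompt_spec("dna"), tok)
  expect_equal(empty$ids, unname(tok$tag_ids))
  expect_error(build_prompt(prompt_spec("dna", tags = "<Q>"), tok),
               "unknown tag")
  # protein: start token 1M then residues, stop id exposed by tokenizer
  ptok <- protein_tokenizer()
  pp <- build_prompt(prompt_spec("protein", sequence = "KV",
                                 start_token = "1M"), ptok)
  expect_equal(ptok$tokens[pp$ids], c("1", "M", "K", "V"))
  expect_equal(ptok$stop_token_ids, 2L)
})

test_that("FASTA write/read round-trips with 60-column wrapping", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  set.seed(40)
  recs <- data.frame(
    header = c(fasta_header("toy", 1L, 4L, 0.8), "plain header with spaces"),
    sequence = c(paste(sample(c("A", "C", "G", "T"), 130, replace = TRUE),
                       collapse = ""),
                 "MKV"),
    stringsAsFactors = FALSE)
  write_fasta(recs, tmp)
  back <- read_fasta(tmp)
  expect_equal(back, recs)
  lines <- readLines(tmp)
  # 130 residues wrap to 60 + 60 + 10
  expect_equal(nchar(lines[2:4]), c(60L, 60L, 10L))
})

test_that("FASTA edge cases: empty files and malformed records", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("", "ACGT", ">h1", "ACGT"), bad)
  expect_error(read_fasta(bad), "line 2")
})

test_that("tokenized DNA prompts drive generation end to end", {
  # a toy DNA-like setup: vocabulary of 4 'k-mers', tag id as prompt
  tgt <- make_tabular_toy(1, 4, 77)
  drf <- make_tabular_toy(1, 4, 78)
  cfg <- speculative_config(L = 2, max_new_tokens = 8, seed = 3)
  res <- speculative_generate(tgt, drf, c(1L, 2L), cfg)
  expect_equal(res$sequence$prompt_len, 2L)
  expect_equal(res$n_generated, 8L)
})
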