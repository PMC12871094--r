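Package: specdec
Title: Probabilistic Speculative Decoding for Biological Sequence Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution-preserving speculative decoding for autoregressive
    DNA and protein language models. A lightweight draft model proposes short
    token spans which a larger target model verifies in a single forward pass;
    a probabilistic accept/reject rule with residual resampling guarantees the
    generated sequence follows the target model's sampling distribution
    exactly. Includes training-free layer-truncated draft construction,
    KV-cache-aware and cache-free decoding loops, seeded logit warping
    (temperature, top-k, top-p), non-overlapping 6-mer DNA tokenization and
    FASTA plumbing, perplexity rescoring diagnostics, exactly enumerable toy
    model fixtures for certifying distribution preservation, and benchmark
    sweep utilities reporting tokens per second, acceptance rate and speedup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
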