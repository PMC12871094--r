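---
title: "Distribution-preserving speculative decoding for biological sequence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-preserving speculative decoding for biological sequence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdec)
```

## The problem

Autoregressive DNA and protein language models generate one token per
forward pass of a large transformer. Each pass is memory-bandwidth bound,
so long-sequence generation — synthetic promoter design, protein variant
exploration, large-scale in silico mutagenesis — pays the full cost of the
big model at every single position.

Speculative decoding amortizes that cost. A cheap *draft* model proposes a
span of `L` candidate tokens; the expensive *target* model evaluates the
whole span in **one** forward pass; a probabilistic accept/reject rule
keeps a prefix of the span and corrects the first rejected position. The
crucial property is that this is not an approximation: the generated
sequence is distributed *exactly* as if it had been sampled token by token
from the target.

## The acceptance rule and why it is exact

At span position $i$, let $p_d$ and $p_t$ be the draft and target
next-token distributions (both warped by the shared sampling policy —
see below), and let $x_i$ be the drafted token. The token is accepted
with probability

$$\alpha_i = \min\!\left(1, \frac{p_t(x_i)}{p_d(x_i)}\right).$$

On the first rejection, a replacement is drawn from the *residual
distribution*

$$r(x) \propto \max\!\big(0,\, p_t(x) - p_d(x)\big),$$

and the rest of the span is discarded. The emitted-token marginal is then

$$m(x) = p_d(x)\min\!\left(1,\tfrac{p_t(x)}{p_d(x)}\right) +
\Big(1 - \sum_y p_d(y)\min\!\big(1,\tfrac{p_t(y)}{p_d(y)}\big)\Big)\, r(x)
= p_t(x),$$

an algebraic identity: the accepted mass at $x$ is $\min(p_d, p_t)$, and
the residual redistributes the rejection mass as exactly
$p_t - \min(p_d, p_t)$. `exact_step_marginal()` computes the left-hand
side in closed form, and the test suite confirms $m = p_t$ to $10^{-10}$
over a thousand random distribution pairs. Because each position is
exactly target-distributed given its prefix, the chain rule extends the
guarantee to whole sequences. When every drafted token is accepted, one
*bonus* token may additionally be drawn directly from the target's
post-span distribution, which costs nothing extra and cannot bias the
output (it *is* a target sample).

A subtlety worth stating explicitly: the guarantee holds only if the
$p_d$ and $p_t$ entering the ratio are the *same* warped distributions
the tokens are actually sampled from. The engine therefore applies one
`sampling_policy()` — temperature, then softmax, then top-k, then top-p,
then renormalization — identically to both models, at sampling time and
at acceptance time. Warp order is fixed as temperature → top-k → top-p
(the dominant convention in generation stacks); top-k ties at the
boundary break toward the lower token id for determinism; the nucleus
rule always includes the token straddling the cumulative threshold, so
the support can never be emptied. Tokens with zero warped draft
probability can never be drafted, so the acceptance ratio never divides
by zero. If the residual mass falls below $10^{-12}$ the two warped
distributions are numerically identical — rejection is then a round-off
fluke — and the residual falls back to $p_t$ itself.

## Tunable parameters

* `L` (speculation window, default grids use 2–7): tokens proposed per
  round. Longer windows amortize more target compute but require draft
  and target to agree on longer spans, so the acceptance rate falls;
  small-to-moderate windows are usually optimal.
* `temperature` (0.8–1.2 in typical sweeps): shared by draft and target.
  Flatter distributions (higher temperature) increase draft/target
  overlap and acceptance; sharper ones concentrate disagreements.
* `top_k` / `top_p`: standard truncation, applied identically to both
  models.
* `bonus_enabled` (default `TRUE`): the free extra target token on full
  acceptance; a round then emits up to `L + 1` tokens.
* `use_kv_cache` (default `TRUE`): with caching, both models advance
  per-layer key/value buffers as tokens are accepted, and rejections
  truncate the buffers back to the accepted prefix; without it, every
  round recomputes the full prefix. The two modes are token-identical
  under a shared seed, which the suite checks on 100 random
  configurations — the cache is purely an optimization.

## Random-number protocol

Each generation consumes one seeded stream in a fixed documented order:
draft draws in position order, acceptance uniforms in position order,
then the residual draw, then the bonus draw. Categorical sampling uses
inverse-CDF with exactly one uniform per draw. This is what makes
cached/uncached runs, replay comparisons, and the compiled batch kernels
bit-comparable.

## Toy model families: what they emulate and what they do not

Real checkpoints cannot certify distribution preservation — their
sequence distributions are not enumerable. The package therefore ships
two self-contained fixtures.

**Tabular models** (`make_tabular_toy()`, `make_tabular_model()`) are
bounded-order Markov chains (order ≤ 2, vocabulary ≤ 8 for the random
generator) with explicit conditional tables, strictly positive Dirichlet
rows drawn reproducibly from a seed. Their exact suffix distribution is
computable by chain-rule enumeration (`enumerate_suffix_distribution()`),
which turns "does speculative decoding preserve the target
distribution?" into a testable goodness-of-fit question. The default
certification chain uses vocabulary 3, order 1, seed 42, horizon 3 —
small enough that all 27 suffix probabilities are exact, large enough
that skew between draft and target is substantial.

**Tiny transformers** (`make_tiny_transformer()`) are structurally
faithful GPT-style decoders — embeddings, positional table, pre-norm
blocks with causal multi-head attention and GELU MLPs, final layer norm,
linear head — exposed component by component so layer truncation can
operate on them exactly as it would on a GPT-2-style checkpoint. They
run in double precision (R's native arithmetic); the incremental/full
agreement contract is stated at an absolute logit tolerance of `1e-5`,
generous for double precision but kept as the documented contract since
accumulation order differs between the batched and token-by-token paths.

What the toys do *not* emulate: learned biological structure, large
vocabularies (a 6-mer DNA model has 4096 core tokens), BPE tokenization,
and real hardware cost ratios between a 0.1B draft and a 3B target.
Passing tests therefore certify the *algorithm* — exactness of the
acceptance rule, cache bookkeeping, reproducibility — not the throughput
one would measure on datacenter GPUs with billion-parameter checkpoints,
which depends on hardware and weights. Wall-clock speedups measured on
the toy transformer (the acceptance script reports one) demonstrate the
mechanism, not production numbers.

## Truncated drafts

`build_truncated_draft()` carves a draft out of the target: it keeps the
token embeddings, a subset of transformer blocks, the end-of-stack layer
normalization and the language-modeling head, all shared by reference —
no copying, no training. The default selection is `first:k` (early
contiguous layers), which gave the best acceptance in comparisons across
selection modes; `last:k` and explicit `indices:` are retained for such
comparisons. Block indices are 1-based, following R convention. Layer
norms inside discarded blocks are dropped with their blocks; the final
normalization is applied directly after the last retained block. Where a
checkpoint unties embedding and head weights, both are reused unchanged.
Per-token draft cost scales with the number of retained blocks, so depth
is the knob trading draft fidelity against draft cost.

## Diagnostics

`score_suffix()` rescores generated suffixes under a model's canonical
distribution — temperature 1, no truncation — regardless of the policy
used at generation time, reporting mean log-probability (nats/token),
NLL and perplexity (`exp(NLL)`). Only the generated suffix is scored,
never the prompt. Since generation happens under a warped policy while
scoring is canonical, absolute values are cross-entropy estimates; the
informative quantity is the *difference* between decoders, which for a
faithful implementation is statistically zero.

`distribution_equivalence_check()` is the strongest diagnostic: it
compares a large sample of generations against the exactly enumerated
target chain with a chi-square goodness-of-fit test and reports the
total-variation distance. Numerical choices: cells with zero exact
probability must stay empty (an observation there forces p = 0, since
the decoder can provably never emit a zero-probability token); cells
with expected count below 5 are pooled into one, the standard validity
rule for the chi-square approximation — without pooling, a single
occurrence of a probability $\sim 10^{-7}$ suffix would dominate the
statistic and spuriously reject a correct sampler. The significance
level used by the suite is 0.001 with seeds fixed in advance. The
`always_accept` mode disables the acceptance rule and, paired with a
deliberately skewed draft, serves as the negative control showing the
test has power (it rejects at $p < 10^{-6}$).

## The compiled batch kernels

Certification needs hundreds of thousands of generations per setting.
The reference R loop (`speculative_generate()`) is the specification of
the algorithm; `speculative_generate_batch()` and
`baseline_generate_batch()` are C++ kernels that replay it for tabular
models, consuming the random stream in the identical order with
long-double accumulation matching R's `sum()`/`cumsum()`. A property
test draws hundreds of generations both ways under shared seeds —
across temperatures, top-k, top-p, greedy, and bonus on/off — and
asserts token-for-token identity plus identical acceptance counts. The
large goodness-of-fit runs then use the kernels (about 0.6 s per 200,000
three-token generations on one CPU core instead of minutes).

## Problem sizes used by the shipped checks

The test suite certifies: the single-step identity on 1,000 random
distribution pairs (vocabularies 2–8); sequence-level goodness of fit at
200,000 generations per setting on the vocabulary-3 chain, varying one
factor at a time around the default cell (L ∈ {1,2,3}, bonus off,
temperature 0.8 and 1.2, top-p 0.9) plus the baseline sampler at each
distinct policy; cache on/off identity on 100 random configurations;
full-depth truncation identity on 100 random prefixes; and perplexity
parity between 10,000 baseline and 10,000 speculative generations.
These sizes keep every check on a single CPU core in seconds to a few
minutes while leaving Monte-Carlo error far below the effects being
tested.

## Known limitations

* No adapter to hosted checkpoints is shipped; the causal-LM contract
  (`vocabulary()`, `forward_full()`, `forward_incremental()`,
  `truncate_cache()`) is the documented integration surface for wrapping
  GPT-style models, and everything downstream of the contract is
  model-agnostic.
* Single-sequence decoding only: no tree/multi-candidate speculation, no
  batched multi-sequence decoding, no early-exit self-speculation.
* The 6-mer DNA tokenizer rejects ambiguity codes (N, IUPAC) rather than
  mapping them; its vocabulary is defined over A/C/G/T only.
* Protein text beyond the toy character-level tokenizer is the
  responsibility of the wrapped model's own tokenizer; the package does
  not implement BPE.
* One observed effect at checkpoint scale — draft-only sequences scoring
  slightly *better* than target-generated ones under canonical rescoring,
  a tail-exploration effect of sampling-based generation — depends on the
  relative conservatism of real drafts and is not asserted at toy scale.
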