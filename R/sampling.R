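#' Sampling policy shared by draft and target models
#'
#' Bundles the logit-warping settings (temperature, top-k, top-p, greedy)
#' applied identically to the draft and target distributions. The
#' distribution-preservation guarantee of speculative decoding holds only
#' when both models sample from, and are compared on, distributions warped
#' under the *same* policy, so one policy object is shared by the whole
#' decoding run.
#'
#' @param temperature Positive scalar; logits are divided by it before the
#'   softmax. 1 leaves the distribution unmodified; values below 1 sharpen
#'   it, values above 1 flatten it.
#' @param top_k Optional positive integer; after the softmax only the
#'   `top_k` most probable tokens keep mass (ties at the boundary broken by
#'   lower token id).
#' @param top_p Optional scalar in (0, 1]; nucleus sampling. The minimal
#'   set of highest-probability tokens with cumulative mass >= `top_p` keeps
#'   mass (the token straddling the boundary is included, so the support is
#'   never empty).
#' @param greedy If `TRUE`, warping returns a one-hot distribution at the
#'   argmax and the other settings are ignored.
#' @return An object of class `sampling_policy`.
#' @examples
#' sampling_policy(temperature = 0.8, top_p = 0.9)
#' @export
sampling_policy <- function(temperature = 1.0, top_k = NULL, top_p = NULL,
                            greedy = FALSE) {
  if (!greedy && (!is.numeric(temperature) || temperature <= 0))
    stop("temperature must be > 0 unless greedy")
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (top_k < 1L) stop("top_k must be a positive integer")
  }
  if (!is.null(top_p)) {
    if (!is.numeric(top_p) || top_p <= 0 || top_p > 1)
      stop("top_p must lie in (0, 1]")
  }
  structure(
    list(temperature = as.numeric(temperature), top_k = top_k,
         top_p = top_p, greedy = isTRUE(greedy)),
    class = "sampling_policy"
  )
}

#' Warp logits into a sampling distribution
#'
#' Applies, in order: division by temperature, softmax, top-k masking,
#' top-p (nucleus) masking, and a final renormalization. With
#' `policy$greedy` the result is a one-hot vector at the argmax. The
#' surviving probabilities keep the relative order of the input logits.
#'
#' @param logits Finite numeric vector of unnormalized log-scores over the
#'   vocabulary.
#' @param policy A [sampling_policy()].
#' @return A numeric probability vector of the same length: nonnegative,
#'   summing to 1, with nonempty support.
#' @examples
#' warp_logits(c(0, 0, log(2)), sampling_policy())  # 0.25 0.25 0.50
#' @export
warp_logits <- function(logits, policy) {
  if (policy$greedy) {
    p <- numeric(length(logits))
    p[which.max(logits)] <- 1
    return(p)
  }
  z <- logits / policy$temperature
  z <- z - max(z)
  p <- exp(z)
  p <- p / sum(p)
  if (!is.null(policy$top_k) && policy$top_k < length(p)) {
    # stable order(): ties at the k-th probability go to the lower token id
    ord <- order(p, decreasing = TRUE)
    p[ord[-seq_len(policy$top_k)]] <- 0
  }
  if (!is.null(policy$top_p) && policy$top_p < 1) {
    ord <- order(p, decreasing = TRUE)
    cum <- cumsum(p[ord])
    # minimal prefix reaching top_p; the boundary token is kept
    cut <- which(cum >= min(policy$top_p, cum[length(cum)]))[1L]
    if (cut < length(ord)) p[ord[(cut + 1L):length(ord)]] <- 0
  }
  p / sum(p)
}

#' Draw token ids from a categorical distribution
#'
#' Inverse-CDF sampling consuming exactly one uniform variate per draw from
#' R's global random stream, which keeps the RNG consumption order of the
#' decoding loop reproducible and auditable. Returned ids always have
#' nonzero probability.
#'
#' @param probs Probability vector (nonnegative, summing to 1).
#' @param n Number of draws.
#' @return Integer vector of `n` token ids in `1:length(probs)`.
#' @export
sample_categorical <- function(probs, n = 1L) {
  cs <- cumsum(probs)
  ids <- findInterval(stats::runif(n), cs) + 1L
  # guard against round-off landing past the last positive-mass token
  bad <- ids > length(probs) | probs[pmin(ids, length(probs))] <= 0
  if (any(bad)) {
    pos <- which(probs > 0)
    for (j in which(bad)) {
      k <- pos[pos >= ids[j]]
      ids[j] <- if (length(k)) k[1L] else pos[length(pos)]
    }
  }
  ids
}

#' Residual distribution used after a rejection
#'
#' The replacement token drawn when a drafted token is rejected comes from
#' the normalized positive part of (target - draft):
#' `r(x) = max(0, p_t(x) - p_d(x)) / sum(...)`. Together with the
#' `min(1, p_t/p_d)` acceptance rule this makes the emitted token exactly
#' target-distributed (see [exact_step_marginal()]).
#'
#' If the total residual mass is below `1e-12` the two distributions are
#' numerically identical, rejection was a measure-zero fluke of round-off,
#' and `p_target` itself is returned.
#'
#' @param p_target,p_draft Probability vectors over the same vocabulary.
#' @return A probability vector.
#' @examples
#' residual_distribution(c(0.5, 0.3, 0.2), c(0.2, 0.5, 0.3))  # 1 0 0
#' @export
residual_distribution <- function(p_target, p_draft) {
  if (length(p_target) != length(p_draft))
    stop("p_target and p_draft must cover the same vocabulary")
  r <- p_target - p_draft
  r[r < 0] <- 0
  m <- sum(r)
  if (m < 1e-12) return(p_target)
  r / m
}
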