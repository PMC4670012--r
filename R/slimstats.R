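# Occurrence probabilities, exact Poisson-binomial tails over Unrelated
# Protein Clusters, and search-space-corrected significance.

#' Probability that a sequence contains a motif at least once
#'
#' For each fixed-length variant `v` of the pattern, the per-start match
#' probability is the product over defined positions of the summed unmasked
#' composition of the allowed residues (wildcards contribute factor 1). With
#' `n_v = max(0, L - len(v) + 1)` candidate starts on the full sequence length
#' `L`, the sequence-level probability is
#' `p_seq = 1 - prod_v (1 - p_v)^{n_v}`, computed in log space and clamped to
#' `[0, 1]`. Starts are treated as independent, which is accurate for
#' non-self-overlapping patterns and small `p_v`; masking enters through the
#' composition (and through any defined residue of frequency zero).
#'
#' @param m `slim_motif` or pattern string.
#' @param mseq `masked_seq` (see [masked_sequence()]).
#' @param problen `"full"` (default) counts candidate starts on the full
#'   length; `"masked"` uses the effective (unmasked) length.
#' @return probability in `[0, 1]`; 0 for a fully masked sequence.
#' @export
sequence_occurrence_probability <- function(m, mseq, problen = c("full", "masked")) {
  if (is.character(m)) m <- parse_motif(m)
  problen <- match.arg(problen)
  if (mseq$effective_length == 0L) return(0)
  f <- mseq$composition
  L <- if (problen == "full") nchar(mseq$sequence) else mseq$effective_length
  log_none <- 0
  for (v in m$variants) {
    w <- length(v)
    n_v <- max(0L, L - w + 1L)
    if (n_v == 0L) next
    p_v <- 1
    for (allowed in v) {
      if (is.null(allowed)) next
      p_v <- p_v * sum(f[allowed])
    }
    p_v <- min(p_v, 1)
    log_none <- log_none + n_v * log1p(-p_v)
  }
  min(max(-expm1(log_none), 0), 1)
}

#' Probability that an Unrelated Protein Cluster contains a motif
#'
#' Aggregates per-sequence occurrence probabilities over the members of one
#' UPC. The default mode `"max"` treats a cluster as its most motif-prone
#' member — conservative under homology, and invariant to adding homolog
#' copies. Mode `"independent"` treats members as independent trials,
#' `1 - prod(1 - p_seq)`.
#'
#' @param m `slim_motif` or pattern string.
#' @param cluster character vector of member accessions.
#' @param masked_seqs named list of `masked_seq` covering the cluster.
#' @param mode `"max"` or `"independent"`.
#' @return probability in `[0, 1]`.
#' @export
upc_probability <- function(m, cluster, masked_seqs,
                            mode = c("max", "independent")) {
  mode <- match.arg(mode)
  stopifnot(length(cluster) >= 1L)
  p <- vapply(cluster, function(a)
    sequence_occurrence_probability(m, masked_seqs[[a]]), 0)
  if (mode == "max") max(p) else min(max(-expm1(sum(log1p(-p))), 0), 1)
}

#' Exact Poisson-binomial tail probabilities
#'
#' Let `X = sum_i Bernoulli(p_i)` count the clusters containing a motif. The
#' full distribution of `X` is computed exactly by dynamic-programming
#' convolution over the clusters, and both inclusive tails are returned.
#'
#' @param probs per-cluster probabilities, each in `[0, 1]`.
#' @param k observed count, `0 <= k <= length(probs)`.
#' @return list with `p_ge` = P(X >= k), `p_le` = P(X <= k), `expected` =
#'   `sum(probs)`, and `dist`, the probability mass of `X = 0..n`.
#' @export
poisson_binomial_tails <- function(probs, k) {
  stopifnot(all(probs >= 0 & probs <= 1), k >= 0, k <= length(probs))
  dist <- 1
  for (p in probs) dist <- c(dist * (1 - p), 0) + c(0, dist * p)
  list(p_ge = sum(dist[(k + 1L):length(dist)]),
       p_le = sum(dist[1L:(k + 1L)]),
       expected = sum(probs),
       dist = dist)
}

#' Search-space-corrected significance
#'
#' Dampens a single-motif tail probability for the size of the motif space
#' the discovery run searched, via the Sidak correction
#' `Sig = 1 - (1 - p)^space`, clamped to `[0, 1]`.
#'
#' @param p single-motif tail probability.
#' @param search_space_size number of motifs in the searched space (>= 1).
#' @return corrected significance in `[0, 1]`.
#' @export
corrected_significance <- function(p, search_space_size) {
  stopifnot(search_space_size >= 1)
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  min(max(-expm1(search_space_size * log1p(-p)), 0), 1)
}

#' Size of the enumerable motif space
#'
#' The number of distinct unambiguous patterns expressible under the
#' enumeration limits: `sum_{k=2}^{max_defined} 20^k * (max_wildcard+1)^(k-1)`
#' (20 residue choices per defined position, and an exact spacer of
#' `0..max_wildcard` wildcards between consecutive defined positions). This is
#' the de novo discovery correction space; query-restricted discovery instead
#' counts the patterns constructible from the query sequence.
#'
#' @param max_defined maximum number of defined positions.
#' @param max_wildcard maximum wildcard spacer length.
#' @return numeric scalar (can exceed integer range).
#' @export
motif_space_size <- function(max_defined = 5L, max_wildcard = 2L) {
  k <- 2:max_defined
  sum(20^k * (max_wildcard + 1)^(k - 1))
}
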