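# Noise-free hard-limit surrogate: responses are exactly R_max times the
# transcoded sequence, the reference fixture for estimator consistency.
hard_spec <- function() surrogate_spec(miss_width = 0, cell_cv = 0, mu0 = 0)

# Brute-force count of binary sequences whose 1s are pairwise more than k
# slots apart (independent oracle for count_fixed_points / transcode).
brute_count_valid <- function(L, k) {
  seqs <- all_sequences(L)
  sum(vapply(seqs, function(s) {
    ones <- which(strsplit(s, "")[[1]] == "1")
    length(ones) < 2 || min(diff(ones)) > k
  }, logical(1)))
}

# Direct evaluation of MI = H(Y) - H(Y|X) for the deterministic transcoding
# channel as a finite double sum over the joint distribution.
brute_mi_deterministic <- function(partition, p) {
  outputs <- unique(partition$representative)
  joint <- outer(
    seq_along(p), seq_along(outputs),
    Vectorize(function(i, j) {
      if (partition$representative[i] == outputs[j]) p[i] else 0
    })
  )
  py <- colSums(joint)
  px <- rowSums(joint)
  terms <- joint * log2(joint / (px %o% py))
  sum(terms[joint > 0])
}
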