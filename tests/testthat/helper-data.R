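# Shared fixture builders (all in code; no data files needed).

chars <- function(s) strsplit(s, "")[[1L]]

`%+%` <- function(a, b) paste0(a, b)

toy_set <- function(seqs, region = "toy", ref_start = 1L, ref_id = NULL) {
  aligned_set(seqs, region_name = region, ref_start = ref_start, ref_id = ref_id)
}

# random gap-free alignment of n sequences, pairwise-divergent from one root
rand_alignment <- function(n, L, seed, mut_rate = 0.05) {
  set.seed(seed)
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- t(vapply(seq_len(n), function(i) {
    s <- root
    k <- stats::rbinom(1L, L, mut_rate)
    if (k > 0) {
      j <- sample.int(L, k)
      s[j] <- vapply(s[j], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
    }
    s
  }, character(L)))
  rownames(m) <- sprintf("t%02d", seq_len(n))
  aligned_set(m, region_name = "sim", ref_start = 1L)
}

# random unrooted tree with comfortably positive branch lengths and its
# additive (patristic) distance matrix
rand_additive_case <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, D = stats::cophenetic(tr))
}
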