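test_that("three taxa give the closed-form star tree", {
  ids <- c("A", "B", "C")
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3, dimnames = list(ids, ids))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), ids)
  bl <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2L])],
                        tr$tip.label)
  # v_A = (dAB + dAC - dBC)/2 = 1, v_B = 2, v_C = 3
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3")
})

test_that("NJ exactly recovers additive matrices", {
  for (seed in 1:10) {
    case <- rand_additive_case(4 + (seed %% 5), seed)
    est <- nj_tree(case$D)
    expect_equal(ape::dist.topo(ape::unroot(case$tree), est),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
    got <- stats::cophenetic(est)[rownames(case$D), colnames(case$D)]
    expect_equal(got, case$D, tolerance = 1e-10)
  }
})

test_that("NJ topology agrees with an established implementation", {
  for (seed in c(21, 22, 23)) {
    s <- rand_alignment(7, 400, seed = seed)
    dm <- k2p_matrix(s)
    mine <- nj_tree(dm)
    ref <- ape::nj(stats::as.dist(unclass(dm)))
    expect_equal(ape::dist.topo(mine, ref), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
  }
})

test_that("exact Q ties break towards the lowest index pair, deterministically", {
  # four equidistant taxa: every Q(i,j) ties; the documented tie-break joins
  # the first pair in current label order
  ids <- c("w", "x", "y", "z")
  D <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  t1 <- nj_tree(D)
  t2 <- nj_tree(D)
  expect_identical(write_newick(t1), write_newick(t2))
  # w and x are joined first: the tree contains the w|x cherry
  pp <- ape::prop.part(t1)
  labs <- attr(pp, "labels")
  cherries <- Filter(function(x) length(x) == 2L,
                     lapply(pp, function(i) sort(labs[i])))
  expect_true(list(c("w", "x")) %in% cherries)
})

test_that("NJ handles the degenerate all-zero matrix", {
  ids <- c("a", "b", "c", "d")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), ids)
  expect_true(all(tr$edge.length == 0))
})

test_that("negative branch lengths are clamped with the deficit moved over", {
  # a non-additive matrix known to produce a negative NJ branch
  ids <- c("a", "b", "c", "d")
  D <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.45, 0.4,
                0.4, 0.45, 0, 0.05,
                0.45, 0.4, 0.05, 0), 4, 4, dimnames = list(ids, ids))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_true(!is.null(attr(tr, "raw_joins")))
})

test_that("Newick writing round-trips topology, lengths and supports", {
  case <- rand_additive_case(6, 99)
  tr <- nj_tree(case$D)
  tr$node.label <- c("", as.character(seq_len(tr$Nnode - 1L) * 10))
  nwk <- write_newick(tr)
  expect_match(nwk, ";$")
  back <- read_newick(nwk)
  expect_equal(ape::dist.topo(tr, back), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  o <- order(tr$tip.label)
  ob <- order(back$tip.label)
  d_tr <- stats::cophenetic(tr); d_back <- stats::cophenetic(back)
  expect_equal(d_back[rownames(d_tr), colnames(d_tr)], d_tr, tolerance = 1e-5)
  expect_setequal(setdiff(back$node.label, ""), setdiff(tr$node.label, ""))

  # zero-length clamped edges are written explicitly
  ids <- c("a", "b", "c")
  D0 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  expect_match(write_newick(nj_tree(D0)), ":0.000000")

  # file round-trip
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_equal(ape::dist.topo(read_newick(path), tr),
               structure(0, names = "PH85"), ignore_attr = TRUE)
})

test_that("bootstrap supports are percentages attached to original splits", {
  fx <- mangalitsa_like_fixture()
  both <- concatenate_alignments(fx$dloop, fx$cytb)
  cat_ <- collapse_haplotypes(both, fx$pops)
  reps <- vapply(cat_$entries$members, `[[`, character(1), 1L)
  sub <- aligned_set(unclass(both)[reps, ], "concat", 15455L)
  rownames(sub) <- cat_$entries$haplotype_id[match(reps, reps)]

  bs1 <- bootstrap_support(sub, B = 1L, seed = 7L)
  expect_true(all(bs1$support %in% c(0, 100)))

  bs <- bootstrap_support(sub, B = 30L, seed = 7L)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  expect_equal(bs$B_used, 30L)
})

test_that("supports are leaf-order invariant on well-separated data", {
  # deep pairwise divergence keeps every replicate free of exact Q ties, so
  # the permutation equivariance of NJ carries over to the support values
  s <- rand_alignment(6, 500, seed = 31, mut_rate = 0.12)
  bs <- bootstrap_support(s, B = 25L, seed = 9L)
  set.seed(1)
  perm <- sample(rownames(s))
  bs2 <- bootstrap_support(aligned_set(unclass(s)[perm, ], "sim", 1L),
                           B = 25L, seed = 9L)
  expect_setequal(names(bs2$support), names(bs$support))
  expect_equal(bs2$support[names(bs$support)], bs$support)
})

test_that("outgroup rooting bisects the pendant edge and keeps supports", {
  fx <- mangalitsa_like_fixture()
  both <- concatenate_alignments(fx$dloop, fx$cytb)
  ids <- c("MangalitsaRO_01", "MangalitsaRO_14", "MangalitsaRO_27",
           "WildBoarRO_01", "AsianPanel_01", "AsianPanel_09", "Warthog")
  sub <- aligned_set(unclass(both)[ids, ], "concat", 15455L)
  bs <- bootstrap_support(sub, B = 20L, seed = 3L)
  un <- bs$tree
  rooted <- root_with_outgroup(un, "Warthog")
  expect_true(ape::is.rooted(rooted))
  root_node <- length(rooted$tip.label) + 1L
  expect_equal(sum(rooted$edge[, 1L] == root_node), 2L)

  # the two root edges are equal halves of the outgroup pendant edge
  re <- which(rooted$edge[, 1L] == root_node)
  expect_equal(rooted$edge.length[re[1L]], rooted$edge.length[re[2L]])

  # rooting preserves the bipartition set (rooting is split-invariant)
  expect_setequal(mtphylo:::tree_splits(rooted), mtphylo:::tree_splits(un))

  # supports survive rerooting, matched by split
  skey_un <- mtphylo:::tree_split_keys_by_node(un)
  skey_ro <- mtphylo:::tree_split_keys_by_node(rooted)
  for (k in seq_along(skey_ro)) {
    if (is.na(skey_ro[k]) || rooted$node.label[k] == "") next
    j <- match(skey_ro[k], skey_un)
    if (!is.na(j)) expect_equal(rooted$node.label[k], un$node.label[j])
  }

  expect_error(root_with_outgroup(un, "nope"), "not a tip")

  # ingroup monophyly with a planted outgroup: the rooted tree has a clade
  # containing every ingroup tip
  ingroup <- setdiff(rooted$tip.label, "Warthog")
  pp <- ape::prop.part(rooted)
  labs <- attr(pp, "labels")
  clades <- lapply(pp, function(i) sort(labs[i]))
  expect_true(list(sort(ingroup)) %in% clades)
})
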