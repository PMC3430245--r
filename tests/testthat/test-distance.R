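test_that("K2P evaluates the closed form and flags saturation", {
  a <- chars("ACGTACGTAC")
  r0 <- k2p(a, a)
  expect_equal(r0$distance, 0)
  expect_equal(r0$P, 0)
  expect_equal(r0$Q, 0)

  # independent re-derivation: -1/2 log(0.5) - 1/4 log(0.8)
  expect_equal(k2p_from_pq(0.2, 0.1), -0.5 * log(0.5) - 0.25 * log(0.8))
  expect_equal(round(k2p_from_pq(0.2, 0.1), 5), 0.40236)

  expect_error(k2p_from_pq(0.45, 0.1), "saturation")
  expect_error(k2p_from_pq(0.1, 0.5), "saturation")

  # counted proportions: 2 transitions + 1 transversion over 10 sites
  b <- chars("GCGTATGTAA")   # A->G ti (pos1), C->T ti (pos5), C->A tv (pos10)
  r <- k2p(a, b)
  expect_equal(r$P, 0.2)
  expect_equal(r$Q, 0.1)
  expect_equal(r$valid_sites, 10L)
  expect_equal(r$distance, k2p_from_pq(0.2, 0.1))
})

test_that("pairwise deletion drops gap and N columns per pair", {
  r <- k2p(chars("ACGTACGT-C"), chars("ACGTNCGTAC"))
  expect_equal(r$valid_sites, 8L)
  expect_equal(r$distance, 0)
  expect_error(k2p(chars("NNNN"), chars("ACGT")), "no valid")
})

test_that("K2P dominates the uncorrected proportion and respects symmetry", {
  set.seed(1)
  n_ok <- 0L
  for (i in 1:1000) {
    P <- stats::runif(1, 0, 0.5); Q <- stats::runif(1, 0, 0.5)
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
      expect_error(k2p_from_pq(P, Q), "saturation")
    } else {
      d <- k2p_from_pq(P, Q)
      expect_gte(d, P + Q)
      n_ok <- n_ok + 1L
    }
  }
  expect_gt(n_ok, 500L)   # the valid region dominates the draw

  # equality only at P = Q = 0
  expect_equal(k2p_from_pq(0, 0), 0)

  # complement invariance: A<->T, C<->G preserves ti/tv classes
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s1 <- chars("ACGTACGTACGTACGTACGT")
  s2 <- chars("GCGTATGTAAGTACGCACTT")
  expect_equal(k2p(unname(comp[s1]), unname(comp[s2]))$distance,
               k2p(s1, s2)$distance)
})

test_that("K2P with Q = 0 reduces to the two-state form", {
  expect_equal(k2p_from_pq(0.2, 0), -0.5 * log(1 - 2 * 0.2))
})

test_that("distance matrices agree with an established implementation", {
  s <- rand_alignment(8, 500, seed = 3)
  dm <- k2p_matrix(s)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(apply(unclass(s), 2, tolower)),
                                 model = "K80", pairwise.deletion = TRUE))
  expect_equal(unclass(dm)[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-10, ignore_attr = TRUE)

  # permutation invariance
  perm <- sample(rownames(s))
  dm2 <- k2p_matrix(aligned_set(unclass(s)[perm, ], "sim", 1L))
  expect_equal(unclass(dm2)[rownames(dm), colnames(dm)], unclass(dm)[, ],
               ignore_attr = TRUE)
})

test_that("saturated pairs abort with the pair named", {
  m <- rbind(x = chars("AGAGAGAGAG"), y = chars("GAGAGAGAGA"))
  expect_error(k2p_matrix(aligned_set(m, "sat", 1L)), "x / y")
})

test_that("net between-group distance follows Nei's decomposition", {
  # two singleton groups at distance d: K = d
  dm <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  pops <- population_assignment(c("a", "b"), c("A", "B"), c("X", "Y"))
  gd <- net_between_group(dm, pops, "X", "Y")
  expect_equal(gd$K, 0.4)
  expect_equal(gd$d_x, 0)

  # identical duplicated groups: K = 0
  ids <- c("a1", "a2", "b1", "b2")
  dm2 <- matrix(0.3, 4, 4, dimnames = list(ids, ids)); diag(dm2) <- 0
  pops2 <- population_assignment(ids, ids, c("X", "X", "Y", "Y"))
  expect_equal(net_between_group(dm2, pops2, "X", "Y")$K, 0)

  # 2+2 toy with hand-computed means
  dm3 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  dm3["a1", "a2"] <- dm3["a2", "a1"] <- 0.02
  dm3["b1", "b2"] <- dm3["b2", "b1"] <- 0.04
  cross <- rbind(c("a1", "b1"), c("a1", "b2"), c("a2", "b1"), c("a2", "b2"))
  vals <- c(0.10, 0.12, 0.11, 0.13)
  for (k in 1:4) dm3[cross[k, 1], cross[k, 2]] <- dm3[cross[k, 2], cross[k, 1]] <- vals[k]
  gd3 <- net_between_group(dm3, pops2, "X", "Y")
  expect_equal(gd3$d_xy, mean(vals))
  expect_equal(gd3$K, mean(vals) - (0.02 + 0.04) / 2)

  expect_error(net_between_group(dm3, pops2, "X", "Z"), "no members")

  # K <= d_xy always
  expect_lte(gd3$K, gd3$d_xy)
})

test_that("K is unchanged under mean-preserving member duplication", {
  ids <- c("a1", "a2", "b1")
  dm <- matrix(c(0, .02, .1, .02, 0, .12, .1, .12, 0), 3, 3,
               dimnames = list(ids, ids))
  pops <- population_assignment(ids, ids, c("X", "X", "Y"))
  k0 <- net_between_group(dm, pops, "X", "Y")$K
  # duplicate b1 as b2 at distance 0 from b1: within-Y mean becomes 0 but
  # cross mean unchanged; instead duplicate preserving both means by
  # replicating the whole group Y's distance profile
  ids2 <- c(ids, "b2")
  dm2 <- rbind(cbind(dm, b2 = dm[, "b1"]), b2 = c(dm["b1", ], 0))
  dimnames(dm2) <- list(ids2, ids2)
  pops2 <- population_assignment(ids2, ids2, c("X", "X", "Y", "Y"))
  gd2 <- net_between_group(dm2, pops2, "X", "Y")
  expect_equal(gd2$d_xy, mean(dm[c("a1", "a2"), "b1"]))  # cross mean preserved
  expect_equal(gd2$K, k0 - 0)   # within-Y mean now 0 (b1 == b2): K unchanged
})

test_that("site-bootstrap SE of K is reproducible and well-scaled", {
  cfg <- generator_config(seed = 77L, divergence = 0.03,
                          populations = list(
                            list(name = "P1", clade = "X", hap_ids = 1:2,
                                 counts = c(5L, 5L)),
                            list(name = "P2", clade = "Y", hap_ids = 1:2,
                                 counts = c(5L, 5L))))
  d <- generate_dataset(cfg)
  both <- concatenate_alignments(d$dloop, d$cytb)
  gd1 <- net_between_group_boot(both, d$pops, "X", "Y", B = 50L, seed = 4L)
  gd2 <- net_between_group_boot(both, d$pops, "X", "Y", B = 50L, seed = 4L)
  expect_equal(gd1$sd, gd2$sd)
  expect_gt(gd1$sd, 0)
  expect_lt(gd1$sd, 0.05)
  expect_equal(gd1$K, net_between_group(k2p_matrix(both), d$pops, "X", "Y")$K)
})
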