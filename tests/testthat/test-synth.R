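test_that("generation is byte-identical under a fixed seed", {
  d1 <- generate_dataset(generator_config(seed = 33L))
  d2 <- generate_dataset(generator_config(seed = 33L))
  expect_identical(unclass(d1$dloop)[, ], unclass(d2$dloop)[, ])
  expect_identical(unclass(d1$cytb)[, ], unclass(d2$cytb)[, ])
  expect_identical(d1$pops, d2$pops)
  expect_identical(d1$truth$assignment, d2$truth$assignment)
  d3 <- generate_dataset(generator_config(seed = 34L))
  expect_false(identical(unclass(d1$dloop)[, ], unclass(d3$dloop)[, ]))
})

test_that("zero divergence and single haplotypes give identical sequences", {
  cfg <- generator_config(seed = 2L, divergence = 0, mut_per_hap = 0L,
                          indel_prob = 0,
                          populations = list(
                            list(name = "P1", clade = "X", hap_ids = 1L,
                                 counts = 5L),
                            list(name = "P2", clade = "Y", hap_ids = 1L,
                                 counts = 5L)))
  d <- generate_dataset(cfg)
  both <- concatenate_alignments(d$dloop, d$cytb)
  ingroup <- d$pops$id[d$pops$clade %in% c("X", "Y")]
  sub <- aligned_set(unclass(both)[ingroup, ], "concat", 1L)
  expect_equal(nrow(collapse_haplotypes(sub)$entries), 1L)
  expect_equal(nrow(find_variable_sites(sub)), 0L)
})

test_that("realised ancestor divergence sits within binomial bounds", {
  for (seed in c(3L, 4L, 5L)) {
    div <- 0.04
    cfg <- generator_config(seed = seed, divergence = div)
    d <- generate_dataset(cfg)
    L <- cfg$L_dloop + cfg$L_cytb
    # expected differing-site proportion for a total branch of `div`
    # expected substitutions/site under the generating process
    p <- mtphylo:::k2p_change_probs(div, cfg$kappa)
    p_diff <- p[["ti"]] + 2 * p[["tv"]]
    se <- sqrt(p_diff * (1 - p_diff) / L)
    expect_lt(abs(d$truth$realized_ancestor_divergence - p_diff),
              3 * se + 2 / L)   # stop-rejection in cytb nudges a few sites
  }
})

test_that("the planted haplotype partition matches the collapsed catalog", {
  d <- generate_dataset(generator_config(seed = 8L))
  if (!d$truth$back_mutation) {
    both <- concatenate_alignments(d$dloop, d$cytb)
    ingroup <- d$pops$id[!(d$pops$clade %in% c("Outgroup", "Unassigned"))]
    sub <- aligned_set(unclass(both)[ingroup, ], "concat", 1L)
    cat_ <- collapse_haplotypes(sub)
    truth_part <- split(names(d$truth$assignment[ingroup]),
                        d$truth$assignment[ingroup])
    got_part <- cat_$entries$members
    expect_equal(length(got_part), length(truth_part))
    norm <- function(p) sort(vapply(p, function(x) paste(sort(x), collapse = ","),
                                    character(1)))
    expect_equal(unname(norm(got_part)), unname(norm(truth_part)))
  }
})

test_that("per-population mutation truth predicts the observed Eta", {
  d <- generate_dataset(generator_config(seed = 13L))
  if (!d$truth$back_mutation && is.null(d$truth$deletion)) {
    both <- concatenate_alignments(d$dloop, d$cytb)
    ids <- d$pops$id[d$pops$population == "MangalitsaRO"]
    sub <- aligned_set(unclass(both)[ids, ], "concat", 1L)
    expect_equal(count_mutations(sub)$Eta,
                 unname(d$truth$per_population_mutations[["MangalitsaRO"]]))
  }
  # the default design plants 3 derived haplotypes x 2 mutations
  expect_equal(unname(d$truth$per_population_mutations[["MangalitsaRO"]]), 6L)
})

test_that("cytochrome b is generated and mutated in frame without stops", {
  d <- generate_dataset(generator_config(seed = 21L))
  stops <- c("TAA", "TAG", "AGA", "AGG")
  for (id in rownames(d$cytb)) {
    s <- unclass(d$cytb)[id, ]
    if (any(s == "-")) next
    cods <- apply(matrix(s, nrow = 3), 2, paste, collapse = "")
    expect_false(any(cods %in% stops))
  }
})

test_that("the deletion is planted as a single D-loop gap column", {
  d <- generate_dataset(generator_config(seed = 44L, indel_prob = 1))
  expect_false(is.null(d$truth$deletion))
  gaps <- which(unclass(d$dloop) == "-", arr.ind = TRUE)
  expect_equal(unique(unname(gaps[, "col"])), d$truth$deletion$column)
  expect_equal(d$truth$deletion$ref_position,
               15455L + d$truth$deletion$column - 1L)
  d0 <- generate_dataset(generator_config(seed = 44L, indel_prob = 0))
  expect_true(is.null(d0$truth$deletion))
  expect_false(any(unclass(d0$dloop) == "-"))
})

test_that("the bundled fixture has the documented shape", {
  fx <- mangalitsa_like_fixture()
  both <- concatenate_alignments(fx$dloop, fx$cytb)
  cat_ <- collapse_haplotypes(both, fx$pops)
  counts <- cat_$per_population_counts
  expect_equal(sum(counts["MangalitsaRO", ] > 0), 4)
  expect_equal(sort(counts["MangalitsaRO", counts["MangalitsaRO", ] > 0],
                    decreasing = TRUE), c(13, 13, 12, 7), ignore_attr = TRUE)
  expect_equal(sum(counts["WildBoarRO", ] > 0), 1)
  # one Mangalitsa haplotype is shared with the second population
  shared <- colnames(counts)[counts["MangalitsaRO", ] > 0 &
                             counts["MangalitsaHU", ] > 0]
  expect_equal(length(shared), 1L)
  expect_equal(round(haplotype_diversity(c(13L, 13L, 12L, 7L)), 3), 0.755)
  # deterministic across calls
  fx2 <- mangalitsa_like_fixture()
  expect_identical(unclass(fx$dloop)[, ], unclass(fx2$dloop)[, ])
})

test_that("dataset writing emits files the package's own readers parse", {
  d <- generate_dataset(generator_config(seed = 6L))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  dl <- read_alignment(file.path(dir, "dloop.fasta"), "dloop", 15455L)
  expect_identical(unclass(dl)[, ], unclass(d$dloop)[, ])
  pm <- read_population_map(file.path(dir, "population_map.tsv"))
  expect_equal(nrow(pm), nrow(d$pops))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$seed, 6L)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(kappa = 0), "kappa")
  expect_error(generator_config(L_cytb = 100L), "divisible")
  expect_error(generator_config(populations = list(
    list(name = "A", clade = "X", hap_ids = 1:2, counts = 3L))), "mismatch")
  expect_error(generator_config(populations = list(
    list(name = "A", clade = "X", hap_ids = 1L, counts = 3L))), "two ingroup")
})
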