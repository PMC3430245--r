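#' Configuration for the two-clade mtDNA simulator
#'
#' The generator emulates the structure of a small swine mtDNA panel: a
#' D-loop block and an in-frame cytochrome b block, two clades of haplotypes
#' separated by a tunable net divergence, within-clade haplotype sharing
#' across populations, transition-biased substitution, a rare single-column
#' deletion, an outgroup, and a gap-free reference row used for numbering.
#'
#' Defaults mirror the study design the package is built around: a
#' 45-animal population carrying four haplotypes at counts 13/13/12/7, a
#' singleton population sharing one of those haplotypes, a 15-animal wild
#' boar population fixed for its own haplotype, a 15-animal opposite-clade
#' panel, a 613-column D-loop block anchored at reference position 15,455
#' and a 1,140-bp cytochrome b gene. The transition/transversion rate ratio
#' `kappa = 15` reproduces the roughly 7.5:1 transition:transversion count
#' ratio typical of such panels, and the default net between-clade
#' divergence of 0.03 substitutions/site sits in the range observed between
#' European and Asian swine mtDNA.
#'
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @param populations List of population descriptors, each a list with
#'   `name`, `clade`, `hap_ids` (indices into the clade's haplotype pool)
#'   and `counts` (individuals per haplotype, parallel to `hap_ids`).
#' @param L_dloop,L_cytb Region lengths; `L_cytb` must be divisible by 3.
#' @param ref_start_dloop Reference position of the first D-loop column.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param divergence Expected substitutions/site separating the two clade
#'   ancestors (each clade evolves `divergence/2` from the root).
#' @param mut_per_hap Substitutions separating each non-founder haplotype
#'   from its clade ancestor (haplotype 1 of each pool is the ancestor).
#' @param indel_prob Probability that the dataset carries one single-column
#'   deletion in the D-loop of one haplotype (default 1: exactly one, the
#'   typical situation in such panels).
#' @param outgroup_divergence Expected substitutions/site from the root to
#'   the outgroup.
#' @param outgroup_name,reference_name Labels; set `reference_name = NULL`
#'   to omit the reference row.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             populations = list(
                               list(name = "MangalitsaRO", clade = "European",
                                    hap_ids = 1:4, counts = c(13L, 13L, 12L, 7L)),
                               list(name = "MangalitsaHU", clade = "European",
                                    hap_ids = 2L, counts = 1L),
                               list(name = "WildBoarRO", clade = "European",
                                    hap_ids = 5L, counts = 15L),
                               list(name = "AsianPanel", clade = "Asian",
                                    hap_ids = 1:3, counts = c(8L, 4L, 3L))),
                             L_dloop = 613L, L_cytb = 1140L,
                             ref_start_dloop = 15455L,
                             kappa = 15, divergence = 0.03,
                             mut_per_hap = 2L, indel_prob = 1,
                             outgroup_divergence = 0.15,
                             outgroup_name = "Warthog",
                             reference_name = "REF") {
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (L_dloop < 1L || L_cytb < 3L) stop("region lengths too small", call. = FALSE)
  if (L_cytb %% 3L != 0L) stop("L_cytb must be divisible by 3", call. = FALSE)
  if (divergence < 0 || outgroup_divergence < 0)
    stop("divergences must be >= 0", call. = FALSE)
  for (p in populations) {
    if (length(p$hap_ids) != length(p$counts) || any(p$counts < 0))
      stop("population '", p$name, "': hap_ids and counts mismatch", call. = FALSE)
  }
  clades <- unique(vapply(populations, `[[`, character(1), "clade"))
  if (length(clades) != 2L)
    stop("exactly two ingroup clades are required, got: ",
         paste(clades, collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), populations = populations,
                 L_dloop = as.integer(L_dloop), L_cytb = as.integer(L_cytb),
                 ref_start_dloop = as.integer(ref_start_dloop),
                 kappa = kappa, divergence = divergence,
                 mut_per_hap = as.integer(mut_per_hap),
                 indel_prob = indel_prob,
                 outgroup_divergence = outgroup_divergence,
                 outgroup_name = outgroup_name,
                 reference_name = reference_name),
            class = "generator_config")
}

# K2P transition probabilities for branch length d (expected subst/site)
# with rate ratio kappa; rates normalised so alpha + 2 beta = 1.
k2p_change_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  p_ti <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * d)   # each of the two transversions
  c(ti = p_ti, tv = p_tv)
}

TI_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

# Evolve a character vector along a branch of expected length d under the
# K2P process; returns the new sequence.
evolve_k2p <- function(seq, d, kappa) {
  p <- k2p_change_probs(d, kappa)
  u <- stats::runif(length(seq))
  out <- seq
  ti <- u < p[["ti"]]
  tv1 <- !ti & u < p[["ti"]] + p[["tv"]]
  tv2 <- !ti & !tv1 & u < p[["ti"]] + 2 * p[["tv"]]
  out[ti] <- TI_PARTNER[seq[ti]]
  out[tv1] <- vapply(seq[tv1], function(x) TV_PARTNERS[[x]][1L], character(1))
  out[tv2] <- vapply(seq[tv2], function(x) TV_PARTNERS[[x]][2L], character(1))
  out
}

MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

# Revert any codon that a mutation batch turned into a stop (vertebrate
# mitochondrial code): in-frame evolution by rejection.
fix_stops <- function(new, old) {
  nc <- length(new) / 3L
  for (ci in seq_len(nc)) {
    idx <- (3L * ci - 2L):(3L * ci)
    if (paste(new[idx], collapse = "") %in% MITO_STOPS) new[idx] <- old[idx]
  }
  new
}

random_inframe_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  ok <- setdiff(all_codons, MITO_STOPS)
  unlist(strsplit(sample(ok, n_codons, replace = TRUE), ""))
}

# Apply k point substitutions at k distinct columns of the concatenated
# sequence, transition-biased; returns list(seq, events).
apply_point_mutations <- function(seq, k, kappa, L_dloop) {
  if (k == 0L) return(list(seq = seq, events = NULL))
  cols <- sample.int(length(seq), k)
  p_ti <- kappa / (kappa + 2)
  events <- vector("list", k)
  for (e in seq_len(k)) {
    j <- cols[e]
    from <- seq[j]
    if (stats::runif(1) < p_ti) {
      to <- TI_PARTNER[[from]]; cls <- "transition"
    } else {
      to <- sample(TV_PARTNERS[[from]], 1L); cls <- "transversion"
    }
    seq[j] <- to
    events[[e]] <- data.frame(column = j,
                              region = if (j <= L_dloop) "dloop" else "cytb",
                              from = from, to = to, class = cls,
                              stringsAsFactors = FALSE)
  }
  list(seq = seq, events = do.call(rbind, events))
}

#' Generate a synthetic two-clade mtDNA dataset
#'
#' Draws a uniform-random ancestral sequence (cytochrome b in frame, free of
#' stop codons), evolves each clade ancestor `divergence/2` expected
#' substitutions/site from the root under the K2P process, derives the
#' within-clade haplotype pools by a fixed number of transition-biased point
#' mutations, samples individuals according to the configured haplotype
#' counts, evolves an outgroup from the root, and optionally plants a
#' single-column deletion. The output is deterministic given the
#' configuration (including its seed).
#'
#' @param config A [generator_config()].
#' @return A list with `dloop` and `cytb` (`aligned_set` objects), `pops`
#'   (population assignment data frame) and `truth` (a list recording the
#'   planted haplotypes, mutation events with classes, the configured and
#'   realised between-ancestor divergence, the deletion if any, per-population
#'   mutation counts, and whether any column was hit more than once).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  L <- config$L_dloop + config$L_cytb
  root <- c(sample(c("A", "C", "G", "T"), config$L_dloop, replace = TRUE),
            random_inframe_cds(config$L_cytb / 3L))

  clades <- unique(vapply(config$populations, `[[`, character(1), "clade"))
  anc <- list()
  for (cl in clades) {
    s <- evolve_k2p(root, config$divergence / 2, config$kappa)
    s[(config$L_dloop + 1L):L] <-
      fix_stops(s[(config$L_dloop + 1L):L], root[(config$L_dloop + 1L):L])
    anc[[cl]] <- s
  }
  realized <- mean(anc[[clades[1L]]] != anc[[clades[2L]]])

  # clade haplotype pools: hap 1 is the clade ancestor, the rest carry
  # mut_per_hap private substitutions; identical planted haplotypes are
  # redrawn (with a warning) up to 20 times
  pool_ids <- lapply(clades, function(cl) {
    sort(unique(unlist(lapply(config$populations,
                              function(p) if (p$clade == cl) p$hap_ids))))
  })
  names(pool_ids) <- clades
  pools <- list()
  events <- list()
  for (cl in clades) {
    pool <- list()
    for (h in pool_ids[[cl]]) {
      if (h == 1L) { pool[["1"]] <- anc[[cl]]; next }
      for (attempt in 1:20) {
        m <- apply_point_mutations(anc[[cl]], config$mut_per_hap,
                                   config$kappa, config$L_dloop)
        s <- m$seq
        s[(config$L_dloop + 1L):L] <-
          fix_stops(s[(config$L_dloop + 1L):L],
                    anc[[cl]][(config$L_dloop + 1L):L])
        dup <- any(vapply(pool, identical, logical(1), y = s))
        if (!dup) break
        warning("planted haplotype collision in clade ", cl,
                "; redrawing", call. = FALSE)
      }
      pool[[as.character(h)]] <- s
      if (!is.null(m$events)) {
        m$events$clade <- cl; m$events$haplotype <- h
        events[[length(events) + 1L]] <- m$events
      }
    }
    pools[[cl]] <- pool
  }

  # optional single-column D-loop deletion in one non-ancestor haplotype
  deletion <- NULL
  if (stats::runif(1) < config$indel_prob) {
    cl <- sample(clades, 1L)
    hs <- names(pools[[cl]])
    h <- if (length(hs) > 1L) sample(hs[-1L], 1L) else hs
    j <- sample.int(config$L_dloop, 1L)
    pools[[cl]][[h]][j] <- "-"
    deletion <- data.frame(clade = cl, haplotype = as.integer(h), column = j,
                           ref_position = config$ref_start_dloop + j - 1L,
                           stringsAsFactors = FALSE)
  }

  outg <- evolve_k2p(root, config$outgroup_divergence, config$kappa)
  outg[(config$L_dloop + 1L):L] <-
    fix_stops(outg[(config$L_dloop + 1L):L], root[(config$L_dloop + 1L):L])

  ids <- character(0); pop <- character(0); clade <- character(0)
  rows <- list()
  hap_of <- character(0)
  for (p in config$populations) {
    k <- 0L
    for (hi in seq_along(p$hap_ids)) {
      h <- p$hap_ids[hi]
      for (rep_ in seq_len(p$counts[hi])) {
        k <- k + 1L
        id <- sprintf("%s_%02d", p$name, k)
        ids <- c(ids, id); pop <- c(pop, p$name); clade <- c(clade, p$clade)
        rows[[id]] <- pools[[p$clade]][[as.character(h)]]
        hap_of <- c(hap_of, sprintf("%s_h%d", p$clade, h))
      }
    }
  }
  ids <- c(ids, config$outgroup_name)
  pop <- c(pop, config$outgroup_name)
  clade <- c(clade, "Outgroup")
  rows[[config$outgroup_name]] <- outg
  hap_of <- c(hap_of, "outgroup")
  if (!is.null(config$reference_name)) {
    ids <- c(ids, config$reference_name)
    pop <- c(pop, "Reference")
    clade <- c(clade, "Unassigned")
    rows[[config$reference_name]] <- root
    hap_of <- c(hap_of, "reference")
  }

  m <- do.call(rbind, rows)
  rownames(m) <- ids
  dloop <- aligned_set(m[, seq_len(config$L_dloop), drop = FALSE],
                       region_name = "dloop",
                       ref_start = config$ref_start_dloop,
                       ref_id = config$reference_name)
  cytb <- aligned_set(m[, (config$L_dloop + 1L):L, drop = FALSE],
                      region_name = "cytb", ref_start = 1L,
                      ref_id = config$reference_name)
  pops <- population_assignment(ids, pop, clade)

  ev <- if (length(events)) do.call(rbind, events) else NULL
  hit_cols <- c(which(root != anc[[clades[1L]]]), which(root != anc[[clades[2L]]]),
                if (!is.null(ev)) ev$column)
  truth <- list(
    haplotype_pools = lapply(pools, function(pl)
      vapply(pl, paste, character(1), collapse = "")),
    assignment = stats::setNames(hap_of, ids),
    configured_divergence = config$divergence,
    realized_ancestor_divergence = realized,
    mutation_events = ev,
    deletion = deletion,
    per_population_mutations = stats::setNames(
      vapply(config$populations, function(p) {
        if (is.null(ev)) return(0L)
        sum(ev$clade == p$clade & ev$haplotype %in% p$hap_ids[p$counts > 0])
      }, integer(1)),
      vapply(config$populations, `[[`, character(1), "name")),
    back_mutation = anyDuplicated(hit_cols) > 0L,
    seed = config$seed)

  list(dloop = dloop, cytb = cytb, pops = pops, truth = truth)
}

#' Deterministic bundled example dataset
#'
#' A fixed-seed instance of [generate_dataset()] with the default
#' configuration: 45 ingroup animals carrying four haplotypes at counts
#' 13/13/12/7 (one shared with a second population), a 15-animal wild boar
#' population fixed for a single haplotype, an opposite-clade panel, an
#' outgroup, and a reference row — the shape of a typical primitive-breed
#' mtDNA survey. Regenerated on demand; byte-stable across calls.
#'
#' @return See [generate_dataset()].
#' @export
mangalitsa_like_fixture <- function() {
  generate_dataset(generator_config(seed = 20120709L %% 2147483647L))
}

#' Write generator output to disk
#'
#' Emits the two region FASTA files, the tab-separated population map and
#' the truth record (YAML).
#'
#' @param data A list from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(data$dloop, file.path(dir, "dloop.fasta"))
  write_alignment(data$cytb, file.path(dir, "cytb.fasta"))
  utils::write.table(data$pops, file.path(dir, "population_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  truth <- data$truth
  truth$mutation_events <- if (!is.null(truth$mutation_events))
    as.list(truth$mutation_events) else NULL
  truth$deletion <- if (!is.null(truth$deletion)) as.list(truth$deletion) else NULL
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
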