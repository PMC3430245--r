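#' Haplotype (gene) diversity
#'
#' Nei's unbiased haplotype diversity: the probability that two sequences
#' drawn at random carry different haplotypes, with the small-sample
#' correction `n/(n-1)`:
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` where `p_i` are haplotype frequencies.
#'
#' @param counts Integer vector of haplotype counts.
#' @param n Sample size; defaults to `sum(counts)`.
#' @return `Hd` in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  if (n < 2L) stop("haplotype diversity needs n >= 2", call. = FALSE)
  if (sum(counts) != n) stop("counts must sum to n", call. = FALSE)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity (pi)
#'
#' Mean proportion of differing sites over all unordered sequence pairs,
#' with pairwise deletion: for each pair, only columns where both sequences
#' have a base in `A, C, G, T` are compared (gaps and `N` are skipped).
#'
#' @param set An `aligned_set` with at least two sequences.
#' @return Per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(set) {
  n <- nrow(set)
  if (n < 2L) stop("nucleotide diversity needs >= 2 sequences", call. = FALSE)
  base <- set %in% c("A", "C", "G", "T")
  dim(base) <- dim(set)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- base[i, ] & base[j, ]
    L <- sum(ok)
    if (L == 0L) stop("pair ", rownames(set)[i], "/", rownames(set)[j],
                      " shares no valid sites", call. = FALSE)
    tot <- tot + sum(set[i, ok] != set[j, ok]) / L
  }
  tot / (n * (n - 1L) / 2)
}

#' Count mutations (Eta) and segregating sites (S)
#'
#' `S` is the number of variable columns; `Eta` counts each extra state at a
#' column separately, so a column with three observed bases contributes two
#' mutations. `N` is missing. Columns whose variability involves the gap
#' character are excluded by default (the indel is reported as a site
#' elsewhere but kept out of the substitution-based estimators); set
#' `include_indels = TRUE` to count gap states too.
#'
#' @param set An `aligned_set`.
#' @param include_indels Count gap states as mutations (default `FALSE`).
#' @return A list with `Eta`, `S` and `L` (columns usable for per-site
#'   scaling: non-indel columns under the default).
#' @export
count_mutations <- function(set, include_indels = FALSE) {
  Eta <- 0L; S <- 0L; L <- 0L
  for (j in seq_len(ncol(set))) {
    col <- set[, j]
    col <- col[col != "N"]
    states <- unique(col)
    has_gap <- "-" %in% states
    if (!include_indels) {
      if (has_gap && length(setdiff(states, "-")) <= 1L) {
        # indel-only column: skipped entirely
        next
      }
      states <- setdiff(states, "-")
      if (has_gap) {
        # mixed column: substitution states still counted, site length kept
      }
    }
    L <- L + 1L
    if (length(states) >= 2L) {
      S <- S + 1L
      Eta <- Eta + (length(states) - 1L)
    }
  }
  list(Eta = Eta, S = S, L = L)
}

#' Watterson's theta from the number of mutations
#'
#' `theta_seq = Eta / a_n` with `a_n = sum_{i=1}^{n-1} 1/i` (the harmonic
#' number of `n - 1`), and `theta_site = theta_seq / L`. Using Eta (total
#' mutations) rather than S follows the finite-sites convention of standard
#' polymorphism software.
#'
#' @param Eta Total number of mutations (>= 0).
#' @param n Sample size (>= 2).
#' @param L Number of sites used for the per-site value.
#' @return A list with `theta_seq` and `theta_site`.
#' @export
watterson_theta <- function(Eta, n, L) {
  if (n < 2L) stop("watterson_theta needs n >= 2", call. = FALSE)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (Eta < 0) stop("Eta must be >= 0", call. = FALSE)
  a_n <- sum(1 / seq_len(n - 1L))
  theta_seq <- Eta / a_n
  list(theta_seq = theta_seq, theta_site = theta_seq / L)
}

#' Per-population diversity statistics
#'
#' Computes, for each population with at least two members, the haplotype
#' count `k`, haplotype diversity `Hd`, nucleotide diversity `Pi`, mutation
#' count `Eta`, segregating sites `S` and Watterson's theta per sequence and
#' per site.
#'
#' @param set An `aligned_set`.
#' @param pops Population assignment data frame; `NULL` treats the whole set
#'   as one population `"All"`.
#' @param include_indels Passed to [count_mutations()].
#' @return A data frame with one row per population and columns
#'   `population`, `n`, `k`, `Hd`, `Pi`, `Eta`, `S`, `theta_seq`,
#'   `theta_site`, `L`.
#' @export
diversity_stats <- function(set, pops = NULL, include_indels = FALSE) {
  pop_of <- if (is.null(pops)) {
    stats::setNames(rep("All", nrow(set)), rownames(set))
  } else assignment_for(pops, rownames(set), "population")
  rows <- lapply(unique(pop_of), function(p) {
    ids <- names(pop_of)[pop_of == p]
    if (length(ids) < 2L) return(NULL)
    sub <- set[ids, , drop = FALSE]
    cat_ <- collapse_haplotypes(sub)
    counts <- cat_$entries$n
    mut <- count_mutations(sub, include_indels = include_indels)
    th <- watterson_theta(mut$Eta, length(ids), mut$L)
    data.frame(population = p, n = length(ids), k = length(counts),
               Hd = haplotype_diversity(counts),
               Pi = nucleotide_diversity(sub),
               Eta = mut$Eta, S = mut$S,
               theta_seq = th$theta_seq, theta_site = th$theta_site,
               L = mut$L, stringsAsFactors = FALSE)
  })
  rbind_rows(rows,
             data.frame(population = character(), n = integer(), k = integer(),
                        Hd = numeric(), Pi = numeric(), Eta = integer(),
                        S = integer(), theta_seq = numeric(),
                        theta_site = numeric(), L = integer(),
                        stringsAsFactors = FALSE))
}

#' Write a diversity table as tab-separated text
#'
#' Values are rounded to report precision (Hd 3 dp; Pi and theta 5 dp).
#'
#' @param tab Data frame from [diversity_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(tab, path) {
  out <- tab
  out$Hd <- round(out$Hd, 3)
  out$Pi <- round(out$Pi, 5)
  out$theta_seq <- round(out$theta_seq, 5)
  out$theta_site <- round(out$theta_site, 5)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
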