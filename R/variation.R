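#' Classify a substitution between two alignment states
#'
#' Purine-purine (`A<->G`) and pyrimidine-pyrimidine (`C<->T`) changes are
#' transitions; base changes across the two classes are transversions; a
#' base against the gap character is a deletion.
#'
#' @param a,b Distinct characters from `A, C, G, T, -`.
#' @return One of `"transition"`, `"transversion"`, `"deletion"`.
#' @export
classify_pair <- function(a, b) {
  if (a == b) stop("states are identical: '", a, "'", call. = FALSE)
  ok <- c("A", "C", "G", "T", "-")
  if (!(a %in% ok) || !(b %in% ok))
    stop("states must be in {A,C,G,T,-}, got '", a, "', '", b, "'", call. = FALSE)
  if (a == "-" || b == "-") return("deletion")
  purine <- c("A", "G")
  if ((a %in% purine) == (b %in% purine)) "transition" else "transversion"
}

#' Find variable alignment columns
#'
#' A column is variable when at least two distinct states among
#' `A, C, G, T, -` are observed. `N` is treated as missing and never creates
#' variability. Two-state columns are classified via [classify_pair()];
#' columns with more than two non-missing states are tagged `multi-state`
#' and carry the class of their majority state pair (ties broken by count,
#' then alphabetically) in `majority_class`.
#'
#' @param set An `aligned_set`.
#' @return A data frame (one row per variable site, sorted by reference
#'   position) with columns `ref_position`, `column`, `states` (collapsed
#'   `state:count` string), `reference_state` (from the set's `ref_id` row,
#'   or `NA`), `classification` and `majority_class`.
#' @export
find_variable_sites <- function(set) {
  if (nrow(set) == 0L) stop("empty sequence set", call. = FALSE)
  ref_id <- attr(set, "ref_id")
  ref_row <- if (!is.null(ref_id) && ref_id %in% rownames(set)) set[ref_id, ] else NULL
  rows <- lapply(seq_len(ncol(set)), function(j) {
    col <- set[, j]
    col <- col[col != "N"]
    if (length(col) == 0L) return(NULL)
    tab <- table(col)
    if (length(tab) < 2L) return(NULL)
    # count desc; on ties bases precede the gap, then alphabetical
    tab <- tab[order(-as.integer(tab),
                     match(names(tab), c("A", "C", "G", "T", "-")))]
    states <- names(tab)
    maj <- classify_pair(states[1L], states[2L])
    cls <- if (length(tab) == 2L) maj else "multi-state"
    data.frame(ref_position = ref_positions(set, j),
               column = j,
               states = paste(sprintf("%s:%d", states, as.integer(tab)),
                              collapse = ","),
               reference_state = if (is.null(ref_row)) NA_character_ else ref_row[j],
               classification = cls,
               majority_class = maj,
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows,
                    data.frame(ref_position = integer(), column = integer(),
                               states = character(),
                               reference_state = character(),
                               classification = character(),
                               majority_class = character(),
                               stringsAsFactors = FALSE))
  out[order(out$ref_position), , drop = FALSE]
}

#' Collapse aligned sequences into haplotypes
#'
#' Exact string identity defines a haplotype. Sequences containing `N` are
#' assigned to the unique haplotype they match at all non-`N` positions; if
#' no unique match exists they found their own haplotype (with a warning).
#' Haplotypes are labelled `H1, H2, ...` in order of first occurrence.
#'
#' @param set An `aligned_set`.
#' @param pops Optional population assignment data frame (`id`,
#'   `population`, `clade`); ids absent from it count as `Unassigned`.
#' @return An object of class `haplotype_catalog`: a list with `entries`
#'   (data frame: `haplotype_id`, `sequence`, `n`, `members` list-column)
#'   and `per_population_counts` (population x haplotype count matrix).
#' @export
collapse_haplotypes <- function(set, pops = NULL) {
  if (nrow(set) == 0L) stop("empty sequence set", call. = FALSE)
  seqs <- apply(set, 1L, paste, collapse = "")
  has_n <- grepl("N", seqs, fixed = TRUE)
  ids <- rownames(set)

  hap_seq <- character(0)   # pattern sequences, first-occurrence order
  members <- list()
  for (i in seq_along(seqs)) {
    if (!has_n[i]) {
      j <- match(seqs[i], hap_seq)
      if (is.na(j)) {
        hap_seq <- c(hap_seq, seqs[i]); members <- c(members, list(ids[i]))
      } else members[[j]] <- c(members[[j]], ids[i])
    } else {
      v <- set[i, ]
      known <- v != "N"
      hits <- which(vapply(hap_seq, function(h) {
        all(strsplit(h, "")[[1L]][known] == v[known])
      }, logical(1)))
      if (length(hits) == 1L) {
        members[[hits]] <- c(members[[hits]], ids[i])
      } else {
        if (length(hits) > 1L)
          warning("sequence '", ids[i], "' with N matches ", length(hits),
                  " haplotypes; founding its own", call. = FALSE)
        else
          warning("sequence '", ids[i], "' contains N and matches no haplotype; ",
                  "founding its own", call. = FALSE)
        hap_seq <- c(hap_seq, seqs[i]); members <- c(members, list(ids[i]))
      }
    }
  }

  hap_id <- paste0("H", seq_along(hap_seq))
  entries <- data.frame(haplotype_id = hap_id, sequence = hap_seq,
                        n = lengths(members), stringsAsFactors = FALSE)
  entries$members <- members

  pop_of <- if (is.null(pops)) {
    stats::setNames(rep("All", length(ids)), ids)
  } else assignment_for(pops, ids, "population")
  pop_levels <- unique(pop_of[ids])
  counts <- matrix(0L, nrow = length(pop_levels), ncol = length(hap_id),
                   dimnames = list(pop_levels, hap_id))
  for (j in seq_along(members))
    for (id in members[[j]])
      counts[pop_of[[id]], j] <- counts[pop_of[[id]], j] + 1L

  structure(list(entries = entries, per_population_counts = counts),
            class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat("Haplotype catalog:", nrow(x$entries), "haplotypes over",
      sum(x$entries$n), "sequences\n")
  print(data.frame(haplotype_id = x$entries$haplotype_id, n = x$entries$n))
  invisible(x)
}

#' Per-population polymorphism summary
#'
#' For each population, counts the polymorphic sites and breaks them into
#' transitions, transversions and deletions, alongside the haplotype count —
#' the usual per-breed summary table for mtDNA panels. By default
#' (`mode = "vs-reference"`) a site counts as polymorphic for a population
#' when its members differ among themselves *or* from the designated
#' reference sequence, so a monomorphic breed still shows its divergence
#' from the reference; `mode = "within"` counts only within-population
#' variation.
#'
#' @param set An `aligned_set` whose `ref_id` names the reference row
#'   (required for `mode = "vs-reference"`).
#' @param pops Population assignment data frame.
#' @param mode `"vs-reference"` (default) or `"within"`.
#' @param exclude One or more population labels to leave out (the reference
#'   and outgroup are excluded automatically when identifiable).
#' @return A data frame with columns `population`, `n`, `polymorphic_sites`,
#'   `haplotypes`, `transitions`, `transversions`, `deletions`.
#' @export
population_summary <- function(set, pops, mode = c("vs-reference", "within"),
                               exclude = character(0)) {
  mode <- match.arg(mode)
  ref_id <- attr(set, "ref_id")
  if (mode == "vs-reference" && (is.null(ref_id) || !(ref_id %in% rownames(set))))
    stop("mode 'vs-reference' needs the set's ref_id to name a row", call. = FALSE)
  pop_of <- assignment_for(pops, rownames(set), "population")
  pop_levels <- setdiff(unique(pop_of), exclude)
  # never summarise the reference itself as a breed of one
  if (!is.null(ref_id) && ref_id %in% names(pop_of)) {
    ref_pop <- pop_of[[ref_id]]
    if (sum(pop_of == ref_pop) == 1L) pop_levels <- setdiff(pop_levels, ref_pop)
  }
  ref_row <- if (!is.null(ref_id) && ref_id %in% rownames(set)) set[ref_id, ] else NULL

  rows <- lapply(pop_levels, function(p) {
    ids <- names(pop_of)[pop_of == p]
    if (length(ids) == 0L) {
      warning("population '", p, "' has no members; omitted", call. = FALSE)
      return(NULL)
    }
    sub <- set[ids, , drop = FALSE]
    n_ti <- n_tv <- n_del <- 0L
    n_sites <- 0L
    for (j in seq_len(ncol(sub))) {
      col <- sub[, j]
      col <- col[col != "N"]
      states <- unique(col)
      if (mode == "vs-reference" && !is.null(ref_row) && ref_row[j] != "N")
        states <- unique(c(states, ref_row[j]))
      if (length(states) < 2L) next
      n_sites <- n_sites + 1L
      tab <- table(factor(c(sub[, j][sub[, j] != "N"],
                            if (mode == "vs-reference") ref_row[j]),
                          levels = states))
      tab <- tab[order(-as.integer(tab),
                       match(names(tab), c("A", "C", "G", "T", "-")))]
      cls <- if (length(states) == 2L) classify_pair(states[1L], states[2L])
             else classify_pair(names(tab)[1L], names(tab)[2L])
      if (cls == "transition") n_ti <- n_ti + 1L
      else if (cls == "transversion") n_tv <- n_tv + 1L
      else n_del <- n_del + 1L
    }
    k <- nrow(collapse_haplotypes(sub)$entries)
    data.frame(population = p, n = length(ids), polymorphic_sites = n_sites,
               haplotypes = k, transitions = n_ti, transversions = n_tv,
               deletions = n_del, stringsAsFactors = FALSE)
  })
  rbind_rows(rows,
             data.frame(population = character(), n = integer(),
                        polymorphic_sites = integer(), haplotypes = integer(),
                        transitions = integer(), transversions = integer(),
                        deletions = integer(), stringsAsFactors = FALSE))
}

# rbind a list of single-row data frames, dropping NULLs; `empty` is the
# zero-row prototype returned when nothing survives.
rbind_rows <- function(rows, empty) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Haplotype-by-variable-site text matrix
#'
#' Renders the classic haplotype figure: rows are haplotypes, columns are
#' variable sites labelled by reference position; cells matching the
#' reference state are drawn as a dot and deletions as a dash.
#'
#' @param set An `aligned_set` with a `ref_id` row.
#' @param sites Data frame from [find_variable_sites()].
#' @param catalog A `haplotype_catalog` from [collapse_haplotypes()].
#' @param dot,dash Glyphs for identity and deletion (defaults `"."`, `"-"`).
#' @return A character matrix (haplotypes x sites) with the reference as its
#'   first row; `format()`/`writeLines()`-ready via [write_haplotype_matrix()].
#' @export
haplotype_matrix <- function(set, sites, catalog, dot = ".", dash = "-") {
  ref_id <- attr(set, "ref_id")
  if (is.null(ref_id) || !(ref_id %in% rownames(set)))
    stop("haplotype matrix needs the set's ref_id to name a row", call. = FALSE)
  ref_row <- set[ref_id, sites$column]
  haps <- catalog$entries
  m <- matrix("", nrow = nrow(haps) + 1L, ncol = nrow(sites),
              dimnames = list(c(ref_id, haps$haplotype_id), sites$ref_position))
  m[1L, ] <- ref_row
  for (i in seq_len(nrow(haps))) {
    chars <- strsplit(haps$sequence[i], "")[[1L]][sites$column]
    cell <- ifelse(chars == ref_row, dot, ifelse(chars == "-", dash, chars))
    m[i + 1L, ] <- cell
  }
  m
}

#' Write a haplotype matrix as fixed-width text
#'
#' Site positions are written as vertical digit headers above the matrix.
#'
#' @param m Matrix from [haplotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_matrix <- function(m, path) {
  lab_w <- max(nchar(rownames(m))) + 2L
  pos <- colnames(m)
  wid <- max(nchar(pos))
  pos_pad <- formatC(pos, width = wid, flag = " ")
  header <- vapply(seq_len(wid), function(k) {
    paste0(strrep(" ", lab_w),
           paste(substring(pos_pad, k, k), collapse = ""))
  }, character(1))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste0(formatC(rownames(m)[i], width = -lab_w),
           paste(m[i, ], collapse = ""))
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
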