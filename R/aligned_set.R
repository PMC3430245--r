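#' Aligned sequence sets
#'
#' An `aligned_set` is a character matrix of aligned mtDNA sequences (one row
#' per sequence, one column per alignment position) over the alphabet
#' `A, C, G, T, N, -`, anchored to a reference coordinate system: column `c`
#' corresponds to reference position `ref_start + c - 1` (1-based, inclusive).
#' The reference (here the complete pig mitochondrial genome used for
#' numbering) is assumed gap-free over the analysed span, so gap columns in
#' non-reference taxa still occupy one reference position each.
#'
#' @param seqs Named character vector of equal-length sequence strings, or a
#'   character matrix of single characters with row names.
#' @param region_name Label for the region (e.g. `"dloop"`, `"cytb"`).
#' @param ref_start 1-based reference position of alignment column 1.
#' @param ref_id Optional id of the reference sequence within the set.
#'
#' @return An object of class `aligned_set`: a character matrix with
#'   attributes `region_name`, `ref_start`, `ref_id` and `regions` (a
#'   data frame of region blocks, maintained by [concatenate_alignments()]).
#' @export
aligned_set <- function(seqs, region_name = "region", ref_start = 1L,
                        ref_id = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop("all sequences must be named", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[lens != lens[1L]][1L]
      stop("alignment is ragged: sequence '", bad, "' has length ",
           nchar(seqs[[bad]]), ", expected ", lens[1L], call. = FALSE)
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (ncol(m) < 1L) stop("alignment must have at least one column", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate sequence ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  bad <- which(!(m %in% c("A", "C", "G", "T", "N", "-")))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop("illegal character '", m[bad[1L]], "' in sequence '",
         rownames(m)[i[1L]], "' at alignment column ", i[2L], call. = FALSE)
  }
  structure(m,
            region_name = region_name,
            ref_start = as.integer(ref_start),
            ref_id = ref_id,
            regions = data.frame(region = region_name,
                                 start_col = 1L, end_col = ncol(m),
                                 ref_start = as.integer(ref_start),
                                 stringsAsFactors = FALSE),
            class = c("aligned_set", "matrix", "array"))
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("Aligned sequence set '", attr(x, "region_name"), "': ",
      nrow(x), " sequences x ", ncol(x), " columns (reference positions ",
      attr(x, "ref_start"), "-", attr(x, "ref_start") + ncol(x) - 1L, ")\n",
      sep = "")
  invisible(x)
}

#' Reference positions of alignment columns
#'
#' @param set An `aligned_set`.
#' @param columns Column indices (default: all).
#' @return Integer vector of 1-based reference positions.
#' @export
ref_positions <- function(set, columns = seq_len(ncol(set))) {
  attr(set, "ref_start") + as.integer(columns) - 1L
}

#' Read an aligned FASTA file
#'
#' Reads a pre-aligned FASTA file (wrapped or unwrapped) into an
#' [aligned_set()]. Case is normalised to upper and `U` is mapped to `T`;
#' records must all have the same length.
#'
#' @inheritParams aligned_set
#' @param path Path to a FASTA file.
#' @return An `aligned_set`.
#' @export
read_alignment <- function(path, region_name = "region", ref_start = 1L,
                           ref_id = NULL) {
  bin <- ape::read.FASTA(path)
  if (length(bin) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  chr <- lapply(as.character(bin), toupper)
  lens <- lengths(chr)
  if (length(unique(lens)) > 1L) {
    bad <- names(chr)[lens != lens[1L]][1L]
    stop("alignment is ragged: record '", bad, "' has length ",
         length(chr[[bad]]), ", expected ", lens[1L], call. = FALSE)
  }
  seqs <- vapply(chr, paste, character(1), collapse = "")
  aligned_set(seqs, region_name = region_name, ref_start = ref_start,
              ref_id = ref_id)
}

#' Write an aligned set as FASTA
#'
#' @param set An `aligned_set`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(set, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in rownames(set)) {
    s <- paste(set[id, ], collapse = "")
    writeLines(paste0(">", id), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Truncate an alignment to a reference coordinate range
#'
#' Keeps the columns whose reference positions fall inside
#' `[ref_from, ref_to]` (inclusive) and updates `ref_start`. This mirrors the
#' common practice of truncating control-region alignments to the span
#' covered by short published fragments.
#'
#' @param set An `aligned_set`.
#' @param ref_from,ref_to 1-based reference positions, `ref_from <= ref_to`,
#'   both within the set's span.
#' @return The truncated `aligned_set`.
#' @export
truncate_alignment <- function(set, ref_from, ref_to) {
  if (ref_from > ref_to)
    stop("ref_from (", ref_from, ") exceeds ref_to (", ref_to, ")", call. = FALSE)
  pos <- ref_positions(set)
  if (ref_from < pos[1L] || ref_to > pos[length(pos)])
    stop("range ", ref_from, "-", ref_to, " outside the reference span ",
         pos[1L], "-", pos[length(pos)], call. = FALSE)
  keep <- which(pos >= ref_from & pos <= ref_to)
  aligned_set(set[, keep, drop = FALSE],
              region_name = attr(set, "region_name"),
              ref_start = as.integer(ref_from),
              ref_id = attr(set, "ref_id"))
}

#' Concatenate two aligned regions over an identical taxon set
#'
#' Joins two alignments horizontally per sequence id, recording the region
#' boundaries so per-region slices can be recovered later (see
#' [region_slice()]).
#'
#' @param a,b `aligned_set` objects over identical id sets.
#' @return An `aligned_set` of width `ncol(a) + ncol(b)`.
#' @export
concatenate_alignments <- function(a, b) {
  if (ncol(b) == 0L) return(a)
  ids_a <- rownames(a); ids_b <- rownames(b)
  if (!setequal(ids_a, ids_b)) {
    diff <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    stop("id sets differ; only in one set: ", paste(diff, collapse = ", "),
         call. = FALSE)
  }
  m <- cbind(a, b[ids_a, , drop = FALSE])
  regs_a <- attr(a, "regions")
  regs_b <- attr(b, "regions")
  regs_b$start_col <- regs_b$start_col + ncol(a)
  regs_b$end_col <- regs_b$end_col + ncol(a)
  out <- aligned_set(m,
                     region_name = paste(attr(a, "region_name"),
                                         attr(b, "region_name"), sep = "+"),
                     ref_start = attr(a, "ref_start"),
                     ref_id = attr(a, "ref_id"))
  attr(out, "regions") <- rbind(regs_a, regs_b)
  out
}

#' Extract one region block from a concatenated alignment
#'
#' @param set An `aligned_set` (typically from [concatenate_alignments()]).
#' @param region Region name recorded in the set's `regions` attribute.
#' @return The `aligned_set` for that block with its own `ref_start`.
#' @export
region_slice <- function(set, region) {
  regs <- attr(set, "regions")
  i <- match(region, regs$region)
  if (is.na(i))
    stop("unknown region '", region, "'; available: ",
         paste(regs$region, collapse = ", "), call. = FALSE)
  aligned_set(set[, regs$start_col[i]:regs$end_col[i], drop = FALSE],
              region_name = region, ref_start = regs$ref_start[i],
              ref_id = attr(set, "ref_id"))
}

#' Read a population / clade assignment map
#'
#' The map is a 3-column tab-separated file `id<TAB>population<TAB>clade`
#' with `#` comment lines. Clade labels are free-form; the conventional set
#' is `European`, `Asian`, `WildBoar-European`, `WildBoar-Asian`, `Outgroup`
#' and `Unassigned`.
#'
#' @param path Path to the tab-separated map.
#' @return A data frame with columns `id`, `population`, `clade`.
#' @export
read_population_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("id", "population", "clade"),
                          colClasses = "character", blank.lines.skip = TRUE)
  if (anyDuplicated(df$id))
    stop("duplicate ids in population map: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  df
}

#' Build a population assignment in memory
#'
#' @param id,population,clade Equal-length character vectors.
#' @return A data frame with columns `id`, `population`, `clade`.
#' @export
population_assignment <- function(id, population, clade) {
  if (anyDuplicated(id)) stop("duplicate ids", call. = FALSE)
  data.frame(id = as.character(id), population = as.character(population),
             clade = as.character(clade), stringsAsFactors = FALSE)
}

# Assignment lookup with Unassigned fallback for ids absent from the map.
assignment_for <- function(pops, ids, what = c("population", "clade")) {
  what <- match.arg(what)
  out <- pops[[what]][match(ids, pops$id)]
  out[is.na(out)] <- "Unassigned"
  names(out) <- ids
  out
}
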