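#' Molecular-clock divergence time from a net distance
#'
#' Applies the standard molecular-clock relation `T = K / (2 r)`: the net
#' between-clade divergence `K` (as a percentage) accumulated along both
#' lineages at substitution rate `r` per lineage. Rates are given in the
#' conventional units of 1e-9 substitutions/site/year, so
#' `T = (K/100) / (2 * r * 1e-9)` years.
#'
#' @param K_percent Net between-group distance, in percent (>= 0).
#' @param rate_1e9 Substitution rate in units of 1e-9 subst/site/year (> 0).
#' @return Divergence time in years.
#' @export
divergence_time <- function(K_percent, rate_1e9) {
  if (any(rate_1e9 <= 0)) stop("substitution rate must be positive", call. = FALSE)
  if (any(K_percent < 0)) stop("K must be >= 0", call. = FALSE)
  (K_percent / 100) / (2 * rate_1e9 * 1e-9)
}

#' Build a divergence-dating table
#'
#' One row per mtDNA region/partition, pairing the net distance with its
#' rate and the implied time, rounded to integer thousands of years for
#' reporting (unrounded years kept in `T_years`).
#'
#' @param region Character vector of region labels (e.g.
#'   `"cytb_synonymous"`, `"dloop_ETAS"`).
#' @param K_percent,K_sd Net distances and their SDs, percent.
#' @param rate_1e9,rate_sd Rates and their SDs, 1e-9 subst/site/year.
#' @return A data frame of class `divergence_table` with columns `region`,
#'   `rate_1e9`, `rate_sd`, `K_percent`, `K_sd`, `T_years`, `T_thousands`.
#' @export
divergence_table <- function(region, K_percent, rate_1e9,
                             K_sd = NA_real_, rate_sd = NA_real_) {
  T_years <- divergence_time(K_percent, rate_1e9)
  out <- data.frame(region = region, rate_1e9 = rate_1e9, rate_sd = rate_sd,
                    K_percent = K_percent, K_sd = K_sd,
                    T_years = T_years,
                    T_thousands = round(T_years / 1000),
                    stringsAsFactors = FALSE)
  class(out) <- c("divergence_table", "data.frame")
  out
}

#' Average divergence times across regions
#'
#' Arithmetic mean of the *unrounded* times, reported in integer thousands
#' of years, with and without an excluded region set. Averaging unrounded
#' values avoids the half-unit ambiguity that averaging the rounded
#' per-region times would introduce.
#'
#' @param tab A `divergence_table`.
#' @param exclude Region labels to drop from the second average.
#' @return A list with `T_all_years`, `T_all_thousands` and (when `exclude`
#'   is non-empty) `T_excluded_years`, `T_excluded_thousands`.
#' @export
summarize_times <- function(tab, exclude = character(0)) {
  if (nrow(tab) == 0L) stop("no estimates to average", call. = FALSE)
  all_mean <- mean(tab$T_years)
  out <- list(T_all_years = all_mean,
              T_all_thousands = round(all_mean / 1000))
  if (length(exclude)) {
    keep <- !(tab$region %in% exclude)
    if (!any(keep)) stop("all regions excluded", call. = FALSE)
    ex_mean <- mean(tab$T_years[keep])
    out$T_excluded_years <- ex_mean
    out$T_excluded_thousands <- round(ex_mean / 1000)
  }
  out
}

#' Slice a control-region alignment into ETAS and central domains
#'
#' The control region's ETAS (Extended Termination-Associated Sequences)
#' domain evolves much faster than the conserved central domain, so net
#' distances are computed per domain. Domain boundaries are reference
#' coordinates supplied by the user; there is no hard-coded default.
#'
#' @param set The D-loop `aligned_set`.
#' @param etas_range,central_range Length-2 integer vectors
#'   `c(ref_from, ref_to)`; must not overlap.
#' @return A list with elements `ETAS` and `central`, each an `aligned_set`.
#' @export
dloop_domain_slices <- function(set, etas_range, central_range) {
  stopifnot(length(etas_range) == 2L, length(central_range) == 2L)
  if (etas_range[1L] > etas_range[2L] || central_range[1L] > central_range[2L])
    stop("domain ranges must be increasing", call. = FALSE)
  if (max(etas_range[1L], central_range[1L]) <=
      min(etas_range[2L], central_range[2L]))
    stop("ETAS and central domain ranges overlap", call. = FALSE)
  list(ETAS = truncate_alignment(set, etas_range[1L], etas_range[2L]),
       central = truncate_alignment(set, central_range[1L], central_range[2L]))
}

#' Read a substitution-rate table
#'
#' Tab-separated file with a header and columns `region`, `rate_1e9`,
#' `rate_sd` (rates in units of 1e-9 substitutions/site/year).
#'
#' @param path Path to the rate file.
#' @return A data frame.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("region", "rate_1e9", "rate_sd")
  if (!all(need %in% names(df)))
    stop("rate table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$rate_1e9 <= 0)) stop("rates must be positive", call. = FALSE)
  df
}

#' Write a dating report
#'
#' Tab-separated table with per-region rows followed by the averages.
#'
#' @param tab A `divergence_table`.
#' @param path Output path.
#' @param exclude Regions excluded from the second average.
#' @return `path`, invisibly.
#' @export
write_dating_report <- function(tab, path, exclude = character(0)) {
  avg <- summarize_times(tab, exclude = exclude)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("region", "rate_1e9", "rate_sd", "K_percent", "K_sd",
                   "T_thousands", sep = "\t"), con)
  for (i in seq_len(nrow(tab)))
    writeLines(paste(tab$region[i], tab$rate_1e9[i], tab$rate_sd[i],
                     tab$K_percent[i], tab$K_sd[i], tab$T_thousands[i],
                     sep = "\t"), con)
  writeLines(paste("average_all", "", "", "", "", avg$T_all_thousands,
                   sep = "\t"), con)
  if (length(exclude))
    writeLines(paste(paste0("average_without_", paste(exclude, collapse = "+")),
                     "", "", "", "", avg$T_excluded_thousands, sep = "\t"), con)
  invisible(path)
}
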