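#' Read a pipeline run configuration (YAML)
#'
#' The configuration has either a `files:` block (paths `dloop`, `cytb`,
#' `population_map`) or a `synth:` block ([generator_config()] fields);
#' plus optional `ref_id`, `ref_start_dloop`, `ref_start_cytb`, `outgroup`,
#' `bootstrap` (replicates `B` and `seed`), `clades` (pair used for dating),
#' `rates` (path to a rate table), `etas_range`, `central_range` and
#' `out_dir`.
#'
#' @param path Path to a YAML file.
#' @return A list usable as the `config` argument of [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!xor(is.null(cfg$files), is.null(cfg$synth)))
    stop("config must have exactly one of 'files' or 'synth'", call. = FALSE)
  cfg
}

#' Run the full mtDNA phylogeography pipeline
#'
#' From aligned D-loop and cytochrome b blocks plus a population map (read
#' from files, passed in memory, or simulated), the pipeline produces: the
#' variable-site report, the haplotype-by-site text matrix, the per-breed
#' polymorphism summary, the diversity table, three Neighbor-Joining trees
#' (per region and concatenated) with bootstrap supports and outgroup
#' rooting, the K2P distance matrices, and — when a rate table and clade
#' pair are configured — the net-divergence dating report.
#'
#' @param config A list, typically from [read_run_config()]. Recognised
#'   elements: `files` (paths `dloop`, `cytb`, `population_map`) or `synth`
#'   (arguments to [generator_config()]) or `data` (a
#'   [generate_dataset()]-shaped list); `ref_id`; `ref_start_dloop`
#'   (default 15455); `ref_start_cytb` (default 1); `outgroup`;
#'   `bootstrap = list(B =, seed =)`; `clades = c(a, b)`; `rates` (path);
#'   `region_map` (named list matching rate-table regions to alignments,
#'   see Details); `etas_range`, `central_range`; `out_dir`.
#'
#' @details Dating needs a mapping from rate-table regions to alignment
#'   partitions. The built-in regions are `cytb_synonymous` /
#'   `cytb_nonsynonymous` (dS/dN on the cytochrome b block) and
#'   `dloop_ETAS` / `dloop_central` (K2P on the configured domain slices).
#'
#' @return An object of class `mtphylo_run`: a list with the input sets,
#'   catalogs, tables, trees, distances, dating results and a `log`
#'   character vector. Files are written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  log <- c(sprintf("mtphylo run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("R %s; mtphylo %s", getRversion(),
                   as.character(utils::packageVersion("mtphylo"))))
  say <- function(...) log <<- c(log, sprintf(...))

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$synth)) {
      gc_args <- config$synth
      cfg <- do.call(generator_config, gc_args)
      data <- generate_dataset(cfg)
      say("input: synthetic dataset (seed %d)", cfg$seed)
    } else if (!is.null(config$data)) {
      data <- config$data
      say("input: in-memory dataset")
    } else {
      f <- config$files
      dloop <- read_alignment(f$dloop, "dloop",
                              ref_start = config$ref_start_dloop %||% 15455L,
                              ref_id = config$ref_id)
      cytb <- read_alignment(f$cytb, "cytb",
                             ref_start = config$ref_start_cytb %||% 1L,
                             ref_id = config$ref_id)
      data <- list(dloop = dloop, cytb = cytb,
                   pops = read_population_map(f$population_map), truth = NULL)
      say("input: %s, %s, %s", f$dloop, f$cytb, f$population_map)
    }
    dloop <- data$dloop; cytb <- data$cytb; pops <- data$pops
    both <- concatenate_alignments(dloop, cytb)
    say("alignments: dloop %d, cytb %d, concatenated %d columns",
        ncol(dloop), ncol(cytb), ncol(both))

    stage <- "variation"
    sites <- find_variable_sites(both)
    catalog <- collapse_haplotypes(both, pops)
    say("variation: %d variable sites, %d haplotypes", nrow(sites),
        nrow(catalog$entries))
    summary_tab <- if (!is.null(attr(both, "ref_id")) &&
                       attr(both, "ref_id") %in% rownames(both))
      population_summary(both, pops) else NULL

    stage <- "diversity"
    div <- diversity_stats(both, pops)

    stage <- "trees"
    B <- config$bootstrap$B %||% 1000L
    seed <- config$bootstrap$seed %||% 1L
    outgroup <- config$outgroup
    hap_sets <- haplotype_sets(both, catalog,
                               keep = c(outgroup, attr(both, "ref_id")))
    trees <- list()
    for (rg in c("dloop", "cytb", "concat")) {
      sub <- if (rg == "concat") hap_sets else region_slice_hap(hap_sets, rg)
      bs <- bootstrap_support(sub, B = B, seed = seed)
      tr <- bs$tree
      if (!is.null(outgroup) && outgroup %in% tr$tip.label)
        tr <- root_with_outgroup(tr, outgroup)
      trees[[rg]] <- tr
      say("tree %s: %d tips, B = %d (%d used)", rg,
          length(tr$tip.label), bs$B, bs$B_used)
    }

    stage <- "dating"
    dating <- NULL
    if (!is.null(config$rates) && !is.null(config$clades)) {
      rates <- if (is.character(config$rates)) read_rate_table(config$rates)
               else config$rates
      dating <- date_clades(dloop, cytb, pops,
                            clades = config$clades, rates = rates,
                            etas_range = config$etas_range,
                            central_range = config$central_range,
                            B = B, seed = seed)
      say("dating: %d regions, average %d kyr", nrow(dating$table),
          dating$summary$T_all_thousands)
    }

    list(dloop = dloop, cytb = cytb, concat = both, pops = pops,
         truth = data$truth, sites = sites, catalog = catalog,
         population_summary = summary_tab, diversity = div, trees = trees,
         dating = dating)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  res$log <- log
  class(res) <- "mtphylo_run"

  if (!is.null(config$out_dir)) write_run_outputs(res, config$out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One representative sequence per haplotype (tree taxon set). A haplotype
# containing one of the `keep` ids (outgroup, reference) is represented by
# that id under its original label, so rooting and numbering still find it;
# the rest are labelled by haplotype id.
haplotype_sets <- function(set, catalog, keep = NULL) {
  keep <- intersect(keep, rownames(set))
  ids <- character(0); lab <- character(0)
  for (i in seq_len(nrow(catalog$entries))) {
    mem <- catalog$entries$members[[i]]
    sp <- intersect(mem, keep)
    if (length(sp)) {
      ids <- c(ids, sp[1L]); lab <- c(lab, sp[1L])
    } else {
      ids <- c(ids, mem[1L]); lab <- c(lab, catalog$entries$haplotype_id[i])
    }
  }
  m <- unclass(set)[ids, , drop = FALSE]
  rownames(m) <- lab
  out <- aligned_set(m, region_name = attr(set, "region_name"),
                     ref_start = attr(set, "ref_start"),
                     ref_id = attr(set, "ref_id"))
  attr(out, "regions") <- attr(set, "regions")
  out
}

region_slice_hap <- function(set, region) {
  out <- region_slice(set, region)
  # collapse again is not needed for tree building; identical rows are fine
  out
}

#' Net-divergence dating between two clades
#'
#' Computes the net between-clade distance for each dated partition —
#' synonymous and non-synonymous cytochrome b (Nei-Gojobori) and, when
#' domain ranges are configured, K2P on the ETAS and central control-region
#' domains — with site-bootstrap SDs for the K2P partitions, and converts
#' each to a divergence time via `T = K/2r`.
#'
#' @param dloop,cytb `aligned_set` objects.
#' @param pops Population assignment with a `clade` column.
#' @param clades Length-2 character vector: the clade pair.
#' @param rates Rate table data frame (`region`, `rate_1e9`, `rate_sd`).
#' @param etas_range,central_range Optional domain ranges (reference
#'   coordinates) for the control-region partitions.
#' @param B,seed Site-bootstrap replicates and seed for the K SDs.
#' @return A list with `table` (a [divergence_table()]), `summary`
#'   (from [summarize_times()], excluding `dloop_central` when present) and
#'   `K` (the per-partition `group_divergence` objects).
#' @export
date_clades <- function(dloop, cytb, pops, clades, rates,
                        etas_range = NULL, central_range = NULL,
                        B = 1000L, seed = 1L) {
  stopifnot(length(clades) == 2L)
  Ks <- list()
  for (type in c("dS", "dN")) {
    rg <- if (type == "dS") "cytb_synonymous" else "cytb_nonsynonymous"
    if (rg %in% rates$region) {
      dm <- syn_nonsyn_matrix(cytb, type)
      Ks[[rg]] <- net_between_group(dm, pops, clades[1L], clades[2L])
    }
  }
  if (!is.null(etas_range) && !is.null(central_range)) {
    doms <- dloop_domain_slices(dloop, unlist(etas_range), unlist(central_range))
    for (rg in c("dloop_ETAS", "dloop_central")) {
      if (!(rg %in% rates$region)) next
      sub <- if (rg == "dloop_ETAS") doms$ETAS else doms$central
      Ks[[rg]] <- net_between_group_boot(sub, pops, clades[1L], clades[2L],
                                         B = B, seed = seed)
    }
  }
  if (length(Ks) == 0L) stop("no dated partitions configured", call. = FALSE)
  regions <- names(Ks)
  r <- rates[match(regions, rates$region), ]
  tab <- divergence_table(region = regions,
                          K_percent = 100 * vapply(Ks, `[[`, numeric(1), "K"),
                          rate_1e9 = r$rate_1e9,
                          K_sd = 100 * vapply(Ks, `[[`, numeric(1), "sd"),
                          rate_sd = r$rate_sd)
  excl <- intersect("dloop_central", regions)
  list(table = tab, summary = summarize_times(tab, exclude = excl), K = Ks)
}

#' Write the output bundle of a pipeline run
#'
#' @param run An `mtphylo_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$sites, file.path(dir, "variable_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(attr(run$concat, "ref_id")) &&
      attr(run$concat, "ref_id") %in% rownames(run$concat)) {
    hm <- haplotype_matrix(run$concat, run$sites, run$catalog)
    write_haplotype_matrix(hm, file.path(dir, "haplotype_matrix.txt"))
  }
  if (!is.null(run$population_summary))
    utils::write.table(run$population_summary,
                       file.path(dir, "population_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$diversity))
    write_diversity_table(run$diversity, file.path(dir, "diversity.tsv"))
  for (rg in names(run$trees))
    write_newick(run$trees[[rg]], file.path(dir, sprintf("tree_%s.nwk", rg)))
  if (!is.null(run$dating)) {
    write_dating_report(run$dating$table, file.path(dir, "dating.tsv"),
                        exclude = intersect("dloop_central",
                                            run$dating$table$region))
  }
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.mtphylo_run <- function(x, ...) {
  cat("mtphylo pipeline run\n")
  cat("  sequences:", nrow(x$concat), "x", ncol(x$concat), "columns\n")
  cat("  variable sites:", nrow(x$sites),
      sprintf("(%.1f%% of columns)", 100 * nrow(x$sites) / ncol(x$concat)), "\n")
  cat("  haplotypes:", nrow(x$catalog$entries), "\n")
  cat("  trees:", paste(names(x$trees), collapse = ", "), "\n")
  if (!is.null(x$dating))
    cat("  dating: average", x$dating$summary$T_all_thousands, "kyr\n")
  invisible(x)
}

#' @export
summary.mtphylo_run <- function(object, ...) {
  print(object)
  if (!is.null(object$diversity)) {
    cat("\nPer-population diversity:\n")
    print(object$diversity, digits = 4)
  }
  if (!is.null(object$population_summary)) {
    cat("\nPolymorphism summary:\n")
    print(object$population_summary)
  }
  if (!is.null(object$dating)) {
    cat("\nDivergence dating:\n")
    print(as.data.frame(object$dating$table))
  }
  invisible(object)
}
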