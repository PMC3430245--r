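# Vertebrate mitochondrial genetic code, built once from the standard
# translation machinery (NCBI table 2).
codon_table_env <- new.env(parent = emptyenv())

vertebrate_mito_code <- function() {
  if (is.null(codon_table_env$tab)) {
    bases <- c("T", "C", "A", "G")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                              function(ab, c) paste0(t(ab), c)))
    codons <- sort(codons)
    aa <- vapply(codons, function(cod) {
      seqinr::translate(strsplit(cod, "")[[1L]], numcode = 2)
    }, character(1))
    codon_table_env$tab <- stats::setNames(aa, codons)
  }
  codon_table_env$tab
}

translate_codon <- function(codon, code = vertebrate_mito_code()) {
  aa <- code[[codon]]
  if (is.null(aa)) stop("not a codon: '", codon, "'", call. = FALSE)
  aa
}

# Synonymous/non-synonymous site counts for one codon (Nei-Gojobori):
# each position contributes the fraction of its three possible changes that
# are synonymous. Changes creating a stop codon count as non-synonymous.
ng_codon_sites <- function(codon, code = vertebrate_mito_code()) {
  aa0 <- translate_codon(codon, code)
  if (aa0 == "*") stop("stop codon '", codon, "' in frame", call. = FALSE)
  chars <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars; mut[pos] <- nt
      aa1 <- code[[paste(mut, collapse = "")]]
      if (aa1 == aa0) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

# Synonymous/non-synonymous difference counts between two codons with
# equal-weight averaging over substitution pathways; pathways passing
# through a stop codon are excluded (all pathways used if every one is
# blocked).
ng_codon_diffs <- function(a, b, code = vertebrate_mito_code()) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  pos <- which(ca != cb)
  k <- length(pos)
  if (k == 0L) return(c(Sd = 0, Nd = 0))
  perms <- if (k == 1L) list(pos) else {
    if (k == 2L) list(pos, rev(pos)) else {
      list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
           pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
    }
  }
  score_path <- function(order) {
    cur <- ca; sd_ <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- cb[p]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" || aa_cur == "*") return(NULL)
      if (aa_cur == aa_nxt) sd_ <- sd_ + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd_, nd)
  }
  scores <- Filter(Negate(is.null), lapply(perms, score_path))
  if (length(scores) == 0L)  # every pathway crosses a stop: use them anyway
    scores <- lapply(perms, function(order) {
      cur <- ca; sd_ <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- cb[p]
        if (code[[paste(cur, collapse = "")]] ==
            code[[paste(nxt, collapse = "")]]) sd_ <- sd_ + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd_, nd)
    })
  m <- colMeans(do.call(rbind, scores))
  c(Sd = m[[1L]], Nd = m[[2L]])
}

# Precomputed per-codon site counts and 64x64 pathway-averaged difference
# matrices; built lazily once per session.
ng_tables <- function() {
  if (is.null(codon_table_env$ng)) {
    code <- vertebrate_mito_code()
    codons <- names(code)
    is_stop <- unname(code == "*")
    S <- N <- rep(NA_real_, length(codons))
    for (k in which(!is_stop)) {
      s <- ng_codon_sites(codons[k], code)
      S[k] <- s[["S"]]; N[k] <- s[["N"]]
    }
    nC <- length(codons)
    Sd <- Nd <- matrix(NA_real_, nC, nC)
    for (i in which(!is_stop)) for (j in which(!is_stop)) {
      d <- ng_codon_diffs(codons[i], codons[j], code)
      Sd[i, j] <- d[["Sd"]]; Nd[i, j] <- d[["Nd"]]
    }
    codon_table_env$ng <- list(codons = codons, is_stop = is_stop,
                               S = S, N = N, Sd = Sd, Nd = Nd)
  }
  codon_table_env$ng
}

#' Synonymous and non-synonymous distances (Nei-Gojobori)
#'
#' Counts synonymous and non-synonymous sites and differences over an
#' in-frame codon alignment under the vertebrate mitochondrial genetic code,
#' with equal-weight pathway averaging for codons differing at more than one
#' position, and applies the Jukes-Cantor correction
#' `d = -3/4 log(1 - 4p/3)` to each proportion. Codons containing gaps or
#' `N` in either sequence are skipped (pairwise deletion at codon level).
#'
#' @param a,b Character vectors (aligned sequences) of equal length
#'   divisible by 3, in reading frame.
#' @return For `syn_nonsyn_counts()`: a list with `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `pS`, `pN` and `codons_used`. `syn_nonsyn_distance()` adds
#'   the corrected `dS` and `dN` (erroring on saturation, `p >= 3/4`).
#' @export
syn_nonsyn_counts <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  if (length(a) %% 3 != 0L) stop("length not divisible by 3", call. = FALSE)
  tabs <- ng_tables()
  nc <- length(a) / 3L
  dim(a) <- dim(b) <- c(3L, nc)
  ca <- paste0(a[1L, ], a[2L, ], a[3L, ])
  cb <- paste0(b[1L, ], b[2L, ], b[3L, ])
  ia <- match(ca, tabs$codons); ib <- match(cb, tabs$codons)
  ok <- !is.na(ia) & !is.na(ib)           # pairwise deletion, codon level
  if (!any(ok)) stop("no usable codons shared", call. = FALSE)
  if (any(tabs$is_stop[ia[ok]]) || any(tabs$is_stop[ib[ok]]))
    stop("stop codon in frame at codon ",
         which(ok & (tabs$is_stop[ia] | tabs$is_stop[ib]))[1L], call. = FALSE)
  ia <- ia[ok]; ib <- ib[ok]
  used <- length(ia)
  S_sites <- sum((tabs$S[ia] + tabs$S[ib]) / 2)
  N_sites <- sum((tabs$N[ia] + tabs$N[ib]) / 2)
  lin <- cbind(ia, ib)
  Sd <- sum(tabs$Sd[lin]); Nd <- sum(tabs$Nd[lin])
  pS <- if (S_sites > 0) Sd / S_sites else 0
  pN <- if (N_sites > 0) Nd / N_sites else 0
  list(S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, codons_used = used)
}

#' @rdname syn_nonsyn_counts
#' @export
syn_nonsyn_distance <- function(a, b) {
  cnt <- syn_nonsyn_counts(a, b)
  jc <- function(p) {
    if (p >= 0.75) stop("saturation: proportion ", signif(p, 4),
                        " >= 3/4", call. = FALSE)
    -0.75 * log(1 - 4 * p / 3)
  }
  c(list(dS = jc(cnt$pS), dN = jc(cnt$pN)), cnt)
}

#' Pairwise dS or dN distance matrix over a codon alignment
#'
#' @param set An in-frame `aligned_set` whose width is divisible by 3.
#' @param type `"dS"` or `"dN"`.
#' @return A `pairwise_dist` matrix tagged with the method.
#' @export
syn_nonsyn_matrix <- function(set, type = c("dS", "dN")) {
  type <- match.arg(type)
  n <- nrow(set)
  if (n < 2L) stop("distance matrix needs >= 2 sequences", call. = FALSE)
  ids <- rownames(set)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- tryCatch(syn_nonsyn_distance(set[i, ], set[j, ]), error = function(e)
      stop("pair ", ids[i], " / ", ids[j], ": ", conditionMessage(e),
           call. = FALSE))
    d[i, j] <- d[j, i] <- r[[type]]
  }
  structure(d, method = type, class = c("pairwise_dist", "matrix", "array"))
}
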