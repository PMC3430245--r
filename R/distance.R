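#' Kimura 2-parameter distance between two aligned sequences
#'
#' Counts the transition proportion `P` and transversion proportion `Q` over
#' the valid sites (both sequences carrying a base, pairwise deletion of
#' gaps and `N`) and applies the two-parameter correction
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param a,b Character vectors of equal length over `A, C, G, T, N, -`.
#' @return A list with `distance`, `P`, `Q` and `valid_sites`.
#' @export
k2p <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  L <- sum(ok)
  if (L == 0L) stop("no valid (ungapped, non-N) sites shared", call. = FALSE)
  aa <- a[ok]; bb <- b[ok]
  diff <- aa != bb
  pur_a <- aa %in% c("A", "G"); pur_b <- bb %in% c("A", "G")
  ti <- sum(diff & (pur_a == pur_b))
  tv <- sum(diff & (pur_a != pur_b))
  P <- ti / L; Q <- tv / L
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturation): P = ", signif(P, 4),
         ", Q = ", signif(Q, 4), call. = FALSE)
  list(distance = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q,
       valid_sites = L)
}

#' K2P distance evaluated from transition/transversion proportions
#'
#' @param P,Q Transition and transversion proportions.
#' @return The K2P distance.
#' @export
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0))
    stop("K2P distance undefined (saturation)", call. = FALSE)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix
#'
#' All unordered pairs via [k2p()] with pairwise deletion. A saturated pair
#' aborts with the pair named.
#'
#' @param set An `aligned_set` with at least two sequences.
#' @return An object of class `pairwise_dist`: a symmetric numeric matrix
#'   with a `method` attribute (`"K2P"`) and a `valid_sites` matrix
#'   attribute.
#' @export
k2p_matrix <- function(set) {
  n <- nrow(set)
  if (n < 2L) stop("distance matrix needs >= 2 sequences", call. = FALSE)
  ids <- rownames(set)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  vs <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- tryCatch(k2p(set[i, ], set[j, ]), error = function(e) {
      stop("pair ", ids[i], " / ", ids[j], ": ", conditionMessage(e),
           call. = FALSE)
    })
    d[i, j] <- d[j, i] <- r$distance
    vs[i, j] <- vs[j, i] <- r$valid_sites
  }
  structure(d, method = "K2P", valid_sites = vs,
            class = c("pairwise_dist", "matrix", "array"))
}

#' @export
print.pairwise_dist <- function(x, digits = 5, ...) {
  cat(attr(x, "method"), "distance matrix,", nrow(x), "taxa\n")
  print(round(unclass(x)[, , drop = FALSE], digits))
  invisible(x)
}

# Per-pair per-column indicator matrices used for fast site bootstraps:
# ti[p, c] / tv[p, c] = 1 when pair p differs by a transition / transversion
# in column c; valid[p, c] = 1 when both members carry a base there.
pair_site_indicators <- function(set, pairs) {
  L <- ncol(set)
  base <- set %in% c("A", "C", "G", "T"); dim(base) <- dim(set)
  pur <- set %in% c("A", "G"); dim(pur) <- dim(set)
  np <- nrow(pairs)
  ti <- matrix(0, np, L); tv <- matrix(0, np, L); valid <- matrix(0, np, L)
  for (p in seq_len(np)) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    ok <- base[i, ] & base[j, ]
    df <- ok & (set[i, ] != set[j, ])
    same_class <- pur[i, ] == pur[j, ]
    ti[p, ] <- as.numeric(df & same_class)
    tv[p, ] <- as.numeric(df & !same_class)
    valid[p, ] <- as.numeric(ok)
  }
  list(ti = ti, tv = tv, valid = valid)
}

#' Nei net between-group distance
#'
#' `K = d_xy - (d_x + d_y)/2`, where `d_xy` is the mean distance over all
#' cross-group pairs and `d_x`, `d_y` the mean within-group distances
#' (defined as 0 for singleton groups). `K` estimates the divergence accrued
#' since the two groups split, net of within-group polymorphism.
#'
#' @param dm A `pairwise_dist` matrix (or any symmetric labelled matrix).
#' @param pops Population assignment data frame with a `clade` column.
#' @param a,b Clade labels.
#' @return An object of class `group_divergence`: a list with `group_a`,
#'   `group_b`, `d_xy`, `d_x`, `d_y`, `K` and (when computed via
#'   [net_between_group_boot()]) `sd`.
#' @export
net_between_group <- function(dm, pops, a, b) {
  clade_of <- assignment_for(pops, rownames(dm), "clade")
  ia <- which(clade_of == a); ib <- which(clade_of == b)
  if (length(ia) == 0L) stop("clade '", a, "' has no members", call. = FALSE)
  if (length(ib) == 0L) stop("clade '", b, "' has no members", call. = FALSE)
  within_mean <- function(idx) {
    if (length(idx) < 2L) return(0)
    m <- dm[idx, idx, drop = FALSE]
    mean(m[upper.tri(m)])
  }
  d_xy <- mean(dm[ia, ib, drop = FALSE])
  d_x <- within_mean(ia); d_y <- within_mean(ib)
  structure(list(group_a = a, group_b = b, d_xy = d_xy, d_x = d_x, d_y = d_y,
                 K = d_xy - (d_x + d_y) / 2, sd = NA_real_),
            class = "group_divergence")
}

#' @export
print.group_divergence <- function(x, ...) {
  cat("Net between-group divergence ", x$group_a, " vs ", x$group_b, ":\n",
      "  d_xy = ", signif(x$d_xy, 5), ", d_x = ", signif(x$d_x, 5),
      ", d_y = ", signif(x$d_y, 5), "\n  K = ", signif(x$K, 5),
      if (!is.na(x$sd)) paste0(" +/- ", signif(x$sd, 3), " (site bootstrap)"),
      "\n", sep = "")
  invisible(x)
}

#' Net between-group K2P divergence with a site-bootstrap standard error
#'
#' Recomputes the full K2P matrix and the net distance on alignments whose
#' columns are resampled with replacement, and reports the bootstrap
#' standard deviation of `K`. Replicates in which some pair saturates are
#' dropped (an error is raised if more than 10% are lost).
#'
#' @param set An `aligned_set`.
#' @inheritParams net_between_group
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the replicate column draws.
#' @return A `group_divergence` with the `sd` slot filled and attributes
#'   `B_used` (replicates kept) and `K_boot` (the replicate values).
#' @export
net_between_group_boot <- function(set, pops, a, b, B = 1000L, seed = 1L) {
  dm <- k2p_matrix(set)
  est <- net_between_group(dm, pops, a, b)
  n <- nrow(set); L <- ncol(set)
  clade_of <- assignment_for(pops, rownames(set), "clade")
  keep <- which(clade_of %in% c(a, b))
  pairs <- t(utils::combn(keep, 2L))
  ind <- pair_site_indicators(set, pairs)
  cl <- clade_of[keep]
  pi_ <- match(pairs[, 1L], keep); pj <- match(pairs[, 2L], keep)
  cross <- cl[pi_] != cl[pj]
  in_a <- cl[pi_] == a & cl[pj] == a
  in_b <- cl[pi_] == b & cl[pj] == b

  set.seed(seed)
  W <- matrix(0, L, B)
  for (r in seq_len(B)) W[, r] <- tabulate(sample.int(L, L, replace = TRUE), L)
  TI <- ind$ti %*% W; TV <- ind$tv %*% W; V <- ind$valid %*% W
  Kb <- rep(NA_real_, B)
  for (r in seq_len(B)) {
    v <- V[, r]
    if (any(v == 0)) next
    P <- TI[, r] / v; Q <- TV[, r] / v
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    if (any(w1 <= 0) || any(w2 <= 0)) next
    d <- -0.5 * log(w1) - 0.25 * log(w2)
    d_xy <- mean(d[cross])
    d_x <- if (any(in_a)) mean(d[in_a]) else 0
    d_y <- if (any(in_b)) mean(d[in_b]) else 0
    Kb[r] <- d_xy - (d_x + d_y) / 2
  }
  dropped <- sum(is.na(Kb))
  if (dropped > 0.1 * B)
    stop(dropped, " of ", B, " bootstrap replicates dropped (saturation)",
         call. = FALSE)
  est$sd <- stats::sd(Kb[!is.na(Kb)])
  attr(est, "B_used") <- B - dropped
  attr(est, "K_boot") <- Kb[!is.na(Kb)]
  est
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm A labelled symmetric distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste0(formatC(rownames(dm)[i], width = -10),
                      paste(sprintf("%.6f", dm[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' Write a distance matrix in long (tab-separated) format
#'
#' @param dm A labelled symmetric distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_matrix <- function(dm, path) {
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  df <- data.frame(id1 = rownames(dm)[idx[, 1L]],
                   id2 = colnames(dm)[idx[, 2L]],
                   distance = dm[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
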