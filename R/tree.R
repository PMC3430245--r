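#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei Neighbor-Joining: at each step the pair minimising
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` (with `R_i` the row sum over the
#' `r` active nodes) is joined; branch lengths follow the standard split
#' formula and the final three-taxon join closes the unrooted tree. Exactly
#' tied `Q` minima are broken deterministically towards the lowest
#' `(row, column)` index pair in the current label order. Negative branch
#' lengths are clamped to zero with the deficit moved onto the sister edge
#' (raw lengths are kept in the `raw_joins` attribute).
#'
#' @param dm Symmetric labelled distance matrix with at least 3 taxa.
#' @return An unrooted `phylo` object (trifurcating root node).
#' @export
nj_tree <- function(dm) {
  n <- nrow(dm)
  if (n < 3L) stop("Neighbor-Joining needs >= 3 taxa", call. = FALSE)
  labels <- rownames(dm)
  if (any(grepl("[(),:;]|\\s", labels)))
    stop("taxon labels may not contain Newick metacharacters or spaces",
         call. = FALSE)
  D <- unclass(dm)[seq_len(n), seq_len(n)]
  sub <- labels            # current subtree Newick fragments
  joins <- list()

  clamp2 <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    c(max(vi, 0), max(vj, 0))
  }

  while (length(sub) > 3L) {
    r <- length(sub)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    joins[[length(joins) + 1L]] <- c(vi_raw = vi, vj_raw = vj)
    v <- clamp2(vi, vj)
    new_sub <- sprintf("(%s:%.17g,%s:%.17g)", sub[i], v[1L], sub[j], v[2L])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D[i, ] <- dnew; D[, i] <- dnew; D[i, i] <- 0
    keep <- setdiff(seq_len(r), j)
    D <- D[keep, keep, drop = FALSE]
    sub[i] <- new_sub
    sub <- sub[-j]
  }
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  v1 <- max((d12 + d13 - d23) / 2, 0)
  v2 <- max((d12 + d23 - d13) / 2, 0)
  v3 <- max((d13 + d23 - d12) / 2, 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 sub[1L], v1, sub[2L], v2, sub[3L], v3)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "raw_joins") <- do.call(rbind, joins)
  tree
}

# Canonical bipartition keys of the internal edges of a tree, as
# "lab1|lab2|..." strings over the side NOT containing the alphabetically
# first tip label. Invariant under rerooting.
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (k in seq_along(pp)) {
    tips <- labs[pp[[k]]]
    side <- if (anchor %in% tips) setdiff(labs, tips) else tips
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for the internal edges of an NJ tree
#'
#' Resamples alignment columns with replacement (length preserved), rebuilds
#' the NJ tree for each replicate, and reports for every internal bipartition
#' of the original-data tree the percentage of replicates containing it.
#' Replicates whose distance matrix fails (e.g. K2P saturation) are dropped
#' with a message; losing more than 10% of replicates is an error.
#'
#' @param set An `aligned_set` (or plain character matrix with row names).
#' @param B Number of replicates (>= 1).
#' @param seed RNG seed.
#' @param distance_fn Function mapping a character matrix to a distance
#'   matrix (default [k2p_matrix()]).
#' @return A list with `tree` (the original NJ tree, `node.label` set to the
#'   integer support percentages, `""` at the root), `support` (named vector
#'   keyed by bipartition), `B` and `B_used`.
#' @export
bootstrap_support <- function(set, B = 1000L, seed = 1L,
                              distance_fn = k2p_matrix) {
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  m <- unclass(set)[seq_len(nrow(set)), , drop = FALSE]
  tree <- nj_tree(distance_fn(m))
  orig <- tree_splits(tree)
  hits <- stats::setNames(numeric(length(orig)), orig)
  L <- ncol(m)
  set.seed(seed)
  used <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_splits <- tryCatch(tree_splits(nj_tree(distance_fn(m[, cols, drop = FALSE]))),
                           error = function(e) NULL)
    if (is.null(rep_splits)) next
    used <- used + 1L
    hits[orig %in% rep_splits] <- hits[orig %in% rep_splits] + 1
  }
  if (used < 0.9 * B)
    stop(B - used, " of ", B, " bootstrap replicates dropped", call. = FALSE)
  if (used < B)
    message(B - used, " bootstrap replicate(s) dropped (distance failure)")
  support <- round(100 * hits / used)
  list(tree = annotate_supports(tree, support), support = support,
       B = B, B_used = used)
}

#' Attach bipartition supports to a tree's node labels
#'
#' Matches each internal node's bipartition against a named support vector
#' (as produced by [bootstrap_support()]) and writes the value into
#' `node.label`. Because the match is by bipartition, the annotation is
#' stable under rerooting.
#'
#' @param tree A `phylo` object.
#' @param support Named numeric vector keyed by bipartition string.
#' @return The tree with `node.label` filled (empty where no support known).
#' @export
annotate_supports <- function(tree, support) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  node_lab <- character(tree$Nnode)
  for (k in seq_along(pp)) {
    tips <- labs[pp[[k]]]
    side <- if (anchor %in% tips) setdiff(labs, tips) else tips
    if (length(side) < 2L || length(side) > ntip - 2L) next
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) node_lab[k] <- as.character(support[[key]])
  }
  tree$node.label <- node_lab
  tree
}

#' Root a tree on an outgroup
#'
#' Roots the tree at the midpoint of the outgroup's pendant edge. Bipartition
#' supports in `node.label` survive because they are re-matched by split
#' (see [annotate_supports()]).
#'
#' @param tree A `phylo` object.
#' @param outgroup A tip label present in the tree.
#' @return A rooted `phylo` object with a two-child root.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!(outgroup %in% tree$tip.label))
    stop("outgroup '", outgroup, "' is not a tip of the tree", call. = FALSE)
  support <- NULL
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    keys <- tree_split_keys_by_node(tree)
    keep <- !is.na(keys) & lab != ""
    support <- stats::setNames(suppressWarnings(as.numeric(lab[keep])), keys[keep])
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  # split the outgroup pendant edge evenly across the two root edges
  root_node <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1L] == root_node)
  if (length(re) == 2L) {
    total <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- total / 2
  }
  if (!is.null(support)) rooted <- annotate_supports(rooted, support)
  rooted
}

# Split key for each internal node (parallel to node.label); NA where the
# node does not define an internal bipartition.
tree_split_keys_by_node <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  vapply(seq_along(pp), function(k) {
    tips <- labs[pp[[k]]]
    side <- if (anchor %in% tips) setdiff(labs, tips) else tips
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with six decimals and internal node labels
#' (bootstrap supports) verbatim; output round-trips through
#' [read_newick()].
#'
#' @param tree A `phylo` object.
#' @param path Optional output path; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- tree$tip.label[node]
    } else {
      ch <- kids[[as.character(node)]]
      s <- paste0("(",
                  paste(vapply(ch, function(e) fmt(tree$edge[e, 2L], e),
                               character(1)), collapse = ","),
                  ")")
      if (!is.null(tree$node.label)) s <- paste0(s, tree$node.label[node - ntip])
    }
    if (!is.null(edge_idx)) s <- paste0(s, sprintf(":%.6f", tree$edge.length[edge_idx]))
    s
  }
  nwk <- paste0(fmt(root, NULL), ";")
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}

#' Read a Newick tree
#'
#' @param x A Newick string or a path to a file containing one.
#' @return A `phylo` object.
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}
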