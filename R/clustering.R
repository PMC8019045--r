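# Agglomerative clustering of core units on association similarity.
#
# Clustering merges the most-similar pair first; internally this is ordinary
# agglomerative clustering on the distance d = 1 - AI, with merge heights
# mapped back to the AI scale so that the clan cutoff (default 0.05) keeps
# its meaning as an association index. Ward's method uses the standard
# recurrence on that (non-Euclidean) distance without checking Euclidean
# embeddability, mirroring common practice in field toolchains.

LINKAGES <- c(average = "average", ward = "ward.D", complete = "complete",
              single = "single")

#' Build a cluster tree over units
#'
#' @param x an `assoc_matrix` (undefined dyads enter as similarity 0) or a
#'   symmetric numeric similarity matrix with unit names.
#' @param linkage one of `"average"`, `"ward"`, `"complete"`, `"single"`.
#' @return a `clan_tree`: the underlying `hclust` object plus `height_ai`
#'   (merge heights on the AI scale, `1 - distance height`) and the linkage
#'   name. Merge-order ties are broken deterministically by presenting units
#'   in lexicographic order.
#' @export
build_tree <- function(x, linkage = c("average", "ward", "complete", "single")) {
  linkage <- match.arg(linkage)
  sim <- as_similarity(x)
  ord <- order(rownames(sim))
  sim <- sim[ord, ord]
  hc <- stats::hclust(stats::as.dist(1 - sim), method = LINKAGES[[linkage]])
  structure(
    list(hclust = hc, height_ai = 1 - hc$height, linkage = linkage,
         leaves = hc$labels),
    class = "clan_tree"
  )
}

as_similarity <- function(x) {
  if (inherits(x, "assoc_matrix")) {
    sim <- x$ai
    sim[!x$defined] <- 0
    diag(sim) <- 1
    return(sim)
  }
  if (!is.matrix(x) || !isSymmetric(unname(x))) {
    stop("`x` must be an assoc_matrix or a symmetric similarity matrix",
         call. = FALSE)
  }
  if (is.null(rownames(x))) {
    rownames(x) <- colnames(x) <- paste0("U", seq_len(nrow(x)))
  }
  x
}

#' @export
print.clan_tree <- function(x, ...) {
  cat(sprintf("Cluster tree: %d units, %s linkage; merge heights (AI) %s\n",
              length(x$leaves), x$linkage,
              paste(sprintf("%.3f", sort(x$height_ai, decreasing = TRUE)),
                    collapse = ", ")))
  invisible(x)
}

#' Cophenetic correlation of a tree with its input matrix
#'
#' Pearson correlation, over defined dyads, between the input association
#' indices and the cophenetic similarities implied by the tree (the AI-scale
#' height of the lowest merge joining the two units). A constant input
#' (zero variance on either side) has no defined correlation and returns
#' `NA` with a warning.
#'
#' @param tree a `clan_tree` whose leaves match the matrix units.
#' @param x the `assoc_matrix` (or similarity matrix) the tree was built on.
#' @return correlation in `[-1, 1]`, or `NA` when degenerate.
#' @export
cophenetic_correlation <- function(tree, x) {
  sim <- as_similarity(x)
  if (!setequal(rownames(sim), tree$leaves)) {
    stop("tree leaves and matrix units differ", call. = FALSE)
  }
  defined <- if (inherits(x, "assoc_matrix")) x$defined else !is.na(sim)
  coph <- 1 - as.matrix(stats::cophenetic(tree$hclust))
  coph <- coph[rownames(sim), colnames(sim)]
  keep <- upper.tri(sim) & defined
  if (sum(keep) < 3) stop("need at least 3 defined dyads", call. = FALSE)
  a <- sim[keep]
  b <- coph[keep]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("degenerate input: zero variance, cophenetic correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Select the best-fitting linkage by cophenetic correlation
#'
#' Evaluates all four linkages and returns the one with the highest
#' cophenetic correlation coefficient (CCC); exact ties resolve in the fixed
#' order average, ward, complete, single.
#'
#' @inheritParams build_tree
#' @return list with `linkage` (chosen name), `tree` (its `clan_tree`), and
#'   `ccc` (tibble of linkage and CCC for all four).
#' @export
select_linkage <- function(x) {
  sim <- as_similarity(x)
  if (nrow(sim) < 3) stop("need at least 3 units", call. = FALSE)
  linkages <- names(LINKAGES)
  trees <- lapply(linkages, function(l) build_tree(x, l))
  ccc <- vapply(trees, function(tr) cophenetic_correlation(tr, x), 1)
  best <- which.max(ccc)   # first max wins -> fixed tie order
  list(
    linkage = linkages[best],
    tree = trees[[best]],
    ccc = tibble::tibble(linkage = linkages, ccc = ccc)
  )
}

#' Cut a tree into clans at an AI threshold
#'
#' Units connected by merges at AI-scale height `>= cutoff` share a clan;
#' units whose every connection is weaker form singleton clans (the pattern
#' of an all-male unit in loose association with the main clans).
#'
#' @param tree a `clan_tree`.
#' @param cutoff AI threshold in (0, 1); default 0.05.
#' @return a `clan_partition` tibble: `unit`, `clan` (labels `"C1"`, `"C2"`,
#'   ... in order of first appearance), with the cutoff as an attribute.
#' @export
cut_clans <- function(tree, cutoff = 0.05) {
  if (!(cutoff > 0 && cutoff < 1)) stop("`cutoff` must lie in (0, 1)", call. = FALSE)
  # union of all merges at or above the cutoff (robust to the tiny height
  # inversions floating-point ties can produce, where cutree would fail)
  hc <- tree$hclust
  n <- length(hc$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_members <- vector("list", nrow(hc$merge))
  side <- function(v) if (v < 0) -v else cluster_members[[v]]
  for (m in seq_len(nrow(hc$merge))) {
    cluster_members[[m]] <- c(side(hc$merge[m, 1]), side(hc$merge[m, 2]))
  }
  for (m in seq_len(nrow(hc$merge))) {
    if (tree$height_ai[m] >= cutoff) {
      l <- side(hc$merge[m, 1])[1]; r <- side(hc$merge[m, 2])[1]
      ri <- find(r); parent[ri] <- find(l)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  k <- stats::setNames(match(roots, unique(roots)), hc$labels)
  labels <- paste0("C", match(k, unique(k[order(names(k))])))
  out <- tibble::tibble(unit = names(k), clan = labels)
  out <- out[order(out$unit), ]
  attr(out, "cutoff") <- cutoff
  class(out) <- c("clan_partition", class(out))
  out
}

#' Compare two clan partitions
#'
#' The adjusted Rand index (ARI) over the shared units measures agreement up
#' to label permutation (1 = identical grouping). `moved_units` lists the
#' units whose co-membership profile changed: units that, relative to the
#' other period, gained or lost at least one clan-mate among the shared
#' units.
#'
#' @param p1,p2 `clan_partition` tibbles (or any unit/clan data frames).
#' @return list with `ari` and `moved_units`.
#' @export
compare_partitions <- function(p1, p2) {
  shared <- intersect(p1$unit, p2$unit)
  if (!length(shared)) stop("partitions share no units", call. = FALSE)
  a <- p1$clan[match(shared, p1$unit)]
  b <- p2$clan[match(shared, p2$unit)]
  # minimal set of units whose removal reconciles the two partitions:
  # greedily peel the unit with the most co-membership disagreements
  keep <- seq_along(shared)
  moved <- character(0)
  repeat {
    co_a <- outer(a[keep], a[keep], "==")
    co_b <- outer(b[keep], b[keep], "==")
    dis <- colSums(co_a != co_b)
    if (!any(dis > 0)) break
    worst <- keep[which.max(dis)]
    moved <- c(moved, shared[worst])
    keep <- setdiff(keep, worst)
  }
  list(ari = adjusted_rand(a, b), moved_units = sort(moved))
}

# Adjusted Rand index from the pair-counting form.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Export a cluster tree
#'
#' `tree_newick()` renders the merge tree as a Newick string whose node
#' heights are on the AI similarity scale (leaf branch lengths measured from
#' similarity 1); `write_merge_table()` writes the merge list as CSV;
#' `write_partition()` writes a `unit,clan` CSV.
#'
#' @param tree a `clan_tree`.
#' @return a Newick string.
#' @export
tree_newick <- function(tree) {
  hc <- tree$hclust
  h_ai <- tree$height_ai
  node <- function(i) {
    if (i < 0) return(list(label = hc$labels[-i], h = 1))
    l <- node(hc$merge[i, 1])
    r <- node(hc$merge[i, 2])
    lab <- sprintf("(%s:%.6g,%s:%.6g)", l$label, l$h - h_ai[i], r$label,
                   r$h - h_ai[i])
    list(label = lab, h = h_ai[i])
  }
  top <- node(nrow(hc$merge))
  paste0(top$label, ";")
}

#' @rdname tree_newick
#' @param path output path.
#' @export
write_merge_table <- function(tree, path) {
  hc <- tree$hclust
  utils::write.csv(data.frame(
    merge = seq_along(tree$height_ai),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height_ai = tree$height_ai
  ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tree_newick
#' @param partition a `clan_partition`.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(as.data.frame(partition[, c("unit", "clan")]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
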