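# Distance-based clustering of screened cystatins: pairwise distances from an
# externally produced alignment, a neighbor-joining tree, and a k-group cut on
# the longest internal edges.

#' Pairwise distances between aligned proteins
#'
#' p-distance = mismatches / compared columns, where any column with a gap in
#' either sequence is excluded; the Poisson-corrected distance is
#' `-ln(1 - p)`.
#'
#' @param aligned Named character vector (or list of [protein_record()]s) of
#'   equal-length aligned sequences; `-` and `.` are gaps.
#' @param model `"p"` or `"poisson"`.
#' @return A `"distance_matrix"`: list with `labels` and symmetric matrix `d`.
#' @export
pairwise_distance <- function(aligned, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (is.list(aligned)) {
    labs <- vapply(aligned, `[[`, "", "id")
    aligned <- stats::setNames(vapply(aligned, `[[`, "", "aa_seq"), labs)
  }
  labs <- names(aligned)
  if (is.null(labs)) labs <- paste0("seq", seq_along(aligned))
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) stop("aligned sequences must be equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  is_gap <- mat == "-" | mat == "."
  n <- length(aligned)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- !is_gap[i, ] & !is_gap[j, ]
      if (!any(keep)) stop(sprintf("no comparable columns for %s vs %s",
                                   labs[i], labs[j]))
      p <- mean(mat[i, keep] != mat[j, keep])
      if (model == "poisson") {
        if (p >= 1) stop(sprintf("infinite Poisson distance for %s vs %s",
                                 labs[i], labs[j]))
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  structure(list(labels = labs, d = d), class = "distance_matrix")
}

as_distance_matrix <- function(x) {
  if (inherits(x, "distance_matrix")) return(x)
  if (inherits(x, "dist")) x <- as.matrix(x)
  stopifnot(is.matrix(x), isTRUE(all.equal(x, t(x))), all(diag(x) == 0),
            all(is.finite(x)))
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(x)))
  dimnames(x) <- list(labs, labs)
  structure(list(labels = labs, d = x), class = "distance_matrix")
}

#' Neighbor-joining tree
#'
#' Saitou–Nei agglomeration (exact on additive matrices). Any negative branch
#' length is clamped to zero with the deficit shifted to its sister edge.
#'
#' @param dm A [pairwise_distance()] result, a symmetric matrix, or a `dist`.
#' @return An [ape::ape-package] `phylo` tree (unrooted for >= 3 leaves).
#' @export
nj_tree <- function(dm) {
  dm <- as_distance_matrix(dm)
  if (length(dm$labels) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(dm$d))
  clamp_negative_edges(tr)
}

# Zero out negative edge lengths, moving the deficit to the sister edge
# (the other edge sharing the same parent node), so path lengths through the
# parent are preserved as far as possible.
clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
      if (tr$edge.length[sibs[1]] < 0) tr$edge.length[sibs[1]] <- 0
    }
  }
  tr
}

#' Cut a tree into k groups on its longest internal edges
#'
#' Removes the k-1 longest internal edges (ties broken lexicographically by
#' the edge's node pair) and returns the connected components' leaf sets.
#'
#' @param tree A `phylo` object.
#' @param k Number of groups, `1 <= k <=` leaf count.
#' @return Named character vector: leaf label -> group id (`"g1"`, `"g2"`, ...
#'   ordered by each group's first leaf in label order).
#' @export
cut_groups <- function(tree, k) {
  n_tip <- length(tree$tip.label)
  stopifnot(k >= 1, k <= n_tip)
  internal <- which(tree$edge[, 1] > n_tip & tree$edge[, 2] > n_tip)
  if (k - 1 > length(internal)) {
    stop(sprintf("tree has %d internal edges; cannot cut into %d groups",
                 length(internal), k))
  }
  key <- sprintf("%06d-%06d", tree$edge[internal, 1], tree$edge[internal, 2])
  ord <- internal[order(-tree$edge.length[internal], key)]
  drop <- ord[seq_len(k - 1)]
  # components of the node graph without the dropped edges
  keep_edges <- tree$edge[setdiff(seq_len(nrow(tree$edge)), drop), , drop = FALSE]
  n_nodes <- max(tree$edge)
  comp <- seq_len(n_nodes)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (r in seq_len(nrow(keep_edges))) {
    a <- find(keep_edges[r, 1]); b <- find(keep_edges[r, 2])
    if (a != b) comp[b] <- a
  }
  tip_comp <- vapply(seq_len(n_tip), find, 0L)
  ord_tips <- order(tree$tip.label)
  group_of <- stats::setNames(rep(NA_character_, n_tip), tree$tip.label)
  next_id <- 1L
  seen <- integer(0)
  for (i in ord_tips) {
    if (!tip_comp[i] %in% seen) {
      seen <- c(seen, tip_comp[i])
    }
  }
  ids <- stats::setNames(paste0("g", seq_along(seen)), seen)
  group_of[] <- ids[as.character(tip_comp)]
  group_of
}

#' Path-length (patristic) distances on a tree
#'
#' @param tree A `phylo` object.
#' @return Symmetric matrix of leaf-to-leaf path lengths.
#' @export
tree_distances <- function(tree) {
  stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
}
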