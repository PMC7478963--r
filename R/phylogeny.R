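# Phylogeny: exhaustive enumeration of subclone trees under the prevalence
# ordering rule (a child's peak prevalence cannot exceed its parent's) and
# the sum rule (a parent's prevalence must cover the sum of its children's,
# leaving a non-negative own fraction phi).

#' Enumerate all valid subclone trees
#'
#' Subclones are labelled `1..C` in decreasing order of peak prevalence; the
#' largest peak (the founding clone, prevalence = purity) is the root. All
#' parent assignments `parent[j] < j` are enumerated and a tree is kept when
#' every node's own fraction `phi_j = rho_j - sum(rho of children)` is
#' non-negative. The descending chain is always valid, so at least one tree
#' is returned.
#'
#' @param peaks subclone peak prevalences, sorted decreasing.
#' @param cap enumeration cap on the number of subclones (default 8; the
#'   number of parent assignments grows as `(C-1)!`).
#' @return a list of trees; each tree is a list with `parent` (root's parent
#'   encoded as 0, the normal-cell population), `proportions` (`phi_j`),
#'   `peaks`, and `rank_score` (filled by [rank_trees()]).
#' @examples
#' length(enumerate_trees(c(0.8, 0.5, 0.2)))  # 2: chain and star
#' length(enumerate_trees(c(0.8, 0.5, 0.4)))  # 1: only the chain
#' @export
enumerate_trees <- function(peaks, cap = 8) {
  C <- length(peaks)
  if (C == 0) stop("cannot build a tree with zero subclones")
  if (is.unsorted(rev(peaks), strictly = FALSE)) {
    stop("peaks must be sorted in decreasing order")
  }
  if (C > cap) {
    stop("tree enumeration capped at ", cap, " subclones (got ", C, ")")
  }
  if (C == 1) {
    return(list(list(parent = 0L, proportions = peaks[1], peaks = peaks,
                     rank_score = NA_real_)))
  }
  choices <- lapply(2:C, function(j) seq_len(j - 1L))
  grid <- do.call(expand.grid, choices)
  trees <- list()
  for (i in seq_len(nrow(grid))) {
    parent <- c(0L, as.integer(unlist(grid[i, ])))
    child_sum <- numeric(C)
    for (j in 2:C) {
      child_sum[parent[j]] <- child_sum[parent[j]] + peaks[j]
    }
    phi <- peaks - child_sum
    if (all(phi >= -1e-9)) {
      trees[[length(trees) + 1L]] <- list(
        parent = parent, proportions = pmax(phi, 0), peaks = peaks,
        rank_score = NA_real_)
    }
  }
  trees
}

tree_depth <- function(parent) {
  depth <- integer(length(parent))
  for (j in seq_along(parent)) {
    d <- 1L
    p <- parent[j]
    while (p != 0L) {
      d <- d + 1L
      p <- parent[p]
    }
    depth[j] <- d
  }
  max(depth)
}

#' Rank candidate trees by SNV load
#'
#' Later subclones tend to carry more mutations (genome instability
#' accumulates as the tumor progresses), so trees placing SNV-rich clones
#' deeper are preferred: each tree scores `+1` for every edge whose child
#' carries more SNVs than its parent, `-1` when fewer, `0` on ties. Ties in
#' the score prefer the deeper tree (the chain first), then the original
#' enumeration order, making the ranking deterministic.
#'
#' @param trees list of trees from [enumerate_trees()].
#' @param snv_support SNV count per subclone (from [assign_all()]).
#' @return the list of trees sorted best-first, each with `rank_score` set.
#' @export
rank_trees <- function(trees, snv_support) {
  if (length(trees) == 0) stop("no trees to rank")
  scores <- vapply(trees, function(tr) {
    child <- which(tr$parent != 0L)
    if (length(child) == 0) return(0)
    sum(sign(snv_support[child] - snv_support[tr$parent[child]]))
  }, numeric(1))
  depths <- vapply(trees, function(tr) tree_depth(tr$parent), integer(1))
  ord <- order(-scores, -depths, seq_along(trees))
  out <- trees[ord]
  for (i in seq_along(out)) out[[i]]$rank_score <- scores[ord][i]
  out
}

#' Ancestor matrix of a subclone tree
#'
#' @param tree a tree from [enumerate_trees()] (or any list with a `parent`
#'   vector, root's parent 0).
#' @return a `C x C` 0/1 matrix with `A[i, j] = 1` iff subclone `i` is a
#'   strict ancestor of subclone `j`.
#' @export
ancestor_matrix <- function(tree) {
  parent <- if (is.list(tree)) tree$parent else tree
  C <- length(parent)
  A <- matrix(0, C, C)
  for (j in seq_len(C)) {
    p <- parent[j]
    while (p != 0L) {
      A[p, j] <- 1
      p <- parent[p]
    }
  }
  A
}
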