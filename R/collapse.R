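# Test #1: collapse weakly supported branches and ask whether the two
# candidate fragments become sister leaves.
#
# Rationale: two fragments of one gene share no columns, so the alignment
# carries no signal about their relative placement; they attach close to
# the same point of the tree but are separated by short, weakly supported
# branches. Erasing all branches whose support falls below a threshold
# should therefore merge them into a common polytomy, whereas genuinely
# distinct paralogs stay separated by well-supported branches.

#' Collapse internal branches with low support
#'
#' Every internal branch whose support is strictly below `threshold` is
#' contracted (its children reattach to the grandparent, keeping their own
#' branch lengths), possibly yielding multifurcations. Leaf branches are
#' never contracted; missing supports count as 1 (never collapsed). The
#' tree is treated as unrooted: a degree-2 root is suppressed first.
#'
#' @param tree [ape::phylo] with supports on internal node labels (both
#'   [0,1] and percentage dialects accepted).
#' @param threshold Collapse threshold in [0,1].
#' @return The collapsed tree, with attribute `n_collapsed` (number of
#'   contracted branches).
#' @examples
#' tr <- read_newick("((A:1,(f1:1,f2:1)0.5:1)0.99:1,B:1,C:1);")
#' ape::Nnode(collapse_low_support(tr, 0.95))
#' @export
collapse_low_support <- function(tree, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  tr <- safe_unroot(tree)
  ntip <- ape::Ntip(tr)
  if (ntip <= 2L || tr$Nnode <= 1L) {
    attr(tr, "n_collapsed") <- 0L
    return(tr)
  }
  root <- unique(setdiff(tr$edge[, 1L], tr$edge[, 2L]))
  sup <- tree_supports(tr, missing = 1)        # node order ntip+1, ...
  internal <- seq.int(ntip + 1L, ntip + tr$Nnode)
  contract <- internal[internal != root & sup[internal - ntip] < threshold]
  parent <- integer(ntip + tr$Nnode)
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]
  elen <- numeric(ntip + tr$Nnode)
  elen[tr$edge[, 2L]] <- tr$edge.length
  final_parent <- function(v) {
    p <- parent[v]
    while (p %in% contract) p <- parent[p]
    p
  }
  keep_internal <- setdiff(internal, contract)
  kids <- lapply(stats::setNames(keep_internal, keep_internal), function(x) integer(0))
  for (v in c(seq_len(ntip), setdiff(keep_internal, root))) {
    p <- as.character(final_parent(v))
    kids[[p]] <- c(kids[[p]], v)
  }
  labs <- if (is.null(tr$node.label)) rep("", tr$Nnode) else tr$node.label
  fmt <- function(v) {
    if (v <= ntip) return(sprintf("%s:%.12g", tr$tip.label[v], elen[v]))
    inner <- paste(vapply(kids[[as.character(v)]], fmt, character(1)),
                   collapse = ",")
    lab <- labs[v - ntip]
    if (v == root) sprintf("(%s)%s", inner, lab)
    else sprintf("(%s)%s:%.12g", inner, lab, elen[v])
  }
  out <- ape::read.tree(text = paste0(fmt(root), ";"))
  attr(out, "n_collapsed") <- length(contract)
  out
}

#' Are two leaves sisters?
#'
#' TRUE when both leaves attach to the same node of the unrooted tree;
#' polytomies count, so any two members of a common multifurcation are
#' sisters.
#'
#' @param tree [ape::phylo].
#' @param id1,id2 Leaf labels.
#' @return Logical scalar.
#' @export
are_sister_leaves <- function(tree, id1, id2) {
  tr <- safe_unroot(tree)
  i1 <- match(id1, tr$tip.label)
  i2 <- match(id2, tr$tip.label)
  if (is.na(i1)) stop("leaf not in tree: ", id1)
  if (is.na(i2)) stop("leaf not in tree: ", id2)
  if (ape::Ntip(tr) == 2L) return(TRUE)
  p1 <- tr$edge[tr$edge[, 2L] == i1, 1L]
  p2 <- tr$edge[tr$edge[, 2L] == i2, 1L]
  p1 == p2
}

#' Collapse test for a candidate pair
#'
#' Collapses branches below `threshold` and calls the pair a split gene
#' if the two fragments end up as sister leaves.
#'
#' @param tree Family tree with branch supports covering both ids.
#' @param id1,id2 Candidate fragment ids (leaves of `tree`).
#' @param threshold Support threshold in [0,1] (default 0.95; branches
#'   with support `< threshold` are collapsed, support equal to the
#'   threshold survives).
#' @return An object of class `collapse_result`: list with `id1`, `id2`,
#'   `threshold`, `collapsed_tree`, `n_collapsed`, `is_split`.
#' @export
collapse_test <- function(tree, id1, id2, threshold = 0.95) {
  ct <- collapse_low_support(tree, threshold)
  structure(list(id1 = id1, id2 = id2, threshold = threshold,
                 collapsed_tree = ct,
                 n_collapsed = attr(ct, "n_collapsed"),
                 is_split = are_sister_leaves(ct, id1, id2)),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("Collapse test (threshold %.2f): %s / %s -> %s (%d branch(es) collapsed)\n",
              x$threshold, x$id1, x$id2,
              if (x$is_split) "sister leaves: SPLIT" else "not sisters",
              x$n_collapsed))
  invisible(x)
}
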