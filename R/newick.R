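# Newick tree I/O with branch supports as internal node labels.
#
# Both support dialects occur in the wild: proportions in [0,1]
# (e.g. FastTree local supports) and percentages in (1,100] (classical
# bootstrap). Values above 1 are divided by 100 on input so downstream
# thresholds always work on [0,1].

#' Read a Newick tree
#'
#' Internal node labels that parse as numbers are interpreted as branch
#' supports and normalized to the [0,1] scale (values > 1 are divided
#' by 100). Non-numeric labels are left untouched.
#'
#' @param path Path to a Newick file, or a Newick string (must contain
#'   `;`).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else {
    stopifnot(file.exists(path))
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  check_newick_syntax(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick input")
  normalize_supports(tr)
}

# Cheap pre-parse so malformed input fails with a character offset rather
# than an opaque parser state.
check_newick_syntax <- function(txt) {
  ch <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "(") depth <- depth + 1L
    if (ch[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at character ", i, " of Newick input")
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' in Newick input (", depth, " unclosed)")
  bad <- regexpr(":[^0-9eE+.,();-]", txt)
  if (bad > 0L)
    stop("non-numeric branch length at character ", bad, " of Newick input")
  invisible(TRUE)
}

normalize_supports <- function(tr) {
  if (!is.null(tr$node.label)) {
    v <- suppressWarnings(as.numeric(tr$node.label))
    num <- !is.na(v)
    v[num & v > 1] <- v[num & v > 1] / 100
    if (any(num & (v < 0 | v > 1), na.rm = TRUE))
      stop("branch support outside [0,100]")
    tr$node.label[num] <- format_support(v[num])
  }
  tr
}

format_support <- function(x) sub("\\.$", "", sub("0+$", "", sprintf("%.10f", x)))

#' Branch supports of a tree
#'
#' @param tree An [ape::phylo] tree.
#' @param missing Value substituted for absent/non-numeric node labels.
#'   The conservative default 1 means "never collapsed".
#' @return Numeric vector of supports in [0,1], one per internal node, in
#'   node order (`Ntip+1`, `Ntip+2`, ...).
#' @export
tree_supports <- function(tree, missing = 1) {
  n_int <- tree$Nnode
  out <- rep(missing, n_int)
  if (!is.null(tree$node.label)) {
    v <- suppressWarnings(as.numeric(tree$node.label))
    v[!is.na(v) & v > 1] <- v[!is.na(v) & v > 1] / 100
    out[!is.na(v)] <- v[!is.na(v)]
  }
  out
}

#' Write a tree to a Newick file
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# Unrooted view of a tree: a degree-2 root introduced by a builder is
# contracted; trees with <= 2 tips pass through.
safe_unroot <- function(tree) {
  if (ape::Ntip(tree) <= 2L) return(tree)
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree
}
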