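# Maximum-likelihood engine: Felsenstein pruning likelihood under an
# empirical amino-acid model, NJ starting trees on ML distances, NNI
# hill-climbing, branch-length optimization and column-resampling
# bootstrap supports. phangorn does the numerics; these wrappers pin the
# contracts the split-gene tests rely on (gaps and X as missing data,
# determinism under an explicit seed, branch lengths in [1e-8, 10]).

BL_MIN <- 1e-8
BL_MAX <- 10

engine_fit <- function(tree, log_likelihood, model, converged = TRUE, pml = NULL) {
  stopifnot(is.finite(log_likelihood))
  structure(list(tree = tree, log_likelihood = log_likelihood,
                 model = model, converged = converged, pml = pml),
            class = "engine_fit")
}

#' @export
print.engine_fit <- function(x, ...) {
  cat(sprintf("ML fit (%s): %d tips, log-likelihood %.4f\n",
              x$model, ape::Ntip(x$tree), x$log_likelihood))
  invisible(x)
}

check_tree_data <- function(tree, msa) {
  if (!setequal(tree$tip.label, names(msa$rows)))
    stop("tree leaves and alignment rows differ: ",
         paste(utils::head(c(setdiff(tree$tip.label, names(msa$rows)),
                             setdiff(names(msa$rows), tree$tip.label)), 3L),
               collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  invisible(TRUE)
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning likelihood, summed over columns on the natural-log
#' scale. Gaps and `X` are missing data (all-ones partial likelihoods), so
#' an all-gap column contributes exactly zero. For reversible models the
#' value is invariant under re-rooting.
#'
#' @param tree [ape::phylo] with branch lengths; leaf set must equal the
#'   alignment's row set.
#' @param msa An [aa_alignment()].
#' @param model Model name (see [aa_model()]).
#' @return Log-likelihood (natural log), a finite scalar.
#' @export
tree_log_likelihood <- function(tree, msa, model = "LG") {
  check_tree_data(tree, msa)
  tree <- safe_unroot(tree)
  fit <- phangorn::pml(tree, as_phydat(msa), model = model)
  ll <- as.numeric(fit$logLik)
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

pml_ctrl <- function(tol) phangorn::pml.control(epsilon = 1e-8, maxit = 25L,
                                                trace = 0L, tau = BL_MIN)

# 2-tip trees: phangorn's optimizer refuses them, so the single distance
# is optimized directly on [BL_MIN, BL_MAX].
fit_two_tip <- function(msa, model, tol) {
  ids <- names(msa$rows)
  data <- as_phydat(msa)
  ll_at <- function(t) {
    tr <- ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);",
                                        ids[1L], t / 2, ids[2L], t / 2))
    as.numeric(phangorn::pml(tr, data, model = model)$logLik)
  }
  opt <- stats::optimize(ll_at, interval = c(BL_MIN, BL_MAX),
                         maximum = TRUE, tol = min(tol, 1e-6))
  t_hat <- opt$maximum
  if (ll_at(BL_MIN) >= opt$objective) t_hat <- BL_MIN
  tr <- ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);",
                                      ids[1L], t_hat / 2, ids[2L], t_hat / 2))
  engine_fit(tr, max(opt$objective, ll_at(BL_MIN)), model)
}

#' Optimize branch lengths on a fixed topology
#'
#' @param tree Starting tree ([ape::phylo], branch lengths required).
#' @param msa An [aa_alignment()] whose rows match the tree's leaves.
#' @param model Model name.
#' @param tol Convergence tolerance in log-likelihood units.
#' @return An `engine_fit` (tree, `log_likelihood`, model, convergence
#'   flag). The final log-likelihood is never below the starting one.
#' @export
optimize_branch_lengths <- function(tree, msa, model = "LG", tol = 1e-4) {
  check_tree_data(tree, msa)
  if (ape::Ntip(tree) == 2L) return(fit_two_tip(msa, model, tol))
  tree <- clamp_edges(safe_unroot(tree))
  fit <- phangorn::pml(tree, as_phydat(msa), model = model)
  of <- phangorn::optim.pml(fit, optEdge = TRUE, optNni = FALSE,
                            control = pml_ctrl(tol))
  if (!is.finite(of$logLik)) stop("non-finite log-likelihood during optimization")
  engine_fit(of$tree, as.numeric(of$logLik), model, pml = of)
}

clamp_edges <- function(tree) {
  tree$edge.length <- pmin(pmax(tree$edge.length, BL_MIN), BL_MAX)
  tree
}

# ML distances are undefined for row pairs sharing no columns (e.g. two
# fragments of one gene). Such entries are imputed additively through the
# best shared neighbor, d(i,j) = min_k [d(i,k) + d(k,j)], falling back to
# a cap when no neighbor has finite distances to both.
sanitize_dist <- function(d) {
  m <- as.matrix(d)
  diag(m) <- 0
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cap <- if (any(is.finite(m) & m > 0)) max(m[is.finite(m)]) * 1.5 else 1
    cap <- min(cap, BL_MAX)
    fill <- m
    for (r in seq_len(nrow(bad))) {
      i <- bad[r, 1L]; j <- bad[r, 2L]
      thru <- m[i, ] + m[, j]
      thru <- thru[is.finite(thru)]
      fill[i, j] <- if (length(thru) > 0L) min(thru) else cap
    }
    m <- fill
  }
  stats::as.dist(m)
}

# Pairwise ML distances with undefined pairs marked missing: two rows
# sharing no residue-bearing column have no pairwise information at all
# (dist.ml silently returns 0 for them), so those entries are set NA and
# imputed by sanitize_dist().
ml_distances <- function(msa, model) {
  m <- as.matrix(msa)
  occ <- m != "-" & m != "X"
  shared <- tcrossprod(occ * 1L)
  d <- as.matrix(phangorn::dist.ml(as_phydat(msa), model = model))
  d[shared[rownames(d), colnames(d)] == 0L] <- NA_real_
  diag(d) <- 0
  sanitize_dist(stats::as.dist(d))
}

#' Build a maximum-likelihood tree
#'
#' Without a starting tree: neighbor joining on maximum-likelihood
#' pairwise distances, followed by NNI hill-climbing with branch-length
#' re-optimization until no rearrangement improves the log-likelihood.
#' With a starting tree: NNI search from that topology. Deterministic
#' given `seed`.
#'
#' @param msa An [aa_alignment()] with at least two rows.
#' @param model Model name.
#' @param start Optional starting tree covering the alignment's rows.
#' @param seed Optional integer seed.
#' @param optimize_topology Run the NNI search (default TRUE); FALSE
#'   optimizes branch lengths only.
#' @param tol Convergence tolerance in log-likelihood units.
#' @return An `engine_fit`.
#' @export
build_tree <- function(msa, model = "LG", start = NULL, seed = NULL,
                       optimize_topology = TRUE, tol = 1e-4) {
  stopifnot(inherits(msa, "aa_alignment"))
  n <- length(msa$rows)
  if (n < 2L) stop("need at least 2 sequences to build a tree")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n == 2L) return(fit_two_tip(msa, model, tol))
  data <- as_phydat(msa)
  if (is.null(start)) {
    tr <- ape::nj(ml_distances(msa, model))
  } else {
    if (!setequal(start$tip.label, names(msa$rows)))
      stop("starting tree does not cover the alignment rows")
    tr <- start
  }
  tr <- clamp_edges(safe_unroot(tr))
  fit <- phangorn::pml(tr, data, model = model)
  of <- phangorn::optim.pml(fit, optEdge = TRUE,
                            optNni = optimize_topology && n > 3L,
                            control = pml_ctrl(tol))
  if (!is.finite(of$logLik)) stop("non-finite log-likelihood during tree search")
  engine_fit(of$tree, as.numeric(of$logLik), model, pml = of)
}

#' Bootstrap branch supports by column resampling
#'
#' Classical (Felsenstein) bootstrap: columns are resampled with
#' replacement `n_reps` times, a tree is rebuilt per replicate, and each
#' internal branch of `tree` gets as support the fraction of replicate
#' trees containing the same bipartition. Replicate `r` draws with seed
#' `seed + r`.
#'
#' @param msa An [aa_alignment()].
#' @param tree Tree whose internal branches are annotated (built from
#'   `msa`).
#' @param model Model name.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param rebuild `"nj"` (default): replicate trees by NJ on ML distances;
#'   `"search"`: full NNI search per replicate.
#' @return The tree with supports in [0,1] written to `node.label` (root
#'   label empty).
#' @export
bootstrap_supports <- function(msa, tree, model = "LG", n_reps = 100L,
                               seed = 1L, rebuild = c("nj", "search")) {
  rebuild <- match.arg(rebuild)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  tree <- safe_unroot(tree)
  check_tree_data(tree, msa)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(as.integer(seed) + r)
    idx <- sample.int(msa$n_cols, msa$n_cols, replace = TRUE)
    rep_aln <- aln_cols(msa, idx)
    if (rebuild == "search") {
      reps[[r]] <- build_tree(rep_aln, model = model)$tree
    } else {
      reps[[r]] <- clamp_edges(safe_unroot(ape::nj(ml_distances(rep_aln, model))))
    }
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- counts / n_reps
  lab <- format_support(sup)
  lab[1L] <- ""  # root pseudo-node carries no support
  tree$node.label <- lab
  tree
}
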