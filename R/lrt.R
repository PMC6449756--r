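# Test #2: likelihood ratio test of the split-gene hypothesis.
#
# H_s ("split"): the two fragments are pieces of one gene; the family has
# n-1 genes and the fragments are concatenated into a single row. H_p
# ("paralogs"): the fragments are distinct genes; the family has n genes.
# The statistic is T = 2 * [ln L(H_p) - ln L(H_s)], with L() the maximized
# likelihood under each hypothesis. The models are not nested, so the null
# distribution of T is estimated by a non-parametric bootstrap: columns of
# the H_s (merged) alignment are resampled with replacement, each
# replicate is split back into two fragments by its per-column provenance,
# and the statistic is recomputed. Failure to reject H_s
# (p_B = #{T* >= T0}/n >= alpha) yields the split-gene prediction.

#' Merge two candidate fragments into one alignment row
#'
#' Builds the H_s alignment: the two fragment rows are replaced by a
#' single merged row (`<primary>+<secondary>`), where the primary fragment
#' is the one with more residues (ties: lexicographically smaller id). Per
#' column, the merged row takes the primary's residue where the primary is
#' occupied, else the secondary's, else a gap; a per-column provenance
#' label in {F1, F2, BOTH, NONE} records which fragment contributed, which
#' is what makes column resampling splittable.
#'
#' @param msa Family [aa_alignment()] containing both fragment rows.
#' @param id1,id2 Fragment row ids.
#' @param max_frac Overlap filter bound; merging a pair that fails
#'   [passes_overlap_filter()] is a contract violation and errors.
#' @return An object of class `merged_alignment`: list with `aln` (the
#'   H_s alignment), `provenance` (character vector over columns), `id1`
#'   (primary), `id2` (secondary), `merged_id`, `stats`.
#' @examples
#' msa <- aa_alignment(c(a = "MKLWCVNQRY", b = "AHDEI-----",
#'                       c = "-----FGSTP"))
#' merge_fragments(msa, "b", "c")$aln
#' @export
merge_fragments <- function(msa, id1, id2, max_frac = 0.1) {
  st <- aligned_overlap(msa, id1, id2)
  if (!passes_overlap_filter(st, max_frac))
    stop("pair ", id1, "/", id2, " fails the overlap filter (a12=", st$a12,
         ", l1=", st$l1, ", l2=", st$l2, ")")
  # primary = fragment with more residues; lexicographic tie-break
  if (st$l2 > st$l1 || (st$l1 == st$l2 && id2 < id1)) {
    tmp <- id1; id1 <- id2; id2 <- tmp
    st <- aligned_overlap(msa, id1, id2)
  }
  c1 <- strsplit(aln_row(msa, id1), "", fixed = TRUE)[[1]]
  c2 <- strsplit(aln_row(msa, id2), "", fixed = TRUE)[[1]]
  in1 <- c1 != "-"; in2 <- c2 != "-"
  prov <- rep("NONE", msa$n_cols)
  prov[in1 & !in2] <- "F1"
  prov[!in1 & in2] <- "F2"
  prov[in1 & in2] <- "BOTH"
  merged <- ifelse(in1, c1, ifelse(in2, c2, "-"))
  merged_id <- paste0(id1, "+", id2)
  rows <- msa$rows
  pos <- match(id1, names(rows))
  rows[pos] <- paste(merged, collapse = "")
  names(rows)[pos] <- merged_id
  rows <- rows[names(rows) != id2]
  structure(list(aln = aa_alignment(rows), provenance = prov,
                 id1 = id1, id2 = id2, merged_id = merged_id, stats = st),
            class = "merged_alignment")
}

#' @export
print.merged_alignment <- function(x, ...) {
  cat(sprintf("Merged alignment (H_s): %s [F1=%d, F2=%d, BOTH=%d, NONE=%d]\n",
              x$merged_id, sum(x$provenance == "F1"), sum(x$provenance == "F2"),
              sum(x$provenance == "BOTH"), sum(x$provenance == "NONE")))
  print(x$aln)
  invisible(x)
}

#' Split a merged alignment back into fragment rows
#'
#' Inverse of [merge_fragments()] on F1/F2 columns: the primary fragment
#' receives F1 and BOTH columns, the secondary F2 columns (so on an
#' overlap column the secondary's residue is not recoverable — a
#' documented lossy corner of < 10% of either fragment). Works on
#' column-resampled merged alignments because routing is by provenance
#' label, not by position.
#'
#' @param merged A `merged_alignment` (possibly resampled via
#'   [resample_merged()]).
#' @return An [aa_alignment()] with the fragment rows restored (primary in
#'   place, secondary appended) and all other rows unchanged.
#' @export
split_merged <- function(merged) {
  stopifnot(inherits(merged, "merged_alignment"))
  m <- strsplit(aln_row(merged$aln, merged$merged_id), "", fixed = TRUE)[[1]]
  take1 <- merged$provenance %in% c("F1", "BOTH")
  take2 <- merged$provenance == "F2"
  r1 <- ifelse(take1, m, "-")
  r2 <- ifelse(take2, m, "-")
  rows <- merged$aln$rows
  pos <- match(merged$merged_id, names(rows))
  rows[pos] <- paste(r1, collapse = "")
  names(rows)[pos] <- merged$id1
  rows <- c(rows, stats::setNames(paste(r2, collapse = ""), merged$id2))
  aa_alignment(rows)
}

#' Resample columns of a merged alignment
#'
#' Draws the given columns (with repetition allowed) from the H_s
#' alignment. Two provenance schemes govern how the replicate is later
#' split under H_p:
#'
#' * `"positional"` (default, used by the bootstrap null): the replicate
#'   keeps the *original* provenance pattern by column position — the gene
#'   is split "at the same position as in the original alignment". Column
#'   content and fragment membership are thereby decoupled, which is what
#'   imposes the one-gene null H_s on the replicates: under H_s the
#'   fragments are exchangeable pieces of one sequence, so the
#'   reassignment is distribution-preserving, while any genuine
#'   two-paralog signal is scrambled away.
#' * `"carried"`: each drawn column keeps its own label (pure column
#'   bookkeeping; preserves the observed signal, so it is *not* a null —
#'   useful only for mechanical round-trip checks).
#'
#' @param merged A `merged_alignment`.
#' @param idx Integer column indices (typically a with-replacement draw of
#'   `n_cols` columns).
#' @param provenance `"positional"` or `"carried"`.
#' @return A `merged_alignment` over the resampled columns.
#' @export
resample_merged <- function(merged, idx,
                            provenance = c("positional", "carried")) {
  provenance <- match.arg(provenance)
  prov <- if (provenance == "positional") {
    if (length(idx) != length(merged$provenance))
      stop("positional provenance needs a full-length draw")
    merged$provenance
  } else merged$provenance[idx]
  structure(list(aln = aln_cols(merged$aln, idx),
                 provenance = prov,
                 id1 = merged$id1, id2 = merged$id2,
                 merged_id = merged$merged_id, stats = merged$stats),
            class = "merged_alignment")
}

# Replace the merged leaf of the H_s tree by a (id1, id2) cherry: the stem
# keeps its branch length, the two new pendant branches start near zero.
# Under gaps-as-missing this tree reproduces the H_s likelihood, which is
# what makes the guided H_p search a floor for T0.
graft_cherry <- function(tree, leaf, id1, id2, pendant = 1e-6) {
  w <- match(leaf, tree$tip.label)
  if (is.na(w)) stop("leaf not in tree: ", leaf)
  if (ape::Ntip(tree) == 2L) {
    other <- setdiff(tree$tip.label, leaf)
    stem <- sum(tree$edge.length)
    return(ape::read.tree(text = sprintf(
      "((%s:%.12g,%s:%.12g):%.12g,%s:%.12g);",
      id1, pendant, id2, pendant, stem / 2, other, stem / 2)))
  }
  cherry <- ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g):0;",
                                          id1, pendant, id2, pendant))
  ape::bind.tree(tree, cherry, where = w)
}

#' Likelihood-ratio statistic for a candidate pair
#'
#' Fits H_s by a tree search on the merged alignment, and H_p as the
#' better of (i) a de-novo tree search on the original family alignment
#' and (ii) a guided search started from the H_s tree with the merged leaf
#' replaced by an (id1, id2) cherry (stem keeps its length, pendant
#' branches near zero). The guided start guarantees
#' `T0 >= -2 * optimizer tolerance`.
#'
#' @param msa Family [aa_alignment()] with both fragments as rows.
#' @param id1,id2 Fragment ids.
#' @param model Substitution model name.
#' @param seed Optional integer seed (tree searches are deterministic
#'   given it).
#' @param max_frac Overlap bound forwarded to [merge_fragments()].
#' @param tol Optimizer tolerance in log-likelihood units.
#' @return List with `T0`, `fit_s`, `fit_p_denovo`, `fit_p_guided`,
#'   `log_lik_p` (max of the two H_p searches) and `merged`.
#' @export
lrt_statistic <- function(msa, id1, id2, model = "LG", seed = NULL,
                          max_frac = 0.1, tol = 1e-4) {
  merged <- merge_fragments(msa, id1, id2, max_frac = max_frac)
  fit_s <- build_tree(merged$aln, model = model, seed = seed, tol = tol)
  fit_p_denovo <- build_tree(msa, model = model, seed = seed, tol = tol)
  start <- graft_cherry(fit_s$tree, merged$merged_id, merged$id1, merged$id2)
  fit_p_guided <- build_tree(msa, model = model, start = start, seed = seed,
                             tol = tol)
  log_lik_p <- max(fit_p_denovo$log_likelihood, fit_p_guided$log_likelihood)
  list(T0 = 2 * (log_lik_p - fit_s$log_likelihood),
       fit_s = fit_s, fit_p_denovo = fit_p_denovo,
       fit_p_guided = fit_p_guided, log_lik_p = log_lik_p, merged = merged)
}

#' Bootstrap null distribution of the LRT statistic
#'
#' Each replicate draws `n_cols` columns of the merged (H_s) alignment
#' with replacement (replicate `i` uses seed `seed + i`), splits the
#' replicate at the original positions for H_p (see [resample_merged()]:
#' positional provenance is what makes the replicates a *null*
#' distribution), and recomputes the statistic. Two
#' replicate-fitting modes: `"full"` repeats the complete machinery (tree
#' searches under both hypotheses); `"fast"` keeps the topologies of the
#' original fits and re-optimizes branch lengths only — much cheaper, for
#' desk-scale suites.
#'
#' @param merged A `merged_alignment` for the candidate pair.
#' @param n Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param model Substitution model name.
#' @param mode `"full"` or `"fast"`.
#' @param fits Result of [lrt_statistic()] for the pair; required in
#'   `"fast"` mode (supplies the fixed topologies).
#' @param tol Optimizer tolerance.
#' @return Numeric vector of `n` replicate statistics, with attribute
#'   `mode`.
#' @export
bootstrap_null <- function(merged, n = 100L, seed = 1L, model = "LG",
                           mode = c("full", "fast"), fits = NULL, tol = 1e-4) {
  mode <- match.arg(mode)
  if (n < 1L) stop("need at least 1 bootstrap replicate")
  if (mode == "fast" && is.null(fits))
    stop("fast mode needs the original fits from lrt_statistic()")
  if (mode == "fast") {
    tree_s <- fits$fit_s$tree
    tree_p <- if (fits$fit_p_guided$log_likelihood >=
                  fits$fit_p_denovo$log_likelihood)
      fits$fit_p_guided$tree else fits$fit_p_denovo$tree
  }
  Ts <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(as.integer(seed) + i)
    idx <- sample.int(merged$aln$n_cols, merged$aln$n_cols, replace = TRUE)
    rep_m <- resample_merged(merged, idx)
    rep_split <- split_merged(rep_m)
    if (mode == "full") {
      f_s <- build_tree(rep_m$aln, model = model, tol = tol)
      f_d <- build_tree(rep_split, model = model, tol = tol)
      g0 <- graft_cherry(f_s$tree, rep_m$merged_id, rep_m$id1, rep_m$id2)
      f_g <- build_tree(rep_split, model = model, start = g0, tol = tol)
      lp <- max(f_d$log_likelihood, f_g$log_likelihood)
      Ts[i] <- 2 * (lp - f_s$log_likelihood)
    } else {
      f_s <- optimize_branch_lengths(tree_s, rep_m$aln, model = model, tol = tol)
      f_p <- optimize_branch_lengths(tree_p, rep_split, model = model, tol = tol)
      Ts[i] <- 2 * (f_p$log_likelihood - f_s$log_likelihood)
    }
  }
  attr(Ts, "mode") <- mode
  Ts
}

#' Empirical bootstrap p-value
#'
#' Proportion of replicate statistics equal to or above the observed one;
#' ties count in the numerator.
#'
#' @param T0 Observed statistic.
#' @param Ts Replicate statistics (non-empty).
#' @return `p_B = #\{T*_i >= T0\} / n`, an exact multiple of `1/n`.
#' @examples
#' bootstrap_pvalue(3, c(1, 2, 3, 4))  # 0.5 - the tie counts
#' @export
bootstrap_pvalue <- function(T0, Ts) {
  if (length(Ts) == 0L) stop("empty replicate set")
  sum(Ts >= T0) / length(Ts)
}

#' Likelihood ratio test for a candidate pair
#'
#' Computes the observed statistic, the bootstrap null and the empirical
#' p-value; `p_B >= alpha` — failure to reject the one-gene null — yields
#' the split prediction.
#'
#' @inheritParams lrt_statistic
#' @param alpha Significance level (default 0.01).
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @param mode Replicate fitting mode, see [bootstrap_null()].
#' @return An object of class `lrt_result`: `id1`, `id2`, `T0`, `Ts`,
#'   `p_B`, `alpha`, `n_boot`, `mode`, `seed`, `is_split`, `fits`.
#' @export
lrt_test <- function(msa, id1, id2, alpha = 0.01, n_boot = 100L, seed = 1L,
                     model = "LG", mode = c("full", "fast"), max_frac = 0.1,
                     tol = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, alpha <= 1)
  st <- lrt_statistic(msa, id1, id2, model = model, seed = seed,
                      max_frac = max_frac, tol = tol)
  Ts <- bootstrap_null(st$merged, n = n_boot, seed = seed, model = model,
                       mode = mode, fits = st, tol = tol)
  p <- bootstrap_pvalue(st$T0, Ts)
  structure(list(id1 = st$merged$id1, id2 = st$merged$id2, T0 = st$T0,
                 Ts = as.numeric(Ts), p_B = p, alpha = alpha,
                 n_boot = length(Ts), mode = mode, seed = seed,
                 is_split = p >= alpha, fits = st),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("\n\tSplit-gene likelihood ratio test (bootstrap null)\n\n")
  cat(sprintf("pair: %s / %s\n", x$id1, x$id2))
  cat(sprintf("T0 = %.4f, bootstrap replicates = %d (%s mode), p_B = %.4g\n",
              x$T0, x$n_boot, x$mode, x$p_B))
  cat(sprintf("alpha = %g; H_s (one gene) %s => %s\n", x$alpha,
              if (x$is_split) "not rejected" else "rejected",
              if (x$is_split) "SPLIT-GENE prediction" else "distinct paralogs"))
  invisible(x)
}
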