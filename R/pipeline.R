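# Per-family orchestration: align, enumerate candidates, run the
# configured tests, combine by intersection, classify ambiguity, report.

#' Pipeline configuration
#'
#' Defaults follow the whole-genome run of the method: collapse threshold
#' 0.95, LRT significance 0.01, 100 bootstrap replicates, fragments at
#' least 50 aa, pairwise overlap below 10%, tests combined by
#' intersection.
#'
#' @param collapse_threshold Support threshold for the collapse test.
#' @param alpha LRT significance level.
#' @param n_boot LRT bootstrap replicates.
#' @param support_reps Bootstrap replicates for branch supports.
#' @param min_len Minimum fragment length (aa).
#' @param max_overlap_frac Maximum aligned-overlap fraction.
#' @param mode Which calls make a prediction: `"intersection"` (both
#'   tests), `"collapse"`, or `"lrt"`.
#' @param replicate_mode LRT replicate fitting, `"full"` or `"fast"`.
#' @param model Substitution model name.
#' @param seed Base integer seed; family `i` (in sorted family order) uses
#'   `seed + 10000 * i`, and pair `j` within it adds `100 * j`.
#' @param aligner Optional aligner function ([external_aligner()]); NULL
#'   uses the built-in progressive aligner.
#' @param treebuilder Optional tree-builder function
#'   ([external_treebuilder()]); NULL uses the built-in engine (ML search
#'   plus Felsenstein bootstrap supports).
#' @param locations Optional `gene_id -> location` gate
#'   ([read_locations()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(collapse_threshold = 0.95, alpha = 0.01,
                       n_boot = 100L, support_reps = 100L, min_len = 50L,
                       max_overlap_frac = 0.1,
                       mode = c("intersection", "collapse", "lrt"),
                       replicate_mode = c("full", "fast"), model = "LG",
                       seed = 1L, aligner = NULL, treebuilder = NULL,
                       locations = NULL) {
  mode <- match.arg(mode)
  replicate_mode <- match.arg(replicate_mode)
  stopifnot(collapse_threshold >= 0, collapse_threshold <= 1,
            alpha >= 0, alpha <= 1, n_boot >= 1, support_reps >= 1,
            min_len >= 1, max_overlap_frac >= 0, max_overlap_frac <= 1)
  structure(list(collapse_threshold = collapse_threshold, alpha = alpha,
                 n_boot = as.integer(n_boot),
                 support_reps = as.integer(support_reps),
                 min_len = as.integer(min_len),
                 max_overlap_frac = max_overlap_frac, mode = mode,
                 replicate_mode = replicate_mode, model = model,
                 seed = as.integer(seed), aligner = aligner,
                 treebuilder = treebuilder, locations = locations),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("Split-gene run config: mode=%s, collapse threshold=%.2f,",
                     " alpha=%g, n_boot=%d (%s), min_len=%d, overlap<%.0f%%, seed=%d\n"),
              x$mode, x$collapse_threshold, x$alpha, x$n_boot,
              x$replicate_mode, x$min_len, 100 * x$max_overlap_frac, x$seed))
  invisible(x)
}

empty_predictions <- function() {
  data.frame(family_id = character(), id1 = character(), id2 = character(),
             l1 = integer(), l2 = integer(), a12 = integer(),
             collapse_support_threshold = numeric(),
             collapse_is_split = logical(), T0 = numeric(),
             n_boot = integer(), p_B = numeric(), alpha = numeric(),
             lrt_is_split = logical(), combined_split = logical(),
             ambiguity = character(), chain = character(),
             stringsAsFactors = FALSE)
}

#' Align a family (precomputed, adapter, or built-in fallback)
#'
#' @param family A [gene_family()].
#' @param config A [run_config()].
#' @param msa Optional precomputed [aa_alignment()]; returned as-is after
#'   a coverage check.
#' @return An [aa_alignment()] covering the family.
#' @export
align_family <- function(family, config = run_config(), msa = NULL) {
  if (!is.null(msa)) {
    if (!all(family$members$id %in% names(msa$rows)))
      stop("family ", family$family_id, ": precomputed alignment misses members")
    return(aln_rows(msa, family$members$id))
  }
  if (!is.null(config$aligner)) return(config$aligner(family))
  align_sequences(family)
}

#' Analyse one gene family
#'
#' Aligns the family, enumerates candidate pairs, runs the configured
#' tests on each and labels ambiguity. Families with fewer than four
#' members are skipped (no informative unrooted topology question below
#' four taxa).
#'
#' @param family A [gene_family()].
#' @param config A [run_config()].
#' @param msa Optional precomputed family alignment.
#' @param tree Optional precomputed family tree with branch supports
#'   (e.g. from FastTree via [external_treebuilder()], or
#'   [bootstrap_supports()]).
#' @return Prediction data frame, one row per candidate pair (columns:
#'   family_id, id1, id2, l1, l2, a12, collapse_support_threshold,
#'   collapse_is_split, T0, n_boot, p_B, alpha, lrt_is_split,
#'   combined_split, ambiguity, chain).
#' @export
analyze_family <- function(family, config = run_config(), msa = NULL,
                           tree = NULL) {
  stopifnot(inherits(family, "gene_family"), inherits(config, "run_config"))
  if (nrow(family$members) < 4L) {
    message("family ", family$family_id, " skipped: fewer than 4 members")
    return(empty_predictions())
  }
  msa <- align_family(family, config, msa)
  cands <- enumerate_candidates(family, msa, min_len = config$min_len,
                                max_frac = config$max_overlap_frac,
                                locations = config$locations)
  if (nrow(cands) == 0L) return(empty_predictions())
  need_collapse <- config$mode %in% c("intersection", "collapse")
  need_lrt <- config$mode %in% c("intersection", "lrt")
  if (need_collapse && is.null(tree)) {
    if (!is.null(config$treebuilder)) {
      tree <- config$treebuilder(msa)
    } else {
      fit <- build_tree(msa, model = config$model, seed = config$seed)
      tree <- bootstrap_supports(msa, fit$tree, model = config$model,
                                 n_reps = config$support_reps,
                                 seed = config$seed)
    }
  }
  out <- empty_predictions()
  for (j in seq_len(nrow(cands))) {
    row <- cands[j, ]
    col_res <- if (need_collapse)
      collapse_test(tree, row$id1, row$id2, config$collapse_threshold) else NULL
    lrt_res <- if (need_lrt)
      lrt_test(msa, row$id1, row$id2, alpha = config$alpha,
               n_boot = config$n_boot, seed = config$seed + 100L * j,
               model = config$model, mode = config$replicate_mode,
               max_frac = config$max_overlap_frac) else NULL
    combined <- switch(config$mode,
                       intersection = col_res$is_split && lrt_res$is_split,
                       collapse = col_res$is_split,
                       lrt = lrt_res$is_split)
    out <- rbind(out, data.frame(
      family_id = family$family_id, id1 = row$id1, id2 = row$id2,
      l1 = row$l1, l2 = row$l2, a12 = row$a12,
      collapse_support_threshold =
        if (need_collapse) config$collapse_threshold else NA_real_,
      collapse_is_split = if (need_collapse) col_res$is_split else NA,
      T0 = if (need_lrt) lrt_res$T0 else NA_real_,
      n_boot = if (need_lrt) lrt_res$n_boot else NA_integer_,
      p_B = if (need_lrt) lrt_res$p_B else NA_real_,
      alpha = if (need_lrt) config$alpha else NA_real_,
      lrt_is_split = if (need_lrt) lrt_res$is_split else NA,
      combined_split = combined, ambiguity = NA_character_,
      chain = NA_character_, stringsAsFactors = FALSE))
  }
  classify_ambiguity(out, msa, config$max_overlap_frac)
}

#' Classify multi-way predictions of a family
#'
#' Among positive (`combined_split`) predictions sharing a gene: if the
#' two partner fragments overlap in the alignment (i.e. fail the overlap
#' filter between themselves), the pairing cannot be resolved and both
#' predictions are `ambiguous`; ambiguity propagates through the whole
#' conflict component. Predictions sharing a gene whose partners are
#' mutually non-overlapping describe a gene split into more than two
#' pieces: they stay `unambiguous` and the ordered fragment chain (by
#' first occupied alignment column) is reported in `chain`.
#'
#' @param preds Prediction data frame of one family ([analyze_family()]
#'   layout).
#' @param msa The family alignment.
#' @param max_frac Overlap bound used for the partner-conflict check.
#' @return `preds` with `ambiguity` and `chain` filled for positive rows.
#' @export
classify_ambiguity <- function(preds, msa, max_frac = 0.1) {
  pos <- which(preds$combined_split %in% TRUE)
  if (length(pos) == 0L) return(preds)
  preds$ambiguity[pos] <- "unambiguous"
  k <- length(pos)
  conflict <- matrix(FALSE, k, k)
  compatible <- matrix(FALSE, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a >= b) next
    pa <- c(preds$id1[pos[a]], preds$id2[pos[a]])
    pb <- c(preds$id1[pos[b]], preds$id2[pos[b]])
    shared <- intersect(pa, pb)
    if (length(shared) == 0L) next
    partners <- c(setdiff(pa, shared), setdiff(pb, shared))
    if (length(partners) != 2L) {  # same pair twice cannot happen; guard
      conflict[a, b] <- conflict[b, a] <- TRUE
      next
    }
    ok <- passes_overlap_filter(aligned_overlap(msa, partners[1L], partners[2L]),
                                max_frac)
    if (ok) compatible[a, b] <- compatible[b, a] <- TRUE
    else conflict[a, b] <- conflict[b, a] <- TRUE
  }
  # propagate ambiguity through connected components of the conflict graph
  comp <- components_of(conflict)
  for (cc in comp) if (length(cc) > 1L) preds$ambiguity[pos[cc]] <- "ambiguous"
  # chains over compatible components (multi-piece splits)
  chain_comp <- components_of(compatible)
  for (cc in chain_comp) {
    genes <- unique(c(preds$id1[pos[cc]], preds$id2[pos[cc]]))
    starts <- vapply(genes, function(g) occupancy(msa, g)[1L], integer(1))
    preds$chain[pos[cc]] <- paste(genes[order(starts)], collapse = "+")
  }
  preds
}

components_of <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        m <- min(comp[i], comp[j]); comp[i] <- m; comp[j] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(seq_len(n), comp)
}

#' Run the split-gene scan over a dataset
#'
#' Orchestrates [analyze_family()] over every family; per-family failures
#' are caught, logged and reported, never aborting the run.
#'
#' @param seqs Sequence data frame ([read_fasta()]), or a character vector
#'   of FASTA paths (row-bound).
#' @param family_map Family map data frame or TSV path
#'   ([read_family_map()]).
#' @param target_genome Target genome label.
#' @param config A [run_config()].
#' @param alignments Optional named list of precomputed family alignments
#'   (names = family ids).
#' @param trees Optional named list of precomputed family trees with
#'   supports.
#' @param out_dir Optional directory; when given, writes
#'   `predictions.tsv`, `summary.tsv` and `failures.log`.
#' @return An object of class `split_scan`: list with `predictions`
#'   (data frame), `summary` (per-family counts), `failures` (data frame),
#'   `config`.
#' @export
run_split_scan <- function(seqs, family_map, target_genome,
                           config = run_config(), alignments = NULL,
                           trees = NULL, out_dir = NULL) {
  if (is.character(seqs))
    seqs <- do.call(rbind, lapply(seqs, read_fasta))
  fams <- build_families(seqs, family_map, target_genome)
  preds <- empty_predictions()
  failures <- data.frame(family_id = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_along(fams)) {
    fam <- fams[[i]]
    cfg <- config
    cfg$seed <- config$seed + 10000L * i
    res <- tryCatch(
      analyze_family(fam, cfg, msa = alignments[[fam$family_id]],
                     tree = trees[[fam$family_id]]),
      error = function(e)
        data.frame(family_id = fam$family_id, error = conditionMessage(e),
                   stringsAsFactors = FALSE))
    if (!is.null(res$error)) failures <- rbind(failures, res)
    else preds <- rbind(preds, res)
  }
  summary_df <- scan_summary(preds)
  out <- structure(list(predictions = preds, summary = summary_df,
                        failures = failures, config = config),
                   class = "split_scan")
  if (!is.null(out_dir)) write_scan(out, out_dir)
  out
}

scan_summary <- function(preds) {
  if (nrow(preds) == 0L)
    return(data.frame(family_id = character(), n_pairs = integer(),
                      n_split = integer(), n_unambiguous = integer(),
                      n_ambiguous = integer(), stringsAsFactors = FALSE))
  by_fam <- split(preds, preds$family_id)
  do.call(rbind, lapply(by_fam, function(p) data.frame(
    family_id = p$family_id[1L], n_pairs = nrow(p),
    n_split = sum(p$combined_split %in% TRUE),
    n_unambiguous = sum(p$ambiguity %in% "unambiguous"),
    n_ambiguous = sum(p$ambiguity %in% "ambiguous"),
    stringsAsFactors = FALSE, row.names = NULL)))
}

write_scan <- function(scan, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_tsv(scan$predictions, "predictions.tsv")
  write_tsv(scan$summary, "summary.tsv")
  writeLines(if (nrow(scan$failures) > 0L)
    paste(scan$failures$family_id, scan$failures$error, sep = "\t")
    else character(), file.path(out_dir, "failures.log"))
  invisible(out_dir)
}

#' @export
print.split_scan <- function(x, ...) {
  n_split <- sum(x$predictions$combined_split %in% TRUE)
  cat(sprintf(paste0("Split-gene scan: %d candidate pair(s) in %d family(ies); ",
                     "%d predicted split(s) (%d unambiguous, %d ambiguous); ",
                     "%d failed family(ies)\n"),
              nrow(x$predictions), length(unique(x$predictions$family_id)),
              n_split, sum(x$predictions$ambiguity %in% "unambiguous"),
              sum(x$predictions$ambiguity %in% "ambiguous"),
              nrow(x$failures)))
  invisible(x)
}

#' Union of two prediction sets
#'
#' Post-hoc merge utility (e.g. to union the intersection calls with an
#' external pairwise method's call set). Pairs are matched on
#' (family-insensitive) unordered id pairs; rows from `a` win on overlap.
#'
#' @param a,b Prediction data frames with `id1`, `id2` columns.
#' @return Row-bound data frame with duplicate pairs removed.
#' @export
union_predictions <- function(a, b) {
  key <- function(df) paste(pmin(df$id1, df$id2), pmax(df$id1, df$id2))
  b_new <- b[!(key(b) %in% key(a)), , drop = FALSE]
  common <- intersect(names(a), names(b_new))
  rbind(a[, common, drop = FALSE], b_new[, common, drop = FALSE])
}
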