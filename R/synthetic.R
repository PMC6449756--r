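# Synthetic benchmark generator: protein families evolved along a species
# tree, with planted true splits (one gene cut into two fragments) and
# planted negatives (complementary fragments of two post-duplication
# paralog copies). No indels are simulated, so the true alignment is
# exact and the tests are isolated from aligner error.

#' Simulation scenario
#'
#' The defaults encode the benchmark design: one target genome plus 8
#' reference taxa on a balanced species tree with branch lengths drawn
#' uniformly from `scale` (moderate divergence, 0.05-0.3
#' substitutions/site per branch), 400-aa parent genes, fragments at least
#' 50 aa from parents at least 100 aa, and negatives from paralog copies
#' that diverged `dup_depth` substitutions/site each since duplication.
#'
#' @param n_ref Number of reference taxa.
#' @param seq_length Parent gene length in amino acids.
#' @param scale Length-2 range for branch lengths (substitutions/site).
#' @param model Substitution model name.
#' @param n_positive Number of families with a planted true split.
#' @param n_negative Number of families with a planted paralog-fragment
#'   negative pair.
#' @param dup_depth Post-duplication divergence of each paralog copy
#'   (substitutions/site); 0 makes the copies identical to the parent —
#'   the hardest, inherently indistinguishable negative.
#' @param min_frag Minimum fragment length (aa).
#' @param seed Integer seed; family `i` uses `seed + i`.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_ref = 8L, seq_length = 400L, scale = c(0.05, 0.3),
                         model = "LG", n_positive = 30L, n_negative = 30L,
                         dup_depth = 0.4, min_frag = 50L, seed = 1L) {
  stopifnot(n_ref >= 2L, seq_length >= 2L * min_frag, length(scale) == 2L,
            all(scale > 0), n_positive >= 0L, n_negative >= 0L,
            dup_depth >= 0, min_frag >= 1L)
  structure(list(n_ref = as.integer(n_ref), seq_length = as.integer(seq_length),
                 scale = scale, model = model,
                 n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative), dup_depth = dup_depth,
                 min_frag = as.integer(min_frag), seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("Simulation scenario: %d ref taxa, %d-aa genes, ",
                     "%d split(s) + %d paralog negative(s) (dup depth %.2f), ",
                     "branch lengths U(%.2f, %.2f), seed %d\n"),
              x$n_ref, x$seq_length, x$n_positive, x$n_negative,
              x$dup_depth, x$scale[1L], x$scale[2L], x$seed))
  invisible(x)
}

#' Reference species tree for simulation
#'
#' Balanced topology over the reference taxa (`ref1..refN`), branch
#' lengths drawn uniformly from `scale`; the target genome's leaf
#' (`target`) is grafted as sister to a random reference.
#'
#' @param n_ref Number of reference taxa.
#' @param scale Branch-length range.
#' @param seed Integer seed.
#' @return An [ape::phylo] with `n_ref + 1` leaves and branch lengths.
#' @export
ref_species_tree <- function(n_ref = 8L, scale = c(0.05, 0.3), seed = 1L) {
  set.seed(as.integer(seed))
  base <- if (log2(n_ref) %% 1 == 0) ape::stree(n_ref, type = "balanced")
          else ape::rtree(n_ref, br = NULL)
  base$tip.label <- paste0("ref", seq_len(n_ref))
  base$edge.length <- rep(1, nrow(base$edge))
  base <- ape::unroot(base)
  sister <- sample(base$tip.label, 1L)
  cherry <- ape::read.tree(text = "(target:1):0;")
  tr <- ape::bind.tree(base, cherry, where = match(sister, base$tip.label))
  tr <- ape::unroot(tr)
  tr$edge.length <- stats::runif(nrow(tr$edge), scale[1L], scale[2L])
  tr
}

#' Evolve a gene family along a tree
#'
#' Root sequence drawn from the model's stationary frequencies,
#' descendants by sampling the transition distribution per site per
#' branch; no indels, so the true alignment is the sequences themselves.
#'
#' @param tree Species tree with branch lengths.
#' @param length Gene length (aa).
#' @param model Substitution model name.
#' @param seed Integer seed.
#' @param family_id Family identifier.
#' @param target_genome Which leaf is the target genome (default
#'   `"target"`).
#' @return List with `family` ([gene_family()]) and `aln` (the exact
#'   [aa_alignment()]).
#' @export
evolve_family <- function(tree, length, model = "LG", seed = 1L,
                          family_id = "fam1", target_genome = "target") {
  set.seed(as.integer(seed))
  sim <- phangorn::simSeq(tree, l = length, type = "AA", model = model)
  m <- toupper(as.character(sim))
  rows <- stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
  members <- data.frame(id = names(rows), genome = names(rows),
                        residues = unname(rows), length = nchar(rows),
                        stringsAsFactors = FALSE)
  list(family = gene_family(family_id, members, target_genome),
       aln = aa_alignment(rows))
}

draw_cut <- function(L, min_frag) {
  rng <- seq.int(min_frag, L - min_frag)
  if (length(rng) == 1L) rng else sample(rng, 1L)
}

place_fragment <- function(n_cols, cols, residues) {
  ch <- rep("-", n_cols)
  ch[cols] <- residues
  paste(ch, collapse = "")
}

#' Plant a true split in a family
#'
#' Replaces the target gene by two fragments cut at a position `s` drawn
#' uniformly so both pieces have at least `min_frag` residues; the parent
#' must be at least `2 * min_frag` long.
#'
#' @param fam_aln List `(family, aln)` as from [evolve_family()].
#' @param target_gene Id of the gene to split.
#' @param seed Integer seed.
#' @param min_frag Minimum fragment length (aa).
#' @return List `(family, aln, truth)`; `truth` is a one-row data frame
#'   with `family_id`, `id1`, `id2`, `label = "true_split"` and
#'   `split_pos`.
#' @export
plant_split <- function(fam_aln, target_gene = "target", seed = 1L,
                        min_frag = 50L) {
  fam <- fam_aln$family; aln <- fam_aln$aln
  occ <- occupancy(aln, target_gene)
  L <- length(occ)
  if (L < 2L * min_frag)
    stop("gene ", target_gene, " too short to split (", L, " aa)")
  set.seed(as.integer(seed))
  s <- draw_cut(L, min_frag)
  res <- strsplit(aln_ungap(aln, target_gene), "", fixed = TRUE)[[1]]
  ids <- paste0(target_gene, c("_f1", "_f2"))
  rows <- aln$rows[names(aln$rows) != target_gene]
  rows[ids[1L]] <- place_fragment(aln$n_cols, occ[seq_len(s)], res[seq_len(s)])
  rows[ids[2L]] <- place_fragment(aln$n_cols, occ[seq.int(s + 1L, L)],
                                  res[seq.int(s + 1L, L)])
  genome <- fam$members$genome[fam$members$id == target_gene]
  members <- fam$members[fam$members$id != target_gene, , drop = FALSE]
  members <- rbind(members, data.frame(
    id = ids, genome = genome, residues = c(paste(res[seq_len(s)], collapse = ""),
                                            paste(res[seq.int(s + 1L, L)], collapse = "")),
    length = c(s, L - s), stringsAsFactors = FALSE))
  list(family = gene_family(fam$family_id, members, fam$target_genome),
       aln = aa_alignment(rows),
       truth = data.frame(family_id = fam$family_id, id1 = min(ids),
                          id2 = max(ids), label = "true_split",
                          split_pos = s, stringsAsFactors = FALSE))
}

# Graft a duplicate lineage: a new tip attached `depth` substitutions/site
# above `tip` along its root path (capped just below the root), with a
# pendant branch of length `depth`.
graft_duplicate <- function(tree, tip, depth, label) {
  w <- match(tip, tree$tip.label)
  if (is.na(w)) stop("leaf not in tree: ", tip)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- unique(setdiff(tree$edge[, 1L], tree$edge[, 2L]))
  node <- w
  below <- 0
  while (TRUE) {
    len <- elen[node]
    if (below + len > depth || parent[node] == root) break
    below <- below + len
    node <- parent[node]
  }
  pos <- min(depth - below, elen[node] * 0.999)
  tipt <- ape::read.tree(text = sprintf("(%s:%.12g):0;", label, depth))
  out <- ape::bind.tree(tree, tipt, where = node, position = pos)
  ape::collapse.singles(out)
}

#' Plant a paralog-derived negative pair
#'
#' Simulates a gene duplication `dup_depth` substitutions/site before the
#' present: a duplicate lineage is grafted onto the species tree that far
#' above the target leaf (so reference lineages diverging more recently
#' than the duplication separate the two copies), the family is evolved
#' along the augmented tree, and the two full-length copies are replaced
#' by complementary fragments — the N-terminal piece of copy 1 and the
#' C-terminal piece of copy 2. The fragments are non-overlapping by
#' construction (`a12 = 0`) yet come from two distinct genes: the false
#' positive the method must resist. With `dup_depth = 0` the duplication
#' is at the leaf itself, the copies are identical, and the pair is
#' inherently indistinguishable from a true split (the species-specific
#' close-paralog limit).
#'
#' @param tree Species tree ([ref_species_tree()] or similar) containing
#'   the target leaf.
#' @param length Gene length in amino acids (>= `2 * min_frag`).
#' @param dup_depth Time since duplication, substitutions/site.
#' @param seed Integer seed.
#' @param min_frag Minimum fragment length (aa).
#' @param model Substitution model name.
#' @param family_id Family identifier.
#' @param target_gene Target leaf label (also the target genome).
#' @return List `(family, aln, truth)` with `label = "paralog_negative"`.
#' @export
plant_paralog_pair <- function(tree, length, dup_depth = 0.4, seed = 1L,
                               min_frag = 50L, model = "LG",
                               family_id = "fam1", target_gene = "target") {
  if (length < 2L * min_frag)
    stop("gene too short to cut (", length, " aa)")
  dup <- paste0(target_gene, "_duplineage")
  tr2 <- if (dup_depth > 0) graft_duplicate(tree, target_gene, dup_depth, dup)
         else tree
  fa <- evolve_family(tr2, length, model = model, seed = seed,
                      family_id = family_id, target_genome = target_gene)
  aln <- fa$aln; fam <- fa$family
  if (dup_depth == 0) {
    aln$rows[dup] <- aln$rows[[target_gene]]
    fam$members <- rbind(fam$members,
                         within(fam$members[fam$members$id == target_gene, ],
                                id <- dup))
  }
  occ <- occupancy(aln, target_gene)
  L <- base::length(occ)
  set.seed(as.integer(seed))
  s <- draw_cut(L, min_frag)
  copy1 <- strsplit(aln_ungap(aln, target_gene), "", fixed = TRUE)[[1]]
  copy2 <- strsplit(aln_ungap(aln, dup), "", fixed = TRUE)[[1]]
  ids <- paste0(target_gene, c("_p1", "_p2"))
  rows <- aln$rows[!names(aln$rows) %in% c(target_gene, dup)]
  rows[ids[1L]] <- place_fragment(aln$n_cols, occ[seq_len(s)], copy1[seq_len(s)])
  rows[ids[2L]] <- place_fragment(aln$n_cols, occ[seq.int(s + 1L, L)],
                                  copy2[seq.int(s + 1L, L)])
  members <- fam$members[!fam$members$id %in% c(target_gene, dup), , drop = FALSE]
  members <- rbind(members, data.frame(
    id = ids, genome = target_gene,
    residues = c(paste(copy1[seq_len(s)], collapse = ""),
                 paste(copy2[seq.int(s + 1L, L)], collapse = "")),
    length = c(s, L - s), stringsAsFactors = FALSE))
  list(family = gene_family(family_id, members, target_gene),
       aln = aa_alignment(rows),
       truth = data.frame(family_id = family_id, id1 = min(ids),
                          id2 = max(ids), label = "paralog_negative",
                          split_pos = s, stringsAsFactors = FALSE))
}

# Gene ids must be unique across a dataset (families partition genes), so
# simulated ids are prefixed with their family id: "fam0001.ref3".
prefix_family <- function(planted, fid) {
  pre <- function(x) paste(fid, x, sep = ".")
  planted$family$members$id <- pre(planted$family$members$id)
  names(planted$aln$rows) <- pre(names(planted$aln$rows))
  planted$truth$id1 <- pre(planted$truth$id1)
  planted$truth$id2 <- pre(planted$truth$id2)
  planted
}

#' Simulate a full benchmark dataset
#'
#' One family per planted case: `n_positive` families with a true split,
#' then `n_negative` families with a paralog negative. Family `i` draws
#' its branch lengths and sequences with seed `seed + i`. Gene ids are
#' prefixed with the family id so that ids are unique across the dataset.
#'
#' @param scenario A [sim_scenario()].
#' @return An object of class `sim_data`: `families` (named list),
#'   `alignments` (named list of exact alignments), `truth` (data frame),
#'   `scenario`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n <- scenario$n_positive + scenario$n_negative
  families <- list(); alignments <- list(); truth <- NULL
  for (i in seq_len(n)) {
    fid <- sprintf("fam%04d", i)
    s_i <- scenario$seed + i
    tr <- ref_species_tree(scenario$n_ref, scenario$scale, seed = s_i)
    planted <- if (i <= scenario$n_positive) {
      fa <- evolve_family(tr, scenario$seq_length, model = scenario$model,
                          seed = s_i, family_id = fid)
      plant_split(fa, seed = s_i, min_frag = scenario$min_frag)
    } else {
      plant_paralog_pair(tr, scenario$seq_length,
                         dup_depth = scenario$dup_depth, seed = s_i,
                         min_frag = scenario$min_frag, model = scenario$model,
                         family_id = fid)
    }
    planted <- prefix_family(planted, fid)
    families[[fid]] <- planted$family
    alignments[[fid]] <- planted$aln
    truth <- rbind(truth, planted$truth)
  }
  structure(list(families = families, alignments = alignments,
                 truth = truth, scenario = scenario),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d families (%d true splits, %d paralog negatives)\n",
              length(x$families), sum(x$truth$label == "true_split"),
              sum(x$truth$label == "paralog_negative")))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits one FASTA per genome, the family map TSV, the truth TSV, one
#' aligned FASTA per family (under `alignments/`) and a scenario
#' snapshot.
#'
#' @param sim A `sim_data` object.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE,
             recursive = TRUE)
  members <- do.call(rbind, lapply(names(sim$families), function(fid) {
    m <- sim$families[[fid]]$members
    m$family_id <- fid
    m
  }))
  for (g in sort(unique(members$genome)))
    write_fasta(members[members$genome == g, , drop = FALSE],
                file.path(dir, paste0(g, ".fa")))
  utils::write.table(
    data.frame(gene_id = members$id, genome_id = members$genome,
               family_id = members$family_id),
    file.path(dir, "family_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (fid in names(sim$alignments))
    write_alignment(sim$alignments[[fid]],
                    file.path(dir, "alignments", paste0(fid, ".fa")))
  sc <- sim$scenario
  writeLines(c(sprintf("n_ref=%d", sc$n_ref),
               sprintf("seq_length=%d", sc$seq_length),
               sprintf("scale=%g,%g", sc$scale[1L], sc$scale[2L]),
               sprintf("model=%s", sc$model),
               sprintf("n_positive=%d", sc$n_positive),
               sprintf("n_negative=%d", sc$n_negative),
               sprintf("dup_depth=%g", sc$dup_depth),
               sprintf("min_frag=%d", sc$min_frag),
               sprintf("seed=%d", sc$seed)),
             file.path(dir, "scenario.cfg"))
  invisible(dir)
}

#' Score predictions against the planted truth
#'
#' TP: predicted pairs labelled `true_split`; FP: predicted pairs that are
#' planted negatives or unplanted; FN: planted splits not predicted.
#' Precision is `NA` when there are no predictions.
#'
#' @param predictions Prediction data frame ([run_split_scan()]'s
#'   `predictions`, or any frame with `id1`, `id2` and optionally
#'   `combined_split` — when present only positive rows count as
#'   predictions).
#' @param truth Truth data frame ([simulate_scenario()]'s `truth`).
#' @return An object of class `split_eval`: `precision`, `recall`,
#'   `counts` (TP, FP, FN).
#' @export
evaluate_predictions <- function(predictions, truth) {
  stopifnot(nrow(truth) > 0L)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pred <- predictions
  if ("combined_split" %in% names(pred))
    pred <- pred[pred$combined_split %in% TRUE, , drop = FALSE]
  pk <- unique(key(pred$id1, pred$id2))
  pos_k <- key(truth$id1, truth$id2)[truth$label == "true_split"]
  tp <- sum(pk %in% pos_k)
  fp <- length(pk) - tp
  fn <- sum(!(pos_k %in% pk))
  structure(list(precision = if (length(pk) == 0L) NA_real_ else tp / (tp + fp),
                 recall = if (length(pos_k) == 0L) NA_real_ else tp / (tp + fn),
                 counts = c(TP = tp, FP = fp, FN = fn)),
            class = "split_eval")
}

#' @export
print.split_eval <- function(x, ...) {
  cat(sprintf("Evaluation: TP=%d FP=%d FN=%d | precision=%s recall=%s\n",
              x$counts["TP"], x$counts["FP"], x$counts["FN"],
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              ifelse(is.na(x$recall), "NA", sprintf("%.3f", x$recall))))
  invisible(x)
}
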