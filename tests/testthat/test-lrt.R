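# Fragment merging, bootstrap null and the likelihood ratio test.

test_that("merging disjoint fragments concatenates them with provenance", {
  msa <- aa_alignment(c(a = "MKLWCVNQRY", b = "AHDEI-----", c = "-----FGSTP"))
  mg <- merge_fragments(msa, "b", "c")
  expect_equal(aln_row(mg$aln, mg$merged_id), "AHDEIFGSTP")
  expect_equal(mg$provenance, c(rep("F1", 5), rep("F2", 5)))
  expect_equal(length(mg$aln$rows), 2L)
})

test_that("overlap columns take the longer fragment's residue", {
  set.seed(4)
  blk <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
  # long (30 aa) and short (20 aa) with exactly 1 shared column
  long <- paste0(blk(30), strrep("-", 19))
  short <- paste0(strrep("-", 29), blk(20))
  msa <- aa_alignment(c(s = short, l = long, ref = blk(49)))
  mg <- merge_fragments(msa, "s", "l")
  expect_equal(mg$id1, "l")                      # reoriented to the longer
  expect_equal(mg$provenance[30], "BOTH")
  expect_equal(substr(aln_row(mg$aln, mg$merged_id), 30, 30),
               substr(long, 30, 30))
  expect_equal(sum(mg$provenance == "F1") + sum(mg$provenance == "BOTH"), 30)
  expect_equal(sum(mg$provenance == "F2") + sum(mg$provenance == "BOTH"), 20)
})

test_that("merging a pair that fails the overlap filter is an error", {
  set.seed(5)
  blk <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
  r1 <- blk(20); r2 <- paste0(strrep("-", 10), blk(10))
  msa <- aa_alignment(c(a = r1, b = paste0(r2)))
  expect_error(merge_fragments(msa, "a", "b"), "overlap filter")
})

test_that("provenance counts match fragment lengths on random pairs", {
  set.seed(17)
  for (i in 1:30) {
    n <- 120
    occ1 <- sort(sample(n, 55)); occ2 <- sort(sample(setdiff(seq_len(n), occ1), 50))
    # allow a small overlap below 10%
    occ2[1:2] <- occ1[1:2]
    r1 <- rep("-", n); r1[occ1] <- sample(AA20, 55, TRUE)
    r2 <- rep("-", n); r2[unique(occ2)] <- sample(AA20, length(unique(occ2)), TRUE)
    msa <- aa_alignment(c(a = paste(r1, collapse = ""),
                          b = paste(r2, collapse = "")))
    st <- aligned_overlap(msa, "a", "b")
    if (!passes_overlap_filter(st)) next
    mg <- merge_fragments(msa, "a", "b")
    l1 <- length(occupancy(msa, mg$id1)); l2 <- length(occupancy(msa, mg$id2))
    expect_equal(sum(mg$provenance == "F1") + sum(mg$provenance == "BOTH"), l1)
    expect_equal(sum(mg$provenance == "F2") + sum(mg$provenance == "BOTH"), l2)
  }
})

test_that("split_merged inverts merge_fragments on non-overlap columns", {
  msa <- aa_alignment(c(a = "MKLWCVNQRY", b = "AHDEI-----", c = "-----FGSTP",
                        d = "MKLWCVNQRY"))
  mg <- merge_fragments(msa, "b", "c")
  back <- split_merged(mg)
  expect_equal(aln_row(back, "b"), aln_row(msa, "b"))
  expect_equal(aln_row(back, "c"), aln_row(msa, "c"))
  expect_equal(aln_row(back, "a"), aln_row(msa, "a"))
  # all-F1 provenance: the secondary row comes back empty on split
  mg2 <- mg; mg2$provenance <- rep("F1", 10)
  back2 <- split_merged(mg2)
  expect_equal(aln_row(back2, mg$id2), strrep("-", 10))
})

test_that("resampling routes columns by the requested provenance scheme", {
  msa <- aa_alignment(c(a = "MKLWCVNQRY", b = "AHDEI-----", c = "-----FGSTP"))
  mg <- merge_fragments(msa, "b", "c")
  idx <- c(6L, 7L, 1L, 2L, 10L, 3L, 3L, 8L, 4L, 5L)
  carried <- resample_merged(mg, idx, provenance = "carried")
  expect_equal(carried$provenance, mg$provenance[idx])
  positional <- resample_merged(mg, idx, provenance = "positional")
  expect_equal(positional$provenance, mg$provenance)
  # carried + split reproduces per-column bookkeeping exactly
  sp <- split_merged(carried)
  merged_row <- strsplit(aln_row(mg$aln, mg$merged_id), "", fixed = TRUE)[[1]]
  got1 <- strsplit(aln_row(sp, mg$id1), "", fixed = TRUE)[[1]]
  for (k in seq_along(idx)) {
    if (mg$provenance[idx[k]] %in% c("F1", "BOTH"))
      expect_equal(got1[k], merged_row[idx[k]])
    else expect_equal(got1[k], "-")
  }
})

test_that("bootstrap p-value is the exact tie-inclusive proportion", {
  expect_equal(bootstrap_pvalue(3, c(1, 2, 3, 4)), 0.5)
  expect_equal(bootstrap_pvalue(-5, c(1, 2, 3, 4)), 1)
  expect_equal(bootstrap_pvalue(99, c(1, 2, 3, 4)), 0)
  expect_error(bootstrap_pvalue(1, numeric(0)), "empty")
})

test_that("replicate column draws are uniform (seed-derivation check)", {
  # mirrors bootstrap_null's draw: replicate i uses seed + i
  n_cols <- 4L; reps <- 10000L; seed <- 123L
  counts <- numeric(n_cols)
  for (i in seq_len(reps)) {
    set.seed(seed + i)
    idx <- sample.int(n_cols, n_cols, replace = TRUE)
    counts <- counts + tabulate(idx, n_cols)
  }
  total <- reps * n_cols
  p_hat <- counts / total
  sigma <- sqrt(0.25 * 0.75 / total)
  expect_true(all(abs(p_hat - 0.25) <= 3 * sigma + 1e-12))
})

test_that("bootstrap null is reproducible and degenerate on constant columns", {
  pl <- small_split_family(81, n_ref = 4, len = 150)
  pair <- enumerate_candidates(pl$family, pl$aln)
  st <- lrt_statistic(pl$aln, pair$id1[1], pair$id2[1], seed = 1)
  t1 <- bootstrap_null(st$merged, n = 5, seed = 9, mode = "fast", fits = st)
  t2 <- bootstrap_null(st$merged, n = 5, seed = 9, mode = "fast", fits = st)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_length(as.numeric(t1), 5L)
  expect_error(bootstrap_null(st$merged, n = 0, seed = 1, mode = "fast",
                              fits = st), "at least 1")
})

test_that("constant-column alignments give constant replicate statistics", {
  set.seed(6)
  col <- sample(AA20, 5, TRUE)
  col[2] <- col[1]  # both fragments carry the same residue per column
  m <- matrix(col, 5, 60)
  rownames(m) <- c("t_a", "t_b", "r1", "r2", "r3")
  m["t_a", 31:60] <- "-"; m["t_b", 1:30] <- "-"
  aln <- aa_alignment(stats::setNames(apply(m, 1, paste, collapse = ""),
                                      rownames(m)))
  st <- lrt_statistic(aln, "t_a", "t_b", seed = 1)
  Ts <- bootstrap_null(st$merged, n = 5, seed = 3, mode = "fast", fits = st)
  expect_lt(max(Ts) - min(Ts), 1e-6)
})

test_that("T0 has the guided-search floor and ranks split vs paralog", {
  # same-gene fragments: T0 >= -2*tol
  pl <- small_split_family(91, n_ref = 5, len = 200)
  pair <- enumerate_candidates(pl$family, pl$aln)
  st <- lrt_statistic(pl$aln, pair$id1[1], pair$id2[1], seed = 1)
  expect_gte(st$T0, -2e-4)
  expect_equal(st$log_lik_p, max(st$fit_p_denovo$log_likelihood,
                                 st$fit_p_guided$log_likelihood))
  # paired background: deep paralog fragments score higher
  pn <- small_paralog_family(91, n_ref = 5, len = 200, dup_depth = 0.5)
  pairn <- enumerate_candidates(pn$family, pn$aln)
  stn <- lrt_statistic(pn$aln, pairn$id1[1], pairn$id2[1], seed = 1)
  expect_gt(stn$T0, st$T0)
})

test_that("3-taxon family: T0 equals the direct two-likelihood difference", {
  set.seed(101)
  tr <- ape::read.tree(text = "(target:0.1,ref1:0.2);")
  fa <- evolve_family(tr, 160, seed = 101, family_id = "f3")
  pl <- plant_split(fa, seed = 101)
  st <- lrt_statistic(pl$aln, "target_f1", "target_f2", seed = 1)
  # oracle: H_s = optimal 2-leaf distance by grid; H_p = single 3-leaf
  # topology optimized by the engine's fixed-topology path
  mg <- merge_fragments(pl$aln, "target_f1", "target_f2")
  grid <- seq(0.005, 1.5, by = 5e-4)
  lls <- vapply(grid, function(t) {
    t2 <- ape::read.tree(text = sprintf("(%s:%f,ref1:%f);", mg$merged_id,
                                        t / 2, t / 2))
    tree_log_likelihood(t2, mg$aln)
  }, numeric(1))
  ll_s <- max(lls)
  t3 <- ape::read.tree(text = "(target_f1:0.1,target_f2:0.1,ref1:0.1);")
  ll_p <- optimize_branch_lengths(t3, pl$aln)$log_likelihood
  expect_equal(st$T0, 2 * (ll_p - ll_s), tolerance = 1e-2)
})

test_that("the decision rule follows p_B >= alpha including the boundary", {
  fake <- function(p, a) p >= a
  expect_true(fake(0.40, 0.01))
  expect_false(fake(0.005, 0.01))
  expect_true(fake(0.01, 0.01))
  # end-to-end: p_B and is_split agree on a real pair
  pl <- small_split_family(111, n_ref = 4, len = 150)
  pair <- enumerate_candidates(pl$family, pl$aln)
  res <- lrt_test(pl$aln, pair$id1[1], pair$id2[1], n_boot = 10, seed = 2,
                  mode = "fast")
  expect_equal(res$p_B, sum(res$Ts >= res$T0) / res$n_boot)
  expect_identical(res$is_split, res$p_B >= res$alpha)
  expect_true(res$p_B %in% ((0:10) / 10))
})

test_that("LRT decisions are monotone in alpha on a fixed replicate set", {
  set.seed(7)
  for (i in 1:50) {
    T0 <- stats::rnorm(1); Ts <- stats::rnorm(40)
    p <- bootstrap_pvalue(T0, Ts)
    if (p >= 0.05) expect_gte(p, 0.01)  # call at 0.05 implies call at 0.01
  }
})
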