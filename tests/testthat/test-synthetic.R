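# Benchmark generator: evolution, split/paralog planting, evaluation.

test_that("zero branch lengths copy the root to every leaf", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  fa <- evolve_family(tr, 50, seed = 1)
  expect_length(unique(unname(fa$aln$rows)), 1L)
})

test_that("evolution is deterministic under a fixed seed", {
  tr <- ref_species_tree(4, seed = 2)
  a <- evolve_family(tr, 80, seed = 99)
  b <- evolve_family(tr, 80, seed = 99)
  expect_identical(a$aln$rows, b$aln$rows)
  c <- evolve_family(tr, 80, seed = 100)
  expect_false(identical(a$aln$rows, c$aln$rows))
})

test_that("long branches drive pairwise identity to the stationary expectation", {
  m <- aa_model("LG")
  tr <- ape::read.tree(text = "(a:5,b:5);")
  fa <- evolve_family(tr, 10000, seed = 3)
  id_obs <- mean(strsplit(fa$aln$rows[["a"]], "")[[1]] ==
                 strsplit(fa$aln$rows[["b"]], "")[[1]])
  id_exp <- sum(m$pi^2)
  expect_lt(abs(id_obs - id_exp), 3 * sqrt(id_exp * (1 - id_exp) / 10000))
})

test_that("plant_split respects the boundary and conserves residues", {
  tr <- ref_species_tree(4, seed = 5)
  fa <- evolve_family(tr, 100, seed = 5)
  pl <- plant_split(fa, seed = 5)
  expect_equal(pl$truth$split_pos, 50L)  # L = 2*min_frag forces s = 50
  f1 <- pl$family$members[pl$family$members$id == "target_f1", ]
  f2 <- pl$family$members[pl$family$members$id == "target_f2", ]
  expect_equal(paste0(f1$residues, f2$residues),
               aln_ungap(fa$aln, "target"))

  fa300 <- evolve_family(tr, 300, seed = 6)
  pl300 <- plant_split(fa300, seed = 6)
  lens <- pl300$family$members$length[grepl("_f", pl300$family$members$id)]
  expect_true(all(lens >= 50))
  expect_equal(sum(lens), 300L)
  # too-short parent errors
  fa80 <- evolve_family(tr, 80, seed = 7)
  expect_error(plant_split(fa80, seed = 7), "too short")
})

test_that("split positions are uniform on [min_frag, L - min_frag]", {
  set.seed(8)
  L <- 300L; min_frag <- 50L
  draws <- vapply(seq_len(10000L), function(i)
    phylosplit:::draw_cut(L, min_frag), integer(1))
  expect_gte(min(draws), min_frag)
  expect_lte(max(draws), L - min_frag)
  bins <- cut(draws, breaks = seq(min_frag - 0.5, L - min_frag + 0.5,
                                  length.out = 21))
  expect_gt(stats::chisq.test(table(bins))$p.value, 1e-4)
})

test_that("paralog planting: fragments are complementary and non-overlapping", {
  pn <- small_paralog_family(9, n_ref = 6, len = 200, dup_depth = 0.6)
  st <- aligned_overlap(pn$aln, pn$truth$id1, pn$truth$id2)
  expect_equal(st$a12, 0L)
  expect_equal(st$l1 + st$l2, 200L)
})

test_that("dup_depth 0 reduces to fragments of one identical sequence", {
  tr <- ref_species_tree(4, seed = 10)
  pn <- plant_paralog_pair(tr, 150, dup_depth = 0, seed = 10)
  fa <- evolve_family(tr, 150, seed = 10)
  frag <- pn$family$members
  joined <- paste0(frag$residues[frag$id == "target_p1"],
                   frag$residues[frag$id == "target_p2"])
  expect_equal(joined, aln_ungap(fa$aln, "target"))
})

test_that("deep duplications approach stationary identity between copies", {
  tr <- ref_species_tree(4, seed = 11, scale = c(0.05, 0.1))
  m <- aa_model("LG")
  # identity between the two fragments' sources cannot be read off the
  # fragments (disjoint); instead check the duplicate leaf directly
  tr2 <- phylosplit:::graft_duplicate(tr, "target", 2.5, "dup")
  fa <- evolve_family(tr2, 5000, seed = 11)
  id_obs <- mean(strsplit(fa$aln$rows[["target"]], "")[[1]] ==
                 strsplit(fa$aln$rows[["dup"]], "")[[1]])
  t_tot <- stats::cophenetic(tr2)["target", "dup"]
  id_exp <- sum(m$pi * diag(as.matrix(Matrix::expm(m$Q * t_tot))))
  expect_lt(abs(id_obs - id_exp), 3 * sqrt(id_exp * (1 - id_exp) / 5000))
  expect_gt(id_exp, sum(m$pi^2))  # decays toward the stationary floor
})

test_that("planted pairs always pass the candidate filters", {
  for (s in 21:26) {
    pl <- if (s %% 2 == 0) small_split_family(s, n_ref = 5, len = 180)
          else small_paralog_family(s, n_ref = 5, len = 180)
    cands <- enumerate_candidates(pl$family, pl$aln)
    key <- paste(cands$id1, cands$id2)
    expect_true(paste(pl$truth$id1, pl$truth$id2) %in% key)
  }
})

test_that("simulate_scenario assembles families, alignments and truth", {
  sim <- simulate_scenario(sim_scenario(n_ref = 4, seq_length = 120,
                                        n_positive = 2, n_negative = 2,
                                        seed = 30))
  expect_length(sim$families, 4L)
  expect_equal(sort(unique(sim$truth$label)),
               c("paralog_negative", "true_split"))
  expect_equal(nrow(sim$truth), 4L)
  # round-trip through disk
  d <- withr::local_tempdir()
  write_sim_data(sim, d)
  map <- read_family_map(file.path(d, "family_map.tsv"))
  expect_equal(sort(unique(map$family_id)), sort(names(sim$families)))
  fa <- read_fasta(file.path(d, "target.fa"))
  expect_true(all(grepl("target_[fp][12]$", fa$id)))
})

test_that("evaluate_predictions matches a brute-force confusion matrix", {
  truth <- data.frame(family_id = "f",
                      id1 = c("a1", "b1", "c1"), id2 = c("a2", "b2", "c2"),
                      label = c("true_split", "true_split", "paralog_negative"),
                      stringsAsFactors = FALSE)
  pred <- data.frame(id1 = c("a2", "c1", "zz"), id2 = c("a1", "c2", "qq"),
                     stringsAsFactors = FALSE)
  ev <- evaluate_predictions(pred, truth)
  expect_equal(unname(ev$counts), c(1L, 2L, 1L))  # TP, FP (neg + unplanted), FN
  expect_equal(ev$precision, 1 / 3)
  expect_equal(ev$recall, 1 / 2)
  # no predictions: precision NA, recall 0
  ev0 <- evaluate_predictions(pred[0, ], truth)
  expect_true(is.na(ev0$precision))
  expect_equal(ev0$recall, 0)
  # perfect calls
  evp <- evaluate_predictions(truth[truth$label == "true_split", c("id1", "id2")],
                              truth)
  expect_equal(evp$precision, 1); expect_equal(evp$recall, 1)
})

test_that("randomized prediction sets match brute-force counting", {
  set.seed(44)
  truth <- data.frame(family_id = "f", id1 = sprintf("p%02da", 1:20),
                      id2 = sprintf("p%02db", 1:20),
                      label = sample(c("true_split", "paralog_negative"), 20, TRUE),
                      stringsAsFactors = FALSE)
  for (i in 1:10) {
    take <- sample(20, sample(0:20, 1))
    extra <- if (stats::runif(1) < 0.5)
      data.frame(id1 = "xx", id2 = "yy", stringsAsFactors = FALSE) else NULL
    pred <- rbind(truth[take, c("id1", "id2")], extra)
    ev <- evaluate_predictions(pred, truth)
    tp <- sum(truth$label[take] == "true_split")
    fp <- sum(truth$label[take] == "paralog_negative") + !is.null(extra)
    fn <- sum(truth$label == "true_split") - tp
    expect_equal(unname(ev$counts), c(tp, fp, fn))
  }
})
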