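# ML engine wrappers: likelihood contracts, branch-length optimization,
# tree search, bootstrap supports, external-tool adapters.

test_that("two identical leaves at ~zero distance match the closed form", {
  m <- aa_model("LG")
  aln <- aa_alignment(c(x = "MKV", y = "MKV"))
  tr <- ape::read.tree(text = "(x:1e-9,y:1e-9);")
  expect_equal(tree_log_likelihood(tr, aln),
               sum(log(m$pi[c("M", "K", "V")])), tolerance = 1e-6)
})

test_that("pruning likelihood equals exhaustive enumeration (4 leaves, gaps, X)", {
  set.seed(3)
  m <- aa_model("LG")
  tr <- ape::rtree(4)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  aln <- evolve_family(ape::unroot(tr), 8, seed = 3)$aln
  ch <- strsplit(aln$rows[[1]], "", fixed = TRUE)[[1]]
  ch[2] <- "-"; ch[4] <- "X"
  aln$rows[[1]] <- paste(ch, collapse = "")
  expect_equal(tree_log_likelihood(tr, aln), enum_loglik(tr, aln, m),
               tolerance = 1e-10)
})

test_that("all-gap columns contribute exactly zero", {
  set.seed(8)
  tr <- ape::rtree(4); tr$edge.length <- stats::runif(6, 0.1, 0.4)
  aln <- evolve_family(ape::unroot(tr), 30, seed = 8)$aln
  ll0 <- tree_log_likelihood(tr, aln)
  m <- as.matrix(aln)
  m2 <- cbind(m, matrix("-", nrow(m), 5))
  aln2 <- aa_alignment(stats::setNames(apply(m2, 1, paste, collapse = ""),
                                       rownames(m2)))
  expect_equal(tree_log_likelihood(tr, aln2), ll0, tolerance = 1e-9)
})

test_that("likelihood validates its inputs", {
  aln <- aa_alignment(c(x = "MKV", y = "MKL"))
  tr <- ape::read.tree(text = "(x:0.1,z:0.1);")
  expect_error(tree_log_likelihood(tr, aln), "differ")
  tr2 <- ape::read.tree(text = "(x:-0.1,y:0.1);")
  expect_error(tree_log_likelihood(tr2, aln), "negative branch length")
})

test_that("optimize_branch_lengths: identical pair collapses to ~zero", {
  row <- paste(rep(c("M", "K", "V", "L"), 25), collapse = "")
  aln <- aa_alignment(c(x = row, y = row))
  fit <- optimize_branch_lengths(ape::read.tree(text = "(x:0.3,y:0.3);"), aln)
  expect_lte(sum(fit$tree$edge.length), 1e-6)
})

test_that("two-sequence optimum matches a grid search of the likelihood", {
  set.seed(12)
  tr0 <- ape::read.tree(text = "(x:0.15,y:0.15);")
  aln <- evolve_family(tr0, 150, seed = 12)$aln
  fit <- optimize_branch_lengths(ape::read.tree(text = "(x:0.5,y:0.5);"), aln)
  grid <- seq(0.01, 1.2, by = 1e-3)
  ll <- vapply(grid, function(t) {
    tr <- ape::read.tree(text = sprintf("(x:%f,y:%f);", t / 2, t / 2))
    tree_log_likelihood(tr, aln)
  }, numeric(1))
  t_grid <- grid[which.max(ll)]
  expect_equal(sum(fit$tree$edge.length), t_grid, tolerance = 2e-3)
  expect_gte(fit$log_likelihood, max(ll) - 1e-6)
})

test_that("branch-length optimization never decreases the log-likelihood", {
  set.seed(21)
  for (i in 1:3) {
    tr <- ape::rtree(5); tr$edge.length <- stats::runif(8, 0.05, 0.5)
    aln <- evolve_family(ape::unroot(tr), 60, seed = 20 + i)$aln
    start <- tr; start$edge.length <- rep(0.3, 8)  # deliberately wrong
    ll0 <- tree_log_likelihood(start, aln)
    fit <- optimize_branch_lengths(start, aln)
    expect_gte(fit$log_likelihood, ll0 - 1e-8)
  }
})

test_that("build_tree recovers a known 5-taxon topology", {
  set.seed(31)
  true <- ape::unroot(ape::rtree(5))
  true$edge.length <- stats::runif(nrow(true$edge), 0.1, 0.5)
  aln <- evolve_family(true, 500, seed = 31)$aln
  fit <- build_tree(aln, seed = 1)
  expect_equal(phangorn::RF.dist(fit$tree, true), 0)
  # starting from the truth can only match or improve
  fit2 <- build_tree(aln, start = true, seed = 1)
  bl_only <- optimize_branch_lengths(true, aln)
  expect_gte(fit2$log_likelihood, bl_only$log_likelihood - 1e-6)
})

test_that("build_tree handles the minimal cases", {
  set.seed(41)
  aln3 <- rand_alignment(3, 60, gap_prob = 0.1)
  fit3 <- build_tree(aln3, seed = 1)
  expect_equal(sort(fit3$tree$tip.label), sort(names(aln3$rows)))
  expect_error(build_tree(aa_alignment(c(a = "MKV")), seed = 1), "at least 2")
})

test_that("re-evaluating a fit reproduces its log-likelihood", {
  pl <- small_split_family(61, n_ref = 4, len = 120)
  fit <- build_tree(pl$aln, seed = 2)
  expect_equal(tree_log_likelihood(fit$tree, pl$aln), fit$log_likelihood,
               tolerance = 1e-6)
})

test_that("bootstrap supports are valid, deterministic and label-stable", {
  set.seed(51)
  true <- ape::read.tree(text = "((a:0.2,b:0.2):0.5,(c:0.2,d:0.2):0.5);")
  aln <- evolve_family(ape::unroot(true), 800, seed = 51)$aln
  fit <- build_tree(aln, seed = 1)
  st <- bootstrap_supports(aln, fit$tree, n_reps = 40, seed = 7)
  sup <- tree_supports(st, missing = NA)
  expect_true(all(stats::na.omit(sup) >= 0 & stats::na.omit(sup) <= 1))
  # strongly informative central branch
  central <- sup[!is.na(sup)]
  expect_gte(max(central), 0.9)
  # identical under re-run (determinism) and row permutation
  st2 <- bootstrap_supports(aln, fit$tree, n_reps = 40, seed = 7)
  expect_identical(st$node.label, st2$node.label)
  perm <- aa_alignment(aln$rows[rev(names(aln$rows))])
  st3 <- bootstrap_supports(perm, fit$tree, n_reps = 40, seed = 7)
  expect_identical(st$node.label, st3$node.label)
  expect_error(bootstrap_supports(aln, fit$tree, n_reps = 0), ">= 1")
})

test_that("external adapters validate their tools and outputs", {
  # missing executable fails at configuration time
  expect_error(external_aligner("no_such_tool_xyz {input}"),
               "configuration error")
  # 'cat' is a degenerate aligner: valid only when input is already aligned
  al <- external_aligner("cat {input}")
  seqs <- data.frame(id = c("a", "b"), genome = "g",
                     residues = c("MKVL", "MKIL"), length = 4L,
                     stringsAsFactors = FALSE)
  aln <- al(seqs)
  expect_s3_class(aln, "aa_alignment")
  expect_equal(aln_ungap(aln, "a"), "MKVL")
  tb <- external_treebuilder("fasttree -quiet {input}")
  pl <- small_split_family(71, n_ref = 4, len = 120)
  tr <- tb(pl$aln)
  expect_setequal(tr$tip.label, names(pl$aln$rows))
  sup <- tree_supports(tr, missing = NA)
  expect_true(all(stats::na.omit(sup) >= 0 & stats::na.omit(sup) <= 1))
})
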