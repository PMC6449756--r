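# Independent oracles used across the suite. Deliberately implemented
# from first principles (matrix exponentials + exhaustive enumeration),
# not via the package's likelihood path.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Exhaustive-state log-likelihood: sum over columns of
# sum_{internal assignments} pi(root) * prod_edges P_e[parent, child],
# with tips observed (missing = factor 1). Feasible for <= 5 leaves.
enum_loglik <- function(tree, msa, model = aa_model("LG")) {
  tr <- ape::reorder.phylo(phylosplit:::safe_unroot(tree), "postorder")
  ntip <- ape::Ntip(tr)
  chars <- as.matrix(msa)[tr$tip.label, , drop = FALSE]
  P <- lapply(seq_len(nrow(tr$edge)), function(k)
    as.matrix(Matrix::expm(model$Q * tr$edge.length[k])))
  root <- unique(setdiff(tr$edge[, 1], tr$edge[, 2]))
  internal <- sort(unique(tr$edge[, 1]))
  G <- as.matrix(expand.grid(rep(list(seq_len(20L)), length(internal))))
  colnames(G) <- internal
  ll <- 0
  for (col in seq_len(msa$n_cols)) {
    pr <- model$pi[G[, as.character(root)]]
    for (k in seq_len(nrow(tr$edge))) {
      par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
      sp <- G[, as.character(par)]
      if (ch <= ntip) {
        obs <- chars[ch, col]
        if (obs %in% c("-", "X", "?")) next
        pr <- pr * P[[k]][cbind(sp, match(obs, AA20))]
      } else {
        pr <- pr * P[[k]][cbind(sp, G[, as.character(ch)])]
      }
    }
    ll <- ll + log(sum(pr))
  }
  ll
}

# Brute-force aligned-overlap count: per-column double loop.
overlap_bruteforce <- function(row1, row2) {
  c1 <- strsplit(row1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(row2, "", fixed = TRUE)[[1]]
  a12 <- 0L
  for (k in seq_along(c1))
    if (c1[k] != "-" && c2[k] != "-") a12 <- a12 + 1L
  list(l1 = sum(c1 != "-"), l2 = sum(c2 != "-"), a12 = a12)
}

# Random gapped row over the AA alphabet.
rand_gapped_row <- function(n_cols, gap_prob = 0.5) {
  ch <- ifelse(stats::runif(n_cols) < gap_prob, "-",
               sample(AA20, n_cols, replace = TRUE))
  if (all(ch == "-")) ch[sample.int(n_cols, 1L)] <- sample(AA20, 1L)
  paste(ch, collapse = "")
}

rand_alignment <- function(n_rows, n_cols, gap_prob = 0.3) {
  rows <- vapply(seq_len(n_rows), function(i) rand_gapped_row(n_cols, gap_prob),
                 character(1))
  names(rows) <- paste0("s", seq_len(n_rows))
  # guarantee no all-gap column
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  for (j in which(colSums(m != "-") == 0L)) m[1L, j] <- sample(AA20, 1L)
  aa_alignment(stats::setNames(apply(m, 1L, paste, collapse = ""), names(rows)))
}

# Canonical bipartition set of an unrooted tree: each internal edge as the
# sorted label set of its smaller (ties: lexicographically first) side.
bip_set <- function(tree) {
  tr <- phylosplit:::safe_unroot(tree)
  ntip <- ape::Ntip(tr)
  if (tr$Nnode <= 1L) return(character(0))
  root <- unique(setdiff(tr$edge[, 1], tr$edge[, 2]))
  labs <- sort(tr$tip.label)
  out <- character(0)
  for (node in setdiff(unique(tr$edge[, 1]), root)) {
    tips <- unlist(phangorn::Descendants(tr, node, type = "tips"))
    side <- sort(tr$tip.label[tips])
    other <- setdiff(labs, side)
    pick <- if (length(side) < length(other) ||
                (length(side) == length(other) &&
                 paste(side, collapse = ",") < paste(other, collapse = ",")))
      side else other
    if (length(pick) >= 2L && length(pick) <= ntip - 2L)
      out <- c(out, paste(pick, collapse = ","))
  }
  sort(unique(out))
}

# Small planted-split family fixture.
small_split_family <- function(seed, n_ref = 6L, len = 200L) {
  tr <- ref_species_tree(n_ref, seed = seed)
  fa <- evolve_family(tr, len, seed = seed,
                      family_id = sprintf("fam_s%d", seed))
  plant_split(fa, seed = seed)
}

small_paralog_family <- function(seed, n_ref = 6L, len = 200L,
                                 dup_depth = 0.4) {
  tr <- ref_species_tree(n_ref, seed = seed)
  plant_paralog_pair(tr, len, dup_depth = dup_depth, seed = seed,
                     family_id = sprintf("fam_p%d", seed))
}
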