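# Built-in progressive aligner: sequential profile alignment with
# BLOSUM62 sum-of-pairs scores and a linear gap penalty. It is a
# fallback so the pipeline runs with no external tools; for production
# alignments plug in mafft via external_aligner(). The synthetic-data
# module emits exact (indel-free) alignments, so this code is off the
# critical path there.

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62[AA_LEVELS, AA_LEVELS]
  storage.mode(b) <- "double"
  b
}

profile_counts <- function(m) {
  # 20 x n_cols residue counts; X spread uniformly
  pc <- matrix(0, 20L, ncol(m), dimnames = list(AA_LEVELS, NULL))
  for (a in AA_LEVELS) pc[a, ] <- colSums(m == a)
  pc <- pc + matrix(colSums(m == "X") / 20, 20L, ncol(m), byrow = TRUE)
  pc
}

# Needleman-Wunsch on two profiles; returns the merged character matrix.
align_profiles <- function(ma, mb, gap = -6) {
  ca <- profile_counts(ma); cb <- profile_counts(mb)
  wa <- colSums(ca); wb <- colSums(cb)
  S <- t(ca) %*% blosum62_matrix() %*% cb
  na <- ncol(ma); nb <- ncol(mb)
  M <- matrix(-Inf, na + 1L, nb + 1L)
  M[1L, ] <- c(0, cumsum(gap * wb))
  M[, 1L] <- c(0, cumsum(gap * wa))
  P <- matrix(0L, na + 1L, nb + 1L)  # 1 diag, 2 up (gap in B), 3 left (gap in A)
  for (i in seq_len(na)) {
    mi1 <- M[i, ]; gi <- gap * wa[i]
    row <- numeric(nb + 1L); row[1L] <- M[i, 1L] + gi
    pr <- integer(nb + 1L); pr[1L] <- 2L
    si <- S[i, ]
    for (j in seq_len(nb)) {
      d <- mi1[j] + si[j]
      u <- mi1[j + 1L] + gi
      l <- row[j] + gap * wb[j]
      if (d >= u && d >= l) { row[j + 1L] <- d; pr[j + 1L] <- 1L }
      else if (u >= l)      { row[j + 1L] <- u; pr[j + 1L] <- 2L }
      else                  { row[j + 1L] <- l; pr[j + 1L] <- 3L }
    }
    M[i + 1L, ] <- row
    P[i + 1L, ] <- pr
  }
  # traceback
  i <- na + 1L; j <- nb + 1L
  ops <- integer(0)
  while (i > 1L || j > 1L) {
    op <- if (i == 1L) 3L else if (j == 1L) 2L else P[i, j]
    ops <- c(op, ops)
    if (op == 1L) { i <- i - 1L; j <- j - 1L }
    else if (op == 2L) i <- i - 1L
    else j <- j - 1L
  }
  out <- matrix("-", nrow(ma) + nrow(mb), length(ops))
  rownames(out) <- c(rownames(ma), rownames(mb))
  ia <- 0L; ib <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] != 3L) { ia <- ia + 1L; out[seq_len(nrow(ma)), k] <- ma[, ia] }
    if (ops[k] != 2L) { ib <- ib + 1L; out[nrow(ma) + seq_len(nrow(mb)), k] <- mb[, ib] }
  }
  out
}

#' Align protein sequences (built-in progressive fallback)
#'
#' Center-star progressive alignment: sequences join the growing profile
#' in decreasing length order, each merge a Needleman-Wunsch
#' profile-profile alignment under BLOSUM62 with a linear gap penalty.
#' Adequate for desk-scale families; use [external_aligner()] with mafft
#' for anything serious.
#'
#' @param seqs Data frame with `id` and `residues` columns (or a
#'   [gene_family()]).
#' @param gap Linear gap penalty per residue (negative).
#' @return An [aa_alignment()] whose ungapped rows equal the input
#'   residues.
#' @export
align_sequences <- function(seqs, gap = -6) {
  if (inherits(seqs, "gene_family")) seqs <- seqs$members
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  res <- clean_residues(seqs$residues)
  ids <- seqs$id
  ord <- order(-nchar(res), ids)
  mats <- lapply(ord, function(i) {
    m <- matrix(strsplit(res[i], "", fixed = TRUE)[[1]], nrow = 1L)
    rownames(m) <- ids[i]
    m
  })
  acc <- mats[[1L]]
  for (k in seq_along(mats)[-1L]) acc <- align_profiles(acc, mats[[k]], gap = gap)
  acc <- acc[ids, , drop = FALSE]
  aa_alignment(stats::setNames(apply(acc, 1L, paste, collapse = ""),
                               rownames(acc)))
}
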