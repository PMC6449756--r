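# Gapped protein alignments over a shared column axis.

#' Construct a protein multiple sequence alignment
#'
#' A light container: named, equal-length gapped strings (gap character
#' `-`). Column indices are 1-based. Use [occupancy()] for the residue
#' (non-gap) columns of a row and [aln_ungap()] to recover a row's
#' ungapped residues.
#'
#' @param rows Named character vector of gapped strings (one per sequence).
#' @return An object of class `aa_alignment` with elements `rows` and
#'   `n_cols`.
#' @examples
#' aa_alignment(c(g1 = "MK--", g2 = "--VL"))
#' @export
aa_alignment <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  ids <- names(rows)
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    stop("alignment rows must be named by sequence id")
  if (anyDuplicated(ids)) stop("duplicate row id ", ids[duplicated(ids)][1L])
  nc <- unique(nchar(rows))
  if (length(nc) != 1L)
    stop("rows differ in length: ", paste(nc, collapse = ", "))
  structure(list(rows = rows, n_cols = nc), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Protein alignment:", length(x$rows), "rows x", x$n_cols, "columns\n")
  show <- utils::head(x$rows, 6L)
  for (id in names(show)) {
    s <- show[[id]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-20s %s\n", id, s))
  }
  if (length(x$rows) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
as.matrix.aa_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$rows), "", fixed = TRUE))
  rownames(m) <- names(x$rows)
  m
}

#' Residue-occupied columns of an alignment row
#'
#' @param msa An [aa_alignment()].
#' @param id Row id.
#' @return Integer vector of 1-based column indices where the row holds a
#'   residue (anything but `-`).
#' @export
occupancy <- function(msa, id) {
  r <- aln_row(msa, id)
  which(strsplit(r, "", fixed = TRUE)[[1]] != "-")
}

#' Ungapped residues of an alignment row
#'
#' @inheritParams occupancy
#' @return Character scalar of the row's residues with gaps removed.
#' @export
aln_ungap <- function(msa, id) {
  gsub("-", "", aln_row(msa, id), fixed = TRUE)
}

aln_row <- function(msa, id) {
  stopifnot(inherits(msa, "aa_alignment"))
  if (!id %in% names(msa$rows)) stop("unknown alignment row: ", id)
  msa$rows[[id]]
}

#' Subset alignment columns (e.g. for bootstrap resampling)
#'
#' @param msa An [aa_alignment()].
#' @param idx Integer vector of column indices; duplicates and omissions
#'   allowed (column resampling with replacement).
#' @return An `aa_alignment` over the selected columns.
#' @export
aln_cols <- function(msa, idx) {
  stopifnot(all(idx >= 1L), all(idx <= msa$n_cols))
  m <- as.matrix(msa)[, idx, drop = FALSE]
  aa_alignment(stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m)))
}

#' Subset alignment rows
#'
#' @param msa An [aa_alignment()].
#' @param ids Row ids to keep, in the given order.
#' @return An `aa_alignment` restricted to `ids`.
#' @export
aln_rows <- function(msa, ids) {
  missing <- setdiff(ids, names(msa$rows))
  if (length(missing) > 0L) stop("unknown alignment row: ", missing[1L])
  aa_alignment(msa$rows[ids])
}

#' Drop all-gap columns
#'
#' @param msa An [aa_alignment()].
#' @return An `aa_alignment` without columns that are gaps in every row.
#' @export
aln_drop_allgap <- function(msa) {
  m <- as.matrix(msa)
  keep <- colSums(m != "-") > 0L
  if (all(keep)) return(msa)
  if (!any(keep)) stop("alignment has only all-gap columns")
  aln_cols(msa, which(keep))
}

#' Read an aligned FASTA file
#'
#' `.` gap characters are normalized to `-`; residues are cleaned as in
#' [read_fasta()]. All rows must have equal (gapped) length.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [aa_alignment()].
#' @export
read_alignment <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "[[:space:]]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate id ", ids[duplicated(ids)][1L])
  rows <- chartr(".", "-", toupper(as.character(ss)))
  # clean residues but keep gap placeholders in place
  rows <- vapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    res <- ch != "-"
    ch[res] <- strsplit(clean_residues(paste(ch[res], collapse = "")), "",
                        fixed = TRUE)[[1]]
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(rows) <- ids
  aa_alignment(rows)
}

#' Write an alignment as aligned FASTA
#'
#' All-gap columns are stripped before writing, so a written alignment
#' never contains an empty column.
#'
#' @param msa An [aa_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  msa <- aln_drop_allgap(msa)
  write_fasta(data.frame(id = names(msa$rows), residues = unname(msa$rows),
                         stringsAsFactors = FALSE), path)
}

# phangorn interop: gaps and X enter as all-ones partial likelihoods
# (missing data).
as_phydat <- function(msa) {
  m <- as.matrix(msa)
  m[m == "X"] <- "?"
  phangorn::phyDat(m, type = "AA")
}
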