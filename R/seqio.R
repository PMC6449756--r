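# Protein sequence I/O and residue cleaning.
#
# The working alphabet is the 20 canonical amino acids plus X. Rare IUPAC
# codes (B, Z, U, O, J) are remapped to X on input; X is treated as missing
# data by every downstream likelihood computation.

AA_LEVELS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Clean a raw protein string
#'
#' Upper-cases, strips terminal stop symbols (`*`) and maps the ambiguity
#' codes B/Z/U/O/J (and any internal `*`) to `X`.
#'
#' @param x Character vector of raw residue strings.
#' @return Character vector of cleaned residue strings.
#' @keywords internal
clean_residues <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", x))
  x <- sub("\\*+$", "", x)
  x <- chartr("BZUOJ*", "XXXXXX", x)
  bad <- regmatches(x, regexpr(sprintf("[^%sX]", paste(AA_LEVELS, collapse = "")), x))
  if (length(unlist(bad)) > 0L)
    stop("invalid residue symbol(s): ", paste(unique(unlist(bad)), collapse = ", "))
  x
}

#' Read protein sequences from a FASTA file
#'
#' Headers are parsed as `>id [key=value ...]`: the first whitespace-separated
#' token is the sequence id; an optional `genome=` key assigns the genome of
#' origin. When a family map carries genome labels too, the map wins (single
#' source of truth, see [build_families()]).
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param genome Optional single genome label applied to every record that
#'   has no `genome=` header key.
#' @return A data frame with columns `id`, `genome`, `residues`, `length`
#'   (residue count in amino acids).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 genome=wheat", "MKVLW"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[[`, character(1), 1L)
  if (any(ids == "")) stop("empty sequence id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate id ", dup[1L], " in ", path)
  gen <- rep(if (is.null(genome)) NA_character_ else genome, length(ids))
  m <- regmatches(headers, regexpr("genome=[^[:space:]]+", headers))
  has <- grepl("genome=", headers)
  gen[has] <- sub("^genome=", "", m)
  res <- clean_residues(as.character(ss))
  if (any(nchar(res) == 0L))
    stop("empty sequence for id ", ids[which(nchar(res) == 0L)[1L]])
  data.frame(id = ids, genome = gen, residues = res,
             length = nchar(res), stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Data frame as returned by [read_fasta()] (columns `id`,
#'   `residues`, optionally `genome`).
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    hdr <- paste0(">", seqs$id[i])
    if (!is.null(seqs$genome) && !is.na(seqs$genome[i]))
      hdr <- paste0(hdr, " genome=", seqs$genome[i])
    writeLines(hdr, con)
    r <- seqs$residues[i]
    starts <- seq(1L, nchar(r), by = width)
    writeLines(substring(r, starts, pmin(starts + width - 1L, nchar(r))), con)
  }
  invisible(path)
}
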