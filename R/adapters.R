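# Adapters for external aligners and tree builders (e.g. mafft,
# FastTree). Disabled unless configured; the pipeline runs fully on the
# built-in engine without them. Adapter output is validated against the
# same invariants as built-in results.

run_template <- function(template, input, output = NULL) {
  cmd <- gsub("{input}", shQuote(input), template, fixed = TRUE)
  capture <- !grepl("{output}", template, fixed = TRUE)
  if (!capture) cmd <- gsub("{output}", shQuote(output), cmd, fixed = TRUE)
  res <- suppressWarnings(system(paste(cmd, "2>/tmp/phylosplit_tool_stderr"),
                                 intern = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L) {
    err <- tryCatch(readLines("/tmp/phylosplit_tool_stderr", warn = FALSE),
                    error = function(e) character())
    stop("external tool failed (exit ", status, "): ", cmd, "\n",
         paste(utils::tail(err, 5L), collapse = "\n"))
  }
  if (capture) res else readLines(output, warn = FALSE)
}

check_executable <- function(template) {
  exe <- strsplit(trimws(template), "[[:space:]]+")[[1]][1]
  if (Sys.which(exe) == "")
    stop("configuration error: executable '", exe, "' not found on PATH")
  invisible(exe)
}

#' Adapter around an external multiple-sequence aligner
#'
#' `template` is a shell command with an `{input}` placeholder for a FASTA
#' file (and optionally `{output}`; without it, stdout is captured), e.g.
#' `"mafft --auto {input}"`. The executable is resolved at adapter
#' creation, so a missing tool fails at configuration time, not mid-run.
#' The returned function has the contract of the built-in aligner: it maps
#' a sequence data frame to an [aa_alignment()]; the row set and the
#' ungapped residues must be preserved, otherwise the adapter errors.
#'
#' @param template Command template with `{input}` (and optional
#'   `{output}`).
#' @return A function `(seqs) -> aa_alignment`.
#' @export
external_aligner <- function(template) {
  check_executable(template)
  function(seqs) {
    if (inherits(seqs, "gene_family")) seqs <- seqs$members
    fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
    on.exit(unlink(c(fin, fout)))
    write_fasta(seqs, fin)
    out <- run_template(template, fin, fout)
    writeLines(out, fout)
    aln <- read_alignment(fout)
    if (!setequal(names(aln$rows), seqs$id))
      stop("aligner changed the sequence set")
    for (id in seqs$id)
      if (aln_ungap(aln, id) != clean_residues(seqs$residues[seqs$id == id]))
        stop("aligner altered residues of ", id)
    aln
  }
}

#' Adapter around an external tree builder
#'
#' Same conventions as [external_aligner()]; the template receives an
#' aligned FASTA file, e.g. `"fasttree {input}"` (FastTree reads protein
#' alignments by default and emits Newick with local supports on internal
#' nodes, which are normalized to [0,1]).
#'
#' @param template Command template with `{input}` (and optional
#'   `{output}`).
#' @return A function `(msa) -> phylo` with supports on `node.label`.
#' @export
external_treebuilder <- function(template) {
  check_executable(template)
  function(msa) {
    fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".nwk")
    on.exit(unlink(c(fin, fout)))
    write_alignment(msa, fin)
    out <- run_template(template, fin, fout)
    tr <- read_newick(paste(out, collapse = ""))
    if (!setequal(tr$tip.label, names(msa$rows)))
      stop("tree builder changed the leaf set")
    sup <- tree_supports(tr, missing = NA)
    if (any(!is.na(sup) & (sup < 0 | sup > 1)))
      stop("tree builder emitted supports outside [0,1]")
    tr
  }
}
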