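# Gene families: the unit of analysis. A family stands in for a
# hierarchical orthologous group (HOG) or a database gene family; family
# membership is an input, never inferred here.

#' Construct a gene family
#'
#' @param family_id Family identifier.
#' @param members Data frame of member sequences (columns `id`, `genome`,
#'   `residues`, `length`, as from [read_fasta()]).
#' @param target_genome Label of the genome whose annotation is screened
#'   for split genes.
#' @return An object of class `gene_family`.
#' @export
gene_family <- function(family_id, members, target_genome) {
  stopifnot(is.character(family_id), length(family_id) == 1L, nzchar(family_id))
  stopifnot(is.data.frame(members),
            all(c("id", "genome", "residues", "length") %in% names(members)))
  if (anyDuplicated(members$id))
    stop("duplicate member id in family ", family_id)
  if (anyNA(members$genome))
    stop("family ", family_id, ": every member needs a genome label")
  structure(list(family_id = family_id, members = members,
                 target_genome = target_genome),
            class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  n_t <- sum(x$members$genome == x$target_genome)
  cat(sprintf("Gene family %s: %d members (%d from target genome '%s')\n",
              x$family_id, nrow(x$members), n_t, x$target_genome))
  invisible(x)
}

#' Read a gene-family membership map
#'
#' Tab-separated file with a header row and columns `gene_id`, `genome_id`,
#' `family_id`. Families must partition genes: a gene listed in two
#' families is a hard error.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `gene_id`, `genome_id`, `family_id`.
#' @export
read_family_map <- function(path) {
  stopifnot(file.exists(path))
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "genome_id", "family_id")
  if (!all(need %in% names(map)))
    stop("family map needs columns: ", paste(need, collapse = ", "))
  map <- map[, need]
  multi <- unique(map$gene_id[duplicated(map[, c("gene_id")])])
  # a gene may appear once per family only, and in a single family
  fam_per_gene <- tapply(map$family_id, map$gene_id, function(f) length(unique(f)))
  if (any(fam_per_gene > 1L))
    stop("gene ", names(fam_per_gene)[fam_per_gene > 1L][1L],
         " is listed in more than one family")
  if (length(multi) > 0L)
    stop("gene ", multi[1L], " listed twice in the family map")
  map
}

#' Assemble gene families from sequences and a family map
#'
#' Genome labels come from the map (single source of truth); sequences
#' absent from the map are reported via `message()` and dropped.
#'
#' @param seqs Data frame of sequences ([read_fasta()] output, possibly
#'   row-bound across genomes).
#' @param map Family map data frame ([read_family_map()]) or path to one.
#' @param target_genome Target genome label.
#' @return Named list of [gene_family()] objects, keyed and sorted by
#'   family id.
#' @export
build_families <- function(seqs, map, target_genome) {
  if (is.character(map)) map <- read_family_map(map)
  if (anyDuplicated(seqs$id)) stop("duplicate id ", seqs$id[duplicated(seqs$id)][1L])
  orphans <- setdiff(seqs$id, map$gene_id)
  if (length(orphans) > 0L)
    message(length(orphans), " gene(s) in no family were dropped: ",
            paste(utils::head(orphans, 5L), collapse = ", "),
            if (length(orphans) > 5L) ", ..." else "")
  unseq <- setdiff(map$gene_id, seqs$id)
  if (length(unseq) > 0L)
    message(length(unseq), " mapped gene(s) without sequence were dropped")
  map <- map[map$gene_id %in% seqs$id, , drop = FALSE]
  fams <- lapply(split(map, map$family_id), function(fm) {
    mem <- seqs[match(fm$gene_id, seqs$id), , drop = FALSE]
    mem$genome <- fm$genome_id
    rownames(mem) <- NULL
    gene_family(fm$family_id[1L], mem, target_genome)
  })
  fams[order(names(fams))]
}
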