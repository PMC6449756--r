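# Candidate split-gene pairs: same-family target-genome genes that are
# long enough and (nearly) non-overlapping in the family alignment.

#' Aligned overlap between two alignment rows
#'
#' Counts residues of the two rows that sit in the same alignment column
#' (`a12`), together with the two ungapped lengths. Symmetric in the two
#' ids.
#'
#' @param msa An [aa_alignment()].
#' @param id1,id2 Row ids.
#' @return An object of class `overlap_stats`: list with `id1`, `id2`,
#'   `l1`, `l2`, `a12`.
#' @examples
#' msa <- aa_alignment(c(g1 = "MK--", g2 = "--VL"))
#' aligned_overlap(msa, "g1", "g2")
#' @export
aligned_overlap <- function(msa, id1, id2) {
  o1 <- occupancy(msa, id1)
  o2 <- occupancy(msa, id2)
  structure(list(id1 = id1, id2 = id2,
                 l1 = length(o1), l2 = length(o2),
                 a12 = length(intersect(o1, o2))),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap %s/%s: l1=%d l2=%d a12=%d\n",
              x$id1, x$id2, x$l1, x$l2, x$a12))
  invisible(x)
}

#' Overlap filter for candidate pairs
#'
#' A pair qualifies when strictly fewer than `max_frac` of the residues of
#' *both* fragments share an alignment column:
#' `a12 < max_frac * l1` AND `a12 < max_frac * l2`. The inequalities are
#' strict, so a pair sitting exactly on the boundary is rejected.
#'
#' @param stats An `overlap_stats` object from [aligned_overlap()].
#' @param max_frac Maximum overlap fraction (default 0.1).
#' @return Logical scalar.
#' @export
passes_overlap_filter <- function(stats, max_frac = 0.1) {
  stopifnot(inherits(stats, "overlap_stats"), max_frac >= 0)
  stats$a12 < max_frac * stats$l1 && stats$a12 < max_frac * stats$l2
}

#' Read an optional gene-location table
#'
#' Two tab-separated columns `gene_id`, `location` (header required). Used
#' by the optional location gate of [enumerate_candidates()]: candidate
#' pairs must share a location (e.g. the same chromosome arm) when the
#' gate is active.
#'
#' @param path Path to the TSV file.
#' @return Named character vector `gene_id -> location`.
#' @export
read_locations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "location") %in% names(tab)))
    stop("location table needs columns gene_id, location")
  stats::setNames(tab$location, tab$gene_id)
}

#' Enumerate candidate split-gene pairs in a family
#'
#' All unordered pairs of target-genome genes whose ungapped lengths are
#' both at least `min_len` amino acids and that pass
#' [passes_overlap_filter()]. A family with fewer than two target-genome
#' genes yields an empty set (not an error).
#'
#' @param family A [gene_family()].
#' @param msa Family alignment covering the family's members.
#' @param min_len Minimum fragment length in amino acids (default 50).
#' @param max_frac Maximum overlap fraction (default 0.1).
#' @param locations Optional named vector `gene_id -> location`
#'   ([read_locations()]); when given, pairs with differing (or missing)
#'   locations are excluded.
#' @return Data frame with columns `family_id`, `id1`, `id2` (pair ordered
#'   lexicographically), `l1`, `l2`, `a12`, sorted by `id1` then `id2`.
#' @export
enumerate_candidates <- function(family, msa, min_len = 50L, max_frac = 0.1,
                                 locations = NULL) {
  stopifnot(inherits(family, "gene_family"), inherits(msa, "aa_alignment"))
  tg <- sort(family$members$id[family$members$genome == family$target_genome])
  missing_rows <- setdiff(tg, names(msa$rows))
  if (length(missing_rows) > 0L)
    stop("family ", family$family_id, ": target gene ", missing_rows[1L],
         " missing from alignment")
  empty <- data.frame(family_id = character(), id1 = character(),
                      id2 = character(), l1 = integer(), l2 = integer(),
                      a12 = integer(), stringsAsFactors = FALSE)
  if (length(tg) < 2L) return(empty)
  occ <- lapply(tg, function(id) occupancy(msa, id))
  names(occ) <- tg
  len <- lengths(occ)
  out <- empty
  for (i in seq_len(length(tg) - 1L)) for (j in seq.int(i + 1L, length(tg))) {
    a <- tg[i]; b <- tg[j]
    if (len[[a]] < min_len || len[[b]] < min_len) next
    if (!is.null(locations)) {
      la <- locations[a]; lb <- locations[b]
      if (is.na(la) || is.na(lb) || la != lb) next
    }
    a12 <- length(intersect(occ[[a]], occ[[b]]))
    st <- structure(list(id1 = a, id2 = b, l1 = len[[a]], l2 = len[[b]],
                         a12 = a12), class = "overlap_stats")
    if (passes_overlap_filter(st, max_frac))
      out <- rbind(out, data.frame(family_id = family$family_id, id1 = a,
                                   id2 = b, l1 = len[[a]], l2 = len[[b]],
                                   a12 = a12, stringsAsFactors = FALSE))
  }
  out[order(out$id1, out$id2), , drop = FALSE]
}
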