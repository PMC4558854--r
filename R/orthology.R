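# Reciprocal-best-hit orthology and core-genome reconstruction.
#
# Orthologs between two genomes are defined operationally as gene pairs
# that are each other's best alignment hit in both search directions.  A
# genus core genome is the set of reference-genome loci with an ortholog in
# every member genome; the last-common-ancestor (LCA) core of two genera is
# the intersection of their cores, matched through an ortholog table
# bridging the two reference genomes.  Paralog copy number is deliberately
# ignored throughout (presence/absence of an ortholog only).

#' Reciprocal best hits between two genomes
#'
#' @param best_ab best-hit table from [best_hits()] run with genome A as
#'   queries and genome B as subjects
#' @param best_ba the reverse direction
#' @param a_id,b_id genome identifiers for the two directions
#' @return an `ortholog_table`: data.frame (`a_locus`, `b_locus`) of
#'   one-to-one reciprocal pairs with attributes `a_id` and `b_id`
#' @export
reciprocal_best_hits <- function(best_ab, best_ba, a_id, b_id) {
  if (identical(a_id, b_id) && !identical(best_ab, best_ba)) {
    stop("genome ids are identical but the hit tables differ")
  }
  back <- stats::setNames(best_ba$subject_locus, best_ba$query_locus)
  keep <- !is.na(back[best_ab$subject_locus]) &
    back[best_ab$subject_locus] == best_ab$query_locus
  keep[is.na(keep)] <- FALSE
  pairs <- data.frame(a_locus = best_ab$query_locus[keep],
                      b_locus = best_ab$subject_locus[keep],
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(pairs, a_id = a_id, b_id = b_id,
            class = c("ortholog_table", "data.frame"))
}

#' Compute the reciprocal-best-hit table for a genome pair
#'
#' Convenience wrapper running [best_hits()] in both directions.
#'
#' @param genome_a,genome_b gene-record data.frames
#' @param params an [align_params()]
#' @return an `ortholog_table`
#' @export
rbh_table <- function(genome_a, genome_b, params = align_params()) {
  a_id <- genome_a$genome_id[[1L]]
  b_id <- genome_b$genome_id[[1L]]
  reciprocal_best_hits(best_hits(genome_a, genome_b, params),
                       best_hits(genome_b, genome_a, params),
                       a_id, b_id)
}

# partner lookup in either orientation; NA when absent
#' @noRd
ortholog_partner <- function(table, genome_id, loci) {
  if (identical(attr(table, "a_id"), genome_id)) {
    stats::setNames(table$b_locus, table$a_locus)[loci]
  } else if (identical(attr(table, "b_id"), genome_id)) {
    stats::setNames(table$a_locus, table$b_locus)[loci]
  } else {
    stop("ortholog table does not cover genome ", genome_id)
  }
}

# find the table covering a given genome pair in a list of tables
#' @noRd
find_table <- function(tables, x_id, y_id) {
  for (tb in tables) {
    ids <- c(attr(tb, "a_id"), attr(tb, "b_id"))
    if (setequal(ids, c(x_id, y_id))) return(tb)
  }
  NULL
}

#' Genus core genome anchored on a reference genome
#'
#' The core is the set of reference loci that have a reciprocal-best-hit
#' ortholog in every member genome.  An ortholog table must exist for each
#' (reference, member) pair; a missing table is an error, never an implicit
#' absence.
#'
#' @param reference gene-record data.frame of the reference genome
#' @param member_ids character vector of member genome ids (the reference
#'   itself need not be listed)
#' @param tables list of `ortholog_table`s covering every
#'   (reference, member) pair
#' @param clade label for the clade (e.g. the genus name)
#' @return a `core_genome`: list with `clade`, `reference`, `loci`
#'   (character vector of reference locus ids) and `members`
#' @export
genus_core <- function(reference, member_ids, tables, clade = "clade") {
  ref_id <- reference$genome_id[[1L]]
  loci <- reference$locus_id
  for (m in setdiff(member_ids, ref_id)) {
    tb <- find_table(tables, ref_id, m)
    if (is.null(tb)) {
      stop("no ortholog table for reference ", ref_id, " and member ", m)
    }
    partner <- ortholog_partner(tb, ref_id, loci)
    loci <- loci[!is.na(partner)]
  }
  structure(list(clade = clade, reference = ref_id, loci = sort(loci),
                 members = unique(c(ref_id, member_ids))),
            class = "core_genome")
}

#' Last-common-ancestor core of two genus cores
#'
#' Retains the genes conserved in both genus-specific core genomes.  The
#' result is expressed in the coordinates of `core_a`'s reference genome:
#' a locus of `core_a` survives if its bridge ortholog lies in `core_b`.
#'
#' @param core_a,core_b `core_genome` objects
#' @param bridge an `ortholog_table` linking the two reference genomes
#' @return a `core_genome` in `core_a`'s reference coordinates
#' @export
lca_core <- function(core_a, core_b, bridge) {
  ids <- c(attr(bridge, "a_id"), attr(bridge, "b_id"))
  if (!setequal(ids, c(core_a$reference, core_b$reference))) {
    stop("bridge table does not link the two reference genomes")
  }
  partner <- ortholog_partner(bridge, core_a$reference, core_a$loci)
  keep <- !is.na(partner) & partner %in% core_b$loci
  structure(list(clade = paste0(core_a$clade, "/", core_b$clade, " LCA"),
                 reference = core_a$reference,
                 loci = sort(core_a$loci[keep]),
                 members = unique(c(core_a$members, core_b$members))),
            class = "core_genome")
}

#' Account for core-genome loss in a target genome
#'
#' Splits the LCA core into loci retained in the target (those with a
#' reciprocal-best-hit ortholog) and loci lost, and tallies the lost genes
#' by functional category.  Loci without a category are counted under the
#' reserved label `"hypothetical"`.
#'
#' @param lca a `core_genome` (typically from [lca_core()])
#' @param target_id genome id of the target
#' @param orthologs an `ortholog_table` covering the LCA reference genome
#'   and the target
#' @param categories optional data.frame (`locus_id`, `category`) for the
#'   LCA reference genome's loci
#' @return a `loss_ledger`: list with `lca_size`, `retained`, `lost`
#'   (character vectors) and `category_counts` (data.frame `category`,
#'   `n_lost`)
#' @export
loss_accounting <- function(lca, target_id, orthologs, categories = NULL) {
  ids <- c(attr(orthologs, "a_id"), attr(orthologs, "b_id"))
  if (!setequal(ids, unique(c(lca$reference, target_id)))) {
    stop("ortholog table does not cover the LCA reference and the target")
  }
  partner <- ortholog_partner(orthologs, lca$reference, lca$loci)
  retained <- lca$loci[!is.na(partner)]
  lost <- setdiff(lca$loci, retained)

  cat_map <- character(0)
  if (!is.null(categories)) {
    cat_map <- stats::setNames(as.character(categories$category),
                               categories$locus_id)
  }
  lost_cat <- cat_map[lost]
  lost_cat[is.na(lost_cat) | lost_cat == ""] <- "hypothetical"
  if (length(lost_cat) == 0L) {
    counts <- data.frame(category = character(0), n_lost = integer(0),
                         stringsAsFactors = FALSE)
  } else {
    tab <- table(lost_cat)
    counts <- data.frame(category = names(tab),
                         n_lost = as.integer(tab),
                         stringsAsFactors = FALSE)
  }
  structure(list(lca_size = length(lca$loci), retained = retained,
                 lost = lost, target = target_id,
                 category_counts = counts),
            class = "loss_ledger")
}

#' @export
print.core_genome <- function(x, ...) {
  cat("Core genome [", x$clade, "]: ", length(x$loci),
      " loci on reference ", x$reference, " (", length(x$members),
      " genomes)\n", sep = "")
  invisible(x)
}

#' @export
print.loss_ledger <- function(x, ...) {
  cat("Loss ledger vs ", x$target, ": LCA core ", x$lca_size, ", retained ",
      length(x$retained), ", lost ", length(x$lost), "\n", sep = "")
  invisible(x)
}
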