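# Readers and writers for the plain-text interchange formats: CDS
# multi-FASTA (headers ">genome_id|locus_id" or bare locus ids), two-column
# category TSV, ortholog/hit tables, presence/absence matrices and loss
# ledgers.  FASTA parsing is delegated to Biostrings.

#' Read a CDS multi-FASTA into a gene-record table
#'
#' Headers of the form `>genome|locus` carry their own genome id; bare
#' headers require `genome_id`.  Sequences are upper-cased; input order is
#' preserved.  An empty file yields an empty table.
#'
#' @param path FASTA file path
#' @param genome_id genome id to assign when headers are bare locus ids
#' @return gene-record data.frame (`locus_id`, `genome_id`, `seq`,
#'   `category` all `NA`)
#' @export
read_cds_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    return(gene_records(character(0), character(0), character(0)))
  }
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e))
                  })
  headers <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  has_bar <- grepl("|", headers, fixed = TRUE)
  if (all(has_bar)) {
    gid <- sub("\\|.*$", "", headers)
    locus <- sub("^[^|]*\\|", "", headers)
  } else {
    if (is.null(genome_id)) {
      stop("headers in ", path, " carry no genome id; supply genome_id")
    }
    gid <- rep(genome_id, length(headers))
    locus <- headers
  }
  gene_records(locus, gid, unname(seqs))
}

#' Write gene records as CDS multi-FASTA
#'
#' @param records gene-record data.frame
#' @param path output path
#' @param width sequence line width
#' @return invisibly, `path`
#' @export
write_cds_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$genome_id[i], "|", records$locus_id[i]),
               con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a two-column locus/category TSV
#'
#' @param path TSV with header `locus_id<TAB>category`
#' @return data.frame (`locus_id`, `category`)
#' @export
read_category_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("locus_id", "category") %in% names(df))) {
    stop("category table ", path, " must have columns locus_id, category")
  }
  df[, c("locus_id", "category")]
}

#' @rdname read_category_tsv
#' @param categories data.frame (`locus_id`, `category`)
#' @export
write_category_tsv <- function(categories, path) {
  utils::write.table(categories[, c("locus_id", "category")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a best-hit or ortholog pair table as TSV
#'
#' Hit tables use the fixed column order `query_locus`, `subject_locus`,
#' `identity_pct`, `query_coverage_pct`, `score`; identities and coverages
#' are written as percentages.
#'
#' @param hits a [best_hits()] table
#' @param path output path
#' @export
write_hit_tsv <- function(hits, path) {
  out <- data.frame(query_locus = hits$query_locus,
                    subject_locus = hits$subject_locus,
                    identity_pct = round(100 * hits$identity, 2),
                    query_coverage_pct = round(100 * hits$query_coverage, 2),
                    score = hits$score, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_tsv
#' @param orthologs an `ortholog_table`
#' @export
write_ortholog_tsv <- function(orthologs, path) {
  utils::write.table(as.data.frame(orthologs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog pair TSV written by [write_ortholog_tsv()]
#'
#' @param path TSV path
#' @param a_id,b_id genome ids of the two columns
#' @return an `ortholog_table`
#' @export
read_ortholog_tsv <- function(path, a_id, b_id) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  structure(df[, c("a_locus", "b_locus")], a_id = a_id, b_id = b_id,
            class = c("ortholog_table", "data.frame"))
}

#' Write a presence/absence matrix as 0/1 TSV (loci rows, genome columns)
#'
#' @param presence a `presence_absence` or logical matrix
#' @param path output path
#' @export
write_presence_tsv <- function(presence, path) {
  mat <- if (inherits(presence, "presence_absence")) presence$matrix else
    presence
  df <- data.frame(locus = rownames(mat), apply(mat, 2L, as.integer),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a loss ledger (retained/lost loci and category summary)
#'
#' Emits `<stem>_loci.tsv` (locus, status) and `<stem>_categories.tsv`
#' (category, n_lost).
#'
#' @param ledger a [loss_accounting()] result
#' @param stem output path stem
#' @return invisibly, the two paths written
#' @export
write_loss_ledger <- function(ledger, stem) {
  loci <- data.frame(
    locus = c(ledger$retained, ledger$lost),
    status = c(rep("retained", length(ledger$retained)),
               rep("lost", length(ledger$lost))),
    stringsAsFactors = FALSE)
  p1 <- paste0(stem, "_loci.tsv")
  p2 <- paste0(stem, "_categories.tsv")
  utils::write.table(loci, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ledger$category_counts, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write a multiple alignment or supermatrix as aligned FASTA
#'
#' @param x a `multiple_alignment` or `supermatrix`
#' @param path output path
#' @export
write_alignment_fasta <- function(x, path) {
  rows <- if (inherits(x, "supermatrix")) x$aln else unclass(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in names(rows)) {
    writeLines(c(paste0(">", tx), rows[[tx]]), con)
  }
  invisible(path)
}

#' Write a supermatrix partition map in RAxML-style format
#'
#' One line per gene: `DNA, gene = start-end` (1-based inclusive).
#'
#' @param sm a `supermatrix`
#' @param path output path
#' @export
write_partitions <- function(sm, path) {
  type <- if (sm$alphabet == "nt") "DNA" else "AA"
  lines <- sprintf("%s, %s = %d-%d", type, sm$partitions$gene,
                   sm$partitions$start + 1L, sm$partitions$end)
  writeLines(lines, path)
  invisible(path)
}
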