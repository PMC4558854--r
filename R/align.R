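# Pairwise nucleotide CDS comparison: exact affine-gap local alignment with
# a shared-k-mer prefilter for all-vs-all speed.  This is the deterministic
# stand-in for a heuristic sequence-database search: every reported hit
# carries percent identity over the aligned columns, coverage of the query,
# and the raw alignment score.

#' Construct a gene-record table
#'
#' The package's common currency: one row per annotated CDS.
#'
#' @param locus_id character vector, unique within a genome
#' @param genome_id genome identifier (recycled if scalar)
#' @param seq nucleotide sequences (upper-cased; non-ACGT letters are kept
#'   and score as universal mismatches in alignments)
#' @param category optional functional category labels
#' @return data.frame with columns `locus_id`, `genome_id`, `seq`,
#'   `category`
#' @export
gene_records <- function(locus_id, genome_id, seq, category = NA_character_) {
  if (length(genome_id) == 1L) genome_id <- rep(genome_id, length(locus_id))
  stopifnot(length(locus_id) == length(seq),
            length(genome_id) == length(locus_id))
  if (any(nchar(seq) < 1)) stop("sequences must be non-empty")
  for (g in unique(genome_id)) {
    if (anyDuplicated(locus_id[genome_id == g])) {
      stop("locus_id values must be unique within genome ", g)
    }
  }
  data.frame(locus_id = as.character(locus_id),
             genome_id = as.character(genome_id),
             seq = toupper(as.character(seq)),
             category = rep_len(as.character(category), length(locus_id)),
             stringsAsFactors = FALSE)
}

#' Alignment scoring parameters
#'
#' Defaults follow common nucleotide-search practice: match +2, mismatch -3,
#' affine gaps costing `gap_open + L * gap_extend`.  Hits scoring below
#' `min_score` are suppressed (the stand-in for an E-value cutoff).  The
#' best-hit search only aligns pairs sharing at least one `kmer`-length
#' exact word.
#'
#' @param match,mismatch substitution scores
#' @param gap_open,gap_extend affine gap penalties (positive numbers)
#' @param min_score minimum reportable local-alignment score
#' @param kmer word size of the shared-word prefilter
#' @param min_words number of distinct shared words required before a pair
#'   is aligned.  At the default of 4, unrelated CDS essentially never
#'   trigger a full alignment (codon-usage bias makes 1-2 chance word
#'   collisions common), while genuine homologs share tens to hundreds of
#'   words up to roughly 25-30% nucleotide divergence; set to 1 for
#'   maximum sensitivity at all-vs-all cost
#' @return a list of class `align_params`
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = 5,
                         gap_extend = 2, min_score = 50, kmer = 11L,
                         min_words = 4L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            kmer >= 4, min_words >= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = min_score,
                 kmer = as.integer(kmer), min_words = as.integer(min_words)),
            class = "align_params")
}

# 5-letter nucleotide alphabet; every non-ACGT character maps to N, which
# mismatches everything (including itself)
#' @noRd
nt_sub_matrix <- function(params) {
  m <- matrix(params$mismatch, 5, 5,
              dimnames = list(c(NUCS, "N"), c(NUCS, "N")))
  diag(m) <- params$match
  m["N", "N"] <- params$mismatch
  m
}

#' @noRd
encode_nt <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1L]], NUCS)
  x[is.na(x)] <- 5L
  x
}

#' @noRd
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

# core alignment on encoded sequences; returns NULL or a hit row
#' @noRd
align_encoded <- function(qa, sa, params, submat) {
  res <- .align_dp(qa, sa, submat, params$gap_open, params$gap_extend,
                   local = TRUE)
  if (length(res$a_idx) == 0L) return(NULL)
  both <- res$a_idx > 0L & res$b_idx > 0L
  matches <- sum(both & qa[pmax(res$a_idx, 1L)] == sa[pmax(res$b_idx, 1L)] &
                   qa[pmax(res$a_idx, 1L)] != 5L)
  list(score = res$score,
       identity = matches / length(res$a_idx),
       q_span = range(res$a_idx[res$a_idx > 0L]),
       s_span = range(res$b_idx[res$b_idx > 0L]),
       n_columns = length(res$a_idx))
}

#' Align two CDS records by exact local dynamic programming
#'
#' Computes the optimal affine-gap local alignment on both the forward and
#' reverse-complement orientation of the subject and keeps the better.
#' Identity is matches over aligned columns (gap columns included);
#' query coverage is the fraction of the query inside the aligned region.
#'
#' @param a,b single gene records (one-row data.frames or lists with
#'   `locus_id` and `seq`)
#' @param params an [align_params()] object
#' @return one-row data.frame (`query_locus`, `subject_locus`, `identity`,
#'   `query_coverage`, `score`, `strand`), or `NULL` when the best score
#'   falls below `min_score`
#' @export
align_pair <- function(a, b, params = align_params()) {
  qseq <- toupper(a$seq[[1L]]); sseq <- toupper(b$seq[[1L]])
  if (nchar(qseq) == 0 || nchar(sseq) == 0) stop("sequences must be non-empty")
  submat <- nt_sub_matrix(params)
  qa <- encode_nt(qseq)
  fwd <- align_encoded(qa, encode_nt(sseq), params, submat)
  rev <- align_encoded(qa, encode_nt(revcomp(sseq)), params, submat)
  best <- NULL; strand <- "+"
  if (!is.null(fwd)) best <- fwd
  if (!is.null(rev) && (is.null(best) || rev$score > best$score)) {
    best <- rev; strand <- "-"
  }
  if (is.null(best) || best$score < params$min_score) return(NULL)
  data.frame(query_locus = a$locus_id[[1L]], subject_locus = b$locus_id[[1L]],
             identity = best$identity,
             query_coverage = (best$q_span[2L] - best$q_span[1L] + 1L) /
               nchar(qseq),
             score = best$score, strand = strand, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# shared-k-mer prefilter
# ---------------------------------------------------------------------------

# k-mers of one sequence at the given stride (always includes the final
# window so short sequences are fully represented).  Low-complexity words
# (fewer than 3 distinct bases: homopolymer and dinucleotide repeats) are
# masked from seeding, as such words match promiscuously across unrelated
# CDS and would flood the candidate list.
#' @noRd
seq_kmers <- function(seq, k, stride = 1L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- unique(c(seq(1L, n - k + 1L, by = stride), n - k + 1L))
  words <- unique(substring(seq, starts, starts + k - 1L))
  complex <- vapply(strsplit(words, "", fixed = TRUE),
                    function(ch) length(unique(ch)) >= 3L, logical(1L))
  if (!all(complex) && any(complex)) words <- words[complex]
  words
}

# candidate (query, subject, strand) index pairs sharing >= min_words
# distinct k-mer words
#' @noRd
kmer_candidates <- function(qseqs, sseqs, k, min_words = 2L) {
  qstride <- 3L  # query k-mers subsampled; subject side indexed densely
  qk <- lapply(qseqs, seq_kmers, k = k, stride = qstride)
  sk_f <- lapply(sseqs, seq_kmers, k = k, stride = 1L)
  sk_r <- lapply(vapply(sseqs, revcomp, character(1L)), seq_kmers,
                 k = k, stride = 1L)
  qdt <- data.table::data.table(
    kmer = unlist(qk, use.names = FALSE),
    q = rep.int(seq_along(qk), lengths(qk)))
  # short queries cannot carry min_words distinct words
  need <- pmin(min_words, pmax(lengths(qk), 1L))
  pair_up <- function(sk, strand) {
    sdt <- data.table::data.table(
      kmer = unlist(sk, use.names = FALSE),
      s = rep.int(seq_along(sk), lengths(sk)))
    mm <- merge(qdt, sdt, by = "kmer", allow.cartesian = TRUE)
    if (nrow(mm) == 0L) {
      return(data.table::data.table(q = integer(0), s = integer(0),
                                    strand = character(0)))
    }
    n_words <- NULL  # appease R CMD check; data.table scoping
    cnt <- mm[, list(n_words = .N), by = c("q", "s")]
    out <- cnt[cnt$n_words >= need[cnt$q], c("q", "s")]
    out$strand <- strand
    out
  }
  res <- rbind(pair_up(sk_f, "+"), pair_up(sk_r, "-"))
  as.data.frame(res)
}

#' Best hit of every query against a subject genome
#'
#' All query/subject pairs sharing at least one k-mer word (on either
#' strand) are aligned exactly; for each query the single highest-scoring
#' hit at or above `min_score` is kept.  Ties break by higher identity,
#' then by lexicographically smallest subject locus.  Queries with no
#' qualifying hit are absent from the result.
#'
#' @param queries,subjects gene-record data.frames
#' @param params an [align_params()] object
#' @return data.frame with one row per query that has a hit: columns
#'   `query_locus`, `subject_locus`, `identity`, `query_coverage`, `score`,
#'   `strand`
#' @export
best_hits <- function(queries, subjects, params = align_params()) {
  if (nrow(subjects) == 0L) stop("subject set must be non-empty")
  if (nrow(queries) == 0L) {
    return(empty_hit_table())
  }
  submat <- nt_sub_matrix(params)
  qenc <- lapply(queries$seq, encode_nt)
  senc_f <- lapply(subjects$seq, encode_nt)
  senc_r <- lapply(subjects$seq, function(s) encode_nt(revcomp(s)))
  cand <- kmer_candidates(queries$seq, subjects$seq, params$kmer,
                          params$min_words)
  if (nrow(cand) == 0L) return(empty_hit_table())

  nc <- nrow(cand)
  h_id <- numeric(nc); h_cov <- numeric(nc); h_score <- numeric(nc)
  keep <- logical(nc)
  for (i in seq_len(nc)) {
    q <- cand$q[i]; s <- cand$s[i]
    senc <- if (cand$strand[i] == "+") senc_f[[s]] else senc_r[[s]]
    al <- align_encoded(qenc[[q]], senc, params, submat)
    if (is.null(al) || al$score < params$min_score) next
    keep[i] <- TRUE
    h_id[i] <- al$identity
    h_cov[i] <- (al$q_span[2L] - al$q_span[1L] + 1L) / length(qenc[[q]])
    h_score[i] <- al$score
  }
  if (!any(keep)) return(empty_hit_table())
  hits <- data.frame(
    query_locus = queries$locus_id[cand$q[keep]],
    subject_locus = subjects$locus_id[cand$s[keep]],
    identity = h_id[keep], query_coverage = h_cov[keep],
    score = h_score[keep], strand = cand$strand[keep],
    stringsAsFactors = FALSE)
  # best orientation per (query, subject), then best subject per query
  hits <- hits[order(hits$query_locus, -hits$score, -hits$identity,
                     hits$subject_locus), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("query_locus", "subject_locus")]), ,
               drop = FALSE]
  hits <- hits[order(hits$query_locus, -hits$score, -hits$identity,
                     hits$subject_locus), , drop = FALSE]
  out <- hits[!duplicated(hits$query_locus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
empty_hit_table <- function() {
  data.frame(query_locus = character(0), subject_locus = character(0),
             identity = numeric(0), query_coverage = numeric(0),
             score = numeric(0), strand = character(0),
             stringsAsFactors = FALSE)
}
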