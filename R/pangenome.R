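# Reference pan-genome construction and presence/absence scanning.
#
# Genes are clustered greedily into pan-loci: processed in decreasing
# length (ties broken lexicographically), each gene joins the first
# existing locus whose representative it matches under the allelic-variant
# criterion -- identity at or above `identity_threshold` over an aligned
# span covering at least `coverage_threshold` of the longer of the two
# sequences -- otherwise it founds a new locus.  Representatives are
# therefore always at least as long as their members, and the clustering
# is a deterministic partition of the input genes.

# does one local alignment satisfy the allelic-variant criterion?
# coverage is measured on the LONGER of the two sequences
#' @noRd
variant_match <- function(al, qlen, slen, identity_threshold,
                          coverage_threshold) {
  if (is.null(al)) return(FALSE)
  span_q <- al$q_span[2L] - al$q_span[1L] + 1L
  span_s <- al$s_span[2L] - al$s_span[1L] + 1L
  cov_longer <- if (qlen >= slen) span_q / qlen else span_s / slen
  al$identity >= identity_threshold && cov_longer >= coverage_threshold
}

# scoring used for variant matching: local DP without the min-score floor,
# so short-but-valid matches (e.g. 10% coverage) are not suppressed
#' @noRd
variant_params <- function(params) {
  params$min_score <- 1
  params
}

#' Build a reference pan-genome by greedy incremental clustering
#'
#' @param genomes list of gene-record data.frames
#' @param identity_threshold minimum nucleotide identity over the aligned
#'   region (default 0.70)
#' @param coverage_threshold minimum fraction of the longer sequence covered
#'   by the alignment (default 0.10)
#' @param params an [align_params()]; only pairs sharing a k-mer word are
#'   aligned
#' @return a `pangenome`: list of pan-loci, each a list with `locus_id`
#'   (the representative's qualified id `genome|locus`), `representative`
#'   (sequence) and `members` (data.frame `genome_id`, `locus_id`)
#' @export
build_reference_pangenome <- function(genomes, identity_threshold = 0.70,
                                      coverage_threshold = 0.10,
                                      params = align_params()) {
  if (length(genomes) == 0L) stop("genome list must be non-empty")
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  pool <- do.call(rbind, genomes)
  # deterministic processing order: decreasing length, then genome, locus
  ord <- order(-nchar(pool$seq), pool$genome_id, pool$locus_id)
  pool <- pool[ord, , drop = FALSE]
  vparams <- variant_params(params)
  submat <- nt_sub_matrix(params)
  k <- params$kmer

  reps <- list()           # representative encoded seqs
  rep_len <- integer(0)
  rep_seq <- character(0)
  rep_id <- character(0)
  members <- list()        # per-rep member data.frames
  kindex <- new.env(parent = emptyenv(), hash = TRUE)

  for (i in seq_len(nrow(pool))) {
    seq <- pool$seq[i]
    enc <- encode_nt(seq)
    kmers <- seq_kmers(seq, k, stride = 3L)
    cand <- integer(0)
    for (km in kmers) {
      hit <- kindex[[km]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    # require min_words distinct shared words (capped by what the gene has)
    need <- min(params$min_words, max(length(kmers), 1L))
    tab <- table(cand)
    cand <- sort(as.integer(names(tab)[tab >= need]))  # founding order
    joined <- NA_integer_
    for (r in cand) {
      al <- align_encoded(enc, reps[[r]], vparams, submat)
      if (variant_match(al, length(enc), rep_len[r], identity_threshold,
                        coverage_threshold)) {
        joined <- r
        break
      }
    }
    if (is.na(joined)) {
      r <- length(reps) + 1L
      reps[[r]] <- enc
      rep_len[r] <- length(enc)
      rep_seq[r] <- seq
      rep_id[r] <- paste0(pool$genome_id[i], "|", pool$locus_id[i])
      members[[r]] <- data.frame(genome_id = pool$genome_id[i],
                                 locus_id = pool$locus_id[i],
                                 stringsAsFactors = FALSE)
      for (km in seq_kmers(seq, k, stride = 1L)) {
        kindex[[km]] <- c(kindex[[km]], r)
      }
    } else {
      members[[joined]] <- rbind(members[[joined]],
                                 data.frame(genome_id = pool$genome_id[i],
                                            locus_id = pool$locus_id[i],
                                            stringsAsFactors = FALSE))
    }
  }

  loci <- lapply(seq_along(reps), function(r) {
    list(locus_id = rep_id[r], representative = rep_seq[r],
         members = members[[r]])
  })
  structure(list(loci = loci,
                 identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold),
            class = "pangenome")
}

#' Scan genomes for presence of pan-genome loci
#'
#' A genome is present at a locus when at least one of its genes matches
#' the locus representative under the pan-genome's identity/coverage
#' criterion.  Matching is recomputed from the sequences, so genomes that
#' did not contribute to the pan-genome can be scanned too.
#'
#' @param pangenome a [build_reference_pangenome()] result
#' @param genomes named list of gene-record data.frames
#' @param params an [align_params()]
#' @return a `presence_absence` object: logical matrix (loci x genomes)
#'   plus a `matches` data.frame recording, per present cell, the matching
#'   gene with best identity/coverage
#' @export
scan_presence <- function(pangenome, genomes, params = align_params()) {
  stopifnot(inherits(pangenome, "pangenome"))
  if (length(pangenome$loci) == 0L) stop("pan-genome must be non-empty")
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, function(g) g$genome_id[[1L]],
                             character(1L))
  }
  idt <- pangenome$identity_threshold
  cvt <- pangenome$coverage_threshold
  vparams <- variant_params(params)
  submat <- nt_sub_matrix(params)
  rep_seqs <- vapply(pangenome$loci, `[[`, character(1L), "representative")
  rep_ids <- vapply(pangenome$loci, `[[`, character(1L), "locus_id")
  rep_enc <- lapply(rep_seqs, encode_nt)

  mat <- matrix(FALSE, nrow = length(rep_ids), ncol = length(genomes),
                dimnames = list(rep_ids, names(genomes)))
  match_rows <- list()
  for (gid in names(genomes)) {
    gn <- genomes[[gid]]
    if (nrow(gn) == 0L) next
    cand <- kmer_candidates(gn$seq, rep_seqs, params$kmer,
                            params$min_words)
    if (nrow(cand) == 0L) next
    genc <- lapply(gn$seq, encode_nt)
    # best match per locus within this genome
    best <- list()
    for (i in seq_len(nrow(cand))) {
      q <- cand$q[i]; r <- cand$s[i]
      if (cand$strand[i] == "-") next  # CDS sets share orientation
      al <- align_encoded(genc[[q]], rep_enc[[r]], vparams, submat)
      if (!variant_match(al, length(genc[[q]]), length(rep_enc[[r]]),
                         idt, cvt)) next
      prev <- best[[as.character(r)]]
      if (is.null(prev) || al$score > prev$score) {
        best[[as.character(r)]] <- list(score = al$score, gene = q,
                                        identity = al$identity)
      }
    }
    for (rkey in names(best)) {
      r <- as.integer(rkey)
      mat[r, gid] <- TRUE
      match_rows[[length(match_rows) + 1L]] <- data.frame(
        pan_locus = rep_ids[r], genome_id = gid,
        gene_locus = gn$locus_id[best[[rkey]]$gene],
        identity = best[[rkey]]$identity, stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(pan_locus = character(0), genome_id = character(0),
               gene_locus = character(0), identity = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(matrix = mat, matches = matches), class = "presence_absence")
}

#' Core loci at a prevalence threshold
#'
#' Loci present in at least `ceiling(prevalence * n_genomes)` genomes.
#'
#' @param presence a `presence_absence` from [scan_presence()], or a logical
#'   matrix (loci x genomes)
#' @param prevalence fraction in (0, 1], default 0.90
#' @return character vector of pan-locus ids
#' @export
core_loci <- function(presence, prevalence = 0.90) {
  stopifnot(prevalence > 0, prevalence <= 1)
  mat <- if (inherits(presence, "presence_absence")) presence$matrix else
    presence
  need <- ceiling(prevalence * ncol(mat))
  rownames(mat)[rowSums(mat) >= need]
}

#' Scan genomes for named query genes
#'
#' Reports, for each query CDS (e.g. a virulence factor), its best match in
#' each genome and whether it qualifies as present under the
#' identity/coverage criterion.
#'
#' @param queries gene-record data.frame of named query genes
#' @param genomes named list of gene-record data.frames
#' @param identity_threshold,coverage_threshold allelic-variant criterion
#'   (coverage measured on the longer sequence; boundaries inclusive)
#' @param params an [align_params()]
#' @return data.frame with one row per (query, genome): `query`,
#'   `genome_id`, `present`, `best_identity`, `best_coverage`,
#'   `best_gene` (`NA` where nothing aligned)
#' @export
query_scan <- function(queries, genomes, identity_threshold = 0.70,
                       coverage_threshold = 0.10, params = align_params()) {
  if (nrow(queries) == 0L) stop("query list must be non-empty")
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, function(g) g$genome_id[[1L]],
                             character(1L))
  }
  vparams <- variant_params(params)
  submat <- nt_sub_matrix(params)
  qenc <- lapply(queries$seq, encode_nt)
  out <- list()
  for (gid in names(genomes)) {
    gn <- genomes[[gid]]
    cand <- if (nrow(gn))
      kmer_candidates(queries$seq, gn$seq, params$kmer, params$min_words)
      else data.frame(q = integer(0), s = integer(0), strand = character(0))
    genc <- lapply(gn$seq, encode_nt)
    for (qi in seq_len(nrow(queries))) {
      rows <- cand[cand$q == qi & cand$strand == "+", , drop = FALSE]
      best <- NULL
      for (j in seq_len(nrow(rows))) {
        s <- rows$s[j]
        al <- align_encoded(qenc[[qi]], genc[[s]], vparams, submat)
        if (is.null(al)) next
        if (is.null(best) || al$score > best$al$score) {
          best <- list(al = al, gene = gn$locus_id[s],
                       slen = length(genc[[s]]))
        }
      }
      if (is.null(best)) {
        out[[length(out) + 1L]] <- data.frame(
          query = queries$locus_id[qi], genome_id = gid, present = FALSE,
          best_identity = NA_real_, best_coverage = NA_real_,
          best_gene = NA_character_, stringsAsFactors = FALSE)
      } else {
        al <- best$al
        qlen <- length(qenc[[qi]])
        span_q <- al$q_span[2L] - al$q_span[1L] + 1L
        span_s <- al$s_span[2L] - al$s_span[1L] + 1L
        cov <- if (qlen >= best$slen) span_q / qlen else span_s / best$slen
        out[[length(out) + 1L]] <- data.frame(
          query = queries$locus_id[qi], genome_id = gid,
          present = al$identity >= identity_threshold &&
            cov >= coverage_threshold,
          best_identity = al$identity, best_coverage = cov,
          best_gene = best$gene, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.pangenome <- function(x, ...) {
  n_mem <- sum(vapply(x$loci, function(l) nrow(l$members), integer(1L)))
  cat("Reference pan-genome: ", length(x$loci), " loci from ", n_mem,
      " genes (identity >= ", x$identity_threshold, ", coverage >= ",
      x$coverage_threshold, " of the longer sequence)\n", sep = "")
  invisible(x)
}
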