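# Pairwise dN/dS by the Nei-Gojobori (1986) counting method.
#
# Ortholog pairs are aligned codon-aware: the two CDS are translated under
# the bacterial genetic code, the proteins aligned by global affine-gap DP,
# and the protein gaps back-mapped to codons.  Codon columns containing a
# gap, an ambiguous base or a stop are dropped.  On the retained gap-free
# codon columns, synonymous and nonsynonymous sites are counted per codon
# and observed differences are resolved by equal-weight averaging over all
# minimal mutational pathways (pathways through stop codons excluded).
# Proportions are Jukes-Cantor corrected; dS beyond the saturation
# threshold (default 3) or an undefined correction flags the pair as
# saturated.

# minimum surviving codon columns for a usable pair (the stand-in for
# discarding low-quality, gap-rich alignments)
.MIN_RETAINED_CODONS <- 30L

#' Codon-aware pairwise alignment of two CDS
#'
#' @param a,b single gene records (lists or one-row data.frames with
#'   `locus_id` and `seq`); sequence lengths must be multiples of 3
#' @return a `codon_alignment`: list with `a_codons`, `b_codons` (equal
#'   length character vectors of retained codon columns) and `dropped`
#'   (number of codon columns removed)
#' @export
codon_align <- function(a, b) {
  aseq <- toupper(a$seq[[1L]]); bseq <- toupper(b$seq[[1L]])
  for (s in list(aseq, bseq)) {
    if (nchar(s) < 3L) stop("sequences must be at least one codon long")
    if (nchar(s) %% 3L != 0L) {
      stop("CDS length is not a multiple of 3")
    }
  }
  acod <- substring(aseq, seq(1L, nchar(aseq), 3L), seq(3L, nchar(aseq), 3L))
  bcod <- substring(bseq, seq(1L, nchar(bseq), 3L), seq(3L, nchar(bseq), 3L))
  # trailing stop codons are annotation convention, not signal
  if (acod[length(acod)] %in% stop_codons()) acod <- acod[-length(acod)]
  if (bcod[length(bcod)] %in% stop_codons()) bcod <- bcod[-length(bcod)]
  apro <- translate_codons(acod)
  bpro <- translate_codons(bcod)
  if (any(apro == "*") || any(bpro == "*")) {
    stop("internal stop codon in frame 0; gene pair skipped")
  }

  submat <- aa_sub_matrix()
  al <- .align_dp(encode_aa(paste(apro, collapse = "")),
                  encode_aa(paste(bpro, collapse = "")),
                  submat, 10, 1, local = FALSE)
  keep_a <- character(0); keep_b <- character(0)
  dropped <- 0L
  sense <- sense_codons()
  for (col in seq_along(al$a_idx)) {
    ai <- al$a_idx[col]; bi <- al$b_idx[col]
    if (ai == 0L || bi == 0L) { dropped <- dropped + 1L; next }
    ca <- acod[ai]; cb <- bcod[bi]
    if (!(ca %in% sense) || !(cb %in% sense)) { dropped <- dropped + 1L; next }
    keep_a <- c(keep_a, ca); keep_b <- c(keep_b, cb)
  }
  if (length(keep_a) < .MIN_RETAINED_CODONS) {
    stop("fewer than ", .MIN_RETAINED_CODONS,
         " codon columns survive filtering; gene pair skipped")
  }
  structure(list(a_codons = keep_a, b_codons = keep_b, dropped = dropped),
            class = "codon_alignment")
}

#' Nei-Gojobori dN/dS estimate for one codon alignment
#'
#' @param ca a [codon_align()] result
#' @param saturation_threshold dS above which the pair is flagged saturated
#'   (default 3.0)
#' @return one-row data.frame: `codons_retained`, `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `saturated`.  `dS`/`dN`
#'   are `NA` when the Jukes-Cantor correction is undefined; `omega` is
#'   `NA` when dS is zero, undefined, or saturated.
#' @export
ng86_estimate <- function(ca, saturation_threshold = 3.0) {
  stopifnot(inherits(ca, "codon_alignment"))
  sites <- ng86_site_table()
  tabs <- ng86_diff_tables()
  L <- length(ca$a_codons)
  s_a <- sum(sites[ca$a_codons])
  s_b <- sum(sites[ca$b_codons])
  S <- (s_a + s_b) / 2
  N <- 3 * L - S
  ia <- match(ca$a_codons, sense_codons())
  ib <- match(ca$b_codons, sense_codons())
  Sd <- sum(tabs$sd[cbind(ia, ib)])
  Nd <- sum(tabs$nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    arg <- 1 - 4 / 3 * p
    if (arg <= 0) NA_real_ else -0.75 * log(arg)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  saturated <- is.na(dS) || dS > saturation_threshold
  omega <- if (!saturated && !is.na(dS) && dS > 0 && !is.na(dN)) dN / dS
    else NA_real_
  data.frame(codons_retained = L, S_sites = S, N_sites = N, Sd = Sd,
             Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
             saturated = saturated, stringsAsFactors = FALSE)
}

#' Genome-wide pairwise dN/dS over an ortholog table
#'
#' Runs [codon_align()] and [ng86_estimate()] for every reciprocal-best-hit
#' pair; pairs failing the frame or retained-codon filters are skipped and
#' logged.  The summary reports the mean dS over unsaturated pairs, the
#' fraction of estimable pairs flagged saturated, and the fraction of pairs
#' with omega > 1.
#'
#' @param orthologs an `ortholog_table`
#' @param genome_a,genome_b the gene-record data.frames the table refers to
#' @param saturation_threshold dS saturation flag threshold (default 3.0)
#' @return list with `table` (one row per estimable pair: `a_locus`,
#'   `b_locus` plus the [ng86_estimate()] columns), `summary` (list
#'   `n_pairs`, `n_skipped`, `mean_dS_unsaturated`, `fraction_saturated`,
#'   `fraction_omega_gt1`) and `skipped` (data.frame of skipped pairs with
#'   reasons)
#' @export
genome_wide_dnds <- function(orthologs, genome_a, genome_b,
                             saturation_threshold = 3.0) {
  stopifnot(inherits(orthologs, "ortholog_table"))
  if (nrow(orthologs) == 0L) stop("ortholog table has no pairs")
  a_map <- stats::setNames(seq_len(nrow(genome_a)), genome_a$locus_id)
  b_map <- stats::setNames(seq_len(nrow(genome_b)), genome_b$locus_id)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(orthologs))) {
    al <- orthologs$a_locus[i]; bl <- orthologs$b_locus[i]
    ga <- genome_a[a_map[[al]], ]; gb <- genome_b[b_map[[bl]], ]
    est <- tryCatch({
      ca <- codon_align(ga, gb)
      cbind(data.frame(a_locus = al, b_locus = bl,
                       stringsAsFactors = FALSE),
            ng86_estimate(ca, saturation_threshold))
    }, error = function(e) conditionMessage(e))
    if (is.character(est)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        a_locus = al, b_locus = bl, reason = est, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- est
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(tab)) {
    warning("all ortholog pairs were filtered out; empty dN/dS table")
    tab <- data.frame(a_locus = character(0), b_locus = character(0))
  }
  skip_df <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(a_locus = character(0), b_locus = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  n_est <- nrow(tab)
  summary <- list(
    n_pairs = n_est,
    n_skipped = nrow(skip_df),
    mean_dS_unsaturated = if (n_est && any(!tab$saturated))
      mean(tab$dS[!tab$saturated]) else NA_real_,
    fraction_saturated = if (n_est) mean(tab$saturated) else NA_real_,
    fraction_omega_gt1 = if (n_est && any(!is.na(tab$omega)))
      mean(tab$omega > 1, na.rm = TRUE) else NA_real_)
  list(table = tab, summary = summary, skipped = skip_df)
}
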