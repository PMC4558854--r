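# Gene-by-gene multiple alignment, supermatrix concatenation, pairwise
# distances and neighbor-joining trees with bootstrap support.
#
# Multiple alignment is center-star progressive: the center sequence is the
# one minimizing the sum of pairwise edit distances; every other sequence
# is aligned to the center by global affine-gap DP and merged under the
# "once a gap, always a gap" rule.  Trees are canonical Saitou-Nei
# neighbor joining on p/Jukes-Cantor/Kimura-2P (nucleotide) or p/Poisson
# (amino acid) distances with pairwise deletion of gapped columns.

#' Multiple alignment of one gene by center-star progressive alignment
#'
#' @param seqs named character vector (>= 2 unaligned sequences, nucleotide
#'   or amino acid; the alphabet is auto-detected)
#' @return a `multiple_alignment`: named character vector of equal-length
#'   rows with gap character `-`, attribute `alphabet` (`"nt"` or `"aa"`)
#' @export
align_gene <- function(seqs) {
  if (length(seqs) < 2L) stop("at least 2 sequences are required")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique taxon names")
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  seqs <- toupper(seqs)
  alphabet <- detect_alphabet(seqs)

  # all rows equal and identical -> trivial gap-free alignment
  if (length(unique(seqs)) == 1L) {
    return(new_alignment(seqs, alphabet))
  }

  center_i <- which.min(rowSums(utils::adist(seqs)))
  center <- seqs[[center_i]]
  L <- nchar(center)
  others <- setdiff(seq_along(seqs), center_i)

  if (alphabet == "nt") {
    submat <- nt_sub_matrix(align_params())
    enc <- function(s) encode_nt(s)
    gap_open <- 5; gap_ext <- 2
  } else {
    submat <- aa_sub_matrix()
    enc <- function(s) encode_aa(s)
    gap_open <- 10; gap_ext <- 1
  }

  cenc <- enc(center)
  aligned_res <- list()   # per seq: length-L vector of residues or "-"
  ins_blocks <- list()    # per seq: list gap-slot (0..L as char) -> string
  for (i in others) {
    oenc <- enc(seqs[[i]])
    al <- .align_dp(cenc, oenc, submat, gap_open, gap_ext, local = FALSE)
    ochars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    res <- rep("-", L)
    sub_cols <- al$a_idx > 0L & al$b_idx > 0L
    res[al$a_idx[sub_cols]] <- ochars[al$b_idx[sub_cols]]
    ins <- list()
    ins_cols <- which(al$a_idx == 0L)
    if (length(ins_cols) > 0L) {
      # gap slot = number of center residues consumed before the column
      consumed <- cummax(pmax(al$a_idx, 0L))
      by_slot <- split(ochars[al$b_idx[ins_cols]], consumed[ins_cols])
      ins <- lapply(by_slot, paste, collapse = "")
    }
    aligned_res[[as.character(i)]] <- res
    ins_blocks[[as.character(i)]] <- ins
  }

  # master insertion widths per gap slot (once a gap, always a gap)
  width <- integer(L + 1L)
  for (ins in ins_blocks) {
    for (slot in names(ins)) {
      g <- as.integer(slot) + 1L
      width[g] <- max(width[g], nchar(ins[[slot]]))
    }
  }

  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  any_ins <- any(width > 0L)
  build_row <- function(res, ins) {
    if (!any_ins) return(paste(res, collapse = ""))
    parts <- character(0)
    for (g in 0:L) {
      if (width[g + 1L] > 0L) {
        parts <- c(parts, pad(ins[[as.character(g)]] %||% "", width[g + 1L]))
      }
      if (g < L) parts <- c(parts, res[g + 1L])
    }
    paste(parts, collapse = "")
  }

  out <- character(length(seqs))
  names(out) <- names(seqs)
  cchars <- strsplit(center, "", fixed = TRUE)[[1L]]
  out[center_i] <- build_row(cchars, list())
  for (i in others) {
    out[i] <- build_row(aligned_res[[as.character(i)]],
                        ins_blocks[[as.character(i)]])
  }
  new_alignment(out, alphabet)
}

#' @noRd
new_alignment <- function(rows, alphabet) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(rows, alphabet = alphabet, class = "multiple_alignment")
}

#' @noRd
detect_alphabet <- function(seqs) {
  ch <- unique(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]])
  if (all(ch %in% c(NUCS, "N", "-"))) "nt" else "aa"
}

#' @noRd
aa_sub_matrix <- function() {
  if (is.null(.panevo$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .panevo$blosum62 <- e$BLOSUM62
  }
  .panevo$blosum62
}

#' @noRd
encode_aa <- function(seq) {
  ab <- rownames(aa_sub_matrix())
  x <- match(strsplit(seq, "", fixed = TRUE)[[1L]], ab)
  x[is.na(x)] <- match("X", ab)
  x
}

#' Concatenate gene alignments into a supermatrix
#'
#' @param alignments named list of `multiple_alignment` objects
#' @param taxon_policy `"drop-incomplete"` keeps only taxa present in every
#'   gene (gap-free supermatrix rows across genes); `"pad-gaps"` keeps all
#'   taxa and fills missing genes with all-gap rows
#' @return a `supermatrix`: list with `aln` (named character vector),
#'   `partitions` (data.frame `gene`, `start`, `end`; 0-based half-open)
#'   and `alphabet`
#' @export
concatenate <- function(alignments,
                        taxon_policy = c("drop-incomplete", "pad-gaps")) {
  taxon_policy <- match.arg(taxon_policy)
  if (length(alignments) == 0L) stop("at least one alignment is required")
  if (is.null(names(alignments))) {
    names(alignments) <- sprintf("gene%03d", seq_along(alignments))
  }
  alphabet <- unique(vapply(alignments, attr, character(1L), "alphabet"))
  if (length(alphabet) != 1L) stop("alignments mix alphabets")
  taxa_sets <- lapply(alignments, names)
  taxa <- if (taxon_policy == "drop-incomplete") {
    Reduce(intersect, taxa_sets)
  } else {
    Reduce(union, taxa_sets)
  }
  if (length(taxa) == 0L) {
    stop("no taxon is present in every gene alignment")
  }
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  pos <- 0L
  for (g in names(alignments)) {
    a <- alignments[[g]]
    w <- nchar(a[[1L]])
    blank <- strrep("-", w)
    for (tx in taxa) {
      rows[tx] <- paste0(rows[tx], if (tx %in% names(a)) a[[tx]] else blank)
    }
    parts[[g]] <- data.frame(gene = g, start = pos, end = pos + w,
                             stringsAsFactors = FALSE)
    pos <- pos + w
  }
  partitions <- do.call(rbind, parts)
  rownames(partitions) <- NULL
  structure(list(aln = rows, partitions = partitions, alphabet = alphabet),
            class = "supermatrix")
}

# character matrix (taxa x columns) from a supermatrix or alignment
#' @noRd
aln_char_matrix <- function(x) {
  rows <- if (inherits(x, "supermatrix")) x$aln else unclass(x)
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

#' Pairwise distances from a supermatrix
#'
#' Distances use pairwise deletion: each pair is compared only over columns
#' where both taxa carry an unambiguous residue (`ACGT` for nucleotides,
#' the 20 standard amino acids otherwise).  Corrections that are undefined
#' at the observed divergence (logarithm of a non-positive number) are
#' capped at `saturation_cap` and flagged in the `saturated` attribute.
#'
#' @param sm a `supermatrix` or `multiple_alignment`
#' @param model `"p"`, `"jc"` (Jukes-Cantor) or `"k2p"` (Kimura 2-parameter)
#'   for nucleotides; `"p"` or `"poisson"` for amino acids
#' @param saturation_cap distance assigned to saturated pairs (default 5)
#' @return symmetric numeric matrix with zero diagonal, attributes
#'   `saturated` (logical matrix) and `model`
#' @export
distance_matrix <- function(sm, model = c("p", "jc", "k2p", "poisson"),
                            saturation_cap = 5) {
  model <- match.arg(model)
  alphabet <- if (inherits(sm, "supermatrix")) sm$alphabet else
    attr(sm, "alphabet")
  if (alphabet == "nt" && model == "poisson") {
    stop("poisson correction applies to amino-acid alignments")
  }
  if (alphabet == "aa" && model %in% c("jc", "k2p")) {
    stop("model '", model, "' applies to nucleotide alignments")
  }
  M <- aln_char_matrix(sm)
  taxa <- if (inherits(sm, "supermatrix")) names(sm$aln) else names(sm)
  dist_from_chars(M, taxa, alphabet, model, saturation_cap)
}

# distance computation on a pre-split character matrix (taxa x columns);
# shared by distance_matrix() and the bootstrap resampler
#' @noRd
dist_from_chars <- function(M, taxa, alphabet, model, saturation_cap) {
  n <- nrow(M)
  if (n < 2L) stop("at least 2 taxa are required")
  valid_set <- if (alphabet == "nt") NUCS else
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  ok <- matrix(M %in% valid_set, nrow = n)

  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  SAT <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  purine <- c("A", "G")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      nc <- sum(use)
      if (nc == 0L) {
        stop("taxa ", taxa[i], " and ", taxa[j],
             " share no comparable columns")
      }
      xi <- M[i, use]; xj <- M[j, use]
      p <- mean(xi != xj)
      sat <- FALSE
      d <- switch(model,
        p = p,
        jc = , poisson = {
          arg <- if (model == "jc") 1 - 4 / 3 * p else 1 - p
          if (arg <= 0) { sat <- TRUE; saturation_cap }
          else if (model == "jc") -0.75 * log(arg) else -log(arg)
        },
        k2p = {
          diffs <- xi != xj
          ti <- mean(diffs & ((xi %in% purine) == (xj %in% purine)))
          tv <- p - ti
          a1 <- 1 - 2 * ti - tv
          a2 <- 1 - 2 * tv
          if (a1 <= 0 || a2 <= 0) { sat <- TRUE; saturation_cap }
          else -0.5 * log(a1) - 0.25 * log(a2)
        })
      D[i, j] <- D[j, i] <- d
      SAT[i, j] <- SAT[j, i] <- sat
    }
  }
  attr(D, "saturated") <- SAT
  attr(D, "model") <- model
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical agglomeration by the Q criterion.  A
#' negative pendant branch length arising at a join is clamped to zero and
#' its deficit transferred to the sister branch, so all branch lengths are
#' non-negative.  With an outgroup the tree is rooted on the branch leading
#' to it.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa)
#' @param outgroup optional taxon name to root on
#' @return an [ape::phylo] tree
#' @export
nj_tree <- function(d, outgroup = NULL) {
  D <- as.matrix(d)
  taxa <- rownames(D)
  n <- length(taxa)
  if (n < 3L) stop("at least 3 taxa are required")
  if (!is.null(outgroup) && !outgroup %in% taxa) {
    stop("outgroup '", outgroup, "' is not among the taxa")
  }
  frags <- vapply(taxa, quote_taxon, character(1L))

  while (n > 3L) {
    r <- rowSums(D) / (n - 2)
    Q <- D - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- min(best[1L, ]); j <- max(best[1L, ])
    li <- 0.5 * D[i, j] + 0.5 * (r[i] - r[j])
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt_len(li),
                       frags[j], fmt_len(lj))
    dm <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    dm <- pmax(dm, 0)
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dm[keep]),
                c(dm[keep], 0))
    frags <- c(frags[keep], newfrag)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
    n <- n - 1L
  }

  # close the final three clusters around an unresolved central node
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- c(l1, l2, l3)
  for (k in which(ls < 0)) {
    sister <- which.max(ls)
    ls[sister] <- ls[sister] + ls[k]
    ls[k] <- 0
  }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frags[1], fmt_len(ls[1]), frags[2], fmt_len(ls[2]),
                    frags[3], fmt_len(ls[3]))
  phy <- ape::read.tree(text = newick)
  phy$edge.length[phy$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  phy
}

#' @noRd
fmt_len <- function(x) formatC(x, digits = 15, format = "g")

#' @noRd
quote_taxon <- function(x) {
  if (grepl("[ (),:;'\\[\\]]", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples supermatrix columns (or whole genes) with replacement,
#' rebuilds the NJ tree per pseudoreplicate, and reports for every internal
#' bipartition of the point-estimate tree the percentage of replicate trees
#' containing it (as `node.label`).
#'
#' @param sm a `supermatrix`
#' @param n_reps number of pseudoreplicates (>= 1)
#' @param model distance model passed to [distance_matrix()]
#' @param seed integer seed; resampling is deterministic given the seed
#' @param outgroup optional taxon to root the point-estimate tree on
#' @param gene_wise resample whole genes (partitions) instead of columns
#' @param saturation_cap passed to [distance_matrix()]
#' @return the point-estimate [ape::phylo] tree with bootstrap percentages
#'   in `node.label`
#' @export
bootstrap_support <- function(sm, n_reps = 100L, model = "jc", seed = 1L,
                              outgroup = NULL, gene_wise = FALSE,
                              saturation_cap = 5) {
  stopifnot(inherits(sm, "supermatrix"), n_reps >= 1)
  M <- aln_char_matrix(sm)
  taxa <- names(sm$aln)
  point <- nj_tree(distance_matrix(sm, model = model,
                                   saturation_cap = saturation_cap),
                   outgroup = outgroup)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      cols <- if (gene_wise) {
        gsel <- sample.int(nrow(sm$partitions), replace = TRUE)
        unlist(lapply(gsel, function(g) {
          (sm$partitions$start[g] + 1L):sm$partitions$end[g]
        }))
      } else {
        sample.int(ncol(M), replace = TRUE)
      }
      d_b <- tryCatch(dist_from_chars(M[, cols, drop = FALSE], taxa,
                                      sm$alphabet, model, saturation_cap),
                      error = function(e) NULL)
      if (is.null(d_b)) NULL else
        tryCatch(nj_tree(d_b), error = function(e) NULL)
    })
  })
  reps <- reps[!vapply(reps, is.null, logical(1L))]
  if (length(reps) == 0L) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- as.character(round(100 * counts / length(reps)))
  point
}
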