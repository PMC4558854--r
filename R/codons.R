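# Codon-level machinery shared by the simulator and the dN/dS estimator.
# Everything uses the bacterial/archaeal genetic code (translation table 11),
# whose codon-to-amino-acid map is retrieved from Biostrings.

NUCS <- c("A", "C", "G", "T")

#' @noRd
genetic_code_11 <- function() {
  if (is.null(.panevo$gc11)) {
    .panevo$gc11 <- Biostrings::getGeneticCode("11")
  }
  .panevo$gc11
}

#' @noRd
all_codons <- function() {
  if (is.null(.panevo$codons)) {
    .panevo$codons <- apply(expand.grid(NUCS, NUCS, NUCS,
                                        stringsAsFactors = FALSE)[, 3:1],
                            1L, paste, collapse = "")
  }
  .panevo$codons
}

#' @noRd
stop_codons <- function() {
  gc <- genetic_code_11()
  names(gc)[gc == "*"]
}

#' @noRd
sense_codons <- function() {
  setdiff(all_codons(), stop_codons())
}

#' Translate in-frame codons under the bacterial genetic code
#'
#' Codons containing characters outside `ACGT` translate to `X`.
#'
#' @param codons character vector of 3-letter codons
#' @return character vector of single-letter amino acids (`*` for stops)
#' @noRd
translate_codons <- function(codons) {
  gc <- genetic_code_11()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# All nine single-nucleotide neighbors of a codon, as a character vector.
#' @noRd
codon_neighbors <- function(codon) {
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  out <- character(9L)
  k <- 0L
  for (pos in 1:3) {
    for (nt in NUCS[NUCS != chars[pos]]) {
      tmp <- chars
      tmp[pos] <- nt
      k <- k + 1L
      out[k] <- paste(tmp, collapse = "")
    }
  }
  out
}

#' @noRd
is_transition <- function(from, to) {
  (from %in% c("A", "G") && to %in% c("A", "G")) ||
    (from %in% c("C", "T") && to %in% c("C", "T"))
}

# ---------------------------------------------------------------------------
# Nei-Gojobori (1986) site counting.
#
# For each codon position the synonymous-site fraction is the number of the
# three possible single-nucleotide changes that preserve the amino acid,
# divided by 3.  Changes that create a stop codon count as nonsynonymous.
# A codon therefore contributes s = sum_p n_syn(p)/3 synonymous sites and
# 3 - s nonsynonymous sites, so S + N = 3 x (number of codons) exactly.
# ---------------------------------------------------------------------------

#' @noRd
ng86_site_table <- function() {
  if (!is.null(.panevo$ng86_sites)) return(.panevo$ng86_sites)
  gc <- genetic_code_11()
  sense <- sense_codons()
  s <- vapply(sense, function(cod) {
    aa <- gc[[cod]]
    nb <- codon_neighbors(cod)
    sum(gc[nb] == aa) / 3
  }, numeric(1L))
  .panevo$ng86_sites <- s
  s
}

# ---------------------------------------------------------------------------
# Nei-Gojobori pathway counting for codon pairs.
#
# A pair of codons differing at d positions is connected by up to d! minimal
# mutational pathways (orderings of the single-site changes).  Each step of a
# pathway is synonymous or nonsynonymous by amino-acid comparison; pathways
# passing through a stop codon are excluded and the remaining pathways are
# averaged with equal weights.  In the rare case that every pathway crosses a
# stop codon, all pathways are averaged (steps to/from a stop count as
# nonsynonymous).
# ---------------------------------------------------------------------------

# enumerate all orderings of positions 'diff_pos' for one codon pair;
# returns c(sd, nd) averaged over admitted pathways
#' @noRd
ng86_pair_counts <- function(c1, c2) {
  ch1 <- strsplit(c1, "", fixed = TRUE)[[1L]]
  ch2 <- strsplit(c2, "", fixed = TRUE)[[1L]]
  diff_pos <- which(ch1 != ch2)
  d <- length(diff_pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  gc <- genetic_code_11()
  stops <- stop_codons()

  perms <- permutations_of(diff_pos)
  path_sd <- numeric(0)
  path_nd <- numeric(0)
  path_ok <- logical(0)
  for (ord in perms) {
    cur <- ch1
    sd <- 0; nd <- 0; ok <- TRUE
    for (k in seq_along(ord)) {
      nxt <- cur
      nxt[ord[k]] <- ch2[ord[k]]
      from <- gc[[paste(cur, collapse = "")]]
      to_codon <- paste(nxt, collapse = "")
      to <- gc[[to_codon]]
      if (identical(from, to)) sd <- sd + 1 else nd <- nd + 1
      if (k < length(ord) && to_codon %in% stops) ok <- FALSE
      cur <- nxt
    }
    path_sd <- c(path_sd, sd)
    path_nd <- c(path_nd, nd)
    path_ok <- c(path_ok, ok)
  }
  use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_sd))
  c(sd = mean(path_sd[use]), nd = mean(path_nd[use]))
}

# all permutations of a small vector (d <= 3 here)
#' @noRd
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# 61 x 61 matrices of averaged synonymous / nonsynonymous difference counts
#' @noRd
ng86_diff_tables <- function() {
  if (!is.null(.panevo$ng86_sd)) {
    return(list(sd = .panevo$ng86_sd, nd = .panevo$ng86_nd))
  }
  sense <- sense_codons()
  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cnt <- ng86_pair_counts(sense[i], sense[j])
      sd[i, j] <- cnt[["sd"]]
      nd[i, j] <- cnt[["nd"]]
    }
  }
  .panevo$ng86_sd <- sd
  .panevo$ng86_nd <- nd
  list(sd = sd, nd = nd)
}

# ---------------------------------------------------------------------------
# Codon substitution rate matrix for the simulator: single-nucleotide
# exchanges among the 61 sense codons, transitions weighted by kappa,
# nonsynonymous changes by omega.  Off-diagonal symmetry makes the chain
# reversible with a uniform stationary distribution over sense codons.
# ---------------------------------------------------------------------------

#' @noRd
codon_rate_matrix <- function(kappa, omega) {
  gc <- genetic_code_11()
  sense <- sense_codons()
  n <- length(sense)
  Q <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    ci <- sense[i]
    chi <- strsplit(ci, "", fixed = TRUE)[[1L]]
    for (cj in codon_neighbors(ci)) {
      j <- match(cj, sense)
      if (is.na(j)) next  # change to a stop codon: rate 0
      chj <- strsplit(cj, "", fixed = TRUE)[[1L]]
      pos <- which(chi != chj)
      r <- if (is_transition(chi[pos], chj[pos])) kappa else 1
      if (gc[[ci]] != gc[[cj]]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# transition probability matrix exp(Q * t) via symmetric eigendecomposition
# (Q has symmetric off-diagonals, hence is symmetric as a whole)
#' @noRd
codon_transition_probs <- function(eig, t) {
  P <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}
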