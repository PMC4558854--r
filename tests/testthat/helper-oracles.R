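# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly n_sub positions, never recreating the original base
mutate_seq <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# interior, well-spaced substitution positions so the optimal local
# alignment of original vs mutant spans both sequences end to end
spaced_positions <- function(len, n_sub, margin = 4L, gap = 3L) {
  pos <- seq(margin + 1L, len - margin, by = gap)
  sort(sample(pos, n_sub))
}

# ---------------------------------------------------------------------------
# Naive full-matrix affine-gap local alignment in plain R (Gotoh with three
# complete score matrices and traceback).  Quadratic space, no rolling rows,
# written independently of the package's compiled aligner.
# ---------------------------------------------------------------------------
naive_local_align <- function(a, b, match = 2, mismatch = -3,
                              gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  oe <- gap_open + gap_ext
  M <- matrix(-Inf, n + 1L, m + 1L)
  X <- matrix(-Inf, n + 1L, m + 1L)
  Y <- matrix(-Inf, n + 1L, m + 1L)
  M[, 1L] <- 0; M[1L, ] <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      M[i, j] <- max(0, s + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                                Y[i - 1L, j - 1L]))
      X[i, j] <- max(M[i - 1L, j] - oe, X[i - 1L, j] - gap_ext,
                     Y[i - 1L, j] - oe)
      Y[i, j] <- max(M[i, j - 1L] - oe, Y[i, j - 1L] - gap_ext,
                     X[i, j - 1L] - oe)
    }
  }
  best <- max(M)
  if (best <= 0) return(list(score = 0))
  # among co-optimal endpoints take the first in row-major order, the same
  # convention as the package aligner
  ends <- which(M == best, arr.ind = TRUE)
  end <- ends[order(ends[, 1L], ends[, 2L])[1L], ]
  end <- unname(end)
  # traceback for identity / spans
  i <- end[1L]; j <- end[2L]; state <- "M"
  cols <- 0L; matches <- 0L
  qmin <- qmax <- i - 1L
  repeat {
    if (state == "M") {
      if (M[i, j] == 0) break
      cols <- cols + 1L
      if (A[i - 1L] == B[j - 1L]) matches <- matches + 1L
      qmin <- i - 1L
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      prev <- M[i, j] - s
      state <- if (isTRUE(all.equal(prev, M[i - 1L, j - 1L]))) "M"
        else if (isTRUE(all.equal(prev, X[i - 1L, j - 1L]))) "X" else "Y"
      i <- i - 1L; j <- j - 1L
      if (state == "M" && M[i, j] == 0) break
    } else if (state == "X") {
      cols <- cols + 1L
      qmin <- i - 1L
      v <- X[i, j]
      state <- if (isTRUE(all.equal(v, M[i - 1L, j] - oe))) "M"
        else if (isTRUE(all.equal(v, X[i - 1L, j] - gap_ext))) "X" else "Y"
      i <- i - 1L
    } else {
      cols <- cols + 1L
      v <- Y[i, j]
      state <- if (isTRUE(all.equal(v, M[i, j - 1L] - oe))) "M"
        else if (isTRUE(all.equal(v, Y[i, j - 1L] - gap_ext))) "Y" else "X"
      j <- j - 1L
    }
  }
  list(score = best, identity = matches / cols,
       query_coverage = (qmax - qmin + 1L) / n)
}

# ---------------------------------------------------------------------------
# Exhaustive pathway enumerator for Nei-Gojobori difference counting,
# written with hard-coded orderings (independent of the package's recursive
# permutation code).  Steps through stop codons invalidate a pathway; if no
# valid pathway exists, all are averaged.
# ---------------------------------------------------------------------------
oracle_ng86_pair <- function(c1, c2) {
  code <- Biostrings::getGeneticCode("11")
  ch1 <- strsplit(c1, "", fixed = TRUE)[[1L]]
  ch2 <- strsplit(c2, "", fixed = TRUE)[[1L]]
  dpos <- which(ch1 != ch2)
  d <- length(dpos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  orderings <- switch(d,
    list(dpos),
    list(dpos[c(1, 2)], dpos[c(2, 1)]),
    list(dpos[c(1, 2, 3)], dpos[c(1, 3, 2)], dpos[c(2, 1, 3)],
         dpos[c(2, 3, 1)], dpos[c(3, 1, 2)], dpos[c(3, 2, 1)]))
  walk <- function(ord) {
    cur <- ch1
    sd <- 0; nd <- 0; valid <- TRUE
    for (k in seq_along(ord)) {
      nxt <- cur; nxt[ord[k]] <- ch2[ord[k]]
      aa_from <- code[[paste(cur, collapse = "")]]
      aa_to <- code[[paste(nxt, collapse = "")]]
      if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
      if (k < length(ord) && aa_to == "*") valid <- FALSE
      cur <- nxt
    }
    c(sd, nd, valid)
  }
  res <- t(vapply(orderings, walk, numeric(3L)))
  use <- if (any(res[, 3L] == 1)) res[, 3L] == 1 else rep(TRUE, nrow(res))
  c(sd = mean(res[use, 1L]), nd = mean(res[use, 2L]))
}

# ortholog table built directly from paired row order (simulator output)
paired_ortholog_table <- function(a, b) {
  structure(data.frame(a_locus = a$locus_id, b_locus = b$locus_id,
                       stringsAsFactors = FALSE),
            a_id = a$genome_id[[1L]], b_id = b$genome_id[[1L]],
            class = c("ortholog_table", "data.frame"))
}

# map recovered reference-genome loci to ancestral locus ids via the truth
recovered_as_ancestral <- function(loci, truth, leaf) {
  mp <- truth_locus_map(truth, leaf)
  sort(unname(mp[loci][!is.na(mp[loci])]))
}
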