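# Synthetic genome-evolution generator.
#
# Clades of annotated bacterial genomes are simulated from a known ancestral
# gene repertoire: codon sequences evolve along a rooted tree under a
# 61-state sense-codon Markov chain (transitions weighted by kappa, amino
# acid changes by omega, stop codons unreachable), while whole genes are
# lost and gained per branch.  The recorded truth table makes downstream
# orthology, core-genome, pan-genome and dN/dS stages testable by parameter
# recovery.

# COG-like functional category labels with roughly realistic frequencies;
# "S" (function unknown) is the most common, as in real annotations.
.CATEGORY_LEVELS <- c("S", "E", "G", "K", "J", "M", "C", "P", "L", "T",
                      "O", "H", "V", "F", "N", "U")
.CATEGORY_WEIGHTS <- c(0.25, 0.08, 0.07, 0.07, 0.06, 0.06, 0.06, 0.05,
                       0.05, 0.04, 0.04, 0.04, 0.04, 0.03, 0.03, 0.03)

# genes longer than this are not drawn; keeps pairwise DP memory bounded
# while spanning the realistic bacterial CDS length range
.MAX_GENE_CODONS <- 1500L

#' Simulate an ancestral gene repertoire
#'
#' Draws `n_genes` protein-coding genes: each starts with `ATG`, contains no
#' internal stop codon, and has length (in codons) of at least 50, geometric
#' around `mean_len_codons`.  Codons after the start are drawn i.i.d. from
#' the 61 sense codons with nucleotide weights solved numerically so the
#' realized G+C fraction matches `gc_target`.
#'
#' @param n_genes number of genes (>= 1)
#' @param mean_len_codons mean gene length in codons (>= 50)
#' @param gc_target target G+C fraction, in (0, 1)
#' @param seed integer seed; the same seed reproduces the repertoire exactly
#' @return an `ancestral_repertoire`: data.frame with columns `locus_id`,
#'   `seq`, `category` and attribute `gc_target`
#' @examples
#' anc <- simulate_ancestor(5, 60, 0.52, seed = 1)
#' nchar(anc$seq)
#' @export
simulate_ancestor <- function(n_genes, mean_len_codons = 300L,
                              gc_target = 0.52, seed = 1L) {
  stopifnot(is.numeric(n_genes), length(n_genes) == 1L)
  if (n_genes < 1) stop("n_genes must be a positive integer")
  if (mean_len_codons < 50) stop("mean_len_codons must be at least 50")
  if (!is.numeric(gc_target) || gc_target <= 0 || gc_target >= 1) {
    stop("gc_target must be a fraction in (0, 1)")
  }
  n_genes <- as.integer(n_genes)

  with_seed(seed, {
    lens <- sample_gene_lengths(n_genes, mean_len_codons)
    w <- sense_codon_weights(gc_target)
    sense <- sense_codons()
    seqs <- vapply(lens, function(L) {
      body <- sample(sense, L - 1L, replace = TRUE, prob = w)
      paste0("ATG", paste(body, collapse = ""))
    }, character(1L))
    cats <- sample(.CATEGORY_LEVELS, n_genes, replace = TRUE,
                   prob = .CATEGORY_WEIGHTS)
    anc <- data.frame(
      locus_id = sprintf("anc_%05d", seq_len(n_genes)),
      seq = seqs,
      category = cats,
      stringsAsFactors = FALSE
    )
    attr(anc, "gc_target") <- gc_target
    class(anc) <- c("ancestral_repertoire", "data.frame")
    anc
  })
}

# geometric lengths with floor 50 codons and a fixed cap
#' @noRd
sample_gene_lengths <- function(n, mean_len) {
  p <- 1 / (mean_len - 49)
  lens <- 50L + stats::rgeom(n, p)
  pmin(lens, .MAX_GENE_CODONS)
}

# nucleotide weight g solved so the expected G+C over sense codons hits the
# target (stop-codon exclusion skews simple i.i.d. nucleotide sampling)
#' @noRd
sense_codon_weights <- function(gc_target) {
  sense <- sense_codons()
  gc_count <- vapply(strsplit(sense, "", fixed = TRUE),
                     function(ch) sum(ch %in% c("G", "C")), numeric(1L))
  exp_gc <- function(g) {
    p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    w <- vapply(strsplit(sense, "", fixed = TRUE),
                function(ch) prod(p[ch]), numeric(1L))
    sum(w * gc_count / 3) / sum(w)
  }
  g <- stats::uniroot(function(g) exp_gc(g) - gc_target,
                      interval = c(0.02, 0.98))$root
  p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  vapply(strsplit(sense, "", fixed = TRUE),
         function(ch) prod(p[ch]), numeric(1L))
}

#' Define a genome-evolution scenario
#'
#' @param tree rooted binary tree (`ape::phylo`) with branch lengths in
#'   expected accepted substitutions per codon; leaf names must be unique
#' @param loss_prob per-branch probability that each surviving gene is lost;
#'   a scalar, or a vector along `tree$edge` rows
#' @param gain_rate per-branch Poisson mean of newly gained genes; scalar or
#'   per-edge vector
#' @param omega dN/dS ratio of the accepted substitution process (> 0)
#' @param kappa transition/transversion rate ratio of the proposal (> 0)
#' @param seed integer seed driving all randomness in [evolve_clade()]
#' @return an `evolution_scenario` object
#' @export
evolution_scenario <- function(tree, loss_prob = 0.05, gain_rate = 10,
                               omega = 0.2, kappa = 2.0, seed = 1L) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("leaf names must be unique")
  if (ape::Ntip(tree) < 2) stop("tree must have at least 2 leaves")
  ne <- nrow(tree$edge)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, ne)
    if (length(x) != ne) stop(what, " must be a scalar or one value per edge")
    x
  }
  loss_prob <- expand(loss_prob, "loss_prob")
  gain_rate <- expand(gain_rate, "gain_rate")
  if (any(loss_prob < 0 | loss_prob > 1)) stop("loss_prob must lie in [0, 1]")
  if (any(gain_rate < 0)) stop("gain_rate must be >= 0")
  if (!is.numeric(omega) || omega <= 0) stop("omega must be > 0")
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  structure(list(tree = tree, loss_prob = loss_prob, gain_rate = gain_rate,
                 omega = omega, kappa = kappa, seed = as.integer(seed)),
            class = "evolution_scenario")
}

#' Evolve a clade of genomes from an ancestral repertoire
#'
#' Codon sequences evolve independently per codon under a 61-state
#' continuous-time Markov chain built from single-nucleotide exchanges
#' (transition:transversion proposal ratio `kappa`, nonsynonymous changes
#' accepted at relative rate `omega`, changes to stop codons forbidden).
#' The chain is scaled so one unit of branch length equals one expected
#' accepted substitution per codon at the ancestral codon composition.  The
#' start codon of each gene is held fixed.  On each branch every surviving
#' gene is lost independently with the branch's `loss_prob`, and a
#' Poisson(`gain_rate`) number of novel genes (simulated de novo, never
#' homologous to ancestral loci) is gained.
#'
#' @param ancestor an [simulate_ancestor()] repertoire
#' @param scenario an [evolution_scenario()]
#' @return a list with `genomes` (named list of gene-record data.frames, one
#'   per leaf, columns `locus_id`, `genome_id`, `seq`, `category`) and
#'   `truth` (a `truth_table`: per-leaf gene provenance plus the true
#'   ancestral core of every named clade)
#' @export
evolve_clade <- function(ancestor, scenario) {
  if (!inherits(ancestor, "ancestral_repertoire") || nrow(ancestor) == 0) {
    stop("ancestor must be a non-empty ancestral_repertoire")
  }
  if (!inherits(scenario, "evolution_scenario")) {
    stop("scenario must be an evolution_scenario")
  }
  tree <- scenario$tree
  sense <- sense_codons()
  gc_target <- attr(ancestor, "gc_target") %||% 0.52

  with_seed(scenario$seed, {
    Q <- codon_rate_matrix(scenario$kappa, scenario$omega)
    anc_idx <- lapply(ancestor$seq, codon_indices, sense = sense)
    # scale: mean leaving rate over the ancestral codon composition
    counts <- tabulate(unlist(anc_idx), nbins = length(sense))
    rbar <- sum(counts * (-diag(Q))) / sum(counts)
    eig <- eigen(Q, symmetric = TRUE)

    ntip <- ape::Ntip(tree)
    root <- ntip + 1L
    n_nodes <- ntip + tree$Nnode

    # per-node gene sets
    node_genes <- vector("list", n_nodes)
    node_genes[[root]] <- list(
      locus = ancestor$locus_id,
      provenance = rep("ancestral", nrow(ancestor)),
      ancestral_locus = ancestor$locus_id,
      gain_branch = rep(NA_character_, nrow(ancestor)),
      category = ancestor$category,
      idx = anc_idx
    )

    gene_weights <- sense_codon_weights(gc_target)
    gain_counter <- 0L

    # preorder edge traversal (parents before children)
    po <- rev(ape::postorder(tree))
    for (e in po) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      t_branch <- tree$edge.length[e]
      g <- node_genes[[parent]]

      # substitution: evolve all codons except the fixed start codon
      if (t_branch > 0 && length(g$locus) > 0) {
        P <- codon_transition_probs(eig, t_branch / rbar)
        lens <- lengths(g$idx)
        v <- unlist(g$idx, use.names = FALSE)
        evolvable <- rep(TRUE, length(v))
        evolvable[cumsum(c(1L, lens[-length(lens)]))] <- FALSE
        v2 <- v
        for (s in unique(v[evolvable])) {
          sel <- which(evolvable & v == s)
          v2[sel] <- sample.int(length(sense), length(sel),
                                replace = TRUE, prob = P[s, ])
        }
        g$idx <- split_by_lengths(v2, lens)
      }

      # gene loss
      if (length(g$locus) > 0 && scenario$loss_prob[e] > 0) {
        keep <- stats::runif(length(g$locus)) >= scenario$loss_prob[e]
        g <- filter_gene_set(g, keep)
      }

      # gene gain: novel sequences, never homologous to ancestral loci
      n_gain <- stats::rpois(1L, scenario$gain_rate[e])
      if (n_gain > 0) {
        lens_new <- sample_gene_lengths(n_gain, 300L)
        new_idx <- lapply(lens_new, function(L) {
          c(match("ATG", sense),
            sample.int(length(sense), L - 1L, replace = TRUE,
                       prob = gene_weights))
        })
        ids <- sprintf("gain_n%d_%04d", child, gain_counter + seq_len(n_gain))
        gain_counter <- gain_counter + n_gain
        g$locus <- c(g$locus, ids)
        g$provenance <- c(g$provenance, rep("gained", n_gain))
        g$ancestral_locus <- c(g$ancestral_locus, rep(NA_character_, n_gain))
        g$gain_branch <- c(g$gain_branch, rep(node_label(tree, child), n_gain))
        g$category <- c(g$category,
                        sample(.CATEGORY_LEVELS, n_gain, replace = TRUE,
                               prob = .CATEGORY_WEIGHTS))
        g$idx <- c(g$idx, new_idx)
      }
      node_genes[[child]] <- g
    }

    # emit leaf genomes with leaf-local locus tags
    genomes <- list()
    truth_rows <- list()
    for (leaf in seq_len(ntip)) {
      g <- node_genes[[leaf]]
      leaf_name <- tree$tip.label[leaf]
      n <- length(g$locus)
      tags <- sprintf("%s_g%05d", leaf_name, seq_len(n))
      seqs <- vapply(g$idx, function(ix) paste(sense[ix], collapse = ""),
                     character(1L))
      genomes[[leaf_name]] <- data.frame(
        locus_id = tags, genome_id = leaf_name, seq = seqs,
        category = g$category, stringsAsFactors = FALSE)
      truth_rows[[leaf_name]] <- data.frame(
        leaf = leaf_name, locus = tags, provenance = g$provenance,
        ancestral_locus = g$ancestral_locus, origin_locus = g$locus,
        gain_branch = g$gain_branch, stringsAsFactors = FALSE)
    }
    truth_df <- do.call(rbind, truth_rows)
    rownames(truth_df) <- NULL
    truth <- build_truth_table(truth_df, tree)
    list(genomes = genomes, truth = truth)
  })
}

#' @noRd
node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) tree$tip.label[node] else paste0("node_", node)
}

#' @noRd
filter_gene_set <- function(g, keep) {
  list(locus = g$locus[keep], provenance = g$provenance[keep],
       ancestral_locus = g$ancestral_locus[keep],
       gain_branch = g$gain_branch[keep], category = g$category[keep],
       idx = g$idx[keep])
}

#' @noRd
codon_indices <- function(seq, sense) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length must be a multiple of 3")
  cods <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  ix <- match(cods, sense)
  if (anyNA(ix)) stop("sequence contains a stop codon or non-ACGT characters")
  ix
}

#' @noRd
split_by_lengths <- function(v, lens) {
  f <- rep.int(seq_along(lens), lens)
  unname(split(v, f))
}

# truth table: per-leaf provenance plus true ancestral core of every clade
#' @noRd
build_truth_table <- function(truth_df, tree) {
  ntip <- ape::Ntip(tree)
  clade_cores <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    leaves <- tree$tip.label[leaves_under(tree, node)]
    inv <- lapply(leaves, function(lf) {
      rows <- truth_df$leaf == lf & truth_df$provenance == "ancestral"
      unique(truth_df$ancestral_locus[rows])
    })
    clade_cores[[paste0("node_", node)]] <- sort(Reduce(intersect, inv))
  }
  structure(list(genes = truth_df, clade_cores = clade_cores, tree = tree),
            class = "truth_table")
}

#' @noRd
leaves_under <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, leaves_under, tree = tree))
}

#' Ancestral gene inventory of one simulated leaf
#'
#' @param truth a `truth_table` from [evolve_clade()]
#' @param leaf leaf name
#' @param ancestral_only if `TRUE` (default) return ancestral locus ids;
#'   otherwise leaf-local locus tags of all genes
#' @return character vector of locus ids
#' @export
truth_inventory <- function(truth, leaf, ancestral_only = TRUE) {
  stopifnot(inherits(truth, "truth_table"))
  df <- truth$genes[truth$genes$leaf == leaf, , drop = FALSE]
  if (nrow(df) == 0) stop("unknown leaf: ", leaf)
  if (ancestral_only) {
    unique(df$ancestral_locus[df$provenance == "ancestral"])
  } else {
    df$locus
  }
}

#' True ancestral core of a set of leaves
#'
#' The intersection of the leaves' ancestral gene inventories -- the ground
#' truth that recovered core genomes are compared against.
#'
#' @param truth a `truth_table`
#' @param leaves character vector of leaf names
#' @return sorted character vector of ancestral locus ids
#' @export
truth_core <- function(truth, leaves) {
  inv <- lapply(leaves, function(lf) truth_inventory(truth, lf))
  sort(Reduce(intersect, inv))
}

#' Map leaf-local locus tags to ancestral loci
#'
#' @param truth a `truth_table`
#' @param leaf leaf name
#' @return named character vector: leaf locus tag -> ancestral locus id
#'   (`NA` for gained genes)
#' @export
truth_locus_map <- function(truth, leaf) {
  df <- truth$genes[truth$genes$leaf == leaf, , drop = FALSE]
  stats::setNames(df$ancestral_locus, df$locus)
}

#' Expected pairwise synonymous divergence between two leaves
#'
#' Converts a path length on the scenario tree (expected accepted
#' substitutions per codon) into the expected number of synonymous
#' substitutions per Nei-Gojobori synonymous site, the scale on which dS is
#' estimated and on which saturation (dS > 3) is declared.
#'
#' @param ancestor the ancestral repertoire (sets codon composition)
#' @param omega,kappa substitution-process parameters
#' @param t_total total path length between the two leaves, in expected
#'   accepted substitutions per codon
#' @return expected dS (numeric scalar)
#' @export
expected_pairwise_ds <- function(ancestor, omega, kappa, t_total) {
  stopifnot(inherits(ancestor, "ancestral_repertoire"))
  sense <- sense_codons()
  Q <- codon_rate_matrix(kappa, omega)
  gc <- genetic_code_11()
  aa <- translate_codons(sense)
  # synonymous leaving rate per codon
  syn_rate <- vapply(seq_along(sense), function(i) {
    nb <- codon_neighbors(sense[i])
    nb <- nb[nb %in% sense]
    sum(Q[i, nb][aa[match(nb, sense)] == aa[i]])
  }, numeric(1L))
  idx <- unlist(lapply(ancestor$seq, codon_indices, sense = sense))
  counts <- tabulate(idx, nbins = length(sense))
  freq <- counts / sum(counts)
  rbar <- sum(freq * (-diag(Q)))
  syn_subs_per_codon <- t_total * sum(freq * syn_rate) / rbar
  s_sites_per_codon <- sum(freq * ng86_site_table())
  syn_subs_per_codon / s_sites_per_codon
}

#' Simulate diverged ortholog pairs with known omega
#'
#' Convenience wrapper around [evolve_clade()] for a two-leaf tree with no
#' gene turnover: every ancestral gene yields one orthologous pair at total
#' divergence `t_total`.
#'
#' @param n_pairs number of gene pairs
#' @param mean_len_codons mean gene length in codons
#' @param t_total total divergence between the two leaves (expected accepted
#'   substitutions per codon)
#' @param omega,kappa substitution-process parameters
#' @param seed integer seed
#' @param gc_target ancestral G+C fraction
#' @return list with `a`, `b` (gene-record data.frames whose rows pair up),
#'   `ancestor` and `truth`
#' @export
simulate_ortholog_pairs <- function(n_pairs, mean_len_codons = 300L, t_total,
                                    omega, kappa = 1.0, seed = 1L,
                                    gc_target = 0.52) {
  anc <- simulate_ancestor(n_pairs, mean_len_codons, gc_target, seed = seed)
  tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t_total / 2, t_total / 2))
  sc <- evolution_scenario(tr, loss_prob = 0, gain_rate = 0, omega = omega,
                           kappa = kappa, seed = seed + 1L)
  sim <- evolve_clade(anc, sc)
  list(a = sim$genomes$A, b = sim$genomes$B, ancestor = anc,
       truth = sim$truth)
}

#' Write a simulated clade to disk as plain-text fixtures
#'
#' Emits one CDS multi-FASTA (`<genome>.fasta`, headers
#' `><genome_id>|<locus_id>`) and one two-column category TSV per genome,
#' plus one truth TSV; all round-trip losslessly through the package
#' readers.
#'
#' @param genomes named list of gene-record data.frames from [evolve_clade()]
#' @param truth the matching `truth_table`
#' @param out_dir output directory (created if needed)
#' @return invisibly, a manifest data.frame (`type`, `genome`, `path`)
#' @export
write_fixture <- function(genomes, truth, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  manifest <- list()
  for (gid in names(genomes)) {
    fa <- file.path(out_dir, paste0(gid, ".fasta"))
    tsv <- file.path(out_dir, paste0(gid, "_categories.tsv"))
    write_cds_fasta(genomes[[gid]], fa)
    write_category_tsv(genomes[[gid]][, c("locus_id", "category")], tsv)
    manifest[[length(manifest) + 1L]] <-
      data.frame(type = c("cds_fasta", "categories"), genome = gid,
                 path = c(fa, tsv), stringsAsFactors = FALSE)
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth$genes, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest[[length(manifest) + 1L]] <-
    data.frame(type = "truth", genome = NA_character_, path = truth_path,
               stringsAsFactors = FALSE)
  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  invisible(out)
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
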