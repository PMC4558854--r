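# Pipeline driver: chains orthology, core-genome reconstruction, loss
# accounting, pan-genome scanning, the core-locus NJ tree and genome-wide
# dN/dS into one deterministic, config-driven run.

#' Assemble and validate a pipeline configuration
#'
#' @param genomes named list of gene-record data.frames (names = genome ids)
#' @param genera named list; each element a list with `reference` (genome
#'   id) and `members` (character vector of genome ids).  The first two
#'   genera define the LCA reconstruction; the first genus's reference
#'   anchors the LCA coordinates.
#' @param targets genome ids whose loss relative to the LCA core is
#'   accounted
#' @param dnds_pairs list of 2-vectors of genome ids for genome-wide dN/dS
#' @param identity,coverage allelic-variant thresholds for the pan-genome
#' @param prevalence core-locus prevalence threshold
#' @param saturation dS saturation threshold
#' @param min_score minimum reportable local-alignment score
#' @param bootstrap bootstrap pseudoreplicates for the core-genome tree
#' @param seed integer seed (bootstrap resampling)
#' @param out_dir output directory
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(genomes, genera, targets = character(0),
                            dnds_pairs = list(), identity = 0.70,
                            coverage = 0.10, prevalence = 0.90,
                            saturation = 3.0, min_score = 50,
                            bootstrap = 100L, seed = 1L, out_dir) {
  stopifnot(is.list(genomes), length(genomes) >= 2L,
            !is.null(names(genomes)))
  if (length(genera) < 2L) {
    stop("at least two genera are required for LCA reconstruction")
  }
  all_ids <- names(genomes)
  for (gn in names(genera)) {
    g <- genera[[gn]]
    if (!g$reference %in% all_ids) {
      stop("genus ", gn, ": unknown reference genome ", g$reference)
    }
    if (!all(g$members %in% all_ids)) {
      stop("genus ", gn, ": unknown member genome(s)")
    }
  }
  if (!all(targets %in% all_ids)) stop("unknown target genome(s)")
  for (p in dnds_pairs) {
    if (length(p) != 2L || !all(p %in% all_ids)) {
      stop("each dnds pair must name two known genomes")
    }
  }
  check_fraction <- function(x, what) {
    if (!is.numeric(x) || x <= 0 || x > 1) stop(what, " must lie in (0, 1]")
  }
  check_fraction(identity, "identity")
  check_fraction(coverage, "coverage")
  check_fraction(prevalence, "prevalence")
  if (saturation <= 0) stop("saturation threshold must be positive")
  structure(list(genomes = genomes, genera = genera, targets = targets,
                 dnds_pairs = dnds_pairs, identity = identity,
                 coverage = coverage, prevalence = prevalence,
                 saturation = saturation, min_score = min_score,
                 bootstrap = as.integer(bootstrap), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file names per-genome CDS FASTA (and optional category TSV) paths,
#' genus membership, targets, thresholds and the seed; all paths are
#' validated before any computation.  Relative paths resolve against the
#' config file's directory.
#'
#' @param path YAML config file
#' @return a `pipeline_config` with all genome files loaded
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  if (is.null(y$genomes) || length(y$genomes) == 0L) {
    stop("config lists no genomes")
  }
  genomes <- list()
  genus_members <- list()
  for (gid in names(y$genomes)) {
    entry <- y$genomes[[gid]]
    fa <- resolve(entry$fasta)
    if (!file.exists(fa)) stop("genome ", gid, ": missing FASTA ", fa)
    rec <- read_cds_fasta(fa, genome_id = gid)
    rec$genome_id <- gid
    if (!is.null(entry$categories)) {
      ct <- resolve(entry$categories)
      if (!file.exists(ct)) stop("genome ", gid, ": missing categories ", ct)
      cats <- read_category_tsv(ct)
      rec$category <- stats::setNames(cats$category,
                                      cats$locus_id)[rec$locus_id]
    }
    genomes[[gid]] <- rec
    if (!is.null(entry$genus)) {
      genus_members[[entry$genus]] <- c(genus_members[[entry$genus]], gid)
    }
  }
  genera <- list()
  for (gn in names(y$genera)) {
    genera[[gn]] <- list(reference = y$genera[[gn]]$reference,
                         members = genus_members[[gn]] %||%
                           y$genera[[gn]]$members)
  }
  th <- y$thresholds %||% list()
  pipeline_config(
    genomes = genomes, genera = genera,
    targets = unlist(y$targets) %||% character(0),
    dnds_pairs = y$dnds_pairs %||% list(),
    identity = th$identity %||% 0.70, coverage = th$coverage %||% 0.10,
    prevalence = th$prevalence %||% 0.90,
    saturation = th$saturation %||% 3.0,
    min_score = th$min_score %||% 50,
    bootstrap = y$bootstrap %||% 100L, seed = y$seed %||% 1L,
    out_dir = resolve(y$out_dir %||% "panevo_out"))
}

#' Run the full comparative-genomics pipeline
#'
#' Stages: reciprocal-best-hit ortholog tables for every required genome
#' pair; genus core genomes; the two-genus LCA core; loss ledgers for each
#' target genome; the reference pan-genome, presence/absence matrix and
#' core loci; the core-locus supermatrix and bootstrapped NJ tree; and
#' genome-wide dN/dS for each configured pair.  All outputs are written
#' under `config$out_dir` together with a JSON run manifest; a rerun with
#' the same config reproduces the bundle byte for byte.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with elements `rbh`, `cores`, `lca`, `losses`,
#'   `pangenome`, `presence`, `core_loci`, `supermatrix`, `tree`, `dnds`
#'   and `manifest`
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- align_params(min_score = config$min_score)
  genomes <- config$genomes
  stage <- function(name, expr) {
    message("[panevo] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  genera <- config$genera
  genus_names <- names(genera)
  ref_a <- genera[[1L]]$reference
  ref_b <- genera[[2L]]$reference

  # -- orthology ------------------------------------------------------------
  rbh <- list()
  need_pairs <- list()
  for (gn in genus_names[1:2]) {
    for (m in setdiff(genera[[gn]]$members, genera[[gn]]$reference)) {
      need_pairs[[length(need_pairs) + 1L]] <- c(genera[[gn]]$reference, m)
    }
  }
  need_pairs[[length(need_pairs) + 1L]] <- c(ref_a, ref_b)
  for (tg in config$targets) {
    need_pairs[[length(need_pairs) + 1L]] <- c(ref_a, tg)
  }
  for (p in config$dnds_pairs) need_pairs[[length(need_pairs) + 1L]] <- p
  stage("reciprocal best hits", {
    for (p in need_pairs) {
      key <- paste(sort(p), collapse = "|")
      if (!is.null(rbh[[key]])) next
      tb <- rbh_table(genomes[[p[1L]]], genomes[[p[2L]]], params)
      rbh[[key]] <- tb
      write_ortholog_tsv(tb, file.path(out_dir,
                                       paste0("rbh_", gsub("\\|", "_", key),
                                              ".tsv")))
      message("  ", key, ": ", nrow(tb), " ortholog pairs")
    }
  })
  tables <- unname(rbh)

  # -- core genomes and loss accounting -------------------------------------
  cores <- list()
  lca <- NULL
  losses <- list()
  stage("core genomes", {
    for (gn in genus_names[1:2]) {
      g <- genera[[gn]]
      cores[[gn]] <- genus_core(genomes[[g$reference]],
                                 setdiff(g$members, g$reference), tables,
                                 clade = gn)
      message("  ", gn, " core: ", length(cores[[gn]]$loci), " loci")
    }
  })
  stage("LCA core", {
    bridge <- find_table(tables, ref_a, ref_b)
    lca <- lca_core(cores[[1L]], cores[[2L]], bridge)
    message("  LCA core: ", length(lca$loci), " loci")
    writeLines(lca$loci, file.path(out_dir, "lca_core_loci.txt"))
  })
  stage("loss accounting", {
    ref_cat <- genomes[[ref_a]][, c("locus_id", "category")]
    for (tg in config$targets) {
      tb <- find_table(tables, ref_a, tg)
      led <- loss_accounting(lca, tg, tb, categories = ref_cat)
      losses[[tg]] <- led
      write_loss_ledger(led, file.path(out_dir, paste0("loss_", tg)))
      message("  ", tg, ": retained ", length(led$retained), ", lost ",
              length(led$lost))
    }
  })

  # -- pan-genome -----------------------------------------------------------
  pg <- NULL; presence <- NULL; core_ids <- NULL
  stage("pan-genome", {
    pg <- build_reference_pangenome(genomes, config$identity,
                                     config$coverage, params)
    message("  ", length(pg$loci), " pan-loci")
  })
  stage("presence/absence scan", {
    presence <- scan_presence(pg, genomes, params)
    write_presence_tsv(presence, file.path(out_dir, "presence_absence.tsv"))
    core_ids <- core_loci(presence, config$prevalence)
    writeLines(core_ids, file.path(out_dir, "core_loci.txt"))
    message("  ", length(core_ids), " core loci at prevalence >= ",
            config$prevalence)
  })

  # -- core-locus supermatrix and NJ tree -----------------------------------
  sm <- NULL; tree <- NULL
  stage("core-locus phylogeny", {
    alns <- list()
    seq_of <- lapply(genomes, function(g) {
      stats::setNames(g$seq, g$locus_id)
    })
    mm <- presence$matches
    for (lid in core_ids) {
      sub <- mm[mm$pan_locus == lid, , drop = FALSE]
      if (nrow(sub) < 2L) next
      seqs <- stats::setNames(
        vapply(seq_len(nrow(sub)), function(i) {
          seq_of[[sub$genome_id[i]]][[sub$gene_locus[i]]]
        }, character(1L)), sub$genome_id)
      alns[[lid]] <- align_gene(seqs)
    }
    if (length(alns) == 0L) stop("no alignable core loci")
    sm <- concatenate(alns, taxon_policy = "drop-incomplete")
    write_alignment_fasta(sm, file.path(out_dir, "core_supermatrix.fasta"))
    write_partitions(sm, file.path(out_dir, "core_supermatrix.partitions"))
    tree <- bootstrap_support(sm, n_reps = config$bootstrap, model = "jc",
                               seed = config$seed)
    ape::write.tree(tree, file.path(out_dir, "core_nj_tree.nwk"))
    message("  supermatrix: ", length(sm$aln), " taxa x ",
            nchar(sm$aln[[1L]]), " columns; NJ tree with ",
            config$bootstrap, " bootstrap replicates")
  })

  # -- dN/dS ----------------------------------------------------------------
  dnds <- list()
  stage("dN/dS", {
    for (p in config$dnds_pairs) {
      key <- paste(sort(p), collapse = "|")
      tb <- find_table(tables, p[1L], p[2L])
      a_id <- attr(tb, "a_id"); b_id <- attr(tb, "b_id")
      res <- genome_wide_dnds(tb, genomes[[a_id]], genomes[[b_id]],
                              config$saturation)
      dnds[[key]] <- res
      utils::write.table(res$table,
                         file.path(out_dir,
                                   paste0("dnds_", gsub("\\|", "_", key),
                                          ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message("  ", key, ": ", res$summary$n_pairs, " pairs, mean dS (uns) ",
              signif(res$summary$mean_dS_unsaturated, 3),
              ", saturated ", signif(res$summary$fraction_saturated, 3))
    }
  })

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package = "panevo",
    version = as.character(utils::packageVersion("panevo")),
    seed = config$seed,
    thresholds = list(identity = config$identity,
                      coverage = config$coverage,
                      prevalence = config$prevalence,
                      saturation = config$saturation,
                      min_score = config$min_score),
    genomes = lapply(genomes, nrow),
    genera = lapply(config$genera, function(g) g),
    targets = config$targets,
    results = list(
      genus_core_sizes = lapply(cores, function(cc) length(cc$loci)),
      lca_core_size = length(lca$loci),
      losses = lapply(losses, function(l) {
        list(retained = length(l$retained), lost = length(l$lost))
      }),
      pangenome_loci = length(pg$loci),
      core_loci = length(core_ids),
      supermatrix = if (!is.null(sm))
        list(taxa = length(sm$aln), columns = nchar(sm$aln[[1L]])),
      dnds = lapply(dnds, function(d) d$summary)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(rbh = rbh, cores = cores, lca = lca, losses = losses,
                 pangenome = pg, presence = presence, core_loci = core_ids,
                 supermatrix = sm, tree = tree, dnds = dnds,
                 manifest = manifest))
}
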