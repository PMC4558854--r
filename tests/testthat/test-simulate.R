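test_that("ancestor generator yields valid genes, deterministically", {
  one <- simulate_ancestor(1, 50, 0.5, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_gte(nchar(one$seq), 150L)
  expect_equal(substr(one$seq, 1, 3), "ATG")
  cods <- substring(one$seq, seq(1, nchar(one$seq), 3),
                    seq(3, nchar(one$seq), 3))
  expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))

  again <- simulate_ancestor(1, 50, 0.5, seed = 3)
  expect_identical(one, again)
  other <- simulate_ancestor(1, 50, 0.5, seed = 4)
  expect_false(identical(one$seq, other$seq))

  expect_error(simulate_ancestor(0, 50, 0.5), "positive")
  expect_error(simulate_ancestor(10, 20, 0.5), "at least 50")
  expect_error(simulate_ancestor(10, 50, 1.2), "fraction")
})

test_that("realized GC content tracks the target", {
  anc <- simulate_ancestor(1000, 100, gc_target = 0.53, seed = 11)
  all_nt <- strsplit(paste(anc$seq, collapse = ""), "", fixed = TRUE)[[1L]]
  gc <- mean(all_nt %in% c("G", "C"))
  expect_gte(gc, 0.50)
  expect_lte(gc, 0.56)
})

test_that("no-event and zero-divergence limits reproduce the ancestor", {
  anc <- simulate_ancestor(40, 60, 0.52, seed = 5)
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  sc <- evolution_scenario(tr, loss_prob = 0, gain_rate = 0, omega = 1,
                           kappa = 1, seed = 2)
  sim <- evolve_clade(anc, sc)
  for (leaf in c("A", "B", "C", "D")) {
    expect_identical(sim$genomes[[leaf]]$seq, anc$seq)
    expect_setequal(truth_inventory(sim$truth, leaf), anc$locus_id)
  }
})

test_that("per-branch gene loss is binomial at the stated probability", {
  anc <- simulate_ancestor(1000, 50, 0.52, seed = 6)
  tr <- ape::read.tree(text = "(A:0.01,B:0.01);")
  sc <- evolution_scenario(tr, loss_prob = 0.1, gain_rate = 0, omega = 1,
                           kappa = 1, seed = 7)
  sim <- evolve_clade(anc, sc)
  lo <- qbinom(0.005, 1000, 0.9)
  hi <- qbinom(0.995, 1000, 0.9)
  for (leaf in c("A", "B")) {
    kept <- length(truth_inventory(sim$truth, leaf))
    expect_gte(kept, lo)
    expect_lte(kept, hi)
  }
})

test_that("truth clade cores equal recomputed inventory intersections", {
  anc <- simulate_ancestor(120, 60, 0.52, seed = 8)
  tr <- ape::read.tree(
    text = "((A:0.05,B:0.05):0.02,(C:0.05,D:0.05):0.02);")
  sc <- evolution_scenario(tr, loss_prob = 0.15, gain_rate = 5, omega = 0.3,
                           kappa = 2, seed = 9)
  sim <- evolve_clade(anc, sc)
  # direct recomputation for every named clade
  desc <- function(node) {
    ntip <- ape::Ntip(tr)
    if (node <= ntip) return(node)
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  for (nd in names(sim$truth$clade_cores)) {
    node <- as.integer(sub("node_", "", nd))
    leaves <- tr$tip.label[desc(node)]
    expect_identical(sim$truth$clade_cores[[nd]],
                     truth_core(sim$truth, leaves))
    inv <- lapply(leaves, function(lf) truth_inventory(sim$truth, lf))
    expect_identical(sim$truth$clade_cores[[nd]],
                     sort(Reduce(intersect, inv)))
  }
})

test_that("gained genes are novel and labelled with their branch", {
  anc <- simulate_ancestor(30, 60, 0.52, seed = 10)
  tr <- ape::read.tree(text = "(A:0.02,B:0.02);")
  sc <- evolution_scenario(tr, loss_prob = 0, gain_rate = 8, omega = 0.5,
                           kappa = 2, seed = 11)
  sim <- evolve_clade(anc, sc)
  tg <- sim$truth$genes
  gained <- tg[tg$provenance == "gained", ]
  expect_gt(nrow(gained), 0L)
  expect_true(all(is.na(gained$ancestral_locus)))
  expect_true(all(!is.na(gained$gain_branch)))
  ancestral <- tg[tg$provenance == "ancestral", ]
  expect_true(all(ancestral$ancestral_locus %in% anc$locus_id))
})

test_that("scenario validation rejects malformed inputs", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  expect_error(evolution_scenario(tr, loss_prob = 1.5), "loss_prob")
  expect_error(evolution_scenario(tr, omega = -1), "omega")
  expect_error(evolution_scenario(tr, kappa = 0), "kappa")
  tr2 <- tr; tr2$edge.length <- NULL
  expect_error(evolution_scenario(tr2), "branch lengths")
  anc <- simulate_ancestor(5, 50, 0.5, seed = 1)
  expect_error(evolve_clade(anc[0, ], evolution_scenario(tr)), "non-empty")
})

test_that("fixtures round-trip through the package readers", {
  anc <- simulate_ancestor(25, 55, 0.52, seed = 12)
  tr <- ape::read.tree(text = "(A:0.03,B:0.03);")
  sc <- evolution_scenario(tr, loss_prob = 0.1, gain_rate = 2, omega = 0.4,
                           kappa = 2, seed = 13)
  sim <- evolve_clade(anc, sc)
  out <- withr::local_tempdir()
  manifest <- write_fixture(sim$genomes, sim$truth, out)
  expect_equal(sum(manifest$type == "cds_fasta"), 2L)
  expect_equal(sum(manifest$type == "categories"), 2L)
  expect_equal(sum(manifest$type == "truth"), 1L)

  for (gid in c("A", "B")) {
    back <- read_cds_fasta(file.path(out, paste0(gid, ".fasta")))
    expect_identical(back$locus_id, sim$genomes[[gid]]$locus_id)
    expect_identical(back$seq, sim$genomes[[gid]]$seq)
    expect_identical(back$genome_id, sim$genomes[[gid]]$genome_id)
  }

  # truth core of the root clade from re-read files
  truth_back <- read.table(file.path(out, "truth.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  inv <- lapply(c("A", "B"), function(lf) {
    fa <- read_cds_fasta(file.path(out, paste0(lf, ".fasta")))
    rows <- truth_back[truth_back$leaf == lf &
                         truth_back$provenance == "ancestral", ]
    expect_true(all(rows$locus %in% fa$locus_id))
    rows$ancestral_locus
  })
  expect_identical(sim$truth$clade_cores$node_3,
                   sort(Reduce(intersect, inv)))
})
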