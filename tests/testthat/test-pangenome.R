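test_that("clustering is a partition with the expected locus counts", {
  set.seed(41)
  g1 <- gene_records(sprintf("g%02d", 1:10), "G1",
                     replicate(10, random_dna(200)))
  pg <- build_reference_pangenome(list(G1 = g1))
  expect_length(pg$loci, 10L)

  g2 <- g1; g2$genome_id <- "G2"
  pg2 <- build_reference_pangenome(list(G1 = g1, G2 = g2))
  expect_length(pg2$loci, 10L)
  all_members <- do.call(rbind, lapply(pg2$loci, `[[`, "members"))
  expect_equal(nrow(all_members), 20L)  # every gene in exactly one locus
  expect_false(anyDuplicated(paste(all_members$genome_id,
                                   all_members$locus_id)) > 0)
  # representative is a member
  for (l in pg2$loci) {
    rep_gid <- sub("\\|.*$", "", l$locus_id)
    rep_lid <- sub("^[^|]*\\|", "", l$locus_id)
    expect_true(any(l$members$genome_id == rep_gid &
                      l$members$locus_id == rep_lid))
  }
})

test_that("truncated copies merge under loose but not strict coverage", {
  set.seed(42)
  full <- replicate(6, random_dna(600))
  trunc <- substr(full, 1, 180)  # 30% of the coding length
  g1 <- gene_records(sprintf("f%02d", 1:6), "G1", full)
  g2 <- gene_records(sprintf("t%02d", 1:6), "G2", trunc)
  loose <- build_reference_pangenome(list(G1 = g1, G2 = g2),
                                     coverage_threshold = 0.10)
  strict <- build_reference_pangenome(list(G1 = g1, G2 = g2),
                                      coverage_threshold = 0.70)
  expect_length(loose$loci, 6L)
  expect_length(strict$loci, 12L)
})

test_that("raising thresholds never merges more", {
  set.seed(43)
  base <- replicate(5, random_dna(300))
  variants <- vapply(base, function(s) mutate_seq(s, sample(300, 60)),
                     character(1L))
  g1 <- gene_records(sprintf("a%02d", 1:5), "G1", base)
  g2 <- gene_records(sprintf("b%02d", 1:5), "G2", variants)
  n_locus <- function(idt) {
    length(build_reference_pangenome(list(G1 = g1, G2 = g2),
                                     identity_threshold = idt)$loci)
  }
  counts <- vapply(c(0.5, 0.7, 0.9), n_locus, numeric(1L))
  expect_true(all(diff(counts) >= 0))
})

test_that("presence scan is self-consistent and handles empty genomes", {
  anc <- simulate_ancestor(40, 60, 0.52, seed = 44)
  tr <- ape::read.tree(text = "(A:0.03,B:0.03);")
  sc <- evolution_scenario(tr, loss_prob = 0.15, gain_rate = 3, omega = 0.3,
                           kappa = 2, seed = 45)
  sim <- evolve_clade(anc, sc)
  pg <- build_reference_pangenome(sim$genomes)
  genomes <- c(sim$genomes,
               list(EMPTY = gene_records(character(0), character(0),
                                         character(0))))
  genomes$EMPTY$genome_id <- character(0)
  pa <- scan_presence(pg, genomes)
  # every contributing genome is present at its own loci
  for (l in pg$loci) {
    for (gid in unique(l$members$genome_id)) {
      expect_true(pa$matrix[l$locus_id, gid])
    }
  }
  expect_false(any(pa$matrix[, "EMPTY"]))
})

test_that("per-locus prevalence matches truth occupancy on simulations", {
  anc <- simulate_ancestor(60, 60, 0.52, seed = 46)
  tr <- ape::read.tree(
    text = "((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  sc <- evolution_scenario(tr, loss_prob = 0.2, gain_rate = 0, omega = 0.3,
                           kappa = 2, seed = 47)
  sim <- evolve_clade(anc, sc)
  pg <- build_reference_pangenome(sim$genomes)
  pa <- scan_presence(pg, sim$genomes)
  # truth occupancy per ancestral locus
  occ_truth <- table(sim$truth$genes$ancestral_locus[
    sim$truth$genes$provenance == "ancestral"])
  # map pan-locus representative back to its ancestral id
  rep_anc <- vapply(pg$loci, function(l) {
    gid <- sub("\\|.*$", "", l$locus_id)
    lid <- sub("^[^|]*\\|", "", l$locus_id)
    mp <- truth_locus_map(sim$truth, gid)
    mp[[lid]] %||% NA_character_
  }, character(1L))
  scanned <- rowSums(pa$matrix)
  comparable <- !is.na(rep_anc)
  mismatch <- sum(scanned[comparable] !=
                    as.integer(occ_truth[rep_anc[comparable]]))
  expect_lte(mismatch, ceiling(0.02 * sum(comparable)))
})

test_that("core-locus prevalence uses ceiling arithmetic", {
  mat <- matrix(FALSE, nrow = 3, ncol = 141,
                dimnames = list(c("just_below", "at_threshold", "everywhere"),
                                sprintf("g%03d", 1:141)))
  mat["just_below", 1:126] <- TRUE     # need ceiling(0.9 * 141) = 127
  mat["at_threshold", 1:127] <- TRUE
  mat["everywhere", ] <- TRUE
  expect_setequal(core_loci(mat, 0.90), c("at_threshold", "everywhere"))
  expect_setequal(core_loci(mat, 1.0), "everywhere")
  expect_setequal(core_loci(mat, 1e-9), rownames(mat))
  # monotone non-increasing in prevalence
  sizes <- vapply(c(0.2, 0.5, 0.9, 1.0),
                  function(p) length(core_loci(mat, p)), numeric(1L))
  expect_true(all(diff(sizes) <= 0))
})

test_that("query scan reports presence under the inclusive criterion", {
  anc <- simulate_ancestor(30, 70, 0.52, seed = 48)
  tr <- ape::read.tree(text = "(A:0,B:0);")
  sc <- evolution_scenario(tr, loss_prob = c(0, 0.4), gain_rate = 0,
                           omega = 1, kappa = 1, seed = 49)
  sim <- evolve_clade(anc, sc)
  # queries drawn verbatim from the ancestor (present in A, some lost in B)
  queries <- gene_records(anc$locus_id[1:10], "Q", anc$seq[1:10])
  rep <- query_scan(queries, sim$genomes)
  repA <- rep[rep$genome_id == "A", ]
  expect_true(all(repA$present))
  expect_true(all(repA$best_identity == 1))
  lost_b <- setdiff(anc$locus_id, truth_inventory(sim$truth, "B"))
  repB <- rep[rep$genome_id == "B", ]
  expect_true(all(!repB$present[repB$query %in% lost_b]))
  expect_true(all(repB$present[!repB$query %in% lost_b]))

  # boundary: exactly the identity threshold counts as present.  The first
  # 31 nt are intact (k-mer anchor); 89 substitutions every third position
  # keep the full-span alignment optimal, giving identity exactly 211/300.
  set.seed(50)
  s <- random_dna(300)
  q <- gene_records("q", "Q", s)
  hit <- mutate_seq(s, seq(32, 296, by = 3))
  gset <- list(T1 = gene_records("t", "T1", hit))
  r <- query_scan(q, gset, identity_threshold = 211 / 300)
  expect_equal(r$best_identity, 211 / 300)
  expect_true(r$present)
  strict <- query_scan(q, gset, identity_threshold = 211 / 300 + 1e-9)
  expect_false(strict$present)
})

test_that("zero-divergence pan-genome size equals the distinct-locus union", {
  anc <- simulate_ancestor(50, 60, 0.52, seed = 51)
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  sc <- evolution_scenario(tr, loss_prob = 0.2, gain_rate = 4, omega = 1,
                           kappa = 1, seed = 52)
  sim <- evolve_clade(anc, sc)
  pg <- build_reference_pangenome(sim$genomes)
  # distinct loci: gains on internal branches are inherited by several
  # leaves but constitute one locus each, which origin_locus records
  n_distinct <- length(unique(sim$truth$genes$origin_locus))
  expect_equal(length(pg$loci), n_distinct)
})
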