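test_that("center-star alignment handles identities, indels and orthologs", {
  al0 <- align_gene(c(x = "ACGTACGT", y = "ACGTACGT"))
  expect_false(any(grepl("-", unclass(al0), fixed = TRUE)))

  al1 <- align_gene(c(x = "ACGT", y = "AGT"))
  expect_equal(unique(nchar(unclass(al1))), 4L)
  aln_chars <- strsplit(unclass(al1), "", fixed = TRUE)
  expect_equal(sum(aln_chars$y == "-"), 1L)
  expect_equal(sum(aln_chars$x == aln_chars$y), 3L)

  sim <- simulate_ortholog_pairs(1, 80, t_total = 0.1, omega = 0.5,
                                 kappa = 2, seed = 61)
  anc <- sim$ancestor
  tr5 <- ape::read.tree(
    text = "(((A:0.02,B:0.02):0.02,C:0.04):0.01,(D:0.05,E:0.05):0.01);")
  sc <- evolution_scenario(tr5, loss_prob = 0, gain_rate = 0, omega = 0.5,
                           kappa = 2, seed = 62)
  clade <- evolve_clade(anc, sc)
  seqs <- vapply(clade$genomes, function(g) g$seq[1], character(1L))
  al <- align_gene(seqs)
  expect_false(any(grepl("-", unclass(al), fixed = TRUE)))
  expect_equal(unique(nchar(unclass(al))), nchar(anc$seq[1]))
})

test_that("concatenation tiles partitions and applies taxon policies", {
  a1 <- align_gene(c(A = strrep("ACGTG", 20), B = strrep("ACGTG", 20)))
  sm1 <- concatenate(list(g1 = a1))
  expect_equal(unname(sm1$aln), unname(unclass(a1)), ignore_attr = TRUE)
  expect_equal(sm1$partitions$start, 0L)
  expect_equal(sm1$partitions$end, 100L)

  set.seed(63)
  s2 <- random_dna(250)
  a2 <- align_gene(c(A = s2, B = mutate_seq(s2, sample(250, 10)),
                     C = s2))
  sm2 <- concatenate(list(g1 = a1, g2 = a2))
  expect_equal(nchar(sm2$aln[["A"]]), 350L)
  expect_equal(sm2$partitions$end - sm2$partitions$start, c(100L, 250L))
  expect_false("C" %in% names(sm2$aln))  # absent from g1 under drop policy

  smp <- concatenate(list(g1 = a1, g2 = a2), taxon_policy = "pad-gaps")
  expect_true("C" %in% names(smp$aln))
  expect_equal(substr(smp$aln[["C"]], 1, 100), strrep("-", 100))

  a3 <- align_gene(c(D = "ACGTACGT", E = "ACGTACGT"))
  expect_error(concatenate(list(a1, a3)), "no taxon")
})

test_that("distance corrections match closed forms and flag saturation", {
  # p = 0.30 under Jukes-Cantor
  set.seed(64)
  s <- random_dna(300)
  t <- mutate_seq(s, spaced_positions(300, 90))
  al <- align_gene(c(A = s, B = t))
  D <- distance_matrix(al, model = "jc")
  expect_equal(D["A", "B"], -0.75 * log(1 - 0.4), tolerance = 1e-10)
  expect_false(attr(D, "saturated")["A", "B"])
  expect_equal(distance_matrix(al, model = "p")["A", "B"], 0.30)

  # p = 0.75 is outside the Jukes-Cantor domain (alignment built
  # directly: aligning such a pair would itself re-find similarity)
  rot <- chartr("ACGT", "CGTA", s)  # p = 1 position-wise
  al2 <- panevo:::new_alignment(c(A = s, B = rot), "nt")
  D2 <- distance_matrix(al2, model = "jc", saturation_cap = 7)
  expect_true(attr(D2, "saturated")["A", "B"])
  expect_equal(D2["A", "B"], 7)

  # identical rows are at distance zero
  al3 <- align_gene(c(A = s, B = s))
  expect_equal(distance_matrix(al3, "jc")["A", "B"], 0)
})

test_that("distances agree with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(65)
  seqs <- c(A = random_dna(400), B = NA, C = NA, D = NA)
  seqs["B"] <- mutate_seq(seqs[["A"]], sample(400, 40))
  seqs["C"] <- mutate_seq(seqs[["A"]], sample(400, 80))
  seqs["D"] <- mutate_seq(seqs[["B"]], sample(400, 60))
  al <- align_gene(seqs)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unclass(al)), "")))
  for (pair in list(c("p", "raw"), c("jc", "JC69"), c("k2p", "K80"))) {
    mine <- distance_matrix(al, model = pair[1L])
    theirs <- as.matrix(ape::dist.dna(bin, model = pair[2L],
                                      pairwise.deletion = TRUE))
    expect_equal(unclass(mine)[rownames(theirs), colnames(theirs)],
                 theirs, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("supermatrix p-distance is the column-weighted gene average", {
  set.seed(66)
  s1 <- random_dna(120); s2 <- random_dna(300)
  g1 <- align_gene(c(A = s1, B = mutate_seq(s1, sample(120, 30))))
  g2 <- align_gene(c(A = s2, B = mutate_seq(s2, sample(300, 45))))
  sm <- concatenate(list(g1 = g1, g2 = g2))
  p_all <- distance_matrix(sm, "p")["A", "B"]
  p1 <- distance_matrix(g1, "p")["A", "B"]
  p2 <- distance_matrix(g2, "p")["A", "B"]
  w1 <- nchar(g1[[1L]]); w2 <- nchar(g2[[1L]])
  expect_equal(p_all, (p1 * w1 + p2 * w2) / (w1 + w2), tolerance = 1e-10)
})

test_that("NJ solves three taxa exactly and recovers additive trees", {
  # three-point closed form
  D3 <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy3 <- nj_tree(D3)
  cd <- ape::cophenetic.phylo(phy3)
  expect_equal(cd[rownames(D3), colnames(D3)], D3, tolerance = 1e-9)

  # additive four-taxon tree with the ((A,B),(C,D)) split
  tree4 <- ape::read.tree(text = "((A:2,B:3):1.5,(C:1,D:4):2);")
  D4 <- ape::cophenetic.phylo(tree4)
  phy4 <- nj_tree(D4)
  expect_equal(phangorn::RF.dist(ape::unroot(phy4), ape::unroot(tree4)), 0)
  expect_equal(ape::cophenetic.phylo(phy4)[rownames(D4), colnames(D4)],
               D4, tolerance = 1e-9)

  # random additive 6-taxon trees: exact topology and path lengths
  set.seed(67)
  for (rep in 1:5) {
    tr <- ape::rtree(6)
    tr$edge.length <- runif(nrow(tr$edge), 0.5, 3)
    D <- ape::cophenetic.phylo(tr)
    phy <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(phy), ape::unroot(tr)), 0)
    expect_equal(ape::cophenetic.phylo(phy)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("NJ agrees with the reference implementation and roots correctly", {
  set.seed(68)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
  D <- ape::cophenetic.phylo(tr)
  noise <- matrix(runif(64, 0, 0.02), 8, 8)
  noise <- (noise + t(noise)) / 2; diag(noise) <- 0
  Dn <- D + noise
  mine <- nj_tree(Dn)
  ref <- ape::nj(as.dist(Dn))
  expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
  expect_true(all(mine$edge.length >= 0))

  rooted <- nj_tree(Dn, outgroup = "t1")
  expect_true(ape::is.rooted(rooted))
  expect_error(nj_tree(Dn, outgroup = "absent"), "not among")
})

test_that("low-divergence simulated supermatrices recover the true tree", {
  anc <- simulate_ancestor(25, 80, 0.52, seed = 69)
  true_tr <- ape::read.tree(text = paste0(
    "(((A:0.02,B:0.02):0.02,(C:0.02,D:0.02):0.02):0.01,",
    "((E:0.02,F:0.02):0.02,G:0.04):0.01);"))
  sc <- evolution_scenario(true_tr, loss_prob = 0, gain_rate = 0,
                           omega = 0.3, kappa = 2, seed = 70)
  sim <- evolve_clade(anc, sc)
  alns <- lapply(seq_len(nrow(anc)), function(i) {
    align_gene(vapply(sim$genomes, function(g) g$seq[i], character(1L)))
  })
  sm <- concatenate(alns)
  phy <- nj_tree(distance_matrix(sm, "jc"))
  expect_equal(phangorn::RF.dist(ape::unroot(phy), ape::unroot(true_tr)), 0)
})

test_that("bootstrap supports behave at the signal extremes", {
  anc <- simulate_ancestor(20, 80, 0.52, seed = 71)
  tr <- ape::read.tree(
    text = "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):0.02,(E:0.1,F:0.1):0.02);")
  sc <- evolution_scenario(tr, loss_prob = 0, gain_rate = 0, omega = 0.3,
                           kappa = 2, seed = 72)
  sim <- evolve_clade(anc, sc)
  alns <- lapply(seq_len(nrow(anc)), function(i) {
    align_gene(vapply(sim$genomes, function(g) g$seq[i], character(1L)))
  })
  sm <- concatenate(alns)
  bs <- bootstrap_support(sm, n_reps = 30, model = "jc", seed = 5)
  sup <- as.numeric(bs$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  expect_gt(mean(sup), 60)  # strong signal

  one <- bootstrap_support(sm, n_reps = 1, model = "jc", seed = 6)
  expect_true(all(as.numeric(one$node.label) %in% c(0, 100)))

  # deterministic given the seed
  again <- bootstrap_support(sm, n_reps = 30, model = "jc", seed = 5)
  expect_identical(bs$node.label, again$node.label)
})
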