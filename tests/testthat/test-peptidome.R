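test_that("tryptic digestion honours cleavage, proline and missed-cleavage rules", {
  p0 <- digest_params(max_missed_cleavages = 0, min_length = 5)
  expect_setequal(digest("AAGGGKGGGGGRCCCCC", p0),
                  c("AAGGGK", "GGGGGR", "CCCCC"))
  expect_equal(digest("AAGGGKPGGGGR", digest_params(min_length = 5)),
               "AAGGGKPGGGGR")
  # missed cleavages are enumerated, length window applied
  p2 <- digest_params(max_missed_cleavages = 2, min_length = 5, max_length = 35)
  expect_true("AAGGGKGGGGGR" %in% digest("AAGGGKGGGGGRCCCCC", p2))
  expect_error(digest("AABZ9", p0), "illegal character")
  expect_error(digest_params(max_missed_cleavages = 9), "0..5")
  expect_error(digest_params(min_length = 3), ">= 5")
})

test_that("digestion agrees with a position-scanning oracle on random proteins", {
  set.seed(11)
  params <- digest_params()
  for (i in 1:30) {
    seq <- random_protein_seq(sample(50:300, 1))
    expect_setequal(digest(seq, params),
                    oracle_digest(seq, 2, 7, 35))
    # duplicates per site preserved: counts must match too
    expect_equal(sort(digest(seq, params)),
                 sort(oracle_digest(seq, 2, 7, 35)))
  }
})

test_that("peptide masses match an independent residue-mass summation", {
  params <- digest_params()
  expect_equal(peptide_mass("GGGGG", params), oracle_mass("GGGGG"),
               tolerance = 1e-9)
  set.seed(12)
  for (i in 1:20) {
    pep <- random_protein_seq(sample(6:20, 1))
    n_ox <- sample(0:sum(strsplit(pep, "")[[1]] == "M"), 1)
    expect_equal(peptide_mass(pep, params, n_ox), oracle_mass(pep, n_ox),
                 tolerance = 1e-9)
  }
  # fixed carbamidomethyl adds exactly its shift per cysteine
  expect_equal(peptide_mass("ACDEK", params) - peptide_mass("ADEK", params),
               103.00919 + 57.02146, tolerance = 1e-9)
  # oxidation requires a methionine
  expect_error(peptide_mass("ACDEK", params, n_oxidations = 1), "methionine")
  expect_error(peptide_mass("ACDEB", params), "residue without a mass")
})

test_that("index maps shared and unique peptides to the right organisms", {
  tree <- tiny_tree()
  prot <- data.table::data.table(
    accession = c("a1", "a2", "b1"),
    organism_id = c("s1", "s2", "s2"),
    sequence = c("MAAAGGGKCCCDDDR", "MAAAGGGKCCCDDDR", "WWWYYYKFFFHHHR"))
  idx <- build_index(prot, digest_params(min_length = 5), tree)
  expect_setequal(organisms_of_peptide(idx, "MAAAGGGK"), c("s1", "s2"))
  expect_equal(organisms_of_peptide(idx, "WWWYYYK"), "s2")
  expect_error(organisms_of_peptide(idx, "NOTTHERE"), "not in index")
  expect_error(build_index(prot[0], digest_params()), "empty")
})

test_that("I/L equivalence folds mass-indistinguishable peptides onto one key", {
  tree <- tiny_tree()
  prot <- data.table::data.table(
    accession = c("a", "b"), organism_id = c("s1", "s2"),
    sequence = c("GGGGLKAAAAAR", "GGGGIKAAAAAR"))
  idx <- build_index(prot, digest_params(min_length = 5), tree)
  expect_setequal(organisms_of_peptide(idx, "GGGGLK"), c("s1", "s2"))
  expect_false("GGGGIK" %in% idx$peptide)
  idx_raw <- build_index(prot, digest_params(min_length = 5,
                                             il_equivalent = FALSE), tree)
  expect_equal(organisms_of_peptide(idx_raw, "GGGGIK"), "s2")
})

test_that("index equals brute-force reconstruction on random instances", {
  set.seed(13)
  tree <- tiny_tree()
  for (rep in 1:3) {
    n <- sample(20:50, 1)
    prot <- data.table::data.table(
      accession = sprintf("p%02d", 1:n),
      organism_id = sample(c("s1", "s2", "s3", "s4"), n, replace = TRUE),
      sequence = vapply(sample(60:200, n, TRUE), random_protein_seq,
                        character(1)))
    idx <- build_index(prot, digest_params(), tree)
    oracle <- oracle_index(prot)
    expect_setequal(idx$peptide, ls(oracle))
    for (p in sample(ls(oracle), min(50, length(ls(oracle)))))
      expect_setequal(organisms_of_peptide(idx, p), get(p, oracle))
  }
})

test_that("species dereplication keeps one deterministic representative", {
  nodes <- rbind(tiny_nodes(), data.table::data.table(
    taxon_id = c("o1a", "o1b", "o2a"),
    name = c("strainA", "strainB", "strainC"),
    rank = "organism", parent_id = c("s1", "s1", "s2")))
  tree <- taxonomy_tree(nodes)
  prot <- data.table::data.table(
    accession = c("x", "y", "z"),
    organism_id = c("o1a", "o1b", "o2a"),
    sequence = rep("MAAAGGGKCCCDDDR", 3))
  out <- dereplicate_per_species(prot, tree)
  expect_setequal(unique(out$organism_id), c("o1a", "o2a"))
  expect_equal(dereplicate_per_species(out, tree), out)  # idempotent

  ref <- simulate_reference(sim_params(seed = 14, proteins_per_species = 2,
                                       protein_length = 80))
  derep <- dereplicate_per_species(ref$proteins, ref$tree)
  n_species <- sum(ref$tree$nodes$rank == "species")
  expect_equal(length(unique(derep$organism_id)), n_species)
})

test_that("peptide rank specificity escalates with rank and matches lca brute force", {
  tree <- tiny_tree()
  prot <- data.table::data.table(
    accession = c("a", "b", "c"),
    organism_id = c("s1", "s3", "s4"),
    sequence = c("MAAAGGGKDDDEEER", "MAAAGGGKWWWYYYR", "HHHFFFKPPPSSSR"))
  idx <- build_index(prot, digest_params(min_length = 5), tree)
  # peptide in s1 only: specific at every rank
  expect_equal(nrow(taxa_of_peptide(idx, tree, "DDDEEER", "species")), 1)
  expect_equal(taxa_of_peptide(idx, tree, "DDDEEER", "genus")$taxon_id, "g1")
  # peptide in two genera of one family: escalates to family
  expect_equal(nrow(taxa_of_peptide(idx, tree, "MAAAGGGK", "genus")), 2)
  expect_equal(taxa_of_peptide(idx, tree, "MAAAGGGK", "family")$taxon_id, "f1")

  ref <- simulate_reference(sim_params(seed = 15, proteins_per_species = 3,
                                       protein_length = 100))
  idx2 <- build_index(ref$proteins, digest_params(), ref$tree)
  peps <- unique(idx2$peptide)
  for (p in sample(peps, min(200, length(peps)))) {
    rk <- sample(canonical_ranks(), 1)
    expect_setequal(
      taxa_of_peptide(idx2, ref$tree, p, rk)$taxon_id,
      lca_rank_set(ref$tree, organisms_of_peptide(idx2, p), rk)$taxon_id)
  }
})

test_that("specificity is monotone in rank and organism spePEPs are disjoint", {
  ref <- simulate_reference(sim_params(seed = 16, proteins_per_species = 5,
                                       protein_length = 120))
  idx <- build_index(ref$proteins, digest_params(), ref$tree)
  peps <- unique(idx$peptide)
  set.seed(3)
  rks <- canonical_ranks()
  for (p in sample(peps, 150)) {
    n_taxa <- vapply(rks, function(r)
      nrow(taxa_of_peptide(idx, ref$tree, p, r)), integer(1))
    # number of distinct ancestors can only grow with depth
    expect_true(all(diff(n_taxa) >= 0))
  }
  # organism-level specific peptides are disjoint across organisms by
  # construction: each maps to exactly one organism
  counts <- idx[, .N, by = peptide]
  solo <- counts[N == 1L, peptide]
  expect_equal(anyDuplicated(idx[peptide %in% solo, peptide]), 0)
})

test_that("index serialization round-trips and FASTA IO preserves records", {
  ref <- simulate_reference(sim_params(seed = 17, proteins_per_species = 2,
                                       protein_length = 80))
  idx <- build_index(ref$proteins, digest_params(), ref$tree)
  tmp <- tempfile(fileext = ".tsv")
  write_index(idx, tmp)
  idx2 <- read_index(tmp)
  expect_equal(data.table::setkey(data.table::as.data.table(idx2), peptide, organism_id),
               data.table::setkey(data.table::as.data.table(idx), peptide, organism_id))

  fa <- tempfile(fileext = ".fasta")
  write_proteins(ref$proteins, fa)
  back <- read_proteins(fa)
  expect_equal(back, ref$proteins)
})
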