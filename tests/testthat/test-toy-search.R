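make_cand <- function(peptides, params = digest_params()) {
  data.table::data.table(peptide = peptides, n_ox = 0L,
                         mass = peptide_mass(peptides, params))[order(mass)]
}

test_that("a spectrum of a peptide's own fragments matches that peptide", {
  params <- digest_params()
  pep <- "SAMPLEPEPTLDEK"
  s <- peptide_spectrum(pep, "s1", charge = 2L, params = params)
  cand <- make_cand(c(pep, "WWWWWWWWK", "GGGGGGGGGGR"))
  hit <- match_spectrum(s, cand, precursor_tol_ppm = 5,
                        fragment_tol_da = 0.02, params = params)
  expect_equal(hit$peptide, pep)
  expect_equal(hit$n_matched_fragments, 2 * (nchar(pep) - 1))
  expect_lt(hit$p_value, 0.05)
})

test_that("fragments outside the tolerance are not counted", {
  params <- digest_params()
  pep <- "SAMPLEPEPTLDEK"
  mz <- fragment_mz(pep, params)
  peaks <- cbind(mz, 1)
  peaks[1, 1] <- peaks[1, 1] + 0.05   # displace one fragment by 0.05 Da
  s <- spectrum("s1", peptide_mass(pep, params) / 2 + 1.007276466879, 2L, peaks)
  cand <- make_cand(pep)
  hit <- match_spectrum(s, cand, 5, 0.02, params)
  expect_equal(hit$n_matched_fragments, 2 * (nchar(pep) - 1) - 1)
})

test_that("empty candidate sets yield no PSM, not an error", {
  s <- peptide_spectrum("GGGGGGGGGGR", "s1")
  cand <- make_cand("WWWWWWWWWWK")  # far away in mass
  expect_null(match_spectrum(s, cand, 5, 0.02))
})

test_that("tightening tolerances never increases matched fragments", {
  params <- digest_params()
  set.seed(21)
  pep <- "ELVLSPADKTNVK"
  mz <- fragment_mz(pep, params) + runif(24, -0.03, 0.03)
  s <- spectrum("s1", peptide_mass(pep, params) / 2 + 1.007276466879, 2L,
                cbind(mz, 1))
  cand <- make_cand(pep)
  tols <- c(0.05, 0.02, 0.01, 0.005)
  k <- vapply(tols, function(t)
    match_spectrum(s, cand, 50, t, params)$n_matched_fragments, integer(1))
  expect_true(all(diff(k) <= 0))
})

test_that("the p-value decreases as more fragments match, at fixed peak count", {
  # direct property of the binomial tail used by the scorer
  p <- vapply(0:20, function(k) pbinom(k - 1, 20, 0.01, lower.tail = FALSE),
              numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("random-spectrum p-values are calibrated against the binomial null", {
  params <- digest_params()
  set.seed(22)
  # candidates with well-separated masses: exactly one survives the filter
  peps <- unique(replicate(30, random_protein_seq(sample(9:14, 1))))
  peps <- peps[!grepl("X", peps)]
  cand <- make_cand(peps, params)
  cand <- cand[c(TRUE, diff(mass) > 1)]  # enforce >1 Da separation

  n_spec <- 1000
  m_peaks <- 60
  lo <- 50; hi <- 2000
  obs <- logical(n_spec)
  expd <- numeric(n_spec)
  q_true <- 1 - (1 - 2 * 0.02 / (hi - lo))^m_peaks
  for (i in seq_len(n_spec)) {
    tgt <- cand[sample(.N, 1)]
    peak_mz <- sort(runif(m_peaks, lo, hi))
    s <- spectrum(paste0("r", i), tgt$mass / 2 + 1.007276466879, 2L,
                  cbind(peak_mz, 1))
    hit <- match_spectrum(s, cand, 5, 0.02, params)
    obs[i] <- !is.null(hit) && hit$p_value < 0.05
    # expected P(p < 0.05) under the null: find the smallest k whose
    # binomial tail (as the scorer computes it) is below 0.05, then the
    # chance of >= k uniform-peak matches
    n_frag <- 2 * (nchar(tgt$peptide) - 1)
    span <- max(peak_mz) - min(peak_mz)
    p0_est <- 2 * 0.02 * m_peaks / span
    tails <- pbinom((0:n_frag) - 1, n_frag, p0_est, lower.tail = FALSE)
    kstar <- which(tails < 0.05)[1] - 1L
    expd[i] <- pbinom(kstar - 1, n_frag, q_true, lower.tail = FALSE)
  }
  expect_lt(abs(mean(obs) - mean(expd)), 0.02)
})

test_that("batch search equals the per-spectrum loop and is deterministic", {
  params <- digest_params()
  ref <- simulate_reference(sim_params(seed = 23, proteins_per_species = 3,
                                       protein_length = 150))
  idx <- build_index(ref$proteins, params, ref$tree)
  iso <- simulate_isolate(ref, sim_params(seed = 23, proteins_per_species = 3,
                                          protein_length = 150,
                                          spectra_per_isolate = 60,
                                          noise_fraction = 0.2),
                          output = "spectra")
  cand <- candidate_table(idx, params)
  batch <- search_batch(iso$spectra, idx, 5, 0.02, candidates = cand,
                        params = params)
  loop <- data.table::rbindlist(Filter(Negate(is.null),
    lapply(iso$spectra, match_spectrum, candidates = cand,
           precursor_tol_ppm = 5, fragment_tol_da = 0.02, params = params)))
  expect_equal(batch, loop)
  batch2 <- search_batch(iso$spectra, idx, 5, 0.02, candidates = cand,
                         params = params)
  expect_identical(batch, batch2)

  expect_equal(nrow(search_batch(list(), idx)), 0)
  dup <- iso$spectra[c(1, 1)]
  expect_error(search_batch(dup, idx), "duplicate spectrum_id")
})

test_that("spectra from a known organism are mostly assigned to its proteome", {
  params <- digest_params()
  p <- sim_params(seed = 24, proteins_per_species = 15, protein_length = 150,
                  spectra_per_isolate = 150, noise_fraction = 0.15)
  ref <- simulate_reference(p)
  iso <- simulate_isolate(ref, p, output = "spectra")
  target <- iso$truth$target_organism
  idx <- build_index(ref$proteins, params, ref$tree)
  psms <- search_batch(iso$spectra, idx, 5, 0.02, params = params)
  target_peps <- unique(idx[idx$organism_id == target]$peptide)
  signal_ids <- iso$truth$sources[noise == FALSE, spectrum_id]
  assigned <- psms[psms$spectrum_id %in% signal_ids]
  expect_gte(nrow(assigned) / length(signal_ids), 0.9)
  expect_gte(mean(assigned$peptide %in% target_peps), 0.9)
})

test_that("MGF files round-trip through the reader and writer", {
  s1 <- peptide_spectrum("SAMPLEPEPTLDEK", "scan=1", 2L)
  s2 <- peptide_spectrum("ELVLSPADKTNVK", "scan=2", 3L)
  tmp <- tempfile(fileext = ".mgf")
  write_mgf(list(s1, s2), tmp)
  back <- read_mgf(tmp)
  expect_length(back, 2)
  expect_equal(back[[1]]$spectrum_id, "scan=1")
  expect_equal(back[[2]]$charge, 3L)
  expect_equal(back[[1]]$precursor_mz, s1$precursor_mz, tolerance = 1e-9)
  expect_equal(back[[2]]$peaks[, "mz"], s2$peaks[, "mz"], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PSM tables round-trip through TSV", {
  psms <- data.table::data.table(
    spectrum_id = c("a", "b"), peptide = c("PEPTLDEK", "SAMPLER"),
    charge = c(2L, 3L), p_value = c(0.01, 0.2), step = c(3L, 3L))
  tmp <- tempfile(fileext = ".tsv")
  write_psms(psms, tmp)
  expect_equal(read_psms(tmp), psms)
  bad <- tempfile(fileext = ".tsv")
  writeLines("a\tb", bad)
  expect_error(read_psms(bad), "columns")
})
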