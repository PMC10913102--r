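# Seeded simulator: reference taxonomies and proteomes whose tryptic-peptide
# sharing decays with phylogenetic distance, plus isolate peptidomes with a
# skewed abundance profile, noise spectra and novel-taxon scenarios. This is
# the test bed standing in for real deposited raw data.

# Approximate Swiss-Prot amino-acid frequencies; gives realistic tryptic
# site density (K+R ~ 11%) and hence realistic peptide lengths.
AA_FREQ <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
             E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
             M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
             Y = 2.92, V = 6.87) / 100

#' Simulation parameters
#'
#' Defaults describe a desk-scale cohort: 2 families x 3 genera x 3 species,
#' 200 proteins of mean length 300 per species, per-residue substitution
#' rates increasing with phylogenetic depth (0.02 within genus, 0.08 between
#' genera, 0.15 between families), 10,000 spectra per isolate of which 60%
#' are noise (so roughly 40% of recorded spectra yield PSMs, as in typical
#' isolate runs), and a power-law abundance skew over proteins.
#'
#' @param seed integer seed; all randomness flows through it.
#' @param n_families,genera_per_family,species_per_genus taxonomy shape.
#' @param proteins_per_species proteins per organism (default 200).
#' @param protein_length mean protein length in residues (default 300).
#' @param rate_within_genus,rate_between_genera,rate_between_families
#'   per-residue substitution rates applied along the corresponding branches.
#' @param scenario `"known_species"`, `"novel_species"` or `"novel_genus"`.
#' @param spectra_per_isolate recorded MS/MS spectra per isolate.
#' @param noise_fraction fraction of spectra drawn from decoy peptides.
#' @param abundance_skew power-law exponent for per-protein spectral counts.
#' @return a `sim_params` list.
#' @export
sim_params <- function(seed = 1L, n_families = 2L, genera_per_family = 3L,
                       species_per_genus = 3L, proteins_per_species = 200L,
                       protein_length = 300L, rate_within_genus = 0.02,
                       rate_between_genera = 0.08,
                       rate_between_families = 0.15,
                       scenario = c("known_species", "novel_species",
                                    "novel_genus"),
                       spectra_per_isolate = 10000L, noise_fraction = 0.6,
                       abundance_skew = 1.5) {
  scenario <- match.arg(scenario)
  rates <- c(rate_within_genus, rate_between_genera, rate_between_families)
  if (any(rates < 0 | rates >= 1)) stop_input("rates must be in [0, 1)")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop_input("noise_fraction must be in [0, 1)")
  if (min(n_families, genera_per_family, species_per_genus,
          proteins_per_species) < 1L)
    stop_input("taxonomy and proteome counts must be >= 1")
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 proteins_per_species = as.integer(proteins_per_species),
                 protein_length = as.integer(protein_length),
                 rate_within_genus = rate_within_genus,
                 rate_between_genera = rate_between_genera,
                 rate_between_families = rate_between_families,
                 scenario = scenario,
                 spectra_per_isolate = as.integer(spectra_per_isolate),
                 noise_fraction = noise_fraction,
                 abundance_skew = abundance_skew),
            class = "sim_params")
}

.random_protein <- function(len) {
  paste(sample(names(AA_FREQ), len, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

.mutate_seqs <- function(seqs, rate) {
  if (rate == 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    k <- stats::rbinom(1L, n, rate)
    if (k > 0L) {
      pos <- sample.int(n, k)
      ch[pos] <- sample(names(AA_FREQ), k, replace = TRUE, prob = AA_FREQ)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a reference taxonomy and its proteomes
#'
#' Ancestral proteins are mutated down a fixed-shape tree (family, genus,
#' species branches at the configured rates), so the fraction of shared
#' tryptic peptides between two organisms decays with their phylogenetic
#' distance. Deterministic for a given seed.
#'
#' @param params a [sim_params()] object.
#' @return a `sim_reference`: list with the `taxonomy_tree`, the protein
#'   table, the ancestral proteomes per family and genus (used for
#'   novel-taxon isolates) and the parameters.
#' @export
simulate_reference <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)

  nodes <- list(data.table::data.table(
    taxon_id = c("sk:Bacteria", "ph:P1", "cl:C1", "or:O1"),
    name = c("Bacteria", "Simulophyla", "Simulia", "Simulales"),
    rank = c("superkingdom", "phylum", "class", "order"),
    parent_id = c("-", "sk:Bacteria", "ph:P1", "cl:C1")))

  lens <- pmax(60L, round(stats::rnorm(params$proteins_per_species,
                                       params$protein_length,
                                       0.2 * params$protein_length)))
  root_prot <- vapply(lens, .random_protein, character(1))

  fam_anc <- list()
  gen_anc <- list()
  prot_rows <- list()
  for (f in seq_len(params$n_families)) {
    fid <- sprintf("fam:F%d", f)
    nodes[[length(nodes) + 1L]] <- data.table::data.table(
      taxon_id = fid, name = sprintf("Famibacteraceae%d", f),
      rank = "family", parent_id = "or:O1")
    fam_anc[[fid]] <- .mutate_seqs(root_prot, params$rate_between_families)
    for (g in seq_len(params$genera_per_family)) {
      gid <- sprintf("gen:F%dG%d", f, g)
      nodes[[length(nodes) + 1L]] <- data.table::data.table(
        taxon_id = gid, name = sprintf("Genusium%d_%d", f, g),
        rank = "genus", parent_id = fid)
      gen_anc[[gid]] <- .mutate_seqs(fam_anc[[fid]],
                                     params$rate_between_genera)
      for (s in seq_len(params$species_per_genus)) {
        sid <- sprintf("sp:F%dG%dS%d", f, g, s)
        oid <- sprintf("org:F%dG%dS%d", f, g, s)
        spname <- sprintf("Genusium%d_%d speciens%d", f, g, s)
        nodes[[length(nodes) + 1L]] <- data.table::data.table(
          taxon_id = c(sid, oid),
          name = c(spname, paste0(spname, " T1")),
          rank = c("species", "organism"), parent_id = c(gid, sid))
        seqs <- .mutate_seqs(gen_anc[[gid]], params$rate_within_genus)
        prot_rows[[length(prot_rows) + 1L]] <- data.table::data.table(
          accession = sprintf("%s_p%04d", oid, seq_along(seqs)),
          organism_id = oid, sequence = seqs)
      }
    }
  }
  tree <- taxonomy_tree(data.table::rbindlist(nodes))
  structure(list(tree = tree,
                 proteins = data.table::rbindlist(prot_rows),
                 family_ancestors = fam_anc, genus_ancestors = gen_anc,
                 params = params),
            class = "sim_reference")
}

.decoy_peptide <- function(template) {
  ch <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(ch)
  body <- sample(names(AA_FREQ), n - 1L, replace = TRUE, prob = AA_FREQ)
  paste(c(body, if (ch[n] %in% c("K", "R")) ch[n] else "K"), collapse = "")
}

#' Simulate an isolate peptidome
#'
#' Draws per-spectrum source peptides from an isolate proteome. Scenarios:
#' `known_species` samples an organism present in the reference;
#' `novel_species` evolves a fresh sister branch inside one genus (at the
#' within-genus rate); `novel_genus` evolves a fresh branch mixing the
#' proteomes of two genera of one family (at the between-genera rate), so
#' its peptidome carries specific material of several database genera but of
#' no single species. Spectral counts follow the configured power-law skew
#' over proteins, and a `noise_fraction` of spectra receive decoy peptides.
#'
#' @param reference a [simulate_reference()] result.
#' @param params a [sim_params()] object (defaults to the reference's, with
#'   its scenario field selecting the truth structure).
#' @param output `"psms"` for a PSM table with simulated validation
#'   p-values, or `"spectra"` for `spectrum` objects built from the source
#'   peptides' b/y ions (use small `spectra_per_isolate` in that mode).
#' @param digest a [digest_params()] object used to digest the isolate.
#' @return list with `psms` (or `spectra`), and `truth` (scenario, target
#'   organism or nearest relatives, per-spectrum source table).
#' @export
simulate_isolate <- function(reference, params = reference$params,
                             output = c("psms", "spectra"),
                             digest = digest_params()) {
  stopifnot(inherits(reference, "sim_reference"),
            inherits(params, "sim_params"))
  output <- match.arg(output)
  set.seed(params$seed %% 999999937L + 104729L)

  tree <- reference$tree
  if (params$scenario == "novel_genus" && params$genera_per_family < 2L)
    stop_input("novel_genus scenario needs >= 2 genera per family")

  if (params$scenario == "known_species") {
    target <- sample(tree$organism_ids, 1L)
    iso_prot <- reference$proteins[organism_id == target, sequence]
    relatives <- target
  } else if (params$scenario == "novel_species") {
    gid <- sample(names(reference$genus_ancestors), 1L)
    iso_prot <- .mutate_seqs(reference$genus_ancestors[[gid]],
                             params$rate_within_genus)
    target <- NA_character_
    relatives <- gid
  } else {
    fams <- split(names(reference$genus_ancestors),
                  sub("G[0-9]+$", "", names(reference$genus_ancestors)))
    fams <- fams[lengths(fams) >= 2L]
    pick <- sample(names(fams), 1L)
    gids <- sample(fams[[pick]], 2L)
    mix <- ifelse(stats::runif(length(reference$genus_ancestors[[gids[1]]])) < 0.5,
                  reference$genus_ancestors[[gids[1]]],
                  reference$genus_ancestors[[gids[2]]])
    iso_prot <- .mutate_seqs(mix, params$rate_between_genera)
    target <- NA_character_
    relatives <- gids
  }

  pep_by_prot <- lapply(iso_prot, digest, params = digest)
  has_pep <- lengths(pep_by_prot) > 0L
  pep_by_prot <- pep_by_prot[has_pep]
  np <- length(pep_by_prot)
  if (!np) stop_input("isolate proteome produced no peptides")

  w <- sample(seq_len(np))^(-params$abundance_skew)
  n <- params$spectra_per_isolate
  prot_idx <- sample.int(np, n, replace = TRUE, prob = w / sum(w))
  src_pep <- vapply(prot_idx, function(i) {
    p <- pep_by_prot[[i]]
    p[[sample.int(length(p), 1L)]]
  }, character(1))
  is_noise <- stats::runif(n) < params$noise_fraction
  src_pep[is_noise] <- vapply(src_pep[is_noise], .decoy_peptide, character(1))
  charge <- sample(c(2L, 3L), n, replace = TRUE)
  p_value <- ifelse(is_noise, stats::runif(n, 0.3, 1),
                    ifelse(stats::runif(n) < 0.9,
                           stats::runif(n, 0, 0.05),
                           stats::runif(n, 0.05, 0.3)))
  spectrum_id <- sprintf("spec%06d", seq_len(n))
  truth <- list(scenario = params$scenario, target_organism = target,
                relatives = relatives,
                sources = data.table::data.table(
                  spectrum_id = spectrum_id, peptide = src_pep,
                  noise = is_noise))
  if (output == "psms") {
    list(psms = data.table::data.table(
           spectrum_id = spectrum_id, peptide = src_pep, charge = charge,
           p_value = p_value, step = NA_integer_),
         truth = truth)
  } else {
    spectra <- lapply(seq_len(n), function(i)
      peptide_spectrum(src_pep[[i]], spectrum_id[[i]], charge[[i]], digest))
    list(spectra = spectra, truth = truth)
  }
}

#' Write a canonical fixture suite
#'
#' Generates a small, fully deterministic set of files exercising every
#' reader in the package: taxonomy TSV, protein FASTA, isolate PSM TSV, a
#' small MGF, a marker identity TSV, a truth table and a manifest recording
#' the parameters.
#'
#' @param out_dir writable output directory (created if missing).
#' @param params a [sim_params()] object; the default is a reduced cohort
#'   sized for test suites.
#' @param n_mgf_spectra number of spectra materialised into the MGF file.
#' @return named character vector of the files written.
#' @export
make_fixture_suite <- function(out_dir,
                               params = sim_params(
                                 seed = 42L, proteins_per_species = 30L,
                                 protein_length = 200L,
                                 spectra_per_isolate = 600L,
                                 noise_fraction = 0.2),
                               n_mgf_spectra = 25L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(params)
  iso <- simulate_isolate(ref, params)
  files <- c(taxonomy = file.path(out_dir, "taxonomy.tsv"),
             proteins = file.path(out_dir, "proteins.fasta"),
             psms = file.path(out_dir, "isolate_psms.tsv"),
             mgf = file.path(out_dir, "isolate.mgf"),
             identities = file.path(out_dir, "identities.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             manifest = file.path(out_dir, "manifest.yaml"))
  write_taxonomy(ref$tree, files[["taxonomy"]])
  write_proteins(ref$proteins, files[["proteins"]])
  write_psms(iso$psms, files[["psms"]])
  signal <- iso$truth$sources[noise == FALSE]
  take <- head(seq_len(nrow(signal)), n_mgf_spectra)
  spectra <- lapply(take, function(i)
    peptide_spectrum(signal$peptide[[i]], signal$spectrum_id[[i]], 2L))
  write_mgf(spectra, files[["mgf"]])
  data.table::fwrite(data.table::data.table(
    sample_id = c("iso1", "iso2", "iso3"),
    best_hit = c("Genusium1_1 speciens1", "Genusium1_2 speciens1",
                 "Genusium2_1 speciens2"),
    identity = c(99.4, 97.2, 94.3)), files[["identities"]], sep = "\t")
  data.table::fwrite(iso$truth$sources, files[["truth"]], sep = "\t")
  yaml::write_yaml(c(unclass(params),
                     list(target_organism = iso$truth$target_organism)),
                   files[["manifest"]])
  files
}
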