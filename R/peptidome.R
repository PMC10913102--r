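# In silico tryptic digestion of reference proteomes and the
# peptide -> organism index behind TSM and spePEP accounting.

# Monoisotopic residue masses (Da), 20 canonical amino acids.
MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
MASS_WATER <- 18.0105646863
MASS_PROTON <- 1.007276466879
MOD_CARBAMIDOMETHYL <- 57.02146
MOD_OXIDATION <- 15.99491
AA_ALPHABET <- c(names(MONO_RESIDUE), "X")

#' Digestion and modification parameters
#'
#' Parameters of the in silico tryptic digestion and of peptide mass
#' computation: cleavage after K/R except before P, up to
#' `max_missed_cleavages` internal missed sites, peptide length bounds,
#' carbamidomethylation of cysteine as fixed modification (+57.02146 Da),
#' oxidation of methionine as variable modification (+15.99491 Da).
#' `il_equivalent` folds isoleucine onto leucine in peptide keys, reflecting
#' their identical mass in MS/MS.
#'
#' @param max_missed_cleavages integer, 0 to 5 (default 2).
#' @param min_length minimum peptide length in residues (>= 5; default 7).
#' @param max_length maximum peptide length (default 35).
#' @param il_equivalent fold I onto L in peptide keys (default `TRUE`).
#' @return a `digest_params` list.
#' @export
#' @examples
#' digest("AAGGGKGGGGGRCCCCC", digest_params(max_missed_cleavages = 0,
#'                                           min_length = 5))
digest_params <- function(max_missed_cleavages = 2L, min_length = 7L,
                          max_length = 35L, il_equivalent = TRUE) {
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  if (max_missed_cleavages < 0L || max_missed_cleavages > 5L)
    stop_input("max_missed_cleavages must be in 0..5")
  if (min_length < 5L) stop_input("min_length must be >= 5")
  if (max_length < min_length) stop_input("max_length < min_length")
  structure(list(
    enzyme = "trypsin",
    max_missed_cleavages = max_missed_cleavages,
    min_length = as.integer(min_length),
    max_length = as.integer(max_length),
    fixed_mods = c(C = MOD_CARBAMIDOMETHYL),
    variable_mods = c(M = MOD_OXIDATION),
    il_equivalent = isTRUE(il_equivalent)),
    class = "digest_params")
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop_input("sequence must be a single non-empty string")
  if (grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence))
    stop_input("illegal character in sequence: ", sequence)
}

#' Tryptic digest of one protein sequence
#'
#' Cleaves after K or R except when the next residue is P, produces all
#' products with 0..`max_missed_cleavages` internal missed sites and filters
#' them to the configured length window. Duplicated sequences arising from
#' different sites are preserved (they are unified downstream by
#' [peptide_key()]).
#'
#' @param sequence protein sequence (20 canonical letters plus X).
#' @param params a [digest_params()] object.
#' @return character vector of peptides in N- to C-terminal order.
#' @export
digest <- function(sequence, params = digest_params()) {
  .check_sequence(sequence)
  stopifnot(inherits(params, "digest_params"))
  n <- nchar(sequence)
  m <- gregexpr("[KR](?!P)", sequence, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer() else as.integer(m)
  bounds <- c(0L, cuts[cuts < n], n)   # fragment i spans bounds[i]+1..bounds[i+1]
  nf <- length(bounds) - 1L
  out <- character()
  for (i in seq_len(nf)) {
    jmax <- min(nf, i + params$max_missed_cleavages)
    for (j in i:jmax) {
      len <- bounds[j + 1L] - bounds[i]
      if (len >= params$min_length && len <= params$max_length)
        out <- c(out, substr(sequence, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  out
}

#' Canonical peptide key
#'
#' Peptide keys are bare sequences; modifications change mass only. With
#' `il_equivalent` the mass-indistinguishable I is folded onto L.
#'
#' @param peptides character vector of peptide sequences.
#' @param params a [digest_params()] object.
#' @return character vector of keys.
#' @export
peptide_key <- function(peptides, params = digest_params()) {
  if (params$il_equivalent) chartr("I", "L", peptides) else peptides
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus water, plus the fixed
#' carbamidomethyl shift for every cysteine and `n_oxidations` times the
#' oxidation shift (each oxidation requires a methionine).
#'
#' @param peptides character vector of peptide sequences (no X).
#' @param params a [digest_params()] object.
#' @param n_oxidations integer vector (recycled), number of oxidised M.
#' @return numeric vector of neutral monoisotopic masses in Da.
#' @export
peptide_mass <- function(peptides, params = digest_params(), n_oxidations = 0L) {
  n_oxidations <- rep_len(as.integer(n_oxidations), length(peptides))
  chars <- strsplit(peptides, "", fixed = TRUE)
  vapply(seq_along(peptides), function(i) {
    ch <- chars[[i]]
    if (!length(ch)) stop_input("empty peptide")
    m <- MONO_RESIDUE[ch]
    if (anyNA(m))
      stop_input("residue without a mass in peptide: ", peptides[[i]])
    n_m <- sum(ch == "M")
    if (n_oxidations[[i]] > n_m)
      stop_input("n_oxidations exceeds methionine count in ", peptides[[i]])
    if (n_oxidations[[i]] < 0L) stop_input("n_oxidations must be >= 0")
    sum(m) + MASS_WATER +
      MOD_CARBAMIDOMETHYL * sum(ch == "C") +
      MOD_OXIDATION * n_oxidations[[i]]
  }, numeric(1))
}

.check_proteins <- function(proteins, tree = NULL) {
  proteins <- data.table::as.data.table(proteins)
  need <- c("accession", "organism_id", "sequence")
  if (!all(need %in% names(proteins)))
    stop_input("proteins need columns: ", paste(need, collapse = ", "))
  if (!nrow(proteins)) stop_input("empty protein list")
  if (any(!nzchar(proteins$sequence))) stop_input("empty protein sequence")
  if (!is.null(tree)) .check_organisms(tree, unique(proteins$organism_id))
  proteins
}

#' Build the peptide-to-organism index
#'
#' Digests every protein and records, for each peptide key, the set of
#' organisms whose proteome contains it. The index is a pure function of the
#' protein list and digestion parameters.
#'
#' @param proteins data.frame with columns `accession`, `organism_id`,
#'   `sequence`.
#' @param params a [digest_params()] object.
#' @param tree optional `taxonomy_tree` used to validate organism ids.
#' @return a `peptide_index`: keyed data.table of unique
#'   (`peptide`, `organism_id`) pairs, with the digestion parameters attached.
#' @export
build_index <- function(proteins, params = digest_params(), tree = NULL) {
  proteins <- .check_proteins(proteins, tree)
  pieces <- lapply(seq_len(nrow(proteins)), function(i) {
    pep <- digest(proteins$sequence[[i]], params)
    if (!length(pep)) return(NULL)
    data.table::data.table(peptide = peptide_key(pep, params),
                           organism_id = proteins$organism_id[[i]])
  })
  idx <- unique(data.table::rbindlist(pieces))
  if (!nrow(idx)) stop_input("digestion produced no peptides in length window")
  data.table::setkey(idx, peptide)
  structure(idx, class = c("peptide_index", class(idx)), digest_params = params)
}

#' Organisms carrying a peptide
#'
#' @param index a `peptide_index`.
#' @param peptide a single peptide key.
#' @return character vector of organism ids.
#' @export
organisms_of_peptide <- function(index, peptide) {
  stopifnot(inherits(index, "peptide_index"))
  pep <- peptide
  orgs <- index[data.table::J(pep), organism_id, nomatch = NULL]
  if (!length(orgs)) stop_input("peptide not in index: ", peptide)
  orgs
}

#' Rank-level taxa carrying a peptide
#'
#' Distinct `rank`-level ancestors of the organisms containing `peptide`.
#' The peptide is specific to a taxon at that rank exactly when a single row
#' is returned.
#'
#' @param index a `peptide_index`.
#' @param tree a `taxonomy_tree`.
#' @param peptide a peptide key present in the index.
#' @param rank one of [canonical_ranks()] or `"organism"`.
#' @return data.table of distinct taxa (`taxon_id`, `name`, `rank`).
#' @export
taxa_of_peptide <- function(index, tree, peptide, rank) {
  lca_rank_set(tree, organisms_of_peptide(index, peptide), rank)
}

#' Reduce a protein list to one organism per species
#'
#' Keeps, within every species, the proteins of the lexicographically
#' smallest organism identifier; organisms already unique in their species
#' pass through unchanged. This mirrors the construction of
#' species-dereplicated reference databases.
#'
#' @inheritParams build_index
#' @param tree a `taxonomy_tree` (required: species membership comes from it).
#' @return the filtered protein data.table.
#' @export
dereplicate_per_species <- function(proteins, tree) {
  proteins <- .check_proteins(proteins, tree)
  orgs <- unique(proteins$organism_id)
  key <- data.table::data.table(organism_id = orgs, rank = "species")
  sp <- tree$lineage[key, on = c("organism_id", "rank"),
                     .(organism_id, species = taxon_id)]
  keep <- sp[, .(organism_id = min(organism_id)), by = species]$organism_id
  proteins[organism_id %in% keep]
}

#' Restrict an index to a set of organisms
#'
#' @param index a `peptide_index`.
#' @param organisms organism identifiers to keep.
#' @return the restricted `peptide_index` (peptides with no remaining
#'   organism are dropped).
#' @export
subset_index <- function(index, organisms) {
  stopifnot(inherits(index, "peptide_index"))
  out <- index[organism_id %in% organisms]
  data.table::setkey(out, peptide)
  structure(out, class = class(index),
            digest_params = attr(index, "digest_params"))
}

#' Serialize a peptide index to TSV
#'
#' Two columns: `peptide` and comma-joined, sorted `organism_ids`.
#'
#' @param index a `peptide_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "peptide_index"))
  flat <- index[, .(organism_ids = paste(sort(organism_id), collapse = ",")),
                by = peptide]
  data.table::fwrite(flat, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a serialized peptide index
#'
#' @param path TSV written by [write_index()].
#' @param params the [digest_params()] the index was built with.
#' @return a `peptide_index`.
#' @export
read_index <- function(path, params = digest_params()) {
  flat <- data.table::fread(path, sep = "\t", colClasses = "character")
  idx <- flat[, .(organism_id = strsplit(organism_ids, ",", fixed = TRUE)[[1]]),
              by = peptide]
  data.table::setkey(idx, peptide)
  structure(idx, class = c("peptide_index", class(idx)), digest_params = params)
}

#' Read reference proteins from FASTA
#'
#' Headers follow `"<accession> organism_id=<id>"`; anything else in the
#' description is ignored.
#'
#' @param path protein FASTA file.
#' @return data.table with `accession`, `organism_id`, `sequence`.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  acc <- sub("\\s.*$", "", hdr)
  org <- regmatches(hdr, regexpr("organism_id=\\S+", hdr))
  if (length(org) != length(hdr))
    stop_input("every FASTA header needs an organism_id=<id> tag")
  data.table::data.table(accession = acc,
                         organism_id = sub("^organism_id=", "", org),
                         sequence = as.character(aa))
}

#' Write reference proteins to FASTA
#'
#' @param proteins data.table as from [read_proteins()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  proteins <- .check_proteins(proteins)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- paste0(proteins$accession, " organism_id=", proteins$organism_id)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
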