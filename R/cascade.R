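# Three-step cascade search with database reduction, and the TSM/spePEP
# accounting that turns validated PSMs into a per-rank taxonomic profile.
#
# Step 1 searches a capped batch of spectra against the species-dereplicated
# reference at a permissive validation threshold and keeps the genera of the
# matched organisms; step 2 searches all spectra against the database
# restricted to those genera and their descendants; step 3 restricts further
# to the species identified in step 2 and applies the strictest threshold.

#' Cascade search parameters
#'
#' @param step1_spectrum_cap number of spectra (scan order) used in step 1
#'   (default 10,000).
#' @param p_thresholds strictly decreasing validation p-value thresholds for
#'   steps 1-3 (default 0.3, 0.15, 0.05).
#' @param precursor_tol_ppm per-step precursor tolerances in ppm
#'   (default 3, 5, 5).
#' @param fragment_tol_da fragment tolerance in Da (default 0.02).
#' @param charges precursor charges considered (default 2 and 3).
#' @param digest a [digest_params()] object.
#' @return a `cascade_params` list.
#' @export
cascade_params <- function(step1_spectrum_cap = 10000L,
                           p_thresholds = c(0.3, 0.15, 0.05),
                           precursor_tol_ppm = c(3, 5, 5),
                           fragment_tol_da = 0.02,
                           charges = c(2L, 3L),
                           digest = digest_params()) {
  if (step1_spectrum_cap < 1L) stop_input("step1_spectrum_cap must be >= 1")
  if (length(p_thresholds) != 3L || any(diff(p_thresholds) >= 0))
    stop_input("p_thresholds must be three strictly decreasing values")
  if (length(precursor_tol_ppm) != 3L)
    stop_input("precursor_tol_ppm must have one value per step")
  structure(list(step1_spectrum_cap = as.integer(step1_spectrum_cap),
                 p_thresholds = p_thresholds,
                 precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_da = fragment_tol_da,
                 charges = as.integer(charges),
                 digest = digest),
            class = "cascade_params")
}

.empty_psms <- function() {
  data.table::data.table(spectrum_id = character(), peptide = character(),
                         charge = integer(), n_matched_fragments = integer(),
                         p_value = numeric())
}

# one cascade step over either spectra or an external PSM table
.cascade_step <- function(x, index, ppm, pthr, spectrum_ids, params) {
  if (inherits(x, "data.frame")) {
    hits <- x[spectrum_id %in% spectrum_ids & p_value < pthr &
                peptide %in% index$peptide]
    # keep the best PSM per spectrum (smallest p, then peptide key)
    data.table::setorder(hits, p_value, peptide)
    hits[!duplicated(spectrum_id)]
  } else {
    sel <- x[vapply(x, function(s) s$spectrum_id, character(1)) %in% spectrum_ids]
    sel <- sel[vapply(sel, function(s) s$charge, integer(1)) %in% params$charges]
    hits <- search_batch(sel, index, precursor_tol_ppm = ppm,
                         fragment_tol_da = params$fragment_tol_da,
                         params = params$digest)
    if (!nrow(hits)) return(.empty_psms())
    hits[p_value < pthr]
  }
}

.taxa_of_psms <- function(psms, index, tree, rank) {
  peps <- unique(psms$peptide)
  orgs <- unique(index[data.table::J(peps), organism_id, nomatch = NULL])
  lca_rank_set(tree, orgs, rank)
}

#' Run the three-step cascade search
#'
#' @param x either a list of `spectrum` objects or an externally produced PSM
#'   data.frame (`spectrum_id`, `peptide`, `charge`, `p_value`). With a PSM
#'   table, step membership is recomputed from the taxa of the peptides
#'   retained at each threshold against the reduced databases.
#' @param proteins reference protein table (`accession`, `organism_id`,
#'   `sequence`).
#' @param tree a `taxonomy_tree`.
#' @param params a [cascade_params()] object.
#' @param n_spectra_recorded total recorded MS/MS spectra; defaults to the
#'   number of spectra supplied (spectra input) or of distinct spectrum ids
#'   (PSM input).
#' @return a `cascade_result`: step-1 genera, step-2 species, final validated
#'   PSMs, the per-rank [compute_profile()] and a step log.
#' @export
run_cascade <- function(x, proteins, tree, params = cascade_params(),
                        n_spectra_recorded = NULL) {
  stopifnot(inherits(tree, "taxonomy_tree"), inherits(params, "cascade_params"))
  is_psm <- inherits(x, "data.frame")
  if (is_psm) {
    x <- data.table::as.data.table(x)
    x[, peptide := peptide_key(peptide, params$digest)]
    ids <- unique(x$spectrum_id)
  } else {
    if (!length(x)) stop_input("at least one spectrum is required")
    ids <- vapply(x, function(s) s$spectrum_id, character(1))
    if (anyDuplicated(ids)) stop_input("duplicate spectrum_id in input")
  }
  if (is.null(n_spectra_recorded)) n_spectra_recorded <- length(ids)

  derep <- dereplicate_per_species(proteins, tree)
  index1 <- build_index(derep, params$digest, tree)

  log <- list()
  step1_ids <- head(ids, params$step1_spectrum_cap)
  psms1 <- .cascade_step(x, index1, params$precursor_tol_ppm[1],
                         params$p_thresholds[1], step1_ids, params)
  if (!nrow(psms1))
    stop_input("cascade error at step 1: no validated PSMs")
  genera <- .taxa_of_psms(psms1, index1, tree, "genus")
  log[[1]] <- data.table::data.table(
    step = 1L, db_organisms = length(unique(index1$organism_id)),
    db_peptides = length(unique(index1$peptide)),
    searched_spectra = length(step1_ids), retained_psms = nrow(psms1))

  orgs2 <- descendants(tree, genera$taxon_id)
  index2 <- subset_index(index1, orgs2)
  if (!nrow(index2))
    stop_input("cascade error at step 2: database empty after genus reduction")
  psms2 <- .cascade_step(x, index2, params$precursor_tol_ppm[2],
                         params$p_thresholds[2], ids, params)
  if (!nrow(psms2))
    stop_input("cascade error at step 2: no validated PSMs")
  species <- .taxa_of_psms(psms2, index2, tree, "species")
  log[[2]] <- data.table::data.table(
    step = 2L, db_organisms = length(orgs2),
    db_peptides = length(unique(index2$peptide)),
    searched_spectra = length(ids), retained_psms = nrow(psms2))

  orgs3 <- descendants(tree, species$taxon_id)
  index3 <- subset_index(index1, orgs3)
  if (!nrow(index3))
    stop_input("cascade error at step 3: database empty after species reduction")
  psms3 <- .cascade_step(x, index3, params$precursor_tol_ppm[3],
                         params$p_thresholds[3], ids, params)
  if (!nrow(psms3))
    stop_input("cascade error at step 3: no validated PSMs")
  if ("step" %in% names(psms3)) psms3[, step := NULL]
  psms3[, step := 3L]
  log[[3]] <- data.table::data.table(
    step = 3L, db_organisms = length(orgs3),
    db_peptides = length(unique(index3$peptide)),
    searched_spectra = length(ids), retained_psms = nrow(psms3))

  profile <- compute_profile(psms3, index1, tree, n_spectra_recorded)
  structure(list(step1_genera = genera, step2_species = species,
                 final_psms = psms3, profile = profile,
                 log = data.table::rbindlist(log),
                 index = index1,
                 n_spectra_recorded = n_spectra_recorded),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("cascade_result:", x$n_spectra_recorded, "spectra recorded,",
      nrow(x$final_psms), "final PSMs\n")
  cat("  step 1 genera:", paste(head(x$step1_genera$name, 5), collapse = ", "),
      if (nrow(x$step1_genera) > 5) "..." else "", "\n")
  print(x$log)
  invisible(x)
}

#' Per-rank TSM and spePEP profile of a PSM set
#'
#' For every canonical rank r and taxon t: `tsm` counts the PSMs whose
#' peptide occurs in at least one organism under t (so sibling taxa sharing
#' peptides also share TSMs); `spepep` counts the distinct observed peptide
#' keys that occur in organisms of t only, i.e. are specific to t at rank r.
#' Specificity is assessed against the full index supplied, not against the
#' cascade-reduced databases. `attribution_rate` is
#' `100 * tsm / n_spectra_recorded`, rounded half-up to one decimal.
#'
#' @param psms validated PSM data.table (at most one row per spectrum).
#' @param index the `peptide_index` used for attribution.
#' @param tree a `taxonomy_tree`.
#' @param n_spectra_recorded total recorded MS/MS spectra.
#' @return a `tsm_profile` data.table (`rank`, `taxon_id`, `name`,
#'   `parent_id`, `tsm`, `spepep`, `attribution_rate`) with attributes
#'   `n_spectra_recorded` and `n_psms`.
#' @export
compute_profile <- function(psms, index, tree, n_spectra_recorded) {
  stopifnot(inherits(index, "peptide_index"), inherits(tree, "taxonomy_tree"))
  psms <- data.table::as.data.table(psms)
  if (anyDuplicated(psms$spectrum_id))
    stop_input("PSM set must contain at most one PSM per spectrum")
  if (n_spectra_recorded < nrow(psms))
    stop_input("n_spectra_recorded (", n_spectra_recorded,
               ") < number of PSMs (", nrow(psms), ")")
  peps <- unique(psms$peptide)
  pairs <- index[data.table::J(peps), .(peptide, organism_id), nomatch = NA]
  if (anyNA(pairs$organism_id))
    stop_input("PSM peptide(s) missing from index: ",
               paste(head(pairs$peptide[is.na(pairs$organism_id)], 3),
                     collapse = ", "))

  lin <- tree$lineage[rank %in% CANONICAL_RANKS]
  map <- merge(pairs, lin, by = "organism_id", allow.cartesian = TRUE)
  pep_taxa <- unique(map[, .(peptide, rank, taxon_id, name)])

  counts <- psms[, .(n_psm = .N), by = peptide]
  tsm <- merge(pep_taxa, counts, by = "peptide")[,
    .(tsm = sum(n_psm)), by = .(rank, taxon_id, name)]

  spec <- pep_taxa[, .(n_taxa = data.table::uniqueN(taxon_id)),
                   by = .(peptide, rank)]
  spe <- merge(pep_taxa, spec[n_taxa == 1L], by = c("peptide", "rank"))[,
    .(spepep = data.table::uniqueN(peptide)), by = .(rank, taxon_id)]

  prof <- merge(tsm, spe, by = c("rank", "taxon_id"), all.x = TRUE)
  prof[is.na(spepep), spepep := 0L]

  # parent taxon at the next shallower canonical rank
  wide <- data.table::dcast(lin, organism_id ~ rank, value.var = "taxon_id")
  edges <- unique(data.table::rbindlist(lapply(2:length(CANONICAL_RANKS),
    function(i) data.table::data.table(
      rank = CANONICAL_RANKS[i],
      taxon_id = wide[[CANONICAL_RANKS[i]]],
      parent_id = wide[[CANONICAL_RANKS[i - 1L]]]))))
  prof <- merge(prof, edges, by = c("rank", "taxon_id"), all.x = TRUE)

  prof[, attribution_rate := round_half_up(100 * tsm / n_spectra_recorded, 1)]
  prof[, rank := factor(rank, levels = CANONICAL_RANKS)]
  data.table::setorder(prof, rank, -tsm, -spepep, name)
  prof[, rank := as.character(rank)]
  data.table::setcolorder(prof, c("rank", "taxon_id", "name", "parent_id",
                                  "tsm", "spepep", "attribution_rate"))
  structure(prof, class = c("tsm_profile", class(prof)),
            n_spectra_recorded = n_spectra_recorded, n_psms = nrow(psms))
}

#' Assemble a profile from precomputed counts
#'
#' Builds a `tsm_profile` from a plain table of per-rank, per-taxon TSM and
#' spePEP counts (for example a published identification table), computing
#' attribution rates from `n_spectra_recorded`.
#'
#' @param df data.frame with columns `rank`, `name`, `tsm`, `spepep` and
#'   optionally `taxon_id` and `parent_id` (parent taxon at the next
#'   shallower rank; used for species-level confidence ratios).
#' @param n_spectra_recorded total recorded MS/MS spectra.
#' @param n_psms total validated PSMs, if known.
#' @return a `tsm_profile`.
#' @export
as_tsm_profile <- function(df, n_spectra_recorded, n_psms = NA_integer_) {
  prof <- data.table::as.data.table(df)
  need <- c("rank", "name", "tsm", "spepep")
  if (!all(need %in% names(prof)))
    stop_input("profile needs columns: ", paste(need, collapse = ", "))
  if (!all(prof$rank %in% CANONICAL_RANKS))
    stop_input("unknown rank in profile")
  if (!"taxon_id" %in% names(prof)) prof[, taxon_id := name]
  if (!"parent_id" %in% names(prof)) prof[, parent_id := NA_character_]
  prof[, attribution_rate := round_half_up(100 * tsm / n_spectra_recorded, 1)]
  prof[, rank := factor(rank, levels = CANONICAL_RANKS)]
  data.table::setorder(prof, rank, -tsm, -spepep, name)
  prof[, rank := as.character(rank)]
  data.table::setcolorder(prof, c("rank", "taxon_id", "name", "parent_id",
                                  "tsm", "spepep", "attribution_rate"))
  structure(prof, class = c("tsm_profile", class(prof)),
            n_spectra_recorded = n_spectra_recorded, n_psms = n_psms)
}

#' Attribution rate
#'
#' Percentage of recorded spectra attributed to a taxon:
#' `100 * tsm_count / n_spectra`, rounded half-up to one decimal, the form in
#' which per-taxon assignment rates are conventionally reported.
#'
#' @param tsm_count number of taxon-to-spectrum matches.
#' @param n_spectra number of recorded MS/MS spectra (> 0).
#' @return percentage with one decimal.
#' @export
#' @examples
#' attribution_rate(5241, 10509) # 49.9
attribution_rate <- function(tsm_count, n_spectra) {
  if (any(n_spectra <= 0)) stop_input("n_spectra must be > 0")
  if (any(tsm_count < 0)) stop_input("tsm_count must be >= 0")
  round_half_up(100 * tsm_count / n_spectra, 1)
}

#' Write a profile report
#'
#' Per-sample report with one row per (rank, taxon).
#'
#' @param profile a `tsm_profile`.
#' @param path output TSV path.
#' @param sample_id identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, sample_id = "sample") {
  out <- data.table::copy(data.table::as.data.table(profile))
  out[, sample_id := sample_id]
  data.table::setcolorder(out, "sample_id")
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
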