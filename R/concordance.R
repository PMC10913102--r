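# Marker-gene identity classification under the standard species-delineation
# thresholds, and concordance tables between proteotyping and 16S calls.

#' Species-delineation thresholds
#'
#' Conventional boundaries: 98.7% 16S rRNA identity for species, 95% as the
#' genus floor; 95-96% ANI band for species; 70% dDDH.
#'
#' @param rrna_species 16S species threshold (percent).
#' @param rrna_genus_floor 16S genus floor (percent).
#' @param ani_species two-value ANI species band (percent).
#' @param ddh_species dDDH species threshold (percent).
#' @return a `delineation_thresholds` list.
#' @export
delineation_thresholds <- function(rrna_species = 98.7, rrna_genus_floor = 95,
                                   ani_species = c(95, 96), ddh_species = 70) {
  if (rrna_genus_floor >= rrna_species)
    stop_input("rrna_genus_floor must be below rrna_species")
  vals <- c(rrna_species, rrna_genus_floor, ani_species, ddh_species)
  if (any(vals <= 0 | vals > 100)) stop_input("thresholds must be in (0, 100]")
  structure(list(rrna_species = rrna_species,
                 rrna_genus_floor = rrna_genus_floor,
                 ani_species = sort(ani_species),
                 ddh_species = ddh_species),
            class = "delineation_thresholds")
}

#' Classify a 16S rRNA percent identity
#'
#' `>= 98.7` percent identity to the closest described species indicates a
#' species-level match; identities in `[95, 98.7)` indicate genus-level
#' identification only (a potential new species); below 95 the isolate
#' likely represents a new genus. Lower boundaries are inclusive.
#'
#' @param identity percent identity in (0, 100], vectorised.
#' @param thresholds a [delineation_thresholds()] object.
#' @return character vector in `{"species_match", "potential_new_species",
#'   "potential_new_genus"}`.
#' @export
#' @examples
#' classify_identity(c(99.47, 97.60, 94.99))
classify_identity <- function(identity, thresholds = delineation_thresholds()) {
  if (any(is.na(identity) | identity <= 0 | identity > 100))
    stop_input("identity must be in (0, 100]")
  ifelse(identity >= thresholds$rrna_species, "species_match",
         ifelse(identity >= thresholds$rrna_genus_floor,
                "potential_new_species", "potential_new_genus"))
}

#' Classify an average nucleotide identity value
#'
#' Below the band: distinct species; above: same species; inside the 95-96%
#' band: ambiguous.
#'
#' @inheritParams classify_identity
#' @param ani ANI percent, vectorised.
#' @return character vector in `{"distinct_species", "ambiguous",
#'   "same_species"}`.
#' @export
classify_ani <- function(ani, thresholds = delineation_thresholds()) {
  if (any(is.na(ani) | ani <= 0 | ani > 100))
    stop_input("ani must be in (0, 100]")
  ifelse(ani < thresholds$ani_species[1], "distinct_species",
         ifelse(ani >= thresholds$ani_species[2], "same_species", "ambiguous"))
}

#' Classify a digital DNA-DNA hybridization value
#'
#' @inheritParams classify_identity
#' @param ddh dDDH percent, vectorised.
#' @return character vector in `{"distinct_species", "same_species"}`.
#' @export
classify_ddh <- function(ddh, thresholds = delineation_thresholds()) {
  if (any(is.na(ddh) | ddh <= 0 | ddh > 100))
    stop_input("ddh must be in (0, 100]")
  ifelse(ddh >= thresholds$ddh_species, "same_species", "distinct_species")
}

.genus_of_name <- function(name) tolower(sub("\\s.*$", "", trimws(name)))

#' Concordance between proteotyping and marker-gene calls
#'
#' Tallies, over a cohort of isolates, the agreement between proteotyping
#' rank calls and 16S identity classifications. Name agreement is
#' case-insensitive exact matching of the genus (first word) and the full
#' species binomial.
#'
#' @param proteo data.frame with columns `sample_id`, `genus`, `species`
#'   (best taxa), and logical `new_species`, `new_genus` flags (as raised by
#'   [call_rank()]).
#' @param marker data.frame with columns `sample_id`, `best_hit` (closest
#'   species binomial) and `identity` (16S percent identity).
#' @param thresholds a [delineation_thresholds()] object.
#' @return a `concordance_table` data.table of category counts.
#' @export
concordance <- function(proteo, marker,
                        thresholds = delineation_thresholds()) {
  proteo <- data.table::as.data.table(proteo)
  marker <- data.table::as.data.table(marker)
  if (!setequal(proteo$sample_id, marker$sample_id))
    stop_input("proteo and marker tables must cover the same sample ids")
  m <- merge(proteo, marker, by = "sample_id")
  m[, marker_class := classify_identity(identity, thresholds)]
  same_genus <- !is.na(m$genus) &
    .genus_of_name(m$genus) == .genus_of_name(m$best_hit)
  same_species <- !is.na(m$species) &
    tolower(trimws(m$species)) == tolower(trimws(m$best_hit))
  new_sp_marker <- m$marker_class == "potential_new_species"
  new_gen_marker <- m$marker_class == "potential_new_genus"
  out <- data.table::data.table(
    category = c("identification_same_genus", "identification_same_species",
                 "potential_new_species_16s",
                 "potential_new_species_proteotyping",
                 "potential_new_species_both",
                 "potential_new_genus_16s",
                 "potential_new_genus_proteotyping"),
    count = c(sum(same_genus), sum(same_species),
              sum(new_sp_marker), sum(m$new_species),
              sum(new_sp_marker & m$new_species),
              sum(new_gen_marker), sum(m$new_genus)))
  structure(out, class = c("concordance_table", class(out)),
            n_isolates = nrow(m))
}

#' Summarise a rank call for concordance input
#'
#' @param call a `rank_call`.
#' @param sample_id isolate identifier.
#' @return one-row data.frame with the columns [concordance()] expects.
#' @export
call_summary <- function(call, sample_id) {
  best <- call$best_taxon_per_rank
  gx <- best[best$rank == "genus", ]
  sx <- best[best$rank == "species", ]
  data.table::data.table(
    sample_id = sample_id,
    genus = if (nrow(gx)) gx$name else NA_character_,
    species = if (nrow(sx)) sx$name else NA_character_,
    new_species = "potential_new_species" %in% call$flags,
    new_genus = "potential_new_genus" %in% call$flags)
}

#' Read a marker identity table
#'
#' Tab-separated columns: `sample_id`, `best_hit`, `identity`.
#'
#' @param path TSV path.
#' @return data.table.
#' @export
read_identities <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("sample_id", "best_hit", "identity")
  if (!all(need %in% names(dt)))
    stop_input("identity TSV needs columns: ", paste(need, collapse = ", "))
  dt[]
}
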