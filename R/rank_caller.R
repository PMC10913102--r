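# Deterministic interpretation of a TSM/spePEP profile: deepest confident
# rank plus novelty flags. When similar numbers of TSMs and spePEPs are
# spread over several closely related taxa, only the shallower rank is
# considered valid; the thresholds below make that rule explicit and
# reproducible.

#' Rank-calling parameters
#'
#' @param species_tsm_dominance minimum fraction of the genus-level TSMs that
#'   the top species must hold for species-level confidence (default 0.90).
#'   A species sharing most of its genus' spectra is unambiguous; a sharp
#'   TSM drop from genus to species signals a missing reference genome.
#' @param spepep_dominance minimum ratio of the top taxon's spePEP count to
#'   the runner-up's at the same rank (default 5).
#' @param min_spepep minimum spePEP count for a confident taxon (default 50).
#' @return a `call_params` list.
#' @export
call_params <- function(species_tsm_dominance = 0.90, spepep_dominance = 5,
                        min_spepep = 50L) {
  if (species_tsm_dominance <= 0 || species_tsm_dominance > 1)
    stop_input("species_tsm_dominance must be in (0, 1]")
  if (spepep_dominance < 1) stop_input("spepep_dominance must be >= 1")
  structure(list(species_tsm_dominance = species_tsm_dominance,
                 spepep_dominance = spepep_dominance,
                 min_spepep = as.integer(min_spepep)),
            class = "call_params")
}

.rank_rows <- function(profile, r) {
  rows <- profile[profile$rank == r, ]
  data.table::setorderv(rows, c("tsm", "spepep", "name"),
                        order = c(-1L, -1L, 1L))
  rows
}

.rank_confident <- function(profile, r, params) {
  rows <- .rank_rows(profile, r)
  if (!nrow(rows)) return(NA)
  top <- rows[1L]
  if (is.na(top$spepep) || top$spepep < params$min_spepep) return(FALSE)
  if (nrow(rows) > 1L) {
    runner <- max(rows$spepep[-1L])
    if (top$spepep < params$spepep_dominance * runner) return(FALSE)
  }
  if (r == "species") {
    genus_rows <- .rank_rows(profile, "genus")
    gt <- if (!is.na(top$parent_id) && top$parent_id %in% genus_rows$taxon_id) {
      genus_rows$tsm[match(top$parent_id, genus_rows$taxon_id)]
    } else if (nrow(genus_rows)) {
      genus_rows$tsm[1L]
    } else {
      NA_integer_
    }
    if (!is.na(gt) && gt > 0 && top$tsm / gt < params$species_tsm_dominance)
      return(FALSE)
  }
  TRUE
}

#' Call the deepest confident rank of a profile
#'
#' Walks the canonical ranks from species upward. A rank is confident when
#' its top taxon (largest TSM, then spePEP, then name) carries at least
#' `min_spepep` specific peptides and at least `spepep_dominance` times the
#' runner-up's spePEP count; the species rank additionally requires the top
#' species to hold at least `species_tsm_dominance` of its genus' TSMs.
#'
#' Flags: `potential_new_species` when the call stops at genus;
#' `potential_new_genus` when the genus rank is ambiguous while two or more
#' genera each carry at least `min_spepep` specific peptides;
#' `db_gap_suspected` when the top species holds under half of the genus
#' TSMs yet over 90% of the genus spePEPs (a missing sibling genome rather
#' than a novel taxon).
#'
#' @param profile a `tsm_profile`.
#' @param params a [call_params()] object.
#' @return a `rank_call`: list with `confident_rank` (`NA` when no rank
#'   passes), `best_taxon_per_rank`, `confidence_per_rank` and `flags`.
#' @export
call_rank <- function(profile, params = call_params()) {
  profile <- data.table::as.data.table(profile)
  if (!nrow(profile)) stop_input("empty profile")
  if (!nrow(profile[rank == "genus"]))
    stop_input("profile must contain genus-rank rows")

  ranks_present <- intersect(CANONICAL_RANKS, unique(profile$rank))
  best <- data.table::rbindlist(lapply(ranks_present, function(r)
    .rank_rows(profile, r)[1L]))
  conf <- vapply(ranks_present, function(r)
    isTRUE(.rank_confident(profile, r, params)), logical(1))
  names(conf) <- ranks_present

  confident_rank <- NA_character_
  for (r in rev(ranks_present)) {   # deepest first
    if (conf[[r]]) {
      confident_rank <- r
      break
    }
  }

  flags <- character()
  genus_rows <- .rank_rows(profile, "genus")
  species_conf <- isTRUE(conf[["species"]])
  genus_conf <- isTRUE(conf[["genus"]])
  if (identical(confident_rank, "genus"))
    flags <- c(flags, "potential_new_species")
  if (!genus_conf && !species_conf &&
      sum(genus_rows$spepep >= params$min_spepep) >= 2L)
    flags <- c(flags, "potential_new_genus")
  sp_rows <- .rank_rows(profile, "species")
  if (nrow(sp_rows) && nrow(genus_rows)) {
    top_sp <- sp_rows[1L]
    gt <- genus_rows$tsm[1L]
    gs <- genus_rows$spepep[1L]
    if (gt > 0 && gs > 0 &&
        top_sp$tsm / gt < 0.5 && top_sp$spepep / gs > 0.9)
      flags <- c(flags, "db_gap_suspected")
  }

  structure(list(confident_rank = confident_rank,
                 best_taxon_per_rank = best,
                 confidence_per_rank = conf,
                 flags = flags,
                 params = params),
            class = "rank_call")
}

#' @export
print.rank_call <- function(x, ...) {
  cat("rank_call: confident rank =",
      if (is.na(x$confident_rank)) "none (ambiguous)" else x$confident_rank,
      "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  best <- x$best_taxon_per_rank
  for (i in seq_len(nrow(best)))
    cat(sprintf("  %-12s %s (TSM %s, spePEP %s)%s\n", best$rank[i],
                best$name[i], best$tsm[i], best$spepep[i],
                if (isTRUE(x$confidence_per_rank[[best$rank[i]]])) " *" else ""))
  invisible(x)
}

#' Write rank calls as a TSV report
#'
#' @param calls named list of `rank_call` objects (names are sample ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  rows <- data.table::rbindlist(lapply(names(calls), function(id) {
    cl <- calls[[id]]
    best <- cl$best_taxon_per_rank
    gx <- best[best$rank == "genus", ]
    sx <- best[best$rank == "species", ]
    data.table::data.table(
      sample_id = id,
      confident_rank = cl$confident_rank,
      best_genus = if (nrow(gx)) gx$name else NA_character_,
      best_species = if (nrow(sx)) sx$name else NA_character_,
      flags = paste(cl$flags, collapse = ";"))
  }))
  hdr <- sprintf(
    "# call thresholds: species_tsm_dominance=%g spepep_dominance=%g min_spepep=%d",
    calls[[1]]$params$species_tsm_dominance,
    calls[[1]]$params$spepep_dominance, calls[[1]]$params$min_spepep)
  writeLines(hdr, path)
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}
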