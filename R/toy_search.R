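# A small deterministic spectrum-to-peptide matcher. It stands in for a
# commercial search engine: candidate peptides are filtered by precursor mass
# within a ppm tolerance, scored by the number of singly charged b/y fragment
# ions found within the fragment tolerance, and assigned a p-value from a
# binomial null with a per-fragment match probability estimated from the
# spectrum's peak density. Externally produced PSM tables can bypass this
# module entirely (see read_psms()).

#' Construct a spectrum
#'
#' @param spectrum_id unique identifier.
#' @param precursor_mz precursor m/z in Da.
#' @param charge precursor charge, 2 or 3 (the charges retained for
#'   fragmentation).
#' @param peaks two-column matrix or data.frame of fragment (m/z, intensity);
#'   stored sorted by m/z.
#' @return a `spectrum` object.
#' @export
spectrum <- function(spectrum_id, precursor_mz, charge, peaks) {
  if (!charge %in% c(2L, 3L)) stop_input("charge must be 2 or 3")
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop_input("peaks must have two columns (mz, intensity)")
  colnames(peaks) <- c("mz", "intensity")
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge),
                 peaks = peaks),
            class = "spectrum")
}

#' Singly charged b/y fragment m/z values of a peptide
#'
#' Fixed modifications are applied to the residues; variable oxidation is
#' handled at the precursor level only.
#'
#' @param peptide peptide sequence.
#' @param params a [digest_params()] object.
#' @return numeric vector of the 2(L-1) fragment m/z values.
#' @export
fragment_mz <- function(peptide, params = digest_params()) {
  ch <- strsplit(peptide, "", fixed = TRUE)[[1]]
  res <- MONO_RESIDUE[ch]
  if (anyNA(res)) stop_input("residue without a mass in peptide: ", peptide)
  res <- res + ifelse(ch == "C", MOD_CARBAMIDOMETHYL, 0)
  n <- length(res)
  if (n < 2L) return(numeric())
  b <- cumsum(res[-n]) + MASS_PROTON
  y <- rev(cumsum(rev(res[-1L]))) + MASS_WATER + MASS_PROTON
  c(b, y)
}

#' Theoretical spectrum of a peptide
#'
#' Builds a spectrum containing every singly charged b/y ion at unit
#' intensity; convenient for fixtures and simulations.
#'
#' @inheritParams fragment_mz
#' @param spectrum_id identifier for the new spectrum.
#' @param charge precursor charge (2 or 3).
#' @param n_oxidations oxidised methionines carried by the precursor.
#' @return a `spectrum`.
#' @export
peptide_spectrum <- function(peptide, spectrum_id = peptide, charge = 2L,
                             params = digest_params(), n_oxidations = 0L) {
  mz <- fragment_mz(peptide, params)
  mass <- peptide_mass(peptide, params, n_oxidations)
  spectrum(spectrum_id, precursor_mz = mass / charge + MASS_PROTON,
           charge = charge, peaks = cbind(mz, rep(1, length(mz))))
}

#' Candidate table for spectrum matching
#'
#' Precomputes neutral monoisotopic masses for every peptide of an index,
#' including variable-modification variants (0..`max_ox` oxidised
#' methionines, bounded by the methionine count).
#'
#' @param index a `peptide_index`.
#' @param params a [digest_params()] object.
#' @param max_ox maximum number of oxidations per peptide (default 2).
#' @return data.table (`peptide`, `n_ox`, `mass`) sorted by mass.
#' @export
candidate_table <- function(index, params = attr(index, "digest_params"),
                            max_ox = 2L) {
  stopifnot(inherits(index, "peptide_index"))
  peps <- unique(index$peptide)
  peps <- peps[!grepl("X", peps, fixed = TRUE)]
  n_m <- vapply(strsplit(peps, "", fixed = TRUE),
                function(ch) sum(ch == "M"), integer(1))
  base <- peptide_mass(peps, params, 0L)
  pieces <- lapply(0:max_ox, function(k) {
    sel <- n_m >= k
    if (!any(sel)) return(NULL)
    data.table::data.table(peptide = peps[sel], n_ox = k,
                           mass = base[sel] + MOD_OXIDATION * k)
  })
  out <- data.table::rbindlist(pieces)
  data.table::setorder(out, mass)
  out
}

.binom_pvalue <- function(k, n_frag, p0) {
  stats::pbinom(k - 1L, n_frag, p0, lower.tail = FALSE)
}

.match_count <- function(frag, peak_mz, tol) {
  # number of theoretical fragments with at least one peak within tol
  lo <- findInterval(frag - tol, peak_mz)
  hi <- findInterval(frag + tol, peak_mz)
  sum(hi > lo)
}

#' Match one spectrum against candidate peptides
#'
#' Candidates are filtered by `|observed neutral mass - candidate mass|`
#' within `precursor_tol_ppm`; each survivor is scored by the number of its
#' singly charged b/y fragments matched within `fragment_tol_da`, and
#' assigned the binomial tail p-value \eqn{P(X \ge k)} with
#' \eqn{X \sim Bin(n_{frag}, p_0)}, \eqn{p_0 = 2\,tol\,m / span} for a
#' spectrum of m peaks spanning `span` Da. The candidate with the smallest
#' p-value wins; ties break by more matched fragments, then lexicographic
#' peptide key.
#'
#' @param s a `spectrum`.
#' @param candidates a [candidate_table()].
#' @param precursor_tol_ppm precursor tolerance in ppm.
#' @param fragment_tol_da fragment tolerance in Da.
#' @param params a [digest_params()] object.
#' @return one-row data.table (`spectrum_id`, `peptide`, `charge`,
#'   `n_matched_fragments`, `p_value`) or `NULL` when no candidate passes the
#'   precursor filter.
#' @export
match_spectrum <- function(s, candidates, precursor_tol_ppm = 5,
                           fragment_tol_da = 0.02, params = digest_params()) {
  stopifnot(inherits(s, "spectrum"))
  neutral <- (s$precursor_mz - MASS_PROTON) * s$charge
  tol_da <- neutral * precursor_tol_ppm * 1e-6
  lo <- findInterval(neutral - tol_da, candidates$mass)
  hi <- findInterval(neutral + tol_da, candidates$mass)
  if (hi <= lo) return(NULL)
  sel <- unique(candidates$peptide[(lo + 1L):hi])
  peak_mz <- s$peaks[, "mz"]
  m <- length(peak_mz)
  span <- max(1, peak_mz[m] - peak_mz[1])
  p0 <- min(1, 2 * fragment_tol_da * m / span)
  best <- NULL
  for (pep in sel) {
    frag <- fragment_mz(pep, params)
    k <- .match_count(frag, peak_mz, fragment_tol_da)
    p <- .binom_pvalue(k, length(frag), p0)
    cand <- list(peptide = pep, k = k, p = p)
    if (is.null(best) ||
        p < best$p ||
        (p == best$p && (k > best$k || (k == best$k && pep < best$peptide))))
      best <- cand
  }
  data.table::data.table(spectrum_id = s$spectrum_id, peptide = best$peptide,
                         charge = s$charge,
                         n_matched_fragments = best$k, p_value = best$p)
}

#' Search a batch of spectra
#'
#' Deterministic wrapper applying [match_spectrum()] to every spectrum; at
#' most one best PSM is retained per spectrum.
#'
#' @param spectra list of `spectrum` objects with unique identifiers.
#' @param index a `peptide_index`.
#' @param precursor_tol_ppm,fragment_tol_da tolerances.
#' @param candidates optional precomputed [candidate_table()].
#' @param params a [digest_params()] object.
#' @return data.table of PSMs (possibly zero rows).
#' @export
search_batch <- function(spectra, index, precursor_tol_ppm = 5,
                         fragment_tol_da = 0.02, candidates = NULL,
                         params = attr(index, "digest_params")) {
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids))
    stop_input("duplicate spectrum_id: ", ids[duplicated(ids)][1])
  if (!length(spectra))
    return(data.table::data.table(spectrum_id = character(),
                                  peptide = character(), charge = integer(),
                                  n_matched_fragments = integer(),
                                  p_value = numeric()))
  if (is.null(candidates)) candidates <- candidate_table(index, params)
  hits <- lapply(spectra, match_spectrum, candidates = candidates,
                 precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_da = fragment_tol_da, params = params)
  data.table::rbindlist(hits[!vapply(hits, is.null, logical(1))])
}

#' Read spectra from an MGF file
#'
#' Minimal Mascot generic format reader: BEGIN IONS/END IONS blocks with
#' TITLE, PEPMASS and CHARGE headers followed by peak lines.
#'
#' @param path MGF file path.
#' @return list of `spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop_input("malformed MGF: unbalanced BEGIN IONS/END IONS")
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, "", 1L))
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
    peaks <- do.call(rbind, lapply(strsplit(trimws(block[!hdr]), "\\s+"),
                                   function(x) as.numeric(x[1:2])))
    spectrum(
      spectrum_id = vals[keys == "TITLE"][1],
      precursor_mz = as.numeric(strsplit(vals[keys == "PEPMASS"][1], " ")[[1]][1]),
      charge = as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1])),
      peaks = peaks)
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra list of `spectrum` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 paste0("PEPMASS=", format(s$precursor_mz, digits = 12)),
                 paste0("CHARGE=", s$charge, "+"),
                 paste(format(s$peaks[, "mz"], digits = 12, trim = TRUE),
                       format(s$peaks[, "intensity"], digits = 6, trim = TRUE)),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read a PSM table
#'
#' Tab-separated with columns `spectrum_id`, `peptide`, `charge`, `p_value`
#' and optionally `step`; the entry point for search-engine output produced
#' outside this package.
#'
#' @param path TSV path.
#' @return data.table of PSMs.
#' @export
read_psms <- function(path) {
  psms <- data.table::fread(path, sep = "\t")
  need <- c("spectrum_id", "peptide", "charge", "p_value")
  if (!all(need %in% names(psms)))
    stop_input("PSM TSV needs columns: ", paste(need, collapse = ", "))
  psms[, spectrum_id := as.character(spectrum_id)]
  psms[]
}

#' Write a PSM table
#'
#' @param psms data.table of PSMs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psms <- function(psms, path) {
  data.table::fwrite(psms, path, sep = "\t", quote = FALSE)
  invisible(path)
}
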