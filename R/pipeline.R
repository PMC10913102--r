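# End-to-end driver tying the stages together, plus the configuration
# surface used by the command-line script in inst/cli/taxoproteo.R.

#' Assemble and validate a run configuration
#'
#' @param taxonomy path to the taxonomy TSV.
#' @param proteins path to the reference protein FASTA.
#' @param psms path to a PSM TSV (external search-engine output), or `NULL`.
#' @param mgf path to an MGF spectra file, or `NULL`. Exactly one of `psms`
#'   and `mgf` must be given.
#' @param identities optional path to a 16S identity TSV for concordance.
#' @param out_dir output directory.
#' @param sample_id isolate identifier used in reports.
#' @param n_spectra_recorded recorded spectra (defaults to input size).
#' @param cascade a [cascade_params()] object.
#' @param call a [call_params()] object.
#' @param thresholds a [delineation_thresholds()] object.
#' @return a validated `run_config` list.
#' @export
run_config <- function(taxonomy, proteins, psms = NULL, mgf = NULL,
                       identities = NULL, out_dir = ".",
                       sample_id = "sample", n_spectra_recorded = NULL,
                       cascade = cascade_params(), call = call_params(),
                       thresholds = delineation_thresholds()) {
  for (p in c(taxonomy, proteins, psms, mgf, identities))
    if (!file.exists(p)) stop_input("input file not found: ", p)
  if (is.null(psms) == is.null(mgf))
    stop_input("exactly one of psms/mgf must be supplied")
  structure(list(taxonomy = taxonomy, proteins = proteins, psms = psms,
                 mgf = mgf, identities = identities, out_dir = out_dir,
                 sample_id = sample_id,
                 n_spectra_recorded = n_spectra_recorded,
                 cascade = cascade, call = call, thresholds = thresholds),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Top-level keys mirror the arguments of [run_config()]; nested `cascade`,
#' `call` and `thresholds` blocks override individual parameter defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fun, block) do.call(fun, as.list(block %||% list()))
  run_config(taxonomy = y$taxonomy, proteins = y$proteins, psms = y$psms,
             mgf = y$mgf, identities = y$identities,
             out_dir = y$out_dir %||% ".",
             sample_id = y$sample_id %||% "sample",
             n_spectra_recorded = y$n_spectra_recorded,
             cascade = build(cascade_params, y$cascade),
             call = build(call_params, y$call),
             thresholds = build(delineation_thresholds, y$thresholds))
}

#' Run the full proteotyping pipeline
#'
#' Loads the reference and observed data, runs the cascade, calls the
#' deepest confident rank, and writes TSV reports (`profile.tsv`,
#' `calls.tsv`, `cascade_log.tsv`, and `concordance.tsv` when an identity
#' table is configured) into the output directory. Every report number is
#' recomputable from the intermediate tables it cites.
#'
#' @param config a [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the `cascade_result`, the `rank_call` and
#'   the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)

  say("loading taxonomy: ", config$taxonomy)
  tree <- load_taxonomy(config$taxonomy)
  say("loading proteins: ", config$proteins)
  proteins <- read_proteins(config$proteins)
  x <- if (!is.null(config$psms)) read_psms(config$psms)
       else read_mgf(config$mgf)

  say("running cascade search")
  res <- run_cascade(x, proteins, tree, config$cascade,
                     n_spectra_recorded = config$n_spectra_recorded)
  call <- call_rank(res$profile, config$call)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(profile = file.path(config$out_dir, "profile.tsv"),
             calls = file.path(config$out_dir, "calls.tsv"),
             log = file.path(config$out_dir, "cascade_log.tsv"))
  write_profile(res$profile, paths[["profile"]], config$sample_id)
  calls <- stats::setNames(list(call), config$sample_id)
  write_calls(calls, paths[["calls"]])
  data.table::fwrite(res$log, paths[["log"]], sep = "\t")

  if (!is.null(config$identities)) {
    marker <- read_identities(config$identities)
    marker <- marker[marker$sample_id == config$sample_id, ]
    if (nrow(marker)) {
      conc <- concordance(call_summary(call, config$sample_id), marker,
                          config$thresholds)
      paths[["concordance"]] <- file.path(config$out_dir, "concordance.tsv")
      data.table::fwrite(conc, paths[["concordance"]], sep = "\t")
    }
  }
  say("confident rank: ",
      if (is.na(call$confident_rank)) "none" else call$confident_rank)
  invisible(list(cascade = res, call = call, paths = paths))
}
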