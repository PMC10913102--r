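# Loaders for the bundled isolate identification profiles.

load_haal_profile <- function(sample, extended = FALSE) {
  f <- system.file("extdata",
                   if (extended) "haal_profiles_extended.tsv"
                   else "haal_profiles.tsv",
                   package = "taxoproteo")
  dt <- data.table::fread(f, sep = "\t")
  rows <- dt[sample_id == sample]
  as_tsm_profile(
    rows[, .(rank, name, tsm, spepep, parent_id = parent)],
    n_spectra_recorded = rows$n_spectra_recorded[1])
}

haal_table <- function() {
  data.table::fread(system.file("extdata", "haal_profiles.tsv",
                                package = "taxoproteo"), sep = "\t")
}
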