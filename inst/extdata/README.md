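# Bundled example data

Both tables hold per-rank identification profiles of microbial isolates
cultivated from high-altitude Andean lakes (HAAL), in the machine-readable
form consumed by `as_tsm_profile()`: one row per (sample, rank, taxon) with
its taxon-to-spectrum-match (`tsm`) and taxon-specific-peptide (`spepep`)
counts, the parent taxon at the next shallower rank, and the number of
recorded MS/MS spectra.

- `haal_profiles.tsv` — the best match per rank for six isolates
  (SS18, HP23, HR17, SM24, SM33, SS13), together with the closest 16S rRNA
  hit and its percent identity. SM24's recorded-spectrum count is not
  available (`NA`): its attribution rates are undefined.
- `haal_profiles_extended.tsv` — the same isolates' profiles extended with
  the runner-up taxa needed for rank calling on the ambiguous cases (SS13's
  second order/family and its three candidate genera). One cell is a
  synthetic completion: the family-level TSM count of *Alteromonadaceae* for
  SS13 is not reported and is filled with its order-level TSM count (2,459),
  an upper bound. It has no effect on rank calls, which use spePEP counts at
  that rank.

`haal_identities` rows are percent identities of the isolate's 16S rRNA gene
to its closest described relative; classify them with `classify_identity()`.
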