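# Packaged study-table reconstructions

These CSVs are reconstructions of published summary tables from the rectal
polyp assessment study the package's rater-statistics module is built
around (32 surgeon raters judging 14 lesion videos as benign or cancer
with 1-5 Likert confidence; lesion size estimates for 6 of the lesions).

- `study_polyp_votes.csv` — per-polyp pathology, majority answer with its
  percentage share, the 1-5 confidence-level frequency counts, and the
  published mean Likert score. Per-polyp benign/cancer vote counts are
  reconstructed from the majority percentage as
  `round(pct * 32 / 100)` (complement `32 - count`); the evenly-split
  polyp 14 is 16/16.
- `study_polyp_sizes.csv` — per-polyp mean size estimate (with range) and
  the actual size from the excisional pathology report. `fully_visible`
  marks lesions wholly visible in a single camera view (polyp 1 was not).

The underlying per-rater raw responses were not published; analyses that
need them (e.g. per-rater accuracy averaging) are exercised on synthetic
rater tables instead. All other fixtures in this package are generated
programmatically at run time.
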