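cleveland_synthetic.csv
  SYNTHETIC stand-in for the public Cleveland subset of the UCI Heart
  Disease "processed" file (headerless 14-field CSV dialect, '?' = missing).
  Generated by this package's own cohort simulator (cohort_spec(n = 303,
  seed = 1903), then masking exactly 2 `thal` and 4 `ca` entries), so it
  matches the documented shape of the real file -- 303 records, 2 missing
  thal, 4 missing ca -- without containing any real patient data.  It is NOT
  the UCI file; download that from the UCI Machine Learning Repository if
  you want the real cohort.
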