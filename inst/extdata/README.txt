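ajcc8_lung_stage_grouping.csv
  AJCC 8th-edition lung cancer stage grouping over the full T x N x M grid
  (7 T levels x 4 N levels x 2 M levels = 56 rows; columns t, n, m, stage).
  Encoded from the published 8th-edition grouping; metastatic subdivisions
  are collapsed to M1 -> stage IV and stage 0/occult is not represented.
  Kept as a data fixture (not hard-coded logic) so it is auditable and
  swappable.
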