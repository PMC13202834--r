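Curated per-variant tables for a 27-trio cerebral palsy cohort, used by the
worked examples and the acceptance checks:

- `acmg_evidence_cp_cohort.tsv` — ACMG evidence-code strings (with strength
  modifiers) asserted for each candidate variant in a CP-associated gene.
- `denovo_scores_cp_genes.tsv` — SIFT / PolyPhen-2 / CADD scores of the
  damaging de novo variants found in CP-associated genes. The PROC row's
  CADD value (21) is reconstructed from a garbled print run; see the package
  documentation.
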