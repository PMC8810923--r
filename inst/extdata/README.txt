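fi_bmi_published_loci.tsv
  Published per-locus GWAS summary statistics for six lead variants:
  effect on body mass index (beta_I, se_I) and on fasting blood insulin
  conditional on BMI (beta_P, se_P), together with the published
  collider-bias-adjusted estimates (Slope-Hunter factor -0.317, DHO factor
  -0.118) for cross-checking adjust_associations().

bcmort_published_loci.tsv
  Published per-locus summary statistics for three lead variants: effect
  on breast cancer risk (beta_I, se_I) and on breast cancer mortality in a
  case-only study (beta_P, se_P), with published adjusted estimates
  (Slope-Hunter factor -0.242, DHO factor -0.053).

All values are printed (rounded) published numbers, not raw data.
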