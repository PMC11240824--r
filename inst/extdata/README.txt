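Published contingency counts used as worked-example inputs.

cbcs_rfd_counts.tsv
  Unadjusted counts of each clinical characteristic by visual-ITH group
  (heterogeneous referent) in the Carolina Breast Cancer Study cohort the
  NML method was developed on, with the published unadjusted relative
  frequency difference (percentage points) for each contrast.

molecular_or_counts.tsv
  2x2 counts of molecular indicators (single-subclone status, TP53
  mutation) by visual-ITH group (exposure = low visual ITH), per image
  compartment, for the CBCS and TCGA-BRCA cohorts, with the published
  odds ratio.
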