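# Column remapping for dbNSFP per-variant extracts. The protein change is
# composed from the aaref/aapos/aaalt triple; dbNSFP rows are
# non-synonymous SNVs, so consequence defaults to missense.
columns:
  rsid: rs_dbSNP
  gene: genename
  polyphen2_class: Polyphen2_HVAR_pred
  polyphen2_score: Polyphen2_HVAR_score
  provean: PROVEAN_score
  sift: SIFT_score
  gerp: GERP++_RS
  phastcons: phastCons17way_primate
  grantham: Grantham
compose_protein_change: [aaref, aapos, aaalt]
default_consequence: missense
class_codes:
  D: probably-damaging
  P: possibly-damaging
  B: benign
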