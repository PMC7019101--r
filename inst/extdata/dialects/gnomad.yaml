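# Column remapping for gnomAD browser variant CSV/TSV exports (v2-style).
# Protein changes arrive in HGVS three-letter form ("p.Arg672Gly") and are
# converted on load.
columns:
  rsid: rsIDs
  gene: Gene
  protein_change: Protein Consequence
  consequence: VEP Annotation
  allele_frequency: Allele Frequency
  allele_count: Allele Count
  hom_count: Number of Homozygotes
  pop_afr: Allele Count African/African American
  pop_amr: Allele Count Latino/Admixed American
  pop_asj: Allele Count Ashkenazi Jewish
  pop_eas: Allele Count East Asian
  pop_sas: Allele Count South Asian
  pop_fin: Allele Count European (Finnish)
  pop_nfe: Allele Count European (non-Finnish)
  pop_oth: Allele Count Other
  male: Allele Count XY
  female: Allele Count XX
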