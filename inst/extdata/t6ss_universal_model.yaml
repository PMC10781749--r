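name: T6SS-universal
components:
  TssB: mandatory
  TssC: mandatory
  TssD: mandatory
  TssE: mandatory
  TssF: mandatory
  TssG: mandatory
  TssH: mandatory
  TssI: mandatory
  TssK: mandatory
min_mandatory: 6
min_total: 6
inter_gene_max_distance: 10
multi_loci: yes
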