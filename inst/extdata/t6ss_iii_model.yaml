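name: T6SSiii
components:
  TssB: accessory
  TssC: accessory
  TssD: accessory
  TssE: accessory
  TssF: accessory
  TssG: accessory
  TssH: accessory
  TssI: accessory
  TssK: accessory
  TssN: mandatory
  TssO: mandatory
  TssP: mandatory
  TssQ: mandatory
  TssR: mandatory
min_mandatory: 1
min_total: 8
inter_gene_max_distance: 10
multi_loci: yes
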