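probes:
- name: COX2
  locus: 1q31.1
  role: gene
  gene_class: oncogene
- name: DBC2
  locus: 8p21.3
  role: gene
  gene_class: tumor_suppressor
- name: MYC
  locus: 8q24.21
  role: gene
  gene_class: oncogene
- name: CCND1
  locus: 11q13.3
  role: gene
  gene_class: oncogene
- name: CDH1
  locus: 16q22.1
  role: gene
  gene_class: tumor_suppressor
- name: TP53
  locus: 17p13.1
  role: gene
  gene_class: tumor_suppressor
- name: HER2
  locus: 17q12
  role: gene
  gene_class: oncogene
- name: ZNF217
  locus: 20q13.2
  role: gene
  gene_class: oncogene
- name: CCP4
  locus: cen4
  role: centromere
  gene_class: none
- name: CCP10
  locus: cen10
  role: centromere
  gene_class: none
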