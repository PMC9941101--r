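# End-to-end demo: simulate both chemistries for a wild-type and a knockout
# condition over the packaged synthetic references and catalogs, score,
# contrast, and classify guide concordance. Paths are relative to this file.
reference: synthetic_rrna.fa
catalog_nm: synthetic_sites_nm.tsv
catalog_psi: synthetic_sites_psi.tsv
guide_de: synthetic_guide_de.tsv
replicates: 3
seed: 42
conditions:
  WT:
    truth_nm: demo_truth_nm_wt.tsv
    truth_psi: demo_truth_psi_wt.tsv
  KO:
    truth_nm: demo_truth_nm_ko.tsv
    truth_psi: demo_truth_psi_ko.tsv
params:
  rms:
    depth: 2000
  hydrapsi:
    depth: 2000
thresholds:
  flank: 6
  window: 10
  affected: 0.05
  heatmap: 0.1
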