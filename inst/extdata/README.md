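# Packaged fixtures (synthetic)

All files here are synthetic stand-ins generated by `scripts/make_fixtures.R`
(fixed seed): the reference sequences in `synthetic_rrna.fa` are random
ACGU strings of realistic mature-rRNA lengths (18S 1869 nt, 28S 5070 nt,
5.8S 157 nt) with the well-known modified residues forced at their published
positions so the catalogs validate. They are **not** the real human rRNA
sequences.

- `synthetic_sites_nm.tsv` — 2'-O-Me catalog: 41 sites on 18S, 67 on 28S,
  2 on 5.8S (110 total). Note: the literature also quotes 109 scored Nm
  positions in one place; the per-molecule counts as stated per modality are
  what this fixture ships, and the one-site discrepancy is left unresolved
  here.
- `synthetic_sites_psi.tsv` — pseudouridine catalog: 44 sites on 18S, 61 on
  28S, 2 on 5.8S. Old-nomenclature numbers are carried in `legacy_position`
  for the sites where they are published (they are data, not an arithmetic
  offset).
- `demo_truth_*.tsv` — ground-truth modification fractions for the demo
  pipeline: a near-saturated baseline (0.85–0.98) with the published
  dynamic wild-type/knockout stoichiometries at their positions.
- `synthetic_guide_de.tsv` — fabricated guide snoRNA differential-expression
  table in the shape of a DESeq2 export plus qPCR rows.
- `demo_config.yaml` — run configuration consumed by `run_demo()`.
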