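# Bundled fixtures

Both tables are **synthetic stand-ins**, generated with a fixed seed; they
encode only the published funnel outcome of the deconvolution stage (250
candidate genes rescreened with three individual siRNAs each, 160 of which
validate at |z| >= 1.6 in the primary-hit direction, a 64% validation rate).
The per-gene z values are draws, not measured data.

- `paper_funnel_candidates_synthetic.csv` — 250 candidate genes with hit
  direction, mean primary-screen z, evidence flags and candidate status.
- `paper_funnel_deconvolution_synthetic.csv` — per-gene deconvolution
  records: primary direction plus the three per-siRNA aggregated robust
  z-scores (`sirna_z_1..3`).
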