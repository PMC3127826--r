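# Demo pipeline configuration: all-simulation run emulating a ~3 kb promoter
# with a hypermethylated block, stripe-offset methylation, E-box motifs and
# McrBC/qPCR + bisulfite + expression read-outs.
seed: 20260911
outdir: stripemeth_demo
reference:
  length: 3000
  gc_fraction: 0.38
  motifs:
    - {motif: CACATG, pos: -1300}
    - {motif: CACATG, pos: -980}
    - {motif: CACATG, pos: -700}
profile:
  base_rates: {CG: 0.016, CHG: 0.169, CHH: 0.202}
  blocks:
    - {start: -1400, end: -501, override: 0.60}  # hypermethylated region
  stripe_delta: 0.093
bisulfite:
  fragments:
    - [-1007, -684]
    - [-534, -184]
  n_clones: 24
  conversion_efficiency: 0.995
  seq_error_rate: 0.001
mcrbc:
  fragments:
    - [-846, -651]
    - [-1411, -1229]
  n_molecules: 3000
  efficiency: 1.9
  ct_at_full_template: 25
  noise_sd: 0.15
  n_replicates: 3
  n_digestions: 2
expression:
  compare: [red, green]
  ref_gene: actin
  genes: {MYB10: 4.0, CHS: 2.5}
  n_replicates: 3
  noise_sd: 0.1
features:
  motif: CACATG
  both_strands: true
  window: [-1411, -555]
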