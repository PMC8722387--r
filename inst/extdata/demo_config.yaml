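# Demonstration screen: simulated selfing cross carrying one recessive
# missense allele, screened down to a single candidate.
seed: 2021
simulate:
  n_embryos_per_pool: 20
  n_background_variants: 500
  n_transcripts: 60
  depth_mean: 60
  depth_dispersion: 10
  seq_error_rate: 0.002
  residual_het_rate: 0.0003
  enu_het_rate: 0.1
screen:
  wt_min_total: 10
  mut_min_total: 5
  sib_min_each_allele: 4
  screen1_hom_fraction: 0.9
  nonsyn_mode: final
express:
  pseudo_count: 1
  top_n: 30
provenance:
  notes: >
    Synthetic data; emulates bubble-caller count tables (e.g. KisSplice
    k-mer 53 on Trinity assemblies). Recorded verbatim, never computed on.
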