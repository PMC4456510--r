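# Demo pipeline configuration: a short wild-type courtship.
duet:
  duration: 60
  sample_rate: 10000
  male_ipi_mean: 21.2
  male_ipi_sd: 1.9
  female_ipi_mean: 55.2
  female_ipi_sd: 26.3
  female_latency_mode: 409
  male_latency_mode: 110
  overlap_probability: 0.02
coupling:
  tarsal_lead_ms: 200
  lick_lead_ms: 50
  lick_female_lag_ms: 0
segmenter:
  n_freqs: 33
  pca_dims: 8
  gmm_components: 3
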