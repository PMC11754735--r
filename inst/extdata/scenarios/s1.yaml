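seed: 1
n_contigs: 2
contig_length_bp: 800000
n_genes: 200
gene_length_min: 2000
gene_length_max: 8000
isolation_bp: 6000
lambda_background: 0.01
lambda_body: 0.2
lambda_window: 2.0
window_offset_min: 500
window_offset_max: 2000
window_length_meanlog: 7.6009025
window_length_sdlog: 0.4
premature_fraction: 0.3
premature_length_meanlog: 7.3132204
premature_length_sdlog: 0.4
premature_margin_tss: 200
premature_margin_pas: 1000
n_replicates:
  A: 3
  B: 2
tss_peak_rate: 0.3
tss_peak_width: 150
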