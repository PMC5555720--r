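# Demo configuration for run_allelome_pipeline(): a small reciprocal-cross
# cohort with strain-biased and imprinted autosomal genes and a skewed-XCI
# X chromosome with planted escapers.
n_autosomal_genes: 500
n_x_genes: 80
frac_strain_biased: 0.05
frac_imprinted: 0.02
frac_escaper: 0.15
true_biased_ratio: 0.9
xci_skew_ratio: 0.7
xci_mode: random_skewed
mean_snps_per_gene: 10
frac_no_snp: 0.05
mean_coverage_per_snp: 50
overdispersion_rho: 0
n_replicates_per_cross: 2
seed: 1
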