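# chromforge default demo profile: ~20 Mb, 5-chromosome simulated genome.
# Keys and domains are documented in ?validate_config.
seed: 42
mode: simulate
n_chrom: 5
total_bp: 20000000
mshsb_frac: 0.3
n_inversions: 10
n_fissions: 2
n_fusions: 3
mean_scaffold_bp: 500000
min_scaffold_bp: 50000
chimera_rate: 0.05
p_chim_zero: 0.9
insert_mean: 3000
insert_sd: 300
cne_density_msHSB: 0.11
cne_density_background: 0.02
desert_halfwidth_intra: 19000
desert_halfwidth_fusion: 23000
desert_halfwidth_fission: 35000
spacing_bp: 400000
position_noise_sd: 0
resolution: 150000
min_block_bp: 5000
split_mean_bp: 60000
gap_bp: 200
threshold_c: calibrate
initial_threshold: 5
w_ref: 1
w_out: 1
w_read: 1
join_min: 2
window_bp: 1000
te_window_bp: 10000
min_mshsb_bp: 1500000
alpha: 0.05
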