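# Example pipeline configuration for `stress-vbm run --config ...`.
# Path keys point at the outputs of `stress-vbm simulate`.
samples: sim/cortisol.tsv
covariates: sim/covariates.tsv
gmv_dir: sim/gmv
atlas: sim/atlas.nii.gz
expression: sim/expression.tsv
out: results/

# analysis settings (defaults shown)
auc_variant: i        # Pruessner AUC variant: g (ground) or i (increase)
t_test: pooled        # pooled | welch
z_threshold: 3        # |z| outlier screen on the UHR CAR values
volume_floor_ul: 200  # saliva volume QC floor, microlitres
timing_tolerance_min: 15
fwhm_mm: 8            # Gaussian smoothing kernel FWHM
p_max: 0.01           # lenient threshold endpoint (uncorrected)
alpha: 0.05           # strict endpoint = alpha / in-mask voxels
spacing: linear       # linear | log steps over the p range
direction: pos        # CAR-correlation test direction
min_cluster_voxels: 1
seed: 1
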