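# radstab

Inter-observer stability analysis of radiomic features for pulmonary
nodules.

When several readers — or an automatic algorithm — segment the same lung
nodule on CT, their regions of interest (ROIs) disagree, and every
radiomic feature computed from those ROIs inherits that disagreement.
`radstab` measures how much. It couples three components:

1. **A synthetic study generator.** Spherical CT-like phantoms in the
   three clinical density classes (solid SN, part-solid pSN, pure
   ground-glass pGGN) with cohort-style diameters (log-normal, median
   0.56 cm, IQR 0.40 cm, truncated below 3 cm), segmented by simulated
   observers whose boundary errors are smooth Gaussian random fields in
   millimetres. Observer panels are calibrated by bisection to target
   mean Dice levels; ground-glass boundaries are made harder to trace in
   proportion to their contrast-to-noise ratio.
2. **A from-scratch 1,246-feature catalogue.** 18 first-order, 14 3D
   shape, 24 GLCM, 16 GLRLM, 16 GLSZM and 14 GLDM features on the
   original image (102), plus first-order + texture on five
   Laplacian-of-Gaussian scales (440) and eight undecimated 3D Coiflet-1
   wavelet sub-bands (704).
3. **Multi-rater agreement statistics.** Dice overlap
   $\mathrm{Dice}(A,B) = 2|A\cap B|/(|A|+|B|)$, Lin's concordance
   correlation coefficient, its multi-observer generalisation

   $$\mathrm{OCCC} = \frac{2\sum_{j<k} s_{jk}}
     {(J-1)\sum_j s_j^2 + \sum_{j<k}(m_j-m_k)^2},$$

   the two-way random-effects absolute-agreement ICC, and the standard
   stability classification: poor (OCCC < 0.5), average [0.5, 0.75),
   good [0.75, 0.90), very good (≥ 0.90). A feature with OCCC ≥ 0.75
   counts as stable.

`run_study()` chains them: generate → segment (J observers) → extract →
agree → one OCCC per feature across observers → classify → summarise,
fully deterministic given one master seed.

## Worked example

Extract the full catalogue from one phantom and check an observer's
overlap:

```r
library(radstab)

ph <- generate_phantom(phantom_spec("SN", diameter_mm = 10, seed = 7))
fv <- extract_all(ph$volume, ph$mask)
round(fv[c("original_firstorder_Mean", "original_shape_MeshVolume",
           "original_shape_Sphericity", "original_glcm_Contrast")], 3)
#>  original_firstorder_Mean original_shape_MeshVolume
#>                    61.155                   507.407
#> original_shape_Sphericity    original_glcm_Contrast
#>                     0.987                     1.439

obs <- simulate_observer_mask(ph$mask,
                              observer_profile("B", jitter_mm = 1,
                                               seed = 2),
                              nodule_seed = 7)
dice(obs, ph$mask)       # 0.845
estimate_diameter(ph$mask)  # 0.99 cm
```

The mean inside a solid nodule sits near its +60 HU attenuation (noise
raises it slightly here), the 10 mm sphere's mesh volume is close to
$\pi d^3/6 \approx 523.6$ mm³ with sphericity near 1, and the estimated
long/short-axis diameter recovers 1 cm.

A small end-to-end study (12 nodules, a reference reader plus three
calibrated observers):

```r
des <- study_design(n_nodules = 12,
                    observer_profiles = default_observer_profiles()[1:4],
                    grid_shape = c(48, 48, 32),
                    diameter_range_mm = c(3, 20), master_seed = 42)
sr <- run_study(des)
sr
#> <study_result> 12 nodules x 4 observers, 1246 features
#>   median DC 0.750; good-stability rate 61.0%
```

The median pairwise Dice of 0.75 says the simulated panel disagrees about
as much as trained readers do; the good-stability rate is the share of
the 1,246 features whose OCCC across observers is at least 0.75.
`stability_table(sr)` breaks that rate down by feature class,
`dc_table(sr)` gives per-observer median (IQR) Dice against the
reference by nodule type, `dc_diameter_analysis(sr)` the
diameter-versus-Dice correlation and slope, and
`subgroup_occc_comparison(sr, "wavelet_subband")` the Kruskal–Wallis /
Bonferroni comparison of stability between transform sub-bands.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/radstab run-all --n-nodules 5 --observers 7 \
    --seed 1 --out study_out
```

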