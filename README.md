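# PEThabitus

Simulation-based optimisation of [⁶⁸Ga]Ga-DOTA-TOC activity
administration for patient habitus in PET imaging.

## The problem

Somatostatin-receptor PET is commonly performed with 100–200 MBq of
[⁶⁸Ga]Ga-DOTA-TOC irrespective of patient size. Because 511 keV photon
attenuation grows exponentially with the tissue path and a fixed
activity is diluted over a larger body, heavy patients systematically
receive noisier images, and small liver metastases can drop below the
detectability threshold. PEThabitus is an R package for physicists and
imaging scientists who want to quantify that interaction and derive a
body-size-adapted prescription that delivers a *constant* liver
signal-to-noise ratio.

The package builds voxel code-image phantom cohorts spanning BMI
19–38 kg/m² with eight liver tumours each (0.15–8.09 mL), paints
SUV-based activity maps (`A_vox = A_inj · SUV_vox · V_vox / w_T`, with
⁶⁸Ga decay over the 60-min uptake), simulates a Poisson-noise PET
acquisition with attenuation (2-D parallel-beam stand-in for the full
Monte Carlo chain), reconstructs with OSEM (3 iterations × 16 subsets,
5.5/4 mm Gaussian post-filter), and measures NEMA-style image quality:

* liver SNR: `SNR_L = x̄_L / σ_L` over a 25 mm spherical VOI,
* tumour CNR: `CNR = (x̄_T − x̄_L) / σ_L`, Rose criterion `CNR ≥ 5`.

The core statistic is the normalised SNR,
`SNR_Norm = SNR_L / √(A_inj · t)`, fitted against candidate body-size
parameters p (weight, BMI, Du Bois BSA, abdominal circumference) as

```
SNR_Fit = a · p^(−d)
```

with the best parameter chosen by R². Inverting the fit yields the
constant-SNR administration protocol

```
A_inj = (1/t) · (SNR_Const / a)² · p^(2d)
```

which is compared against a fixed 100 MBq protocol and a weight-linear
2 MBq/kg protocol.

## A worked example

```r
library(PEThabitus)
cfg <- experimentConfig(masterSeed = 1L)   # 8 phantoms, desk-scale grid
ex  <- runExperiment(cfg)
ex$summary
```

```
  protocol median_SNR_L range_SNR_L n_rose_pass frac_rose_pass
1        i        10.33      10.273          56         0.8750
2       ii        14.18       8.479          59         0.9219
3      iii        15.34       4.359          63         0.9844
```

The simulator sensitivity is calibrated so the weight-linear protocol
(ii) has a cohort median liver SNR of 14.0; the fixed protocol (i) shows
the largest spread across habitus (range 10.3), and the constant-SNR
protocol (iii) centres the cohort near its target of 15 while shrinking
the range to 4.4 and lifting 63 of 64 tumours above the Rose criterion.

```r
ex$bestFit
#> PowerLawFit: SNR_Norm = 2.048e+04 * circumference^(-2.244), R^2 = 0.9645 (n = 8)

subset(ex$results, metric == "SNR_L" & protocol == "iii",
       select = c(phantom, A_inj_MBq, value))
#>  phantom A_inj_MBq value
#>       P1     73.71 15.88
#>       P2    114.23 14.96
#>       ...
#>       P8    410.55 14.79
```

Per-phantom prescriptions range from ~74 MBq for the lightest phantom to
~410 MBq for the heaviest — the price of equal image quality for a
120 kg patient. `vignettes/protocol-optimisation.Rmd` documents the
model chain, its calibrations and its limitations in full.

A thin command-line wrapper is provided at
`inst/scripts/run-experiment.R` (`--seed`, `--outdir`, optional YAML
`--config`), writing the result table as CSV and the fits as JSON.

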