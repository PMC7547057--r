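# petacdose

How low can the CT dose go before PET quantitation breaks?

In PET/CT, the CT scan supplies the attenuation-correction (AC) map — the
511-keV linear-attenuation volume (μ map) that every PET reconstruction
divides through. When the CT is acquired *only* for AC (gated studies,
serial biodistribution and dosimetry scans), its exposure should be driven
as low as possible — but the AC map must stay accurate, or every
standardised uptake value (SUV) in the study silently shifts.
`petacdose` implements, as a fully simulated and tested pipeline, a study
design for answering that question: acquire one PET emission dataset of an
anthropomorphic torso phantom, acquire CT at a grid of exposures
(15–50 mAs × 80–120 kVp × pitch 0.671/0.828), reconstruct each CT with both
filtered back projection (FBP) and iterative reconstruction (IR), and
reconstruct the *same* PET data once per AC map. Every test reconstruction
(TR) is then compared against the reference reconstruction (RR — the
50 mAs / 120 kVp / pitch 0.828 / IR protocol), by ROI statistics and voxel
by voxel.

## The statistics

For a circular 2-D ROI, the noise proxy is the SUV coefficient of
variation,

    SUV COV = SUV SD / SUV mean × 100,

and matched FBP/IR reconstructions of the same acquisition are compared by

    ΔCOV = COV(ROI in FBP) − COV(ROI in IR)

(positive ⇒ FBP noisier), summarised per region (min / median / mean / max)
with a two-sided paired *t* test.

The voxel analysis uses a fixed significance threshold, the
*quantitatively significant difference*:

    QSD = SD(liver ROI of the RR),

about 4% of the liver mean in the physical study. For each TR the pipeline
reports the paired-*t* p value over all support voxels, the percentage of
voxels with |RR − TR| > QSD (strict), the maximum and mean voxel difference
as a percentage of the RR value, a binary significance mask, and the
spatial enrichment of masked voxels in high-activity regions, attenuation
interfaces and the beam-hardening corridor.

## The simulator

Since the physical phantom and scanner are not available, the package ships
a calibrated desk-scale surrogate:

* a parametric torso phantom (soft tissue SUV 1.0, heart 4.0, liver 2.5,
  17-mm lung tumour 4.0, air-filled lungs, spine, two arm-like lateral
  attenuators), rasterized exactly onto a PET grid and a finer CT grid;
* a CT model with dose-scaled correlated noise (SD ∝ CTDI^−1/2), a
  voltage-dependent beam-hardening artifact, and an IR surrogate
  (edge-preserving smoothing, dose-dependent resolution loss, and a
  negative CT-number bias at very low dose — the mechanism reproducing the
  observed IR under-correction at low exposure);
* a CTDI model calibrated to the scanner-reported dose table;
* the standard bilinear HU → μ(511 keV) conversion; and
* a per-slice parallel-beam PET simulator with Poisson counting noise and
  an attenuation-weighted OSEM reconstruction (3 iterations × 3 subsets by
  default). One emission sinogram is generated per study and shared by all
  48 reconstructions, exactly as one physical acquisition would be.

Real co-registered volumes can be analysed instead of simulated ones via
`analyze_external()` (NIfTI in, CSV/NIfTI out).

## Worked example

```r
library(petacdose)
# coarse desk-scale grid: full 512 x 512 x 160 mm field of view at 8 x 8 x 10 mm
spec <- phantom_spec(shape = c(64, 64, 16), spacing = c(8, 8, 10))
bundle <- generate_study(spec, seed = 1)   # 48 reconstructions, ~40 s

rois <- default_rois(spec)
qsd <- compute_qsd(bundle$reference, rois$liver)
cat(sprintf("QSD = %.3f SUV (%.1f%% of the reference liver mean)\n",
            qsd$value, 100 * qsd$value / qsd$liver_mean))
#> QSD = 0.130 SUV (5.2% of the reference liver mean)

vt <- voxel_table(bundle, qsd, support = bundle$labels > 0)
tab <- vt$table
tab[tab$ctdi_mGy == 0.3, c("mAs", "kVp", "pitch", "algorithm", "ctdi_mGy",
                           "pct_gt_qsd", "mean_diff_pct", "p")]
#>    mAs kVp pitch algorithm ctdi_mGy pct_gt_qsd mean_diff_pct p
#> 1   15  80 0.671       FBP      0.3       0.00         -1.30 0
#> 13  15  80 0.828       FBP      0.3       0.00         -1.30 0
#> 25  15  80 0.671        IR      0.3       9.32          5.96 0
#> 37  15  80 0.828        IR      0.3       9.29          5.95 0
```

At the lowest exposure the IR-based AC maps push ~9% of body voxels beyond
the QSD and underestimate voxel SUV by ~6% on average, while FBP-based AC
stays within the threshold everywhere — the central finding of the design:
very low dose CT is adequate for AC, but at the lowest exposures FBP-based
AC is quantitatively safer than IR, and above ~1 mGy the two agree.

## The analysis workflow

The numbered drivers under `analysis/` run the full study at the default
resolution (128 × 128 × 40 PET voxels at 4 mm, 2-mm CT; `--fast` switches
to the coarse grid):

```sh
Rscript analysis/01_simulate.R --seed 1   # phantom + 48 reconstructions -> results/study/
Rscript analysis/02_roi_analysis.R        # ROI stats, delta-COV table   -> results/tables/
Rscript analysis/03_voxel_analysis.R      # QSD, voxel table, masks      -> results/tables,masks/
Rscript analysis/04_figures.R             # SUV/COV/exceedance vs dose   -> results/figures/
```

## Scope

The vendor CT/PET reconstruction algorithms are out of scope and are
replaced by generic, explicitly parameterised surrogates; scatter, randoms,
decay and point-spread corrections are omitted (orthogonal to the AC
question); geometry is slice-stacked parallel-beam rather than helical/TOF.
See the methods vignette (`vignettes/petacdose-methods.Rmd`) for the model,
its calibration and its limitations.
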