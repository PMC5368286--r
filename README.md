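# masct — multi-atlas synthetic CT generation and evaluation

`masct` is an R toolkit for MRI-only radiotherapy planning research. It
generates a synthetic CT (sCT) from MR images by **multi-atlas
registration and locally-weighted fusion**, builds the classical **bulk
density assignment** baseline, and evaluates both against a reference CT
with the field's standard geometric and dosimetric metrics. A seeded
digital-phantom generator and a density-sensitive toy dose model make the
entire workflow runnable end-to-end without any clinical data.

## The method

Given a test subject's MR and a database of intra-subject-aligned MR/CT
pairs:

1. **Registration.** Each atlas MR is aligned to the subject MR by a
   robust affine initialization (center-of-mass + translation multi-start,
   Nelder–Mead over translation/rotation/scale) followed by a
   multi-resolution cubic B-spline free-form deformation maximizing
   normalized mutual information, NMI = (H(A)+H(B))/H(A,B), with analytic
   gradients and a bending-energy penalty.
2. **Fusion.** Atlas CTs are warped into subject space and fused with
   spatially-varying weights: at every voxel, atlases are ranked by the
   local normalized cross-correlation (LNCC, Gaussian window σ = 3 mm)
   between the subject MR and the mapped atlas MR, and weight
   ∝ exp(−β·rank) goes to the top-k atlases,

   sCT_a(x) = Σ_j w_j(x) · CT_j(x),  Σ_j w_j(x) = 1.

3. **Refinement.** Each iteration re-registers every atlas (CT + MR
   channels) to the current (sCT, subject MR) multi-channel pair and
   re-fuses with a similarity that mixes LNCC(sCT, mapped CT) and
   LNCC(MR, mapped MR).

The baseline sCT_bda assigns class densities — bone 1.53 g/cm³ (head &
neck) or 1.22 g/cm³ (prostate), air 0.001, remaining body water — and
converts them to HU through a piecewise-linear calibration anchored at
(0.001 → −1000), (1.0 → 0), (1.53 → 883).

Evaluation: MAE = (1/N) Σ |sCT − CT| over the external, bone
(CT > 150 HU, closed + hole-filled) and soft-tissue (CT > −150 HU minus
bone) regions within the MRI FOV; volume index
VI = (V(ref) − V(eval))/V(ref) + 1 and Dice 2|A∩B|/(|A|+|B|) for
contours; 3-D **local gamma** at 3%/3 mm and 2%/2 mm with pass rate
%(γ ≤ 1); cumulative DVH with D98%, Dmean, D2% and signed percentage
point differences (PPD) against the CT-based dose.

## Worked example

```r
library(masct)

cfg <- run_config(spec = phantom_spec("head_neck_like"),
                  n_atlases = 10, n_refine = 1, seed = 1)
report <- run_full_comparison(cfg)
report$geometry
```

On the standard 32³ (3 mm) head-and-neck-style phantom with 10 deformed
atlases this prints (seed 1):

```
     sct metric      region       value
   sct_a    MAE    external  32.1
   sct_a    MAE        bone  61.7
   sct_a    MAE soft_tissue  29.4
   sct_a     VI        bone   0.879
   sct_a    DSC        bone   0.791
 sct_bda    MAE    external  59.4
 sct_bda    MAE        bone 188.2
 sct_bda    MAE soft_tissue  51.1
 sct_bda     VI        bone   1.221
 sct_bda    DSC        bone   0.876
```

Reading it: the multi-atlas sCT halves the external/soft-tissue error and
cuts the bone error threefold relative to bulk assignment, whose single
bone HU cannot follow marrow and cortical variation. Bone contours from
the atlas sCT come out slightly **larger** than the CT truth (VI < 1,
fusion blur) while bulk-assignment contours come out **smaller** (VI > 1)
— the same directional signature reported in clinical comparisons. Both
methods keep DVH point differences within a fraction of a percent and
local gamma pass rates at 100% under the toy dose model's four-field
geometry. `report$dose` holds the gamma and DVH rows.

A thin CLI wraps the same functions
(`inst/cli/masct.R phantom|synthesize|bulk|eval-geom|gamma|dvh|full`):

```sh
Rscript inst/cli/masct.R full --out run1 --seed 11 --n-atlases 10 --iters 1
```

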