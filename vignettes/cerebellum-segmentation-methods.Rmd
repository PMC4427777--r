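---
title: "Automated cerebellum segmentation: models, parameters and validation"
author: "cerebseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated cerebellum segmentation: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Delineating the cerebellum on a T1-weighted MR volume is harder than its
clear anatomical identity suggests. Three neighbouring structures share its
intensity range: the brain stem, which connects to it through the cerebellar
peduncle with no intensity boundary at all; the cerebellar peduncle itself,
indistinguishable from cerebellar white matter; and the venous sinuses,
blood-filled dural channels separated from the cerebellar surface only by a
sheet of cerebrospinal fluid (CSF) often thinner than a voxel. Deformable
models leak across these weak boundaries and template-based labelling is
defeated by the high anatomical variability of the cerebellar surface, so
both tend to either include the sinuses and peduncle or carve away true
cerebellar tissue.

`cerebseg` implements a sequential, fully automated pipeline that attacks
each confound with the tool suited to it:

1. **Candidate A** — subtract the cerebral region from the skull-stripped
   brain mask. Everything that remains (cerebellum, brain stem, peduncle,
   sinuses, local CSF) is the approximate cerebellar region.
2. **CSF-partial-volume trimming** — threshold the CSF fraction map (voxels
   whose CSF fraction reaches `csfThreshold` are removed), then erode with a
   ball of radius `trimRadius`. The thin CSF sheet between cerebellum and
   sinuses is mostly-CSF at voxel resolution, so thresholding severs it and
   the erosion widens the cut.
3. **Candidate B** — keep the largest connected component (the cerebellum
   with its attached stem; the sinus remnant is now a separate island) and
   restore it toward its original size by dilating with the same ball used
   for the erosion.
4. **Brain-stem removal** — intensity cannot separate stem and peduncle
   from cerebellum, but location can: a brain-stem + peduncle mask drawn in
   template space is aligned to the subject and masked out, followed by a
   morphological opening (radius `openingRadius`) and a final
   largest-component pass so the output remains a single structure.

Accuracy is evaluated against ground truth with the Dice similarity index
`2|Vm ∩ Va| / (|Vm| + |Va|)`, precision `|Vm ∩ Va| / |Va|` and recall
`|Vm ∩ Va| / |Vm|`, where `Vm` is the reference cerebellum and `Va` the
automatic result; method comparisons across cases use a two-sided paired
t-test (`pairedTTest()`, a thin wrapper over `stats::t.test`).

## Tunable parameters

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `csfThreshold` | 0.5 | CSF fraction | majority-fraction convention: a voxel that is mostly CSF is not tissue |
| `trimRadius` | 2 | voxels (mm at the working grid) | severs residual sinus bridges up to ~3 voxels wide; shared by the restoring dilation so "restore to original size" is an erosion/dilation pair with one kernel |
| `openingRadius` | 1 | voxels | removes the voxel-scale debris left where the atlas mask cut through, without reshaping the cerebellar surface |
| `connectivity` | 26 | — | the most permissive 3-D adjacency; avoids fragmenting thin midline structure |
| `polyOrder` (bias fit) | 3 | total degree | order 2 generates the phantom fields; one extra order absorbs mild model mismatch without chasing anatomy |

All pipeline stages operate on a common 1 mm isotropic grid; inputs on other
grids are resampled on load (`resampleToGrid()`, trilinear for intensities,
nearest-neighbour for masks and labels).

## Surrogate preprocessing and its design

The pipeline consumes a bias-corrected volume, a three-class tissue
labelling and a CSF fraction map. The package provides deterministic,
self-contained surrogates for the heavyweight external tools a production
neuroimaging stack would use:

* **Bias correction** (`correctInhomogeneity`): the slowly varying
  multiplicative field is modelled as `exp` of a 3-D polynomial and fitted
  to log-intensities. A naive whole-brain fit absorbs genuine tissue layout
  (where white matter happens to sit) into the "bias" and distorts the
  intensity modes, so the fit is anchored on the dominant intensity mode
  (grey matter in a T1 brain): only voxels near that mode enter, a MAD
  criterion discards outliers, and the selection window narrows over three
  to five passes as the running correction sharpens the mode. The fit uses
  the brain mask eroded by one voxel, because edge voxels mixing with
  background masquerade as spatial structure. The output times the
  estimated field reproduces the input exactly, and the mean brain
  intensity is preserved.
* **Brain extraction** (`extractBrainMask`): Otsu threshold, ball-radius-2
  closing, largest 26-connected component, hole filling. This produces a
  plausible skull-stripped mask; in the phantom validation the pipeline
  receives the ground-truth brain mask as input, as a cortical pipeline
  would supply one.
* **Tissue classification** (`classifyTissue`): a three-component Gaussian
  mixture over brain intensities, with two robustness devices that matter
  on partial-volume data. Initialisation takes the three most prominent,
  mutually separated modes of a smoothed histogram (quantile-based
  initialisation collapses when one class dominates, as grey matter does at
  ~80% of brain voxels). A fourth, uniform "outlier" component over the
  intensity range absorbs the plateaus of interface voxels between the
  modes; without it, EM drags the white-matter component toward the
  grey–white mixing plateau and the fitted means are badly biased. Labels
  are the maximum posterior over the three Gaussians only, so every brain
  voxel receives a tissue class. The fit runs on the eroded brain mask and,
  above 200000 voxels, on an evenly strided subsample; labelling always
  uses all voxels. Everything is deterministic.
* **Partial-volume estimation** (`estimatePVE`): linear two-class mixing
  between adjacent fitted class means — CSF↔GM and GM↔WM only, never
  CSF↔WM. The pipeline consumes only the thresholded CSF fraction, and at
  a CSF/GM interface the linear model is exact for volume-averaged
  intensities, which makes this surrogate both sufficient and directly
  testable against the phantom's analytic ground truth.

## Registration

The template-space stem mask is brought into subject space by a
nine-parameter affine (three translations, rotations, scales) minimising the
mean squared intensity difference, initialised by centre-of-mass translation
and second-moment scaling, optimised by greedy coordinate descent with step
halving, coarse to fine over 4/2/1 mm sampling grids (at most 20000 fixed
sample points above 5% of the fixed maximum). This replaces nonlinear
registration deliberately: the atlas mask is used only as a cut-out region
whose boundary is immediately smoothed by the opening, so the mechanism —
not millimetric boundary placement — is what must be right, and an affine
is exactly recoverable and deterministic. A nonlinear backend could be
slotted in behind `alignAtlas()` without touching the pipeline contract.
Warped masks are resampled nearest-neighbour, so the output stays binary.

## The synthetic phantom

No external dataset is required: `generatePhantom()` builds a
skull-stripped head from analytic primitives with exact ground truth —
ellipsoidal cerebrum and cerebellum (outer grey shell, inner white core), a
vertical cylindrical brain stem, a horizontal cylindrical peduncle bridging
stem and cerebellum, a CSF sheet wrapping the cerebellum, and a curved
venous-sinus slab behind it, separated from the cerebellar surface by at
least `csfSheetThickness` voxels of CSF everywhere. Default tissue means
are CSF 40, GM 100, WM 150 and sinus 95 (arbitrary units): the sinus sits
within 10% of grey matter precisely to reproduce the intensity confound the
pipeline exists to solve. Partial-volume ground truth comes from
evaluating the labels on a 3× supersampled grid and averaging 3×3×3 blocks,
so fraction maps are exact by construction; the T1 image is the
volume-averaged label intensity times a random quadratic bias field (mean
1, peak deviation `biasAmplitude`) plus i.i.d. Gaussian noise. Defaults
(`noiseSigma = 3`, `biasAmplitude = 0.1`) are mild, typical-scanner values;
the validation conditions below set them explicitly. Label and fraction
fields depend only on the geometry parameters and are memoised, so
multi-seed studies pay the anatomy cost once.

The phantom-derived atlas (`phantomAtlas()`) uses the ideal noise- and
bias-free rendering as template and the true stem + peduncle dilated by one
voxel as the stem mask, emulating the deliberately generous manual
delineation of a template atlas. That one-voxel generosity is what makes
stem removal trade a little recall for a large precision gain, the
direction of effect reported for template-based stem removal.

What the phantom does **not** emulate: cortical folding, gyral/sulcal CSF
topology, Rician noise statistics, k-space artefacts, and the anatomical
variability of real cerebella. Passing the phantom validation therefore
demonstrates that the pipeline's mechanisms work as designed on geometry
that contains the stated confounds — not that real-data accuracy figures
carry over.

## Numerical choices and degenerate inputs

* Morphology follows the definitional contracts exactly: outside the grid
  is background for both erosion and dilation (so the erosion–dilation
  duality holds only away from borders, which the tests pad for);
  components are labelled in decreasing size with ties broken by the
  smallest minimum raster index, making every labelling deterministic.
  The compiled kernels are checked bit-for-bit against brute-force
  definitional implementations.
* Empty masks are errors, not zeros: an empty segmentation or reference is
  a pipeline failure and the metrics refuse to score it; pipeline stages
  raise errors naming the stage.
* EM uses a variance floor (0.5 intensity units) so noiseless point masses
  cannot collapse a component, and a relative log-likelihood tolerance of
  1e-6 with a 200-iteration cap.
* Geometry equality between combined volumes is affine agreement within a
  relative 1e-4 — tight enough to catch real mismatches, loose enough to
  absorb float round-trips through NIfTI headers.
* Tissue means must be strictly ordered CSF < GM < WM; unordered fits and
  sub-minimum grids (below 48³) are rejected at validation time.

## Validation design and problem sizes

The test suite validates each module against independent oracles (shifted
array re-implementations for morphology, a voxel-loop for the metrics,
closed-form cases for partial-volume mixing and the paired t-test) and the
pipeline end to end on phantoms: a noiseless 128³ reference case (seed 42)
and ten noisy cases (noise sd 5, bias amplitude 0.1, seeds 1–10). On these
conditions the pipeline reaches Dice ≈ 0.99 (noiseless) and ≥ 0.98 on every
noisy seed, and brain-stem removal raises Dice (≈ 0.90 → 0.99) and
precision (≈ 0.82 → 1.00) while lowering recall (≈ 0.99 → 0.98) on 10/10
seeds — the same direction of effect that motivates template-based stem
removal on real data, where the magnitudes are smaller. Unit tests run on
48³–64³ phantoms, where every mechanism is already exercised, to keep the
default test run fast. `scripts/acceptance.R` reproduces the 128³ study
from scratch and writes all of these quantities as JSON.

## Known limitations

* The affine registration assumes the subject and template share gross
  brain shape; strongly deformed anatomy would need the nonlinear backend
  the operation contract anticipates.
* The GM-anchored bias fit assumes a dominant tissue mode; it degrades
  gracefully (toward no correction) when the histogram has no clear mode.
* The linear partial-volume model ignores noise within mixed voxels; at
  high noise the CSF fraction map becomes conservative near interfaces.
* Phantom realism bounds what the validation can claim (see above); the
  pipeline's numeric accuracy on real T1 data must be established against
  manual delineations.
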