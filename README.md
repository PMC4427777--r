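# cerebseg

Fully automated segmentation of the cerebellum from T1-weighted brain MR
volumes, for researchers who need cerebellar volumes or a cerebellar
reference region (e.g. for PET intensity normalisation) without manual
delineation.

The cerebellum's neighbours defeat purely intensity-driven methods: the
brain stem joins it through the cerebellar peduncle with no intensity
boundary, and the venous sinuses match grey matter intensity and are
separated from the cerebellar surface by a CSF sheet thinner than a voxel.
`cerebseg` combines tissue classification, mathematical morphology and a
template-based mask, in sequence:

1. **Candidate A** = brain mask ∖ cerebral mask — the approximate
   cerebellar region;
2. **CSF-PVE trim** — remove voxels whose CSF partial-volume fraction
   reaches 0.5, then erode with a radius-2 ball: this severs the thin CSF
   sheet toward the sinuses;
3. **Candidate B** — keep the largest 26-connected component (the sinus
   remnant is now a separate island) and dilate with the same ball to
   restore the original size;
4. **Brain-stem removal** — affinely align a brain-stem + peduncle atlas
   mask to the subject, mask it out, apply a radius-1 morphological opening
   and keep the largest component.

Results are scored against a reference delineation *Vm* versus the
automatic result *Va* with

* Dice similarity index `2|Vm ∩ Va| / (|Vm| + |Va|)`,
* precision `|Vm ∩ Va| / |Va|`, recall `|Vm ∩ Va| / |Vm|`,

and per-case metric sequences are compared with a two-sided paired t-test.

The package is self-validating: a synthetic 3-D head phantom generator
(`generatePhantom()`) builds skull-stripped heads with exact ground truth —
cerebrum, cerebellum, brain-stem/peduncle bridge, and venous sinuses behind
a thin CSF sheet at grey-matter-like intensity — so the whole pipeline is
exercised end to end without any external dataset.

## Worked example

```r
library(cerebseg)

cfg   <- phantomConfig(gridShape = 64, noiseSigma = 3, biasAmplitude = 0.1, seed = 7)
case  <- generatePhantom(cfg)          # T1 + ground-truth labels/PVE/bias
atlas <- phantomAtlas(cfg)             # template + stem mask in "template" space

res <- segmentCerebellum(case@t1, brainMask(case), cerebralMask(case), atlas)
res
#> SegmentationResult
#>              stage voxels
#>        candidate_a  15331
#>  trim_with_csf_pve   3865
#>        candidate_b   6894
#>        align_atlas   2127
#>              final   5633

evaluateOverlap(cerebellumMask(case), res@final)
#> EvalReport: |Vm|=5970 |Va|=5633 |Vm n Va|=5621
#>   dice 0.9689  precision 0.9979  recall 0.9415
```

The stage log tells the pipeline's story: candidate A (15331 voxels) holds
cerebellum plus stem, peduncle, sinuses and local CSF; the CSF trim cuts it
to 3865; the restoring dilation yields candidate B (6894), which still
contains the stem; masking the aligned atlas (2127 voxels) and opening
leaves the final cerebellum (5633). Against ground truth the final mask
reaches Dice 0.97; before stem removal candidate B scores Dice 0.92, so the
atlas step trades a little recall (0.94 here) for near-perfect precision
(0.998) — the motivation for template-based stem removal.

## Command line

```sh
cerebseg phantom  --seed 7 --out case/                 # write a phantom case
cerebseg segment  --t1 case/t1.nii.gz --brain-mask brain.nii.gz \
                  --cerebral-mask cerebral.nii.gz --atlas-dir atlas/ \
                  --out result/
cerebseg evaluate --ref truth.nii.gz --seg result/final.nii.gz --out report.json
```

The script lives at `inst/cli/cerebseg` (on the path
`system.file("cli", "cerebseg", package = "cerebseg")` after installation);
every command writes a `manifest.json` with input hashes, seeds and
per-stage voxel counts, and reruns are bit-identical.

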