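## Central S4 classes. All gridded objects share one geometry contract:
## a 3-D array plus a 4x4 voxel(0-based)->world-mm affine (NIfTI sform,
## RAS+ world axes). Spacing is derived from the affine, never stored twice.

.checkGrid <- function(object) {
    msg <- character(0)
    d <- dim(object@data)
    if (length(d) != 3L)
        msg <- c(msg, sprintf("data must be a 3-D array, got %d dimension(s)",
                              length(d)))
    if (any(d < 1L)) msg <- c(msg, "all grid axes must have length >= 1")
    a <- object@affine
    if (!is.matrix(a) || !all(dim(a) == c(4L, 4L)))
        msg <- c(msg, "affine must be a 4x4 matrix")
    else {
        if (max(abs(a[4, ] - c(0, 0, 0, 1))) > 1e-8)
            msg <- c(msg, "last affine row must be (0,0,0,1)")
        if (abs(det(a[1:3, 1:3])) < 1e-12)
            msg <- c(msg, "affine must be invertible")
        else if (any(sqrt(colSums(a[1:3, 1:3]^2)) <= 0))
            msg <- c(msg, "voxel spacing must be strictly positive")
    }
    if (length(msg)) msg else TRUE
}

#' @title Gridded 3-D image (virtual base)
#' @description Virtual parent of [Volume-class] and [BinaryMask-class];
#'   carries the data array and the voxel-to-world affine.
#' @slot data 3-D array.
#' @slot affine 4x4 voxel-index (0-based) to world-mm matrix.
#' @name ImageGrid-class
#' @keywords internal
setClass("ImageGrid",
         representation("VIRTUAL", data = "array", affine = "matrix"),
         validity = .checkGrid)

#' Scalar 3-D volume
#'
#' A 3-D scalar grid with geometry and a declared role. `"intensity"` carries
#' MR intensities (arbitrary units), `"fraction"` carries partial-volume
#' fractions constrained to \[0, 1\], `"bias"` carries a multiplicative bias
#' field, `"label"` carries integer anatomical labels.
#'
#' @slot data 3-D numeric array.
#' @slot affine 4x4 voxel-to-world matrix (NIfTI sform convention).
#' @slot role one of `"intensity"`, `"fraction"`, `"bias"`, `"label"`.
#' @seealso [volume()], [readVolume()], [writeVolume()]
#' @export
setClass("Volume", contains = "ImageGrid",
         representation(role = "character"),
         validity = function(object) {
             msg <- character(0)
             if (length(object@role) != 1L ||
                 !object@role %in% c("intensity", "fraction", "bias", "label"))
                 msg <- c(msg, "role must be one of intensity/fraction/bias/label")
             else if (object@role == "fraction") {
                 r <- range(object@data)
                 if (r[1] < -1e-9 || r[2] > 1 + 1e-9)
                     msg <- c(msg, "fraction volumes must lie in [0, 1]")
             }
             if (length(msg)) msg else TRUE
         })

#' Binary 3-D mask
#'
#' A boolean grid on the same geometry contract as [Volume-class]; used for
#' brain masks, cerebral masks, segmentation candidates A/B, atlas masks and
#' final segmentations.
#'
#' @slot data 3-D logical array.
#' @slot affine 4x4 voxel-to-world matrix.
#' @seealso [binaryMask()], [erodeMask()], [connectedComponents()]
#' @export
setClass("BinaryMask", contains = "ImageGrid",
         validity = function(object) {
             if (!is.logical(object@data))
                 "mask data must be logical (foreground/background only)"
             else if (anyNA(object@data))
                 "mask data must not contain NA"
             else TRUE
         })

#' Structuring element for 3-D binary morphology
#'
#' The voxel-offset kernel of erosion/dilation: all integer offsets within a
#' Euclidean ball of the generating radius. Always contains the origin and is
#' symmetric under negation.
#'
#' @slot offsets integer matrix, one row per offset (x, y, z).
#' @slot radius generating ball radius in voxels.
#' @seealso [ballElement()]
#' @export
setClass("StructuringElement",
         representation(offsets = "matrix", radius = "numeric"),
         validity = function(object) {
             o <- object@offsets
             msg <- character(0)
             if (!is.matrix(o) || ncol(o) != 3L || !is.numeric(o) ||
                 any(o != round(o)))
                 msg <- c(msg, "offsets must be an integer n x 3 matrix")
             else {
                 key <- function(m) paste(m[, 1], m[, 2], m[, 3])
                 if (!"0 0 0" %in% key(o))
                     msg <- c(msg, "structuring element must contain the origin")
                 if (!all(key(-o) %in% key(o)))
                     msg <- c(msg, "structuring element must be symmetric under negation")
             }
             if (length(msg)) msg else TRUE
         })

#' Partial-volume fraction maps
#'
#' Per-voxel CSF, GM and WM fractions on a shared geometry. Inside the brain
#' mask used at estimation time the three fractions sum to 1; outside they
#' are all 0.
#'
#' @slot csf,gm,wm fraction [Volume-class]s on identical geometry.
#' @seealso [estimatePVE()]
#' @export
setClass("PVEMaps", representation(csf = "Volume", gm = "Volume", wm = "Volume"),
         validity = function(object) {
             msg <- character(0)
             for (s in c("csf", "gm", "wm"))
                 if (slot(object, s)@role != "fraction")
                     msg <- c(msg, sprintf("%s must have role 'fraction'", s))
             if (!.sameGeom(object@csf, object@gm) ||
                 !.sameGeom(object@csf, object@wm))
                 msg <- c(msg, "fraction maps must share one geometry")
             else {
                 s <- object@csf@data + object@gm@data + object@wm@data
                 if (!all(s < 1e-6 | abs(s - 1) < 1e-4))
                     msg <- c(msg, "fractions must sum to 1 on brain voxels and 0 outside")
             }
             if (length(msg)) msg else TRUE
         })

#' Discrete tissue classification
#'
#' Voxelwise labels over background(0)/CSF(1)/GM(2)/WM(3) with the fitted
#' class intensity means and standard deviations (ordered CSF < GM < WM).
#'
#' @slot data 3-D integer array of codes 0-3.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot classMeans,classSds named numeric length-3 vectors (csf, gm, wm).
#' @seealso [classifyTissue()]
#' @export
setClass("TissueLabels", contains = "ImageGrid",
         representation(classMeans = "numeric", classSds = "numeric"),
         validity = function(object) {
             msg <- character(0)
             if (!all(object@data %in% 0:3))
                 msg <- c(msg, "labels must be codes 0 (background) to 3 (WM)")
             if (length(object@classMeans) != 3L ||
                 any(diff(object@classMeans) <= 0))
                 msg <- c(msg, "class means must be strictly increasing CSF < GM < WM")
             if (length(object@classSds) != 3L || any(object@classSds <= 0))
                 msg <- c(msg, "class sds must be positive")
             if (length(msg)) msg else TRUE
         })

#' Phantom generator configuration
#'
#' Parameters of the synthetic skull-stripped head phantom. Tissue means are
#' in arbitrary T1-like units and must be ordered CSF < GM < WM; the sinus
#' mean sits close to GM on purpose (the intensity confound the pipeline is
#' built to resolve).
#'
#' @slot gridShape integer length-3, voxels per axis (all >= 48).
#' @slot tissueMeans named numeric: `csf`, `gm`, `wm`, `sinus`.
#' @slot noiseSigma additive Gaussian noise standard deviation (intensity units).
#' @slot biasAmplitude peak multiplicative deviation of the bias field from 1,
#'   in \[0, 0.5\].
#' @slot csfSheetThickness minimum CSF gap (voxels) between sinus and cerebellum.
#' @slot peduncleRadius radius (voxels) of the cerebellar-peduncle bridge.
#' @slot seed integer seed driving bias and noise.
#' @seealso [phantomConfig()], [generatePhantom()]
#' @export
setClass("PhantomConfig",
         representation(gridShape = "integer", tissueMeans = "numeric",
                        noiseSigma = "numeric", biasAmplitude = "numeric",
                        csfSheetThickness = "numeric", peduncleRadius = "numeric",
                        seed = "integer"),
         validity = function(object) {
             msg <- character(0)
             if (length(object@gridShape) != 3L || any(object@gridShape < 48L))
                 msg <- c(msg, "gridShape must be three integers, each >= 48")
             tm <- object@tissueMeans
             if (!all(c("csf", "gm", "wm", "sinus") %in% names(tm)))
                 msg <- c(msg, "tissueMeans must name csf, gm, wm, sinus")
             else if (!(tm["csf"] < tm["gm"] && tm["gm"] < tm["wm"]))
                 msg <- c(msg, "tissue means must be ordered CSF < GM < WM")
             if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
             if (object@biasAmplitude < 0 || object@biasAmplitude > 0.5)
                 msg <- c(msg, "biasAmplitude must lie in [0, 0.5]")
             if (object@csfSheetThickness < 1)
                 msg <- c(msg, "csfSheetThickness must be >= 1 voxel")
             if (object@peduncleRadius < 2)
                 msg <- c(msg, "peduncleRadius must be >= 2 voxels")
             if (length(msg)) msg else TRUE
         })

#' Generated phantom case
#'
#' A synthetic T1 volume with exact ground truth: the anatomical label grid,
#' true partial-volume maps, the applied bias field, the generating
#' configuration and the pose transform applied so far (identity unless
#' [perturbPose()] was used).
#'
#' @slot t1 intensity [Volume-class].
#' @slot labels label [Volume-class] with codes from [phantomLabels()].
#' @slot pve ground-truth [PVEMaps-class].
#' @slot bias bias-field [Volume-class].
#' @slot config the [PhantomConfig-class] used.
#' @slot pose 4x4 world-to-world matrix recording applied pose perturbations.
#' @seealso [generatePhantom()]
#' @export
setClass("PhantomCase",
         representation(t1 = "Volume", labels = "Volume", pve = "PVEMaps",
                        bias = "Volume", config = "PhantomConfig",
                        pose = "matrix"))

#' World-to-world affine transform
#'
#' Homogeneous 4x4 transform in mm, mapping moving-image world coordinates
#' into fixed-image world coordinates.
#'
#' @slot matrix 4x4 matrix, last row (0,0,0,1); the 3x3 block must have a
#'   determinant in \[0.3, 3\] (sanity bound on overall scale).
#' @seealso [registerAffine()], [applyTransform()]
#' @export
setClass("AffineTransform", representation(matrix = "matrix"),
         validity = function(object) {
             m <- object@matrix
             msg <- character(0)
             if (!all(dim(m) == c(4L, 4L)))
                 msg <- c(msg, "transform must be a 4x4 matrix")
             else {
                 if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-8)
                     msg <- c(msg, "last row must be (0,0,0,1)")
                 d <- det(m[1:3, 1:3])
                 if (!is.finite(d) || d < 0.3 || d > 3)
                     msg <- c(msg, sprintf(
                         "3x3 block determinant %.3g outside sanity bound [0.3, 3]", d))
             }
             if (length(msg)) msg else TRUE
         })

#' Brain-stem atlas
#'
#' A template intensity volume together with the brain-stem + cerebellar
#' peduncle mask delineated in the same (template) space. The mask must be a
#' single 26-connected component.
#'
#' @slot template intensity [Volume-class] in template space.
#' @slot stemMask [BinaryMask-class] on the template geometry.
#' @seealso [alignAtlas()], [phantomAtlas()]
#' @export
setClass("BrainStemAtlas",
         representation(template = "Volume", stemMask = "BinaryMask"),
         validity = function(object) {
             msg <- character(0)
             if (!.sameGeom(object@template, object@stemMask))
                 msg <- c(msg, "stemMask geometry must match the template")
             if (!any(object@stemMask@data))
                 msg <- c(msg, "stemMask must be nonempty")
             else {
                 lab <- morph_label(as.vector(object@stemMask@data),
                                    dim(object@stemMask@data),
                                    .connOffsets(26L))
                 if (max(lab) != 1L)
                     msg <- c(msg, "stemMask must be a single 26-connected component")
             }
             if (length(msg)) msg else TRUE
         })

#' Segmentation pipeline configuration
#'
#' Tunable parameters of the cerebellum-segmentation pipeline. Defaults:
#' CSF-fraction threshold 0.5 (majority-fraction convention), trim
#' erosion/dilation ball radius 2 (severs sinus bridges up to ~3 voxels wide
#' at 1 mm), final opening radius 1, 26-connectivity, brain-stem removal on.
#'
#' @slot csfThreshold CSF partial-volume threshold, strictly in (0, 1).
#' @slot trimRadius structuring-element ball radius (voxels) for the
#'   trim erosion and the restoring dilation.
#' @slot openingRadius ball radius (voxels) of the final opening.
#' @slot connectivity 6, 18 or 26.
#' @slot removeBrainstem logical; run the atlas-based brain-stem removal.
#' @seealso [pipelineConfig()], [segmentCerebellum()]
#' @export
setClass("PipelineConfig",
         representation(csfThreshold = "numeric", trimRadius = "integer",
                        openingRadius = "integer", connectivity = "integer",
                        removeBrainstem = "logical"),
         validity = function(object) {
             msg <- character(0)
             if (object@csfThreshold <= 0 || object@csfThreshold >= 1)
                 msg <- c(msg, "csfThreshold must lie strictly in (0, 1)")
             if (object@trimRadius < 1L || object@openingRadius < 1L)
                 msg <- c(msg, "structuring-element radii must be >= 1")
             if (!object@connectivity %in% c(6L, 18L, 26L))
                 msg <- c(msg, "connectivity must be 6, 18 or 26")
             if (length(msg)) msg else TRUE
         })

#' Segmentation result
#'
#' All intermediate masks of a [segmentCerebellum()] run plus the stage log
#' (ordered voxel counts per stage).
#'
#' @slot candidateA brain mask minus cerebral mask.
#' @slot candidateB PVE-trimmed largest component restored by dilation.
#' @slot brainstem warped atlas mask in subject space (empty when brain-stem
#'   removal is off).
#' @slot final the final cerebellum mask.
#' @slot config the [PipelineConfig-class] used.
#' @slot stageLog data.frame with columns `stage` and `voxels`.
#' @export
setClass("SegmentationResult",
         representation(candidateA = "BinaryMask", candidateB = "BinaryMask",
                        brainstem = "BinaryMask", final = "BinaryMask",
                        config = "PipelineConfig", stageLog = "data.frame"))

#' Overlap evaluation report
#'
#' Voxel counts and the derived Dice, precision and recall for one
#' reference/segmentation pair.
#'
#' @slot nRef reference foreground count (Vm).
#' @slot nSeg segmentation foreground count (Va).
#' @slot nIntersect shared foreground count.
#' @slot dice 2|Vm n Va| / (|Vm| + |Va|).
#' @slot precision |Vm n Va| / |Va|.
#' @slot recall |Vm n Va| / |Vm|.
#' @seealso [evaluateOverlap()]
#' @export
setClass("EvalReport",
         representation(nRef = "numeric", nSeg = "numeric",
                        nIntersect = "numeric", dice = "numeric",
                        precision = "numeric", recall = "numeric"),
         validity = function(object) {
             msg <- character(0)
             if (object@nIntersect > min(object@nRef, object@nSeg))
                 msg <- c(msg, "intersection cannot exceed either mask")
             if (abs(object@dice -
                     2 * object@nIntersect / (object@nRef + object@nSeg)) > 1e-12)
                 msg <- c(msg, "dice must equal 2|A n B|/(|A|+|B|)")
             if (length(msg)) msg else TRUE
         })

#' Paired t-test summary
#'
#' Two-sided paired t-test on per-case metric differences, computed via
#' [stats::t.test()].
#'
#' @slot meanDiff mean of a - b.
#' @slot statistic t statistic.
#' @slot pValue two-sided p value.
#' @slot n number of pairs.
#' @seealso [pairedTTest()]
#' @export
setClass("PairedTestResult",
         representation(meanDiff = "numeric", statistic = "numeric",
                        pValue = "numeric", n = "integer"),
         validity = function(object) {
             msg <- character(0)
             if (object@pValue < 0 || object@pValue > 1)
                 msg <- c(msg, "p value must lie in [0, 1]")
             if (object@n < 2L) msg <- c(msg, "need at least 2 pairs")
             if (length(msg)) msg else TRUE
         })
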