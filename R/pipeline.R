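## The cerebellum-segmentation algorithm proper. Stage order is fixed:
## bias correction -> tissue classification -> PVE -> candidate A (brain
## minus cerebrum) -> CSF-PVE threshold + erosion -> largest component +
## restoring dilation (candidate B) -> atlas-based brain-stem removal with
## a final opening and largest-component pass.

#' Pipeline configuration
#'
#' @param csfThreshold CSF partial-volume threshold in (0, 1); voxels whose
#'   CSF fraction reaches it are removed before the trim erosion. Default
#'   0.5, the majority-fraction convention.
#' @param trimRadius ball radius (voxels) shared by the trim erosion and the
#'   restoring dilation; default 2, enough to sever a sinus bridge up to
#'   about 3 voxels wide at 1 mm resolution.
#' @param openingRadius ball radius of the final opening; default 1.
#' @param connectivity component-analysis adjacency (6/18/26); default 26,
#'   the most permissive, which avoids fragmenting thin cerebellar structure.
#' @param removeBrainstem run the atlas-based brain-stem removal stage.
#' @return A validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(csfThreshold = 0.5, trimRadius = 2L,
                           openingRadius = 1L, connectivity = 26L,
                           removeBrainstem = TRUE) {
    new("PipelineConfig", csfThreshold = as.numeric(csfThreshold),
        trimRadius = as.integer(trimRadius),
        openingRadius = as.integer(openingRadius),
        connectivity = as.integer(connectivity),
        removeBrainstem = isTRUE(removeBrainstem))
}

#' Cerebellar region candidate A
#'
#' The approximate cerebellar region: brain mask minus the cerebral mask.
#' An empty result is returned (not an error); downstream stages raise.
#'
#' @param brain,cerebral [BinaryMask-class]s on matching geometry.
#' @return A [BinaryMask-class].
#' @export
candidateA <- function(brain, cerebral) {
    stopifnot(is(brain, "BinaryMask"), is(cerebral, "BinaryMask"))
    .stopGeom(brain, cerebral, "brain and cerebral masks")
    .maskLike(brain@data & !cerebral@data, brain)
}

#' CSF-partial-volume trimming
#'
#' Removes candidate-A voxels whose CSF fraction reaches the threshold
#' (severing the thin CSF sheet toward the venous sinuses), then erodes with
#' the trim ball. The result is a subset of the input.
#'
#' @param candA candidate-A [BinaryMask-class].
#' @param csfPve CSF fraction [Volume-class] on the same geometry.
#' @param config a [PipelineConfig-class].
#' @return The trimmed [BinaryMask-class].
#' @export
trimWithCSF <- function(candA, csfPve, config = pipelineConfig()) {
    stopifnot(is(candA, "BinaryMask"), is(csfPve, "Volume"))
    if (csfPve@role != "fraction")
        stop("csfPve must be a fraction volume", call. = FALSE)
    .stopGeom(candA, csfPve, "candidate A and CSF map")
    validObject(config)
    kept <- .maskLike(candA@data & csfPve@data < config@csfThreshold, candA)
    erodeMask(kept, ballElement(config@trimRadius))
}

#' Cerebellar region candidate B
#'
#' Selects the largest connected component of the trimmed mask as the true
#' positive cerebellar region and restores it toward its original size by
#' dilating with the same ball used for the trim erosion.
#'
#' @param trimmed nonempty trimmed [BinaryMask-class].
#' @param config a [PipelineConfig-class].
#' @return A [BinaryMask-class].
#' @export
candidateB <- function(trimmed, config = pipelineConfig()) {
    stopifnot(is(trimmed, "BinaryMask"))
    if (!any(trimmed@data))
        stop("pipeline stage 'candidate_b': trimmed mask is empty",
             call. = FALSE)
    core <- largestComponent(trimmed, config@connectivity)
    dilateMask(core, ballElement(config@trimRadius))
}

#' Brain-stem and peduncle removal
#'
#' Masks the warped atlas stem region out of candidate B, opens the result
#' to remove noise introduced by the masking, and keeps the largest
#' component so the output remains a single structure. The output is
#' disjoint from the stem mask.
#'
#' @param candB candidate-B [BinaryMask-class].
#' @param stem warped brain-stem [BinaryMask-class] in subject space.
#' @param config a [PipelineConfig-class].
#' @return The final cerebellum [BinaryMask-class].
#' @export
removeBrainstem <- function(candB, stem, config = pipelineConfig()) {
    stopifnot(is(candB, "BinaryMask"), is(stem, "BinaryMask"))
    .stopGeom(candB, stem, "candidate B and stem mask")
    masked <- .maskLike(candB@data & !stem@data, candB)
    if (!any(masked@data))
        stop("pipeline stage 'remove_brainstem': nothing left after stem masking",
             call. = FALSE)
    opened <- openMask(masked, ballElement(config@openingRadius))
    if (!any(opened@data))
        stop("pipeline stage 'remove_brainstem': opening removed all voxels",
             call. = FALSE)
    largestComponent(opened, config@connectivity)
}

#' Fully automated cerebellum segmentation
#'
#' Runs the complete pipeline on a T1 volume: polynomial bias correction,
#' Gaussian-mixture tissue classification, linear partial-volume estimation,
#' candidate A (brain minus cerebrum), CSF-PVE trimming, candidate B
#' (largest component + restoring dilation), affine atlas alignment and
#' brain-stem removal with a final opening. Deterministic for fixed inputs
#' and configuration.
#'
#' @param t1 intensity [Volume-class].
#' @param brain skull-stripped brain [BinaryMask-class].
#' @param cerebral cerebral-region [BinaryMask-class] (e.g. from a cortical
#'   surface, or [cerebralMask()] on phantoms).
#' @param atlas a [BrainStemAtlas-class]; may be `NULL` when
#'   `config@removeBrainstem` is `FALSE`.
#' @param config a [PipelineConfig-class].
#' @param seed integer seed forwarded to [classifyTissue()].
#' @param regControl settings from [registrationControl()].
#' @return A [SegmentationResult-class].
#' @export
segmentCerebellum <- function(t1, brain, cerebral, atlas = NULL,
                              config = pipelineConfig(), seed = 1L,
                              regControl = registrationControl()) {
    stopifnot(is(t1, "Volume"), is(brain, "BinaryMask"),
              is(cerebral, "BinaryMask"))
    validObject(config)
    if (config@removeBrainstem && !is(atlas, "BrainStemAtlas"))
        stop("a BrainStemAtlas is required when removeBrainstem is on",
             call. = FALSE)
    log <- list()
    note <- function(stage, mask) log[[length(log) + 1L]] <<-
        data.frame(stage = stage, voxels = sum(mask@data))

    stage <- "correct_inhomogeneity"
    res <- tryCatch({
        corrected <- correctInhomogeneity(t1, brain)$volume
        stage <- "classify_tissue"
        labels <- classifyTissue(corrected, brain, seed = seed)
        stage <- "estimate_pve"
        pve <- estimatePVE(corrected, labels)
        stage <- "candidate_a"
        candA <- candidateA(brain, cerebral)
        note("candidate_a", candA)
        stage <- "trim_with_csf_pve"
        trimmed <- trimWithCSF(candA, pve@csf, config)
        note("trim_with_csf_pve", trimmed)
        stage <- "candidate_b"
        candB <- candidateB(trimmed, config)
        note("candidate_b", candB)
        if (config@removeBrainstem) {
            stage <- "align_atlas"
            stem <- alignAtlas(atlas, corrected, regControl)
            note("align_atlas", stem)
            stage <- "remove_brainstem"
            final <- removeBrainstem(candB, stem, config)
        } else {
            stem <- .maskLike(array(FALSE, dim(candB@data)), candB)
            final <- candB
        }
        note("final", final)
        list(candA = candA, candB = candB, stem = stem, final = final)
    }, error = function(e) {
        stop(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), call. = FALSE)
    })
    new("SegmentationResult", candidateA = res$candA, candidateB = res$candB,
        brainstem = res$stem, final = res$final, config = config,
        stageLog = do.call(rbind, log))
}

setMethod("show", "SegmentationResult", function(object) {
    cat("SegmentationResult\n")
    print(object@stageLog, row.names = FALSE)
})
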