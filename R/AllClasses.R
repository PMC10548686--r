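#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowRanges
#' @importFrom S4Vectors DataFrame metadata mcols
#' @importFrom GenomicRanges GRanges seqnames start findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom stats approx cor cov integrate lm lm.fit mad median na.omit
#'   pchisq pgamma pnorm pt qchisq qnorm quantile rbinom rnorm runif sd setNames
#'   var complete.cases model.matrix coef vcov optim ks.test varimax rexp
#' @importFrom utils head write.table read.table
NULL

#' Two-study CSF-biomarker GWAS cohort
#'
#' `CsfCohort` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' SNPs are rows: the `"DS"` assay holds imputed effect-allele dosages in
#' \[0, 2\] (hemizygous male X genotypes coded 0/2), and `rowRanges()` carries
#' per-variant metadata (`snp`, `ref`, `alt`, `eaf`, `impQuality`). Samples are
#' columns: `colData()` holds `sex` (female = 1), `age`, five genetic-ancestry
#' components (`ancestry1..5`), `study`, the ordinal `diagnosis`
#' (control < MCI < AD) and the six-column CSF `biomarkers` matrix (missing
#' values allowed). For simulated cohorts, `metadata()$truth` retains the
#' generating configuration so downstream tests can compare against known
#' parameter values.
#'
#' @export
setClass("CsfCohort", contains = "RangedSummarizedExperiment")

.DIAG_LEVELS <- c("control", "MCI", "AD")
.MARKERS <- c("tau", "pTau", "Abeta", "NfL", "YKL40", "Ng")

setValidity("CsfCohort", function(object) {
    msg <- character()
    if (!"DS" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'DS' (dosages) is required")
    else {
        ds <- SummarizedExperiment::assay(object, "DS")
        if (any(ds < -1e-8 | ds > 2 + 1e-8, na.rm = TRUE))
            msg <- c(msg, "dosages must lie in [0, 2]")
    }
    cd <- SummarizedExperiment::colData(object)
    for (f in c("sex", "study", "diagnosis"))
        if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", f))
    if ("sex" %in% colnames(cd) && !all(cd$sex %in% c(0, 1)))
        msg <- c(msg, "sex must be coded 0 (male) / 1 (female)")
    if ("diagnosis" %in% colnames(cd)) {
        d <- cd$diagnosis
        if (anyNA(d) || !all(as.character(d) %in% .DIAG_LEVELS))
            msg <- c(msg, "diagnosis must be defined for all samples as control/MCI/AD")
    }
    if ("biomarkers" %in% colnames(cd) && ncol(cd$biomarkers) != 6L)
        msg <- c(msg, "biomarkers must have six columns")
    if (length(msg)) msg else TRUE
})

#' Rotated principal-component model of the biomarker panel
#'
#' Holds the varimax-rotated loading matrix (structure coefficients:
#' correlations between markers and rotated components), per-component
#' variance explained, the completed (imputed) data matrix the model was
#' fitted on, the frozen scoring weights, and rotation metadata. Created by
#' [fitVarimaxPCA()]; scores for the same or new data come from
#' [computeScores()], which never refits the model.
#'
#' @slot loadings 6 x k rotated loading matrix.
#' @slot varianceExplained k-vector, column sums of squared loadings / 6.
#' @slot k integer component count.
#' @slot rotation list with the varimax rotation matrix and Kaiser flag.
#' @slot center,scale column means / sds of the training matrix.
#' @slot corMatrix marker correlation matrix of the training data.
#' @slot imputed completed n x 6 training matrix.
#' @slot scoreMethod "regression" or "bartlett".
#' @slot markerNames the six marker labels.
#' @slot componentNames component labels with interpretation tags.
#' @export
setClass("PCModel", representation(
    loadings = "matrix",
    varianceExplained = "numeric",
    k = "integer",
    rotation = "list",
    center = "numeric",
    scale = "numeric",
    corMatrix = "matrix",
    imputed = "matrix",
    scoreMethod = "character",
    markerNames = "character",
    componentNames = "character"
))

setValidity("PCModel", function(object) {
    msg <- character()
    if (ncol(object@loadings) != object@k)
        msg <- c(msg, "loadings must have k columns")
    if (length(object@varianceExplained) != object@k)
        msg <- c(msg, "varianceExplained must have length k")
    if (sum(object@varianceExplained) > 1 + 1e-8)
        msg <- c(msg, "variance explained cannot exceed 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CsfCohort", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("CsfCohort: %d SNPs x %d samples\n", nrow(object), ncol(object)))
    cat(sprintf("  studies: %s\n", paste(levels(factor(cd$study)), collapse = ", ")))
    cat(sprintf("  diagnosis: %s\n",
        paste(sprintf("%s=%d", .DIAG_LEVELS, tabulate(factor(cd$diagnosis, .DIAG_LEVELS), 3L)),
              collapse = ", ")))
    if ("biomarkers" %in% colnames(cd)) {
        bm <- cd$biomarkers
        cat(sprintf("  biomarkers: %d markers, %.1f%% missing\n",
                    ncol(bm), 100 * mean(is.na(bm))))
    }
    if (!is.null(S4Vectors::metadata(object)$truth))
        cat("  truth: simulation parameters attached\n")
    invisible(NULL)
})

setMethod("show", "PCModel", function(object) {
    cat(sprintf("PCModel: %d markers, %d varimax-rotated components (%s scores)\n",
                nrow(object@loadings), object@k, object@scoreMethod))
    print(round(object@loadings, 2))
    cat("Variance explained:",
        paste(sprintf("%.2f", object@varianceExplained), collapse = " "),
        sprintf(" (total %.2f)\n", sum(object@varianceExplained)))
    invisible(NULL)
})
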