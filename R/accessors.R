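#' Accessors for CsfCohort objects
#'
#' @param x A [CsfCohort-class] object.
#' @return `dosages()` returns the samples x SNPs dosage matrix (note the
#'   transpose of the internal SNPs-by-samples assay, convenient for
#'   regression); `snpInfo()` a data.frame of per-variant metadata;
#'   `sampleData()` the colData as a data.frame; `biomarkers()` the n x 6
#'   biomarker matrix with NAs for missing cells; `diagnosis()` the ordered
#'   factor; `truthParams()` the simulation configuration or NULL.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
dosages <- function(x) t(SummarizedExperiment::assay(x, "DS"))

#' @rdname cohort-accessors
#' @export
snpInfo <- function(x) {
    gr <- SummarizedExperiment::rowRanges(x)
    data.frame(
        snp = names(gr),
        chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = GenomicRanges::start(gr),
        as.data.frame(S4Vectors::mcols(gr)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname cohort-accessors
#' @export
sampleData <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    as.data.frame(cd[, setdiff(colnames(cd), "biomarkers"), drop = FALSE])
}

#' @rdname cohort-accessors
#' @export
biomarkers <- function(x) {
    bm <- SummarizedExperiment::colData(x)$biomarkers
    rownames(bm) <- colnames(x)
    bm
}

#' @rdname cohort-accessors
#' @export
diagnosis <- function(x)
    factor(SummarizedExperiment::colData(x)$diagnosis, .DIAG_LEVELS, ordered = TRUE)

#' @rdname cohort-accessors
#' @export
truthParams <- function(x) S4Vectors::metadata(x)$truth

#' @rdname cohort-accessors
#' @export
loadings <- function(x) {
    stopifnot(is(x, "PCModel"))
    x@loadings
}

#' @rdname cohort-accessors
#' @export
varianceExplained <- function(x) {
    stopifnot(is(x, "PCModel"))
    x@varianceExplained
}

#' @rdname cohort-accessors
#' @export
imputedMatrix <- function(x) {
    stopifnot(is(x, "PCModel"))
    x@imputed
}
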