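#' Rank-based inverse normal transformation within groups
#'
#' Replaces each non-missing value by the normal quantile of its Blom-offset
#' rank, `qnorm((rank - 3/8) / (n + 1/4))`, separately within each group
#' (here: study), with ties receiving average ranks. This removes skewness and
#' any monotone per-group assay differences, and z-standardizes the scale
#' across studies. Missing values stay missing.
#'
#' @param x numeric vector, NAs allowed.
#' @param group group labels (one transform per group); NULL for a single
#'   group.
#' @param offset rank offset; 3/8 is Blom's.
#' @return numeric vector of the same length.
#' @export
inverseNormalTransform <- function(x, group = NULL, offset = 3/8) {
    if (is.null(group)) group <- rep("all", length(x))
    group <- as.character(group)
    out <- rep(NA_real_, length(x))
    for (g in unique(group)) {
        idx <- which(group == g & !is.na(x))
        if (length(idx) < 2L)
            stop(sprintf("group '%s' has fewer than 2 non-missing values", g))
        r <- rank(x[idx], ties.method = "average")
        out[idx] <- qnorm((r - offset) / (length(idx) - 2 * offset + 1))
    }
    out
}

#' Transform a biomarker panel column-wise within studies
#'
#' Applies [inverseNormalTransform()] to each marker column within each study.
#'
#' @param bm n x 6 biomarker matrix (NAs allowed).
#' @param group per-sample study labels.
#' @return matrix of the same shape.
#' @export
transformPanel <- function(bm, group = NULL) {
    out <- bm
    for (j in seq_len(ncol(bm)))
        out[, j] <- inverseNormalTransform(bm[, j], group)
    out
}
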