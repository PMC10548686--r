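# Cross-study combination of association records: allele harmonization and
# inverse-variance fixed- / random-effects meta-analysis.

.flipAllele <- function(a) chartr("ACGT", "TGCA", a)

.isAmbiguous <- function(ea, oa) {
    (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize effect alleles between two association records
#'
#' Both records must describe the same variant (same chrom:pos). If the
#' second record's effect allele is the first's other allele, its beta sign
#' is flipped and its frequency complemented. Strand-ambiguous (A/T, C/G)
#' variants with frequency in (0.4, 0.6) are dropped with a warning, since
#' their orientation cannot be resolved; incompatible allele sets are dropped
#' too. Applying the operation twice returns the original orientation.
#'
#' @param recA,recB single-row data.frames with `effect_allele`,
#'   `other_allele`, `beta`, and optionally `eaf`.
#' @return list(a, b) with `b` aligned to `a`, or NULL if the variant must be
#'   excluded.
#' @export
harmonizeAlleles <- function(recA, recB) {
    ea <- recA$effect_allele; oa <- recA$other_allele
    if (.isAmbiguous(ea, oa) && !is.null(recA$eaf) &&
        recA$eaf > 0.4 && recA$eaf < 0.6) {
        warning("strand-ambiguous variant with intermediate frequency dropped")
        return(NULL)
    }
    bset <- c(recB$effect_allele, recB$other_allele)
    if (setequal(bset, c(ea, oa))) {
        # same strand
    } else if (setequal(.flipAllele(bset), c(ea, oa))) {
        recB$effect_allele <- .flipAllele(recB$effect_allele)
        recB$other_allele <- .flipAllele(recB$other_allele)
    } else {
        warning("incompatible allele sets; variant excluded")
        return(NULL)
    }
    if (recB$effect_allele == oa) {
        tmp <- recB$effect_allele
        recB$effect_allele <- recB$other_allele
        recB$other_allele <- tmp
        recB$beta <- -recB$beta
        if (!is.null(recB$eaf)) recB$eaf <- 1 - recB$eaf
    }
    list(a = recA, b = recB)
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Weights are the reciprocal squared standard errors; the combined standard
#' error is `1 / sqrt(sum(w))` and the p-value two-sided normal.
#'
#' @param beta,se per-study estimates and standard errors.
#' @param n optional per-study sample sizes (summed into `nTotal`).
#' @return one-row data.frame: beta, se, p, q (Cochran heterogeneity
#'   statistic), tau2 (0 for fixed), method, nStudies, nTotal.
#' @export
fixedEffectMeta <- function(beta, se, n = NULL) {
    ok <- is.finite(beta) & is.finite(se)
    beta <- beta[ok]; se <- se[ok]
    if (length(beta) < 1L) stop("at least one record with finite SE required")
    if (any(se <= 0)) stop("standard errors must be positive")
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    s <- 1 / sqrt(sum(w))
    q <- sum(w * (beta - b)^2)
    data.frame(beta = b, se = s, p = 2 * pnorm(-abs(b / s)),
               q = q, tau2 = 0, method = "fixed",
               nStudies = length(beta),
               nTotal = if (is.null(n)) NA_integer_ else sum(n[ok]))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' The between-study variance is
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))` with fixed-effect
#' weights `w`; studies are then re-weighted by `1 / (se^2 + tau2)`. With a
#' single study the function falls back to the fixed-effect estimate with a
#' warning.
#'
#' @inheritParams fixedEffectMeta
#' @return one-row data.frame as in [fixedEffectMeta()] with
#'   `method = "random"`.
#' @export
randomEffectsMeta <- function(beta, se, n = NULL) {
    ok <- is.finite(beta) & is.finite(se)
    beta <- beta[ok]; se <- se[ok]
    if (length(beta) < 2L) {
        warning("fewer than 2 studies; falling back to fixed effect")
        return(fixedEffectMeta(beta, se, n))
    }
    if (any(se <= 0)) stop("standard errors must be positive")
    w <- 1 / se^2
    bF <- sum(w * beta) / sum(w)
    q <- sum(w * (beta - bF)^2)
    df <- length(beta) - 1L
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (se^2 + tau2)
    b <- sum(wr * beta) / sum(wr)
    s <- 1 / sqrt(sum(wr))
    data.frame(beta = b, se = s, p = 2 * pnorm(-abs(b / s)),
               q = q, tau2 = tau2, method = "random",
               nStudies = length(beta),
               nTotal = if (is.null(n)) NA_integer_ else sum(n[ok]))
}

#' Meta-analyze per-study association tables
#'
#' Joins two or more [runGwas()]-style tables by SNP, harmonizes alleles
#' against the first study, and combines each variant by inverse-variance
#' weighting.
#'
#' @param tables list of association data.frames (columns snp, beta, se, n,
#'   and optionally effect_allele/other_allele/eaf).
#' @param method "fixed" or "random".
#' @return data.frame with one row per SNP present in all tables.
#' @export
metaAnalyze <- function(tables, method = c("fixed", "random")) {
    method <- match.arg(method)
    fun <- if (method == "fixed") fixedEffectMeta else randomEffectsMeta
    common <- Reduce(intersect, lapply(tables, function(t) t$snp))
    rows <- lapply(common, function(s) {
        recs <- lapply(tables, function(t) t[t$snp == s, , drop = FALSE])
        a <- recs[[1L]]
        if (!is.null(a$effect_allele)) {
            for (i in seq_along(recs)[-1L]) {
                h <- harmonizeAlleles(a, recs[[i]])
                if (is.null(h)) return(NULL)
                recs[[i]] <- h$b
            }
        }
        beta <- vapply(recs, function(r) r$beta, 0)
        se <- vapply(recs, function(r) r$se, 0)
        n <- vapply(recs, function(r) if (is.null(r$n)) NA_real_
                    else as.numeric(r$n), 0)
        out <- fun(beta, se, n)
        cbind(a[, intersect(c("snp", "chrom", "pos", "effect_allele",
                              "other_allele", "eaf", "model", "outcome"),
                            names(a)), drop = FALSE],
              out, row.names = NULL)
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    rownames(out) <- NULL
    out
}

#' Read/write METAL-style summary statistics
#'
#' Tab-delimited files with columns MarkerName, Allele1, Allele2, Freq1,
#' Effect, StdErr, P-value, N plus Model and Outcome tags.
#'
#' @param assoc association data.frame from [runGwas()] or [metaAnalyze()].
#' @param path file path.
#' @name metal-io
#' @export
writeMetal <- function(assoc, path) {
    out <- data.frame(
        MarkerName = assoc$snp,
        Allele1 = if (is.null(assoc$effect_allele)) NA else assoc$effect_allele,
        Allele2 = if (is.null(assoc$other_allele)) NA else assoc$other_allele,
        Freq1 = if (is.null(assoc$eaf)) NA else assoc$eaf,
        Effect = assoc$beta,
        StdErr = assoc$se,
        `P-value` = assoc$p,
        N = assoc$n,
        Model = if (is.null(assoc$model)) NA else assoc$model,
        Outcome = if (is.null(assoc$outcome)) NA else assoc$outcome,
        check.names = FALSE)
    data.table::fwrite(out, path, sep = "\t")
    invisible(path)
}

#' @rdname metal-io
#' @param path file path.
#' @export
readMetal <- function(path) {
    x <- data.table::fread(path, sep = "\t", data.table = FALSE)
    data.frame(snp = x$MarkerName, effect_allele = x$Allele1,
               other_allele = x$Allele2, eaf = x$Freq1, beta = x$Effect,
               se = x$StdErr, p = x[["P-value"]], n = x$N,
               model = x$Model, outcome = x$Outcome,
               stringsAsFactors = FALSE)
}
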