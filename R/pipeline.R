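# End-to-end orchestration: transform -> component selection -> imputation ->
# rotated PCA -> scores -> sex-mean tests -> per-study GWAS -> meta ->
# gene tests -> independent hits -> mediation, with a per-stage log.

#' Pipeline run configuration
#'
#' Significance constants follow standard practice for this design: 5e-8
#' genome-wide, 1e-6 suggestive, 0.05/6 for the six mediation/direct
#' pathways, 0.05/5 for the five per-PC sex-mean tests.
#'
#' @param models association models to run.
#' @param k fixed component count, or NULL to select by cross-validation.
#' @param thresholds QC thresholds, see [qcThresholds()].
#' @param snpAlpha,suggestiveAlpha,mediationAlpha,sexAlpha significance
#'   constants.
#' @param r2Max LD ceiling for independent-hit selection.
#' @param bootstrapB mediation bootstrap replicates.
#' @param seed integer seed for all stochastic stages.
#' @param outDir optional output directory for [writeReport()].
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(models = c("main", "male", "female", "interaction"),
                      k = 5L, thresholds = qcThresholds(),
                      snpAlpha = 5e-8, suggestiveAlpha = 1e-6,
                      mediationAlpha = 0.05 / 6, sexAlpha = 0.05 / 5,
                      r2Max = 0.6, bootstrapB = 1000L, seed = 1L,
                      outDir = NULL) {
    models <- match.arg(models, several.ok = TRUE)
    stopifnot(snpAlpha > 0, snpAlpha < 1, mediationAlpha > 0,
              mediationAlpha < 1, sexAlpha > 0, sexAlpha < 1)
    structure(list(models = models, k = k, thresholds = thresholds,
                   snpAlpha = snpAlpha, suggestiveAlpha = suggestiveAlpha,
                   mediationAlpha = mediationAlpha, sexAlpha = sexAlpha,
                   r2Max = r2Max, bootstrapB = as.integer(bootstrapB),
                   seed = as.integer(seed), outDir = outDir),
              class = "RunConfig")
}

#' Per-PC sex mean-difference test
#'
#' OLS of each PC score on sex (female = 1), adjusted for the covariates and
#' for diagnostic status via MCI/AD dummy coding; flagged significant at
#' `alpha` (default 0.05/5).
#'
#' @param scores n x k PC score matrix.
#' @param sex 0/1 vector.
#' @param diagnosisF ordered control/MCI/AD factor (dummy-coded internally;
#'   required).
#' @param covariates additional covariates (age, ancestry, study) or NULL.
#' @param alpha significance level after the per-PC Bonferroni split.
#' @return data.frame with one row per PC: estimate, se, p, significant.
#' @export
sexMeanTest <- function(scores, sex, diagnosisF, covariates = NULL,
                        alpha = 0.05 / 5) {
    if (missing(diagnosisF) || is.null(diagnosisF))
        stop("diagnosis dummies are required covariates of the sex-mean test")
    if (length(unique(sex)) < 2L) stop("both sexes must be present")
    scores <- as.matrix(scores)
    d <- factor(diagnosisF, ordered = FALSE)
    dm <- model.matrix(~ d)[, -1L, drop = FALSE]
    Cov <- if (is.null(covariates)) dm
    else cbind(dm, model.matrix(~ ., as.data.frame(covariates))[, -1L,
                                                                drop = FALSE])
    X <- cbind(`(Intercept)` = 1, sex = sex, Cov)
    XtXi <- chol2inv(chol(crossprod(X)))
    res <- lapply(seq_len(ncol(scores)), function(j) {
        y <- scores[, j]
        cf <- drop(XtXi %*% crossprod(X, y))
        rss <- sum((y - drop(X %*% cf))^2)
        df <- length(y) - ncol(X)
        se <- sqrt(rss / df * diag(XtXi))
        tv <- cf[2L] / se[2L]
        data.frame(component = colnames(scores)[j], estimate = cf[2L],
                   se = se[2L], p = 2 * pt(-abs(tv), df))
    })
    out <- do.call(rbind, res)
    out$significant <- out$p < alpha
    rownames(out) <- NULL
    out
}

.stageLog <- function(log, stage, ...) {
    entry <- sprintf(...)
    message(sprintf("[%s] %s", stage, entry))
    c(log, setNames(entry, stage))
}

#' Run the full multivariate GWAS pipeline on a cohort
#'
#' Stages: per-study inverse normal transform of the six biomarkers;
#' component-count selection by cell-wise CV (unless `config$k` is fixed);
#' regularized iterative-PCA imputation; varimax-rotated PCA and frozen
#' regression scores; per-PC sex-mean tests; QC filtering; per-study GWAS
#' for every requested model and PC; inverse-variance fixed-effect
#' meta-analysis across studies; gene-based tests (when an annotation is
#' given); greedy selection of independent genome-wide significant SNPs; and
#' the mediation model for every independent hit. Any stage error halts the
#' run with the stage name.
#'
#' @param cohort a [CsfCohort-class].
#' @param config a [runConfig()].
#' @param genes optional gene annotation data.frame
#'   (gene, chrom, start, end; 1-based inclusive).
#' @return list bundle: pcModel, scores, sexTable, assoc (per-study),
#'   meta (per model x PC), lambda table, genes, hits, mediation, log,
#'   provenance.
#' @export
runPipeline <- function(cohort, config = runConfig(), genes = NULL) {
    stopifnot(is(cohort, "CsfCohort"), inherits(config, "RunConfig"))
    set.seed(config$seed)
    log <- character()
    sdat <- sampleData(cohort)
    bm <- biomarkers(cohort)

    log <- .stageLog(log, "transform", "INT of %d x %d biomarker cells (%d missing)",
                     nrow(bm), ncol(bm), sum(is.na(bm)))
    z <- transformPanel(bm, sdat$study)

    k <- config$k
    cvCurve <- NULL
    if (is.null(k)) {
        sel <- selectNComponents(z, kMax = ncol(bm) - 1L)
        k <- max(sel$k, 1L)
        cvCurve <- sel$cv
        log <- .stageLog(log, "select_k", "cross-validation selected k = %d", k)
    }
    xc <- if (anyNA(z)) imputeIterativePCA(z, k) else z
    log <- .stageLog(log, "impute", "completed matrix with k = %d", k)
    pcModel <- fitVarimaxPCA(xc, k)
    scores <- computeScores(pcModel)
    log <- .stageLog(log, "pca", "variance explained %.2f",
                     sum(varianceExplained(pcModel)))

    sexTable <- sexMeanTest(scores, sdat$sex, sdat$diagnosis,
                            covariates = data.frame(
                                age = sdat$age, study = sdat$study,
                                sdat[, grep("^ancestry", names(sdat)),
                                     drop = FALSE]),
                            alpha = config$sexAlpha)

    qc <- qcFilter(cohort, config$thresholds)
    log <- .stageLog(log, "qc", "%d of %d SNPs pass QC", length(qc$keep),
                     nrow(cohort))
    G <- dosages(cohort)[, qc$keep, drop = FALSE]
    info <- snpInfo(cohort)
    info <- info[match(qc$keep, info$snp), ]
    infoAssoc <- data.frame(snp = info$snp, chrom = info$chrom,
                            pos = info$pos, effect_allele = info$alt,
                            other_allele = info$ref, eaf = info$eaf)

    studies <- levels(factor(sdat$study))
    ancNames <- grep("^ancestry", names(sdat), value = TRUE)
    assoc <- list(); meta <- list(); lambdas <- NULL
    for (mod in config$models) {
        for (pc in colnames(scores)) {
            perStudy <- lapply(studies, function(s) {
                idx <- sdat$study == s
                covs <- data.frame(age = sdat$age[idx],
                                   sdat[idx, ancNames, drop = FALSE])
                runGwas(G[idx, , drop = FALSE], scores[idx, pc],
                        covariates = covs, model = mod,
                        sex = sdat$sex[idx], snpInfo = infoAssoc,
                        outcomeName = pc, study = s)
            })
            names(perStudy) <- studies
            assoc[[paste(mod, pc, sep = ".")]] <- perStudy
            mt <- if (length(perStudy) > 1L) metaAnalyze(perStudy)
            else perStudy[[1L]]
            mt$model <- mod; mt$outcome <- pc
            meta[[paste(mod, pc, sep = ".")]] <- mt
            lambdas <- rbind(lambdas, data.frame(
                model = mod, outcome = pc,
                lambda = suppressWarnings(genomicLambda(mt$p))))
        }
    }
    log <- .stageLog(log, "gwas", "%d model x PC analyses meta-analyzed",
                     length(meta))

    geneRes <- NULL
    if (!is.null(genes)) {
        gm <- annotateSnpsToGenes(infoAssoc, genes)
        mainTabs <- meta[grep("^main\\.", names(meta))]
        geneRes <- do.call(rbind, lapply(names(mainTabs), function(nm) {
            gt <- geneTestAll(mainTabs[[nm]], gm, G)
            if (!is.null(gt)) gt$outcome <- sub("^main\\.", "", nm)
            gt
        }))
        log <- .stageLog(log, "genes", "%d gene tests",
                         if (is.null(geneRes)) 0L else nrow(geneRes))
    }

    allMeta <- do.call(rbind, c(meta, make.row.names = FALSE))
    ld <- ldMatrix(G)
    hits <- do.call(rbind, lapply(meta, function(mt)
        selectIndependentHits(mt, ld, r2Max = config$r2Max,
                              pMax = config$snpAlpha)))
    if (!is.null(hits) && nrow(hits)) {
        hits <- hits[order(hits$p), ]
        rownames(hits) <- NULL
    }
    log <- .stageLog(log, "hits", "%d independent genome-wide significant SNPs",
                     if (is.null(hits)) 0L else nrow(hits))

    mediation <- list()
    if (!is.null(hits) && nrow(hits)) {
        covs <- data.frame(sex = sdat$sex, age = sdat$age,
                           study = sdat$study,
                           sdat[, ancNames, drop = FALSE])
        for (s in unique(hits$snp)) {
            mediation[[s]] <- fitMediation(
                G[, s], scores, sdat$diagnosis, covariates = covs,
                B = config$bootstrapB, seed = config$seed)
        }
        log <- .stageLog(log, "mediation", "%d SNPs routed to mediation",
                         length(mediation))
    }

    bundle <- list(pcModel = pcModel, scores = scores, cvCurve = cvCurve,
                   sexTable = sexTable, qc = qc, assoc = assoc, meta = allMeta,
                   lambda = lambdas, genes = geneRes, hits = hits,
                   mediation = mediation, log = log,
                   provenance = list(
                       seed = config$seed,
                       rversion = as.character(getRversion()),
                       configHash = sum(utf8ToInt(paste(
                           deparse(config), collapse = "")))))
    if (!is.null(config$outDir)) writeReport(bundle, config$outDir)
    bundle
}

#' Write plot-ready tables and summaries from a pipeline bundle
#'
#' Manhattan/QQ data carry -log10 p winsorized at 1e-10 (i.e. capped at 10);
#' loading, sex-difference, association-hit, mediation, gene and lambda
#' tables are written as TSV.
#'
#' @param bundle output of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeReport <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    wt <- function(x, name) {
        path <- file.path(dir, name)
        data.table::fwrite(as.data.frame(x), path, sep = "\t", na = "NA")
        files <<- c(files, path)
    }
    if (!is.null(bundle$meta)) {
        man <- bundle$meta
        man$logp <- pmin(-log10(man$p), 10)
        wt(man[, intersect(c("snp", "chrom", "pos", "model", "outcome",
                             "beta", "se", "p", "logp"), names(man))],
           "manhattan.tsv")
        qq <- do.call(rbind, lapply(split(man, paste(man$model, man$outcome)),
            function(d) {
                d <- d[order(d$p), ]
                data.frame(model = d$model, outcome = d$outcome,
                           expected = -log10(stats::ppoints(nrow(d))),
                           observed = pmin(-log10(d$p), 10))
            }))
        wt(qq, "qq.tsv")
    }
    if (!is.null(bundle$pcModel)) {
        wt(cbind(marker = rownames(loadings(bundle$pcModel)),
                 as.data.frame(loadings(bundle$pcModel))), "loadings.tsv")
    }
    if (!is.null(bundle$sexTable)) wt(bundle$sexTable, "sex_differences.tsv")
    if (!is.null(bundle$lambda)) wt(bundle$lambda, "lambda.tsv")
    if (!is.null(bundle$genes)) wt(bundle$genes, "gene_tests.tsv")
    wt(if (is.null(bundle$hits) || !nrow(bundle$hits))
        data.frame(snp = character(), model = character(),
                   outcome = character(), beta = numeric(), se = numeric(),
                   p = numeric())
       else bundle$hits, "independent_hits.tsv")
    if (length(bundle$mediation)) {
        med <- do.call(rbind, lapply(names(bundle$mediation), function(s) {
            m <- bundle$mediation[[s]]
            data.frame(snp = s, t(m$perPC), joint = m$joint,
                       direct = m$direct, total = m$total,
                       proportion = round(m$proportion, 2))
        }))
        wt(med, "mediation.tsv")
    } else {
        wt(data.frame(snp = character()), "mediation.tsv")
    }
    invisible(files)
}
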