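# Mediation structural model: SNP -> five biomarker PCs -> latent ordinal AD.
# The ordinal part is a maximum-likelihood probit in its latent-response
# formulation (residual variance 1); coefficients and thresholds are
# re-standardized to the latent-AD SD scale by dividing by
# sqrt(var(linear predictor) + 1), so that products of linear (SNP -> PC) and
# probit (PC -> AD) paths live on a common scale.

.probitFit <- function(y, X, hess = FALSE) {
    df <- data.frame(X, check.names = TRUE)
    df$.y <- factor(y, levels = levels(factor(y)), ordered = TRUE)
    fit <- tryCatch(
        suppressWarnings(MASS::polr(.y ~ ., data = df, method = "probit",
                                    Hess = hess)),
        error = function(e)
            stop("ordinal probit failed to converge: ", conditionMessage(e),
                 call. = FALSE))
    mm <- model.matrix(~ ., df[setdiff(names(df), ".y")])[, -1L, drop = FALSE]
    cf <- coef(fit)
    lp <- drop(mm %*% cf[colnames(mm)])
    denom <- sqrt(var(lp) + 1)
    list(fit = fit, coef = cf, lp = lp, denom = denom,
         thresholds = fit$zeta / denom)
}

#' Fit the latent ordinal Alzheimer's disease model
#'
#' Ordinal probit regression of the control/MCI/AD diagnosis on predictors
#' (typically the biomarker PC scores) and covariates, in the latent-response
#' formulation: a continuous latent AD variable with two thresholds, unit
#' residual variance, re-standardized so the latent AD scale has total SD 1.
#' A predictor's standardized coefficient is `beta * sd(x) / sqrt(var(lp)+1)`
#' (`beta / sqrt(var(lp)+1)` per raw unit, e.g. per effect allele);
#' thresholds are reported on the same standardized scale. With no predictors
#' the thresholds are the normal quantiles of the cumulative category
#' proportions.
#'
#' @param diagnosis ordered factor (or coercible) with at least two observed
#'   categories.
#' @param predictors data.frame/matrix of focal predictors, or NULL.
#' @param covariates data.frame/matrix of adjustment covariates, or NULL.
#' @return list of class `LatentADModel`: `thresholds` (standardized),
#'   `coefficients` (standardized, predictors then covariates),
#'   `coefficientsPerUnit`, `se` (delta-scale), and the raw probit fit.
#' @export
fitLatentAD <- function(diagnosis, predictors = NULL, covariates = NULL) {
    y <- factor(diagnosis)
    if (nlevels(droplevels(y)) < 2L)
        stop("diagnosis needs at least two observed categories")
    parts <- Filter(function(d) !is.null(d) && NCOL(d) > 0,
                    list(predictors, covariates))
    X <- if (length(parts)) do.call(cbind, lapply(parts, as.data.frame))
    else data.frame(row.names = seq_along(y))
    if (ncol(X) == 0L) {
        pr <- cumsum(table(y) / length(y))
        out <- list(thresholds = qnorm(pr[-length(pr)]),
                    coefficients = numeric(0),
                    coefficientsPerUnit = numeric(0),
                    se = numeric(0), fit = NULL, denom = 1)
        class(out) <- "LatentADModel"
        return(out)
    }
    pf <- .probitFit(y, X, hess = TRUE)
    sds <- vapply(as.data.frame(model.matrix(~ ., X)[, -1L, drop = FALSE]),
                  sd, 0)
    cf <- pf$coef[names(sds)]
    seRaw <- tryCatch(sqrt(diag(vcov(pf$fit)))[names(sds)],
                      error = function(e) rep(NA_real_, length(sds)))
    out <- list(thresholds = pf$thresholds,
                coefficients = cf * sds / pf$denom,
                coefficientsPerUnit = cf / pf$denom,
                se = seRaw * sds / pf$denom,
                fit = pf$fit, denom = pf$denom)
    class(out) <- "LatentADModel"
    out
}

#' @export
print.LatentADModel <- function(x, ...) {
    cat("Latent AD ordinal probit (standardized latent scale)\n")
    cat("thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = ", "),
        "\n")
    if (length(x$coefficients)) {
        cat("standardized coefficients:\n")
        print(round(x$coefficients, 3))
    }
    invisible(x)
}

#' Assemble a mediation effect decomposition
#'
#' Pure arithmetic on fitted paths: per-PC mediation effects are `a * b`
#' (or taken as given when `b` is NULL), the joint mediation is their sum,
#' the total effect is joint + direct, and the proportion mediated is
#' joint / total — reported only when joint and total point in the same
#' direction, and NA (undefined) otherwise.
#'
#' @param a per-PC SNP-to-PC paths, or per-PC mediation effects if `b` is
#'   NULL.
#' @param b per-PC PC-to-latent-AD paths, or NULL.
#' @param direct direct SNP-to-latent-AD path.
#' @return list of class `EffectDecomposition`: perPC, joint, direct, total,
#'   proportion.
#' @export
decomposeEffects <- function(a, b = NULL, direct) {
    perPC <- if (is.null(b)) a else a * b
    joint <- sum(perPC)
    total <- joint + direct
    proportion <- if (total == 0) NA_real_
    else if (joint == 0) 0
    else if (sign(joint) == sign(total)) joint / total
    else NA_real_
    structure(list(perPC = perPC, joint = joint, direct = direct,
                   total = total, proportion = proportion),
              class = "EffectDecomposition")
}

#' @export
print.EffectDecomposition <- function(x, ...) {
    cat("per-PC mediation:", paste(sprintf("%.3f", x$perPC), collapse = " "),
        "\n")
    cat(sprintf("joint %.3f + direct %.3f = total %.3f; proportion %s\n",
                x$joint, x$direct, x$total,
                if (is.na(x$proportion)) "undefined (opposite signs)"
                else sprintf("%.2f", x$proportion)))
    invisible(x)
}

# point estimator shared by the plain and moderated mediation fits;
# returns a named numeric vector
.mediationPoint <- function(dosage, S, y, Cmat, sex = NULL) {
    n <- length(dosage)
    k <- ncol(S)
    moderated <- !is.null(sex)
    # a-paths: OLS of every PC on dosage (+ dosage x sex) + covariates
    Xa <- if (moderated) cbind(1, dosage, dosage * sex, sex, Cmat)
    else cbind(1, dosage, Cmat)
    fa <- lm.fit(Xa, S)
    cfa <- fa$coefficients
    a <- cfa[2L, ]
    aInt <- if (moderated) cfa[3L, ] else rep(0, k)
    # b-paths and direct path: joint ordinal probit
    Xb <- data.frame(S, dosage = dosage)
    if (moderated) { Xb$dosage_sex <- dosage * sex; Xb$sexF <- sex }
    if (ncol(Cmat)) Xb <- cbind(Xb, as.data.frame(Cmat))
    pf <- .probitFit(y, Xb)
    bRaw <- pf$coef[colnames(S)] / pf$denom     # per raw score unit
    b <- bRaw * apply(S, 2L, sd)                # per SD (reported)
    direct <- pf$coef[["dosage"]] / pf$denom
    directInt <- if (moderated) pf$coef[["dosage_sex"]] / pf$denom else 0
    med <- a * bRaw                             # per-allele mediated effect
    out <- c(a = a, b = b, med = med,
             joint = sum(med), direct = direct,
             total = sum(med) + direct)
    if (moderated) {
        medF <- (a + aInt) * bRaw
        out <- c(out,
                 aInt = aInt, medDiff = aInt * bRaw,
                 jointF = sum(medF), directF = direct + directInt,
                 totalF = sum(medF) + direct + directInt,
                 directDiff = directInt)
    }
    out
}

.bootstrapStats <- function(statFun, n, B, seed) {
    if (!is.null(seed)) set.seed(seed)
    reps <- matrix(NA_real_, B, length(statFun(seq_len(n))))
    fail <- 0L
    for (i in seq_len(B)) {
        idx <- sample.int(n, n, replace = TRUE)
        r <- tryCatch(statFun(idx), error = function(e) NULL)
        if (is.null(r)) fail <- fail + 1L else reps[i, ] <- r
    }
    list(reps = reps[stats::complete.cases(reps), , drop = FALSE],
         nFailed = fail)
}

.finishMediation <- function(point, boot, B) {
    se <- apply(boot$reps, 2L, sd)
    names(se) <- names(point)
    p <- 2 * pnorm(-abs(point / se))
    dec <- decomposeEffects(point[grep("^med\\.", names(point))],
                            direct = point[["direct"]])
    k <- length(dec$perPC)
    structure(list(
        aPaths = point[grep("^a\\.", names(point))],
        bPaths = point[grep("^b\\.", names(point))],
        perPC = dec$perPC,
        joint = dec$joint, direct = dec$direct, total = dec$total,
        proportion = dec$proportion,
        se = se, p = p, B = B, nBootFailed = boot$nFailed),
        class = "MediationResult")
}

#' Fit the SNP -> biomarker PCs -> latent AD mediation model
#'
#' a-paths (per-allele SNP effects on each PC) are estimated by OLS, b-paths
#' (standardized PC effects on latent AD) and the direct SNP path jointly by
#' an ordinal probit of diagnosis on all PCs plus the SNP, all adjusted for
#' the covariates; paths are multiplied and summed into the per-PC, joint,
#' direct and total effects (see [decomposeEffects()]). Standard errors come
#' from a seeded nonparametric bootstrap over individuals, with p-values from
#' the bootstrap-normal approximation — products of linear and probit
#' coefficients have skewed sampling distributions at realistic effect sizes,
#' which the delta method handles poorly.
#'
#' @param dosage per-sample effect-allele dosage of one QC-passing SNP.
#' @param pcScores n x 5 standardized PC score matrix.
#' @param diagnosis ordered control/MCI/AD factor.
#' @param covariates data.frame of adjustment covariates or NULL.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list of class `MediationResult` with paths, decomposition,
#'   bootstrap SEs and p-values.
#' @export
fitMediation <- function(dosage, pcScores, diagnosis, covariates = NULL,
                         B = 1000L, seed = NULL) {
    S <- as.matrix(pcScores)
    if (is.null(colnames(S))) colnames(S) <- paste0("PC", seq_len(ncol(S)))
    y <- factor(diagnosis)
    Cmat <- if (is.null(covariates)) matrix(0, length(dosage), 0L)
    else model.matrix(~ ., as.data.frame(covariates))[, -1L, drop = FALSE]
    statFun <- function(idx)
        .mediationPoint(dosage[idx], S[idx, , drop = FALSE], y[idx],
                        Cmat[idx, , drop = FALSE])
    point <- statFun(seq_along(dosage))
    boot <- .bootstrapStats(statFun, length(dosage), B, seed)
    .finishMediation(point, boot, B)
}

#' @export
print.MediationResult <- function(x, ...) {
    cat("Mediation model (bootstrap B =", x$B, ")\n")
    tab <- cbind(estimate = c(x$perPC, joint = x$joint, direct = x$direct,
                              total = x$total))
    print(round(tab, 3))
    cat("proportion mediated:",
        if (is.na(x$proportion)) "undefined (opposite signs)"
        else sprintf("%.2f", x$proportion), "\n")
    if (!is.null(x$moderationFlag))
        cat("sex moderation:", if (x$moderationFlag) "detected" else
            "not detected (main-model estimates reported)", "\n")
    invisible(x)
}

#' Moderated (sex-specific) mediation model
#'
#' All SNP paths are duplicated with SNP x sex product terms (female = 1):
#' male estimates are the base terms, female estimates base + interaction.
#' A mediation pathway "differs by sex" when the bootstrap p-value of its
#' interaction product `aInt_j * b_j` is below `alpha`; if no pathway
#' differs, the plain mediation-model estimates are reported (both sets are
#' always returned).
#'
#' @inheritParams fitMediation
#' @param sex 0/1 vector (female = 1); both sexes must be present.
#' @param alpha nominal level of the pathway-difference rule (default 0.05).
#' @return `MediationResult` whose reported paths follow the reporting rule,
#'   with `sexSpecific` (male/female decompositions), `moderationFlag`, and
#'   `pathwayDiffP`.
#' @export
fitModeratedMediation <- function(dosage, pcScores, diagnosis,
                                  covariates = NULL, sex, B = 1000L,
                                  seed = NULL, alpha = 0.05) {
    if (length(unique(sex)) < 2L) stop("both sexes must be represented")
    S <- as.matrix(pcScores)
    if (is.null(colnames(S))) colnames(S) <- paste0("PC", seq_len(ncol(S)))
    y <- factor(diagnosis)
    Cmat <- if (is.null(covariates)) matrix(0, length(dosage), 0L)
    else model.matrix(~ ., as.data.frame(covariates))[, -1L, drop = FALSE]
    k <- ncol(S)
    statFun <- function(idx) {
        mod <- .mediationPoint(dosage[idx], S[idx, , drop = FALSE], y[idx],
                               Cmat[idx, , drop = FALSE], sex = sex[idx])
        main <- .mediationPoint(dosage[idx], S[idx, , drop = FALSE], y[idx],
                                Cmat[idx, , drop = FALSE])
        c(mod, main = main)
    }
    point <- statFun(seq_along(dosage))
    boot <- .bootstrapStats(statFun, length(dosage), B, seed)
    se <- apply(boot$reps, 2L, sd)
    names(se) <- names(point)
    pAll <- 2 * pnorm(-abs(point / se))
    diffIdx <- grep("^medDiff\\.", names(point))
    pathwayDiffP <- pAll[diffIdx]
    flag <- any(pathwayDiffP < alpha, na.rm = TRUE)

    aM <- point[grep("^a\\.", names(point))]
    b <- point[grep("^b\\.", names(point))]
    medM <- point[grep("^med\\.", names(point))]
    medF <- medM + point[grep("^medDiff\\.", names(point))]
    male <- decomposeEffects(medM, direct = point[["direct"]])
    female <- decomposeEffects(medF, direct = point[["directF"]])

    if (flag) {
        reported <- structure(list(
            aPaths = aM, bPaths = b,
            perPC = male$perPC, joint = male$joint, direct = male$direct,
            total = male$total, proportion = male$proportion,
            se = se, p = pAll, B = B, nBootFailed = boot$nFailed),
            class = "MediationResult")
    } else {
        mainNames <- grep("^main\\.", names(point))
        mp <- point[mainNames]; names(mp) <- sub("^main\\.", "", names(mp))
        mse <- se[mainNames]; names(mse) <- names(mp)
        dec <- decomposeEffects(mp[grep("^med\\.", names(mp))],
                                direct = mp[["direct"]])
        reported <- structure(list(
            aPaths = mp[grep("^a\\.", names(mp))],
            bPaths = mp[grep("^b\\.", names(mp))],
            perPC = dec$perPC, joint = dec$joint, direct = dec$direct,
            total = dec$total, proportion = dec$proportion,
            se = mse, p = 2 * pnorm(-abs(mp / mse)), B = B,
            nBootFailed = boot$nFailed),
            class = "MediationResult")
    }
    reported$sexSpecific <- list(male = male, female = female)
    reported$moderationFlag <- flag
    reported$pathwayDiffP <- pathwayDiffP
    reported
}
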