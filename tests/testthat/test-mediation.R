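test_that("intercept-only latent AD model returns quantile thresholds", {
    y <- factor(rep(c("control", "MCI", "AD"), c(2107, 5612, 2282)),
                levels = c("control", "MCI", "AD"), ordered = TRUE)
    m <- fitLatentAD(y)
    expect_equal(unname(m$thresholds), c(-0.804, 0.745), tolerance = 1e-3)
    expect_error(fitLatentAD(factor(rep("AD", 10))), "two observed")
})

test_that("probit standardization recovers the generating effect size", {
    # slope of a single standardized predictor with true standardized effect
    # rho comes back as rho, across the relevant effect range
    set.seed(199)
    for (rho in c(0, 0.2, 0.41)) {
        est <- replicate(15, {
            x <- rnorm(800)
            d <- simulateDiagnosis(cbind(x, 0, 0, 0, 0), c(rho, 0, 0, 0, 0))
            fitLatentAD(d, predictors = data.frame(x = x))$coefficients[["x"]]
        })
        expect_lt(abs(mean(est) - rho), 0.03)
    }
})

test_that("latent AD fit under the study design recovers 0.41 with its thresholds", {
    set.seed(211)
    est <- replicate(15, {
        pc1 <- rnorm(601)
        d <- simulateDiagnosis(cbind(pc1, 0, 0, 0, 0), c(0.41, 0, 0, 0, 0),
                               c(-1.47, 0.40))
        m <- fitLatentAD(d, predictors = data.frame(PC1 = pc1))
        c(m$coefficients[["PC1"]], m$thresholds)
    })
    expect_lt(abs(mean(est[1, ]) - 0.41), 0.03)
    expect_lt(abs(mean(est[2, ]) + 1.47), 0.1)
    expect_lt(abs(mean(est[3, ]) - 0.40), 0.1)
})

test_that("effect decomposition reproduces worked table rows exactly", {
    # strong Abeta-locus variant: all five mediation paths plus direct
    apoe <- decomposeEffects(c(-0.09, -0.13, 0.01, 0.00, 0.00),
                             direct = -0.18)
    expect_equal(apoe$joint, -0.21)
    expect_equal(apoe$total, -0.39)
    expect_equal(round(apoe$proportion, 2), 0.54)
    expect_equal(apoe$total, apoe$joint + apoe$direct)
    # opposite-sign decomposition: proportion undefined
    tmem <- decomposeEffects(c(-0.02, -0.01, 0.07, 0.00, 0.00),
                             direct = -0.08)
    expect_equal(tmem$joint, 0.04)
    expect_equal(tmem$total, -0.04)
    expect_true(is.na(tmem$proportion))
    # a = 0: everything flows through the direct path
    null <- decomposeEffects(rep(0, 5), rep(0.2, 5), direct = 0.1)
    expect_equal(null$joint, 0)
    expect_equal(null$total, 0.1)
    expect_equal(null$proportion, 0)
    expect_true(is.na(decomposeEffects(rep(0, 5), rep(0, 5), 0)$proportion))
    # single active pair
    one <- decomposeEffects(c(0.1, 0, 0, 0, 0), c(0.2, 0, 0, 0, 0), 0.02)
    expect_equal(one$joint, 0.02)
    expect_equal(one$total, 0.04)
    expect_equal(one$proportion, 0.5)
})

test_that("a null SNP produces a null mediation record with exact identity", {
    set.seed(223)
    n <- 500
    g <- rbinom(n, 2, 0.3)
    S <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("PC", 1:5)))
    d <- simulateDiagnosis(S, c(0.3, -0.2, 0.2, 0, 0))
    m <- fitMediation(g, S, d, B = 100, seed = 1)
    expect_lt(abs(m$joint), 0.05)
    expect_lt(abs(m$total), 0.12)
    expect_identical(m$total, m$joint + m$direct)
    expect_true(all(abs(m$perPC) < 0.05))
})

test_that("planted mediation paths are recovered with calibrated bootstrap SE", {
    set.seed(227)
    n <- 500
    truthMed <- 0.26 * 0.27
    onePoint <- function() {
        g <- rbinom(n, 2, 0.42)
        S <- matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("PC", 1:5)))
        S[, 2] <- S[, 2] + 0.26 * g
        d <- simulateDiagnosis(S, c(0, 0.27, 0, 0, 0))
        list(g = g, S = S, d = d)
    }
    pts <- replicate(60, {
        dat <- onePoint()
        pcgwas:::.mediationPoint(dat$g, dat$S, dat$d,
                                 matrix(0, n, 0))[["med.PC2"]]
    })
    expect_lt(abs(mean(pts) - truthMed), 0.01)
    mcSD <- sd(pts)
    bootSE <- replicate(8, {
        dat <- onePoint()
        fitMediation(dat$g, dat$S, dat$d, B = 120,
                     seed = 2)$se[["med.PC2"]]
    })
    expect_lt(abs(mean(bootSE) - mcSD), 0.35 * mcSD)
})

test_that("moderated mediation detects a male-only pathway and not a null one", {
    set.seed(229)
    n <- 700
    g <- rbinom(n, 2, 0.35)
    sex <- rep(c(0, 1), length.out = n)
    S <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("PC", 1:5)))
    S[, 3] <- S[, 3] - 0.45 * g * (sex == 0)
    d <- simulateDiagnosis(S, c(0, 0, 0.4, 0, 0))
    m <- fitModeratedMediation(g, S, d, sex = sex, B = 150, seed = 3)
    expect_true(m$moderationFlag)
    expect_lt(abs(m$sexSpecific$female$joint), 0.06)
    expect_lt(m$sexSpecific$male$joint, -0.08)
    expect_identical(m$sexSpecific$male$total,
                     m$sexSpecific$male$joint + m$sexSpecific$male$direct)
})

test_that("null moderation rarely trips the pathway-difference rule", {
    set.seed(233)
    flags <- vapply(1:6, function(i) {
        n <- 400
        g <- rbinom(n, 2, 0.3)
        sex <- rep(c(0, 1), length.out = n)
        S <- matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("PC", 1:5)))
        S[, 2] <- S[, 2] + 0.2 * g   # same effect in both sexes
        d <- simulateDiagnosis(S, c(0.3, 0.25, 0, 0, 0))
        fitModeratedMediation(g, S, d, sex = sex, B = 100,
                              seed = i)$moderationFlag
    }, TRUE)
    expect_lte(sum(flags), 1L)
})

test_that("without sex differences the moderated model reports the plain fit", {
    set.seed(239)
    n <- 400
    g <- rbinom(n, 2, 0.3)
    sex <- rep(c(0, 1), length.out = n)
    S <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("PC", 1:5)))
    d <- simulateDiagnosis(S, c(0.3, 0, 0, 0, 0))
    mm <- fitModeratedMediation(g, S, d, sex = sex, B = 60, seed = 5)
    plain <- fitMediation(g, S, d, B = 10, seed = 5)
    if (!mm$moderationFlag) {
        expect_equal(mm$perPC, plain$perPC, tolerance = 1e-10)
        expect_equal(mm$direct, plain$direct, tolerance = 1e-10)
        expect_equal(mm$total, plain$total, tolerance = 1e-10)
    }
    expect_error(fitModeratedMediation(g, S, d, sex = rep(1, n), B = 10),
                 "both sexes")
})

test_that("categorization loses little: ordinal fit tracks the linear oracle", {
    set.seed(241)
    n <- 900
    g <- rbinom(n, 2, 0.4)
    S <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("PC", 1:5)))
    S[, 1] <- S[, 1] + 0.2 * g
    lp <- 0.35 * S[, 1]
    latent <- lp + rnorm(n, sd = sqrt(1 - var(lp)))
    d <- cut(latent, c(-Inf, -1.47, 0.40, Inf),
             labels = c("control", "MCI", "AD"), right = FALSE)
    m <- fitMediation(g, S, d, B = 100, seed = 7)
    # linear-SEM oracle on the uncategorized latent outcome
    aHat <- coef(lm(S[, 1] ~ g))[2]
    bHat <- coef(lm(latent ~ S + g))["SPC1"]
    oracle <- aHat * bHat
    expect_lt(abs(m$perPC[["med.PC1"]] - oracle), 2 * m$se[["med.PC1"]])
})
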