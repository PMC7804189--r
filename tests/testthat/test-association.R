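test_that("LRT handles degenerate and closed-form cases", {
    y <- rep(c(1, 0), each = 15)
    # constant gene variable: nested models coincide
    expect_equal(lrtStatistic(y, rep(2, 30))$stat, 0)

    # binary predictor forming the 2x2 table [[10,5],[5,10]]:
    # logistic LRT equals the G-statistic of the table
    g <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
    expect_equal(lrtStatistic(y, g)$stat,
                 oracleGStat(matrix(c(10, 5, 5, 10), 2)),
                 tolerance = 1e-7)

    # gene variable duplicating a covariate adds no information
    set.seed(31)
    x <- rnorm(30)
    expect_lt(lrtStatistic(y, x, matrix(x, ncol = 1))$stat, 1e-8)

    expect_error(lrtStatistic(rep(1, 30), rnorm(30)), "both classes")
})

test_that("LRT agrees with glm() maximum likelihood", {
    set.seed(41)
    for (rep in 1:4) {
        n <- 80
        X <- matrix(rnorm(n * 2), n)
        g <- rnorm(n) + 0.3 * X[, 1]
        y <- rbinom(n, 1, plogis(0.5 * g))
        ours <- lrtStatistic(y, g, X)$stat
        f0 <- glm(y ~ X, family = binomial())
        f1 <- glm(y ~ X + g, family = binomial())
        ref <- as.numeric(2 * (logLik(f1) - logLik(f0)))
        expect_equal(ours, ref, tolerance = 1e-6)
        expect_equal(lrtStatistic(y, g, X)$analytic_p,
                     pchisq(ref, 1, lower.tail = FALSE),
                     tolerance = 1e-6)
    }
})

test_that("separated fits are flagged instead of crashing", {
    y <- rep(c(0, 1), each = 10)
    g <- c(rnorm(10, -3), rnorm(10, 3))   # perfectly separating
    r <- lrtStatistic(y, g)
    expect_true(r$separated)
    expect_true(is.finite(r$stat) && r$stat > 0)
})

test_that("with no covariates the scheme reduces to label permutation", {
    # n = 7: compare sampled permutation statistics against the
    # exhaustive multiset from all 7! reorderings of the gene variable
    y <- c(1, 1, 1, 0, 0, 0, 1)
    g <- c(0.3, 1.2, -0.5, 0.1, -1.0, 0.7, 2.1)
    perms <- allPerms(1:7)
    exact <- apply(perms, 1, function(p) lrtStatistic(y, g[p])$stat)
    r <- permutationP(y, g, bInitial = 300, bMax = 300, seed = 5,
                      returnStats = TRUE)
    for (s in r$perm_stats) {
        expect_lt(min(abs(exact - s)), 1e-7)
    }
    # and the sampled p-value sits near the exhaustive one
    pExact <- mean(exact >= r$stat - 1e-8)
    expect_lt(abs(r$perm_p - pExact), 3 * sqrt(pExact * (1 - pExact) / 300))
})

test_that("permutation p is invariant to affine gene rescaling", {
    set.seed(61)
    n <- 60
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    X <- matrix(rnorm(n), ncol = 1)
    g <- rnorm(n)
    r1 <- permutationP(y, g, X, bInitial = 200, bMax = 200, seed = 9)
    r2 <- permutationP(y, 3 * g + 1, X, bInitial = 200, bMax = 200,
                       seed = 9)
    expect_equal(r1$b_exceed, r2$b_exceed)
    expect_equal(r1$stat, r2$stat, tolerance = 1e-6)
})

test_that("permutation bookkeeping follows b/B with escalation policy", {
    set.seed(71)
    n <- 80
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    g <- rnorm(n)
    r <- permutationP(y, g, bInitial = 400, bMax = 400, seed = 3,
                      returnStats = TRUE)
    expect_equal(r$perm_p, r$b_exceed / r$B)
    expect_equal(r$b_exceed, sum(r$perm_stats >= r$stat - 1e-8))
    expect_false(r$upper_bound)

    # a huge effect exhausts bInitial without exceedances and escalates
    gs <- y * 4 + rnorm(n, 0, 0.1)
    re <- permutationP(y, gs, bInitial = 50, bMax = 400, seed = 3)
    expect_equal(re$B, 400)
    if (re$b_exceed == 0) {
        expect_true(re$upper_bound)
        expect_equal(re$perm_p, 1 / 400)
    }

    # zero-variance gene: flat permutation distribution, p = 1
    r0 <- permutationP(y, rep(1, n), bInitial = 100, bMax = 100, seed = 2)
    expect_equal(r0$stat, 0)
    expect_equal(r0$perm_p, 1)
})

test_that("analytic and permutation p-values agree on null data", {
    set.seed(81)
    n <- 300
    y <- rep(c(0, 1), each = n / 2)
    ps <- t(vapply(1:40, function(i) {
        g <- rnorm(n)
        r <- permutationP(y, g, bInitial = 400, bMax = 400,
                          seed = 1000 + i)
        c(r$analytic_p, r$perm_p)
    }, c(0, 0)))
    # QQ agreement: regression through the origin has slope ~ 1
    slope <- sum(ps[, 1] * ps[, 2]) / sum(ps[, 1]^2)
    expect_gt(slope, 0.9)
    expect_lt(slope, 1.1)
})

test_that("covariate policies enforce the component conventions", {
    pol <- covariatePolicy()
    expect_false("expression_pc" %in% pol$grex)
    expect_true("expression_pc" %in% pol$erex)
    expect_error(covariatePolicy(grex = c("clinical", "expression_pc",
                                          "genotype_pc")),
                 "exclude expression PCs")
    expect_error(covariatePolicy(erex = c("clinical", "genotype_pc")),
                 "must include expression PCs")
    expect_error(covariatePolicy(grex = "clinical"),
                 "genotype PCs")
})

test_that("association scan is deterministic and policy-aware", {
    sim <- tinyCohort(n = 80, G = 4, seed = 23)
    pg <- predictGrex(sim$genotypes, sim$weights)
    obs <- observedExpr(sim$bundle)
    common <- intersect(colnames(obs), colnames(pg$grex))
    bundle <- computeErex(ExpressionBundle(
        obs[, common, drop = FALSE],
        grex = pg$grex[, common, drop = FALSE]))$bundle
    epc <- expressionPCs(obs, 2)
    cov <- buildCovariates(
        clinical = covariateData(sim$covariates)[,
            covariateTags(sim$covariates) == "clinical", drop = FALSE],
        genotypePC = covariateData(sim$covariates)[,
            covariateTags(sim$covariates) == "genotype_pc", drop = FALSE],
        expressionPC = epc)
    a1 <- runAssociation(bundle, sim$phenotype, cov, bInitial = 150,
                         bMax = 150, seed = 7)
    a2 <- runAssociation(bundle, sim$phenotype, cov, bInitial = 150,
                         bMax = 150, seed = 7)
    expect_identical(a1, a2)
    expect_setequal(unique(a1$component), c("observed", "grex", "erex"))
    expect_equal(nrow(a1), 3 * length(common))
    expect_true(all(a1$perm_p > 0 & a1$perm_p <= 1))

    # zero GReX: every grex statistic collapses
    zero <- matrix(0, nrow(obs), length(common),
                   dimnames = list(rownames(obs), common))
    b0 <- computeErex(ExpressionBundle(obs[, common, drop = FALSE],
                                       grex = zero))$bundle
    a0 <- runAssociation(b0, sim$phenotype, cov,
                         components = "grex", bInitial = 100,
                         bMax = 100, seed = 7)
    expect_true(all(a0$lrt_stat == 0))
    expect_true(all(a0$perm_p == 1))

    # misaligned phenotype is rejected
    ph <- Phenotype(rev(sampleIds(bundle)),
                    unname(status(sim$phenotype)))
    expect_error(runAssociation(bundle, ph, cov), "alignCohort")
})

test_that("BH adjustment matches the hand-computed step-up", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFDR(0.3), 0.3)
    expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
    expect_error(bhFDR(c(0.5, 0)), "0, 1")
    expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
})
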