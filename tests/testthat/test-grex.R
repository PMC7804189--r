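test_that("minor allele frequency folds the ALT frequency", {
    expect_equal(variantMAF(c(0, 1, 2, 2)), 0.375)
    expect_equal(variantMAF(c(0, 0, 0)), 0)
    expect_equal(variantMAF(c(1, 1, 1, 1)), 0.5)
    expect_error(variantMAF(numeric(0)), "empty")
    expect_error(variantMAF(c(-0.1, 1)), "0, 2")
})

test_that("HWE exact test matches hand enumeration on small tables", {
    # (1,2,1): configurations het in {0,2,4} weigh 6:48:16; observed modal
    expect_equal(hweExactP(1, 2, 1), 1.0)
    expect_equal(hweExactP(10, 0, 0), 1.0)      # monomorphic
    expect_lt(hweExactP(0, 100, 0), 1e-6)       # heterozygote excess
    expect_error(hweExactP(0, 0, 0), "zero")
    expect_error(hweExactP(-1, 2, 1), "non-negative")
})

test_that("QC keeps strict MAF and HWE thresholds", {
    # n = 50 with HWE-modal genotype configurations at MAF
    # {0.02, 0.05, 0.06, 0.40}; strict > 0.05 keeps exactly two variants
    mk <- function(aa, ab, bb) rep(c(0, 1, 2), c(aa, ab, bb))
    d <- cbind(v1 = mk(48, 2, 0), v2 = mk(45, 5, 0), v3 = mk(44, 6, 0),
               v4 = mk(18, 24, 8))
    rownames(d) <- paste0("s", 1:50)
    vm <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "G",
                     row.names = colnames(d))
    gm <- GenotypeMatrix(d, vm)
    res <- qcFilter(gm)
    expect_equal(res$qc$maf, c(0.02, 0.05, 0.06, 0.40))
    expect_identical(res$qc$pass, c(FALSE, FALSE, TRUE, TRUE))
    expect_identical(variantIds(res$genotypes), c("v3", "v4"))
    # thresholds at zero retain every polymorphic HWE-consistent variant
    expect_true(all(qcFilter(gm, 0, 0)$qc$pass))
})

test_that("GReX is the effect-allele-aligned weighted dosage sum", {
    d <- rbind(s1 = c(v1 = 2, v2 = 0), s2 = c(v1 = 0, v2 = 1))
    vm <- data.frame(chrom = "1", pos = c(1L, 2L), ref = c("A", "C"),
                     alt = c("G", "T"), row.names = c("v1", "v2"))
    gm <- GenotypeMatrix(d, vm)
    w <- WeightMatrix(data.frame(gene = "g1", variant = c("v1", "v2"),
                                 weight = c(0.5, -1.0),
                                 effect_allele = c("G", "T")))
    pg <- predictGrex(gm, w)
    expect_equal(unname(pg$grex[, "g1"]), c(1.0, -1.0))

    # effect allele equal to REF flips the dosage to 2 - d
    wf <- WeightMatrix(data.frame(gene = "g1", variant = "v1",
                                  weight = 0.5, effect_allele = "A"))
    expect_equal(unname(predictGrex(gm, wf)$grex[, "g1"]),
                 0.5 * (2 - c(2, 0)))

    # gene with every variant QC-removed: absent but reported
    w2 <- WeightMatrix(data.frame(
        gene = c("g1", "g2"), variant = c("v1", "vGone"),
        weight = c(0.5, 1), effect_allele = "G"))
    pg2 <- predictGrex(gm, w2)
    expect_false("g2" %in% colnames(pg2$grex))
    expect_identical(pg2$coverage$predicted[pg2$coverage$gene == "g2"],
                     FALSE)
})

test_that("GReX prediction is linear in the dosages", {
    sim <- tinyCohort(n = 30, G = 4, seed = 9)
    d <- dosages(sim$genotypes)
    vm <- variantMeta(sim$genotypes)
    rownames(vm) <- vm$variant_id
    d1 <- d / 2                      # halves stay inside [0, 2]
    d2 <- d / 4
    mk <- function(m) GenotypeMatrix(m, vm)
    p1 <- predictGrex(mk(d1), sim$weights)$grex
    p2 <- predictGrex(mk(d2), sim$weights)$grex
    p12 <- predictGrex(mk(d1 + d2), sim$weights)$grex
    expect_equal(p12, p1 + p2, tolerance = 1e-12)
})

test_that("trained weights recover a noiseless single-variant signal", {
    gm <- simulateGenotypes(120, 10, c(0.2, 0.4), seed = 4)
    d <- dosages(gm)
    y <- 0.7 * d[, "v00003"]
    expr <- matrix(y, ncol = 1, dimnames = list(rownames(d), "g1"))
    tw <- trainWeights(gm, expr, list(g1 = colnames(d)), seed = 2)
    expect_gt(tw$performance$cv_r2[1], 0.99)
    expect_equal(as.numeric(weightValues(tw$weights)["g1", "v00003"]),
                 0.7, tolerance = 0.1)

    # pure-noise expression: cv_r2 stays near zero
    set.seed(10)
    yn <- rnorm(500)
    gm2 <- simulateGenotypes(500, 12, c(0.2, 0.4), seed = 6)
    exprn <- matrix(yn, ncol = 1,
                    dimnames = list(rownames(dosages(gm2)), "g1"))
    twn <- trainWeights(gm2, exprn, list(g1 = variantIds(gm2)), seed = 2)
    expect_lt(twn$performance$cv_r2[1], 0.05)

    # fold assignment is seed-deterministic
    twb <- trainWeights(gm, expr, list(g1 = colnames(d)), seed = 2)
    expect_identical(tw$performance$cv_r2, twb$performance$cv_r2)

    expect_warning(
        trainWeights(gm, matrix(1, 120, 1,
                                dimnames = list(rownames(d), "gc")),
                     list(gc = colnames(d)), seed = 1),
        "constant")
})

test_that("REML h2 hits the boundaries and the grid optimum", {
    gm <- simulateGenotypes(300, 20, c(0.1, 0.5), seed = 12)
    d <- dosages(gm)
    Z <- scale(d)
    set.seed(13)
    u <- drop(Z %*% rnorm(20, 0, 0.3))

    # noiseless genetic signal: estimate at the upper boundary
    expect_gte(estimateH2(d, u)$h2, 0.99)

    # expression independent of genotype: median estimate near zero
    h0 <- replicate(10, estimateH2(d, rnorm(300))$h2)
    expect_lt(median(h0), 0.05)

    # optimizer beats a 101-point grid (within optimizer tolerance)
    y <- u + rnorm(300, 0, sd(u))
    est <- estimateH2(d, y)
    grid <- remlProfile(d, y, seq(0, 0.99, length.out = 101))
    expect_gte(est$loglik, max(grid) - 1e-4)

    expect_error(estimateH2(d[1:30, ], y[1:30]), "50 samples")
    expect_error(estimateH2(d[, 1, drop = FALSE], y), "2 polymorphic")
})

test_that("REML recovers a known simulated heritability", {
    hits <- 0
    for (rep in 1:12) {
        gm <- simulateGenotypes(700, 40, c(0.1, 0.5), seed = 100 + rep)
        Z <- scale(dosages(gm))
        set.seed(200 + rep)
        g <- drop(Z %*% rnorm(40)) / sqrt(40)
        g <- g / sd(g) * sqrt(0.5)
        y <- g + rnorm(700, 0, sqrt(0.5))
        h <- estimateH2(dosages(gm), y)$h2
        if (h > 0.35 && h < 0.65) hits <- hits + 1
    }
    expect_gte(hits, 9)
})

test_that("eigen-basis REML likelihood agrees with the dense formula", {
    gm <- simulateGenotypes(60, 8, c(0.2, 0.5), seed = 31)
    d <- dosages(gm)
    set.seed(32)
    y <- rnorm(60)
    Z <- scale(d)
    K <- tcrossprod(Z) / ncol(Z)
    one <- rep(1, 60)
    denseRestricted <- function(h2) {
        H <- h2 * K + (1 - h2) * diag(60)
        Hi <- solve(H)
        A <- drop(t(one) %*% Hi %*% one)
        mu <- drop(t(one) %*% Hi %*% y) / A
        rss <- drop(t(y - mu) %*% Hi %*% (y - mu))
        sig2 <- rss / 59
        -0.5 * (59 * (log(2 * pi * sig2) + 1) +
                determinant(H)$modulus + log(A))
    }
    hs <- c(0.05, 0.3, 0.6, 0.9)
    ours <- remlProfile(d, y, hs)
    dense <- vapply(hs, denseRestricted, 0)
    # same profile up to an additive constant
    expect_equal(diff(ours), diff(dense), tolerance = 1e-6)
})

test_that("cv R2 and REML h2 correlate on toy vectors", {
    p <- data.frame(gene = c("a", "b", "c"), cv_r2 = c(0.1, 0.2, 0.3))
    h <- data.frame(gene = c("a", "b", "c"), h2 = c(0.1, 0.2, 0.3))
    expect_equal(r2H2Correlation(p, h), 1)
    h$h2 <- c(0.3, 0.2, 0.1)
    expect_equal(r2H2Correlation(p, h), -1)
    h$h2 <- c(0.2, 0.2, 0.2)
    expect_error(r2H2Correlation(p, h), "zero variance")
    expect_error(r2H2Correlation(p[1:2, ], h[1:2, ]), ">= 3 genes")
})
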