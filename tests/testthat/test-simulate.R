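test_that("genotype simulation is seed-deterministic and HWE-binomial", {
    g1 <- simulateGenotypes(50, 8, c(0.1, 0.4), seed = 3)
    g2 <- simulateGenotypes(50, 8, c(0.1, 0.4), seed = 3)
    expect_identical(dosages(g1), dosages(g2))
    expect_false(identical(dosages(g1),
                           dosages(simulateGenotypes(50, 8, c(0.1, 0.4),
                                                     seed = 4))))

    # empirical ALT frequency at n = 10000, f fixed at 0.3
    g <- simulateGenotypes(10000, 4, c(0.3, 0.3), seed = 5)
    f <- colMeans(dosages(g)) / 2
    expect_true(all(f > 0.29 & f < 0.31))

    # degenerate range pins every variant's frequency
    g <- simulateGenotypes(5000, 3, c(0.4, 0.4), seed = 6)
    expect_true(all(abs(colMeans(dosages(g)) / 2 - 0.4) < 0.02))

    expect_error(simulateGenotypes(10, 2, c(0, 0.5)), "mafRange")
    expect_error(simulateGenotypes(10, 2, c(0.1, 0.6)), "mafRange")
})

test_that("weight simulation respects sparsity and determinism", {
    vbg <- list(gA = paste0("v", 1:5), gB = paste0("v", 6:10),
                gC = paste0("v", 11:15))
    w <- simulateWeights(vbg, nCausal = c(0L, 2L, 5L), seed = 8)
    expect_false("gA" %in% geneIds(w))          # nCausal = 0: gene absent
    expect_equal(sum(weightValues(w)["gB", ] != 0), 2)
    expect_equal(sum(weightValues(w)["gC", ] != 0), 5)   # dense row
    w2 <- simulateWeights(vbg, nCausal = c(0L, 2L, 5L), seed = 8)
    expect_equal(weightValues(w)[geneIds(w), variantIds(w)],
                 weightValues(w2)[geneIds(w), variantIds(w)])
    expect_error(simulateWeights(vbg, nCausal = 6L), "exceeds")
})

test_that("cohort decomposition is exactly additive with the target h2", {
    cfg <- simulationConfig(nSamples = 922, nCases = 463, nGenes = 40,
                            snpsPerGene = 10, nCausalPerGene = 4,
                            h2PerGene = 0.3, seed = 21)
    sim <- simulateCohort(cfg)
    obs <- observedExpr(sim$bundle)
    expect_lt(max(abs(obs - sim$truth$trueGrex - sim$truth$trueEnv -
                      sim$truth$noise)), 1e-12)
    ratio <- apply(sim$truth$trueGrex, 2, var) / apply(obs, 2, var)
    expect_true(all(abs(ratio - 0.3) < 0.05))
    expect_equal(sum(status(sim$phenotype)), 463)

    # h2 = 0 turns the genetic component off entirely
    cfg0 <- simulationConfig(nSamples = 100, nCases = 50, nGenes = 5,
                             snpsPerGene = 4, nCausalPerGene = 2,
                             h2PerGene = 0, seed = 1)
    sim0 <- simulateCohort(cfg0)
    expect_true(all(sim0$truth$trueGrex == 0))

    expect_error(simulationConfig(nSamples = 100, nCases = 100), "nCases")
    expect_error(simulationConfig(h2PerGene = 1), "h2")
})

test_that("null cohorts give standard-normal case/control t-statistics", {
    cfg <- simulationConfig(nSamples = 400, nCases = 200, nGenes = 500,
                            snpsPerGene = 2, nCausalPerGene = 1,
                            h2PerGene = 0.15, seed = 33)
    sim <- simulateCohort(cfg)
    obs <- observedExpr(sim$bundle)
    st <- unname(status(sim$phenotype))
    tstat <- apply(obs, 2, function(y)
        t.test(y[st == 1], y[st == 0])$statistic)
    ks <- ks.test(tstat, "pnorm")
    expect_gt(ks$p.value, 0.01)
})

test_that("the environmental shift lands at the configured size", {
    G <- 40
    cfg <- simulationConfig(nSamples = 900, nCases = 450, nGenes = G,
                            snpsPerGene = 4, nCausalPerGene = 2,
                            h2PerGene = 0.15,
                            envEffectGenes = sprintf("gene%04d", 1:20),
                            envEffectSize = 1.0, seed = 55)
    sim <- simulateCohort(cfg)
    obs <- observedExpr(sim$bundle)
    st <- unname(status(sim$phenotype))
    sdEnv <- sqrt(0.7 * (1 - 0.15))
    diffs <- colMeans(obs[st == 1, 1:20]) - colMeans(obs[st == 0, 1:20])
    # mean case-control difference ~ envEffectSize * sd_env within 10%
    expect_lt(abs(mean(diffs) - sdEnv) / sdEnv, 0.10)
    lab <- sim$truth$labels
    expect_true(all(lab[1:20] == "env_driven"))
    expect_true(all(lab[21:40] == "null"))
})

test_that("grex-driven phenotypes separate cases along the genetic axis", {
    genes <- sprintf("gene%04d", 1:10)
    cfg <- simulationConfig(nSamples = 600, nCases = 300, nGenes = 10,
                            snpsPerGene = 8, nCausalPerGene = 4,
                            h2PerGene = 0.4, grexEffectGenes = genes[1:5],
                            grexEffectSize = 1.0, seed = 77)
    sim <- simulateCohort(cfg)
    st <- unname(status(sim$phenotype))
    gsum <- rowSums(scale(sim$truth$trueGrex[, 1:5]))
    expect_gt(mean(gsum[st == 1]) - mean(gsum[st == 0]), 0.3)
})
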