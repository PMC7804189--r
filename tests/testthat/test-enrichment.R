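test_that("hypergeometric tail matches combinatorics and enumeration", {
    expect_equal(hypergeomUpperTail(10, 5, 4, 4), 5 / 210)
    expect_equal(hypergeomUpperTail(100, 10, 20, 0), 1)
    expect_error(hypergeomUpperTail(10, 12, 4, 2), "inconsistent")
    expect_error(hypergeomUpperTail(10, 5, 4, 5), "inconsistent")

    # exhaustive draw enumeration for every universe up to 12
    for (N in c(5, 8, 12)) {
        for (K in 0:N) {
            for (n in 1:N) {
                for (x in 0:min(K, n)) {
                    expect_equal(hypergeomUpperTail(N, K, n, x),
                                 oracleHyperTail(1:N, K, n, x),
                                 tolerance = 1e-12,
                                 info = sprintf("N=%d K=%d n=%d x=%d",
                                                N, K, n, x))
                }
            }
        }
    }
})

test_that("the tail is monotone in the observed overlap", {
    for (x in 0:5)
        expect_lte(hypergeomUpperTail(40, 8, 10, x + 1),
                   hypergeomUpperTail(40, 8, 10, x))
})

test_that("top-N overlap counting follows the published ranking", {
    # the interferon pathway genes sit at these observed-expression
    # ranks among the differentially expressed genes of the bundled
    # example table: six of them fall inside the top 30
    tab <- exampleTable("ifn_odegs")
    ranked <- rep(NA_character_, 5359)
    ranked[tab$odeg_rank] <- tab$gene
    ranked[is.na(ranked)] <- paste0("G", seq_len(5359 - nrow(tab)))
    gs <- GeneSet("ifn", tab$gene)
    universe2 <- ranked
    enr <- topNEnrichment(ranked, gs, universe2,
                          N = c(30, 60, 100, 150, 200, 300))
    expect_equal(enr$overlap[enr$N_top == 30], 6)
    # overlap is non-decreasing in N
    expect_true(all(diff(enr$overlap) >= 0))
    expect_true(all(enr$p_value > 0 & enr$p_value <= 1))

    # disjoint set: K = 0 and p = 1 everywhere
    enr0 <- topNEnrichment(ranked, GeneSet("none", c("zz1", "zz2")),
                           universe2, N = c(30, 60))
    expect_true(all(enr0$pathway_in_universe == 0))
    expect_true(all(enr0$p_value == 1))

    # set equal to the universe: the draw is saturated, p = 1
    enrU <- topNEnrichment(ranked, GeneSet("all", universe2), universe2,
                           N = 30)
    expect_equal(enrU$overlap, 30)
    expect_equal(enrU$p_value, 1)

    expect_warning(topNEnrichment(ranked[1:50], gs, universe2, N = 60),
                   "truncated")
})

test_that("gene ranking breaks permutation-p ties deterministically", {
    assoc <- data.frame(
        gene_id = c("b", "a", "c", "d"), component = "erex",
        perm_p = c(0.01, 0.01, 0.001, 0.01),
        lrt_stat = c(5, 5, 9, 7))
    expect_identical(rankGenes(assoc, "erex"), c("c", "d", "a", "b"))
    expect_error(rankGenes(assoc, "grex"), "no rows")
})

test_that("pi1 estimation matches hand counts and simulations", {
    expect_warning(
        expect_equal(estimatePi1(c(0.001, 0.2, 0.4, 0.6, 0.8, 1.0),
                                 lambda = 0.5)$pi1, 0),
        "fewer than 10")
    r <- suppressWarnings(
        estimatePi1(c(0.001, 0.002, 0.003, 0.6, 0.9), lambda = 0.5))
    expect_equal(r$pi0, 0.8)
    expect_equal(r$pi1, 0.2, tolerance = 1e-12)
    expect_error(estimatePi1(c(0.2, 0.3), lambda = 1), "lambda")
    expect_error(estimatePi1(c(0, 0.3)), "0, 1")

    set.seed(91)
    pUnif <- runif(10000)
    expect_lt(estimatePi1(pUnif)$pi1, 0.02)

    # permutation invariance
    p <- runif(50)
    expect_equal(estimatePi1(p)$pi1, estimatePi1(rev(p))$pi1)
})

test_that("threshold counts reproduce the published worked examples", {
    # interferon pathway table: exactly two genes (MX1, IRF7) reach
    # GReX significance at 0.05
    ifn <- associationLong(exampleTable("ifn_odegs"))
    tc <- thresholdCounts(ifn)
    expect_equal(unname(tc$counts["grex"]), 2L)
    expect_setequal(tc$members$grex, c("MX1", "IRF7"))
    expect_equal(unname(tc$counts["erex"]), 10L)

    # GReX-associated table: nine genes pass for both components
    grexTab <- associationLong(exampleTable("grex_odegs"))
    tc2 <- thresholdCounts(grexTab)
    expect_equal(unname(tc2$counts["erex"]), 9L)
    expect_equal(unname(tc2$overlap["grex&erex"]), 9L)

    # empty table: zero counts
    e <- thresholdCounts(ifn[0, ])
    expect_equal(sum(unlist(e$counts)), 0)
})
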