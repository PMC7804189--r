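# independent oracles and small fixture builders shared across tests

# exact HWE p by direct enumeration: conditional on the minor-allele
# count, weight(h) = multinomial(n; aa, h, bb) * 2^h, normalized by the
# total C(2n, nMinor) pairings (closed form, no log-space recurrence)
oracleHweP <- function(aa, ab, bb) {
    n <- aa + ab + bb
    nAlt <- ab + 2 * bb
    nMin <- min(nAlt, 2 * n - nAlt)
    hets <- seq(nMin %% 2, nMin, by = 2)
    w <- vapply(hets, function(h) {
        a <- (nMin - h) / 2
        b <- n - a - h
        choose(n, a) * choose(n - a, h) * 2^h
    }, 0)
    tot <- choose(2 * n, nMin)
    wObs <- w[match(ab, hets)]
    sum(w[w <= wObs * (1 + 1e-12)]) / tot
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n)
# draws from a labelled universe (feasible for N <= 12)
oracleHyperTail <- function(universe, K, n, x) {
    draws <- utils::combn(universe, n)
    hits <- colSums(draws <= K)          # members are labelled 1..K
    mean(hits >= x)
}

# G-statistic of a 2x2 table: 2 * sum O log(O/E)
oracleGStat <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
}

# all permutations of a vector (recursive; n <= 7 in tests)
allPerms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
        cbind(v[i], allPerms(v[-i]))))
}

# a tiny aligned cohort for io/association plumbing tests
tinyCohort <- function(n = 60, G = 5, seed = 42) {
    cfg <- simulationConfig(nSamples = n, nCases = n %/% 2, nGenes = G,
                            snpsPerGene = 6, nCausalPerGene = 2,
                            h2PerGene = 0.3, nCovariates = 2,
                            nGenotypePCs = 2, seed = seed)
    simulateCohort(cfg)
}

writeTinyVcf <- function(path, headerLines, bodyLines) {
    writeLines(c("##fileformat=VCFv4.2", headerLines, bodyLines), path)
    path
}
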