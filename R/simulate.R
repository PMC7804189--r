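#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-cohort
#' generator. Defaults are the desk-scale preset used throughout the
#' package: a 922-subject cohort (463 cases / 459 controls), 200 genes
#' with 30 cis SNPs each of which 8 carry causal weights, and a cis
#' heritability of 0.15 per gene — the middle of the twin-study range
#' for blood expression.
#'
#' @param nSamples cohort size.
#' @param nCases number of cases (the rest are controls).
#' @param nGenes number of genes.
#' @param snpsPerGene cis variants simulated per gene.
#' @param mafRange ALT-allele frequency range, within (0, 0.5].
#' @param h2PerGene target cis heritability in [0, 1); scalar or one
#'   value per gene.
#' @param nCausalPerGene number of variants per gene with non-zero
#'   weight.
#' @param envEffectGenes gene ids (or indices) whose environmental
#'   component shifts with case status.
#' @param envEffectSize standardized mean shift, in units of the
#'   environmental SD.
#' @param grexEffectGenes gene ids whose genetic component feeds the
#'   phenotype liability.
#' @param grexEffectSize log-odds slope per SD of genetic value.
#' @param nCovariates number of simulated clinical covariates.
#' @param envShare fraction of the non-genetic variance that is
#'   structured environment (the rest is iid noise).
#' @param nGenotypePCs genotype PCs appended to the covariate table.
#' @param seed RNG seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nSamples = 922L, nCases = 463L, nGenes = 200L,
                             snpsPerGene = 30L, mafRange = c(0.05, 0.5),
                             h2PerGene = 0.15, nCausalPerGene = 8L,
                             envEffectGenes = character(),
                             envEffectSize = 0,
                             grexEffectGenes = character(),
                             grexEffectSize = 0,
                             nCovariates = 2L, envShare = 0.7,
                             nGenotypePCs = 5L, seed = 1L) {
    cfg <- list(nSamples = as.integer(nSamples), nCases = as.integer(nCases),
                nGenes = as.integer(nGenes),
                snpsPerGene = as.integer(snpsPerGene), mafRange = mafRange,
                h2PerGene = h2PerGene,
                nCausalPerGene = as.integer(nCausalPerGene),
                envEffectGenes = envEffectGenes,
                envEffectSize = envEffectSize,
                grexEffectGenes = grexEffectGenes,
                grexEffectSize = grexEffectSize,
                nCovariates = as.integer(nCovariates), envShare = envShare,
                nGenotypePCs = as.integer(nGenotypePCs),
                seed = as.integer(seed))
    if (cfg$nCases >= cfg$nSamples || cfg$nCases < 1L)
        stop("need 0 < nCases < nSamples")
    if (any(cfg$h2PerGene < 0) || any(cfg$h2PerGene >= 1))
        stop("h2 values must lie in [0, 1)")
    if (!length(cfg$h2PerGene) %in% c(1L, cfg$nGenes))
        stop("h2PerGene must be scalar or one value per gene")
    if (cfg$mafRange[1L] <= 0 || cfg$mafRange[2L] > 0.5 ||
        cfg$mafRange[1L] > cfg$mafRange[2L])
        stop("mafRange must be within (0, 0.5]")
    if (cfg$nCausalPerGene > cfg$snpsPerGene)
        stop("nCausalPerGene cannot exceed snpsPerGene")
    if (cfg$envShare < 0 || cfg$envShare > 1)
        stop("envShare must be in [0, 1]")
    class(cfg) <- "SimulationConfig"
    cfg
}

.geneNames <- function(n) sprintf("gene%04d", seq_len(n))

.resolveGenes <- function(sel, genes) {
    if (is.numeric(sel)) sel <- genes[sel]
    bad <- setdiff(sel, genes)
    if (length(bad))
        stop("unknown effect gene(s): ", paste(bad, collapse = ", "))
    sel
}

#' Simulate HWE-consistent genotype dosages
#'
#' Each variant's per-sample dosage is Binomial(2, f) with an ALT
#' frequency f drawn uniformly from \code{mafRange}; variants are
#' mutually independent (no LD). Deterministic given \code{seed}.
#'
#' @param nSamples,nVariants dimensions.
#' @param mafRange frequency range within (0, 0.5].
#' @param seed RNG seed.
#' @param chrom chromosome label for the variant metadata.
#' @param posStart 1-based position of the first variant; variants are
#'   spaced 1 kb apart.
#' @param prefix id prefix for samples/variants.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
simulateGenotypes <- function(nSamples, nVariants, mafRange = c(0.05, 0.5),
                              seed = 1L, chrom = "1", posStart = 1L,
                              prefix = "") {
    if (mafRange[1L] <= 0 || mafRange[2L] > 0.5 ||
        mafRange[1L] > mafRange[2L])
        stop("mafRange must be within (0, 0.5]")
    withSeed(seed, {
        f <- stats::runif(nVariants, mafRange[1L], mafRange[2L])
        d <- vapply(f, function(p) stats::rbinom(nSamples, 2L, p),
                    numeric(nSamples))
    })
    dimnames(d) <- list(sprintf("%ss%04d", prefix, seq_len(nSamples)),
                        sprintf("%sv%05d", prefix, seq_len(nVariants)))
    vm <- data.frame(chrom = chrom,
                     pos = posStart + 1000L * (seq_len(nVariants) - 1L),
                     ref = "A", alt = "G", row.names = colnames(d))
    GenotypeMatrix(d, vm)
}

#' Simulate a sparse cis-weight matrix
#'
#' Per gene, \code{nCausal} of its cis variants receive independent
#' Normal(0, effectSd^2) weights; all other variants are absent.
#' Emulates the sparsity pattern of elastic-net trained TWAS weights.
#'
#' @param variantsByGene named list: gene id -> character vector of its
#'   cis variant ids.
#' @param nCausal causal variants per gene (scalar or per-gene); 0 drops
#'   the gene from the result.
#' @param effectSd SD of the causal weights.
#' @param seed RNG seed.
#' @param effectAllele effect allele recorded per variant (default
#'   \code{"G"}, the simulated ALT).
#' @return A \linkS4class{WeightMatrix}.
#' @export
simulateWeights <- function(variantsByGene, nCausal, effectSd = 1,
                            seed = 1L, effectAllele = "G") {
    genes <- names(variantsByGene)
    nCausal <- rep_len(as.integer(nCausal), length(genes))
    avail <- lengths(variantsByGene)
    if (any(nCausal > avail))
        stop("nCausal exceeds available variants for gene(s): ",
             paste(genes[nCausal > avail], collapse = ", "))
    rows <- withSeed(seed, {
        lapply(seq_along(genes), function(i) {
            if (nCausal[i] == 0L) return(NULL)
            vv <- sample(variantsByGene[[i]], nCausal[i])
            data.frame(gene = genes[i], variant = vv,
                       weight = stats::rnorm(nCausal[i], 0, effectSd),
                       effect_allele = effectAllele)
        })
    })
    WeightMatrix(do.call(rbind, c(rows,
        list(data.frame(gene = character(), variant = character(),
                        weight = numeric(), effect_allele = character())))),
        tissue = "simulated")
}

#' Simulate a full cohort with known architecture
#'
#' Builds genotypes, true cis weights, an observed expression matrix that
#' is exactly the sum of a genetic component, a structured environmental
#' component and iid noise, a binary phenotype tied to configurable
#' mixtures of the two components, and a tagged covariate table.
#'
#' Per gene g with target heritability h2_g, the genetic value is the
#' weighted dosage score rescaled to an empirical SD of sqrt(h2_g); the
#' environmental component is Normal(0, envShare * (1 - h2_g)) plus a
#' mean shift of \code{envEffectSize} environmental SDs in cases for the
#' \code{envEffectGenes}; the remaining variance is iid noise. The
#' phenotype is drawn liability-style: a logistic deviate is added to
#' \code{grexEffectSize} times the summed standardized genetic values of
#' the \code{grexEffectGenes}, and the \code{nCases} highest-liability
#' subjects become cases, so exact case/control counts are achieved.
#'
#' Draw order is fixed (genotypes, weights, environment, noise,
#' covariates, liability) so the cohort is fully reproducible from the
#' config.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return named list: \code{genotypes} (\linkS4class{GenotypeMatrix}),
#'   \code{bundle} (\linkS4class{ExpressionBundle}, observed only),
#'   \code{covariates} (\linkS4class{CovariateTable}), \code{phenotype}
#'   (\linkS4class{Phenotype}), \code{weights}
#'   (\linkS4class{WeightMatrix}), \code{cisSets} (gene -> variant ids),
#'   and \code{truth}: list with \code{trueGrex}, \code{trueEnv},
#'   \code{noise} (samples x genes, observed = trueGrex + trueEnv +
#'   noise exactly), \code{trueH2}, and per-gene \code{labels} in
#'   \{env_driven, grex_driven, both, null\}.
#' @export
simulateCohort <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    n <- config$nSamples
    G <- config$nGenes
    genes <- .geneNames(G)
    h2 <- rep_len(config$h2PerGene, G)
    envG <- .resolveGenes(config$envEffectGenes, genes)
    grexG <- .resolveGenes(config$grexEffectGenes, genes)
    seeds <- deriveSeeds(config$seed, 6L)

    gm <- simulateGenotypes(n, G * config$snpsPerGene,
                            mafRange = config$mafRange, seed = seeds[1L])
    d <- dosages(gm)
    cisSets <- split(colnames(d),
                     rep(genes, each = config$snpsPerGene))[genes]
    nCausal <- ifelse(h2 > 0, config$nCausalPerGene, 0L)
    wm <- simulateWeights(cisSets, nCausal, seed = seeds[2L])

    trueGrex <- matrix(0, n, G, dimnames = list(rownames(d), genes))
    for (i in seq_len(G)) {
        if (h2[i] == 0 || !genes[i] %in% geneIds(wm)) next
        vv <- intersect(cisSets[[i]], variantIds(wm))
        w <- as.numeric(weightValues(wm)[genes[i], vv])
        raw <- drop(d[, vv, drop = FALSE] %*% w)
        s <- stats::sd(raw)
        if (s > 0)
            trueGrex[, i] <- (raw - mean(raw)) / s * sqrt(h2[i])
    }

    sdEnv <- sqrt(config$envShare * (1 - h2))
    sdNoise <- sqrt((1 - config$envShare) * (1 - h2))
    env <- withSeed(seeds[3L],
        matrix(stats::rnorm(n * G), n, G) %*% diag(sdEnv, G))
    noise <- withSeed(seeds[4L],
        matrix(stats::rnorm(n * G), n, G) %*% diag(sdNoise, G))
    dimnames(env) <- dimnames(noise) <- dimnames(trueGrex)

    clin <- withSeed(seeds[5L], {
        if (config$nCovariates > 0L)
            matrix(stats::rnorm(n * config$nCovariates), n,
                   dimnames = list(rownames(d),
                                   paste0("cov", seq_len(config$nCovariates))))
        else NULL
    })

    liab <- withSeed(seeds[6L], {
        eta <- if (length(grexG))
            config$grexEffectSize *
                rowSums(scale(trueGrex[, grexG, drop = FALSE]))
        else rep(0, n)
        eta + stats::rlogis(n)
    })
    st <- integer(n)
    st[order(liab, decreasing = TRUE)[seq_len(config$nCases)]] <- 1L

    if (length(envG))
        env[, envG] <- env[, envG] +
            outer(st, config$envEffectSize * sdEnv[match(envG, genes)])

    observed <- trueGrex + env + noise
    gpc <- if (config$nGenotypePCs > 0L)
        genotypePCs(d, k = config$nGenotypePCs) else NULL
    cov <- buildCovariates(clinical = clin, genotypePC = gpc)

    labels <- rep("null", G)
    labels[genes %in% envG] <- "env_driven"
    labels[genes %in% grexG] <- "grex_driven"
    labels[genes %in% intersect(envG, grexG)] <- "both"
    names(labels) <- genes
    names(h2) <- genes

    list(genotypes = gm,
         bundle = ExpressionBundle(observed),
         covariates = cov,
         phenotype = Phenotype(rownames(d), st),
         weights = wm,
         cisSets = cisSets,
         truth = list(trueGrex = trueGrex, trueEnv = env, noise = noise,
                      trueH2 = h2, labels = labels))
}
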