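#' Minor allele frequency of a dosage vector
#'
#' The ALT-allele frequency is \code{mean(dosage)/2}; the MAF is the
#' smaller of that and its complement, hence always in [0, 0.5].
#'
#' @param d numeric dosage vector in [0, 2].
#' @return MAF in [0, 0.5].
#' @examples
#' variantMAF(c(0, 1, 2, 2))  # ALT frequency 0.625 -> MAF 0.375
#' @export
variantMAF <- function(d) {
    if (!length(d)) stop("empty dosage vector")
    if (min(d) < 0 || max(d) > 2) stop("dosages must lie in [0, 2]")
    f <- mean(d) / 2
    min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Standard exact conditional test: conditioning on the observed minor
#' allele count, every compatible heterozygote count is weighted by its
#' conditional probability, and the p-value is the total probability of
#' configurations no more probable than the observed one (no mid-p).
#' Computed in log space.
#'
#' @param nHomRef,nHet,nHomAlt non-negative genotype counts.
#' @return exact p-value in (0, 1].
#' @examples
#' hweExactP(1, 2, 1)    # modal configuration -> 1
#' hweExactP(0, 100, 0)  # extreme heterozygote excess -> ~0
#' @export
hweExactP <- function(nHomRef, nHet, nHomAlt) {
    cnt <- c(nHomRef, nHet, nHomAlt)
    if (any(cnt < 0) || any(cnt != round(cnt)))
        stop("genotype counts must be non-negative integers")
    if (sum(cnt) == 0L) stop("all genotype counts are zero")
    n <- sum(cnt)
    nAlt <- nHet + 2L * nHomAlt
    nMin <- min(nAlt, 2L * n - nAlt)
    # heterozygote counts share the parity of the minor-allele count
    hets <- seq(nMin %% 2L, nMin, by = 2L)
    logw <- vapply(hets, function(h) {
        aa <- (nMin - h) / 2
        bb <- n - aa - h
        lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
            h * log(2)
    }, 0)
    logw <- logw - max(logw)
    pr <- exp(logw) / sum(exp(logw))
    pObs <- pr[match(nHet, hets)]
    if (is.na(pObs)) stop("heterozygote count incompatible with totals")
    min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

#' MAF / HWE variant quality control
#'
#' Retains variants with MAF strictly greater than \code{mafThreshold}
#' and exact HWE p strictly greater than \code{hweThreshold} (both
#' strict, so a variant at MAF exactly 0.05 is removed). Dosages are
#' rounded to the nearest genotype class for the HWE counts when they
#' are non-integer (imputed) values.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param mafThreshold MAF cutoff (default 0.05).
#' @param hweThreshold HWE exact-test p cutoff (default 0.05).
#' @return list with \code{genotypes} (filtered
#'   \linkS4class{GenotypeMatrix}) and \code{qc}, a data.frame with
#'   \code{variant_id}, \code{maf}, \code{hwe_p} and \code{pass} for
#'   every input variant.
#' @export
qcFilter <- function(genotypes, mafThreshold = 0.05, hweThreshold = 0.05) {
    d <- dosages(genotypes)
    maf <- apply(d, 2L, variantMAF)
    hwe <- apply(d, 2L, function(v) {
        g <- pmin(pmax(round(v), 0), 2)
        hweExactP(sum(g == 0), sum(g == 1), sum(g == 2))
    })
    pass <- maf > mafThreshold & hwe > hweThreshold
    qc <- data.frame(variant_id = colnames(d), maf = maf, hwe_p = hwe,
                     pass = pass, row.names = NULL)
    list(genotypes = genotypes[pass, ], qc = qc)
}

#' Impute the genetically regulated expression component
#'
#' GReX of gene g in sample s is the dot product of the gene's weights
#' with the sample's (effect-allele aligned) dosages, summed over the
#' weight variants present in the genotype data, in ascending variant-id
#' order. Dosages of variants whose effect allele equals the REF allele
#' are flipped to \code{2 - d}; strand-ambiguous variants (A/T, C/G) are
#' used as-is with a warning; variants whose effect allele matches
#' neither allele are dropped. Genes with no overlapping variant are
#' omitted from the matrix and reported.
#'
#' @param genotypes a QC-filtered \linkS4class{GenotypeMatrix}.
#' @param weights a \linkS4class{WeightMatrix}.
#' @return list with \code{grex} (samples x genes matrix) and
#'   \code{coverage}, a data.frame per weight-matrix gene with
#'   \code{n_weights}, \code{n_used} and \code{predicted}.
#' @export
predictGrex <- function(genotypes, weights) {
    d <- dosages(genotypes)
    vm <- variantMeta(genotypes)
    w <- weightValues(weights)
    w <- w[, order(colnames(w)), drop = FALSE]   # fixed summation order
    ea <- effectAlleles(weights)
    common <- intersect(colnames(w), colnames(d))
    flip <- dropped <- character()
    ambiPairs <- c(A = "T", T = "A", C = "G", G = "C")
    for (v in common) {
        i <- match(v, vm$variant_id)
        eff <- ea[[v]]
        if (eff == vm$alt[i]) next
        if (eff == vm$ref[i]) flip <- c(flip, v)
        else dropped <- c(dropped, v)
        if (!is.na(ambiPairs[vm$ref[i]]) &&
            ambiPairs[vm$ref[i]] == vm$alt[i])
            warning("strand-ambiguous variant used as-is: ", v)
    }
    common <- setdiff(common, dropped)
    if (length(dropped))
        warning(length(dropped),
                " variant(s) dropped: effect allele matches neither ",
                "REF nor ALT")
    dm <- d[, common, drop = FALSE]
    if (length(flip)) dm[, flip] <- 2 - dm[, flip]
    wUsed <- w[, common, drop = FALSE]
    nUsed <- Matrix::rowSums(wUsed != 0)
    keep <- nUsed > 0
    grex <- as.matrix(Matrix::tcrossprod(dm, wUsed[keep, , drop = FALSE]))
    dimnames(grex) <- list(rownames(d), rownames(w)[keep])
    coverage <- data.frame(gene = rownames(w),
                           n_weights = Matrix::rowSums(w != 0),
                           n_used = nUsed, predicted = keep,
                           row.names = NULL)
    list(grex = grex, coverage = coverage)
}

#' Train sparse cis prediction weights with cross-validated R2
#'
#' Per gene, an elastic-net model (mixing parameter \code{alpha},
#' penalty chosen by internal 5-fold cross-validation) of expression on
#' cis dosages, in the style of TWAS reference-panel training. The
#' reported \code{cv_r2} is the squared Pearson correlation between
#' out-of-fold predictions and observed expression over \code{nFolds}
#' (default ten) outer folds; all fold assignments derive from
#' \code{seed}, so training is deterministic.
#'
#' @param genotypes \linkS4class{GenotypeMatrix} or samples x variants
#'   dosage matrix of the reference cohort (>= 20 samples).
#' @param expression samples x genes matrix aligned to the genotypes.
#' @param cisSets named list: gene id -> its cis variant ids.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param nFolds outer folds for cv_r2 (default 10).
#' @param seed RNG seed for fold assignment.
#' @return list with \code{weights} (\linkS4class{WeightMatrix}; genes
#'   whose final model has no non-zero weight are absent) and
#'   \code{performance}, a data.frame with \code{gene}, \code{cv_r2}
#'   and \code{n_folds}. Genes with constant expression are skipped
#'   with a warning.
#' @export
trainWeights <- function(genotypes, expression, cisSets, alpha = 0.5,
                         nFolds = 10L, seed = 1L) {
    d <- if (is(genotypes, "GenotypeMatrix")) dosages(genotypes)
         else genotypes
    n <- nrow(d)
    if (n < 20L) stop("need at least 20 reference samples")
    stopifnot(identical(rownames(d), rownames(expression)))
    genes <- intersect(names(cisSets), colnames(expression))
    seeds <- deriveSeeds(seed, length(genes) + 1L)
    foldid <- withSeed(seeds[1L],
                       sample(rep_len(seq_len(nFolds), n)))
    rows <- list()
    perf <- data.frame(gene = genes, cv_r2 = NA_real_,
                       n_folds = as.integer(nFolds))
    for (k in seq_along(genes)) {
        g <- genes[k]
        y <- expression[, g]
        if (stats::sd(y) == 0) {
            warning("constant expression for gene ", g, "; skipped")
            next
        }
        X <- d[, cisSets[[g]], drop = FALSE]
        innerSeeds <- deriveSeeds(seeds[k + 1L], nFolds + 1L)
        pred <- rep(NA_real_, n)
        for (f in seq_len(nFolds)) {
            tr <- foldid != f
            cvf <- withSeed(innerSeeds[f],
                glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr],
                                  alpha = alpha, nfolds = 5L,
                                  standardize = TRUE))
            pred[!tr] <- as.numeric(
                stats::predict(cvf, X[!tr, , drop = FALSE],
                               s = "lambda.min"))
        }
        r <- if (stats::sd(pred) > 0) stats::cor(pred, y) else 0
        perf$cv_r2[k] <- r^2
        cvAll <- withSeed(innerSeeds[nFolds + 1L],
            glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = 5L,
                              standardize = TRUE))
        co <- as.matrix(stats::coef(cvAll, s = "lambda.min"))[-1L, 1L]
        nz <- which(co != 0)
        if (length(nz))
            rows[[g]] <- data.frame(gene = g, variant = colnames(X)[nz],
                                    weight = unname(co[nz]),
                                    effect_allele = "G")
    }
    wm <- WeightMatrix(do.call(rbind, c(rows,
        list(data.frame(gene = character(), variant = character(),
                        weight = numeric(), effect_allele = character())))),
        tissue = "trained")
    list(weights = wm, performance = perf)
}

# eigen summaries reused by the REML profile: economy SVD of the
# standardized dosage matrix; the rank-deficient remainder of the GRM
# spectrum is handled in closed form.
.remlParts <- function(dosages, y) {
    Z <- scale(dosages)
    Z <- Z[, apply(dosages, 2L, stats::sd) > 0, drop = FALSE]
    m <- ncol(Z)
    if (m < 2L) stop("need >= 2 polymorphic cis variants")
    n <- nrow(Z)
    if (n < 50L) stop("need >= 50 samples for REML")
    sv <- svd(Z, nu = min(n, m), nv = 0)
    dvals <- sv$d^2 / m                      # non-zero GRM eigenvalues
    r <- sum(dvals > 1e-12)
    U <- sv$u[, seq_len(r), drop = FALSE]
    dvals <- dvals[seq_len(r)]
    one <- rep(1, n)
    w1 <- drop(crossprod(U, y))
    v1 <- drop(crossprod(U, one))
    list(n = n, m = m, r = r, d = dvals, w1 = w1, v1 = v1,
         Sww0 = sum(y^2) - sum(w1^2),
         Svw0 = sum(y) - sum(v1 * w1),
         Svv0 = n - sum(v1^2))
}

.remlLogLik <- function(parts, h2) {
    lam <- h2 * parts$d + (1 - h2)
    lam0 <- 1 - h2
    A <- sum(parts$v1^2 / lam) + parts$Svv0 / lam0
    B <- sum(parts$v1 * parts$w1 / lam) + parts$Svw0 / lam0
    C <- sum(parts$w1^2 / lam) + parts$Sww0 / lam0
    rss <- max(C - B^2 / A, 1e-300)
    n <- parts$n
    sig2 <- rss / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi * sig2) + 1) +
            sum(log(lam)) + (n - parts$r) * log(lam0) + log(A))
}

#' Restricted-likelihood profile over the heritability ratio
#'
#' Evaluates the restricted log-likelihood of the single-variance-
#' component model y ~ N(mu, sigma_g^2 * GRM + sigma_e^2 * I) on a grid
#' of h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) values, with the GRM
#' built as Z Z' / m from column-standardized dosages. Used by
#' \code{\link{estimateH2}} and as a grid diagnostic.
#'
#' @param dosages samples x cis-variants dosage matrix.
#' @param y expression vector.
#' @param h2 vector of ratio values in [0, 1).
#' @return numeric vector of restricted log-likelihoods.
#' @export
remlProfile <- function(dosages, y, h2) {
    parts <- .remlParts(dosages, y)
    vapply(h2, function(r) .remlLogLik(parts, r), 0)
}

#' Local heritability by single-component REML
#'
#' Estimates the fraction of expression variance attributable to the
#' cis-variant GRM by maximizing the restricted log-likelihood over the
#' variance ratio with one-dimensional bounded search (tolerance 1e-6)
#' on the GRM eigenbasis. Estimates are clamped to [0, 1].
#'
#' @param dosages samples x cis-variants dosage matrix (>= 2 polymorphic
#'   variants, >= 50 samples).
#' @param y expression vector aligned to the rows of \code{dosages}.
#' @return list with \code{h2}, \code{loglik} at the optimum and
#'   \code{n_snps} used.
#' @export
estimateH2 <- function(dosages, y) {
    parts <- .remlParts(dosages, y)
    opt <- stats::optimize(function(r) .remlLogLik(parts, r),
                           c(0, 1 - 1e-8), maximum = TRUE, tol = 1e-6)
    # the interior search cannot sit exactly on the bounds; probe them
    cand <- c(opt$maximum, 0)
    ll <- c(opt$objective, .remlLogLik(parts, 0))
    best <- which.max(ll)
    list(h2 = min(max(cand[best], 0), 1), loglik = ll[best],
         n_snps = parts$m)
}

#' Correlation between cross-validated R2 and REML heritability
#'
#' The sanity check that trained prediction models capture the
#' cis-genetic signal: across genes, cross-validated prediction R2
#' should track the REML heritability estimate.
#'
#' @param performance data.frame from \code{\link{trainWeights}} (columns
#'   \code{gene}, \code{cv_r2}).
#' @param heritability data.frame with columns \code{gene}, \code{h2}.
#' @return Pearson correlation across the >= 3 genes present in both.
#' @export
r2H2Correlation <- function(performance, heritability) {
    m <- merge(performance[, c("gene", "cv_r2")],
               heritability[, c("gene", "h2")], by = "gene")
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) < 3L) stop("need >= 3 genes with both cv_r2 and h2")
    if (stats::sd(m$cv_r2) == 0 || stats::sd(m$h2) == 0)
        stop("zero variance in cv_r2 or h2; correlation undefined")
    stats::cor(m$cv_r2, m$h2)
}
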