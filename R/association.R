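#' Component-specific covariate policy
#'
#' Which covariate tags enter the null (background) logistic model for
#' each expression component. The default mirrors the design rationale
#' of GReX being a pure genotype function: expression PCs are
#' confounders for the observed and EReX analyses but not for GReX,
#' while genotype PCs (population stratification) enter every analysis,
#' as do clinical covariates.
#'
#' @param observed,grex,erex character vectors of tags from
#'   \{\code{clinical}, \code{expression_pc}, \code{genotype_pc}\}.
#' @return validated named list of class \code{CovariatePolicy}.
#' @export
covariatePolicy <- function(
        observed = c("clinical", "expression_pc", "genotype_pc"),
        grex = c("clinical", "genotype_pc"),
        erex = c("clinical", "expression_pc", "genotype_pc")) {
    pol <- list(observed = observed, grex = grex, erex = erex)
    for (nm in names(pol))
        if (!all(pol[[nm]] %in% .covariateTags))
            stop("unknown covariate tag in policy for ", nm)
    if ("expression_pc" %in% pol$grex)
        stop("the grex policy must exclude expression PCs: GReX is a ",
             "function of genotype only")
    for (nm in c("observed", "erex"))
        if (!"expression_pc" %in% pol[[nm]])
            stop("the ", nm, " policy must include expression PCs")
    for (nm in names(pol))
        if (!"genotype_pc" %in% pol[[nm]])
            stop("every policy must include genotype PCs")
    class(pol) <- "CovariatePolicy"
    pol
}

# covariate design matrix (with intercept) for one component
.designFor <- function(covariates, tags) {
    if (is.null(covariates))
        return(matrix(1, 0L, 1L))
    keep <- covariateTags(covariates) %in% tags
    cbind(`(Intercept)` = 1,
          as.matrix(covariateData(covariates)[, keep, drop = FALSE]))
}

#' Likelihood-ratio statistic for one gene variable
#'
#' Compares the maximized likelihood of the logistic null model (case /
#' control status on the covariates) with the full model adding the
#' gene variable: \code{lrt = 2 (ll_full - ll_null)}, floored at zero.
#' Convergence uses a relative log-likelihood tolerance of 1e-10 with at
#' most 100 Newton iterations. Perfect separation triggers a refit with
#' a small ridge penalty (1e-6) on the gene coefficient and a flag.
#'
#' @param status 0/1 vector with both classes present.
#' @param geneVariable numeric vector (observed expression, GReX or
#'   EReX of one gene).
#' @param covariates \linkS4class{CovariateTable}, numeric matrix, or
#'   NULL for an intercept-only null model.
#' @return list: \code{stat}, \code{analytic_p} (chi-square(1) upper
#'   tail, diagnostic only), \code{separated}.
#' @export
lrtStatistic <- function(status, geneVariable, covariates = NULL) {
    status <- as.numeric(status)
    if (!all(status %in% c(0, 1)) || length(unique(status)) < 2L)
        stop("status must be 0/1 with both classes present")
    Xnull <- .nullDesign(covariates, length(status))
    if (length(status) < ncol(Xnull) + 6L)
        stop("too few samples for the model size")
    if (stats::sd(geneVariable) == 0)
        return(list(stat = 0, analytic_p = 1, separated = FALSE))
    f <- .cpp_logistic_lrt(Xnull, geneVariable, status)
    list(stat = f$stat,
         analytic_p = stats::pchisq(f$stat, 1L, lower.tail = FALSE),
         separated = f$separated)
}

.nullDesign <- function(covariates, n) {
    if (is.null(covariates)) return(matrix(1, n, 1L))
    if (is(covariates, "CovariateTable"))
        covariates <- as.matrix(covariateData(covariates))
    storage.mode(covariates) <- "double"
    cbind(1, covariates)
}

#' Permutation p-value for one gene variable
#'
#' Freedman-Lane scheme: the gene variable is regressed on the null-
#' model covariates by OLS, the residuals are permuted with a seeded
#' generator, the fitted values are added back and the LRT recomputed.
#' With no covariates this reduces exactly to permuting the gene
#' variable. \code{b_exceed} counts permuted statistics at least as
#' large as the observed one; if none are seen after \code{bInitial}
#' permutations the count is escalated to \code{bMax} total
#' permutations, and a still-zero count is reported as the upper bound
#' \code{1/bMax} with a flag.
#'
#' @inheritParams lrtStatistic
#' @param bInitial initial permutation count (default 8000).
#' @param bMax escalated total (default 1e6).
#' @param seed RNG seed for the permutation stream.
#' @param returnStats also return the \code{bInitial} permuted
#'   statistics (for diagnostics; never kept during escalation).
#' @return list: \code{stat}, \code{analytic_p}, \code{separated},
#'   \code{b_exceed}, \code{B}, \code{perm_p}, \code{upper_bound}
#'   (TRUE when \code{perm_p} is the 1/bMax bound), optionally
#'   \code{perm_stats}.
#' @export
permutationP <- function(status, geneVariable, covariates = NULL,
                         bInitial = 8000L, bMax = 1000000L, seed = 1L,
                         returnStats = FALSE) {
    obs <- lrtStatistic(status, geneVariable, covariates)
    status <- as.numeric(status)
    Xnull <- .nullDesign(covariates, length(status))
    if (stats::sd(geneVariable) == 0) {
        out <- c(obs, list(b_exceed = bInitial, B = bInitial, perm_p = 1,
                           upper_bound = FALSE))
        if (returnStats) out$perm_stats <- rep(0, bInitial)
        return(out)
    }
    # OLS decomposition of the gene variable on the null covariates
    qr0 <- qr(Xnull)
    gfit <- qr.fitted(qr0, geneVariable)
    gres <- geneVariable - gfit
    seeds <- deriveSeeds(seed, 2L)
    pr <- .cpp_perm_lrt(Xnull, gfit, gres, status, obs$stat,
                        as.integer(bInitial), as.double(seeds[1L]),
                        return_stats = returnStats)
    b <- pr$b_exceed
    B <- bInitial
    if (b == 0 && bMax > bInitial) {
        pr2 <- .cpp_perm_lrt(Xnull, gfit, gres, status, obs$stat,
                             as.integer(bMax - bInitial),
                             as.double(seeds[2L]))
        b <- b + pr2$b_exceed
        B <- bMax
    }
    upper <- b == 0
    out <- c(obs, list(b_exceed = b, B = B,
                       perm_p = if (upper) 1 / B else b / B,
                       upper_bound = upper))
    if (returnStats) out$perm_stats <- pr$stats
    out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' validated to lie in (0, 1].
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bhFDR <- function(p) {
    if (any(p <= 0 | p > 1 | is.na(p)))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Component-wise permutation association scan
#'
#' Runs the LRT + permutation test of case/control status against every
#' gene for each requested expression component, using the
#' component-specific covariate sets of \code{policy}. Per-gene,
#' per-component permutation streams are derived from \code{seed} by
#' position, so results do not depend on execution order. Within each
#' component, q-values are Benjamini-Hochberg over the genes.
#'
#' @param bundle \linkS4class{ExpressionBundle} with the assays needed
#'   by \code{components}.
#' @param phenotype \linkS4class{Phenotype} over the bundle's samples.
#' @param covariates \linkS4class{CovariateTable} (or NULL).
#' @param policy a \code{\link{covariatePolicy}}.
#' @param components subset of \code{c("observed", "grex", "erex")}.
#' @param bInitial,bMax permutation counts (see
#'   \code{\link{permutationP}}).
#' @param seed root seed.
#' @return data.frame with one row per gene x component: \code{gene_id},
#'   \code{component}, \code{lrt_stat}, \code{analytic_p},
#'   \code{b_exceed}, \code{B}, \code{perm_p}, \code{upper_bound},
#'   \code{separated}, \code{q_value}.
#' @export
runAssociation <- function(bundle, phenotype, covariates = NULL,
                           policy = covariatePolicy(),
                           components = c("observed", "grex", "erex"),
                           bInitial = 8000L, bMax = 1000000L, seed = 1L) {
    stopifnot(inherits(policy, "CovariatePolicy"))
    components <- match.arg(components, several.ok = TRUE)
    if (!identical(sampleIds(bundle), sampleIds(phenotype)))
        stop("bundle and phenotype sample ids differ; run alignCohort")
    if (!is.null(covariates) &&
        !identical(sampleIds(bundle), sampleIds(covariates)))
        stop("bundle and covariate sample ids differ; run alignCohort")
    st <- unname(status(phenotype))
    genes <- geneIds(bundle)
    allComp <- c("observed", "grex", "erex")
    seedTab <- matrix(deriveSeeds(seed, length(genes) * 3L),
                      nrow = length(genes),
                      dimnames = list(genes, allComp))
    res <- list()
    for (comp in components) {
        m <- .bundleAssay(bundle, comp)
        if (is.null(m))
            stop("bundle has no '", comp, "' assay")
        cv <- if (is.null(covariates)) NULL else {
            keep <- covariateTags(covariates) %in% policy[[comp]]
            as.matrix(covariateData(covariates)[, keep, drop = FALSE])
        }
        rows <- lapply(genes, function(g) {
            r <- permutationP(st, m[, g], cv, bInitial = bInitial,
                              bMax = bMax, seed = seedTab[g, comp])
            data.frame(gene_id = g, component = comp, lrt_stat = r$stat,
                       analytic_p = r$analytic_p, b_exceed = r$b_exceed,
                       B = r$B, perm_p = r$perm_p,
                       upper_bound = r$upper_bound,
                       separated = r$separated)
        })
        tab <- do.call(rbind, rows)
        tab$q_value <- bhFDR(tab$perm_p)
        res[[comp]] <- tab
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
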