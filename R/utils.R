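# internal helpers shared across modules

# run code under a temporary RNG seed, restoring the caller's stream
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# derive k child seeds (< 2^31) reproducibly from one root seed
deriveSeeds <- function(seed, k) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, k, replace = TRUE))
}

#' Principal components of an expression matrix
#'
#' Top-k principal component scores of a samples x genes matrix (columns
#' centered), used as expression-PC confounders in the association stage.
#'
#' @param x samples x genes numeric matrix.
#' @param k number of components (default 10, truncated to what the
#'   matrix supports).
#' @return samples x k matrix of scores, columns named \code{ePC1..k}.
#' @export
expressionPCs <- function(x, k = 10L) {
    xc <- scale(x, center = TRUE, scale = FALSE)
    k <- min(k, nrow(xc) - 1L, ncol(xc))
    if (k < 1L) stop("matrix too small for any principal component")
    sv <- svd(xc, nu = k, nv = 0)
    sc <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
    dimnames(sc) <- list(rownames(x), paste0("ePC", seq_len(k)))
    sc
}

#' Principal components of a dosage matrix
#'
#' Top-k genotype principal components, the population-stratification
#' covariates of the association stage. For wide matrices an evenly
#' spaced subset of variants (deterministic, no RNG) keeps the
#' cross-product affordable.
#'
#' @param dosages samples x variants dosage matrix, or a
#'   \linkS4class{GenotypeMatrix}.
#' @param k number of components (default 5).
#' @param maxVariants cap on the number of variants entering the PCA
#'   (default 2000).
#' @return samples x k score matrix, columns named \code{gPC1..k}.
#' @export
genotypePCs <- function(dosages, k = 5L, maxVariants = 2000L) {
    if (is(dosages, "GenotypeMatrix")) dosages <- dosages(dosages)
    v <- ncol(dosages)
    if (v > maxVariants)
        dosages <- dosages[, round(seq(1L, v, length.out = maxVariants)),
                           drop = FALSE]
    xc <- scale(dosages, center = TRUE, scale = FALSE)
    k <- min(k, nrow(xc) - 1L, ncol(xc))
    if (k < 1L) stop("matrix too small for any principal component")
    cp <- tcrossprod(xc)                 # n x n, cheap for cohort-scale n
    ev <- eigen(cp, symmetric = TRUE)
    sc <- ev$vectors[, seq_len(k), drop = FALSE] *
        rep(sqrt(pmax(ev$values[seq_len(k)], 0)), each = nrow(xc))
    dimnames(sc) <- list(rownames(dosages), paste0("gPC", seq_len(k)))
    sc
}

#' Assemble a CovariateTable from parts
#'
#' Binds clinical covariates, genotype PCs and expression PCs into one
#' tagged \linkS4class{CovariateTable} over a shared sample ordering.
#'
#' @param clinical data.frame or matrix of clinical covariates (may be
#'   NULL); rownames = sample ids.
#' @param genotypePC matrix of genotype PC scores (may be NULL).
#' @param expressionPC matrix of expression PC scores (may be NULL).
#' @return A \linkS4class{CovariateTable}.
#' @export
buildCovariates <- function(clinical = NULL, genotypePC = NULL,
                            expressionPC = NULL) {
    parts <- list(clinical = clinical, genotype_pc = genotypePC,
                  expression_pc = expressionPC)
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (!length(parts)) stop("no covariates supplied")
    ids <- rownames(parts[[1L]])
    dat <- do.call(cbind, lapply(parts, function(p) {
        p <- as.data.frame(p)
        if (!identical(rownames(p), ids))
            stop("covariate parts disagree on sample ids/order")
        p
    }))
    colnames(dat) <- unlist(lapply(parts, colnames), use.names = FALSE)
    rownames(dat) <- ids
    tags <- rep(names(parts), vapply(parts, ncol, 1L))
    CovariateTable(dat, tags = tags)
}
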