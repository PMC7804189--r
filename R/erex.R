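#' Environmentally regulated expression as per-gene regression residuals
#'
#' For every gene, observed expression is regressed on its imputed GReX
#' by ordinary least squares (with intercept, no covariates); the EReX
#' component is the residual vector. It therefore captures the
#' expression variability not explained by the cis-genetic component:
#' environmental effects plus any unmodeled (e.g. trans-genetic)
#' variance. By construction each gene's EReX is orthogonal to its
#' centered GReX, its mean is zero, and Var(observed) = Var(fitted) +
#' Var(EReX).
#'
#' Genes with zero-variance GReX keep their centered observed values as
#' EReX and are flagged in the fit summary rather than dropped.
#'
#' @param observed samples x genes matrix, or an
#'   \linkS4class{ExpressionBundle} carrying \code{observed} and
#'   \code{grex} assays.
#' @param grex samples x genes GReX matrix (ignored when
#'   \code{observed} is a bundle). Genes and samples must match
#'   \code{observed} exactly.
#' @return list with \code{erex} (samples x genes residual matrix),
#'   \code{fit} (data.frame: \code{gene}, \code{slope},
#'   \code{intercept}, \code{r2} variance explained,
#'   \code{degenerate} flag) and, when a bundle was supplied,
#'   \code{bundle}: the input \linkS4class{ExpressionBundle} with the
#'   \code{erex} assay added (restricted to genes present in both
#'   matrices).
#' @examples
#' obs <- matrix(c(1, 3, 2), 3, 1, dimnames = list(paste0("s", 1:3), "g"))
#' grx <- matrix(c(0, 1, 2), 3, 1, dimnames = dimnames(obs))
#' computeErex(obs, grx)$fit     # slope 0.5, intercept 1.5
#' @export
computeErex <- function(observed, grex = NULL) {
    bundle <- NULL
    if (is(observed, "ExpressionBundle")) {
        bundle <- observed
        grex <- grexExpr(bundle)
        if (is.null(grex)) stop("bundle has no grex assay")
        observed <- observedExpr(bundle)
        common <- intersect(colnames(observed), colnames(grex))
        observed <- observed[, common, drop = FALSE]
        grex <- grex[, common, drop = FALSE]
    }
    if (!identical(dimnames(observed), dimnames(grex)))
        stop("observed and grex matrices are not aligned")
    n <- nrow(observed)
    erex <- observed
    fit <- data.frame(gene = colnames(observed), slope = NA_real_,
                      intercept = NA_real_, r2 = NA_real_,
                      degenerate = FALSE, row.names = NULL)
    for (j in seq_len(ncol(observed))) {
        y <- observed[, j]
        x <- grex[, j]
        vx <- stats::var(x)
        if (vx == 0) {
            fit$slope[j] <- 0
            fit$intercept[j] <- mean(y)
            fit$r2[j] <- 0
            fit$degenerate[j] <- TRUE
            erex[, j] <- y - mean(y)
        } else {
            b <- stats::cov(x, y) / vx
            a <- mean(y) - b * mean(x)
            res <- y - a - b * x
            fit$slope[j] <- b
            fit$intercept[j] <- a
            vy <- stats::var(y)
            fit$r2[j] <- if (vy > 0) 1 - stats::var(res) / vy else 0
            erex[, j] <- res
        }
    }
    out <- list(erex = erex, fit = fit)
    if (!is.null(bundle)) {
        out$bundle <- ExpressionBundle(observed, grex = grex, erex = erex)
    }
    out
}
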