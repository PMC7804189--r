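#' Accessors for the core classes
#'
#' \code{dosages} returns the samples x variants dosage matrix of a
#' \linkS4class{GenotypeMatrix}; \code{variantMeta} its per-variant
#' metadata. \code{observedExpr}, \code{grexExpr} and \code{erexExpr}
#' return the samples x genes component matrices of an
#' \linkS4class{ExpressionBundle} (or \code{NULL} when the component has
#' not been computed yet). \code{sampleIds} and \code{geneIds} /
#' \code{variantIds} return the identifier vectors.
#'
#' @param x a package object.
#' @return See above.
#' @name accessors
#' @aliases dosages variantMeta observedExpr grexExpr erexExpr sampleIds
#'   geneIds variantIds weightValues effectAlleles tissueLabel status
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) t(assay(x, "dosage")))

#' @rdname accessors
#' @export
setGeneric("variantMeta", function(x) standardGeneric("variantMeta"))
#' @rdname accessors
#' @export
setMethod("variantMeta", "GenotypeMatrix", function(x) {
    df <- as.data.frame(rowData(x))
    df$variant_id <- rownames(x)
    df[, c("variant_id", "chrom", "pos", "ref", "alt")]
})

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionBundle", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "CovariateTable", function(x) rownames(x@data))
#' @rdname accessors
#' @export
setMethod("sampleIds", "Phenotype", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setMethod("variantIds", "GenotypeMatrix", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("variantIds", "WeightMatrix", function(x) colnames(x@weights))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionBundle", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("geneIds", "WeightMatrix", function(x) rownames(x@weights))

.bundleAssay <- function(x, name) {
    if (!name %in% assayNames(x)) return(NULL)
    t(assay(x, name))
}
#' @rdname accessors
#' @export
setGeneric("observedExpr", function(x) standardGeneric("observedExpr"))
#' @rdname accessors
#' @export
setMethod("observedExpr", "ExpressionBundle",
          function(x) .bundleAssay(x, "observed"))
#' @rdname accessors
#' @export
setGeneric("grexExpr", function(x) standardGeneric("grexExpr"))
#' @rdname accessors
#' @export
setMethod("grexExpr", "ExpressionBundle", function(x) .bundleAssay(x, "grex"))
#' @rdname accessors
#' @export
setGeneric("erexExpr", function(x) standardGeneric("erexExpr"))
#' @rdname accessors
#' @export
setMethod("erexExpr", "ExpressionBundle", function(x) .bundleAssay(x, "erex"))

#' @rdname accessors
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))
#' @rdname accessors
#' @export
setMethod("weightValues", "WeightMatrix", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("effectAlleles", function(x) standardGeneric("effectAlleles"))
#' @rdname accessors
#' @export
setMethod("effectAlleles", "WeightMatrix", function(x) x@effectAllele)

#' @rdname accessors
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))
#' @rdname accessors
#' @export
setMethod("tissueLabel", "WeightMatrix", function(x) x@tissue)

#' @rdname accessors
#' @export
setGeneric("status", function(x) standardGeneric("status"))
#' @rdname accessors
#' @export
setMethod("status", "Phenotype", function(x) {
    s <- x@status
    names(s) <- x@sampleIds
    s
})

#' Covariate data and tags
#'
#' \code{covariateData} returns the numeric covariate data.frame;
#' \code{covariateTags} the per-column tags.
#' @param x a \linkS4class{CovariateTable}.
#' @return data.frame or character vector.
#' @export
setGeneric("covariateData", function(x) standardGeneric("covariateData"))
#' @rdname covariateData
#' @export
setMethod("covariateData", "CovariateTable", function(x) x@data)
#' @rdname covariateData
#' @export
setGeneric("covariateTags", function(x) standardGeneric("covariateTags"))
#' @rdname covariateData
#' @export
setMethod("covariateTags", "CovariateTable", function(x) {
    tg <- x@tags
    names(tg) <- colnames(x@data)
    tg
})

setMethod("show", "WeightMatrix", function(object) {
    w <- object@weights
    cat("WeightMatrix [", object@tissue, "]: ", nrow(w), " genes, ",
        ncol(w), " variants, ", length(w@x), " non-zero weights\n",
        sep = "")
})

setMethod("show", "CovariateTable", function(object) {
    cat("CovariateTable: ", nrow(object@data), " samples x ",
        ncol(object@data), " covariates (",
        paste(sprintf("%s: %d", .covariateTags,
                      tabulate(match(object@tags, .covariateTags), 3L)),
              collapse = ", "), ")\n", sep = "")
})

setMethod("show", "Phenotype", function(object) {
    cat("Phenotype: ", sum(object@status == 1L), " cases / ",
        sum(object@status == 0L), " controls\n", sep = "")
})

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "': ", length(object@members),
        " genes\n", sep = "")
})
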