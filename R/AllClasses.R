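#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' Per-individual ALT-allele dosages for biallelic variants
#'
#' A \code{GenotypeMatrix} stores ALT-allele dosages in \code{[0, 2]} for a
#' set of biallelic variants, together with per-variant metadata
#' (chromosome, 1-based position, REF and ALT alleles). Internally it is a
#' \linkS4class{SummarizedExperiment} with variants as rows and samples as
#' columns and a single \code{"dosage"} assay; the user-facing accessor
#' \code{\link{dosages}} returns the samples x variants orientation used
#' throughout the prediction code.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{readGenotypes}}, \code{\link{simulateGenotypes}},
#'   \code{\link{qcFilter}}
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

.validGenotypeMatrix <- function(object) {
    msg <- NULL
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        if (length(d) && (min(d) < 0 || max(d) > 2))
            msg <- c(msg, "dosages must lie in [0, 2]")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "variant ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(rowData(object))))
        msg <- c(msg, "rowData needs columns chrom, pos, ref, alt")
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix of ALT-allele dosages, samples x variants,
#'   with sample ids as rownames and variant ids as colnames.
#' @param variantMeta data.frame with one row per variant and columns
#'   \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt}. Rownames
#'   (or a \code{variant_id} column) must match the dosage colnames.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' d <- matrix(c(0, 1, 2, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("v1", "v2")))
#' vm <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G",
#'                  row.names = c("v1", "v2"))
#' gm <- GenotypeMatrix(d, vm)
#' dosages(gm)
#' @export
GenotypeMatrix <- function(dosages, variantMeta) {
    stopifnot(is.matrix(dosages))
    if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
        stop("dosage matrix needs sample rownames and variant colnames")
    if ("variant_id" %in% colnames(variantMeta))
        rownames(variantMeta) <- variantMeta$variant_id
    variantMeta <- variantMeta[colnames(dosages), , drop = FALSE]
    se <- SummarizedExperiment(
        assays = list(dosage = t(dosages)),
        rowData = DataFrame(variantMeta[, c("chrom", "pos", "ref", "alt")]))
    new("GenotypeMatrix", se)
}

#' Observed, genetically regulated and environmental expression components
#'
#' An \code{ExpressionBundle} holds up to three genes x samples matrices
#' over identical gene and sample orderings: \code{observed} expression,
#' the imputed genetically regulated component \code{grex}, and the
#' residual environmentally regulated component \code{erex}. It extends
#' \linkS4class{SummarizedExperiment}; accessors return the samples x
#' genes orientation.
#'
#' By construction (\code{\link{computeErex}}) every gene's EReX vector is
#' orthogonal to its centered GReX vector.
#'
#' @seealso \code{\link{predictGrex}}, \code{\link{computeErex}},
#'   \code{\link{runAssociation}}
#' @export
setClass("ExpressionBundle", contains = "SummarizedExperiment")

.validExpressionBundle <- function(object) {
    msg <- NULL
    an <- assayNames(object)
    if (!"observed" %in% an)
        msg <- c(msg, "assay 'observed' is required")
    bad <- setdiff(an, c("observed", "grex", "erex"))
    if (length(bad))
        msg <- c(msg, paste("unknown assays:", paste(bad, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionBundle", .validExpressionBundle)

#' Construct an ExpressionBundle
#'
#' @param observed samples x genes numeric matrix (sample rownames, gene
#'   colnames).
#' @param grex,erex optional samples x genes matrices with identical
#'   dimnames (same orientation as \code{observed}).
#' @return An \linkS4class{ExpressionBundle}.
#' @export
ExpressionBundle <- function(observed, grex = NULL, erex = NULL) {
    stopifnot(is.matrix(observed))
    if (is.null(rownames(observed)) || is.null(colnames(observed)))
        stop("observed matrix needs sample rownames and gene colnames")
    al <- list(observed = t(observed))
    for (nm in c("grex", "erex")) {
        m <- switch(nm, grex = grex, erex = erex)
        if (!is.null(m)) {
            if (!identical(dimnames(m), dimnames(observed)))
                stop(nm, " matrix must share dimnames with observed")
            al[[nm]] <- t(m)
        }
    }
    new("ExpressionBundle", SummarizedExperiment(assays = al))
}

#' Sparse gene x variant cis prediction weights
#'
#' A \code{WeightMatrix} stores the sparse effect weights of a per-gene
#' linear cis prediction model (one matrix per tissue), plus the effect
#' allele of each variant: the allele whose dosage the weight multiplies.
#' Genes without any non-zero weight are not represented.
#'
#' @slot tissue single tissue label.
#' @slot weights \code{Matrix::dgCMatrix}, genes x variants.
#' @slot effectAllele named character vector, one allele per variant
#'   column.
#' @seealso \code{\link{readWeights}}, \code{\link{trainWeights}},
#'   \code{\link{predictGrex}}
#' @export
setClass("WeightMatrix",
    representation(tissue = "character", weights = "Matrix",
                   effectAllele = "character"))

.validWeightMatrix <- function(object) {
    msg <- NULL
    w <- object@weights
    if (length(w@x) && !all(is.finite(w@x)))
        msg <- c(msg, "all stored weights must be finite")
    if (nrow(w) > 0 && any(Matrix::rowSums(w != 0) == 0))
        msg <- c(msg, "every gene must have at least one non-zero weight")
    if (ncol(w) > 0 &&
        !identical(sort(names(object@effectAllele)), sort(colnames(w))))
        msg <- c(msg, "effectAllele must be named by variant id")
    if (length(object@tissue) != 1L)
        msg <- c(msg, "tissue must be a single label")
    if (is.null(msg)) TRUE else msg
}
setValidity("WeightMatrix", .validWeightMatrix)

#' Construct a WeightMatrix from a long table of weights
#'
#' @param entries data.frame with columns \code{gene}, \code{variant},
#'   \code{weight}, \code{effect_allele}.
#' @param tissue tissue label (default \code{"blood"}).
#' @return A \linkS4class{WeightMatrix}. Zero weights are dropped; genes
#'   left without entries are omitted.
#' @export
WeightMatrix <- function(entries, tissue = "blood") {
    need <- c("gene", "variant", "weight", "effect_allele")
    if (!all(need %in% colnames(entries)))
        stop("weight table must have columns: ", paste(need, collapse = ", "))
    entries <- data.frame(gene = as.character(entries$gene),
                          variant = as.character(entries$variant),
                          weight = as.numeric(entries$weight),
                          effect_allele = as.character(
                              entries$effect_allele))
    if (nrow(entries)) {
        key <- paste(entries$gene, entries$variant, sep = "\r")
        if (anyDuplicated(key))
            stop("duplicate (gene, variant) weight entries")
        if (!all(is.finite(entries$weight)))
            stop("non-finite weight values")
    }
    entries <- entries[entries$weight != 0, , drop = FALSE]
    genes <- unique(entries$gene)
    vars <- unique(entries$variant)
    w <- Matrix::sparseMatrix(
        i = match(entries$gene, genes), j = match(entries$variant, vars),
        x = entries$weight, dims = c(length(genes), length(vars)),
        dimnames = list(genes, vars))
    ea <- entries$effect_allele[!duplicated(entries$variant)]
    names(ea) <- entries$variant[!duplicated(entries$variant)]
    new("WeightMatrix", tissue = tissue, weights = w,
        effectAllele = ea[vars])
}

#' Covariate table with per-covariate tags
#'
#' Numeric covariates for the association stage, each tagged as one of
#' \code{clinical}, \code{expression_pc} or \code{genotype_pc}. The tags
#' drive the component-specific covariate policy: expression PCs are
#' confounders for observed expression and EReX but not for GReX, while
#' genotype PCs enter every component's null model.
#'
#' @slot data data.frame of numeric covariates, rownames = sample ids.
#' @slot tags character vector parallel to the columns of \code{data}.
#' @seealso \code{\link{covariatePolicy}}, \code{\link{runAssociation}}
#' @export
setClass("CovariateTable",
    representation(data = "data.frame", tags = "character"))

.covariateTags <- c("clinical", "expression_pc", "genotype_pc")

.validCovariateTable <- function(object) {
    msg <- NULL
    if (length(object@tags) != ncol(object@data))
        msg <- c(msg, "one tag per covariate column is required")
    if (!all(object@tags %in% .covariateTags))
        msg <- c(msg, paste("tags must be in:",
                            paste(.covariateTags, collapse = ", ")))
    if (anyNA(object@data))
        msg <- c(msg, "covariates must not contain missing values")
    if (ncol(object@data) && !all(vapply(object@data, is.numeric, TRUE)))
        msg <- c(msg, "covariates must be numeric")
    if (is.null(msg)) TRUE else msg
}
setValidity("CovariateTable", .validCovariateTable)

#' Construct a CovariateTable
#'
#' @param data data.frame of numeric covariates with sample ids as
#'   rownames.
#' @param tags character vector of tags (\code{clinical},
#'   \code{expression_pc}, \code{genotype_pc}), one per column. Columns
#'   named like \code{ePC<k>} / \code{gPC<k>} are tagged automatically
#'   when \code{tags} is missing; all others default to \code{clinical}.
#' @return A \linkS4class{CovariateTable}.
#' @export
CovariateTable <- function(data, tags = NULL) {
    if (is.null(tags)) {
        tags <- rep("clinical", ncol(data))
        tags[grepl("^ePC[0-9]+$", colnames(data))] <- "expression_pc"
        tags[grepl("^gPC[0-9]+$", colnames(data))] <- "genotype_pc"
    }
    new("CovariateTable", data = as.data.frame(data), tags = tags)
}

#' Binary case/control phenotype
#'
#' @slot sampleIds character vector of sample ids.
#' @slot status integer vector of 0 (control) / 1 (case).
#' @export
setClass("Phenotype",
    representation(sampleIds = "character", status = "integer"))

.validPhenotype <- function(object) {
    msg <- NULL
    if (length(object@sampleIds) != length(object@status))
        msg <- c(msg, "sampleIds and status lengths differ")
    if (anyDuplicated(object@sampleIds))
        msg <- c(msg, "sample ids must be unique")
    if (!all(object@status %in% c(0L, 1L)))
        msg <- c(msg, "status must be 0/1")
    if (length(object@status) && length(unique(object@status)) < 2L)
        msg <- c(msg, "both cases and controls must be present")
    if (is.null(msg)) TRUE else msg
}
setValidity("Phenotype", .validPhenotype)

#' Construct a Phenotype
#'
#' @param sampleIds character sample ids.
#' @param status 0/1 vector (1 = case).
#' @return A \linkS4class{Phenotype}.
#' @export
Phenotype <- function(sampleIds, status) {
    new("Phenotype", sampleIds = as.character(sampleIds),
        status = as.integer(status))
}

#' Named gene set
#'
#' @slot name set name.
#' @slot members unique, non-empty character vector of gene ids.
#' @export
setClass("GeneSet", representation(name = "character", members = "character"))

.validGeneSet <- function(object) {
    msg <- NULL
    if (length(object@members) == 0L)
        msg <- c(msg, "gene set must be non-empty")
    if (anyDuplicated(object@members))
        msg <- c(msg, "gene set members must be unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("GeneSet", .validGeneSet)

#' Construct a GeneSet
#' @param name set name.
#' @param members character vector of gene ids (deduplicated).
#' @return A \linkS4class{GeneSet}.
#' @export
GeneSet <- function(name, members) {
    new("GeneSet", name = name, members = unique(as.character(members)))
}
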