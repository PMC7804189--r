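#' Read genotypes from VCF or a dosage TSV
#'
#' Supports VCF (v4.x) with \code{GT} and/or \code{DS} FORMAT fields, and
#' the package's plain dosage TSV (as written by
#' \code{\link{writeGenotypes}}: columns \code{variant_id, chrom, pos,
#' ref, alt} followed by one dosage column per sample). \code{DS} values
#' are used verbatim when present; otherwise \code{GT} calls 0/0, 0/1,
#' 1/1 map to dosages 0, 1, 2. Multi-allelic records are skipped with a
#' warning; missing genotypes are imputed to the variant's mean dosage.
#'
#' @param path file path (\code{.vcf} or \code{.vcf.gz} treated as VCF,
#'   anything else as dosage TSV; override with \code{format}).
#' @param format \code{"auto"}, \code{"vcf"} or \code{"dosage"}.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("cannot read genotype file: ", path)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
    if (format == "vcf") .readVcfGenotypes(path) else .readDosageTsv(path)
}

.readVcfGenotypes <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi)) {
        warning(sum(multi), " multi-allelic record(s) skipped")
        vcf@fix <- vcf@fix[!multi, , drop = FALSE]
        vcf@gt <- vcf@gt[!multi, , drop = FALSE]
        fix <- fix[!multi, , drop = FALSE]
    }
    if (nrow(fix) == 0L) stop("no biallelic variants retained")
    vid <- fix[, "ID"]
    vid[is.na(vid) | vid == "."] <-
        paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(vid) | vid == "."]
    fmt <- strsplit(vcf@gt[, 1L], ":", fixed = TRUE)
    hasDS <- all(vapply(fmt, function(f) "DS" %in% f, TRUE))
    if (hasDS) {
        ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else {
        gt <- vcfR::extract.gt(vcf, element = "GT")
        if (is.null(gt)) stop("VCF has neither DS nor GT fields")
        cnt <- function(g) {
            al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
            vapply(al, function(a) {
                if (any(a == "." | is.na(a))) NA_real_
                else sum(a == "1")
            }, 0)
        }
        ds <- apply(gt, 2L, cnt)
        if (is.null(dim(ds)))
            ds <- matrix(ds, nrow = nrow(gt), dimnames = dimnames(gt))
    }
    rownames(ds) <- vid
    if (ncol(ds) == 0L) stop("no samples in VCF")
    ds <- .imputeMissingDosages(ds)
    vm <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     row.names = vid)
    GenotypeMatrix(t(ds), vm)
}

# variants x samples matrix in, per-variant mean imputation of NA slots
.imputeMissingDosages <- function(ds) {
    miss <- which(is.na(ds), arr.ind = TRUE)
    if (nrow(miss)) {
        mv <- rowMeans(ds, na.rm = TRUE)
        mv[is.nan(mv)] <- 0
        ds[miss] <- mv[miss[, 1L]]
    }
    ds
}

.readDosageTsv <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    need <- c("variant_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(dt)))
        stop("dosage TSV must have columns: ", paste(need, collapse = ", "))
    smp <- setdiff(colnames(dt), need)
    if (!length(smp) || !nrow(dt))
        stop("zero samples or zero variants in dosage file")
    d <- as.matrix(dt[, smp, drop = FALSE])
    if (!is.numeric(d)) stop("non-numeric dosage values in ", path)
    rownames(d) <- dt$variant_id
    d <- .imputeMissingDosages(d)
    vm <- data.frame(chrom = as.character(dt$chrom), pos = as.integer(dt$pos),
                     ref = dt$ref, alt = dt$alt, row.names = dt$variant_id)
    GenotypeMatrix(t(d), vm)
}

#' Write genotypes as a dosage TSV
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(x, path) {
    vm <- variantMeta(x)
    d <- t(dosages(x))                   # variants x samples
    out <- data.frame(vm, d, check.names = FALSE)
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read an expression TSV
#'
#' Rectangular numeric table with a header row and an id column. The
#' returned matrix is always samples x genes regardless of the on-disk
#' orientation.
#'
#' @param path TSV file.
#' @param orientation \code{"genes_by_samples"} (default: rows are genes)
#'   or \code{"samples_by_genes"}.
#' @return numeric matrix, samples x genes.
#' @export
readExpression <- function(path,
                           orientation = c("genes_by_samples",
                                           "samples_by_genes")) {
    orientation <- match.arg(orientation)
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    num <- if (is.numeric(m)) m else
        suppressWarnings(array(as.numeric(m), dim(m), dimnames(m)))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop("non-numeric or missing value in ", path, " at row '",
             ids[bad[1L]], "', column '", colnames(m)[bad[2L]], "'")
    }
    m <- num
    rownames(m) <- ids
    if (orientation == "genes_by_samples") {
        if (anyDuplicated(ids)) stop("duplicated gene id in ", path)
        t(m)
    } else {
        if (anyDuplicated(colnames(m))) stop("duplicated gene id in ", path)
        m
    }
}

#' Write an expression matrix as TSV (genes x samples on disk)
#'
#' @param x samples x genes numeric matrix.
#' @param path output file.
#' @param idColumn name for the gene-id column (default \code{"gene_id"}).
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, idColumn = "gene_id") {
    # %.17g keeps the text round trip bit-exact for doubles
    tx <- t(x)
    chr <- matrix(sprintf("%.17g", tx), nrow(tx),
                  dimnames = dimnames(tx))
    out <- cbind(stats::setNames(data.frame(colnames(x)), idColumn),
                 as.data.frame(chr, check.names = FALSE))
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read a cis-weight table
#'
#' TSV with columns \code{gene}, \code{variant}, \code{weight},
#' \code{effect_allele}; one row per (gene, variant) pair. Models the
#' usual TWAS weight-matrix interchange (one table per tissue).
#'
#' @param path TSV file.
#' @param tissue tissue label attached to the result.
#' @return A \linkS4class{WeightMatrix}. An empty table (header only)
#'   yields a WeightMatrix with zero genes.
#' @export
readWeights <- function(path, tissue = "blood") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    need <- c("gene", "variant", "weight", "effect_allele")
    if (!all(need %in% colnames(dt)))
        stop("weight table missing column(s): ",
             paste(setdiff(need, colnames(dt)), collapse = ", "))
    WeightMatrix(dt, tissue = tissue)
}

#' Write a WeightMatrix as a long TSV
#'
#' @param x a \linkS4class{WeightMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeWeights <- function(x, path) {
    w <- methods::as(weightValues(x), "TsparseMatrix")
    ord <- order(rownames(w)[w@i + 1L], colnames(w)[w@j + 1L])
    out <- data.frame(gene = rownames(w)[w@i + 1L],
                      variant = colnames(w)[w@j + 1L],
                      weight = w@x,
                      effect_allele =
                          unname(effectAlleles(x)[colnames(w)[w@j + 1L]]))
    data.table::fwrite(out[ord, ], path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read / write covariate tables
#'
#' TSV with a \code{sample_id} column plus one numeric column per
#' covariate. Tags are taken from the column-name convention
#' (\code{ePC<k>} = expression PC, \code{gPC<k>} = genotype PC, all
#' others clinical) unless given explicitly.
#'
#' @param path TSV file.
#' @param tags optional explicit tag vector, one per covariate column.
#' @return A \linkS4class{CovariateTable}.
#' @export
readCovariates <- function(path, tags = NULL) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    if (!"sample_id" %in% colnames(dt))
        stop("covariate TSV needs a sample_id column")
    dat <- dt[, setdiff(colnames(dt), "sample_id"), drop = FALSE]
    rownames(dat) <- dt$sample_id
    CovariateTable(dat, tags = tags)
}

#' @rdname readCovariates
#' @param x a \linkS4class{CovariateTable}.
#' @export
writeCovariates <- function(x, path) {
    out <- cbind(data.frame(sample_id = sampleIds(x)), covariateData(x))
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read / write a binary phenotype table
#'
#' TSV with columns \code{sample_id} and \code{status} (1 = case,
#' 0 = control).
#' @param path TSV file.
#' @return A \linkS4class{Phenotype}.
#' @export
readPhenotype <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    if (!all(c("sample_id", "status") %in% colnames(dt)))
        stop("phenotype TSV needs sample_id and status columns")
    Phenotype(dt$sample_id, dt$status)
}

#' @rdname readPhenotype
#' @param x a \linkS4class{Phenotype}.
#' @export
writePhenotype <- function(x, path) {
    data.table::fwrite(data.frame(sample_id = sampleIds(x),
                                  status = unname(status(x))),
                       path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read / write a gene-set file
#'
#' Plain text, one gene symbol per line; an optional first line starting
#' with \code{#} names the set.
#' @param path text file.
#' @param name set name when the file carries none (default: file name).
#' @return A \linkS4class{GeneSet}.
#' @export
readGeneSet <- function(path, name = NULL) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    if (length(ln) && startsWith(ln[1L], "#")) {
        if (is.null(name)) name <- trimws(sub("^#+", "", ln[1L]))
        ln <- ln[-1L]
    }
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    GeneSet(name, trimws(ln))
}

#' @rdname readGeneSet
#' @param x a \linkS4class{GeneSet}.
#' @export
writeGeneSet <- function(x, path) {
    writeLines(c(paste0("# ", x@name), x@members), path)
    invisible(path)
}

#' Align a cohort on the shared samples
#'
#' Subsets and reorders genotypes, expression, covariates and phenotype
#' to the intersection of their sample ids, preserving the relative
#' sample order of the genotype object. Idempotent; the number of
#' samples dropped per source is reported via \code{message}.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param expression an \linkS4class{ExpressionBundle} or a samples x
#'   genes matrix with sample rownames.
#' @param covariates a \linkS4class{CovariateTable}.
#' @param phenotype a \linkS4class{Phenotype}.
#' @return named list with the four aligned objects.
#' @export
alignCohort <- function(genotypes, expression, covariates, phenotype) {
    exprIds <- if (is(expression, "ExpressionBundle"))
        sampleIds(expression) else rownames(expression)
    idSets <- list(genotypes = sampleIds(genotypes), expression = exprIds,
                   covariates = sampleIds(covariates),
                   phenotype = sampleIds(phenotype))
    common <- Reduce(intersect, idSets)
    keep <- idSets$genotypes[idSets$genotypes %in% common]
    if (!length(keep))
        stop("no samples shared across genotypes, expression, ",
             "covariates and phenotype")
    for (nm in names(idSets)) {
        nd <- length(idSets[[nm]]) - length(keep)
        if (nd > 0)
            message("alignCohort: dropping ", nd, " sample(s) from ", nm)
    }
    expression <- if (is(expression, "ExpressionBundle"))
        expression[, keep] else expression[keep, , drop = FALSE]
    st <- status(phenotype)[keep]
    list(genotypes = genotypes[, keep],
         expression = expression,
         covariates = CovariateTable(
             covariateData(covariates)[keep, , drop = FALSE],
             tags = unname(covariateTags(covariates))),
         phenotype = Phenotype(keep, unname(st)))
}
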