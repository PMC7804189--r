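#' Bundled worked-example association tables
#'
#' Two small reference tables of permutation p-values from a published
#' blood transcriptome case/control study of major depressive disorder
#' (463 cases / 459 controls), shipped for worked examples and
#' regression tests of the counting and enrichment utilities:
#' \describe{
#'   \item{\code{ifn_odegs}}{the ten interferon alpha/beta signaling
#'     pathway genes that were differentially expressed in the observed
#'     data, with observed / EReX / GReX permutation p-values and the
#'     gene's rank among all observed differentially expressed genes.}
#'   \item{\code{grex_odegs}}{the 39 observed differentially expressed
#'     genes whose GReX component was associated with case status at
#'     p < 0.05, with the same columns.}
#' }
#'
#' @param which table name.
#' @return data.frame with columns \code{gene}, \code{p_observed},
#'   \code{p_erex}, \code{p_grex}, \code{odeg_rank}.
#' @export
exampleTable <- function(which = c("ifn_odegs", "grex_odegs")) {
    which <- match.arg(which)
    f <- system.file("extdata", paste0(which, ".tsv"),
                     package = "exprDissect", mustWork = TRUE)
    utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Reshape a wide p-value table to the long association format
#'
#' Turns a table with \code{p_observed} / \code{p_grex} / \code{p_erex}
#' columns (as returned by \code{\link{exampleTable}} or
#' \code{\link{reportTables}}) into the long \code{gene_id} x
#' \code{component} format consumed by \code{\link{thresholdCounts}}.
#'
#' @param wide data.frame with a \code{gene} (or \code{gene_id}) column
#'   and \code{p_<component>} columns.
#' @return data.frame with \code{gene_id}, \code{component},
#'   \code{perm_p}.
#' @export
associationLong <- function(wide) {
    gene <- if ("gene" %in% colnames(wide)) wide$gene else wide$gene_id
    comps <- c("observed", "grex", "erex")
    rows <- lapply(comps, function(cc) {
        col <- paste0("p_", cc)
        if (!col %in% colnames(wide)) return(NULL)
        data.frame(gene_id = gene, component = cc, perm_p = wide[[col]])
    })
    do.call(rbind, rows)
}

.pipelineDefaults <- function() {
    list(sim = list(), maf = 0.05, hwe = 0.05, nExprPCs = 10L,
         alpha = 0.05, bInitial = 8000L, bMax = 1000000L,
         topN = c(30L, 60L, 100L, 150L, 200L, 300L),
         geneSets = character(), components = c("observed", "grex", "erex"),
         seed = 1L, outDir = NULL)
}

#' Run the full dissection pipeline
#'
#' Orchestrates simulate (or load) -> variant QC -> GReX prediction ->
#' EReX residuals -> covariate assembly (expression PCs appended) ->
#' permutation association -> enrichment / pi1 / threshold counts ->
#' report tables, writing every intermediate plus a manifest to
#' \code{outDir}. Identical config and seed give byte-identical numeric
#' outputs.
#'
#' @param config named list overriding the defaults (see Details), or a
#'   path to a YAML file with the same structure.
#'
#' @details Config fields: \code{sim} (arguments for
#'   \code{\link{simulationConfig}}) or \code{inputs} (named paths
#'   \code{genotypes}, \code{expression}, \code{covariates},
#'   \code{phenotype}, \code{weights} for real data); \code{maf},
#'   \code{hwe} QC thresholds; \code{nExprPCs} expression PCs appended
#'   as covariates (0 disables); \code{alpha}; \code{bInitial},
#'   \code{bMax}; \code{topN}; \code{geneSets} (paths to gene-set
#'   files; for simulated runs the environment/genetic effect-gene sets
#'   from the ground truth are added automatically); \code{components};
#'   \code{seed}; \code{outDir} (default: temporary directory).
#' @return list: \code{assoc}, \code{report}, \code{enrichment},
#'   \code{pi1}, \code{counts}, \code{manifest}, \code{outDir},
#'   \code{truth} (simulated runs only).
#' @export
runPipeline <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(.pipelineDefaults(), config)
    if (is.null(cfg$outDir)) cfg$outDir <- tempfile("dissect_run_")
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(seed = cfg$seed, stages = list(),
                     package = as.character(utils::packageVersion(
                         "exprDissect")))
    t00 <- Sys.time()
    stamp <- function(name, t0) {
        manifest$stages[[name]] <<- list(
            stage = name,
            seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    }
    fail <- function(stage, e)
        stop("pipeline stage '", stage, "' failed: ",
             conditionMessage(e), call. = FALSE)

    # stage 1: inputs
    t0 <- Sys.time()
    truth <- NULL
    tryCatch({
        if (!is.null(cfg$inputs)) {
            genotypes <- readGenotypes(cfg$inputs$genotypes)
            observed <- readExpression(cfg$inputs$expression)
            covariates <- readCovariates(cfg$inputs$covariates)
            phenotype <- readPhenotype(cfg$inputs$phenotype)
            weights <- readWeights(cfg$inputs$weights)
            al <- alignCohort(genotypes, observed, covariates, phenotype)
            genotypes <- al$genotypes; observed <- al$expression
            covariates <- al$covariates; phenotype <- al$phenotype
        } else {
            sim <- simulateCohort(do.call(simulationConfig,
                c(cfg$sim, list(seed = cfg$seed))))
            genotypes <- sim$genotypes
            observed <- observedExpr(sim$bundle)
            covariates <- sim$covariates
            phenotype <- sim$phenotype
            weights <- sim$weights
            truth <- sim$truth
            data.table::fwrite(
                data.frame(gene = names(truth$labels),
                           label = unname(truth$labels),
                           true_h2 = unname(truth$trueH2)),
                file.path(cfg$outDir, "ground_truth.tsv"), sep = "\t")
        }
    }, error = function(e) fail("inputs", e))
    stamp("inputs", t0)

    # stage 2: variant QC
    t0 <- Sys.time()
    tryCatch({
        qc <- qcFilter(genotypes, cfg$maf, cfg$hwe)
        message("qc: ", sum(!qc$qc$pass), " of ", nrow(qc$qc),
                " variants removed")
        data.table::fwrite(qc$qc, file.path(cfg$outDir, "variant_qc.tsv"),
                           sep = "\t")
        genotypes <- qc$genotypes
    }, error = function(e) fail("qc", e))
    stamp("qc", t0)

    # stage 3: GReX prediction
    t0 <- Sys.time()
    tryCatch({
        pg <- predictGrex(genotypes, weights)
        message("grex: ", sum(!pg$coverage$predicted),
                " gene(s) without usable weights dropped")
        data.table::fwrite(pg$coverage,
                           file.path(cfg$outDir, "grex_coverage.tsv"),
                           sep = "\t")
        common <- intersect(colnames(observed), colnames(pg$grex))
        if (!length(common)) stop("no genes with both expression and GReX")
        bundle <- ExpressionBundle(observed[, common, drop = FALSE],
                                   grex = pg$grex[, common, drop = FALSE])
        writeExpression(pg$grex, file.path(cfg$outDir, "grex.tsv"))
    }, error = function(e) fail("grex", e))
    stamp("grex", t0)

    # stage 4: EReX residuals
    t0 <- Sys.time()
    tryCatch({
        er <- computeErex(bundle)
        bundle <- er$bundle
        data.table::fwrite(er$fit, file.path(cfg$outDir, "erex_fit.tsv"),
                           sep = "\t")
        writeExpression(er$erex, file.path(cfg$outDir, "erex.tsv"))
    }, error = function(e) fail("erex", e))
    stamp("erex", t0)

    # stage 5: covariates (expression PCs appended)
    t0 <- Sys.time()
    tryCatch({
        if (cfg$nExprPCs > 0L) {
            epc <- expressionPCs(observedExpr(bundle), cfg$nExprPCs)
            covariates <- CovariateTable(
                cbind(covariateData(covariates), as.data.frame(epc)),
                tags = c(unname(covariateTags(covariates)),
                         rep("expression_pc", ncol(epc))))
        }
        writeCovariates(covariates,
                        file.path(cfg$outDir, "covariates.tsv"))
    }, error = function(e) fail("covariates", e))
    stamp("covariates", t0)

    # stage 6: permutation association
    t0 <- Sys.time()
    tryCatch({
        assoc <- runAssociation(bundle, phenotype, covariates,
                                components = cfg$components,
                                bInitial = cfg$bInitial, bMax = cfg$bMax,
                                seed = cfg$seed)
        nEsc <- length(unique(assoc$gene_id[assoc$B > cfg$bInitial]))
        message("association: ", nEsc, " gene(s) escalated to ",
                cfg$bMax, " permutations")
        data.table::fwrite(assoc, file.path(cfg$outDir, "assoc.tsv"),
                           sep = "\t")
    }, error = function(e) fail("association", e))
    stamp("association", t0)

    # stage 7: enrichment, pi1, threshold counts
    t0 <- Sys.time()
    tryCatch({
        sets <- lapply(cfg$geneSets, readGeneSet)
        if (!is.null(truth)) {
            for (lb in c("env_driven", "grex_driven")) {
                mem <- names(truth$labels)[truth$labels %in%
                                           c(lb, "both")]
                if (length(mem)) sets <- c(sets, GeneSet(lb, mem))
            }
        }
        universe <- geneIds(bundle)
        topN <- cfg$topN[cfg$topN <= length(universe)]
        enr <- list()
        for (comp in cfg$components) {
            rk <- rankGenes(assoc, comp)
            for (gs in sets) {
                e <- topNEnrichment(rk, gs, universe, N = topN)
                e$component <- comp
                enr[[length(enr) + 1L]] <- e
            }
        }
        enrichment <- if (length(enr)) do.call(rbind, enr) else
            data.frame()
        pi1 <- do.call(rbind, lapply(cfg$components, function(comp) {
            est <- estimatePi1(assoc$perm_p[assoc$component == comp])
            data.frame(component = comp, pi1 = est$pi1,
                       lambda = est$lambda, m = est$m)
        }))
        counts <- thresholdCounts(assoc, cfg$alpha)
        hist <- do.call(rbind, lapply(cfg$components, function(comp) {
            h <- graphics::hist(assoc$perm_p[assoc$component == comp],
                                breaks = seq(0, 1, 0.05), plot = FALSE)
            data.frame(component = comp, bin_low = utils::head(h$breaks, -1),
                       bin_high = h$breaks[-1L], count = h$counts)
        }))
        if (nrow(enrichment))
            data.table::fwrite(enrichment,
                               file.path(cfg$outDir, "enrichment.tsv"),
                               sep = "\t")
        data.table::fwrite(pi1, file.path(cfg$outDir, "pi1.tsv"),
                           sep = "\t")
        data.table::fwrite(hist, file.path(cfg$outDir, "pvalue_hist.tsv"),
                           sep = "\t")
        data.table::fwrite(
            data.frame(component = names(counts$counts),
                       n_significant = unname(counts$counts)),
            file.path(cfg$outDir, "threshold_counts.tsv"), sep = "\t")
    }, error = function(e) fail("enrichment", e))
    stamp("enrichment", t0)

    # stage 8: report tables
    t0 <- Sys.time()
    tryCatch({
        report <- reportTables(assoc, alpha = cfg$alpha)
        data.table::fwrite(report, file.path(cfg$outDir, "report.tsv"),
                           sep = "\t")
    }, error = function(e) fail("report", e))
    stamp("report", t0)

    yaml::write_yaml(cfg[setdiff(names(cfg), "outDir")],
                     file.path(cfg$outDir, "config.yaml"))
    files <- setdiff(list.files(cfg$outDir), "manifest.json")
    manifest$files <- as.list(tools::md5sum(
        file.path(cfg$outDir, files)))
    names(manifest$files) <- files
    manifest$total_seconds <-
        round(as.numeric(Sys.time() - t00, units = "secs"), 3)
    jsonlite::write_json(manifest,
                         file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(assoc = assoc, report = report, enrichment = enrichment,
         pi1 = pi1, counts = counts, manifest = manifest,
         outDir = cfg$outDir, truth = truth)
}

#' Wide per-gene report of component p-values
#'
#' One row per gene with the observed / EReX / GReX permutation
#' p-values, the gene's rank by observed p-value (ties broken by larger
#' LRT statistic then gene id, so ranks are a permutation of 1..G), and
#' strict significance flags at \code{alpha}.
#'
#' @param assoc association table from \code{\link{runAssociation}}.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: \code{gene}, \code{p_observed}, \code{p_erex},
#'   \code{p_grex}, \code{odeg_rank}, \code{sig_observed},
#'   \code{sig_erex}, \code{sig_grex}.
#' @export
reportTables <- function(assoc, alpha = 0.05) {
    comps <- intersect(c("observed", "erex", "grex"),
                       unique(assoc$component))
    genes <- unique(assoc$gene_id)
    out <- data.frame(gene = genes)
    for (cc in comps) {
        a <- assoc[assoc$component == cc, ]
        out[[paste0("p_", cc)]] <- a$perm_p[match(genes, a$gene_id)]
    }
    if ("observed" %in% comps) {
        rk <- rankGenes(assoc, "observed")
        out$odeg_rank <- match(genes, rk)
    }
    for (cc in comps)
        out[[paste0("sig_", cc)]] <- out[[paste0("p_", cc)]] < alpha
    out
}
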