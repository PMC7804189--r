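#' Upper-tail hypergeometric probability
#'
#' P(X >= x) for X ~ Hypergeometric(universe of size \code{universe},
#' \code{K} successes, draw of size \code{n}), the over-representation
#' tail including the observed value (no mid-p).
#'
#' @param universe universe size.
#' @param K number of pathway members in the universe.
#' @param n draw size (top-N).
#' @param x observed overlap, \code{0 <= x <= min(K, n)}.
#' @return p-value in (0, 1]; exactly 1 when \code{x = 0}.
#' @examples
#' hypergeomUpperTail(10, 5, 4, 4)  # 5 / 210
#' @export
hypergeomUpperTail <- function(universe, K, n, x) {
    if (any(c(universe, K, n, x) < 0) || K > universe || n > universe ||
        x > min(K, n))
        stop("inconsistent hypergeometric counts")
    if (x == 0) return(1)
    stats::phyper(x - 1, K, universe - K, n, lower.tail = FALSE)
}

#' Top-N gene-set enrichment over a ranked list
#'
#' For each N, the overlap between the top-N genes of the ranking and
#' the gene set (both restricted to the universe) is tested with the
#' upper-tail hypergeometric. N values beyond the ranking length are
#' truncated with a warning.
#'
#' @param ranked character vector of gene ids, best first, a subset of
#'   \code{universe}.
#' @param geneSet a \linkS4class{GeneSet} (or character vector of
#'   members).
#' @param universe character vector of all eligible gene ids (the genes
#'   with all components available).
#' @param N integer vector of draw sizes (default
#'   \code{c(30, 60, 100, 150, 200, 300)}).
#' @return data.frame: \code{set_name}, \code{N_top},
#'   \code{universe_size}, \code{pathway_in_universe}, \code{overlap},
#'   \code{p_value}.
#' @export
topNEnrichment <- function(ranked, geneSet, universe,
                           N = c(30L, 60L, 100L, 150L, 200L, 300L)) {
    if (is(geneSet, "GeneSet")) {
        setName <- geneSet@name
        members <- geneSet@members
    } else {
        setName <- "gene_set"
        members <- unique(as.character(geneSet))
    }
    if (!all(ranked %in% universe))
        stop("ranked list contains genes outside the universe")
    Kset <- intersect(members, universe)
    res <- lapply(N, function(nn) {
        if (nn > length(ranked)) {
            warning("N = ", nn, " truncated to ranking length ",
                    length(ranked))
            nn <- length(ranked)
        }
        top <- ranked[seq_len(nn)]
        x <- length(intersect(top, Kset))
        data.frame(set_name = setName, N_top = nn,
                   universe_size = length(universe),
                   pathway_in_universe = length(Kset), overlap = x,
                   p_value = hypergeomUpperTail(length(universe),
                                                length(Kset), nn, x))
    })
    do.call(rbind, res)
}

#' Rank genes of one association component
#'
#' Total ordering by ascending permutation p-value; ties (common at the
#' b/B resolution of permutation p-values) are broken by larger LRT
#' statistic, then lexicographic gene id.
#'
#' @param assoc association table from \code{\link{runAssociation}}.
#' @param component one of \code{"observed"}, \code{"grex"},
#'   \code{"erex"}.
#' @return character vector of gene ids, most significant first.
#' @export
rankGenes <- function(assoc, component) {
    a <- assoc[assoc$component == component, ]
    if (!nrow(a)) stop("no rows for component ", component)
    a$gene_id[order(a$perm_p, -a$lrt_stat, a$gene_id)]
}

#' Proportion of true alternatives among a p-value collection
#'
#' Assuming p-values above \code{lambda} come from the uniform null,
#' pi0 = #\{p > lambda\} / ((1 - lambda) m) estimates the null
#' proportion and pi1 = 1 - pi0 (clamped to [0, 1]) the proportion of
#' true positives. A single fixed lambda (default 0.5, no spline
#' smoothing) keeps the estimator deterministic.
#'
#' @param p p-values in (0, 1].
#' @param lambda tuning threshold in (0, 1).
#' @return list: \code{pi1}, \code{pi0}, \code{lambda}, \code{m}.
#' @examples
#' estimatePi1(c(0.001, 0.002, 0.003, 0.6, 0.9))$pi1  # 0.2
#' @export
estimatePi1 <- function(p, lambda = 0.5) {
    if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
    if (any(p <= 0 | p > 1 | is.na(p)))
        stop("p-values must lie in (0, 1]")
    m <- length(p)
    if (m < 10L) warning("pi1 estimated from fewer than 10 p-values")
    pi0 <- sum(p > lambda) / ((1 - lambda) * m)
    list(pi1 = min(max(1 - pi0, 0), 1), pi0 = pi0, lambda = lambda, m = m)
}

#' Per-component significance counts and cross-tabulation
#'
#' Counts genes with permutation p strictly below \code{alpha} for each
#' component of an association table, plus pairwise overlap counts and
#' the member lists.
#'
#' @param assoc association table from \code{\link{runAssociation}} (any
#'   table with \code{gene_id}, \code{component}, \code{perm_p}
#'   columns).
#' @param alpha significance threshold (default 0.05, strict \code{<}).
#' @return list: \code{counts} (named per component), \code{overlap}
#'   (named counts for each component pair, e.g.
#'   \code{"grex&erex"}), \code{members} (list of significant gene-id
#'   vectors per component and pair).
#' @export
thresholdCounts <- function(assoc, alpha = 0.05) {
    comps <- unique(assoc$component)
    sig <- lapply(comps, function(cc)
        assoc$gene_id[assoc$component == cc & assoc$perm_p < alpha])
    names(sig) <- comps
    counts <- vapply(sig, length, 1L)
    overlap <- integer(0)
    members <- sig
    if (length(comps) > 1L) {
        prs <- utils::combn(comps, 2L, simplify = FALSE)
        for (pr in prs) {
            nm <- paste(pr, collapse = "&")
            both <- intersect(sig[[pr[1L]]], sig[[pr[2L]]])
            overlap[nm] <- length(both)
            members[[nm]] <- both
        }
    }
    list(counts = counts, overlap = overlap, members = members)
}
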