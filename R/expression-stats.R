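#' Differential-transcript filter
#'
#' Two-group differential filtering of a normalized expression matrix.
#' Transcripts whose mean normalized abundance is below \code{min_mean}
#' in both groups are excluded before testing. For the rest, a two-sided
#' Wilcoxon rank-sum test compares the groups, p-values are BH-adjusted
#' across tested transcripts, and a transcript is a DET when
#' |log2 FC| >= log2(\code{fc}) (fold change taken symmetrically, group B
#' over group A), adjusted p < \code{alpha}, and the larger group mean is
#' at least \code{min_mean}.
#'
#' @param se SummarizedExperiment of normalized abundances (e.g. TPM)
#'   with a \code{group} column in colData, or a plain matrix plus
#'   \code{groups}
#' @param group_a,group_b group labels to contrast (fold change is
#'   mean_b / mean_a)
#' @param groups named vector sample -> group (only for matrix input)
#' @param fc fold-change threshold (default 1.3, inclusive)
#' @param alpha adjusted-p threshold (default 0.05)
#' @param min_mean minimum normalized abundance (default 1)
#' @param biotype optional named vector transcript -> biotype label
#' @return data.frame: transcript_id, mean_a, mean_b, fc, log2fc,
#'   p_value, p_adj, tested, is_det, biotype
#' @export
detFilter <- function(se, group_a, group_b, groups = NULL, fc = 1.3,
                      alpha = 0.05, min_mean = 1, biotype = NULL) {
    if (methods::is(se, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(se, 1L)
        groups <- stats::setNames(
            SummarizedExperiment::colData(se)$group, colnames(m))
    } else m <- se
    ga <- names(groups)[groups == group_a]
    gb <- names(groups)[groups == group_b]
    if (length(ga) < 2L || length(gb) < 2L)
        stop("each group needs at least two samples")
    mean_a <- rowMeans(m[, ga, drop = FALSE])
    mean_b <- rowMeans(m[, gb, drop = FALSE])
    tested <- pmax(mean_a, mean_b) >= min_mean
    p <- rep(NA_real_, nrow(m))
    for (i in which(tested))
        p[i] <- suppressWarnings(stats::wilcox.test(
            m[i, gb], m[i, ga], alternative = "two.sided")$p.value)
    p_adj <- rep(NA_real_, nrow(m))
    p_adj[tested] <- bhAdjust(p[tested])
    fc_obs <- mean_b / mean_a
    log2fc <- log2(fc_obs)
    is_det <- tested & !is.na(p_adj) & p_adj < alpha &
        abs(log2fc) >= log2(fc)
    bt <- if (is.null(biotype)) rep(NA_character_, nrow(m))
          else unname(biotype[rownames(m)])
    data.frame(transcript_id = rownames(m), mean_a = mean_a,
               mean_b = mean_b, fc = fc_obs, log2fc = log2fc,
               p_value = p, p_adj = p_adj, tested = tested,
               is_det = unname(is_det), biotype = bt,
               row.names = NULL)
}

#' Biotype composition of a DET list
#'
#' @param dets data.frame from \code{\link{detFilter}} (or any frame with
#'   is_det and biotype columns)
#' @return data.frame: biotype, count, fraction (fractions sum to 1 over
#'   DETs); zero rows when there are no DETs
#' @export
detComposition <- function(dets) {
    d <- dets[dets$is_det, , drop = FALSE]
    if (nrow(d) == 0L)
        return(data.frame(biotype = character(), count = integer(),
                          fraction = numeric()))
    tab <- table(d$biotype, useNA = "ifany")
    data.frame(biotype = names(tab), count = as.integer(tab),
               fraction = as.numeric(tab) / nrow(d), row.names = NULL)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based single-sample enrichment statistic: genes are ordered by
#' decreasing expression (ties broken by gene id), in-set genes are
#' weighted by rank^\code{exponent} (the top gene carrying the largest
#' rank), and the score is the sum over all ranked positions of the
#' difference between the weighted in-set ECDF and the unweighted
#' out-of-set ECDF. Positive scores mean the set is concentrated among
#' highly expressed genes. The statistic depends on the data only through
#' ranks, so it is invariant under strictly monotone transforms of the
#' expression values.
#'
#' @param expr named numeric vector of expression values (one sample)
#' @param gene_set character vector of set member ids; must intersect
#'   \code{names(expr)} and must not cover all genes
#' @param exponent rank-weighting exponent (default 0.25)
#' @param normalize divide the score by the number of genes (default
#'   FALSE, the raw running-sum statistic)
#' @return a single numeric enrichment score
#' @export
ssgseaScore <- function(expr, gene_set, exponent = 0.25,
                        normalize = FALSE) {
    ids <- names(expr)
    if (is.null(ids)) stop("'expr' must be a named vector")
    inset <- ids %in% gene_set
    if (!any(inset)) stop("gene set shares no ids with the expression vector")
    if (all(inset)) stop("gene set covers all genes (empty complement)")
    n <- length(expr)
    ord <- order(-expr, ids)
    inset <- inset[ord]
    rank_val <- n - seq_len(n) + 1L   # top gene gets rank n
    w <- ifelse(inset, rank_val^exponent, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inset) / sum(!inset)
    score <- sum(p_in - p_out)
    if (normalize) score / n else score
}

#' Matrix of single-sample enrichment scores
#'
#' @param se SummarizedExperiment or matrix (transcripts x samples)
#' @param sets named list of gene sets
#' @param exponent rank-weighting exponent (default 0.25)
#' @param normalize GSVA-style normalization of the whole score matrix by
#'   its absolute range (default FALSE)
#' @return matrix, sets x samples
#' @export
ssgseaScores <- function(se, sets, exponent = 0.25, normalize = FALSE) {
    m <- if (methods::is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, 1L) else se
    out <- matrix(NA_real_, length(sets), ncol(m),
                  dimnames = list(names(sets), colnames(m)))
    for (s in names(sets)) for (j in seq_len(ncol(m)))
        out[s, j] <- ssgseaScore(stats::setNames(m[, j], rownames(m)),
                                 sets[[s]], exponent)
    if (normalize) out <- out / (max(out) - min(out))
    out
}

#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability P(X >= k) of drawing at least the observed
#' number of set members when selecting \code{n} genes from the universe.
#'
#' @param selected character vector of selected ids (e.g. DETs)
#' @param gene_set character vector of set member ids
#' @param universe character vector of all testable ids; \code{selected}
#'   and \code{gene_set} are intersected with it
#' @return list: k_hits, K_set, n_selected, N_universe, p_value
#' @export
hypergeomOverrep <- function(selected, gene_set, universe) {
    if (length(universe) == 0L) stop("empty universe")
    universe <- unique(universe)
    selected <- intersect(selected, universe)
    gene_set <- intersect(gene_set, universe)
    k <- length(intersect(selected, gene_set))
    K <- length(gene_set)
    n <- length(selected)
    N <- length(universe)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    list(k_hits = k, K_set = K, n_selected = n, N_universe = N,
         p_value = p)
}

#' Over-representation across a gene-set collection
#'
#' Applies \code{\link{hypergeomOverrep}} to every set and BH-adjusts the
#' p-values in one pooled family.
#'
#' @param selected selected ids
#' @param sets named list of gene sets
#' @param universe all testable ids
#' @param alpha adjusted-p threshold for the \code{enriched} flag
#'   (default 0.05)
#' @return data.frame: set_name, k_hits, K_set, n_selected, N_universe,
#'   p_value, p_adj, enriched
#' @export
pathwayOverrepresentation <- function(selected, sets, universe,
                                      alpha = 0.05) {
    rows <- lapply(names(sets), function(nm) {
        r <- hypergeomOverrep(selected, sets[[nm]], universe)
        data.frame(set_name = nm, k_hits = r$k_hits, K_set = r$K_set,
                   n_selected = r$n_selected, N_universe = r$N_universe,
                   p_value = r$p_value)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- bhAdjust(out$p_value)
    out$enriched <- out$p_adj < alpha
    out
}
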