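#' Minimal number of components reaching a variance threshold
#'
#' @param fractions explained-variance fractions, non-increasing
#' @param threshold cumulative-variance target (default 0.60, inclusive)
#' @return smallest k with cumulative fraction >= threshold
#' @export
chooseComponentCount <- function(fractions, threshold = 0.60) {
    if (any(fractions < 0)) stop("negative variance fraction")
    cs <- cumsum(fractions)
    k <- which(cs >= threshold - 1e-12)[1]
    if (is.na(k)) stop("fractions never reach the variance threshold")
    k
}

#' Principal components of a pathway's expression
#'
#' PCA over samples using the expression of the set's genes (genes
#' centered and, by default, unit-scaled so high-variance transcripts do
#' not dominate). Retains the smallest number of leading components whose
#' cumulative explained variance reaches \code{var_threshold}.
#'
#' @param se SummarizedExperiment or matrix (transcripts x samples)
#' @param gene_set ids of the set's transcripts; at least two must be
#'   present in the matrix
#' @param var_threshold cumulative-variance retention target (default
#'   0.60)
#' @param scale unit-scale genes before PCA (default TRUE,
#'   correlation-matrix PCA); zero-variance genes are dropped with a
#'   warning
#' @return list: scores (samples x k matrix of retained PCs), fractions
#'   (all explained fractions), k
#' @export
computePathwayPCs <- function(se, gene_set, var_threshold = 0.60,
                              scale = TRUE) {
    m <- if (methods::is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, 1L) else se
    present <- intersect(gene_set, rownames(m))
    if (length(present) < 2L)
        stop("fewer than two set genes present in the matrix")
    if (ncol(m) < 3L) stop("need at least three samples")
    x <- t(m[present, , drop = FALSE])
    v <- apply(x, 2L, stats::var)
    if (any(v == 0)) {
        warning("dropping ", sum(v == 0), " zero-variance gene(s)")
        x <- x[, v > 0, drop = FALSE]
        if (ncol(x) < 2L) stop("fewer than two variable set genes")
    }
    pc <- stats::prcomp(x, center = TRUE, scale. = scale)
    fractions <- pc$sdev^2 / sum(pc$sdev^2)
    k <- chooseComponentCount(fractions, var_threshold)
    list(scores = pc$x[, seq_len(k), drop = FALSE],
         fractions = fractions, k = k)
}

#' Regress a transcript's expression on retained pathway PCs
#'
#' Ordinary least squares of the (mean-centered) expression of one
#' transcript on the retained principal components of a pathway. Response
#' and predictors are centered, which drives the intercept to zero
#' exactly; |beta0| is reported as a diagnostic. The overall significance
#' is the F-test of the regression.
#'
#' @param expr numeric vector of the transcript's expression, aligned
#'   with the PC score rows
#' @param pcs result of \code{\link{computePathwayPCs}}
#' @return list: betas, beta0, r_squared, p_value, k, n
#' @export
fitPcRegression <- function(expr, pcs) {
    X <- pcs$scores
    n <- nrow(X); k <- ncol(X)
    if (length(expr) != n) stop("expression and PC scores are misaligned")
    if (n <= k + 1L) stop("need n > k + 1 samples")
    y <- expr - mean(expr)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    if (qr(Xc)$rank < k)
        stop("rank-deficient PC matrix")
    fit <- stats::lm(y ~ Xc)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    p <- if (is.null(fstat)) NA_real_
         else stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
    list(betas = unname(stats::coef(fit)[-1L]),
         beta0 = unname(stats::coef(fit)[1L]),
         r_squared = sm$r.squared, p_value = unname(p), k = k, n = n)
}

#' Spearman co-expression with a t-approximation p-value
#'
#' Tie-aware rank correlation; the two-sided p-value uses the
#' t-distribution approximation t = r sqrt((n-2)/(1-r^2)). Constant
#' vectors give an undefined correlation (NA, with a warning).
#'
#' @param x,y numeric vectors of equal length >= 4
#' @return list(r, p)
#' @export
spearmanCoexpression <- function(x, y) {
    if (length(x) != length(y)) stop("unequal lengths")
    n <- length(x)
    if (n < 4L) stop("need at least four paired samples")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant vector: Spearman correlation undefined")
        return(list(r = NA_real_, p = NA_real_))
    }
    r <- stats::cor(rank(x), rank(y))
    if (abs(r) >= 1) return(list(r = r, p = 0))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Default nearest-neighbor stacking energies
#'
#' A 16-entry stacked-pair energy table (kcal/mol, all negative), indexed
#' by the query-strand dinucleotide of a perfectly paired duplex,
#' following published RNA/RNA nearest-neighbor values (T read as U).
#' This is a simplified, ungapped parameterization: each consecutive pair
#' of matched bases contributes one stack.
#'
#' @return named numeric vector of 16 dinucleotide energies
#' @export
defaultStackTable <- function() {
    c(AA = -0.93, AC = -2.24, AG = -2.08, AT = -1.10,
      CA = -2.11, CC = -3.26, CG = -2.36, CT = -2.08,
      GA = -2.35, GC = -3.42, GG = -3.26, GT = -2.24,
      TA = -1.33, TC = -2.35, TG = -2.11, TT = -0.93)
}

encode_dna <- function(s) {
    v <- strsplit(toupper(as.character(s)), "", fixed = TRUE)[[1]]
    code <- unname(c(A = 0L, C = 1L, G = 2L, T = 3L)[v])
    code[is.na(code)] <- -1L
    code
}

stack_table_matrix <- function(table) {
    b <- c("A", "C", "G", "T")
    keys <- as.vector(t(outer(b, b, paste0)))  # AA AC AG AT CA ...
    as.numeric(table[keys])
}

#' Minimum-energy ungapped duplex between two sequences
#'
#' Scans every ungapped antiparallel window in which the query base-pairs
#' the reverse complement of the target; within a window, each
#' consecutive pair of matched bases contributes one nearest-neighbor
#' stack energy and any mismatch terminates the stack run. Returns the
#' window of minimum (most stable) total energy. Sequences shorter than
#' 12 nt yield a no-hit result with energy 0.
#'
#' @param query_seq query (e.g. lncRNA) nucleotide sequence
#' @param target_seq target nucleotide sequence
#' @param table stacking-energy table (default
#'   \code{\link{defaultStackTable}})
#' @param min_length minimum sequence length to attempt a scan (12)
#' @return list: energy (kcal/mol, <= 0), query_start/query_end and
#'   target_start/target_end (1-based, NA for no hit), length (paired
#'   bases)
#' @export
duplexEnergy <- function(query_seq, target_seq,
                         table = defaultStackTable(), min_length = 12L) {
    q <- toupper(as.character(query_seq))
    t <- toupper(as.character(target_seq))
    nohit <- list(energy = 0, query_start = NA_integer_,
                  query_end = NA_integer_, target_start = NA_integer_,
                  target_end = NA_integer_, length = 0L)
    if (nchar(q) < min_length || nchar(t) < min_length) return(nohit)
    trc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(t)))
    res <- .duplex_scan(encode_dna(q), encode_dna(trc),
                        stack_table_matrix(table))
    if (res$length < 2L) return(nohit)
    qs <- res$q_start + 1L
    rcs <- res$rc_start + 1L
    nt <- nchar(t)
    list(energy = res$energy,
         query_start = qs, query_end = qs + res$length - 1L,
         target_start = nt - (rcs + res$length - 1L) + 1L,
         target_end = nt - rcs + 1L,
         length = res$length)
}

#' Cis target candidates of lncRNAs
#'
#' For each lncRNA, candidate cis targets are transcripts whose genomic
#' span lies within \code{window} bp (gap distance, inclusive; 0 when
#' overlapping) of the lncRNA span on the same sequence, strand-agnostic.
#' Each tested pair gets a Spearman co-expression estimate; p-values are
#' BH-adjusted in one family over all tested cis pairs, and a pair is
#' kept when adjusted p < \code{alpha} and |r| > 0.
#'
#' @param lncrna_ids lncRNA transcript ids (present in \code{catalog} and
#'   the matrix)
#' @param catalog TranscriptCatalog holding lncRNAs and targets
#' @param se expression SummarizedExperiment or matrix
#' @param target_ids candidate target transcript ids
#' @param window maximum gap distance in bp (default 100000, inclusive)
#' @param alpha adjusted-p threshold (default 0.05)
#' @return data.frame: lncrna_id, target_id, distance, r, p_value, p_adj,
#'   kept
#' @export
predictCisTargets <- function(lncrna_ids, catalog, se, target_ids,
                              window = 1e5, alpha = 0.05) {
    m <- if (methods::is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, 1L) else se
    spans <- transcriptSpans(catalog)
    rows <- list()
    for (ln in lncrna_ids) {
        d <- suppressWarnings(GenomicRanges::distance(
            spans[ln], spans[target_ids], ignore.strand = TRUE))
        ok <- !is.na(d) & d <= window
        for (tg in target_ids[ok]) {
            sp <- spearmanCoexpression(m[ln, ], m[tg, ])
            rows[[length(rows) + 1L]] <- data.frame(
                lncrna_id = ln, target_id = tg,
                distance = d[match(tg, target_ids)],
                r = sp$r, p_value = sp$p)
        }
    }
    if (length(rows) == 0L)
        return(data.frame(lncrna_id = character(), target_id = character(),
                          distance = integer(), r = numeric(),
                          p_value = numeric(), p_adj = numeric(),
                          kept = logical()))
    out <- do.call(rbind, rows)
    keep <- !is.na(out$p_value)
    out$p_adj <- NA_real_
    out$p_adj[keep] <- bhAdjust(out$p_value[keep])
    out$kept <- keep & out$p_adj < alpha & abs(out$r) > 0
    out
}

#' Trans target candidates of lncRNAs
#'
#' A target qualifies when (1) it lies outside the lncRNA's cis window,
#' (2) the minimum duplex energy between the lncRNA and the target
#' sequence is strictly below \code{energy_cutoff}, and (3) the pair is
#' co-expressed (Spearman adjusted p < \code{alpha}, |r| > 0; BH family =
#' all energy-passing trans pairs).
#'
#' @param lncrna_ids lncRNA transcript ids
#' @param catalog TranscriptCatalog
#' @param genome DNAStringSet of chromosome sequences
#' @param se expression SummarizedExperiment or matrix
#' @param target_ids candidate target transcript ids
#' @param energy_cutoff energy threshold in kcal/mol (default -10,
#'   strict: a hit at exactly the cutoff is rejected)
#' @param window cis window excluded from trans testing (default 100000)
#' @param alpha adjusted-p threshold (default 0.05)
#' @param table stacking-energy table
#' @return data.frame: lncrna_id, target_id, energy, r, p_value, p_adj,
#'   kept
#' @export
predictTransTargets <- function(lncrna_ids, catalog, genome, se,
                                target_ids, energy_cutoff = -10,
                                window = 1e5, alpha = 0.05,
                                table = defaultStackTable()) {
    m <- if (methods::is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, 1L) else se
    spans <- transcriptSpans(catalog)
    seqs <- transcriptSeqs(genome, catalog[unique(c(lncrna_ids, target_ids))])
    rows <- list()
    for (ln in lncrna_ids) {
        d <- suppressWarnings(GenomicRanges::distance(
            spans[ln], spans[target_ids], ignore.strand = TRUE))
        far <- is.na(d) | d > window
        for (tg in target_ids[far]) {
            hit <- duplexEnergy(seqs[[ln]], seqs[[tg]], table = table)
            if (hit$energy >= energy_cutoff) next
            sp <- spearmanCoexpression(m[ln, ], m[tg, ])
            rows[[length(rows) + 1L]] <- data.frame(
                lncrna_id = ln, target_id = tg, energy = hit$energy,
                r = sp$r, p_value = sp$p)
        }
    }
    if (length(rows) == 0L)
        return(data.frame(lncrna_id = character(), target_id = character(),
                          energy = numeric(), r = numeric(),
                          p_value = numeric(), p_adj = numeric(),
                          kept = logical()))
    out <- do.call(rbind, rows)
    keep <- !is.na(out$p_value)
    out$p_adj <- NA_real_
    out$p_adj[keep] <- bhAdjust(out$p_value[keep])
    out$kept <- keep & out$p_adj < alpha & abs(out$r) > 0
    out
}

#' Fit all lncRNA-pathway PC regressions
#'
#' One regression per (lncRNA, pathway) pair, with BH adjustment in a
#' single family across all pairs.
#'
#' @param se expression SummarizedExperiment or matrix
#' @param lncrna_ids lncRNA transcript ids (rows of the matrix)
#' @param sets named list of pathway transcript-id sets
#' @param var_threshold PC retention threshold (default 0.60)
#' @return data.frame: lncrna_id, set_name, k, r_squared, beta0, p_value,
#'   p_adj
#' @export
fitAllPcRegressions <- function(se, lncrna_ids, sets,
                                var_threshold = 0.60) {
    m <- if (methods::is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, 1L) else se
    pcs <- lapply(sets, function(s)
        computePathwayPCs(m, s, var_threshold = var_threshold))
    rows <- list()
    for (ln in lncrna_ids) for (nm in names(sets)) {
        fit <- fitPcRegression(m[ln, ], pcs[[nm]])
        rows[[length(rows) + 1L]] <- data.frame(
            lncrna_id = ln, set_name = nm, k = fit$k,
            r_squared = fit$r_squared, beta0 = fit$beta0,
            p_value = fit$p_value)
    }
    out <- do.call(rbind, rows)
    out$p_adj <- bhAdjust(out$p_value)
    out
}

#' Call lncRNA pathway regulators
#'
#' A (lncRNA, pathway) pair is called when (1) the PC regression of the
#' lncRNA on the pathway's retained PCs has R^2 >= \code{r2_threshold}
#' and BH-adjusted p < \code{alpha}, and (2) at least one kept cis or
#' trans target of the lncRNA is a member of the pathway.
#'
#' @param fits data.frame from \code{\link{fitAllPcRegressions}}
#' @param cis kept/unkept cis table from \code{\link{predictCisTargets}}
#' @param trans kept/unkept trans table from
#'   \code{\link{predictTransTargets}}
#' @param sets named list of pathway transcript-id sets
#' @param r2_threshold minimum R^2 (default 0.6)
#' @param alpha adjusted-p threshold (default 0.05)
#' @return \code{fits} with added columns n_support (qualifying in-set
#'   targets), supporting_targets (comma-joined "id(mode)") and called
#' @export
callPathwayRegulators <- function(fits, cis, trans, sets,
                                  r2_threshold = 0.6, alpha = 0.05) {
    kept_cis <- cis[cis$kept, , drop = FALSE]
    kept_trans <- trans[trans$kept, , drop = FALSE]
    n_support <- integer(nrow(fits))
    support <- character(nrow(fits))
    for (i in seq_len(nrow(fits))) {
        members <- sets[[fits$set_name[i]]]
        tc <- kept_cis$target_id[kept_cis$lncrna_id == fits$lncrna_id[i]]
        tt <- kept_trans$target_id[kept_trans$lncrna_id == fits$lncrna_id[i]]
        sc <- intersect(tc, members)
        st <- intersect(tt, members)
        n_support[i] <- length(sc) + length(st)
        support[i] <- paste(c(sprintf("%s(cis)", sc),
                              sprintf("%s(trans)", st)), collapse = ",")
    }
    fits$n_support <- n_support
    fits$supporting_targets <- support
    fits$called <- fits$r_squared >= r2_threshold &
        !is.na(fits$p_adj) & fits$p_adj < alpha & n_support > 0L
    fits
}

#' End-to-end lncRNA pathway-regulator inference
#'
#' Convenience wrapper chaining \code{\link{fitAllPcRegressions}},
#' \code{\link{predictCisTargets}}, \code{\link{predictTransTargets}} and
#' \code{\link{callPathwayRegulators}}. Expression values are
#' log2(x + 1)-transformed before PCA/regression (disable with
#' \code{log_transform = FALSE}); Spearman statistics are rank-based and
#' unaffected by the transform.
#'
#' @param catalog TranscriptCatalog
#' @param genome DNAStringSet
#' @param se expression SummarizedExperiment (TPM)
#' @param sets named list of pathway transcript-id sets
#' @param lncrna_ids lncRNA transcript ids
#' @param target_ids candidate target transcript ids
#' @param r2_threshold,alpha,window,energy_cutoff,var_threshold thresholds
#'   (defaults 0.6, 0.05, 1e5, -10, 0.6)
#' @param log_transform log2(x+1)-transform expression first (default
#'   TRUE)
#' @return list: calls (regulator table), cis, trans
#' @export
inferRegulators <- function(catalog, genome, se, sets, lncrna_ids,
                            target_ids, r2_threshold = 0.6, alpha = 0.05,
                            window = 1e5, energy_cutoff = -10,
                            var_threshold = 0.60, log_transform = TRUE) {
    m <- if (methods::is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, 1L) else se
    if (log_transform) m <- log2(m + 1)
    fits <- fitAllPcRegressions(m, lncrna_ids, sets, var_threshold)
    cis <- predictCisTargets(lncrna_ids, catalog, m, target_ids,
                             window = window, alpha = alpha)
    trans <- predictTransTargets(lncrna_ids, catalog, genome, m,
                                 target_ids, energy_cutoff = energy_cutoff,
                                 window = window, alpha = alpha)
    calls <- callPathwayRegulators(fits, cis, trans, sets,
                                   r2_threshold = r2_threshold,
                                   alpha = alpha)
    list(calls = calls, cis = cis, trans = trans)
}
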