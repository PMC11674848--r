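suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
    library(SummarizedExperiment)
})

# build a catalog from a compact spec: list(tx_id = list(gene, strand,
# exons = list(c(start, end), ...), cds = optional list, biotype))
make_catalog <- function(spec, seqname = "chr1") {
    exl <- list(); cdl <- list(); gid <- character(); bt <- character()
    for (id in names(spec)) {
        s <- spec[[id]]
        m <- do.call(rbind, s$exons)
        exl[[id]] <- GRanges(seqname, IRanges(m[, 1], m[, 2]), s$strand)
        if (!is.null(s$cds)) {
            mc <- do.call(rbind, s$cds)
            cdl[[id]] <- GRanges(seqname, IRanges(mc[, 1], mc[, 2]), s$strand)
        }
        gid[id] <- s$gene
        bt[id] <- if (is.null(s$biotype)) NA_character_ else s$biotype
    }
    TranscriptCatalog(exl, geneId = gid,
                      cds = if (length(cdl)) cdl else NULL, biotype = bt)
}

# random multi-transcript catalog for round-trip / overlap properties
random_catalog <- function(n_tx = 10, seqlen = 20000, seed = 1,
                           prefix = "t") {
    set.seed(seed)
    spec <- list()
    for (k in seq_len(n_tx)) {
        n_ex <- sample(1:4, 1)
        pos <- sort(sample(seq_len(seqlen - 200), 2 * n_ex))
        # widen degenerate exons
        exons <- lapply(seq_len(n_ex), function(i)
            c(pos[2 * i - 1], max(pos[2 * i], pos[2 * i - 1] + 1)))
        # enforce disjointness by construction (sorted pairs can touch)
        for (i in seq_len(n_ex - 1))
            if (exons[[i + 1]][1] <= exons[[i]][2] + 1)
                exons[[i + 1]][1] <- exons[[i]][2] + 2
        exons <- lapply(exons, function(e) c(e[1], max(e)))
        spec[[sprintf("%s%03d", prefix, k)]] <- list(
            gene = sprintf("g%02d", sample(1:5, 1)),
            strand = sample(c("+", "-"), 1),
            exons = exons,
            biotype = sample(c("protein_coding", "lncRNA", NA), 1))
    }
    make_catalog(spec)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                               "")[[1]],
                                      n, replace = TRUE), collapse = "")

revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# shared small training set for scorer calibration in recovery tests
calibrated_thresholds <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            train <- simulateAnnotation(simConfig(seed = 9001))
            cod <- transcriptSeqs(train$genome,
                                  train$reference[train$truth$coding_ids])
            nc <- randomNoncodingSeqs(500, seed = 9002)
            cache <<- calibrateScorerThresholds(cod, nc)
        }
        cache
    }
})
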