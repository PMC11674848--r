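#' Candidate filter for lncRNA identification
#'
#' Retains transcripts with spliced length >= 200 nt and at least two
#' exons (both thresholds inclusive).
#'
#' @param catalog a TranscriptCatalog
#' @return character vector of retained transcript ids
#' @export
filterCandidates <- function(catalog) {
    len <- transcriptLengths(catalog)
    nex <- S4Vectors::elementNROWS(exonRanges(catalog))
    names(which(len >= 200L & nex >= 2L))
}

#' Assign a genomic class code relative to a reference annotation
#'
#' Classifies a novel transcript against reference transcript models:
#' \describe{
#'   \item{u}{no overlap between the transcript span and any reference
#'     transcript span (intergenic);}
#'   \item{i}{every transcript base lies within a single reference
#'     transcript's intron;}
#'   \item{x}{every exonic base of the transcript falls within the exon
#'     space of a single reference gene (full exonic overlap);}
#'   \item{o}{any other overlap (partial, spanning exon and intron or
#'     flank).}
#' }
#' Overlap tests ignore strand; the strand distinction is made later by
#' \code{\link{categorizeLncrna}}.
#'
#' @param transcript_id id of the (novel) transcript in \code{catalog}
#' @param catalog TranscriptCatalog holding the transcript
#' @param reference TranscriptCatalog of reference models
#' @return list(code, evidence): the class code and the reference
#'   transcript ids overlapped (empty for "u")
#' @export
assignClassCode <- function(transcript_id, catalog, reference) {
    ex <- exonRanges(catalog)[[transcript_id]]
    q_chr <- as.character(GenomicRanges::seqnames(ex))[1]
    qs <- start(ex); qe <- end(ex)
    q_lo <- min(qs); q_hi <- max(qe)
    idx <- class_code_index(reference)
    hit <- which(idx$tx_chr == q_chr & idx$span_lo <= q_hi &
                 idx$span_hi >= q_lo)
    evidence <- idx$tx_ids[hit]
    if (length(hit) == 0L)
        return(list(code = "u", evidence = character()))
    # i: entirely within a single intron of one reference transcript
    for (h in hit) {
        ee <- idx$exon_ends[[h]]; ss <- idx$exon_starts[[h]]
        if (length(ss) < 2L) next
        int_lo <- ee[-length(ee)] + 1L
        int_hi <- ss[-1L] - 1L
        if (any(int_lo <= q_lo & q_hi <= int_hi))
            return(list(code = "i", evidence = evidence))
    }
    # x: exonic bases contained in the exon space of a single reference gene
    for (g in unique(idx$tx_gene[hit])) {
        merged <- idx$gene_exons[[g]]
        covered <- all(vapply(seq_along(qs), function(i)
            any(merged$lo <= qs[i] & qe[i] <= merged$hi &
                merged$chr == q_chr), logical(1)))
        if (covered)
            return(list(code = "x", evidence = evidence))
    }
    list(code = "o", evidence = evidence)
}

# flat integer index of a reference catalog used by assignClassCode
class_code_index <- function(reference) {
    ex <- exonRanges(reference)
    gr <- unlist(ex, use.names = FALSE)
    f <- rep(seq_along(ex), S4Vectors::elementNROWS(ex))
    st <- start(gr); en <- end(gr)
    chr <- as.character(GenomicRanges::seqnames(gr))
    tx_ids <- names(ex)
    tx_gene <- unname(geneIds(reference)[tx_ids])
    exon_starts <- split(st, f)
    exon_ends <- split(en, f)
    gene_exons <- lapply(split(seq_along(f), tx_gene[f]), function(i) {
        m <- merge_intervals(st[i], en[i], chr[i])
        m
    })
    list(tx_ids = tx_ids, tx_gene = tx_gene,
         tx_chr = vapply(split(chr, f), `[`, character(1), 1L),
         span_lo = vapply(exon_starts, min, numeric(1)),
         span_hi = vapply(exon_ends, max, numeric(1)),
         exon_starts = exon_starts, exon_ends = exon_ends,
         gene_exons = gene_exons)
}

merge_intervals <- function(lo, hi, chr) {
    out_lo <- numeric(); out_hi <- numeric(); out_chr <- character()
    for (cc in unique(chr)) {
        i <- which(chr == cc)
        o <- order(lo[i])
        l <- lo[i][o]; h <- hi[i][o]
        ml <- l[1]; mh <- h[1]
        for (k in seq_along(l)[-1]) {
            if (l[k] <= mh + 1L) mh <- max(mh, h[k])
            else {
                out_lo <- c(out_lo, ml); out_hi <- c(out_hi, mh)
                out_chr <- c(out_chr, cc)
                ml <- l[k]; mh <- h[k]
            }
        }
        out_lo <- c(out_lo, ml); out_hi <- c(out_hi, mh)
        out_chr <- c(out_chr, cc)
    }
    list(lo = out_lo, hi = out_hi, chr = out_chr)
}

#' Categorize an identified lncRNA by genomic position
#'
#' Precedence antisense > intronic > intergenic: antisense when the
#' lncRNA span overlaps a reference gene on the opposite strand; intronic
#' when its class code is "i" on the same strand; intergenic when the
#' class code is "u". Transcripts matching none of these (e.g.
#' same-strand exonic overlap) fall back to intergenic with a warning.
#' Unstranded ("*") lncRNAs are oriented as "+" with a warning.
#'
#' @param transcript_id lncRNA transcript id in \code{catalog}
#' @param catalog TranscriptCatalog holding the lncRNA
#' @param reference reference TranscriptCatalog
#' @param class_code class code from \code{\link{assignClassCode}} (string)
#' @return one of "intergenic", "antisense", "intronic"
#' @export
categorizeLncrna <- function(transcript_id, catalog, reference, class_code) {
    span <- transcriptSpans(catalog[transcript_id])
    str <- as.character(strand(span))
    if (str == "*") {
        warning("unstranded lncRNA ", transcript_id, " oriented as '+'")
        str <- "+"
    }
    ref_spans <- transcriptSpans(reference)
    opp <- ref_spans[as.character(strand(ref_spans)) != str &
                     as.character(strand(ref_spans)) != "*"]
    if (length(opp) && any(IRanges::overlapsAny(opp, span, ignore.strand = TRUE)))
        return("antisense")
    if (class_code == "i") return("intronic")
    if (class_code == "u") return("intergenic")
    warning("lncRNA ", transcript_id,
            " matches no category; reported as intergenic")
    "intergenic"
}

#' Generate random noncoding training sequences
#'
#' Uniform-composition nucleotide sequences for use as the noncoding
#' training set of \code{\link{calibrateScorerThresholds}}.
#'
#' @param n number of sequences
#' @param lengths vector of lengths to sample from (recycled/sampled)
#' @param seed RNG seed
#' @return named character vector of sequences
#' @export
randomNoncodingSeqs <- function(n = 300L, lengths = 300:2000, seed = 1L) {
    with_local_seed(seed, {
        lens <- sample(lengths, n, replace = TRUE)
        stats::setNames(vapply(lens, function(L)
            paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = ""), character(1)),
            sprintf("nc_train_%04d", seq_len(n)))
    })
}

#' Identify lncRNAs in an assembled catalog
#'
#' Runs the full two-step identification: candidate filtering (>= 200 nt
#' spliced, >= 2 exons), five-scorer coding-potential assessment with the
#' unanimous-vote consensus, then class-code assignment and positional
#' categorization against the reference for transcripts absent from it.
#'
#' @param catalog assembled TranscriptCatalog (novel + known transcripts)
#' @param reference reference TranscriptCatalog
#' @param genome DNAStringSet of chromosome sequences
#' @param thresholds scorer thresholds from
#'   \code{\link{calibrateScorerThresholds}}; must carry hexamer tables
#' @return data.frame with one row per candidate: transcript_id, the five
#'   scores, the five verdicts (TRUE = coding vote), is_lncrna,
#'   class_code and category (NA for transcripts present in the
#'   reference or not called)
#' @export
identifyLncRNAs <- function(catalog, reference, genome, thresholds) {
    if (is.null(thresholds$hexamer_tables))
        stop("thresholds must include hexamer_tables ",
             "(use calibrateScorerThresholds)")
    cand <- filterCandidates(catalog)
    seqs <- transcriptSeqs(genome, catalog[cand])
    scores <- codingPotentialScores(seqs, thresholds$hexamer_tables)
    verdicts <- codingVerdicts(scores, thresholds)
    is_lnc <- consensusVote(verdicts)
    res <- data.frame(transcript_id = cand,
        scores, verdicts = verdicts, is_lncrna = unname(is_lnc),
        class_code = NA_character_, category = NA_character_,
        row.names = cand, check.names = FALSE)
    names(res)[7:11] <- paste0("vote_", scorerNames())
    novel <- setdiff(cand, transcriptIds(reference))
    for (id in novel[res[novel, "is_lncrna"]]) {
        cc <- assignClassCode(id, catalog, reference)
        res[id, "class_code"] <- cc$code
        res[id, "category"] <- categorizeLncrna(id, catalog, reference, cc$code)
    }
    res
}

#' Distribution of read intervals over genomic regions
#'
#' Assigns each read interval to one region by precedence CDS > 3'UTR >
#' intron > upstream-10kb > unassigned, where the regions derive from the
#' reference annotation: CDS exon bases; exonic bases downstream of the
#' CDS end (strand-aware) as 3'UTR; intronic bases; and the 10 kb
#' upstream of each transcription start site. A read overlapping several
#' region types counts once, for the highest-precedence type it touches.
#' Fractions are over assigned reads and sum to 1.
#'
#' @param reads GRanges of read intervals
#' @param reference TranscriptCatalog with CDS annotations
#' @param upstream width of the upstream window in bp (default 10000)
#' @return list(counts, fractions): named by
#'   c("CDS","UTR3","intron","upstream"), plus an "unassigned" count
#' @export
regionReadDistribution <- function(reads, reference, upstream = 10000L) {
    cds_all <- unlist(cdsRanges(reference))
    utr3 <- threeUtrRanges(reference)
    introns <- unlist(intronRanges(reference))
    spans <- transcriptSpans(reference)
    up <- GenomicRanges::flank(spans, upstream, start = TRUE)
    up <- GenomicRanges::trim(up)
    assign_one <- function(region)
        IRanges::overlapsAny(reads, region, ignore.strand = TRUE)
    in_cds <- assign_one(cds_all)
    in_utr3 <- assign_one(utr3) & !in_cds
    in_intron <- assign_one(introns) & !in_cds & !in_utr3
    in_up <- assign_one(up) & !in_cds & !in_utr3 & !in_intron
    counts <- c(CDS = sum(in_cds), UTR3 = sum(in_utr3),
                intron = sum(in_intron), upstream = sum(in_up))
    unassigned <- length(reads) - sum(counts)
    fractions <- if (sum(counts) > 0) counts / sum(counts) else counts * NA
    list(counts = c(counts, unassigned = unassigned), fractions = fractions)
}

#' 3'-UTR ranges of coding reference transcripts
#'
#' Exonic bases strictly downstream (strand-aware) of the CDS end.
#'
#' @param reference TranscriptCatalog
#' @return GRanges of 3'UTR pieces
#' @export
threeUtrRanges <- function(reference) {
    ex <- exonRanges(reference)
    cd <- cdsRanges(reference)
    has_cds <- S4Vectors::elementNROWS(cd) > 0L
    pieces <- list(GenomicRanges::GRanges())
    for (id in names(ex)[has_cds]) {
        e <- ex[[id]]
        cc <- cd[[id]]
        str <- as.character(strand(e))[1]
        non_cds <- GenomicRanges::setdiff(e, cc, ignore.strand = TRUE)
        if (length(non_cds) == 0L) next
        keep <- if (str == "-") end(non_cds) < min(start(cc))
                else start(non_cds) > max(end(cc))
        pieces[[length(pieces) + 1L]] <- non_cds[keep]
    }
    do.call(c, pieces)
}
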