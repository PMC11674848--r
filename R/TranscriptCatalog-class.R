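#' TranscriptCatalog: an exon-structured transcript annotation
#'
#' A \code{TranscriptCatalog} holds a set of stranded, exon-structured
#' transcript models, each belonging to a gene, with optional CDS ranges and
#' an optional biotype label. Exons of a transcript live on a single
#' sequence and strand, are pairwise disjoint and sorted by start
#' coordinate. Coordinates are 1-based closed (the GRanges convention);
#' GTF input needs no shifting.
#'
#' @slot exons CompressedGRangesList, one element per transcript (named by
#'   transcript id), each a sorted, disjoint set of exon ranges.
#' @slot cds CompressedGRangesList parallel to \code{exons}; elements may be
#'   empty for non-coding transcripts.
#' @slot geneId named character vector mapping transcript id to gene id.
#' @slot biotype named character vector of biotype labels (NA allowed).
#'
#' @importClassesFrom GenomicRanges CompressedGRangesList
#' @export
setClass("TranscriptCatalog",
    slots = c(
        exons   = "CompressedGRangesList",
        cds     = "CompressedGRangesList",
        geneId  = "character",
        biotype = "character"
    )
)

setValidity("TranscriptCatalog", function(object) {
    ex <- object@exons
    ids <- names(ex)
    msgs <- character()
    if (is.null(ids) || anyDuplicated(ids))
        msgs <- c(msgs, "transcript ids must be unique, non-NULL names of 'exons'")
    if (!identical(ids, names(object@cds)))
        msgs <- c(msgs, "'cds' must be parallel to 'exons' with identical names")
    if (!identical(ids, names(object@geneId)))
        msgs <- c(msgs, "'geneId' must be named by transcript id, parallel to 'exons'")
    if (!identical(ids, names(object@biotype)))
        msgs <- c(msgs, "'biotype' must be named by transcript id, parallel to 'exons'")
    if (any(S4Vectors::elementNROWS(ex) == 0L))
        msgs <- c(msgs, "every transcript needs at least one exon")
    # single seqname/strand per transcript, disjoint sorted exons
    if (length(ex)) {
        gr <- unlist(ex, use.names = FALSE)
        f <- rep(seq_along(ex), S4Vectors::elementNROWS(ex))
        chr <- as.character(GenomicRanges::seqnames(gr))
        str <- as.character(strand(gr))
        if (anyDuplicated(unique(data.frame(f, chr))$f))
            msgs <- c(msgs, "a transcript's exons must share one sequence")
        if (anyDuplicated(unique(data.frame(f, str))$f))
            msgs <- c(msgs, "a transcript's exons must share one strand")
        if (!all(unlist(IRanges::isDisjoint(IRanges::ranges(ex)),
                        use.names = FALSE)))
            msgs <- c(msgs, "a transcript's exons must be pairwise disjoint")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptCatalog
#'
#' @param exons GRangesList (or list of GRanges) named by transcript id.
#' @param geneId character vector of gene ids, one per transcript, either
#'   named by transcript id or parallel to \code{exons}.
#' @param cds optional GRangesList of CDS ranges (subset of transcripts may
#'   be present; missing transcripts get empty CDS).
#' @param biotype optional character vector of biotype labels.
#' @return A \code{TranscriptCatalog}. Exons are sorted by start coordinate
#'   within each transcript.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)), "+"))
#' tc <- TranscriptCatalog(ex, geneId = c(t1 = "g1"))
#' transcriptLengths(tc)
#' @export
TranscriptCatalog <- function(exons, geneId, cds = NULL, biotype = NULL) {
    if (is.list(exons)) exons <- GenomicRanges::GRangesList(exons)
    exons <- methods::as(exons, "CompressedGRangesList")
    ids <- names(exons)
    if (is.null(ids)) stop("'exons' must be named by transcript id")
    exons <- sort_exons(exons)
    if (is.null(names(geneId))) names(geneId) <- ids
    geneId <- geneId[ids]
    if (anyNA(geneId)) stop("every transcript needs a gene_id")
    if (is.null(cds)) {
        empty <- GenomicRanges::GRangesList(lapply(ids, function(i)
            GenomicRanges::GRanges()))
        names(empty) <- ids
        cds <- methods::as(empty, "CompressedGRangesList")
    } else {
        if (is.list(cds)) cds <- GenomicRanges::GRangesList(cds)
        full <- setdiff(ids, names(cds))
        if (length(full)) {
            pad <- GenomicRanges::GRangesList(lapply(full, function(i)
                GenomicRanges::GRanges()))
            names(pad) <- full
            cds <- c(methods::as(cds, "CompressedGRangesList"),
                     methods::as(pad, "CompressedGRangesList"))
        }
        cds <- sort_exons(methods::as(cds[ids], "CompressedGRangesList"))
    }
    if (is.null(biotype)) biotype <- stats::setNames(rep(NA_character_, length(ids)), ids)
    if (is.null(names(biotype))) names(biotype) <- ids
    biotype <- biotype[ids]
    names(biotype) <- ids
    methods::new("TranscriptCatalog", exons = exons, cds = cds,
                 geneId = geneId, biotype = biotype)
}

sort_exons <- function(grl) {
    # sort each element by start, independent of strand
    if (length(grl) == 0L) return(methods::as(grl, "CompressedGRangesList"))
    gr <- unlist(grl, use.names = FALSE)
    f <- rep(seq_along(grl), S4Vectors::elementNROWS(grl))
    o <- order(f, start(gr))
    out <- IRanges::relist(gr[o], grl)
    names(out) <- names(grl)
    methods::as(out, "CompressedGRangesList")
}

#' @describeIn TranscriptCatalog number of transcripts
#' @param x a TranscriptCatalog
#' @export
setMethod("length", "TranscriptCatalog", function(x) length(x@exons))

#' @describeIn TranscriptCatalog transcript identifiers
#' @export
setMethod("transcriptIds", "TranscriptCatalog", function(x) names(x@exons))

#' @describeIn TranscriptCatalog named gene ids (by transcript)
#' @export
setMethod("geneIds", "TranscriptCatalog", function(x) x@geneId)

#' @describeIn TranscriptCatalog exon GRangesList
#' @export
setMethod("exonRanges", "TranscriptCatalog", function(x) x@exons)

#' @describeIn TranscriptCatalog CDS GRangesList (empty elements for
#'   non-coding transcripts)
#' @export
setMethod("cdsRanges", "TranscriptCatalog", function(x) x@cds)

#' @describeIn TranscriptCatalog named biotype labels
#' @export
setMethod("biotypes", "TranscriptCatalog", function(x) x@biotype)

#' @describeIn TranscriptCatalog spliced transcript lengths (sum of exon
#'   widths)
#' @export
setMethod("transcriptLengths", "TranscriptCatalog", function(x)
    stats::setNames(sum(width(x@exons)), names(x@exons)))

#' @describeIn TranscriptCatalog introns as the gaps between consecutive
#'   exons, per transcript
#' @export
setMethod("intronRanges", "TranscriptCatalog", function(x) {
    methods::as(S4Vectors::endoapply(x@exons, function(g) {
        if (length(g) < 2L) return(g[0])
        GenomicRanges::GRanges(GenomicRanges::seqnames(g)[-1],
            IRanges::IRanges(end(g)[-length(g)] + 1L, start(g)[-1] - 1L),
            strand = strand(g)[-1])
    }), "CompressedGRangesList")
})

#' @describeIn TranscriptCatalog genomic span (first exon start to last
#'   exon end) of each transcript, as a GRanges named by transcript id
#' @export
setMethod("transcriptSpans", "TranscriptCatalog", function(x)
    unlist(range(x@exons)))

#' @describeIn TranscriptCatalog subset by transcript id or index
#' @param i transcript ids (character) or indices
#' @param j unused
#' @param ... unused
#' @param drop unused
#' @export
setMethod("[", "TranscriptCatalog", function(x, i, j, ..., drop = FALSE) {
    # slots of a valid catalog stay valid under parallel subsetting, so
    # skip the (costly) validity re-check
    S4Vectors::new2("TranscriptCatalog", exons = x@exons[i],
                    cds = x@cds[i], geneId = x@geneId[i],
                    biotype = x@biotype[i], check = FALSE)
})

setMethod("show", "TranscriptCatalog", function(object) {
    ids <- transcriptIds(object)
    cat("TranscriptCatalog with", length(ids), "transcripts from",
        length(unique(object@geneId)), "genes\n")
    nc <- sum(S4Vectors::elementNROWS(object@cds) > 0L)
    cat("  coding (with CDS):", nc, " | exon count range:",
        paste(range(S4Vectors::elementNROWS(object@exons)), collapse = "-"), "\n")
    if (length(ids) > 0L)
        cat("  transcript ids:", paste(utils::head(ids, 4L), collapse = ", "),
            if (length(ids) > 4L) "..." else "", "\n")
})

#' Map gene ids to their transcript ids
#'
#' @param x a TranscriptCatalog
#' @return named list, gene id -> character vector of transcript ids
#' @export
geneTranscriptMap <- function(x) {
    split(transcriptIds(x), geneIds(x))
}

#' Extract spliced transcript sequences
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for minus-strand transcripts. Strand "*" is treated as "+" with a
#' warning.
#'
#' @param genome a DNAStringSet (or named character vector) of chromosome
#'   sequences
#' @param catalog a TranscriptCatalog
#' @param ranges which ranges to splice: "exons" (default) or "cds"
#' @return DNAStringSet named by transcript id (CDS mode drops transcripts
#'   without CDS)
#' @export
transcriptSeqs <- function(genome, catalog, ranges = c("exons", "cds")) {
    ranges <- match.arg(ranges)
    if (!methods::is(genome, "DNAStringSet"))
        genome <- Biostrings::DNAStringSet(genome)
    grl <- if (ranges == "exons") exonRanges(catalog) else cdsRanges(catalog)
    grl <- grl[S4Vectors::elementNROWS(grl) > 0L]
    if (any(as.character(strand(unlist(grl, use.names = FALSE))) == "*"))
        warning("unstranded transcripts treated as '+' strand")
    seqs <- lapply(seq_along(grl), function(i) {
        g <- grl[[i]]
        chr <- as.character(GenomicRanges::seqnames(g))[1]
        pieces <- Biostrings::extractAt(genome[[chr]],
            IRanges::IRanges(start(g), end(g)))
        s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
        if (as.character(strand(g))[1] == "-")
            s <- Biostrings::reverseComplement(s)
        s
    })
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(grl)
    out
}
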