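#' Read a GTF annotation into a TranscriptCatalog
#'
#' Reads an Ensembl/GENCODE-dialect GTF (exon and CDS features; other
#' feature types are ignored) and groups exons per transcript. Every exon
#' line must carry \code{gene_id} and \code{transcript_id} attributes.
#' Biotype is taken from \code{transcript_biotype} (or \code{gene_biotype})
#' when present.
#'
#' A fast pre-scan rejects malformed lines (fewer than 9 tab-separated
#' fields) with an error naming the offending line number; the heavy
#' parsing is delegated to \code{rtracklayer::import}.
#'
#' @param path path to a GTF file
#' @return a \code{\link{TranscriptCatalog}}
#' @export
readGTF <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- readLines(path)
    body <- !startsWith(raw, "#") & nzchar(raw)
    nf <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
    if (any(nf < 9L)) {
        bad <- which(body)[which(nf < 9L)[1]]
        stop("malformed GTF line ", bad, " in ", path,
             ": expected 9 tab-separated fields, found ", nf[which(nf < 9L)[1]])
    }
    gr <- rtracklayer::import(path, format = "gtf")
    keep <- gr$type %in% c("exon", "CDS")
    gr <- gr[keep]
    if (length(gr) == 0L)
        stop("no exon/CDS features in ", path)
    if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
        stop("exon/CDS feature without transcript_id in ", path)
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
        stop("exon/CDS feature without gene_id in ", path)
    ex <- gr[gr$type == "exon"]
    cd <- gr[gr$type == "CDS"]
    if (length(ex) == 0L) stop("no exon features in ", path)
    exl <- GenomicRanges::split(granges_bare(ex), ex$transcript_id)
    cdl <- if (length(cd)) GenomicRanges::split(granges_bare(cd), cd$transcript_id)
           else NULL
    gene <- vapply(split(ex$gene_id, ex$transcript_id), `[`, character(1), 1L)
    bt <- extract_biotype(ex)
    TranscriptCatalog(exl, geneId = gene[names(exl)], cds = cdl,
                      biotype = bt[names(exl)])
}

granges_bare <- function(gr) {
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                           IRanges::ranges(gr), strand = strand(gr))
}

extract_biotype <- function(ex) {
    bt <- rep(NA_character_, length(ex))
    for (col in c("transcript_biotype", "gene_biotype")) {
        if (!is.null(S4Vectors::mcols(ex)[[col]])) {
            v <- S4Vectors::mcols(ex)[[col]]
            bt[is.na(bt)] <- v[is.na(bt)]
        }
    }
    vapply(split(bt, ex$transcript_id), `[`, character(1), 1L)
}

#' Write a TranscriptCatalog as GTF
#'
#' Emits exon lines (and CDS lines for coding transcripts) with
#' \code{gene_id}, \code{transcript_id} and, when known,
#' \code{transcript_biotype} attributes. Output ordering is deterministic
#' (by transcript id, then start), so two writes of the same catalog are
#' byte-identical and \code{readGTF(writeGTF(x))} reproduces \code{x}.
#'
#' @param catalog a TranscriptCatalog
#' @param path output file path
#' @return invisibly, the path
#' @export
writeGTF <- function(catalog, path) {
    ids <- sort(transcriptIds(catalog))
    con <- file(path, "w")
    on.exit(close(con))
    for (id in ids) {
        ex <- exonRanges(catalog)[[id]]
        cd <- cdsRanges(catalog)[[id]]
        g <- unname(geneIds(catalog)[id])
        bt <- unname(biotypes(catalog)[id])
        attr_str <- sprintf('gene_id "%s"; transcript_id "%s";%s', g, id,
            if (is.na(bt)) "" else sprintf(' transcript_biotype "%s";', bt))
        emit <- function(gr, type) {
            if (length(gr) == 0L) return(invisible())
            lines <- sprintf("%s\tadtrx\t%s\t%d\t%d\t.\t%s\t.\t%s",
                as.character(GenomicRanges::seqnames(gr)), type,
                start(gr), end(gr), as.character(strand(gr)), attr_str)
            writeLines(lines, con)
        }
        emit(ex, "exon")
        emit(cd, "CDS")
    }
    invisible(path)
}

#' Read a FASTA file with validation
#'
#' Thin wrapper over \code{Biostrings} readers that upper-cases sequences
#' and rejects duplicate ids and empty records. The id of a record is the
#' first whitespace-delimited token of its header.
#'
#' @param path path to a FASTA file
#' @param type "DNA" or "AA"
#' @return a DNAStringSet or AAStringSet named by record id
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
    type <- match.arg(type)
    ss <- if (type == "DNA") Biostrings::readDNAStringSet(path)
          else Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(ids))
        stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
    if (any(width(ss) == 0L))
        stop("empty FASTA record: ", ids[width(ss) == 0L][1])
    names(ss) <- ids
    if (type == "DNA") Biostrings::DNAStringSet(toupper(as.character(ss)))
    else Biostrings::AAStringSet(toupper(as.character(ss)))
}

#' Read a transcripts-by-samples expression matrix
#'
#' Parses a TSV whose header row holds sample ids and whose first column
#' holds transcript ids, validates it (no negative values, unique labels,
#' every sample covered by \code{groups}) and returns a
#' \code{SummarizedExperiment} with the unit recorded in its metadata and
#' group labels in \code{colData}.
#'
#' @param path TSV path
#' @param unit "TPM" or "counts"
#' @param groups named character vector or list, sample id -> group label
#' @return a SummarizedExperiment with one assay named after \code{unit}
#' @export
readExpressionMatrix <- function(path, unit = c("TPM", "counts"), groups) {
    unit <- match.arg(unit)
    lines <- readLines(path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (length(unique(nf)) != 1L)
        stop("ragged TSV: line ", which(nf != nf[1])[1], " has ",
             nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
    header <- fields[[1]]
    samples <- header[-1]
    body <- fields[-1]
    ids <- vapply(body, `[`, character(1), 1L)
    vals <- matrix(NA_real_, length(body), length(samples),
                   dimnames = list(ids, samples))
    for (i in seq_along(body))
        vals[i, ] <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(vals)) stop("non-numeric value in matrix ", path)
    makeExpressionSE(vals, unit = unit, groups = groups)
}

#' Assemble an expression SummarizedExperiment from a matrix
#'
#' @param values numeric matrix, transcripts x samples, with dimnames
#' @param unit "TPM" or "counts"
#' @param groups named vector, sample id -> group label; must cover all
#'   samples
#' @return a SummarizedExperiment
#' @export
makeExpressionSE <- function(values, unit = c("TPM", "counts"), groups) {
    unit <- match.arg(unit)
    if (any(values < 0)) stop("negative expression value")
    if (anyDuplicated(rownames(values))) stop("duplicate transcript ids")
    if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
    groups <- unlist(groups)
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
        stop("sample(s) absent from groups map: ",
             paste(missing, collapse = ", "))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = stats::setNames(list(values), unit),
        colData = S4Vectors::DataFrame(
            group = unname(groups[colnames(values)]),
            row.names = colnames(values)))
    S4Vectors::metadata(se)$unit <- unit
    se
}

#' Write an expression SummarizedExperiment as TSV
#'
#' @param se SummarizedExperiment from \code{makeExpressionSE}
#' @param path output path
#' @return invisibly, the path
#' @export
writeExpressionMatrix <- function(se, path) {
    m <- SummarizedExperiment::assay(se, 1L)
    df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Delegates to \code{fgsea::gmtPathways} and validates that no set is
#' empty.
#'
#' @param path GMT file path
#' @return named list of character vectors
#' @export
readGeneSets <- function(path) {
    sets <- fgsea::gmtPathways(path)
    if (any(lengths(sets) == 0L))
        stop("empty gene set: ", names(sets)[lengths(sets) == 0L][1])
    sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors
#' @param path output path
#' @return invisibly, the path
#' @export
writeGeneSets <- function(sets, path) {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a junction inclusion/skipping count table
#'
#' Long-format TSV with columns event_id, sample_id, inclusion, skipping.
#'
#' @param path TSV path
#' @return data.frame with those four columns
#' @export
readJunctionCounts <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("event_id", "sample_id", "inclusion", "skipping")
    if (!all(need %in% names(df)))
        stop("junction table needs columns: ", paste(need, collapse = ", "))
    if (any(df$inclusion < 0 | df$skipping < 0))
        stop("negative junction count")
    df
}
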