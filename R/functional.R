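#' Smith-Waterman local alignment score of a peptide against a protein
#'
#' Local alignment under BLOSUM62 with affine gaps (opening 11,
#' extension 1; a gap of length L costs 11 + L). Deterministic; the score
#' is 0 when no positively scoring local alignment exists.
#'
#' @param peptide query peptide string (standard amino-acid letters)
#' @param protein subject protein string
#' @param gap_opening,gap_extension gap penalties (positive costs)
#' @return list: score, aligned_fraction (aligned query length over
#'   query length)
#' @export
localAlignScore <- function(peptide, protein, gap_opening = 11,
                            gap_extension = 1) {
    check_aa(peptide); check_aa(protein)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(peptide), Biostrings::AAString(protein),
        type = "local", substitutionMatrix = blosum62(),
        gapOpening = gap_opening, gapExtension = gap_extension)
    sc <- max(0, Biostrings::score(aln))
    af <- if (sc > 0)
        nchar(gsub("-", "", as.character(Biostrings::alignedPattern(aln)),
                   fixed = TRUE)) / nchar(peptide)
    else 0
    list(score = sc, aligned_fraction = af)
}

check_aa <- function(s) {
    if (is.null(s) || nchar(s) == 0L) stop("empty amino-acid sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYXBZU*]", toupper(s)))
        stop("invalid amino-acid residue in sequence")
    invisible(s)
}

blosum62 <- local({
    mat <- NULL
    function() {
        if (is.null(mat)) {
            e <- new.env()
            utils::data("BLOSUM62", package = "Biostrings", envir = e)
            mat <<- e$BLOSUM62
        }
        mat
    }
})

#' All-pairs local alignment scores above a threshold
#'
#' Scores every transcript peptide against every database protein and
#' keeps pairs scoring at least \code{min_score}.
#'
#' @param peptides named character vector (or AAStringSet) of query
#'   peptides, named by transcript id
#' @param proteins named character vector (or AAStringSet) of database
#'   proteins
#' @param min_score minimum reported score (default 40)
#' @param gap_opening,gap_extension gap penalties
#' @return data.frame: transcript_id, protein_id, score,
#'   aligned_fraction
#' @export
alignmentScoreTable <- function(peptides, proteins, min_score = 40,
                                gap_opening = 11, gap_extension = 1) {
    peptides <- as_named_chr(peptides)
    proteins <- as_named_chr(proteins)
    pep_set <- Biostrings::AAStringSet(peptides)
    rows <- list()
    for (pid in names(proteins)) {
        aln <- Biostrings::pairwiseAlignment(
            pep_set, Biostrings::AAString(proteins[[pid]]),
            type = "local", substitutionMatrix = blosum62(),
            gapOpening = gap_opening, gapExtension = gap_extension)
        sc <- Biostrings::score(aln)
        hit <- which(sc >= min_score)
        if (length(hit) == 0L) next
        alnP <- gsub("-", "",
                     as.character(Biostrings::alignedPattern(aln[hit])),
                     fixed = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = names(peptides)[hit], protein_id = pid,
            score = sc[hit],
            aligned_fraction = nchar(alnP) / nchar(peptides[hit]))
    }
    if (length(rows) == 0L)
        return(data.frame(transcript_id = character(),
                          protein_id = character(), score = numeric(),
                          aligned_fraction = numeric()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Injective transcript-to-protein functional assignment
#'
#' Global greedy matching: repeatedly assign the highest-scoring
#' remaining (transcript, protein) pair in which both sides are still
#' unassigned, so that no two transcripts ever receive the same protein
#' (function). Ties are broken lexicographically by (transcript_id,
#' protein_id); the result is independent of the input row order.
#'
#' @param scores data.frame from \code{\link{alignmentScoreTable}}
#' @param min_score minimum qualifying score (default 40)
#' @return list: assignments (named character, transcript -> protein),
#'   unassigned (transcript ids with no remaining candidate),
#'   scores_used (the rows realizing the assignments)
#' @export
uniqueAssign <- function(scores, min_score = 40) {
    s <- scores[scores$score >= min_score, , drop = FALSE]
    s <- s[order(-s$score, s$transcript_id, s$protein_id), , drop = FALSE]
    all_tx <- unique(scores$transcript_id)
    assigned <- character()
    used_protein <- character()
    used_rows <- integer()
    for (i in seq_len(nrow(s))) {
        tx <- s$transcript_id[i]; pr <- s$protein_id[i]
        if (tx %in% names(assigned) || pr %in% used_protein) next
        assigned[tx] <- pr
        used_protein <- c(used_protein, pr)
        used_rows <- c(used_rows, i)
    }
    list(assignments = assigned,
         unassigned = setdiff(all_tx, names(assigned)),
         scores_used = s[used_rows, , drop = FALSE])
}

#' Functionally annotate transcripts against a protein database
#'
#' Translates the longest ORF of each transcript, scores all peptides
#' against the database and applies the injective greedy assignment.
#' Transcripts with no ORF are reported unassigned.
#'
#' @param catalog TranscriptCatalog of transcripts to annotate
#' @param genome DNAStringSet of chromosome sequences
#' @param proteins named character vector / AAStringSet protein database
#' @param min_score minimum qualifying alignment score (default 40)
#' @return list as from \code{\link{uniqueAssign}}, plus the peptide set
#' @export
annotateTranscripts <- function(catalog, genome, proteins,
                                min_score = 40) {
    seqs <- transcriptSeqs(genome, catalog)
    peps <- vapply(as.character(seqs), function(s) {
        p <- translateLongestOrf(s)
        if (is.null(p)) NA_character_ else p
    }, character(1))
    names(peps) <- names(seqs)
    no_orf <- names(peps)[is.na(peps) | nchar(peps) == 0L]
    peps <- peps[!is.na(peps) & nchar(peps) > 0L]
    scores <- alignmentScoreTable(peps, proteins, min_score = min_score)
    res <- uniqueAssign(scores, min_score = min_score)
    res$unassigned <- union(res$unassigned, no_orf)
    res$peptides <- peps
    res
}
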