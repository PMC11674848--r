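#' Find the longest open reading frame on the sense strand
#'
#' Scans all three reading frames for ATG-initiated, stop-terminated ORFs
#' and returns the longest (stop codon included in the span). Ties are
#' broken in favour of the 5'-most start. Coordinates are 1-based
#' inclusive positions on the input sequence.
#'
#' @param seq a nucleotide string (ACGTN) or DNAString
#' @return list(start, end, frame) with frame in 0:2, or NULL when the
#'   sequence holds no ORF
#' @examples
#' findLongestOrf("ATGAAATGA")  # start 1, end 9
#' @export
findLongestOrf <- function(seq) {
    s <- toupper(as.character(seq))
    n <- nchar(s)
    if (n < 6L) return(NULL)
    best <- NULL
    stops <- c("TAA", "TAG", "TGA")
    codons_at <- function(off) {
        starts <- seq.int(1L + off, n - 2L, by = 3L)
        substring(s, starts, starts + 2L)
    }
    for (off in 0:2) {
        if (n - off < 6L) next
        cod <- codons_at(off)
        is_start <- cod == "ATG"
        is_stop <- cod %in% stops
        if (!any(is_start) || !any(is_stop)) next
        stop_idx <- which(is_stop)
        open_from <- NA_integer_
        for (i in seq_along(cod)) {
            if (is.na(open_from) && is_start[i]) open_from <- i
            if (!is.na(open_from) && is_stop[i]) {
                len <- (i - open_from + 1L) * 3L
                if (is.null(best) || len > best$len) {
                    st <- 1L + off + (open_from - 1L) * 3L
                    best <- list(start = st, end = st + len - 1L,
                                 frame = off, len = len)
                }
                open_from <- NA_integer_
            }
        }
    }
    if (is.null(best)) return(NULL)
    best[c("start", "end", "frame")]
}

#' Translate the longest ORF of a transcript sequence
#'
#' Standard genetic code; the terminal stop is dropped; codons containing
#' N translate to X.
#'
#' @param seq nucleotide string or DNAString
#' @return a single peptide string, or NULL when the sequence has no ORF
#' @export
translateLongestOrf <- function(seq) {
    orf <- findLongestOrf(seq)
    if (is.null(orf)) return(NULL)
    translate_orf(toupper(as.character(seq)), orf)
}

translate_orf <- function(s, orf) {
    cds <- substr(s, orf$start, orf$end - 3L)
    if (nchar(cds) == 0L) return("")
    starts <- seq.int(1L, nchar(cds) - 2L, by = 3L)
    aa <- Biostrings::GENETIC_CODE[substring(cds, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"   # codons containing N
    paste(aa, collapse = "")
}

pi_of_peptide <- function(pep) {
    pep <- gsub("X", "", pep, fixed = TRUE)
    if (nchar(pep) == 0L) return(NA_real_)
    seqinr::computePI(strsplit(pep, "", fixed = TRUE)[[1]])
}

# Fickett (1982) TESTCODE lookup tables: probability that a sequence with
# the given position-asymmetry or composition value is coding, per base,
# plus the per-base weights. Bin k of the position table covers values
# >= position_cut[k]; bin k of the content table covers fractions >=
# content_cut[k].
.fickett <- list(
    position_cut = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
    content_cut  = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0),
    position_prob = rbind(
        A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
        C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
        G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
        T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
    content_prob = rbind(
        A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
        C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
        G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
        T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
    position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
    content_weight  = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14))

#' Fickett TESTCODE statistic
#'
#' Position/composition coding-potential score from the classic lookup
#' tables: for each base, the asymmetry of its usage across the three
#' codon positions and its overall fraction are binned and converted to
#' coding probabilities, which are combined with fixed per-base weights.
#' Higher values indicate coding-like sequence.
#'
#' @param seq nucleotide string or DNAString, length >= 200
#' @param min_length minimum accepted sequence length
#' @return a single numeric score (published range roughly 0.2-1.1)
#' @export
fickettScore <- function(seq, min_length = 200L) {
    s <- toupper(as.character(seq))
    n <- nchar(s)
    if (n < min_length)
        stop("fickettScore needs length >= ", min_length, ", got ", n)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- (seq_len(n) - 1L) %% 3L
    score <- 0
    for (b in c("A", "C", "G", "T")) {
        cnt <- vapply(0:2, function(p) sum(chars == b & pos == p), numeric(1))
        posval <- max(cnt) / (min(cnt) + 1)
        content <- sum(cnt) / n
        pbin <- which(posval >= .fickett$position_cut)[1]
        cbin <- which(content >= .fickett$content_cut)[1]
        score <- score +
            .fickett$position_prob[b, pbin] * .fickett$position_weight[b] +
            .fickett$content_prob[b, cbin] * .fickett$content_weight[b]
    }
    unname(score)
}

#' Estimate in-frame hexamer frequency tables
#'
#' Builds add-one-smoothed hexamer frequency tables from training
#' sequences: coding sequences contribute their in-frame hexamers (frame
#' fixed at the annotated CDS start, position step 3), noncoding
#' sequences contribute hexamers at every position.
#'
#' @param coding_seqs character vector / DNAStringSet of CDS sequences
#' @param noncoding_seqs character vector / DNAStringSet of noncoding
#'   sequences
#' @return list(coding, noncoding): two named numeric vectors of 4096
#'   hexamer frequencies, each summing to 1
#' @export
trainHexamerTables <- function(coding_seqs, noncoding_seqs) {
    list(coding = hexamer_freqs(coding_seqs, step = 3L),
         noncoding = hexamer_freqs(noncoding_seqs, step = 1L))
}

all_hexamers <- function() {
    b <- c("A", "C", "G", "T")
    g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
    do.call(paste0, g)
}

hexamer_freqs <- function(seqs, step) {
    seqs <- toupper(as.character(seqs))
    counts <- stats::setNames(rep(1, 4096L), all_hexamers())  # add-one
    for (s in seqs) {
        n <- nchar(s)
        if (n < 6L) next
        starts <- seq.int(1L, n - 5L, by = step)
        hx <- substring(s, starts, starts + 5L)
        hx <- hx[!grepl("[^ACGT]", hx)]
        tab <- table(hx)
        counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
    counts / sum(counts)
}

#' Hexamer log-likelihood-ratio score
#'
#' Sum of log(f_coding(h) / f_noncoding(h)) over the in-frame hexamers of
#' the sequence's longest ORF. Positive values favour coding. A sequence
#' without an ORF receives a large negative sentinel (-Inf replacement,
#' \code{-1e6}) so that it always ranks as noncoding.
#'
#' @param seq nucleotide string or DNAString
#' @param tables hexamer tables from \code{\link{trainHexamerTables}}
#' @return a single numeric score
#' @export
hexamerScore <- function(seq, tables) {
    orf <- findLongestOrf(seq)
    if (is.null(orf)) return(-1e6)
    hexamer_llr(substr(toupper(as.character(seq)), orf$start, orf$end),
                tables)
}

hexamer_llr <- function(s, tables) {
    n <- nchar(s)
    if (n < 6L) return(-1e6)
    starts <- seq.int(1L, n - 5L, by = 3L)
    hx <- substring(s, starts, starts + 5L)
    hx <- hx[!grepl("[^ACGT]", hx)]
    if (length(hx) == 0L) return(-1e6)
    sum(log(tables$coding[hx] / tables$noncoding[hx]))
}

#' ORF coverage score
#'
#' Fraction of the transcript covered by its longest ORF; 0 when there is
#' no ORF.
#'
#' @param transcript_length spliced transcript length (nt)
#' @param orf_length ORF length (nt, stop included); must not exceed
#'   \code{transcript_length}
#' @return a value in [0, 1]
#' @export
orfCoverageScore <- function(transcript_length, orf_length) {
    if (is.null(orf_length) || length(orf_length) == 0L) orf_length <- 0L
    if (orf_length > transcript_length)
        stop("orf_length exceeds transcript_length")
    orf_length / transcript_length
}

#' Isoelectric point of the longest-ORF peptide
#'
#' Computes the theoretical isoelectric point (via
#' \code{seqinr::computePI}) of the peptide encoded by the longest ORF, a
#' crude compositional coding-potential feature. NA when the sequence has
#' no ORF or the peptide is empty/ambiguous-only.
#'
#' @param seq nucleotide string or DNAString
#' @return a single numeric pI, or NA
#' @export
isoelectricScore <- function(seq) {
    pep <- translateLongestOrf(seq)
    if (is.null(pep)) return(NA_real_)
    pi_of_peptide(pep)
}

#' Names of the five bundled coding-potential scorers
#' @return character vector of scorer names
#' @export
scorerNames <- function() {
    c("fickett", "hexamer", "orf_coverage", "orf_length", "isoelectric")
}

#' Score sequences with the five bundled coding-potential scorers
#'
#' @param seqs DNAStringSet or named character vector of transcript
#'   sequences
#' @param hexamer_tables tables from \code{\link{trainHexamerTables}}
#' @return data.frame with one row per sequence and one column per scorer
#'   (\code{\link{scorerNames}}); rownames are sequence ids
#' @export
codingPotentialScores <- function(seqs, hexamer_tables) {
    seqs <- as_named_chr(seqs)
    ids <- names(seqs)
    n <- length(seqs)
    out <- data.frame(row.names = ids,
        fickett = rep(NA_real_, n), hexamer = rep(NA_real_, n),
        orf_coverage = rep(NA_real_, n), orf_length = rep(NA_real_, n),
        isoelectric = rep(NA_real_, n))
    for (i in seq_along(seqs)) {
        s <- toupper(seqs[[i]])
        orf <- findLongestOrf(s)
        ol <- if (is.null(orf)) 0L else orf$end - orf$start + 1L
        out$fickett[i] <- fickettScore(s, min_length = min(200L, nchar(s)))
        out$hexamer[i] <- if (is.null(orf)) -1e6 else
            hexamer_llr(substr(s, orf$start, orf$end), hexamer_tables)
        out$orf_coverage[i] <- orfCoverageScore(nchar(s), ol)
        out$orf_length[i] <- ol
        out$isoelectric[i] <- if (is.null(orf)) NA_real_ else
            pi_of_peptide(translate_orf(s, orf))
    }
    out
}

#' Calibrate scorer thresholds on training sequences
#'
#' For each of the five scorers, the decision direction is the sign of
#' (mean coding score - mean noncoding score) and the threshold is the
#' \code{specificity} quantile of the noncoding training scores in that
#' direction. A transcript's verdict is "coding" when its score lies
#' strictly beyond the threshold on the coding side. The high default
#' specificity reflects the unanimous-vote consensus: a true lncRNA is
#' lost whenever any one of the five scorers mislabels it, so each scorer
#' must rarely call noncoding sequence coding.
#'
#' @param coding_seqs training coding transcript sequences
#' @param noncoding_seqs training noncoding sequences
#' @param hexamer_tables hexamer tables; by default trained on the same
#'   training sequences
#' @param specificity per-scorer quantile of the noncoding score
#'   distribution used as threshold (default 1, the training maximum)
#' @return list with elements \code{threshold} (named numeric),
#'   \code{direction} (named, +1 when high scores mean coding) and
#'   \code{hexamer_tables}
#' @export
calibrateScorerThresholds <- function(coding_seqs, noncoding_seqs,
                                      hexamer_tables = NULL,
                                      specificity = 1) {
    if (is.null(hexamer_tables))
        hexamer_tables <- trainHexamerTables(coding_seqs, noncoding_seqs)
    sc <- codingPotentialScores(coding_seqs, hexamer_tables)
    sn <- codingPotentialScores(noncoding_seqs, hexamer_tables)
    thr <- dir <- stats::setNames(numeric(length(scorerNames())), scorerNames())
    for (nm in scorerNames()) {
        a <- sc[[nm]][is.finite(sc[[nm]])]
        b <- sn[[nm]][is.finite(sn[[nm]])]
        dir[nm] <- if (mean(a) >= mean(b)) 1 else -1
        q <- if (dir[nm] > 0) specificity else 1 - specificity
        thr[nm] <- stats::quantile(b, q, names = FALSE, type = 7)
    }
    list(threshold = thr, direction = dir, hexamer_tables = hexamer_tables)
}

#' Conservative built-in scorer thresholds
#'
#' Fixed fallback thresholds for use without calibration: Fickett 0.95
#' (the classic "probably coding" cutoff), hexamer log-likelihood ratio 0,
#' ORF coverage 0.5, ORF length 300 nt, and isoelectric point 9.5 (only
#' strongly basic peptides vote coding). Calibration via
#' \code{\link{calibrateScorerThresholds}} is preferred whenever training
#' sequences are available.
#'
#' @return a thresholds object as from
#'   \code{\link{calibrateScorerThresholds}}, without hexamer tables
#' @export
defaultScorerThresholds <- function() {
    list(threshold = c(fickett = 0.95, hexamer = 0, orf_coverage = 0.5,
                       orf_length = 300, isoelectric = 9.5),
         direction = c(fickett = 1, hexamer = 1, orf_coverage = 1,
                       orf_length = 1, isoelectric = 1),
         hexamer_tables = NULL)
}

#' Turn scorer scores into coding/noncoding verdicts
#'
#' @param scores data.frame from \code{\link{codingPotentialScores}}
#' @param thresholds object from \code{\link{calibrateScorerThresholds}}
#'   or \code{\link{defaultScorerThresholds}}
#' @return data.frame of logicals (TRUE = coding vote), same shape as
#'   \code{scores}; NA scores vote noncoding
#' @export
codingVerdicts <- function(scores, thresholds) {
    out <- scores
    for (nm in scorerNames()) {
        v <- thresholds$direction[nm] *
            (scores[[nm]] - thresholds$threshold[nm]) > 0
        v[is.na(v)] <- FALSE
        out[[nm]] <- v
    }
    out
}

#' Unanimous five-vote lncRNA consensus
#'
#' A transcript is called a lncRNA only if all five coding-potential
#' scorers vote noncoding; a single coding vote vetoes the call.
#'
#' @param verdicts logical vector of exactly five votes (TRUE = coding),
#'   or a five-column logical data.frame/matrix (one row per transcript)
#' @return logical: TRUE = lncRNA (vector input), or a logical vector over
#'   rows (matrix input)
#' @export
consensusVote <- function(verdicts) {
    if (is.data.frame(verdicts) || is.matrix(verdicts)) {
        if (ncol(verdicts) != 5L)
            stop("consensusVote needs exactly five votes, got ", ncol(verdicts))
        return(rowSums(as.matrix(verdicts)) == 0L)
    }
    if (length(verdicts) != 5L)
        stop("consensusVote needs exactly five votes, got ", length(verdicts))
    !any(verdicts)
}
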