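#' Effective form lengths for PSI normalization
#'
#' Number of distinct junction/segment read classes supporting the
#' inclusion and skipping forms of each event type, used to normalize
#' junction counts in \code{\link{computePsi}}: SE and RI have two
#' inclusion junction classes versus one skipping junction; MXE has two
#' of each; A5SS and A3SS one of each.
#'
#' @param type event type, one of SE, A5SS, A3SS, MXE, RI
#' @return c(inclusion, skipping) integer lengths
#' @export
effectiveFormLengths <- function(type) {
    switch(type,
        SE   = c(inclusion = 2L, skipping = 1L),
        MXE  = c(inclusion = 2L, skipping = 2L),
        A5SS = c(inclusion = 1L, skipping = 1L),
        A3SS = c(inclusion = 1L, skipping = 1L),
        RI   = c(inclusion = 2L, skipping = 1L),
        stop("unknown event type: ", type))
}

# junctions of a sorted exon set: (donor = exon end, acceptor = next start)
junctions_of <- function(ex) {
    if (length(ex) < 2L) return(cbind(donor = integer(), acceptor = integer()))
    cbind(donor = end(ex)[-length(ex)], acceptor = start(ex)[-1])
}

has_junction <- function(J, d, a) any(J[, 1] == d & J[, 2] == a)

# events between one ordered transcript pair; t1/t2 are sorted exon GRanges
pair_events <- function(ex1, ex2, strand) {
    ev <- list()
    J1 <- junctions_of(ex1); J2 <- junctions_of(ex2)
    add <- function(type, inc, skp)
        ev[[length(ev) + 1L]] <<- list(type = type, inclusion = inc,
                                       skipping = skp)
    # SE: internal exon of t1 skipped by a t2 junction joining its flanks
    if (length(ex1) >= 3L) {
        for (k in 2:(length(ex1) - 1L)) {
            d <- end(ex1)[k - 1L]; a <- start(ex1)[k + 1L]
            if (has_junction(J2, d, a) &&
                !IRanges::overlapsAny(ex1[k], ex2, ignore.strand = TRUE))
                add("SE",
                    inc = c(d, start(ex1)[k], end(ex1)[k], a),
                    skp = c(d, a))
        }
    }
    # RI: an intron of t1 fully contained in a single exon of t2 that
    # extends through both splice sites
    if (nrow(J1)) {
        for (k in seq_len(nrow(J1))) {
            d <- J1[k, 1]; a <- J1[k, 2]
            if (any(start(ex2) <= d & end(ex2) >= a))
                add("RI", inc = c(d, a), skp = c(d, a))
        }
    }
    # A5SS / A3SS: junction pairs sharing one end; the alternative region
    # must be exonic in the transcript with the shorter intron
    if (nrow(J1) && nrow(J2)) {
        for (k in seq_len(nrow(J1))) for (m in seq_len(nrow(J2))) {
            d1 <- J1[k, 1]; a1 <- J1[k, 2]
            d2 <- J2[m, 1]; a2 <- J2[m, 2]
            if (a1 == a2 && d1 != d2) {
                # alt donor; the later donor's transcript carries the
                # extended exon
                lo <- min(d1, d2); hi <- max(d1, d2)
                long_ex <- if (d1 > d2) ex1 else ex2
                ok <- any(end(long_ex) == hi & start(long_ex) <= lo + 1L)
                if (ok) add(if (strand == "-") "A3SS" else "A5SS",
                            inc = c(hi, a1), skp = c(lo, a1))
            }
            if (d1 == d2 && a1 != a2) {
                lo <- min(a1, a2); hi <- max(a1, a2)
                long_ex <- if (a1 < a2) ex1 else ex2
                ok <- any(start(long_ex) == lo & end(long_ex) >= hi - 1L)
                if (ok) add(if (strand == "-") "A5SS" else "A3SS",
                            inc = c(d1, lo), skp = c(d1, hi))
            }
        }
    }
    # MXE: internal exons with shared outer flanks, mutually absent,
    # non-overlapping
    if (length(ex1) >= 3L && length(ex2) >= 3L) {
        for (k in 2:(length(ex1) - 1L)) for (m in 2:(length(ex2) - 1L)) {
            e1 <- ex1[k]; e2 <- ex2[m]
            if (IRanges::overlapsAny(e1, e2, ignore.strand = TRUE)) next
            d <- end(ex1)[k - 1L]; a <- start(ex1)[k + 1L]
            if (end(ex2)[m - 1L] != d || start(ex2)[m + 1L] != a) next
            if (IRanges::overlapsAny(e1, ex2, ignore.strand = TRUE)) next
            if (IRanges::overlapsAny(e2, ex1, ignore.strand = TRUE)) next
            first <- if (start(e1) <= start(e2)) e1 else e2
            second <- if (start(e1) <= start(e2)) e2 else e1
            add("MXE",
                inc = c(d, start(first), end(first), a),
                skp = c(d, start(second), end(second), a))
        }
    }
    ev
}

#' Detect alternative-splicing events from transcript models
#'
#' Compares transcripts pairwise within each gene and classifies every
#' structural difference into one of the five event types: SE (skipped
#' exon), A5SS / A3SS (alternative 5'/3' splice site, defined relative to
#' strand), MXE (mutually exclusive exons) and RI (retained intron).
#' Events found in several transcript pairs are deduplicated by
#' coordinates. The "inclusion" form is the variant carrying the skipped
#' exon (SE), the genomically first alternative exon (MXE), the longer
#' exon (A5SS/A3SS), or the retained intron (RI).
#'
#' @param catalog a TranscriptCatalog
#' @return data.frame: event_id, gene_id, type, seqnames, strand,
#'   coordinates (semicolon-joined inclusion/skipping form tuples) and
#'   the transcripts involved
#' @export
detectSpliceEvents <- function(catalog) {
    gmap <- geneTranscriptMap(catalog)
    ex <- exonRanges(catalog)
    rows <- list()
    seen <- character()
    for (g in names(gmap)) {
        txs <- gmap[[g]]
        if (length(txs) < 2L) next
        for (i in seq_along(txs)) for (j in seq_along(txs)) {
            if (i == j) next
            e1 <- ex[[txs[i]]]; e2 <- ex[[txs[j]]]
            str <- as.character(strand(e1))[1]
            evs <- pair_events(e1, e2, str)
            for (e in evs) {
                sig <- paste(g, e$type, paste(e$inclusion, collapse = "-"),
                             paste(e$skipping, collapse = "-"), sep = "|")
                if (sig %in% seen) next
                seen <- c(seen, sig)
                rows[[length(rows) + 1L]] <- data.frame(
                    event_id = sig, gene_id = g, type = e$type,
                    seqnames = as.character(GenomicRanges::seqnames(e1))[1],
                    strand = str,
                    inclusion_form = paste(e$inclusion, collapse = ";"),
                    skipping_form = paste(e$skipping, collapse = ";"),
                    transcripts = paste(sort(c(txs[i], txs[j])),
                                        collapse = ","))
            }
        }
    }
    if (length(rows) == 0L)
        return(data.frame(event_id = character(), gene_id = character(),
                          type = character(), seqnames = character(),
                          strand = character(), inclusion_form = character(),
                          skipping_form = character(),
                          transcripts = character()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Percent spliced in
#'
#' PSI = (I / l_I) / (I / l_I + S / l_S), the length-normalized fraction
#' of transcripts supporting the inclusion form. Undefined (NA) when both
#' normalized terms are zero. Vectorized over counts.
#'
#' @param inclusion inclusion-form read count(s), >= 0
#' @param skipping skipping-form read count(s), >= 0
#' @param inclusion_len effective inclusion form length (default 2, SE)
#' @param skipping_len effective skipping form length (default 1)
#' @return PSI in [0, 1], or NA where undefined
#' @export
computePsi <- function(inclusion, skipping, inclusion_len = 2L,
                       skipping_len = 1L) {
    if (any(inclusion < 0) || any(skipping < 0))
        stop("negative junction counts")
    if (any(inclusion_len < 1) || any(skipping_len < 1))
        stop("effective lengths must be >= 1")
    ni <- inclusion / inclusion_len
    ns <- skipping / skipping_len
    out <- ni / (ni + ns)
    out[ni + ns == 0] <- NA_real_
    out
}

#' Per-sample PSI records from a junction-count table
#'
#' @param junctions data.frame with columns event_id, sample_id,
#'   inclusion, skipping, and optionally inc_len / skip_len (defaults 2
#'   and 1)
#' @param groups optional named vector sample_id -> group; merged in when
#'   the table lacks a group column
#' @return the table with a psi column (and group when available)
#' @export
psiTable <- function(junctions, groups = NULL) {
    li <- if ("inc_len" %in% names(junctions)) junctions$inc_len else 2L
    ls <- if ("skip_len" %in% names(junctions)) junctions$skip_len else 1L
    junctions$psi <- computePsi(junctions$inclusion, junctions$skipping,
                                li, ls)
    if (!is.null(groups) && !"group" %in% names(junctions))
        junctions$group <- unname(unlist(groups)[junctions$sample_id])
    junctions
}

#' Test splicing events between two groups
#'
#' Per event, Delta-PSI = mean(PSI in group A) - mean(PSI in group B) and
#' a two-sided Wilcoxon rank-sum p-value on per-sample PSI. An event is
#' kept when p < \code{alpha} and |Delta-PSI| > \code{dpsi}; with
#' \code{direction = "remove"} the Delta-PSI gate is inverted (events
#' with |Delta-PSI| > \code{dpsi} are discarded instead). Events with
#' fewer than two defined PSI values in either group are skipped with a
#' warning.
#'
#' @param psi per-sample PSI table from \code{\link{psiTable}} (columns
#'   event_id, sample_id, psi, group)
#' @param group_a,group_b group labels to contrast
#' @param alpha p-value threshold (default 0.05)
#' @param dpsi Delta-PSI threshold (default 0.05, strict inequality)
#' @param direction "retain" (default) keeps |Delta-PSI| > dpsi;
#'   "remove" discards them
#' @return data.frame: event_id, delta_psi, p_value, kept
#' @export
testSpliceEvents <- function(psi, group_a, group_b, alpha = 0.05,
                             dpsi = 0.05,
                             direction = c("retain", "remove")) {
    direction <- match.arg(direction)
    rows <- list()
    for (ev in unique(psi$event_id)) {
        sub <- psi[psi$event_id == ev, ]
        pa <- sub$psi[sub$group == group_a]
        pb <- sub$psi[sub$group == group_b]
        pa <- pa[!is.na(pa)]; pb <- pb[!is.na(pb)]
        if (length(pa) < 2L || length(pb) < 2L) {
            warning("event ", ev, " skipped: fewer than two defined PSI ",
                    "values in a group")
            next
        }
        dp <- mean(pa) - mean(pb)
        p <- suppressWarnings(
            stats::wilcox.test(pa, pb, alternative = "two.sided")$p.value)
        gate <- if (direction == "retain") abs(dp) > dpsi else abs(dp) <= dpsi
        rows[[length(rows) + 1L]] <- data.frame(
            event_id = ev, delta_psi = dp, p_value = p,
            kept = (p < alpha) && gate)
    }
    if (length(rows) == 0L)
        return(data.frame(event_id = character(), delta_psi = numeric(),
                          p_value = numeric(), kept = logical()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Count kept events and affected genes per type
#'
#' @param events data.frame of kept events with columns gene_id and type
#' @return data.frame: type, n_events, n_genes, plus a "total" row
#'   (genes counted once per type; the total counts distinct genes)
#' @export
countGenesWithEvents <- function(events) {
    types <- c("SE", "A5SS", "A3SS", "MXE", "RI")
    out <- data.frame(type = types, n_events = 0L, n_genes = 0L)
    for (i in seq_along(types)) {
        sub <- events[events$type == types[i], , drop = FALSE]
        out$n_events[i] <- nrow(sub)
        out$n_genes[i] <- length(unique(sub$gene_id))
    }
    rbind(out, data.frame(type = "total", n_events = nrow(events),
                          n_genes = length(unique(events$gene_id))))
}
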