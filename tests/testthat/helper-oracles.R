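# Independent reference implementations used to cross-check the package.

oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
}

# exhaustive ORF scan: every ATG, first in-frame stop; longest wins,
# 5'-most on ties
oracle_orf <- function(s) {
    s <- toupper(s)
    n <- nchar(s)
    best <- NULL
    for (st in seq_len(max(0, n - 5))) {
        if (substr(s, st, st + 2) != "ATG") next
        j <- st + 3
        while (j + 2 <= n) {
            if (substr(s, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
                len <- j + 2 - st + 1
                if (is.null(best) || len > best$len)
                    best <- list(start = st, end = j + 2, len = len)
                break
            }
            j <- j + 3
        }
    }
    best
}

# per-base membership class-code oracle
oracle_class_code <- function(id, catalog, reference) {
    q_ex <- exonRanges(catalog)[[id]]
    q_lo <- min(start(q_ex)); q_hi <- max(end(q_ex))
    q_exbases <- unlist(lapply(seq_along(q_ex), function(i)
        start(q_ex)[i]:end(q_ex)[i]))
    ref_ex <- exonRanges(reference)
    ref_gene <- geneIds(reference)
    spans <- vapply(ref_ex, function(e) c(min(start(e)), max(end(e))),
                    numeric(2))
    hits <- names(ref_ex)[spans[1, ] <= q_hi & spans[2, ] >= q_lo]
    if (length(hits) == 0L) return("u")
    for (r in hits) {
        e <- ref_ex[[r]]
        if (length(e) < 2L) next
        for (k in seq_len(length(e) - 1L)) {
            int_lo <- end(e)[k] + 1L
            int_hi <- start(e)[k + 1L] - 1L
            if (int_lo <= q_lo && q_hi <= int_hi) return("i")
        }
    }
    for (g in unique(ref_gene[hits])) {
        gb <- unlist(lapply(names(ref_gene)[ref_gene == g], function(r) {
            e <- ref_ex[[r]]
            unlist(lapply(seq_along(e), function(i) start(e)[i]:end(e)[i]))
        }))
        if (all(q_exbases %in% gb)) return("x")
    }
    "o"
}

# brute-force splice-event enumeration over ordered transcript pairs,
# emitting canonical coordinate signatures
oracle_events <- function(catalog) {
    sigs <- character()
    ex <- exonRanges(catalog)
    gmap <- split(names(geneIds(catalog)), geneIds(catalog))
    for (g in names(gmap)) {
        txs <- gmap[[g]]
        if (length(txs) < 2L) next
        for (a in txs) for (b in txs) {
            if (a == b) next
            e1 <- ex[[a]]; e2 <- ex[[b]]
            st <- as.character(strand(e1))[1]
            s1 <- start(e1); n1 <- end(e1)
            s2 <- start(e2); n2 <- end(e2)
            ebases2 <- unlist(mapply(seq, s2, n2, SIMPLIFY = FALSE))
            ebases1 <- unlist(mapply(seq, s1, n1, SIMPLIFY = FALSE))
            J1 <- if (length(e1) > 1L)
                cbind(n1[-length(n1)], s1[-1]) else cbind(integer(), integer())
            J2 <- if (length(e2) > 1L)
                cbind(n2[-length(n2)], s2[-1]) else cbind(integer(), integer())
            has_j <- function(J, d, acc)
                any(J[, 1] == d & J[, 2] == acc)
            if (length(e1) >= 3L) for (k in 2:(length(e1) - 1L)) {
                if (has_j(J2, n1[k - 1], s1[k + 1]) &&
                    !any(seq(s1[k], n1[k]) %in% ebases2))
                    sigs <- c(sigs, paste(g, "SE", n1[k - 1], s1[k],
                                          n1[k], s1[k + 1]))
            }
            if (nrow(J1)) for (k in seq_len(nrow(J1))) {
                if (any(s2 <= J1[k, 1] & n2 >= J1[k, 2]))
                    sigs <- c(sigs, paste(g, "RI", J1[k, 1], J1[k, 2]))
            }
            if (nrow(J1) && nrow(J2))
                for (ka in seq_len(nrow(J1))) for (kb in seq_len(nrow(J2))) {
                    da <- J1[ka, 1]; aa <- J1[ka, 2]
                    db <- J2[kb, 1]; ab <- J2[kb, 2]
                    if (aa == ab && da != db) {
                        lo <- min(da, db); hi <- max(da, db)
                        lex <- if (da > db) cbind(s1, n1) else cbind(s2, n2)
                        if (any(lex[, 2] == hi & lex[, 1] <= lo + 1L)) {
                            ty <- if (st == "-") "A3SS" else "A5SS"
                            sigs <- c(sigs, paste(g, ty, lo, hi, aa))
                        }
                    }
                    if (da == db && aa != ab) {
                        lo <- min(aa, ab); hi <- max(aa, ab)
                        lex <- if (aa < ab) cbind(s1, n1) else cbind(s2, n2)
                        if (any(lex[, 1] == lo & lex[, 2] >= hi - 1L)) {
                            ty <- if (st == "-") "A5SS" else "A3SS"
                            sigs <- c(sigs, paste(g, ty, da, lo, hi))
                        }
                    }
                }
            if (length(e1) >= 3L && length(e2) >= 3L)
                for (k in 2:(length(e1) - 1L))
                    for (mm in 2:(length(e2) - 1L)) {
                        if (n1[k - 1] != n2[mm - 1] ||
                            s1[k + 1] != s2[mm + 1]) next
                        if (any(seq(s1[k], n1[k]) %in% ebases2)) next
                        if (any(seq(s2[mm], n2[mm]) %in% ebases1)) next
                        four <- sort(c(s1[k], n1[k], s2[mm], n2[mm]))
                        sigs <- c(sigs, paste(g, "MXE", n1[k - 1],
                                              paste(four, collapse = " "),
                                              s1[k + 1]))
                    }
        }
    }
    sort(unique(sigs))
}

# convert detectSpliceEvents() output into the oracle's signature space
event_signatures <- function(ev) {
    if (nrow(ev) == 0L) return(character())
    sigs <- character(nrow(ev))
    for (i in seq_len(nrow(ev))) {
        inc <- as.integer(strsplit(ev$inclusion_form[i], ";")[[1]])
        skp <- as.integer(strsplit(ev$skipping_form[i], ";")[[1]])
        g <- ev$gene_id[i]; ty <- ev$type[i]
        sigs[i] <- switch(ty,
            SE = paste(g, "SE", inc[1], inc[2], inc[3], inc[4]),
            RI = paste(g, "RI", inc[1], inc[2]),
            MXE = paste(g, "MXE", inc[1],
                        paste(sort(c(inc[2], inc[3], skp[2], skp[3])),
                              collapse = " "), inc[4]),
            {
                # A5SS / A3SS: donor-side events share the acceptor
                if (inc[2] == skp[2])
                    paste(g, ty, min(inc[1], skp[1]),
                          max(inc[1], skp[1]), inc[2])
                else
                    paste(g, ty, inc[1], min(inc[2], skp[2]),
                          max(inc[2], skp[2]))
            })
    }
    sort(unique(sigs))
}

# random multi-isoform gene for the event-detection property
random_event_gene <- function(seed) {
    set.seed(seed)
    n_ex <- sample(3:5, 1)
    w <- sample(20:60, n_ex, replace = TRUE)
    gaps <- sample(30:80, n_ex - 1, replace = TRUE)
    starts <- 100 + cumsum(c(0, w[-n_ex] + gaps))
    base <- cbind(starts, starts + w - 1)
    strand <- sample(c("+", "-"), 1)
    n_tx <- sample(2:4, 1)
    spec <- list()
    for (t in seq_len(n_tx)) {
        keep <- sort(unique(c(1, n_ex,
                              which(stats::runif(n_ex) > 0.3))))
        m <- base[keep, , drop = FALSE]
        # random boundary jitter inside gaps
        for (r in seq_len(nrow(m))) {
            if (stats::runif(1) < 0.3)
                m[r, 1] <- max(1, m[r, 1] - sample(0:20, 1))
            if (stats::runif(1) < 0.3)
                m[r, 2] <- m[r, 2] + sample(0:20, 1)
        }
        # drop transcripts whose jitter merged exons
        if (any(m[-1, 1] <= m[-nrow(m), 2])) next
        spec[[sprintf("t%d", t)]] <- list(
            gene = "g1", strand = strand,
            exons = lapply(seq_len(nrow(m)), function(r) m[r, ]))
    }
    if (length(spec) < 2L) return(NULL)
    make_catalog(spec)
}

# affine-gap Smith-Waterman with gap cost open + L * ext
oracle_sw <- function(a, b, mat, open = 11, ext = 1) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    H <- matrix(0, n + 1, m + 1)
    E <- matrix(-Inf, n + 1, m + 1)
    F <- matrix(-Inf, n + 1, m + 1)
    best <- 0
    for (i in seq_len(n)) for (j in seq_len(m)) {
        E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
        F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
        H[i + 1, j + 1] <- max(0, H[i, j] + mat[av[i], bv[j]],
                               E[i + 1, j + 1], F[i + 1, j + 1])
        best <- max(best, H[i + 1, j + 1])
    }
    best
}

# all-window brute-force duplex scan
oracle_duplex <- function(q, t, table) {
    rc <- revcomp(t)
    qv <- strsplit(toupper(q), "")[[1]]
    rv <- strsplit(toupper(rc), "")[[1]]
    nq <- length(qv); nr <- length(rv)
    ok <- function(x) x %in% c("A", "C", "G", "T")
    best <- 0
    for (i in seq_len(nq)) for (j in seq_len(nr)) {
        if (i > 1 && j > 1 && qv[i - 1] == rv[j - 1] && ok(qv[i - 1]))
            next  # not a run start
        L <- 0
        while (i + L <= nq && j + L <= nr && qv[i + L] == rv[j + L] &&
               ok(qv[i + L])) L <- L + 1
        if (L >= 2) {
            e <- sum(table[paste0(qv[i + 0:(L - 2)], qv[i + 1:(L - 1)])])
            best <- min(best, e)
        }
    }
    best
}

# direct-summation single-sample enrichment oracle
oracle_ssgsea <- function(expr, set, alpha = 0.25) {
    df <- data.frame(id = names(expr), v = as.numeric(expr),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$v, df$id), ]
    N <- nrow(df)
    rk <- N:1
    inset <- df$id %in% set
    w <- ifelse(inset, rk^alpha, 0)
    tot_in <- sum(w); tot_out <- sum(!inset)
    s <- 0; cin <- 0; cout <- 0
    for (j in seq_len(N)) {
        cin <- cin + w[j]
        cout <- cout + as.numeric(!inset[j])
        s <- s + cin / tot_in - cout / tot_out
    }
    s
}

# normal-equations OLS oracle
oracle_ols <- function(y, X) {
    Xc <- cbind(1, scale(X, center = TRUE, scale = FALSE))
    yc <- y - mean(y)
    beta <- solve(t(Xc) %*% Xc, t(Xc) %*% yc)
    fitted <- Xc %*% beta
    rss <- sum((yc - fitted)^2)
    tss <- sum(yc^2)
    list(beta = as.numeric(beta), r2 = 1 - rss / tss)
}
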