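#' Configuration for the synthetic study generator
#'
#' Defines the study conditions of the simulated cohort: a toy genome of
#' multi-exon protein-coding genes with planted lncRNAs of every genomic
#' class, negative-binomial expression with planted group effects and
#' latent-factor regulator co-expression, planted splice events with
#' group-differential PSI, and a mutated protein database with decoys.
#'
#' @param seed RNG seed (all stages are deterministic given the config)
#' @param n_genes number of protein-coding genes (default 60)
#' @param n_lncrna number of planted lncRNAs (default 30); classes u, i,
#'   o, x are cycled in that order
#' @param n_samples_per_group samples per group for the three groups
#'   normal, MCI, AD (default 30)
#' @param nb_dispersion negative-binomial dispersion (default 0.05)
#' @param planted_fc fold change planted on differential transcripts
#'   (default 2.0)
#' @param frac_det fraction of transcripts planted as differential
#'   (default 0.1)
#' @param n_pathways number of pathway gene sets (default 8); the first
#'   \code{n_pathways * pathway_size} genes are assigned round-robin,
#'   remaining genes belong to no pathway
#' @param pathway_size genes per pathway (default 5)
#' @param regulator_strength latent-factor loading on regulator lncRNAs
#'   and their pathway genes, on the log scale (default 0.8)
#' @param n_trans_pairs planted trans regulator pairs (default 4)
#' @param n_cis_pairs planted cis regulator pairs (default 4)
#' @param psi_shift PSI shift of planted splice events in MCI/AD versus
#'   normal (default 0.3)
#' @param n_events number of genes given a second, event-generating
#'   transcript (default 20; types cycled SE, RI, A5SS, A3SS, MXE)
#' @param n_novel_coding novel coding isoforms (intact CDS, shifted TSS)
#'   absent from the reference, challenging lncRNA-call precision
#'   (default 10)
#' @param n_decoys shuffled decoy proteins in the database (default 20)
#' @param junction_depth mean junction read depth per event and sample
#'   (default 50)
#' @param substitution_rate amino-acid substitution rate of database
#'   proteins relative to their source CDS (default 0.05)
#' @return validated config list (class "sim_config")
#' @export
simConfig <- function(seed = 1L, n_genes = 60L, n_lncrna = 30L,
                      n_samples_per_group = 30L, nb_dispersion = 0.05,
                      planted_fc = 2.0, frac_det = 0.1, n_pathways = 8L,
                      pathway_size = 5L,
                      regulator_strength = 0.8, n_trans_pairs = 4L,
                      n_cis_pairs = 4L, psi_shift = 0.3, n_events = 20L,
                      n_novel_coding = 10L, n_decoys = 20L,
                      junction_depth = 50L, substitution_rate = 0.05) {
    cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                n_lncrna = as.integer(n_lncrna),
                n_samples_per_group = as.integer(n_samples_per_group),
                nb_dispersion = nb_dispersion, planted_fc = planted_fc,
                frac_det = frac_det, n_pathways = as.integer(n_pathways),
                pathway_size = as.integer(pathway_size),
                regulator_strength = regulator_strength,
                n_trans_pairs = as.integer(n_trans_pairs),
                n_cis_pairs = as.integer(n_cis_pairs),
                psi_shift = psi_shift, n_events = as.integer(n_events),
                n_novel_coding = as.integer(n_novel_coding),
                n_decoys = as.integer(n_decoys),
                junction_depth = as.integer(junction_depth),
                substitution_rate = substitution_rate)
    stopifnot(cfg$n_genes > 0, cfg$n_lncrna >= 0,
              cfg$n_samples_per_group >= 2, cfg$nb_dispersion > 0,
              cfg$planted_fc > 0, cfg$frac_det > 0, cfg$frac_det < 1,
              cfg$n_pathways > 0, cfg$psi_shift >= 0, cfg$psi_shift < 1,
              cfg$substitution_rate >= 0, cfg$substitution_rate <= 1)
    classes <- lnc_classes(cfg$n_lncrna)
    n_u <- sum(classes == "u")
    if (cfg$n_cis_pairs + cfg$n_trans_pairs > n_u)
        stop("sizing error: need at least ",
             cfg$n_cis_pairs + cfg$n_trans_pairs,
             " intergenic lncRNAs for the regulator pairs, have ", n_u)
    n_hosts <- sum(classes == "i") + sum(classes == "o") +
        sum(classes == "x")
    if (cfg$n_events + n_hosts > cfg$n_genes)
        stop("sizing error: ", cfg$n_genes, " genes cannot host ",
             cfg$n_events, " event variants plus ", n_hosts,
             " lncRNA placements; increase n_genes")
    if (cfg$n_pathways * cfg$pathway_size > cfg$n_genes)
        stop("sizing error: ", cfg$n_pathways, " pathways of ",
             cfg$pathway_size, " genes exceed n_genes")
    if (cfg$n_trans_pairs > cfg$n_pathways)
        stop("sizing error: more trans pairs than pathways")
    class(cfg) <- "sim_config"
    cfg
}

lnc_classes <- function(n) c("u", "i", "o", "x")[(seq_len(n) - 1L) %% 4L + 1L]

.bases <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(.bases, n, replace = TRUE),
                              collapse = "")

# Human-like codon usage (relative frequencies per codon, stop codons
# separate) used to give coding sequence its hexamer bias.
.codon_usage <- c(
    TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9, CTT = 13.2, CTC = 19.6,
    CTA = 7.2, CTG = 39.6, ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
    GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1, TCT = 15.2, TCC = 17.7,
    TCA = 12.2, TCG = 4.4, CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
    ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1, GCT = 18.4, GCC = 27.7,
    GCA = 15.8, GCG = 7.4, TAT = 12.2, TAC = 15.3, CAT = 10.9, CAC = 15.1,
    CAA = 12.3, CAG = 34.2, AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
    GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6, TGT = 10.6, TGC = 12.6,
    TGG = 13.2, CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4, AGT = 12.1,
    AGC = 19.5, AGA = 12.2, AGG = 12.0, GGT = 10.8, GGC = 22.2, GGA = 16.5,
    GGG = 16.5)

.stop_codons <- c(TAA = 0.8, TAG = 0.6, TGA = 1.3)

biased_cds <- function(cds_len) {
    n_codons <- cds_len / 3L
    body <- sample(names(.codon_usage), n_codons - 2L, replace = TRUE,
                   prob = .codon_usage)
    stopc <- sample(names(.stop_codons), 1L, prob = .stop_codons)
    paste(c("ATG", body, stopc), collapse = "")
}

revcomp_chr <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# map a spliced-coordinate interval [sp_start, sp_end] (1-based on the
# 5'->3' transcript) to genomic pieces
spliced_to_genomic <- function(ex, str, sp_start, sp_end) {
    w <- width(ex)
    ord <- if (str == "-") rev(seq_along(w)) else seq_along(w)
    offs <- cumsum(c(0L, w[ord]))
    pieces <- NULL
    for (idx in seq_along(ord)) {
        e <- ord[idx]
        t1 <- offs[idx] + 1L; t2 <- offs[idx] + w[e]
        lo <- max(t1, sp_start); hi <- min(t2, sp_end)
        if (lo > hi) next
        piece <- if (str == "+")
            c(start(ex)[e] + (lo - t1), start(ex)[e] + (hi - t1))
        else
            c(end(ex)[e] - (hi - t1), end(ex)[e] - (lo - t1))
        pieces <- rbind(pieces, piece)
    }
    gr <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(ex))[1],
        IRanges::IRanges(pieces[, 1], pieces[, 2]), str)
    sort(gr)
}

# write a spliced transcript sequence into the genome letter vector at
# the exon positions (plus-strand genome representation)
write_spliced <- function(letters, ex, str, spliced) {
    plus <- if (str == "-") revcomp_chr(spliced) else spliced
    chars <- strsplit(plus, "", fixed = TRUE)[[1]]
    off <- 0L
    for (e in seq_along(ex)) {
        w <- width(ex)[e]
        letters[start(ex)[e]:end(ex)[e]] <- chars[(off + 1L):(off + w)]
        off <- off + w
    }
    letters
}

#' Simulate the annotated toy genome
#'
#' Generates a single-chromosome genome of multi-exon coding genes (CDS
#' with human-like codon bias, flanked by untranslated regions), a
#' reference catalog (primary transcripts plus the known splice-event
#' variants), and an assembled catalog adding novel coding isoforms and
#' the planted lncRNAs: intergenic (u), intronic (i), partially
#' overlapping (o) and exon-contained (x), the latter two on the
#' antisense strand. A subset of intergenic lncRNAs carries an exact
#' 20-nt reverse-complement window of a distant target transcript
#' (trans pairs) or sits within the cis window of its target (cis
#' pairs). Deterministic given the config.
#'
#' @param config a \code{\link{simConfig}}
#' @return list: genome (DNAStringSet), reference and assembled
#'   (TranscriptCatalog), truth (ground-truth list)
#' @export
simulateAnnotation <- function(config) {
    with_local_seed(config$seed, simulate_annotation_impl(config))
}

simulate_annotation_impl <- function(cfg) {
    ng <- cfg$n_genes
    classes <- lnc_classes(cfg$n_lncrna)
    ev_types <- c("SE", "RI", "A5SS", "A3SS", "MXE")[
        (seq_len(cfg$n_events) - 1L) %% 5L + 1L]
    idx_i <- which(classes == "i"); idx_o <- which(classes == "o")
    idx_x <- which(classes == "x"); idx_u <- which(classes == "u")
    host_i <- cfg$n_events + seq_along(idx_i)
    host_o <- cfg$n_events + length(idx_i) + seq_along(idx_o)
    host_x <- cfg$n_events + length(idx_i) + length(idx_o) + seq_along(idx_x)
    cis_lnc <- idx_u[seq_len(cfg$n_cis_pairs)]
    trans_lnc <- idx_u[cfg$n_cis_pairs + seq_len(cfg$n_trans_pairs)]
    # pathway membership: first n_pathways * pathway_size genes,
    # round-robin; trans pairs target pathways 1..n_trans (via the first
    # genes), cis pairs the following pathways via their last member so
    # every pair sits on its own pathway at the defaults
    np <- cfg$n_pathways
    n_inpath <- np * cfg$pathway_size
    pathway_of_gene <- rep(NA_integer_, ng)
    pathway_of_gene[seq_len(n_inpath)] <- (seq_len(n_inpath) - 1L) %% np + 1L
    trans_target_gene <- seq_len(cfg$n_trans_pairs)
    cis_p <- ((cfg$n_trans_pairs + seq_len(cfg$n_cis_pairs) - 1L) %% np) + 1L
    cis_target_gene <- vapply(cis_p, function(p)
        max(which(pathway_of_gene == p)), integer(1))
    trans_home_gene <- ng - seq_len(cfg$n_trans_pairs) + 1L
    other_u <- setdiff(idx_u, c(cis_lnc, trans_lnc))
    # spacers hosting intergenic lncRNAs must be unique
    other_home <- setdiff(seq_len(ng),
                          c(cis_target_gene, trans_home_gene))[
                              seq_along(other_u)]

    # --- gene structures -------------------------------------------------
    genes <- vector("list", ng)
    cursor <- 1L
    for (g in seq_len(ng)) {
        cursor <- cursor + sample(2500:4000, 1L)
        wex <- 3L * sample(50:120, 4L, replace = TRUE)
        win <- sample(700:1500, 3L, replace = TRUE)
        if (g %in% host_i) win[2] <- 2200L
        if (g %in% host_x) wex[4] <- 600L
        if (g <= cfg$n_events && ev_types[g] == "MXE") win[2] <- 1500L
        seg <- cumsum(c(0L, head_add(wex, win)))
        starts <- cursor + seg[seq(1L, length(seg), by = 2L)]
        ex <- IRanges::IRanges(starts, width = wex)
        str <- if (g %% 2L == 0L) "-" else "+"
        L <- sum(wex)
        u5 <- sample(40:90, 1L)
        u3 <- if (g %in% host_x) 480L else sample(80:160, 1L)
        cds_len <- ((L - u5 - u3) %/% 3L) * 3L
        spliced <- paste0(rand_seq(u5), biased_cds(cds_len),
                          rand_seq(L - u5 - cds_len))
        genes[[g]] <- list(exons = ex, strand = str, u5 = u5,
                           cds_len = cds_len, spliced = spliced,
                           id = sprintf("g%03d", g),
                           tx = sprintf("tx_g%03d", g))
        cursor <- max(end(ex))
    }
    genome_len <- cursor + 5000L
    letters <- sample(.bases, genome_len, replace = TRUE)

    gr_of <- function(ir, str) GenomicRanges::GRanges("chr1", ir, str)

    exl <- list(); cdl <- list(); gene_id <- character(); bt <- character()
    for (g in seq_len(ng)) {
        gn <- genes[[g]]
        ex <- gr_of(gn$exons, gn$strand)
        letters <- write_spliced(letters, ex, gn$strand, gn$spliced)
        exl[[gn$tx]] <- ex
        cdl[[gn$tx]] <- spliced_to_genomic(ex, gn$strand, gn$u5 + 1L,
                                           gn$u5 + gn$cds_len)
        gene_id[gn$tx] <- gn$id
        bt[gn$tx] <- "protein_coding"
    }

    # --- splice-event variants (part of the reference) -------------------
    truth_events <- NULL
    for (g in seq_len(cfg$n_events)) {
        gn <- genes[[g]]
        e <- gn$exons
        type <- ev_types[g]
        vex <- switch(type,
            SE = e[c(1L, 3L, 4L)],
            RI = IRanges::IRanges(
                c(start(e)[1], start(e)[2], start(e)[4]),
                c(end(e)[1], end(e)[3], end(e)[4])),
            A5SS = {
                v <- e; end(v)[2] <- end(v)[2] + 90L; v
            },
            A3SS = {
                v <- e; start(v)[3] <- start(v)[3] - 90L; v
            },
            MXE = {
                alt <- IRanges::IRanges(end(e)[2] + 400L, width = 150L)
                c(e[1L], alt, e[3:4])
            })
        # genomic-end extension flips the 5'/3' designation on "-" strand
        planted_type <- type
        if (gn$strand == "-" && type %in% c("A5SS", "A3SS"))
            planted_type <- setdiff(c("A5SS", "A3SS"), type)
        vid <- sprintf("tx_g%03d_var", g)
        exl[[vid]] <- gr_of(vex, gn$strand)
        gene_id[vid] <- gn$id
        bt[vid] <- "protein_coding"
        truth_events <- rbind(truth_events, data.frame(
            event_id = sprintf("ev_%s_%s", gn$id, planted_type),
            gene_id = gn$id, type = planted_type,
            delta_psi = cfg$psi_shift))
    }

    reference <- TranscriptCatalog(exl, geneId = gene_id, cds = cdl,
                                   biotype = bt)

    # --- novel coding isoforms (assembled only) --------------------------
    novel_coding <- character()
    for (k in seq_len(cfg$n_novel_coding)) {
        g <- ((k - 1L) %% ng) + 1L
        gn <- genes[[g]]
        vex <- gn$exons
        if (gn$strand == "+") start(vex)[1] <- start(vex)[1] - 60L
        else end(vex)[4] <- end(vex)[4] + 60L
        vid <- sprintf("novel_tx_g%03d", g)
        exl[[vid]] <- gr_of(vex, gn$strand)
        gene_id[vid] <- gn$id
        bt[vid] <- NA_character_
        novel_coding <- c(novel_coding, vid)
    }

    # --- planted lncRNAs -------------------------------------------------
    flip <- c("+" = "-", "-" = "+")
    lnc_ids <- sprintf("lnc_%03d", seq_len(cfg$n_lncrna))
    categories <- character(cfg$n_lncrna)
    cis_ptr <- trans_ptr <- other_ptr <- 0L
    for (k in seq_len(cfg$n_lncrna)) {
        cl <- classes[k]
        if (cl == "u") {
            home <- if (k %in% cis_lnc) {
                cis_ptr <- cis_ptr + 1L; cis_target_gene[cis_ptr]
            } else if (k %in% trans_lnc) {
                trans_ptr <- trans_ptr + 1L; trans_home_gene[trans_ptr]
            } else {
                other_ptr <- other_ptr + 1L; other_home[other_ptr]
            }
            base <- max(end(genes[[home]]$exons)) + 400L
            w <- sample(150:300, 2L, replace = TRUE)
            gap <- sample(200:400, 1L)
            ex <- IRanges::IRanges(c(base, base + w[1] + gap), width = w)
            str <- "+"
            categories[k] <- "intergenic"
        } else if (cl == "i") {
            host <- genes[[host_i[match(k, idx_i)]]]
            intron2_start <- end(host$exons)[2] + 1L
            base <- intron2_start + 300L
            w <- sample(150:250, 2L, replace = TRUE)
            gap <- sample(100:200, 1L)
            ex <- IRanges::IRanges(c(base, base + w[1] + gap), width = w)
            str <- host$strand
            categories[k] <- "intronic"
        } else if (cl == "o") {
            host <- genes[[host_o[match(k, idx_o)]]]
            gend <- max(end(host$exons))
            ex <- IRanges::IRanges(c(gend - 150L, gend + 250L),
                                   width = c(201L, 201L))
            str <- flip[host$strand]
            categories[k] <- "antisense"
        } else {  # x: inside the 3'UTR-rich wide terminal exon
            host <- genes[[host_x[match(k, idx_x)]]]
            e4 <- host$exons[4]
            base <- if (host$strand == "+") end(e4) - 440L
                    else start(e4) + 20L
            ex <- IRanges::IRanges(c(base, base + 230L), width = 150L)
            str <- flip[host$strand]
            categories[k] <- "antisense"
        }
        exl[[lnc_ids[k]]] <- gr_of(ex, unname(str))
        gene_id[lnc_ids[k]] <- sprintf("gene_%s", lnc_ids[k])
        bt[lnc_ids[k]] <- NA_character_
    }
    names(categories) <- lnc_ids

    # --- trans complementarity windows -----------------------------------
    trans_windows <- NULL
    for (j in seq_len(cfg$n_trans_pairs)) {
        ln <- lnc_ids[trans_lnc[j]]
        tgt <- genes[[trans_target_gene[j]]]
        win <- substr(tgt$spliced, tgt$u5 + 100L, tgt$u5 + 119L)
        ex2 <- exl[[ln]][2]
        pos <- start(ex2) + 10L
        planted <- revcomp_chr(win)
        letters[pos:(pos + 19L)] <- strsplit(planted, "", fixed = TRUE)[[1]]
        trans_windows <- rbind(trans_windows, data.frame(
            lncrna_id = ln, target_id = tgt$tx, window_seq = win))
    }

    assembled <- TranscriptCatalog(exl, geneId = gene_id, cds = cdl,
                                   biotype = bt)
    genome <- Biostrings::DNAStringSet(paste(letters, collapse = ""))
    names(genome) <- "chr1"

    # --- pathways and regulator pairs ------------------------------------
    coding_tx <- vapply(genes, `[[`, character(1), "tx")
    pathways <- lapply(seq_len(np), function(p)
        unname(coding_tx[which(pathway_of_gene == p)]))
    names(pathways) <- sprintf("pathway_%02d", seq_len(np))
    reg <- NULL
    for (j in seq_len(cfg$n_cis_pairs))
        reg <- rbind(reg, data.frame(
            lncrna_id = lnc_ids[cis_lnc[j]],
            set_name = names(pathways)[pathway_of_gene[cis_target_gene[j]]],
            mode = "cis", target_id = coding_tx[cis_target_gene[j]]))
    for (j in seq_len(cfg$n_trans_pairs))
        reg <- rbind(reg, data.frame(
            lncrna_id = lnc_ids[trans_lnc[j]],
            set_name = names(pathways)[pathway_of_gene[trans_target_gene[j]]],
            mode = "trans", target_id = coding_tx[trans_target_gene[j]]))

    truth <- list(
        true_lncrna_ids = lnc_ids,
        true_class_codes = stats::setNames(classes, lnc_ids),
        true_categories = categories,
        coding_ids = unname(coding_tx),
        novel_coding_ids = novel_coding,
        pathways = pathways,
        regulator_pairs = reg,
        trans_windows = trans_windows,
        events = truth_events)
    list(genome = genome, reference = reference, assembled = assembled,
         truth = truth)
}

# interleave exon widths and intron widths into segment offsets
head_add <- function(wex, win) {
    n <- length(win)
    out <- numeric(2L * n)
    out[seq(1L, 2L * n, 2L)] <- wex[seq_len(n)]
    out[seq(2L, 2L * n, 2L)] <- win
    out
}

#' Simulate the expression matrices
#'
#' Negative-binomial counts for every primary coding transcript and
#' lncRNA: log-normal baseline means across transcripts; a planted
#' fraction of transcripts has its mean multiplied (or divided) by the
#' planted fold change in AD, half of them additionally in MCI; each
#' regulator pair contributes a per-sample latent factor loading on the
#' lncRNA and all its pathway's transcripts. TPM is computed from counts
#' and spliced lengths, columns summing to 1e6.
#'
#' @param sim result of \code{\link{simulateAnnotation}}
#' @param config the same \code{\link{simConfig}}
#' @return list: counts and tpm (SummarizedExperiment), truth (the input
#'   truth augmented with true_det_ids per contrast)
#' @export
simulateExpression <- function(sim, config) {
    with_local_seed(config$seed + 1L, simulate_expression_impl(sim, config))
}

simulate_expression_impl <- function(sim, cfg) {
    truth <- sim$truth
    ids <- c(truth$coding_ids, truth$true_lncrna_ids)
    nspg <- cfg$n_samples_per_group
    groups <- rep(c("normal", "MCI", "AD"), each = nspg)
    samples <- sprintf("%s_%02d", groups, rep(seq_len(nspg), times = 3L))
    names(groups) <- samples
    n <- length(ids); m <- length(samples)

    base <- exp(stats::rnorm(n, mean = log(200), sd = 1))
    logmu <- matrix(log(base), n, m, dimnames = list(ids, samples))

    # group effects are planted on rows that carry no regulator latent
    # factor, so differential and co-expression signals stay separable
    factor_rows <- unique(c(truth$regulator_pairs$lncrna_id,
        unlist(truth$pathways[unique(truth$regulator_pairs$set_name)],
               use.names = FALSE)))
    pool <- setdiff(ids, factor_rows)
    n_det <- max(1L, round(cfg$frac_det * n))
    if (n_det > length(pool))
        stop("sizing error: not enough factor-free transcripts to plant ",
             n_det, " differential effects")
    det_ids <- sample(pool, n_det)
    up <- rep(c(TRUE, FALSE), length.out = n_det)
    in_mci <- rep(c(TRUE, FALSE), length.out = n_det)
    in_mci <- sample(in_mci)
    lfc <- ifelse(up, log(cfg$planted_fc), -log(cfg$planted_fc))
    for (d in seq_len(n_det)) {
        cols_ad <- groups == "AD"
        logmu[det_ids[d], cols_ad] <- logmu[det_ids[d], cols_ad] + lfc[d]
        if (in_mci[d]) {
            cols_mci <- groups == "MCI"
            logmu[det_ids[d], cols_mci] <- logmu[det_ids[d], cols_mci] + lfc[d]
        }
    }

    for (r in seq_len(nrow(truth$regulator_pairs))) {
        f <- stats::rnorm(m)
        members <- truth$pathways[[truth$regulator_pairs$set_name[r]]]
        for (tx in c(truth$regulator_pairs$lncrna_id[r], members))
            logmu[tx, ] <- logmu[tx, ] + cfg$regulator_strength * f
    }

    counts <- matrix(stats::rnbinom(n * m, mu = exp(logmu),
                                    size = 1 / cfg$nb_dispersion),
                     n, m, dimnames = list(ids, samples))
    lens <- transcriptLengths(sim$assembled)[ids]
    rate <- counts / lens
    tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6

    truth$true_det_ids <- list(
        AD_vs_normal = det_ids,
        MCI_vs_normal = det_ids[in_mci])
    truth$det_direction_up <- stats::setNames(up, det_ids)
    list(counts = makeExpressionSE(counts, "counts", groups),
         tpm = makeExpressionSE(tpm, "TPM", groups),
         truth = truth)
}

#' Simulate junction inclusion/skipping counts
#'
#' For each planted event and sample, a Poisson total read count is split
#' binomially between the inclusion and skipping forms so that the
#' expected length-normalized PSI equals the group PSI: a per-event base
#' PSI (uniform on [0.35, 0.65]) shifted by \code{psi_shift} in MCI and
#' AD.
#'
#' @param truth ground-truth list with an \code{events} table
#' @param config the \code{\link{simConfig}}
#' @return data.frame: event_id, sample_id, group, inclusion, skipping,
#'   inc_len, skip_len
#' @export
simulateJunctionCounts <- function(truth, config) {
    with_local_seed(config$seed + 2L,
                    simulate_junctions_impl(truth, config))
}

simulate_junctions_impl <- function(truth, cfg) {
    ev <- truth$events
    if (is.null(ev) || nrow(ev) == 0L)
        return(data.frame(event_id = character(), sample_id = character(),
                          group = character(), inclusion = integer(),
                          skipping = integer(), inc_len = integer(),
                          skip_len = integer()))
    nspg <- cfg$n_samples_per_group
    groups <- rep(c("normal", "MCI", "AD"), each = nspg)
    samples <- sprintf("%s_%02d", groups, rep(seq_len(nspg), times = 3L))
    rows <- vector("list", nrow(ev))
    for (i in seq_len(nrow(ev))) {
        base_psi <- stats::runif(1L, 0.35, 0.65)
        lens <- effectiveFormLengths(ev$type[i])
        psi_g <- ifelse(groups == "normal", base_psi,
                        pmin(base_psi + cfg$psi_shift, 0.97))
        q <- lens[1] * psi_g / (lens[1] * psi_g + lens[2] * (1 - psi_g))
        total <- stats::rpois(length(samples), cfg$junction_depth)
        inc <- stats::rbinom(length(samples), total, q)
        rows[[i]] <- data.frame(
            event_id = ev$event_id[i], sample_id = samples,
            group = groups, inclusion = inc, skipping = total - inc,
            inc_len = unname(lens[1]), skip_len = unname(lens[2]))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate the protein database
#'
#' One protein per coding gene: the translation of its CDS with point
#' substitutions at \code{substitution_rate}, plus shuffled decoy
#' proteins.
#'
#' @param sim result of \code{\link{simulateAnnotation}}
#' @param config the \code{\link{simConfig}}
#' @return AAStringSet: proteins named prot_<gene>, decoys named
#'   decoy_<k>; the source transcript of each true protein is recorded in
#'   an attribute-free companion via names (prot_<gene> pairs with
#'   tx_<gene>)
#' @export
simulateProteinDb <- function(sim, config) {
    with_local_seed(config$seed + 3L, simulate_proteins_impl(sim, config))
}

simulate_proteins_impl <- function(sim, cfg) {
    cds_seqs <- transcriptSeqs(sim$genome, sim$reference, ranges = "cds")
    cds_seqs <- cds_seqs[sim$truth$coding_ids]
    prots <- character(length(cds_seqs))
    names(prots) <- sub("^tx_", "prot_", names(cds_seqs))
    for (i in seq_along(cds_seqs)) {
        pep <- as.character(Biostrings::translate(cds_seqs[[i]]))
        pep <- sub("\\*$", "", pep)
        chars <- strsplit(pep, "", fixed = TRUE)[[1]]
        nsub <- stats::rbinom(1L, length(chars), cfg$substitution_rate)
        if (nsub > 0L) {
            pos <- sample(length(chars), nsub)
            for (p in pos)
                chars[p] <- sample(setdiff(.aa20, chars[p]), 1L)
        }
        prots[i] <- paste(chars, collapse = "")
    }
    decoys <- character(cfg$n_decoys)
    names(decoys) <- sprintf("decoy_%02d", seq_len(cfg$n_decoys))
    for (k in seq_len(cfg$n_decoys)) {
        src <- prots[[((k - 1L) %% length(prots)) + 1L]]
        decoys[k] <- paste(sample(strsplit(src, "", fixed = TRUE)[[1]]),
                           collapse = "")
    }
    Biostrings::AAStringSet(c(prots, decoys))
}

#' Generate and serialize a complete synthetic study
#'
#' Runs all four generator stages and writes genome.fa, reference.gtf,
#' assembled.gtf, counts.tsv, tpm.tsv, junctions.tsv, proteins.fa and
#' truth.json into a directory. All outputs are deterministic given the
#' config; the serialized ground truth is what downstream evaluations
#' read.
#'
#' @param config a \code{\link{simConfig}}
#' @param dir output directory (created if missing)
#' @return invisibly, the in-memory study: genome, reference, assembled,
#'   truth, counts, tpm, junctions, proteins
#' @export
simulateStudy <- function(config, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sim <- simulateAnnotation(config)
    expr <- simulateExpression(sim, config)
    sim$truth <- expr$truth
    junctions <- simulateJunctionCounts(sim$truth, config)
    proteins <- simulateProteinDb(sim, config)
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    writeGTF(sim$reference, file.path(dir, "reference.gtf"))
    writeGTF(sim$assembled, file.path(dir, "assembled.gtf"))
    writeExpressionMatrix(expr$counts, file.path(dir, "counts.tsv"))
    writeExpressionMatrix(expr$tpm, file.path(dir, "tpm.tsv"))
    utils::write.table(junctions, file.path(dir, "junctions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(proteins, file.path(dir, "proteins.fa"))
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(genome = sim$genome, reference = sim$reference,
                   assembled = sim$assembled, truth = sim$truth,
                   counts = expr$counts, tpm = expr$tpm,
                   junctions = junctions, proteins = proteins))
}
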