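test_that("component retention reaches 60% cumulative variance inclusively", {
    expect_equal(chooseComponentCount(c(0.6, 0.2, 0.2)), 1L)
    expect_equal(chooseComponentCount(c(0.5, 0.3, 0.2)), 2L)
    expect_equal(chooseComponentCount(rep(0.1, 10)), 6L)
    expect_error(chooseComponentCount(c(-0.1, 1.1)), "negative")
})

test_that("pathway PCs retain a minimal component set", {
    set.seed(19)
    m <- matrix(rnorm(10 * 40), 10, 40,
                dimnames = list(sprintf("t%02d", 1:10),
                                sprintf("s%02d", 1:40)))
    pcs <- computePathwayPCs(m, rownames(m))
    expect_gte(sum(pcs$fractions[seq_len(pcs$k)]), 0.6)
    if (pcs$k > 1)
        expect_lt(sum(pcs$fractions[seq_len(pcs$k - 1)]), 0.6)
    expect_equal(nrow(pcs$scores), 40L)
    expect_error(computePathwayPCs(m, "t01"), "two set genes")
    m0 <- m; m0["t01", ] <- 1
    expect_warning(computePathwayPCs(m0, rownames(m0)), "zero-variance")
})

test_that("PC regression matches the normal-equations oracle", {
    set.seed(20)
    for (k in 1:20) {
        n <- sample(20:60, 1)
        X <- matrix(rnorm(n * 3), n, 3)
        y <- rnorm(n)
        pcs <- list(scores = X, fractions = c(0.5, 0.3, 0.2), k = 3L)
        fit <- fitPcRegression(y, pcs)
        want <- oracle_ols(y, X)
        expect_equal(fit$betas, want$beta[-1], tolerance = 1e-8)
        expect_equal(fit$r_squared, want$r2, tolerance = 1e-10)
        expect_equal(fit$beta0, 0, tolerance = 1e-10)
    }
    # perfect fit on PC1
    set.seed(21)
    sc <- matrix(rnorm(50), 50, 1)
    fit <- suppressWarnings(   # summary.lm flags the exact fit
        fitPcRegression(drop(sc), list(scores = sc, k = 1L)))
    expect_equal(fit$r_squared, 1)
    expect_equal(fit$beta0, 0, tolerance = 1e-12)
    # independent noise: R^2 near k / (n - 1)
    set.seed(22)
    X <- matrix(rnorm(200 * 2), 200, 2)
    fit <- fitPcRegression(rnorm(200), list(scores = X, k = 2L))
    expect_lt(fit$r_squared, 0.05)
})

test_that("Spearman correlation handles the closed-form cases", {
    expect_equal(spearmanCoexpression(1:10, 1:10)$r, 1)
    expect_equal(spearmanCoexpression(1:10, 10:1)$r, -1)
    expect_equal(spearmanCoexpression(c(1, 2, 3, 4), c(1, 2, 4, 3))$r, 0.8)
    expect_warning(out <- spearmanCoexpression(rep(1, 5), 1:5), "constant")
    expect_true(is.na(out$r))
    expect_error(spearmanCoexpression(1:3, 1:3), "four")
})

test_that("duplex energies match the all-window brute force", {
    tab <- defaultStackTable()
    uni <- stats::setNames(rep(-1, 16), names(tab))
    # 12-nt perfect complement under the uniform table: 11 stacks
    a <- "GGGGAATTCCCC"
    expect_equal(duplexEnergy(a, revcomp(a), table = uni)$energy, -11)
    # no complementary window of length >= 2
    expect_equal(duplexEnergy(strrep("A", 20), strrep("A", 20),
                              table = tab)$energy, 0)
    # short input: no-hit result
    expect_equal(duplexEnergy("ACGT", "ACGT")$energy, 0)
    set.seed(23)
    for (k in 1:20) {
        q <- random_dna(sample(15:50, 1))
        t <- random_dna(sample(15:50, 1))
        expect_equal(duplexEnergy(q, t, table = tab)$energy,
                     oracle_duplex(q, t, tab))
    }
    # symmetric under swapping with reverse complementation of both
    for (k in 1:10) {
        q <- random_dna(30); t <- random_dna(30)
        e1 <- duplexEnergy(q, t, table = tab)$energy
        e2 <- duplexEnergy(revcomp(t), revcomp(q), table = tab)$energy
        expect_equal(e1, e2)
    }
})

test_that("reported duplex window coordinates locate the paired bases", {
    t <- random_dna(60)
    q <- paste0(random_dna(15), revcomp(substr(t, 21, 40)), random_dna(10))
    hit <- duplexEnergy(q, t)
    expect_lte(hit$energy, -20)
    win_q <- substr(q, hit$query_start, hit$query_end)
    win_t <- substr(t, hit$target_start, hit$target_end)
    expect_identical(win_q, revcomp(win_t))
})

test_that("cis windows are inclusive at 100 kb and gated on co-expression", {
    spec <- list(
        lnc = list(gene = "L", strand = "+",
                   exons = list(c(1e6, 1e6 + 299), c(1e6 + 400, 1e6 + 699))),
        at_window = list(gene = "gA", strand = "+",
                         exons = list(c(1e6 + 700 + 100000, 1e6 + 700 + 100999))),
        past_window = list(gene = "gB", strand = "+",
                           exons = list(c(1e6 + 700 + 100001 + 1000,
                                          1e6 + 700 + 100001 + 1999))),
        weak = list(gene = "gC", strand = "+",
                    exons = list(c(1e6 - 5000, 1e6 - 4001))))
    tc <- make_catalog(spec)
    # distances: at_window gap exactly 100000; past_window 100001 + slack
    set.seed(24)
    base <- rnorm(40)
    m <- rbind(lnc = base,
               at_window = base + rnorm(40, sd = 0.1),
               past_window = base + rnorm(40, sd = 0.1),
               weak = rnorm(40))
    colnames(m) <- sprintf("s%02d", 1:40)
    res <- predictCisTargets("lnc", tc, m,
                             c("at_window", "past_window", "weak"))
    expect_setequal(res$target_id, c("at_window", "weak"))
    expect_true(res$kept[res$target_id == "at_window"])
    expect_equal(res$distance[res$target_id == "at_window"], 100000)
    expect_false(res$kept[res$target_id == "weak"])
})

test_that("trans prediction is strict at the energy cutoff", {
    uni <- stats::setNames(rep(-1, 16), names(defaultStackTable()))
    # fixed sequences: an 11-base complementary run scores exactly -10
    # under the uniform table (boundary), a 12-base run scores -11
    tgt_seq <- "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTC"
    q_at <- "GGGGGGGGGGGGAGTTACACAGGGGGGGGG"
    q_in <- "GGGGGGGGGGCGGAGTTACACAGGGGGGGG"
    expect_equal(duplexEnergy(q_at, tgt_seq, table = uni)$energy, -10)
    expect_equal(duplexEnergy(q_in, tgt_seq, table = uni)$energy, -11)
    mk_genome <- function(q) Biostrings::DNAStringSet(
        c(chr1 = q, chr2 = tgt_seq))
    tc <- TranscriptCatalog(
        list(lnc = GRanges("chr1", IRanges(1, 30), "+"),
             tgt = GRanges("chr2", IRanges(1, 40), "+")),
        geneId = c(lnc = "L", tgt = "G"))
    set.seed(25)
    base <- rnorm(30)
    m <- rbind(lnc = base, tgt = base + rnorm(30, sd = 0.05))
    colnames(m) <- sprintf("s%02d", 1:30)
    at <- predictTransTargets("lnc", tc, mk_genome(q_at), m, "tgt",
                              table = uni)
    expect_equal(nrow(at), 0L)            # -10 is rejected (strict)
    below <- predictTransTargets("lnc", tc, mk_genome(q_in), m, "tgt",
                                 table = uni)
    expect_true(below$kept)               # -11 plus co-expression passes
})

test_that("regulator calls need fit quality plus in-pathway support", {
    fits <- data.frame(lncrna_id = c("l1", "l1", "l2"),
                       set_name = c("P1", "P2", "P1"),
                       k = 1L,
                       r_squared = c(0.7, 0.7, 0.5),
                       beta0 = 0,
                       p_value = c(1e-5, 1e-5, 1e-5),
                       p_adj = c(1e-4, 1e-4, 1e-4))
    cis <- data.frame(lncrna_id = "l1", target_id = "tA",
                      distance = 0, r = 0.9, p_value = 1e-6,
                      p_adj = 1e-5, kept = TRUE)
    trans <- data.frame(lncrna_id = character(), target_id = character(),
                        energy = numeric(), r = numeric(),
                        p_value = numeric(), p_adj = numeric(),
                        kept = logical())
    sets <- list(P1 = c("tA", "tB"), P2 = c("tC"))
    out <- callPathwayRegulators(fits, cis, trans, sets)
    expect_true(out$called[out$lncrna_id == "l1" & out$set_name == "P1"])
    # qualifying targets exist but none in the pathway
    expect_false(out$called[out$lncrna_id == "l1" & out$set_name == "P2"])
    # R^2 below threshold
    expect_false(out$called[out$lncrna_id == "l2"])
    # raising the threshold never adds calls
    stricter <- callPathwayRegulators(fits, cis, trans, sets,
                                      r2_threshold = 0.9)
    expect_true(all(out$called | !stricter$called))
    # adding a qualifying in-pathway target never removes a call
    cis2 <- rbind(cis, data.frame(lncrna_id = "l1", target_id = "tB",
                                  distance = 0, r = 0.8, p_value = 1e-6,
                                  p_adj = 1e-5, kept = TRUE))
    more <- callPathwayRegulators(fits, cis2, trans, sets)
    expect_true(all(!out$called | more$called))
})

test_that("planted regulator pairs are recovered on synthetic data", {
    cfg <- simConfig(seed = 7)
    sim <- simulateAnnotation(cfg)
    expr <- simulateExpression(sim, cfg)
    tr <- expr$truth
    res <- inferRegulators(sim$assembled, sim$genome, expr$tpm,
                           tr$pathways, lncrna_ids = tr$true_lncrna_ids,
                           target_ids = tr$coding_ids)
    key <- paste(res$calls$lncrna_id, res$calls$set_name)
    tkey <- paste(tr$regulator_pairs$lncrna_id,
                  tr$regulator_pairs$set_name)
    called <- key[res$calls$called]
    expect_gte(length(intersect(called, tkey)) / length(tkey), 0.75)
    expect_lte(length(setdiff(called, tkey)) /
               (length(key) - length(tkey)), 0.1)
    # every planted trans pair carries a passing duplex window
    seqs <- transcriptSeqs(sim$genome, sim$assembled)
    for (i in seq_len(nrow(tr$trans_windows))) {
        hit <- duplexEnergy(seqs[[tr$trans_windows$lncrna_id[i]]],
                            seqs[[tr$trans_windows$target_id[i]]])
        expect_lt(hit$energy, -10)
    }
})
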