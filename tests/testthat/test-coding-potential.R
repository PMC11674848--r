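test_that("longest ORF matches the exhaustive scan oracle", {
    orf <- findLongestOrf("ATGAAATGA")
    expect_equal(orf$start, 1L)
    expect_equal(orf$end, 9L)
    expect_null(findLongestOrf("CCCCCC"))
    # two equal-length ORFs: 5'-most wins
    two <- paste0("ATGAAATAA", "CC", "ATGCCCTAA")
    expect_equal(findLongestOrf(two)$start, 1L)
    set.seed(11)
    for (k in 1:40) {
        s <- random_dna(sample(10:120, 1))
        got <- findLongestOrf(s)
        want <- oracle_orf(s)
        if (is.null(want)) expect_null(got)
        else expect_equal(got[c("start", "end")],
                          want[c("start", "end")])
    }
})

test_that("translation uses the standard code with X for fuzzy codons", {
    expect_identical(translateLongestOrf("ATGAAATGA"), "MK")
    expect_null(translateLongestOrf("CCCCCC"))
    expect_identical(translateLongestOrf("ATGANATAA"), "MX")
})

test_that("fickett statistic equals an independent table lookup", {
    # independent copy of the published lookup tables, rebuilt by hand
    pos_cut <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
    con_cut <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
    pos_p <- list(
        A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
        C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
        G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
        T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
    con_p <- list(
        A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
        C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
        G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
        T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
    pw <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
    cw <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
    lookup <- function(s) {
        ch <- strsplit(s, "")[[1]]
        total <- 0
        for (b in c("A", "C", "G", "T")) {
            cnt <- sapply(0:2, function(p)
                sum(ch == b & (seq_along(ch) - 1) %% 3 == p))
            pv <- max(cnt) / (min(cnt) + 1)
            cv <- sum(cnt) / length(ch)
            total <- total +
                pos_p[[b]][which(pv >= pos_cut)[1]] * pw[b] +
                con_p[[b]][which(cv >= con_cut)[1]] * cw[b]
        }
        unname(total)
    }
    set.seed(5)
    for (k in 1:3) {
        s <- random_dna(300)
        expect_equal(fickettScore(s), lookup(s))
    }
    s <- random_dna(250)
    expect_identical(fickettScore(s), fickettScore(s))
    polyA <- strrep("A", 300)
    expect_equal(fickettScore(polyA), lookup(polyA))
    expect_error(fickettScore("ACGT"), "length")
})

test_that("hexamer log-likelihood ratio has its closed forms", {
    hex <- adtrx:::all_hexamers()
    same <- list(coding = stats::setNames(rep(1 / 4096, 4096), hex),
                 noncoding = stats::setNames(rep(1 / 4096, 4096), hex))
    s <- "ATGAAAGGGCCCTTTTGA"
    expect_equal(hexamerScore(s, same), 0)
    # every per-hexamer ratio = 2 gives k * log 2
    ratio2 <- list(coding = stats::setNames(rep(2, 4096), hex),
                   noncoding = stats::setNames(rep(1, 4096), hex))
    orf <- findLongestOrf(s)
    k <- length(seq.int(1L, (orf$end - orf$start + 1L) - 5L, by = 3L))
    expect_equal(hexamerScore(s, ratio2), k * log(2))
    expect_equal(hexamerScore("CCCCCCCC", same), -1e6)  # no ORF sentinel
    # brute-force summation over a trained table
    set.seed(21)
    tabs <- trainHexamerTables(
        vapply(1:5, function(i) random_dna(300), character(1)),
        vapply(1:5, function(i) random_dna(300), character(1)))
    s <- random_dna(400)
    orf <- findLongestOrf(s)
    if (!is.null(orf)) {
        sub <- substr(s, orf$start, orf$end)
        pos <- seq(1, nchar(sub) - 5, by = 3)
        want <- sum(vapply(pos, function(p) {
            h <- substr(sub, p, p + 5)
            log(tabs$coding[[h]] / tabs$noncoding[[h]])
        }, numeric(1)))
        expect_equal(hexamerScore(s, tabs), want)
    }
})

test_that("ORF coverage is the ORF fraction of the transcript", {
    expect_equal(orfCoverageScore(600, 0), 0)
    expect_equal(orfCoverageScore(600, 600), 1)
    expect_equal(orfCoverageScore(600, 300), 0.5)
    expect_error(orfCoverageScore(100, 200), "exceeds")
})

test_that("the unanimous consensus passes only all-noncoding votes", {
    expect_true(consensusVote(rep(FALSE, 5)))    # five noncoding votes
    expect_false(consensusVote(c(rep(FALSE, 4), TRUE)))
    # exhaustive over all 32 verdict vectors
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
    calls <- apply(grid, 1, function(v) consensusVote(as.logical(v)))
    expect_equal(sum(calls), 1L)
    expect_true(calls[rowSums(grid) == 0])
    # monotone: flipping any vote to coding never creates a lncRNA call
    for (i in seq_len(nrow(grid))) {
        v <- as.logical(grid[i, ])
        for (j in which(!v)) {
            w <- v; w[j] <- TRUE
            expect_false(!consensusVote(v) && consensusVote(w))
        }
    }
    expect_error(consensusVote(rep(FALSE, 4)), "five")
})

test_that("calibrated thresholds separate coding from noncoding training", {
    set.seed(31)
    coding <- vapply(1:25, function(i) {
        body <- sample(names(adtrx:::.codon_usage), 150, replace = TRUE,
                       prob = adtrx:::.codon_usage)
        paste(c("ATG", body, "TAA"), collapse = "")
    }, character(1))
    noncoding <- vapply(1:40, function(i) random_dna(450), character(1))
    thr <- calibrateScorerThresholds(coding, noncoding)
    expect_named(thr$threshold, scorerNames())
    sc <- codingPotentialScores(stats::setNames(coding, paste0("c", 1:25)),
                                thr$hexamer_tables)
    v <- codingVerdicts(sc, thr)
    # hexamer bias alone must flag nearly all coding training sequences
    expect_gte(mean(v$hexamer), 0.9)
})
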