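test_that("the five event archetypes are detected and typed", {
    se_cat <- make_catalog(list(
        t1 = list(gene = "g", strand = "+",
                  exons = list(c(1, 100), c(201, 300), c(401, 500))),
        t2 = list(gene = "g", strand = "+",
                  exons = list(c(1, 100), c(401, 500)))))
    ev <- detectSpliceEvents(se_cat)
    expect_equal(ev$type, "SE")
    expect_equal(ev$inclusion_form, "100;201;300;401")

    a5_cat <- make_catalog(list(
        t1 = list(gene = "g", strand = "+",
                  exons = list(c(1, 100), c(201, 300))),
        t2 = list(gene = "g", strand = "+",
                  exons = list(c(1, 150), c(201, 300)))))
    expect_equal(detectSpliceEvents(a5_cat)$type, "A5SS")
    # on the minus strand the same geometry is an alternative 3' site
    a3_cat <- make_catalog(list(
        t1 = list(gene = "g", strand = "-",
                  exons = list(c(1, 100), c(201, 300))),
        t2 = list(gene = "g", strand = "-",
                  exons = list(c(1, 150), c(201, 300)))))
    expect_equal(detectSpliceEvents(a3_cat)$type, "A3SS")

    ri_cat <- make_catalog(list(
        t1 = list(gene = "g", strand = "+",
                  exons = list(c(1, 100), c(201, 300))),
        t2 = list(gene = "g", strand = "+", exons = list(c(1, 300)))))
    expect_equal(detectSpliceEvents(ri_cat)$type, "RI")

    mxe_cat <- make_catalog(list(
        t1 = list(gene = "g", strand = "+",
                  exons = list(c(1, 100), c(201, 300), c(601, 700))),
        t2 = list(gene = "g", strand = "+",
                  exons = list(c(1, 100), c(401, 500), c(601, 700)))))
    expect_equal(detectSpliceEvents(mxe_cat)$type, "MXE")
})

test_that("event detection equals the brute-force pairwise oracle", {
    n_done <- 0
    s <- 0
    while (n_done < 50) {
        s <- s + 1
        cat1 <- random_event_gene(s)
        if (is.null(cat1)) next
        n_done <- n_done + 1
        expect_identical(event_signatures(detectSpliceEvents(cat1)),
                         oracle_events(cat1), info = paste("seed", s))
    }
})

test_that("PSI is the length-normalized inclusion proportion", {
    expect_equal(computePsi(0, 10), 0)
    expect_equal(computePsi(20, 10, 2, 1), 0.5)
    expect_true(is.na(computePsi(0, 0)))
    expect_error(computePsi(-1, 2), "negative")
    # scale invariance and range
    set.seed(3)
    for (k in 1:20) {
        i <- sample(0:100, 1); s2 <- sample(0:100, 1)
        if (i + s2 == 0) next
        p <- computePsi(i, s2, 2, 1)
        expect_gte(p, 0); expect_lte(p, 1)
        expect_equal(computePsi(7 * i, 7 * s2, 2, 1), p)
    }
})

test_that("event testing applies the p and delta-PSI gates", {
    mk <- function(a, b) {
        data.frame(event_id = "e",
                   sample_id = sprintf("s%02d", seq_len(length(a) + length(b))),
                   psi = c(a, b),
                   group = rep(c("A", "B"), c(length(a), length(b))))
    }
    # strong shift, clear separation: kept
    res <- testSpliceEvents(mk(seq(0.62, 0.8, 0.02), seq(0.30, 0.48, 0.02)),
                            "A", "B")
    expect_gt(res$delta_psi, 0.05)
    expect_lt(res$p_value, 0.05)
    expect_true(res$kept)
    # significant but tiny shift: removed by the delta-PSI gate
    res <- testSpliceEvents(mk(rep(c(0.50, 0.52), 5), rep(c(0.46, 0.48), 5)),
                            "A", "B")
    expect_lt(res$p_value, 0.05)
    expect_lt(abs(res$delta_psi), 0.05)
    expect_false(res$kept)
    # large shift but overlapping groups: p gate removes
    res <- testSpliceEvents(mk(c(0.9, 0.2, 0.8, 0.3), c(0.4, 0.5, 0.2, 0.6)),
                            "A", "B")
    expect_gte(res$p_value, 0.05)
    expect_false(res$kept)
    # the inverted filter direction discards large shifts instead
    res <- testSpliceEvents(mk(seq(0.62, 0.8, 0.02), seq(0.30, 0.48, 0.02)),
                            "A", "B", direction = "remove")
    expect_false(res$kept)
    # degenerate group: skipped with a warning
    expect_warning(
        out <- testSpliceEvents(mk(c(NA, NA, 0.5), c(0.5, 0.6, 0.7)),
                                "A", "B"),
        "skipped")
    expect_equal(nrow(out), 0L)
})

test_that("event/gene counting matches set cardinalities", {
    ev <- data.frame(gene_id = c("g1", "g1", "g1"),
                     type = c("SE", "SE", "SE"))
    out <- countGenesWithEvents(ev)
    expect_equal(out$n_events[out$type == "SE"], 3L)
    expect_equal(out$n_genes[out$type == "SE"], 1L)
    empty <- countGenesWithEvents(ev[0, ])
    expect_true(all(empty$n_events == 0L))
    set.seed(9)
    ev <- data.frame(
        gene_id = sample(sprintf("g%d", 1:6), 40, replace = TRUE),
        type = sample(c("SE", "A5SS", "A3SS", "MXE", "RI"), 40,
                      replace = TRUE))
    out <- countGenesWithEvents(ev)
    for (ty in c("SE", "A5SS", "A3SS", "MXE", "RI")) {
        expect_equal(out$n_events[out$type == ty], sum(ev$type == ty))
        expect_equal(out$n_genes[out$type == ty],
                     length(unique(ev$gene_id[ev$type == ty])))
    }
    expect_equal(out$n_genes[out$type == "total"],
                 length(unique(ev$gene_id)))
})

test_that("planted splice events are recovered and nulls are controlled", {
    cfg <- simConfig(seed = 7)
    sim <- simulateAnnotation(cfg)
    tr <- sim$truth
    detected <- detectSpliceEvents(sim$assembled)
    hit <- merge(tr$events, detected, by = c("gene_id", "type"))
    expect_equal(nrow(hit), nrow(tr$events))   # all planted events found
    jc <- simulateJunctionCounts(tr, cfg)
    res <- testSpliceEvents(psiTable(jc), "AD", "normal")
    expect_gte(mean(res$kept), 0.8)
    # with no planted shift, few events survive the gates
    cfg0 <- simConfig(seed = 8, psi_shift = 0)
    sim0 <- simulateAnnotation(cfg0)
    jc0 <- simulateJunctionCounts(sim0$truth, cfg0)
    res0 <- testSpliceEvents(psiTable(jc0), "AD", "normal")
    expect_lte(mean(res0$kept), 0.07)
})
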