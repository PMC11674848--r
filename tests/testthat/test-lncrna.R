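test_that("candidate filter applies inclusive length and exon thresholds", {
    tc <- make_catalog(list(
        short3 = list(gene = "g1", strand = "+",                 # 199 nt, 3 exons
                      exons = list(c(1, 66), c(100, 166), c(200, 265))),
        exact = list(gene = "g2", strand = "+",                  # 200 nt, 2 exons
                     exons = list(c(1000, 1099), c(1200, 1299))),
        mono = list(gene = "g3", strand = "+",                   # 5000 nt, 1 exon
                    exons = list(c(2000, 6999)))))
    expect_equal(unname(transcriptLengths(tc)[c("short3", "exact", "mono")]),
                 c(199L, 200L, 5000L))
    expect_identical(filterCandidates(tc), "exact")
})

test_that("class codes follow the locational definitions", {
    ref <- make_catalog(list(
        r1 = list(gene = "G1", strand = "+",
                  exons = list(c(1000, 3999), c(6001, 8000)))))
    qry <- make_catalog(list(
        in_intron = list(gene = "q", strand = "+",
                         exons = list(c(5000, 5300), c(5500, 5799))),
        far = list(gene = "q", strand = "+",
                   exons = list(c(20000, 20200), c(20400, 20600))),
        in_exon = list(gene = "q", strand = "-",
                       exons = list(c(1100, 1300), c(1500, 1700))),
        partial = list(gene = "q", strand = "+",
                       exons = list(c(7500, 8300), c(8500, 8700)))))
    comb <- TranscriptCatalog(c(exonRanges(ref), exonRanges(qry)),
                              geneId = c(geneIds(ref), geneIds(qry)))
    expect_equal(assignClassCode("in_intron", comb, ref)$code, "i")
    cc <- assignClassCode("far", comb, ref)
    expect_equal(cc$code, "u")
    expect_length(cc$evidence, 0L)
    expect_equal(assignClassCode("in_exon", comb, ref)$code, "x")
    expect_equal(assignClassCode("partial", comb, ref)$code, "o")
})

test_that("class codes equal the per-base oracle on random catalogs", {
    for (s in 1:12) {
        ref <- random_catalog(n_tx = 8, seqlen = 12000, seed = 100 + s)
        qry <- random_catalog(n_tx = 4, seqlen = 12000, seed = 900 + s,
                              prefix = "q")
        comb <- TranscriptCatalog(c(exonRanges(ref), exonRanges(qry)),
                                  geneId = c(geneIds(ref), geneIds(qry)))
        for (id in transcriptIds(qry))
            expect_equal(assignClassCode(id, comb, ref)$code,
                         oracle_class_code(id, comb, ref),
                         info = paste(s, id))
    }
})

test_that("lncRNA categories respect the antisense > intronic > intergenic precedence", {
    ref <- make_catalog(list(
        r1 = list(gene = "G1", strand = "+",
                  exons = list(c(1000, 3999), c(6001, 8000)))))
    qry <- make_catalog(list(
        anti = list(gene = "q", strand = "-",
                    exons = list(c(1100, 1400), c(1600, 1900))),
        inside = list(gene = "q", strand = "+",
                      exons = list(c(4500, 4700), c(4900, 5100))),
        inside_anti = list(gene = "q", strand = "-",
                           exons = list(c(4500, 4700), c(4900, 5100))),
        lone = list(gene = "q", strand = "+",
                    exons = list(c(30000, 30300), c(30500, 30800)))))
    comb <- TranscriptCatalog(c(exonRanges(ref), exonRanges(qry)),
                              geneId = c(geneIds(ref), geneIds(qry)))
    expect_equal(categorizeLncrna("anti", comb, ref, "x"), "antisense")
    expect_equal(categorizeLncrna("inside", comb, ref, "i"), "intronic")
    # precedence: intron-contained but opposite strand is antisense
    expect_equal(categorizeLncrna("inside_anti", comb, ref, "i"),
                 "antisense")
    expect_equal(categorizeLncrna("lone", comb, ref, "u"), "intergenic")
})

test_that("read-region assignment follows CDS > 3'UTR > intron > upstream", {
    ref <- make_catalog(list(
        r1 = list(gene = "G1", strand = "+",
                  exons = list(c(20000, 20999), c(22000, 22999)),
                  cds = list(c(20100, 20999), c(22000, 22499)))))
    reads <- GRanges("chr1", IRanges(
        c(20200, 22600, 21500, 20950, 10001, 5000, 21990),
        width = c(50, 50, 50, 1100, 50, 50, 20)))
    # reads: CDS; 3'UTR; intron; CDS+intron overlap -> CDS;
    # 9999 bp upstream of the TSS; far upstream (unassigned); intron+CDS
    res <- regionReadDistribution(reads, ref)
    expect_equal(unname(res$counts),
                 c(3L, 1L, 1L, 1L, 1L))
    expect_equal(sum(res$fractions), 1)
    # permuting read order changes nothing
    res2 <- regionReadDistribution(rev(reads), ref)
    expect_equal(res2$counts, res$counts)
})

test_that("3'UTR extraction is strand-aware", {
    ref <- make_catalog(list(
        m = list(gene = "G1", strand = "-",
                 exons = list(c(1000, 1999), c(3000, 3999)),
                 cds = list(c(1500, 1999), c(3000, 3499)))))
    utr <- threeUtrRanges(ref)
    # minus strand: 3'UTR is the genomically first exon part
    expect_equal(start(utr), 1000L)
    expect_equal(end(utr), 1499L)
})

test_that("identification recovers planted lncRNAs on synthetic data", {
    cfg <- simConfig(seed = 7)
    sim <- simulateAnnotation(cfg)
    thr <- calibrated_thresholds()
    res <- identifyLncRNAs(sim$assembled, sim$reference, sim$genome, thr)
    truth <- sim$truth$true_lncrna_ids
    novel <- setdiff(rownames(res), transcriptIds(sim$reference))
    called <- novel[res[novel, "is_lncrna"]]
    sens <- length(intersect(called, truth)) / length(truth)
    prec <- length(intersect(called, truth)) / max(1, length(called))
    expect_gte(sens, 0.9)
    expect_gte(prec, 0.9)
    # class codes and categories of correctly called lncRNAs match truth
    hit <- intersect(called, truth)
    expect_equal(res[hit, "class_code"],
                 unname(sim$truth$true_class_codes[hit]))
    expect_equal(res[hit, "category"],
                 unname(sim$truth$true_categories[hit]))
})
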