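test_that("FPKM follows the closed form and its scaling laws", {
    expect_equal(computeFpkm(10, 1000, 1e6), 10)
    expect_equal(computeFpkm(0, 1000, 1e6), 0)
    expect_equal(computeFpkm(1, 2000, 2e6), 0.25)
    # doubling the library halves FPKM; doubling the count doubles it
    base <- computeFpkm(37, 1534, 3.2e6)
    expect_equal(computeFpkm(37, 1534, 6.4e6), base / 2)
    expect_equal(computeFpkm(74, 1534, 3.2e6), base * 2)
    expect_error(computeFpkm(1, 0, 1e6), "geneLength")
    expect_error(computeFpkm(1, 1000, 0), "librarySize")
})

test_that("the expressed-gene filter is strictly greater-than", {
    rec <- data.frame(gene_id = c("a", "b", "c"), sample_id = "s1",
                      fpkm = c(0.5, 0.51, 0))
    kept <- filterExpressed(rec)
    expect_equal(kept$gene_id, "b")
    expect_equal(nrow(filterExpressed(rec[0, ])), 0L)
})

test_that("reads are assigned to a parent only when all covered sites agree", {
    vs <- make_variant_set(snps = variant_df(
        "chr1", c(10, 20), c("A", "C"), c("G", "T"), gene_id = "g1"))
    pmap <- c(ref = "Nip", alt = "ZH11")

    # one read, one site, ref allele
    obs <- data.frame(read_id = "r1", gene_id = "g1", chrom = "chr1",
                      pos = 10, allele = "A")
    out <- assignReads(obs, vs, pmap)
    expect_equal(out$Nip, 1L)
    expect_equal(out$ZH11, 0L)
    expect_equal(out$discarded, 0L)

    # a read covering two sites that disagree is discarded as conflicting
    obs2 <- data.frame(read_id = "r2", gene_id = "g1", chrom = "chr1",
                       pos = c(10, 20), allele = c("A", "T"))
    out2 <- assignReads(obs2, vs, pmap)
    expect_equal(out2$Nip + out2$ZH11, 0L)
    expect_equal(out2$discarded, 1L)

    # 3 ref-parent reads, 1 conflicting, 2 uninformative -> (3, 0), 3 discarded
    obs3 <- rbind(
        data.frame(read_id = c("a", "b", "c"), gene_id = "g1", chrom = "chr1",
                   pos = 10, allele = "A"),
        data.frame(read_id = "d", gene_id = "g1", chrom = "chr1",
                   pos = c(10, 20), allele = c("A", "T")),
        data.frame(read_id = c("e", "f"), gene_id = "g1", chrom = "chr1",
                   pos = NA, allele = NA))
    out3 <- assignReads(obs3, vs, pmap)
    expect_equal(out3$Nip, 3L)
    expect_equal(out3$ZH11, 0L)
    expect_equal(out3$discarded, 3L)
    # a read never counts for both parents
    expect_equal(out3$Nip + out3$ZH11 + out3$discarded, 6L)

    # an allele matching neither parent discards the read as "other"
    obs4 <- data.frame(read_id = "r9", gene_id = "g1", chrom = "chr1",
                       pos = 10, allele = "C")
    expect_equal(assignReads(obs4, vs, pmap)$discarded, 1L)

    # a position outside the variant set is an input error
    obs5 <- data.frame(read_id = "rX", gene_id = "g1", chrom = "chr1",
                       pos = 99, allele = "A")
    expect_error(assignReads(obs5, vs, pmap), "not present")
})

test_that("parent-line counts are oriented by the cross's female parent", {
    d <- reciprocalCrossDesign("A", "B", tissues = "endosperm")
    sa <- sampleTable(d)
    s_direct <- sa$sample_id[sa$cross_id == "AxB"]
    s_recip <- sa$sample_id[sa$cross_id == "BxA"]
    counts <- data.frame(
        gene_id = "g1",
        sample_id = c(s_direct, s_direct, s_recip, s_recip),
        parent = c("A", "B", "A", "B"),
        reads = c(12L, 4L, 12L, 4L))
    out <- tabulateAsr(counts, d)
    direct <- out[out$sample_id == s_direct, ]
    recip <- out[out$sample_id == s_recip, ]
    expect_equal(c(direct$maternal_asr, direct$paternal_asr), c(12L, 4L))
    # reciprocal cross: the same parent-line counts swap roles
    expect_equal(c(recip$maternal_asr, recip$paternal_asr), c(4L, 12L))

    # zero counts are retained for the ledger
    zero <- data.frame(gene_id = "g2", sample_id = s_direct,
                       parent = c("A", "B"), reads = c(0L, 0L))
    outz <- tabulateAsr(zero, d)
    expect_equal(outz$maternal_asr + outz$paternal_asr, 0L)

    bad <- data.frame(gene_id = "g1", sample_id = "nope", parent = "A", reads = 1L)
    expect_error(tabulateAsr(bad, d), "unknown sample_id")
    badp <- data.frame(gene_id = "g1", sample_id = s_direct, parent = "C", reads = 1L)
    expect_error(tabulateAsr(badp, d), "parent")
})

test_that("detectability statuses are assigned and partition the genes", {
    gm <- toy_genome(c(chrA = 4L))
    ids <- geneIds(gm)
    # g1 has a SNP with reads; g2 has no variant; g3 has a SNP but no reads;
    # g4 has a SNP with balanced reads
    vs <- make_variant_set(snps = variant_df(
        "chrA", c(60, 360, 510), "A", "G", gene_id = ids[c(1, 3, 4)]))
    d <- endosperm_pair()
    rec <- rbind(asr_record(d, ids[1], m = c(95, 93), p = c(5, 7)),
                 asr_record(d, ids[3], m = c(0, 0), p = c(0, 0)),
                 asr_record(d, ids[4], m = c(200, 200), p = c(100, 100)))
    calls <- callImprinting(rec, d)
    ledger <- detectabilityLedger(gm, vs, rec, calls, d)
    status <- setNames(ledger$status, ledger$gene_id)
    expect_equal(unname(status[ids]),
                 c("imprinted", "no_SNP", "no_ASR", "non_significant"))
    s <- summarizeLedger(ledger)
    expect_equal(s$imprinted + s$non_significant + s$no_SNP + s$no_ASR, s$total)
    expect_equal(s$total, length(ids))
})

test_that("ledger partition holds on a full synthetic run", {
    run <- synthetic_run(seed = 7L)
    ledger <- detectabilityLedger(run$genome, run$variants, run$records,
                                  run$calls, run$design)
    s <- summarizeLedger(ledger)
    expect_equal(s$imprinted + s$non_significant + s$no_SNP + s$no_ASR,
                 rep(nGenes(run$genome), nrow(s)))
    # every genome gene appears exactly once per pair
    expect_equal(sort(unique(table(ledger$gene_id))),
                 length(unique(ledger$pair_id)))
    # no-SNP genes in the ledger are exactly the variant-free genes
    snpless <- names(which(variantCount(run$variants, geneIds(run$genome)) == 0))
    expect_setequal(ledger$gene_id[ledger$status == "no_SNP"], snpless)
})
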