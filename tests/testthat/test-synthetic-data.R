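test_that("simulated genomes satisfy the ordering invariants and are seed-deterministic", {
    gm <- simulateGenome(2, 5, 1000, 500, seed = 1)
    expect_equal(nGenes(gm), 10L)
    gr <- geneModels(gm)
    for (chr in GenomeInfoDb::seqlevels(gr)) {
        g <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
        expect_false(is.unsorted(GenomicRanges::start(g), strictly = TRUE))
        expect_true(all(GenomicRanges::start(g)[-1] >
                        GenomicRanges::end(g)[-length(g)]))
    }
    expect_false(anyDuplicated(geneIds(gm)) > 0)

    expect_identical(simulateGenome(2, 5, 1000, 500, seed = 1), gm)

    one <- simulateGenome(1, 1, 1000, 500, seed = 7)
    expect_equal(nGenes(one), 1L)
    expect_equal(S4Vectors::mcols(geneModels(one))$rank, 1L)

    expect_error(simulateGenome(0, 5, 1000, 500), "nChromosomes")
    expect_error(simulateGenome(2, 5, -10, 500), "positive")
})

test_that("variant simulation respects the informative-gene model", {
    gm <- simulateGenome(2, 25, 1000, 500, seed = 3)

    none <- simulateVariants(gm, pGeneHasSnp = 0, seed = 1)
    expect_equal(nrow(snpTable(none)), 0L)
    expect_equal(nrow(indelTable(none)), 0L)

    all_v <- simulateVariants(gm, pGeneHasSnp = 1,
                              meanSnpsPerInformativeGene = 2, seed = 2)
    expect_true(all(variantCount(all_v, geneIds(gm)) >= 1L))

    # variants land inside their gene's interval, ref/alt over A/C/G/T
    gr <- geneModels(gm)
    sn <- snpTable(all_v)
    idx <- match(sn$gene_id, geneIds(gm))
    expect_true(all(sn$pos >= GenomicRanges::start(gr)[idx] &
                    sn$pos <= GenomicRanges::end(gr)[idx]))
    expect_true(all(c(sn$ref, sn$alt) %in% c("A", "C", "G", "T")))
    expect_true(all(sn$ref != sn$alt))

    expect_error(simulateVariants(gm, pGeneHasSnp = 1.5), "probability")
})

test_that("SNP-less gene count follows the binomial model", {
    gm <- simulateGenome(4, 2500, 600, 200, seed = 11)
    vs <- simulateVariants(gm, pGeneHasSnp = 0.3,
                           meanSnpsPerInformativeGene = 1, indelRate = 0,
                           seed = 12)
    n_snpless <- sum(variantCount(vs, geneIds(gm)) == 0L)
    # oracle: exact binomial(10000, 0.7) central 99% interval
    bounds <- qbinom(c(0.005, 0.995), 10000, 0.7)
    expect_gte(n_snpless, bounds[1])
    expect_lte(n_snpless, bounds[2])
})

test_that("truth planting hits exact counts, baselines and adjacency", {
    gm <- toy_genome(c(chrA = 10L, chrB = 10L))

    tr0 <- plantTruth(gm, 0, 0, 0, seed = 1)
    expect_true(all(tr0$planted_class == "none"))
    expect_true(all(tr0$maternal_fraction_endosperm == 2 / 3))
    expect_true(all(tr0$maternal_fraction_embryo == 1 / 2))

    tr <- plantTruth(gm, 5, 2, 1, 0.95, 0.10, seed = 3)
    expect_equal(sum(tr$planted_class == "MEG"), 5L)
    expect_equal(sum(tr$planted_class == "PEG"), 2L)
    expect_equal(sum(tr$maternal_fraction_endosperm != 2 / 3), 7L)
    expect_true(all(tr$maternal_fraction_endosperm[tr$planted_class == "MEG"] > 2 / 3))
    expect_true(all(tr$maternal_fraction_endosperm[tr$planted_class == "PEG"] < 2 / 3))

    # at least one planted adjacent pair, in rank order on one chromosome
    rk <- S4Vectors::mcols(geneModels(gm))$rank
    chr <- as.character(GenomicRanges::seqnames(geneModels(gm)))
    imp <- which(tr$planted_class != "none")
    adj <- any(diff(imp) == 1 & chr[imp[-1]] == chr[imp[-length(imp)]] &
               rk[imp[-1]] == rk[imp[-length(imp)]] + 1)
    expect_true(adj)
    expect_equal(sum(tr$in_planted_cluster), 2L)

    expect_error(plantTruth(gm, 2, 0, 2, seed = 1), "cluster")
    expect_error(plantTruth(gm, 50, 0, 0, seed = 1), "more imprinted genes")
    expect_error(plantTruth(gm, 1, 0, 0, megMaternalFraction = 0.5), "2/3")
})

test_that("simulated ASR counts converge to the parental genomic baselines", {
    gm <- simulateGenome(1, 400, 500, 200, seed = 21)
    vs <- simulateVariants(gm, 1, 1, 0, seed = 22)
    tr <- plantTruth(gm, 0, 0, 0, seed = 23)
    d <- reciprocalCrossDesign("A", "B")
    rec <- simulateAsrCounts(gm, vs, tr, d, meanDepth = 80, dispersion = 5,
                             seed = 24)
    for (ti in c("endosperm", "embryo")) {
        sub <- rec[rec$tissue == ti, ]
        share <- sum(sub$maternal_asr) / sum(sub$maternal_asr + sub$paternal_asr)
        expected <- if (ti == "endosperm") 2 / 3 else 1 / 2
        # ~64k reads pooled per tissue: binomial SE < 0.002
        expect_lt(abs(share - expected), 0.01)
    }
    # orientation follows the female parent in BOTH crosses of the pair
    for (cr in unique(rec$cross_id)) {
        sub <- rec[rec$cross_id == cr & rec$tissue == "endosperm", ]
        expect_lt(abs(sum(sub$maternal_asr) /
                      sum(sub$maternal_asr + sub$paternal_asr) - 2 / 3), 0.02)
    }
})

test_that("planted MEGs emit maternal counts at the planted fraction", {
    gm <- simulateGenome(1, 200, 500, 200, seed = 31)
    vs <- simulateVariants(gm, 1, 1, 0, seed = 32)
    tr <- plantTruth(gm, 100, 0, 0, megMaternalFraction = 0.95, seed = 33)
    d <- reciprocalCrossDesign("A", "B", tissues = "endosperm")
    rec <- simulateAsrCounts(gm, vs, tr, d, meanDepth = 100, dispersion = Inf,
                             seed = 34)
    meg <- rec$gene_id %in% tr$gene_id[tr$planted_class == "MEG"]
    expect_lt(abs(mean(rec$maternal_asr[meg]) - 95), 2)
    expect_lt(abs(sum(rec$maternal_asr[meg]) /
                  sum((rec$maternal_asr + rec$paternal_asr)[meg]) - 0.95), 0.01)
})

test_that("no-SNP and no-ASR genes emit zero reads; detectable genes never all-zero", {
    gm <- simulateGenome(1, 100, 500, 200, seed = 41)
    vs <- simulateVariants(gm, 0.5, 2, 0, seed = 42)
    tr <- plantTruth(gm, 0, 0, 0, seed = 43)
    d <- reciprocalCrossDesign("A", "B")
    rec <- simulateAsrCounts(gm, vs, tr, d, meanDepth = 100,
                             pNoAsrGivenSnp = 0.3, seed = 44)
    tot <- tapply(rec$maternal_asr + rec$paternal_asr, rec$gene_id, sum)
    snpless <- names(which(variantCount(vs, geneIds(gm)) == 0L))
    expect_true(all(tot[snpless] == 0L))

    # with every gene informative and no read dropout, nothing is lost
    vs_all <- simulateVariants(gm, 1, 1, 0, seed = 45)
    rec2 <- simulateAsrCounts(gm, vs_all, tr, d, meanDepth = 100,
                              pNoAsrGivenSnp = 0, seed = 46)
    tot2 <- tapply(rec2$maternal_asr + rec2$paternal_asr, rec2$gene_id, sum)
    expect_true(all(tot2 > 0L))

    # fixed seed => bit-identical tables
    expect_identical(rec, simulateAsrCounts(gm, vs, tr, d, meanDepth = 100,
                                            pNoAsrGivenSnp = 0.3, seed = 44))
    # truth/genome consistency is enforced
    bad <- tr; bad$gene_id[1] <- "nonexistent"
    expect_error(simulateAsrCounts(gm, vs, bad, d, seed = 1), "absent")
})
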