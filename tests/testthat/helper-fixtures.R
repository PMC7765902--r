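# Fixtures built in code: tiny deterministic genomes, variant sets and
# designs used across the test files.

# A toy genome with explicitly placed genes: `sizes` gives genes per
# chromosome; genes are 100 bp with 50 bp gaps, so adjacency in rank order
# is fully controlled.
toy_genome <- function(sizes = c(chrA = 5L, chrB = 5L)) {
    rows <- list()
    for (i in seq_along(sizes)) {
        n <- sizes[[i]]
        chrom <- names(sizes)[i]
        start <- 50L + (seq_len(n) - 1L) * 150L
        rows[[i]] <- data.frame(chrom = chrom, start = start,
                                end = start + 99L,
                                gene_id = sprintf("%s_g%02d", chrom, seq_len(n)))
    }
    tab <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
        tab$chrom, IRanges::IRanges(tab$start, tab$end), strand = "+",
        gene_id = tab$gene_id)
    GenomeInfoDb::seqlengths(gr) <- vapply(split(tab$end, tab$chrom), max,
                                           numeric(1))[unique(tab$chrom)] + 50L
    makeGenomeModel(gr)
}

variant_df <- function(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       gene_id = NA_character_) {
    if (!length(chrom))
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene_id = character()))
    data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
               gene_id = gene_id)
}

make_variant_set <- function(snps = variant_df(), indels = variant_df()) {
    new("VariantSet", snps = snps, indels = indels)
}

# One reciprocal pair, endosperm only, as used by the caller tests.
endosperm_pair <- function() {
    reciprocalCrossDesign("A", "B", pairId = "AB", tissues = "endosperm")
}

# Hand-rolled ASR records for one gene in both crosses of a pair.
asr_record <- function(design, gene_id, m, p, tissue = "endosperm") {
    sa <- merge(sampleTable(design), crossTable(design), by = "cross_id")
    sa <- sa[sa$tissue == tissue, ]
    sa <- sa[order(sa$cross_id), ]
    stopifnot(nrow(sa) == length(m))
    data.frame(gene_id = gene_id, sample_id = sa$sample_id,
               cross_id = sa$cross_id, tissue = tissue,
               maternal_asr = m, paternal_asr = p)
}

# A complete small synthetic run shared by ledger/pipeline tests.
synthetic_run <- function(seed = 42L, n_genes = 120L, p_snp = 0.7,
                          p_no_asr = 0.1, n_meg = 8L, n_peg = 3L) {
    gm <- simulateGenome(2, n_genes / 2, 1000, 500, seed = seed)
    vs <- simulateVariants(gm, p_snp, 2, 0.1, seed = seed + 1L)
    tr <- plantTruth(gm, n_meg, n_peg, 1, seed = seed + 2L)
    d <- reciprocalCrossDesign("ZH11", "Nip")
    rec <- simulateAsrCounts(gm, vs, tr, d, meanDepth = 100, dispersion = 10,
                             pNoAsrGivenSnp = p_no_asr, seed = seed + 3L)
    calls <- callImprinting(rec, d)
    list(genome = gm, variants = vs, truth = tr, design = d,
         records = rec, calls = calls)
}
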