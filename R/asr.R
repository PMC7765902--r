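#' Fragments per kilobase of exon model per million mapped fragments
#'
#' \code{fpkm = count / (length/1000) / (librarySize/1e6)}. Vectorised over
#' \code{fragmentCount} and \code{geneLength}.
#'
#' @param fragmentCount mapped fragment count(s) for the gene
#' @param geneLength gene (exon model) length in bp, > 0
#' @param librarySize total mapped fragments in the library, > 0
#' @return numeric FPKM value(s)
#' @examples
#' computeFpkm(10, 1000, 1e6)   # 10
#' @export
computeFpkm <- function(fragmentCount, geneLength, librarySize) {
    if (any(geneLength <= 0)) stop("'geneLength' must be positive")
    if (any(librarySize <= 0)) stop("'librarySize' must be positive")
    if (any(fragmentCount < 0)) stop("'fragmentCount' must be non-negative")
    fragmentCount / (geneLength / 1000) / (librarySize / 1e6)
}

#' Expressed-gene filter
#'
#' A gene is expressed in a sample iff its FPKM strictly exceeds the
#' threshold (default 0.5); a gene sitting exactly at the threshold is
#' excluded.
#'
#' @param records data.frame with columns \code{gene_id, sample_id, fpkm}
#' @param threshold FPKM cutoff, strict
#' @return the subset of \code{records} passing the filter
#' @export
filterExpressed <- function(records, threshold = 0.5) {
    stopifnot(all(c("gene_id", "sample_id", "fpkm") %in% colnames(records)))
    records[records$fpkm > threshold, , drop = FALSE]
}

#' Assign reads to parental genomes via informative SNPs
#'
#' A read is an allele-specific read (ASR) for a parent iff every informative
#' site it covers supports that parent's allele. Reads covering no informative
#' site, reads whose covered sites support both parents (conflicting), and
#' reads carrying an allele matching neither parent ("other") are discarded
#' and tallied per gene.
#'
#' @param observations data.frame with one row per read x covered site:
#'   \code{read_id, gene_id, chrom, pos, allele}
#' @param variants a [VariantSet-class]; the ref allele belongs to one parent
#'   and the alt allele to the other
#' @param parentOfAllele named character of length 2, e.g.
#'   \code{c(ref = "Nip", alt = "ZH11")}, naming the parent carrying each
#'   allele
#' @return data.frame with one row per gene: a read-count column per parent
#'   (named by the parent), plus \code{discarded} (conflicting + other +
#'   uninformative reads)
#' @export
assignReads <- function(observations, variants, parentOfAllele) {
    need <- c("read_id", "gene_id", "chrom", "pos", "allele")
    stopifnot(all(need %in% colnames(observations)),
              is(variants, "VariantSet"),
              all(c("ref", "alt") %in% names(parentOfAllele)))
    snp <- snpTable(variants)
    key <- function(chrom, pos) paste(chrom, pos, sep = ":")
    informative <- !is.na(observations$pos)   # NA pos: read covers no SNP
    idx <- rep(NA_integer_, nrow(observations))
    idx[informative] <- match(
        key(observations$chrom, observations$pos)[informative],
        key(snp$chrom, snp$pos))
    if (any(informative & is.na(idx)))
        stop("observation at a position not present in the variant set: ",
             key(observations$chrom, observations$pos)[
                 which(informative & is.na(idx))[1]])
    support <- rep("none", nrow(observations))
    support[informative] <-
        ifelse(observations$allele[informative] == snp$ref[idx[informative]], "ref",
        ifelse(observations$allele[informative] == snp$alt[idx[informative]], "alt",
               "other"))
    per_read <- split(support, observations$read_id)
    read_gene <- vapply(split(observations$gene_id, observations$read_id),
                        function(g) g[1], character(1))
    verdict <- vapply(per_read, function(s) {
        s <- setdiff(unique(s), "none")
        if (!length(s)) "uninformative"
        else if ("other" %in% s) "other"
        else if (length(s) == 1L) s          # all sites one parent
        else "conflict"
    }, character(1))
    genes <- sort(unique(observations$gene_id))
    count <- function(v) as.integer(table(factor(read_gene[verdict == v],
                                                 levels = genes)))
    out <- data.frame(gene_id = genes,
                      ref_parent = count("ref"),
                      alt_parent = count("alt"),
                      discarded = count("other") + count("conflict") +
                          count("uninformative"))
    names(out)[2:3] <- unname(parentOfAllele[c("ref", "alt")])
    out
}

#' Orient parent-line read counts to maternal/paternal per the cross design
#'
#' Re-labels per-parent ASR counts as maternal or paternal using each cross's
#' female parent, the orientation step that makes the two crosses of a
#' reciprocal pair comparable. Genes with zero counts are retained so the
#' detectability ledger can account for them.
#'
#' @param parentCounts data.frame in long form: \code{gene_id, sample_id,
#'   parent, reads}, where \code{parent} names the parental line the reads
#'   were assigned to
#' @param design a [CrossDesign-class]; each \code{sample_id} must belong to
#'   a known cross
#' @return data.frame \code{gene_id, sample_id, cross_id, tissue,
#'   maternal_asr, paternal_asr}
#' @export
tabulateAsr <- function(parentCounts, design) {
    need <- c("gene_id", "sample_id", "parent", "reads")
    stopifnot(all(need %in% colnames(parentCounts)), is(design, "CrossDesign"))
    sa <- merge(sampleTable(design), crossTable(design), by = "cross_id",
                sort = FALSE)
    if (!all(parentCounts$sample_id %in% sa$sample_id))
        stop("unknown sample_id in parentCounts: ",
             setdiff(parentCounts$sample_id, sa$sample_id)[1])
    x <- merge(parentCounts, sa, by = "sample_id", sort = FALSE)
    bad <- !(x$parent == x$female_parent | x$parent == x$male_parent)
    if (any(bad))
        stop("parent label not in the sample's cross: ", x$parent[bad][1])
    x$role <- ifelse(x$parent == x$female_parent, "maternal_asr", "paternal_asr")
    wide <- stats::reshape(
        x[, c("gene_id", "sample_id", "cross_id", "tissue", "role", "reads")],
        idvar = c("gene_id", "sample_id", "cross_id", "tissue"),
        timevar = "role", direction = "wide")
    names(wide) <- sub("^reads\\.", "", names(wide))
    for (col in c("maternal_asr", "paternal_asr")) {
        if (!col %in% names(wide)) wide[[col]] <- 0L
        wide[[col]][is.na(wide[[col]])] <- 0L
    }
    rownames(wide) <- NULL
    wide[, c("gene_id", "sample_id", "cross_id", "tissue",
             "maternal_asr", "paternal_asr")]
}

#' Detectability ledger: why each gene is, or is not, called imprinted
#'
#' For each reciprocal pair, classifies every gene of the genome into exactly
#' one of four statuses: \code{no_SNP} (no parental variant, so parental
#' origin is unreadable), \code{no_ASR} (variants exist but no allele-specific
#' read covers them in any sample of the pair), \code{imprinted} (called MEG
#' or PEG), or \code{non_significant} (testable but not called). The statuses
#' partition the assessed genes, so per-pair counts sum to the gene total.
#'
#' @param genome a [GenomeModel-class]
#' @param variants a [VariantSet-class]
#' @param records ASR count table (see [simulateAsrCounts()])
#' @param calls imprinting calls from [callImprinting()]
#' @param design a [CrossDesign-class]
#' @return data.frame \code{pair_id, gene_id, status}
#' @export
detectabilityLedger <- function(genome, variants, records, calls, design) {
    stopifnot(is(genome, "GenomeModel"), is(variants, "VariantSet"),
              is(design, "CrossDesign"))
    ids <- geneIds(genome)
    has_snp <- variantCount(variants, ids) > 0L
    sa <- merge(sampleTable(design), crossTable(design), by = "cross_id",
                sort = FALSE)
    out <- list()
    for (pair in unique(crossTable(design)$pair_id)) {
        pair_samples <- sa$sample_id[sa$pair_id == pair]
        rec <- records[records$sample_id %in% pair_samples, , drop = FALSE]
        tot <- tapply(rec$maternal_asr + rec$paternal_asr,
                      factor(rec$gene_id, levels = ids), sum, default = 0L)
        pc <- calls[calls$pair_id == pair, , drop = FALSE]
        imprinted <- ids %in% pc$gene_id[pc$class %in% c("MEG", "PEG")]
        status <- ifelse(!has_snp, "no_SNP",
                  ifelse(tot == 0L, "no_ASR",
                  ifelse(imprinted, "imprinted", "non_significant")))
        out[[pair]] <- data.frame(pair_id = pair, gene_id = ids,
                                  status = unname(status))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Summarise a detectability ledger into per-pair status counts
#'
#' @param ledger output of [detectabilityLedger()]
#' @return data.frame with one row per pair and columns \code{imprinted,
#'   non_significant, no_SNP, no_ASR, total}
#' @export
summarizeLedger <- function(ledger) {
    lv <- c("imprinted", "non_significant", "no_SNP", "no_ASR")
    tab <- table(ledger$pair_id, factor(ledger$status, levels = lv))
    out <- as.data.frame.matrix(tab)
    out$total <- rowSums(out)
    out <- cbind(pair_id = rownames(out), out)
    rownames(out) <- NULL
    out
}
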