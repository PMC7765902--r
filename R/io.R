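#' @importFrom utils write.table read.delim
NULL

#' Construct a GenomeModel from a GRanges of gene intervals
#'
#' Sorts the ranges, recomputes per-chromosome ranks and validates the
#' non-overlap invariant. Used by the GFF3/BED readers and available for
#' building a model from any annotation source.
#'
#' @param gr GRanges with a \code{gene_id} metadata column; seqlengths may be
#'   missing, in which case each chromosome length defaults to the last gene
#'   end plus 1 kb
#' @return a [GenomeModel-class]
#' @export
makeGenomeModel <- function(gr) {
    stopifnot(is(gr, "GRanges"), "gene_id" %in% colnames(mcols(gr)))
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    if (any(is.na(seqlengths(gr)))) {
        mx <- vapply(split(end(gr), as.character(seqnames(gr))), max, numeric(1))
        sl <- seqlengths(gr)
        miss <- names(sl)[is.na(sl)]
        sl[miss] <- mx[miss] + 1000L
        seqlengths(gr) <- sl
    }
    ord <- order(as.integer(as.factor(seqnames(gr))), start(gr))
    rank <- integer(length(gr))
    rank[ord] <- unlist(lapply(table(as.factor(seqnames(gr))), seq_len),
                        use.names = FALSE)
    mcols(gr)$rank <- rank
    new("GenomeModel", genes = gr)
}

#' Write / read a genome sequence as FASTA
#'
#' @param sequence a \link[Biostrings]{DNAStringSet}
#' @param path output file
#' @return \code{writeGenomeFasta} returns \code{path} invisibly;
#'   \code{readGenomeFasta} returns a DNAStringSet with first-word names.
#' @export
writeGenomeFasta <- function(sequence, path) {
    Biostrings::writeXStringSet(sequence, filepath = path)
    invisible(path)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    x
}

#' Write gene models as BED6 or GFF3
#'
#' BED is 0-based half-open, GFF3 1-based closed; both conversions are done
#' by rtracklayer.
#'
#' @param genome a [GenomeModel-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeGenesBed <- function(genome, path) {
    gr <- geneModels(genome)
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
    mcols(out)$name <- mcols(gr)$gene_id
    mcols(out)$score <- 0L
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' @rdname writeGenesBed
#' @export
writeGenesGff3 <- function(genome, path) {
    gr <- geneModels(genome)
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
    mcols(out)$type <- "gene"
    mcols(out)$ID <- mcols(gr)$gene_id
    mcols(out)$source <- "ImprintScan"
    rtracklayer::export(out, path, format = "GFF3")
    invisible(path)
}

#' Read gene models from BED or GFF3 into a GenomeModel
#'
#' @param path a BED or GFF3 file; format is inferred from the extension
#' @return a [GenomeModel-class]
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path)
    id <- if ("ID" %in% colnames(mcols(gr))) mcols(gr)$ID
          else if ("name" %in% colnames(mcols(gr))) mcols(gr)$name
          else stop("no gene identifier column (ID or name) in ", path)
    if ("type" %in% colnames(mcols(gr))) {
        keep <- as.character(mcols(gr)$type) == "gene"
        gr <- gr[keep]; id <- id[keep]
    }
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
    mcols(out)$gene_id <- as.character(id)
    makeGenomeModel(out)
}

# Convert the internal (non-anchored) indel representation to VCF anchored
# records, which need the base preceding the event.
.anchor_indels <- function(indels, reference) {
    if (!nrow(indels)) return(indels)
    if (any(indels$pos == 1L))
        stop("cannot anchor an indel at position 1 for VCF output")
    anchor <- vapply(seq_len(nrow(indels)), function(k) {
        as.character(Biostrings::subseq(reference[[indels$chrom[k]]],
                                        indels$pos[k] - 1L, indels$pos[k] - 1L))
    }, character(1))
    data.frame(chrom = indels$chrom, pos = indels$pos - 1L,
               ref = paste0(anchor, indels$ref),
               alt = paste0(anchor, indels$alt),
               gene_id = indels$gene_id)
}

#' Write / read a VariantSet as VCF 4.2
#'
#' Internally indels are stored without the VCF anchor base (an empty alt is
#' a deletion, an empty ref an insertion before \code{pos}); on writing, the
#' preceding reference base is prepended per VCF convention, and on reading
#' shared leading bases are stripped again. Multi-allelic records are
#' rejected: the variant model is strictly homozygous-parental.
#'
#' @param variants a [VariantSet-class]
#' @param reference the reference \link[Biostrings]{DNAStringSet} (needed to
#'   anchor indels)
#' @param path output .vcf file
#' @return \code{path}, invisibly
#' @export
writeVariantsVcf <- function(variants, reference, path) {
    stopifnot(is(variants, "VariantSet"), is(reference, "DNAStringSet"))
    tab <- rbind(snpTable(variants),
                 .anchor_indels(indelTable(variants), reference))
    tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
    if (!nrow(tab))
        stop("refusing to write an empty VCF")
    vr <- VariantAnnotation::VRanges(
        seqnames = tab$chrom,
        ranges = IRanges(tab$pos, width = nchar(tab$ref)),
        ref = tab$ref, alt = tab$alt, sampleNames = "parental")
    sl <- stats::setNames(Biostrings::width(reference), names(reference))
    GenomeInfoDb::seqlengths(vr) <- sl[GenomeInfoDb::seqlevels(vr)]
    VariantAnnotation::writeVcf(vr, path)
    invisible(path)
}

#' @rdname writeVariantsVcf
#' @param genome optional [GenomeModel-class]; when given, each variant is
#'   assigned the gene whose interval contains it (NA otherwise)
#' @return \code{readVariantsVcf} returns a [VariantSet-class]
#' @export
readVariantsVcf <- function(path, genome = NULL) {
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    alt_list <- VariantAnnotation::alt(v)
    if (any(lengths(alt_list) != 1L))
        stop("multi-allelic VCF records are not supported")
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    ref <- as.character(VariantAnnotation::ref(v))
    alt <- as.character(unlist(alt_list))
    # strip the shared VCF anchor base from indels
    is_indel <- nchar(ref) != nchar(alt)
    strip <- is_indel & substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
    ref[strip] <- substring(ref[strip], 2L)
    alt[strip] <- substring(alt[strip], 2L)
    pos[strip] <- pos[strip] + 1L
    gene_id <- rep(NA_character_, length(pos))
    if (!is.null(genome)) {
        q <- GRanges(chrom, IRanges(pos, pos + pmax(nchar(ref) - 1L, 0L)))
        hits <- GenomicRanges::findOverlaps(q, geneModels(genome), select = "first")
        gene_id <- geneIds(genome)[hits]
    }
    df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     gene_id = gene_id)
    snp <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
    out <- new("VariantSet", snps = df[snp, , drop = FALSE],
               indels = df[!snp, , drop = FALSE])
    out
}

#' Write / read the per-gene allele-specific count table (TSV)
#'
#' Columns: \code{gene_id sample_id cross_id tissue maternal_asr paternal_asr}.
#'
#' @param records data.frame as produced by [simulateAsrCounts()] or
#'   [tabulateAsr()]
#' @param path a .tsv file
#' @return \code{path} (writer) or the data.frame (reader)
#' @export
writeAsrTable <- function(records, path) {
    need <- c("gene_id", "sample_id", "cross_id", "tissue",
              "maternal_asr", "paternal_asr")
    stopifnot(all(need %in% colnames(records)))
    write.table(records[, need], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeAsrTable
#' @export
readAsrTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "sample_id", "cross_id", "tissue",
              "maternal_asr", "paternal_asr")
    if (!all(need %in% colnames(df)))
        stop("ASR table must have columns ", paste(need, collapse = " "))
    df
}

#' Write / read a CrossDesign as two TSV tables
#'
#' @param design a [CrossDesign-class]
#' @param crossesPath,samplesPath paths for the cross table
#'   (\code{cross_id female_parent male_parent pair_id}) and the sample table
#'   (\code{sample_id cross_id tissue replicate})
#' @return the paths (writer) or a [CrossDesign-class] (reader)
#' @export
writeCrossDesign <- function(design, crossesPath, samplesPath) {
    stopifnot(is(design, "CrossDesign"))
    write.table(crossTable(design), crossesPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sampleTable(design), samplesPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(crossesPath, samplesPath))
}

#' @rdname writeCrossDesign
#' @export
readCrossDesign <- function(crossesPath, samplesPath) {
    new("CrossDesign",
        crosses = read.delim(crossesPath, stringsAsFactors = FALSE),
        samples = read.delim(samplesPath, stringsAsFactors = FALSE))
}

#' Write the liftover map as a five-column TSV
#'
#' Columns \code{chrom ref_start ref_end pseudo_start pseudo_end}, 1-based
#' closed conserved blocks.
#'
#' @param map a [LiftoverMap-class]
#' @param path a .tsv file
#' @return \code{path}, invisibly
#' @export
writeLiftoverTable <- function(map, path) {
    stopifnot(is(map, "LiftoverMap"))
    write.table(map@blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene-set file (one identifier per line)
#'
#' Blank lines and lines starting with '#' are skipped.
#'
#' @param path text file
#' @return character vector of identifiers
#' @export
readGeneSet <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a directed similarity score table
#'
#' Three tab-separated columns \code{query subject score} (a BLAST
#' outfmt-6-compatible subset), as consumed by [bhrMatch()].
#'
#' @param path a .tsv file, with or without a header line
#' @return data.frame with columns query, subject, score
#' @export
readScoreTable <- function(path) {
    first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
    header <- suppressWarnings(is.na(as.numeric(first[3])))
    df <- read.delim(path, header = header, stringsAsFactors = FALSE)
    df <- df[, 1:3]
    colnames(df) <- c("query", "subject", "score")
    if (!is.numeric(df$score)) stop("third column must be numeric scores")
    df
}
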