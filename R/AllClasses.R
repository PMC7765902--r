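#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame mcols metadata runValue
#' @importFrom S4Vectors "mcols<-"
#' @importFrom GenomeInfoDb "seqlengths<-"
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' GenomeModel: an ordered gene catalogue on named chromosomes
#'
#' Holds gene models as a \link[GenomicRanges]{GRanges} sorted by chromosome
#' and start, with per-chromosome gene rank order in \code{mcols(genes)$rank}.
#' Gene intervals on a chromosome are non-overlapping, so rank order equals
#' physical order; adjacency in rank ("no intervening gene") is the notion of
#' tandem neighborhood used by the mini-cluster detector.
#'
#' @slot genes GRanges with metadata columns \code{gene_id} (unique character)
#'   and \code{rank} (1-based rank within its chromosome).
#'
#' @seealso [simulateGenome()], [findMiniClusters()], [neighborNull()]
#' @export
setClass("GenomeModel", representation(genes = "GRanges"))

setValidity("GenomeModel", function(object) {
    gr <- object@genes
    msg <- character()
    if (!all(c("gene_id", "rank") %in% colnames(mcols(gr))))
        return("genes must carry 'gene_id' and 'rank' metadata columns")
    if (anyDuplicated(mcols(gr)$gene_id))
        msg <- c(msg, "gene_id values must be unique")
    if (length(gr)) {
        if (any(is.na(seqlengths(gr))))
            msg <- c(msg, "all chromosomes must have a declared length")
        sp <- split(gr, seqnames(gr))
        for (chr in names(sp)) {
            g <- sp[[chr]]
            if (length(g) < 2L) next
            if (is.unsorted(start(g), strictly = TRUE))
                msg <- c(msg, sprintf("genes on %s are not sorted by start", chr))
            if (any(start(g)[-1L] <= end(g)[-length(g)]))
                msg <- c(msg, sprintf("genes on %s overlap", chr))
        }
        for (chr in seqlevels(gr)) {
            r <- mcols(gr)$rank[as.logical(seqnames(gr) == chr)]
            if (length(r) && !identical(as.integer(r), seq_along(r)))
                msg <- c(msg, sprintf("ranks on %s are not 1..n in order", chr))
        }
    }
    if (length(msg)) msg else TRUE
})

#' VariantSet: homozygous parental SNPs and InDels
#'
#' Variants distinguishing two parental genomes, in reference coordinates
#' (1-based). SNPs have single-base \code{ref}/\code{alt}; indels have
#' \code{ref}/\code{alt} of unequal length (an empty \code{alt} is a deletion;
#' an empty \code{ref} inserts \code{alt} immediately before \code{pos}).
#' Variants never overlap. Only homozygous parental differences are
#' representable: the ref allele is one parent's, the alt the other's.
#'
#' @slot snps data.frame with columns \code{chrom, pos, ref, alt, gene_id}.
#' @slot indels data.frame with the same columns.
#'
#' @seealso [simulateVariants()], [applyVariants()], [readVariantsVcf()]
#' @export
setClass("VariantSet", representation(snps = "data.frame", indels = "data.frame"))

.variant_cols <- c("chrom", "pos", "ref", "alt", "gene_id")

.variant_footprint <- function(df) {
    # closed interval occupied on the reference; pure insertions (ref == "")
    # occupy the zero-width boundary before pos (end = pos - 1)
    data.frame(chrom = df$chrom, start = df$pos,
               end = ifelse(nchar(df$ref) == 0L, df$pos - 1L,
                            df$pos + nchar(df$ref) - 1L))
}

setValidity("VariantSet", function(object) {
    msg <- character()
    for (nm in c("snps", "indels")) {
        df <- slot(object, nm)
        if (!all(.variant_cols %in% colnames(df)))
            return(sprintf("%s must have columns %s", nm,
                           paste(.variant_cols, collapse = ", ")))
        if (nrow(df) && any(df$pos < 1L))
            msg <- c(msg, sprintf("%s positions must be >= 1", nm))
    }
    sn <- object@snps
    if (nrow(sn) && !all(nchar(sn$ref) == 1L & nchar(sn$alt) == 1L))
        msg <- c(msg, "SNPs must have single-base ref and alt")
    if (nrow(sn) && any(sn$ref == sn$alt))
        msg <- c(msg, "SNP ref and alt must differ")
    ind <- object@indels
    if (nrow(ind) && any(nchar(ind$ref) == nchar(ind$alt)))
        msg <- c(msg, "indels must change sequence length")
    all <- rbind(object@snps, object@indels)
    if (nrow(all) > 1L) {
        fp <- .variant_footprint(all)
        o <- order(fp$chrom, fp$start, fp$end)
        fp <- fp[o, ]
        same <- fp$chrom[-1L] == fp$chrom[-nrow(fp)]
        if (any(same & fp$start[-1L] <= fp$end[-nrow(fp)]))
            msg <- c(msg, "variants overlap on the reference")
    }
    if (length(msg)) msg else TRUE
})

#' LiftoverMap: bidirectional coordinate transfer between reference and
#' pseudo-genome
#'
#' Produced by [applyVariants()]. Conserved blocks pair a reference interval
#' with a pseudo-genome interval of identical width; reference positions not
#' covered by any block were deleted during substitution, and pseudo positions
#' not covered were inserted. Lifting a non-deleted position forward then
#' backward is the identity.
#'
#' @slot blocks data.frame \code{chrom, ref_start, ref_end, pseudo_start,
#'   pseudo_end} (1-based, closed; both sides sorted and non-overlapping).
#' @slot ref_seqlengths named integer, reference chromosome lengths.
#' @slot pseudo_seqlengths named integer, pseudo-genome chromosome lengths.
#'
#' @seealso [liftCoord()]
#' @export
setClass("LiftoverMap",
    representation(blocks = "data.frame",
                   ref_seqlengths = "integer",
                   pseudo_seqlengths = "integer"))

setValidity("LiftoverMap", function(object) {
    b <- object@blocks
    need <- c("chrom", "ref_start", "ref_end", "pseudo_start", "pseudo_end")
    if (!all(need %in% colnames(b)))
        return(sprintf("blocks must have columns %s", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(b)) {
        if (!all(b$ref_end - b$ref_start == b$pseudo_end - b$pseudo_start))
            msg <- c(msg, "paired intervals must have equal widths")
        sp <- split(b, b$chrom)
        for (chr in names(sp)) {
            x <- sp[[chr]]
            if (nrow(x) < 2L) next
            if (is.unsorted(x$ref_start, strictly = TRUE) ||
                any(x$ref_start[-1L] <= x$ref_end[-nrow(x)]))
                msg <- c(msg, sprintf("reference blocks on %s overlap or are unsorted", chr))
            if (is.unsorted(x$pseudo_start, strictly = TRUE) ||
                any(x$pseudo_start[-1L] <= x$pseudo_end[-nrow(x)]))
                msg <- c(msg, sprintf("pseudo blocks on %s overlap or are unsorted", chr))
        }
    }
    if (length(msg)) msg else TRUE
})

#' CrossDesign: reciprocal crosses and their sequenced samples
#'
#' Describes which parent was the female in each cross and groups the two
#' orientations of a reciprocal pair under one \code{pair_id}. Every maternal/
#' paternal orientation decision downstream flows from this table.
#'
#' @slot crosses data.frame \code{cross_id, female_parent, male_parent,
#'   pair_id}; each pair_id contains exactly two crosses with the parents
#'   swapped.
#' @slot samples data.frame \code{sample_id, cross_id, tissue, replicate};
#'   tissue is "endosperm" or "embryo".
#'
#' @seealso [reciprocalCrossDesign()], [tabulateAsr()], [callImprinting()]
#' @export
setClass("CrossDesign",
    representation(crosses = "data.frame", samples = "data.frame"))

setValidity("CrossDesign", function(object) {
    cr <- object@crosses; sa <- object@samples
    msg <- character()
    if (!all(c("cross_id", "female_parent", "male_parent", "pair_id") %in% colnames(cr)))
        return("crosses needs cross_id, female_parent, male_parent, pair_id")
    if (!all(c("sample_id", "cross_id", "tissue", "replicate") %in% colnames(sa)))
        return("samples needs sample_id, cross_id, tissue, replicate")
    if (anyDuplicated(cr$cross_id)) msg <- c(msg, "cross_id values must be unique")
    if (anyDuplicated(sa$sample_id)) msg <- c(msg, "sample_id values must be unique")
    for (p in unique(cr$pair_id)) {
        x <- cr[cr$pair_id == p, ]
        ok <- nrow(x) == 2L &&
            x$female_parent[1L] == x$male_parent[2L] &&
            x$male_parent[1L] == x$female_parent[2L]
        if (!ok)
            msg <- c(msg, sprintf("pair '%s' is not a reciprocal pair (two crosses with swapped parents)", p))
    }
    if (nrow(sa) && !all(sa$tissue %in% c("endosperm", "embryo")))
        msg <- c(msg, "tissue must be 'endosperm' or 'embryo'")
    if (nrow(sa) && !all(sa$cross_id %in% cr$cross_id))
        msg <- c(msg, "every sample must reference a known cross_id")
    if (length(msg)) msg else TRUE
})

#' NullDistribution: replicate values from a permutation simulation
#'
#' Stores one summary statistic per permutation replicate together with the
#' seed that produced them, and answers percentile queries. The upper
#' percentile uses the inverse-ECDF convention (smallest stored value k such
#' that at least the requested fraction of replicates is <= k), so integer
#' statistics yield integer bounds.
#'
#' @slot values numeric, one value per replicate.
#' @slot reps integer, number of replicates (= length(values)).
#' @slot seed integer or NULL, RNG seed used.
#' @slot statistic character, label of the simulated statistic.
#'
#' @seealso [neighborNull()], [overlapNull()], [nullQuantile()], [excessTest()]
#' @export
setClass("NullDistribution",
    representation(values = "numeric", reps = "integer",
                   seed = "integerOrNULL", statistic = "character"))

setValidity("NullDistribution", function(object) {
    msg <- character()
    if (length(object@values) != object@reps)
        msg <- c(msg, "number of stored values must equal reps")
    if (object@reps < 1L) msg <- c(msg, "reps must be >= 1")
    if (length(msg)) msg else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "GenomeModel", function(object) {
    gr <- object@genes
    cat(sprintf("GenomeModel with %d genes on %d chromosomes\n",
                length(gr), length(seqlevels(gr))))
    sl <- seqlengths(gr)
    if (length(sl))
        cat("  ", paste(sprintf("%s (%d bp)", names(sl), sl), collapse = ", "),
            "\n", sep = "")
})

setMethod("show", "VariantSet", function(object) {
    cat(sprintf("VariantSet with %d SNPs and %d InDels\n",
                nrow(object@snps), nrow(object@indels)))
})

setMethod("show", "LiftoverMap", function(object) {
    cat(sprintf("LiftoverMap: %d conserved blocks on %d chromosomes\n",
                nrow(object@blocks), length(unique(object@blocks$chrom))))
})

setMethod("show", "CrossDesign", function(object) {
    cat(sprintf("CrossDesign: %d crosses in %d reciprocal pairs, %d samples\n",
                nrow(object@crosses), length(unique(object@crosses$pair_id)),
                nrow(object@samples)))
})

setMethod("show", "NullDistribution", function(object) {
    cat(sprintf("NullDistribution of '%s': %d replicates (seed %s)\n",
                object@statistic, object@reps,
                if (is.null(object@seed)) "unset" else object@seed))
    cat(sprintf("  mean %.4g, upper 95th percentile %.4g\n",
                mean(object@values), nullQuantile(object, 0.95)))
})

## ---- accessors --------------------------------------------------------

#' @rdname GenomeModel-class
#' @param x a GenomeModel
#' @return \code{geneModels()} returns the GRanges of gene models;
#'   \code{geneIds()} the character vector of gene identifiers in genomic
#'   order; \code{nGenes()} the gene count.
#' @export
geneModels <- function(x) {
    stopifnot(is(x, "GenomeModel"))
    x@genes
}

#' @rdname GenomeModel-class
#' @export
geneIds <- function(x) mcols(geneModels(x))$gene_id

#' @rdname GenomeModel-class
#' @export
nGenes <- function(x) length(geneModels(x))

#' @rdname VariantSet-class
#' @param x a VariantSet
#' @return \code{snpTable()} / \code{indelTable()} return the underlying
#'   data.frames; \code{variantCount()} the per-gene number of variants,
#'   named by gene_id.
#' @export
snpTable <- function(x) {
    stopifnot(is(x, "VariantSet"))
    x@snps
}

#' @rdname VariantSet-class
#' @export
indelTable <- function(x) {
    stopifnot(is(x, "VariantSet"))
    x@indels
}

#' @rdname VariantSet-class
#' @param geneIds character vector of gene ids to tally over (zero counts
#'   included); defaults to the ids present in the set.
#' @export
variantCount <- function(x, geneIds = NULL) {
    all <- rbind(snpTable(x), indelTable(x))
    ids <- all$gene_id[!is.na(all$gene_id)]
    if (is.null(geneIds)) geneIds <- sort(unique(ids))
    n <- table(factor(ids, levels = geneIds))
    stats::setNames(as.integer(n), geneIds)
}

#' @rdname CrossDesign-class
#' @param x a CrossDesign
#' @return \code{crossTable()} / \code{sampleTable()} return the underlying
#'   data.frames.
#' @export
crossTable <- function(x) {
    stopifnot(is(x, "CrossDesign"))
    x@crosses
}

#' @rdname CrossDesign-class
#' @export
sampleTable <- function(x) {
    stopifnot(is(x, "CrossDesign"))
    x@samples
}

#' @rdname NullDistribution-class
#' @param x a NullDistribution
#' @return \code{nullValues()} returns the replicate values; \code{nullReps()}
#'   the replicate count.
#' @export
nullValues <- function(x) {
    stopifnot(is(x, "NullDistribution"))
    x@values
}

#' @rdname NullDistribution-class
#' @export
nullReps <- function(x) {
    stopifnot(is(x, "NullDistribution"))
    x@reps
}

#' Upper percentile of a permutation null
#'
#' Inverse-ECDF (type 1) quantile of the replicate values: the smallest
#' stored value v such that at least \code{level} of the replicates are
#' <= v. For integer-valued statistics (set overlaps) this is the integer
#' bound reported by the conservation simulations.
#'
#' @param x a NullDistribution
#' @param level quantile level in (0, 1); default 0.95
#' @return a single numeric value
#' @export
nullQuantile <- function(x, level = 0.95) {
    stopifnot(is(x, "NullDistribution"), level > 0, level < 1)
    unname(stats::quantile(x@values, probs = level, type = 1L, names = FALSE))
}
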