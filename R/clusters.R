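#' Detect mini clusters of imprinted genes
#'
#' A mini cluster is a maximal run of two or more imprinted genes occupying
#' consecutive positions in a chromosome's gene rank order, i.e. tandemly
#' located with no intervening annotated gene. Adjacency never crosses a
#' chromosome boundary. The cluster type is \code{maternal_only} if all
#' members are MEGs, \code{paternal_only} if all are PEGs, and
#' \code{maternal_paternal} otherwise.
#'
#' @param imprinted data.frame with columns \code{gene_id} and \code{class}
#'   ("MEG" or "PEG"); every gene must exist in the genome
#' @param genome a [GenomeModel-class]
#' @return data.frame with one row per cluster: \code{cluster_id, chrom,
#'   members} (comma-separated gene ids in genomic order), \code{size,
#'   cluster_type}
#' @export
findMiniClusters <- function(imprinted, genome) {
    stopifnot(all(c("gene_id", "class") %in% colnames(imprinted)),
              is(genome, "GenomeModel"))
    gr <- geneModels(genome)
    ids <- mcols(gr)$gene_id
    miss <- setdiff(imprinted$gene_id, ids)
    if (length(miss))
        stop("imprinted gene(s) absent from genome: ", miss[1])
    idx <- sort(match(unique(imprinted$gene_id), ids))
    empty <- data.frame(cluster_id = character(), chrom = character(),
                        members = character(), size = integer(),
                        cluster_type = character())
    if (length(idx) < 2L) return(empty)
    chrom <- as.character(seqnames(gr))[idx]
    rank <- mcols(gr)$rank[idx]
    # runs of consecutive ranks on one chromosome
    brk <- c(TRUE, !(chrom[-1L] == chrom[-length(chrom)] &
                     rank[-1L] == rank[-length(rank)] + 1L))
    run <- cumsum(brk)
    cls <- imprinted$class[match(ids[idx], imprinted$gene_id)]
    rows <- lapply(split(seq_along(idx), run), function(i) {
        if (length(i) < 2L) return(NULL)
        classes <- unique(cls[i])
        data.frame(chrom = chrom[i[1L]],
                   members = paste(ids[idx[i]], collapse = ","),
                   size = length(i),
                   cluster_type = if (identical(classes, "MEG")) "maternal_only"
                                  else if (identical(classes, "PEG")) "paternal_only"
                                  else "maternal_paternal")
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(empty)
    res <- do.call(rbind, rows)
    res <- cbind(cluster_id = sprintf("cluster_%03d", seq_len(nrow(res))), res)
    rownames(res) <- NULL
    res
}

#' Fraction of imprinted genes that sit in a mini cluster
#'
#' @param clusters output of [findMiniClusters()]
#' @param nImprinted total number of imprinted genes considered
#' @return \code{sum(cluster sizes) / nImprinted}
#' @export
clusteredFraction <- function(clusters, nImprinted) {
    if (nImprinted <= 0) stop("'nImprinted' must be positive")
    if (nrow(clusters) == 0L) return(0)
    sum(clusters$size) / nImprinted
}

#' Neighbor-permutation null for the clustered fraction
#'
#' In each replicate, \code{nSelect} genes are drawn uniformly without
#' replacement from the genome and the fraction of drawn genes having at
#' least one drawn immediate rank-neighbor on the same chromosome is
#' recorded. This is the null distribution against which the observed
#' clustered fraction of imprinted genes is compared: if random draws of the
#' same size cluster far less, tandem location of imprinted genes is not a
#' sampling artifact.
#'
#' @param genome a [GenomeModel-class]
#' @param nSelect genes drawn per replicate (<= total gene count)
#' @param reps number of replicates
#' @param seed integer RNG seed
#' @return a [NullDistribution-class] of statistic "clustered_fraction"
#' @export
neighborNull <- function(genome, nSelect, reps = 10000L, seed = NULL) {
    stopifnot(is(genome, "GenomeModel"))
    nSelect <- assert_count(nSelect, "nSelect")
    reps <- assert_count(reps, "reps")
    gr <- geneModels(genome)
    n <- length(gr)
    if (nSelect > n)
        stop("cannot draw more genes than the genome contains")
    chrom_idx <- match(as.character(seqnames(gr)), seqlevels(gr))  # genomic order
    vals <- with_seed(seed, {
        vapply(seq_len(reps), function(r) {
            idx <- sort.int(sample.int(n, nSelect))
            if (nSelect < 2L) return(0)
            adj <- (diff(idx) == 1L) & (chrom_idx[idx[-1L]] == chrom_idx[idx[-nSelect]])
            in_pair <- c(adj, FALSE) | c(FALSE, adj)
            sum(in_pair) / nSelect
        }, numeric(1))
    })
    new("NullDistribution", values = vals, reps = reps,
        seed = if (is.null(seed)) NULL else as.integer(seed),
        statistic = "clustered_fraction")
}

#' Does an observed statistic exceed the permutation null?
#'
#' Strict comparison of the observed value against the one-sided upper
#' percentile of the null ([nullQuantile()]); a value exactly at the bound
#' does not exceed.
#'
#' @param observed observed statistic (e.g. clustered fraction or overlap
#'   count)
#' @param null a [NullDistribution-class]
#' @param level percentile level, default 0.95
#' @return TRUE iff \code{observed > nullQuantile(null, level)}
#' @export
excessTest <- function(observed, null, level = 0.95) {
    stopifnot(is(null, "NullDistribution"), length(observed) == 1L)
    observed > nullQuantile(null, level)
}
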