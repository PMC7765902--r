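#' Simulate an ordered genome of non-overlapping genes
#'
#' Builds a [GenomeModel-class] with the given number of chromosomes and genes
#' per chromosome. Gene lengths and intergenic gaps are drawn from exponential
#' distributions around the supplied means (floored at 100 bp and 1 bp), which
#' reproduces the right-skewed length spectrum of plant gene annotations
#' closely enough for testing rank-adjacency statistics. Deterministic for a
#' fixed seed.
#'
#' @param nChromosomes number of chromosomes (>= 1)
#' @param genesPerChromosome genes per chromosome; a single count or a vector
#'   of length \code{nChromosomes}
#' @param meanGeneLength mean gene length in bp
#' @param meanIntergenicGap mean gap between consecutive genes in bp
#' @param seed integer RNG seed (NULL for a non-reproducible draw)
#' @return a [GenomeModel-class]
#' @examples
#' gm <- simulateGenome(2, 5, 1000, 500, seed = 1)
#' nGenes(gm)
#' @export
simulateGenome <- function(nChromosomes, genesPerChromosome,
                           meanGeneLength = 2000, meanIntergenicGap = 1000,
                           seed = NULL) {
    nChromosomes <- assert_count(nChromosomes, "nChromosomes")
    genesPerChromosome <- assert_count(genesPerChromosome, "genesPerChromosome")
    if (length(genesPerChromosome) == 1L)
        genesPerChromosome <- rep(genesPerChromosome, nChromosomes)
    stopifnot(length(genesPerChromosome) == nChromosomes)
    if (meanGeneLength <= 0 || meanIntergenicGap <= 0)
        stop("mean gene length and intergenic gap must be positive")
    with_seed(seed, {
        chroms <- sprintf("chr%d", seq_len(nChromosomes))
        pieces <- vector("list", nChromosomes)
        seqlen <- integer(nChromosomes)
        for (i in seq_len(nChromosomes)) {
            ng <- genesPerChromosome[i]
            lens <- pmax(100L, as.integer(round(stats::rexp(ng, 1 / meanGeneLength))))
            gaps <- pmax(1L, as.integer(round(stats::rexp(ng, 1 / meanIntergenicGap))))
            starts <- cumsum(gaps) + c(0L, cumsum(lens[-ng]))[seq_len(ng)]
            if (ng == 1L) starts <- gaps[1L]
            ends <- starts + lens - 1L
            seqlen[i] <- ends[ng] + pmax(1L, as.integer(round(
                stats::rexp(1, 1 / meanIntergenicGap))))
            pieces[[i]] <- data.frame(
                chrom = chroms[i], start = starts, end = ends,
                strand = sample(c("+", "-"), ng, replace = TRUE),
                gene_id = sprintf("%s_g%05d", chroms[i], seq_len(ng)),
                rank = seq_len(ng))
        }
        tab <- do.call(rbind, pieces)
        gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end), strand = tab$strand,
                      gene_id = tab$gene_id, rank = tab$rank,
                      seqinfo = Seqinfo(chroms, seqlen))
        new("GenomeModel", genes = gr)
    })
}

#' Generate the nucleotide sequence of a simulated genome
#'
#' Uniform random sequence over A/C/G/T for each chromosome, at the lengths
#' declared by the model. Deterministic for a fixed seed, so variant
#' simulation against the same seed produces reference-matching alleles.
#'
#' @param genome a [GenomeModel-class]
#' @param seed integer RNG seed
#' @return a \link[Biostrings]{DNAStringSet} named by chromosome
#' @export
simulateGenomeSequence <- function(genome, seed = NULL) {
    sl <- seqlengths(geneModels(genome))
    with_seed(seed, {
        seqs <- vapply(sl, function(n)
            paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = ""), character(1))
        Biostrings::DNAStringSet(seqs)
    })
}

#' Build the design table for one reciprocal cross pair
#'
#' The two crosses of the pair swap the female and male roles of the same two
#' parents; each cross is sampled in the requested tissues with the requested
#' number of replicates.
#'
#' @param parentA,parentB parent line names; cross 1 has \code{parentA} as the
#'   female parent, cross 2 is the reciprocal
#' @param pairId identifier for the pair (default "parentA_parentB")
#' @param tissues subset of c("endosperm", "embryo")
#' @param replicates replicates per cross and tissue
#' @return a [CrossDesign-class]
#' @examples
#' reciprocalCrossDesign("ZH11", "Nip")
#' @export
reciprocalCrossDesign <- function(parentA, parentB,
                                  pairId = paste(parentA, parentB, sep = "_"),
                                  tissues = c("endosperm", "embryo"),
                                  replicates = 1L) {
    stopifnot(is.character(parentA), is.character(parentB), parentA != parentB)
    tissues <- match.arg(tissues, c("endosperm", "embryo"), several.ok = TRUE)
    replicates <- assert_count(replicates, "replicates")
    crosses <- data.frame(
        cross_id = c(paste0(parentA, "x", parentB), paste0(parentB, "x", parentA)),
        female_parent = c(parentA, parentB),
        male_parent = c(parentB, parentA),
        pair_id = pairId)
    grid <- expand.grid(replicate = seq_len(replicates), tissue = tissues,
                        cross_id = crosses$cross_id, stringsAsFactors = FALSE)
    samples <- data.frame(
        sample_id = sprintf("%s_%s_r%d", grid$cross_id, grid$tissue, grid$replicate),
        cross_id = grid$cross_id, tissue = as.character(grid$tissue),
        replicate = grid$replicate)
    new("CrossDesign", crosses = crosses, samples = samples)
}

#' Combine the cross designs of several reciprocal pairs
#'
#' @param ... CrossDesign objects with disjoint cross and sample identifiers
#' @return a single [CrossDesign-class]
#' @export
combineCrossDesigns <- function(...) {
    ds <- list(...)
    stopifnot(length(ds) >= 1L, all(vapply(ds, is, logical(1), "CrossDesign")))
    new("CrossDesign",
        crosses = do.call(rbind, lapply(ds, crossTable)),
        samples = do.call(rbind, lapply(ds, sampleTable)))
}

#' Simulate homozygous parental variants over a genome
#'
#' Each gene is independently informative (carries at least one parental SNP)
#' with probability \code{pGeneHasSnp}; the remainder carry no variant at all,
#' emulating the fraction of genes undetectable for lack of a parental SNP.
#' Informative genes receive a zero-truncated-Poisson number of SNPs with the
#' stated mean, at distinct positions inside the gene body, and with
#' probability \code{indelRate} one short (1-3 bp) insertion or deletion that
#' does not overlap any SNP. When \code{sequence} is supplied, reference
#' alleles are read from it so the set validates against that sequence.
#'
#' @param genome a [GenomeModel-class]
#' @param pGeneHasSnp probability a gene carries any SNP
#' @param meanSnpsPerInformativeGene mean SNPs per informative gene (>= 1)
#' @param indelRate probability an informative gene also carries one indel
#' @param sequence optional \link[Biostrings]{DNAStringSet} to take reference
#'   alleles from (e.g. from [simulateGenomeSequence()])
#' @param seed integer RNG seed
#' @return a [VariantSet-class]
#' @export
simulateVariants <- function(genome, pGeneHasSnp = 0.5,
                             meanSnpsPerInformativeGene = 2,
                             indelRate = 0.1, sequence = NULL, seed = NULL) {
    assert_prob(pGeneHasSnp, "pGeneHasSnp")
    assert_prob(indelRate, "indelRate")
    if (meanSnpsPerInformativeGene < 1)
        stop("'meanSnpsPerInformativeGene' must be >= 1")
    gr <- geneModels(genome)
    bases <- c("A", "C", "G", "T")
    base_at <- function(chrom, from, to) {
        if (is.null(sequence))
            paste(sample(bases, to - from + 1L, replace = TRUE), collapse = "")
        else as.character(Biostrings::subseq(sequence[[chrom]], from, to))
    }
    with_seed(seed, {
        informative <- stats::runif(length(gr)) < pGeneHasSnp
        snp_rows <- list(); indel_rows <- list()
        for (i in which(informative)) {
            chrom <- as.character(seqnames(gr)[i])
            gid <- mcols(gr)$gene_id[i]
            gstart <- start(gr)[i]; gend <- end(gr)[i]
            width <- gend - gstart + 1L
            k <- 1L + stats::rpois(1L, meanSnpsPerInformativeGene - 1)
            k <- min(k, width)
            pos <- sort(sample.int(width, k)) + gstart - 1L
            ref <- vapply(pos, function(p) base_at(chrom, p, p), character(1))
            alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
            snp_rows[[length(snp_rows) + 1L]] <- data.frame(
                chrom = chrom, pos = pos, ref = ref, alt = unname(alt), gene_id = gid)
            if (stats::runif(1) < indelRate) {
                len <- sample.int(3L, 1L)
                deletion <- stats::runif(1) < 0.5
                for (try in seq_len(20L)) {
                    p <- gstart - 1L + sample.int(max(width - len, 1L), 1L)
                    span <- if (deletion) p:(p + len - 1L) else p
                    if (!any(span %in% pos) && p + len - 1L <= gend) {
                        indel_rows[[length(indel_rows) + 1L]] <- if (deletion)
                            data.frame(chrom = chrom, pos = p,
                                       ref = base_at(chrom, p, p + len - 1L),
                                       alt = "", gene_id = gid)
                        else
                            data.frame(chrom = chrom, pos = p, ref = "",
                                       alt = paste(sample(bases, len, replace = TRUE),
                                                   collapse = ""),
                                       gene_id = gid)
                        break
                    }
                }
            }
        }
        bind <- function(rows) {
            if (!length(rows)) return(empty_variant_df())
            df <- do.call(rbind, rows)
            df[order(df$chrom, df$pos), , drop = FALSE]
        }
        new("VariantSet", snps = bind(snp_rows), indels = bind(indel_rows))
    })
}

#' Plant ground-truth imprinted genes into a genome
#'
#' Assigns each gene an imprinting class and tissue-specific maternal
#' fractions. Non-imprinted genes sit exactly at the parental genomic
#' expectation: maternal fraction 2/3 in the triploid endosperm and 1/2 in the
#' diploid embryo. Planted MEGs/PEGs get the supplied extreme endosperm
#' fractions; their embryo fraction stays 1/2, reflecting that imprinting in
#' this system is essentially an endosperm phenomenon. \code{nClusterPairs}
#' disjoint adjacent same-class pairs are planted to emulate mini clusters of
#' tandemly located imprinted genes.
#'
#' @param genome a [GenomeModel-class]
#' @param nMeg,nPeg number of MEGs and PEGs to plant
#' @param nClusterPairs number of disjoint adjacent planted pairs
#' @param megMaternalFraction endosperm maternal fraction of MEGs (> 2/3)
#' @param pegMaternalFraction endosperm maternal fraction of PEGs (< 2/3)
#' @param seed integer RNG seed
#' @return a data.frame with one row per gene: \code{gene_id, planted_class,
#'   maternal_fraction_endosperm, maternal_fraction_embryo, in_planted_cluster}
#' @export
plantTruth <- function(genome, nMeg, nPeg, nClusterPairs = 0L,
                       megMaternalFraction = 0.95, pegMaternalFraction = 0.10,
                       seed = NULL) {
    nMeg <- assert_count(nMeg, "nMeg", min = 0L)
    nPeg <- assert_count(nPeg, "nPeg", min = 0L)
    nClusterPairs <- assert_count(nClusterPairs, "nClusterPairs", min = 0L)
    assert_prob(megMaternalFraction, "megMaternalFraction")
    assert_prob(pegMaternalFraction, "pegMaternalFraction")
    if (megMaternalFraction <= 2 / 3)
        stop("'megMaternalFraction' must exceed the endosperm baseline 2/3")
    if (pegMaternalFraction >= 2 / 3)
        stop("'pegMaternalFraction' must be below the endosperm baseline 2/3")
    gr <- geneModels(genome)
    n <- length(gr)
    if (nMeg + nPeg > n)
        stop("cannot plant more imprinted genes than there are genes")
    if (2L * nClusterPairs > nMeg + nPeg)
        stop("cluster demand exceeds the number of planted imprinted genes")
    chrom <- as.character(seqnames(gr))
    with_seed(seed, {
        class <- rep("none", n)
        clustered <- logical(n)
        # adjacent candidate pairs: consecutive genes on the same chromosome
        cand <- which(chrom[-n] == chrom[-1L])
        used <- logical(n)
        budget <- c(MEG = nMeg, PEG = nPeg)
        placed <- 0L
        for (i in cand[sample.int(length(cand))]) {
            if (placed == nClusterPairs) break
            if (used[i] || used[i + 1L]) next
            cls <- if (budget["MEG"] >= 2L) "MEG"
                   else if (budget["PEG"] >= 2L) "PEG" else break
            class[c(i, i + 1L)] <- cls
            clustered[c(i, i + 1L)] <- TRUE
            used[c(i, i + 1L)] <- TRUE
            budget[cls] <- budget[cls] - 2L
            placed <- placed + 1L
        }
        if (placed < nClusterPairs)
            stop(sprintf("could only place %d of %d requested adjacent cluster pairs",
                         placed, nClusterPairs))
        free <- which(!used)
        extra <- free[sample.int(length(free), budget[["MEG"]] + budget[["PEG"]])]
        class[extra[seq_len(budget[["MEG"]])]] <- "MEG"
        if (budget[["PEG"]] > 0L)
            class[extra[budget[["MEG"]] + seq_len(budget[["PEG"]])]] <- "PEG"
        data.frame(
            gene_id = mcols(gr)$gene_id,
            planted_class = class,
            maternal_fraction_endosperm = ifelse(class == "MEG", megMaternalFraction,
                                          ifelse(class == "PEG", pegMaternalFraction,
                                                 2 / 3)),
            maternal_fraction_embryo = 0.5,
            in_planted_cluster = clustered)
    })
}

#' Simulate allele-specific read counts for every gene and sample
#'
#' For each sample and each SNP-bearing gene not struck by the no-ASR
#' lottery, the total allele-specific read (ASR) count is drawn from a
#' negative binomial with mean \code{meanDepth} and dispersion
#' \code{dispersion} (Poisson at \code{dispersion = Inf}), then split into
#' maternal and paternal reads by independent binomial trials at the gene's
#' tissue-specific maternal fraction from the truth table. Maternal always
#' means the cross's female parent, so the same parental allele is counted as
#' maternal in one cross of a reciprocal pair and paternal in the other.
#' Genes without any parental SNP, and SNP-bearing genes selected (with
#' probability \code{pNoAsrGivenSnp}, once per gene) to have no read across
#' their SNPs, emit zero ASR in every sample; they populate the no-SNP and
#' no-ASR rows of the detectability ledger.
#'
#' @param genome a [GenomeModel-class]
#' @param variants a [VariantSet-class] over the same genome
#' @param truth truth table from [plantTruth()]
#' @param design a [CrossDesign-class]
#' @param meanDepth mean total ASR per gene per sample
#' @param dispersion negative-binomial size parameter; \code{Inf} gives Poisson
#' @param pNoAsrGivenSnp probability a SNP-bearing gene has no covering read
#' @param seed integer RNG seed
#' @return data.frame with columns \code{gene_id, sample_id, cross_id, tissue,
#'   maternal_asr, paternal_asr}
#' @export
simulateAsrCounts <- function(genome, variants, truth, design,
                              meanDepth = 100, dispersion = 10,
                              pNoAsrGivenSnp = 0, seed = NULL) {
    stopifnot(is(variants, "VariantSet"), is(design, "CrossDesign"))
    if (meanDepth <= 0) stop("'meanDepth' must be positive")
    assert_prob(pNoAsrGivenSnp, "pNoAsrGivenSnp")
    ids <- geneIds(genome)
    if (!all(truth$gene_id %in% ids))
        stop("truth table contains genes absent from the genome")
    samples <- merge(sampleTable(design), crossTable(design), by = "cross_id",
                     sort = FALSE)
    if (nrow(samples) == 0L) stop("design contains no samples")
    truth <- truth[match(ids, truth$gene_id), , drop = FALSE]
    has_snp <- variantCount(variants, ids) > 0L
    nG <- length(ids)
    with_seed(seed, {
        no_asr <- has_snp & (stats::runif(nG) < pNoAsrGivenSnp)
        detectable <- has_snp & !no_asr
        out <- vector("list", nrow(samples))
        for (j in seq_len(nrow(samples))) {
            s <- samples[j, ]
            f <- if (s$tissue == "endosperm") truth$maternal_fraction_endosperm
                 else truth$maternal_fraction_embryo
            total <- integer(nG)
            nd <- sum(detectable)
            total[detectable] <- if (is.finite(dispersion))
                stats::rnbinom(nd, mu = meanDepth, size = dispersion)
            else stats::rpois(nd, meanDepth)
            m <- integer(nG)
            m[detectable] <- stats::rbinom(nd, total[detectable], f[detectable])
            out[[j]] <- data.frame(
                gene_id = ids, sample_id = s$sample_id, cross_id = s$cross_id,
                tissue = s$tissue, maternal_asr = m, paternal_asr = total - m)
        }
        df <- do.call(rbind, out)
        rownames(df) <- NULL
        df
    })
}
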