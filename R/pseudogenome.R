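#' Substitute parental variants into a reference to build a pseudo-genome
#'
#' Applies every SNP and InDel of a [VariantSet-class] to the reference
#' sequence, producing the pseudo-genome of the other parent together with a
#' bidirectional [LiftoverMap-class]. SNP substitution preserves coordinates;
#' insertions and deletions shift everything downstream, and the map records
#' the conserved blocks so positions can be transferred in either direction.
#' Reference alleles are verified against the sequence before anything is
#' modified; a mismatch or an overlapping pair of variants aborts with the
#' offending chromosome and position.
#'
#' Homozygous variant input is required: each record states the single
#' non-reference allele carried by the other parent. Heterozygous parental
#' calls are not representable.
#'
#' @param reference a \link[Biostrings]{DNAStringSet}, one entry per
#'   chromosome, named
#' @param variants a [VariantSet-class] in reference coordinates
#' @return a list with elements \code{sequence} (DNAStringSet of the
#'   pseudo-genome) and \code{map} (a [LiftoverMap-class])
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' vs <- new("VariantSet",
#'           snps = data.frame(chrom = "chr1", pos = 2, ref = "C", alt = "T",
#'                             gene_id = NA_character_),
#'           indels = data.frame(chrom = character(), pos = integer(),
#'                               ref = character(), alt = character(),
#'                               gene_id = character()))
#' as.character(applyVariants(ref, vs)$sequence)
#' @export
applyVariants <- function(reference, variants) {
    stopifnot(is(reference, "DNAStringSet"), is(variants, "VariantSet"))
    if (is.null(names(reference)) || anyDuplicated(names(reference)))
        stop("reference chromosomes must be uniquely named")
    all_var <- rbind(snpTable(variants), indelTable(variants))
    bad <- setdiff(unique(all_var$chrom), names(reference))
    if (length(bad))
        stop("variants reference unknown chromosome(s): ",
             paste(bad, collapse = ", "))
    ref_len <- stats::setNames(Biostrings::width(reference), names(reference))
    pseudo <- reference
    blocks <- list()
    for (chrom in names(reference)) {
        v <- all_var[all_var$chrom == chrom, , drop = FALSE]
        v <- v[order(v$pos, nchar(v$ref) == 0L), , drop = FALSE]
        L <- ref_len[[chrom]]
        if (nrow(v)) {
            if (any(v$pos + pmax(nchar(v$ref) - 1L, 0L) > L))
                stop(sprintf("variant beyond end of %s", chrom))
            # verify declared reference alleles before substituting
            for (k in seq_len(nrow(v))) {
                lr <- nchar(v$ref[k])
                if (lr == 0L) next
                have <- as.character(Biostrings::subseq(
                    reference[[chrom]], v$pos[k], v$pos[k] + lr - 1L))
                if (have != v$ref[k])
                    stop(sprintf(
                        "reference mismatch at %s:%d (declared '%s', found '%s')",
                        chrom, v$pos[k], v$ref[k], have))
            }
            at <- IRanges(start = v$pos, width = nchar(v$ref))
            pseudo[[chrom]] <- Biostrings::replaceAt(
                reference[[chrom]], at, Biostrings::DNAStringSet(v$alt))
        }
        blocks[[chrom]] <- .liftover_blocks(chrom, v, L)
    }
    blk <- do.call(rbind, blocks)
    rownames(blk) <- NULL
    map <- new("LiftoverMap", blocks = blk,
               ref_seqlengths = ref_len,
               pseudo_seqlengths = stats::setNames(Biostrings::width(pseudo),
                                                   names(pseudo)))
    list(sequence = pseudo, map = map)
}

# Conserved-block computation for one chromosome. Only length-changing
# variants break collinearity: SNP positions map one-to-one. For a
# replacement of lr reference bases by la alternate bases, the common
# prefix of min(lr, la) bases stays coordinate-matched; surplus reference
# bases are deleted, surplus alternate bases inserted.
.liftover_blocks <- function(chrom, v, ref_len) {
    empty <- data.frame(chrom = character(), ref_start = integer(),
                        ref_end = integer(), pseudo_start = integer(),
                        pseudo_end = integer())
    v <- v[nchar(v$ref) != nchar(v$alt), , drop = FALSE]
    if (ref_len == 0L) return(empty)
    rows <- list()
    cur_ref <- 1L; cur_pseudo <- 1L
    add <- function(rs, re, ps) {
        if (re >= rs)
            rows[[length(rows) + 1L]] <<- data.frame(
                chrom = chrom, ref_start = rs, ref_end = re,
                pseudo_start = ps, pseudo_end = ps + (re - rs))
    }
    for (k in seq_len(nrow(v))) {
        pos <- v$pos[k]; lr <- nchar(v$ref[k]); la <- nchar(v$alt[k])
        keep <- min(lr, la)
        # collinear stretch before the variant, plus its matched prefix
        add(cur_ref, pos + keep - 1L, cur_pseudo)
        cur_pseudo <- cur_pseudo + (pos + keep - cur_ref) + max(la - lr, 0L)
        cur_ref <- pos + lr
    }
    add(cur_ref, ref_len, cur_pseudo)
    if (!length(rows)) return(empty)
    do.call(rbind, rows)
}

#' Transfer coordinates between reference and pseudo-genome
#'
#' Vectorised over \code{pos}. Positions falling in an interval that was
#' deleted by the substitution (or, in the reverse direction, inserted)
#' return \code{NA} rather than raising an error; positions outside the
#' chromosome bounds of the source coordinate system are an error.
#'
#' @param map a [LiftoverMap-class] from [applyVariants()]
#' @param chrom chromosome name (scalar)
#' @param pos integer vector of 1-based positions in the source system
#' @param direction "refToPseudo" (default) or "pseudoToRef"
#' @return integer vector of lifted positions, \code{NA} where the position
#'   has no image
#' @export
liftCoord <- function(map, chrom, pos,
                      direction = c("refToPseudo", "pseudoToRef")) {
    stopifnot(is(map, "LiftoverMap"), length(chrom) == 1L)
    direction <- match.arg(direction)
    lens <- if (direction == "refToPseudo") map@ref_seqlengths
            else map@pseudo_seqlengths
    if (!chrom %in% names(lens))
        stop(sprintf("unknown chromosome '%s'", chrom))
    pos <- as.integer(pos)
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > lens[[chrom]]))
        stop(sprintf("position out of bounds on %s (length %d)",
                     chrom, lens[[chrom]]))
    b <- map@blocks[map@blocks$chrom == chrom, , drop = FALSE]
    if (direction == "refToPseudo") {
        from_start <- b$ref_start; from_end <- b$ref_end; to_start <- b$pseudo_start
    } else {
        from_start <- b$pseudo_start; from_end <- b$pseudo_end; to_start <- b$ref_start
    }
    out <- rep(NA_integer_, length(pos))
    if (nrow(b)) {
        idx <- findInterval(pos, from_start)
        hit <- idx >= 1L & pos <= from_end[pmax(idx, 1L)]
        out[hit] <- to_start[idx[hit]] + (pos[hit] - from_start[idx[hit]])
    }
    out
}
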