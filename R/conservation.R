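#' Canonicalize gene identifiers through an ID map
#'
#' Applies a functional source-to-canonical mapping (e.g. assembly-specific
#' or legacy identifiers to the canonical annotation). Identifiers absent
#' from the map are kept as-is and reported in the \code{"unmapped"}
#' attribute.
#'
#' @param ids character vector of identifiers
#' @param idMap data.frame with columns \code{source_id, canonical_id}; a
#'   source mapping to two different canonical ids is an error
#' @return character vector of the same length, with attribute
#'   \code{"unmapped"} listing the ids left untranslated
#' @export
canonicalizeIds <- function(ids, idMap) {
    stopifnot(all(c("source_id", "canonical_id") %in% colnames(idMap)))
    map <- unique(idMap[, c("source_id", "canonical_id")])
    if (anyDuplicated(map$source_id))
        stop("idMap is not functional: a source_id maps to multiple canonical ids")
    hit <- match(ids, map$source_id)
    out <- ifelse(is.na(hit), ids, map$canonical_id[hit])
    attr(out, "unmapped") <- ids[is.na(hit)]
    out
}

#' Observed overlaps between two or three gene sets
#'
#' Exact intersection counts for every pair and, with three sets, the triple
#' intersection. Duplicate identifiers within a set are collapsed with a
#' warning; identifiers are canonicalized first when an ID map is given.
#'
#' @param sets named list of 2 or 3 character vectors of gene identifiers
#' @param idMap optional data.frame for [canonicalizeIds()]
#' @return list with elements \code{sizes} (named set sizes),
#'   \code{pairwise} (named intersection counts, names like "A:B") and
#'   \code{kway} (size of the intersection of all sets)
#' @export
overlapCounts <- function(sets, idMap = NULL) {
    stopifnot(is.list(sets), length(sets) %in% 2:3)
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        names(sets) <- paste0("set", seq_along(sets))
    sets <- lapply(sets, function(s) {
        if (!is.null(idMap)) s <- as.character(canonicalizeIds(s, idMap))
        if (anyDuplicated(s)) {
            warning("duplicate identifiers within a set were collapsed")
            s <- unique(s)
        }
        s
    })
    nm <- names(sets)
    pairs <- utils::combn(seq_along(sets), 2L)
    pairwise <- apply(pairs, 2L, function(ij)
        length(intersect(sets[[ij[1]]], sets[[ij[2]]])))
    names(pairwise) <- apply(pairs, 2L, function(ij)
        paste(nm[ij[1]], nm[ij[2]], sep = ":"))
    kway <- length(Reduce(intersect, sets))
    list(sizes = lengths(sets), pairwise = pairwise, kway = kway)
}

#' Permutation null for gene-set overlap on an annotated background
#'
#' In each replicate, sets of the given sizes are drawn uniformly without
#' replacement from a background of \code{backgroundN} genes (each set drawn
#' independently) and the overlap statistic is recorded: the pairwise
#' intersection size for two sets, or the size of the common intersection of
#' all sets for \code{statistic = "kway"}. With \code{drawMode = "fixFirst"}
#' the first set is held fixed and only the others are redrawn, which is
#' statistically near-identical for uniform draws.
#'
#' @param setSizes integer vector of set sizes (length 2 for "pairwise",
#'   >= 2 for "kway")
#' @param backgroundN size of the annotated background gene universe
#' @param reps number of replicates
#' @param seed integer RNG seed
#' @param statistic "pairwise" or "kway"
#' @param drawMode "both" (default; every set redrawn each replicate) or
#'   "fixFirst"
#' @return a [NullDistribution-class] of overlap counts
#' @export
overlapNull <- function(setSizes, backgroundN, reps = 10000L, seed = NULL,
                        statistic = c("pairwise", "kway"),
                        drawMode = c("both", "fixFirst")) {
    statistic <- match.arg(statistic)
    drawMode <- match.arg(drawMode)
    setSizes <- assert_count(setSizes, "setSizes")
    backgroundN <- assert_count(backgroundN, "backgroundN")
    reps <- assert_count(reps, "reps")
    if (statistic == "pairwise" && length(setSizes) != 2L)
        stop("'pairwise' requires exactly two set sizes")
    if (length(setSizes) < 2L)
        stop("need at least two set sizes")
    if (any(setSizes > backgroundN))
        stop("set size exceeds the background gene count")
    vals <- with_seed(seed, {
        first_fixed <- seq_len(setSizes[1L])
        vapply(seq_len(reps), function(r) {
            a <- if (drawMode == "fixFirst") first_fixed
                 else sample.int(backgroundN, setSizes[1L])
            cur <- a
            for (k in seq_along(setSizes)[-1L]) {
                b <- sample.int(backgroundN, setSizes[k])
                cur <- cur[cur %in% b]
                if (!length(cur)) break
            }
            length(cur)
        }, numeric(1))
    })
    new("NullDistribution", values = vals, reps = reps,
        seed = if (is.null(seed)) NULL else as.integer(seed),
        statistic = paste0("overlap_", statistic))
}

#' Conservation verdict for an observed overlap
#'
#' The observed number of shared imprinted genes exceeds chance iff it is
#' strictly greater than the one-sided upper percentile of the permutation
#' null. Identical to [excessTest()]; provided under the name used in the
#' conservation analysis.
#'
#' @param observed observed overlap count
#' @param null a [NullDistribution-class] from [overlapNull()]
#' @param level percentile level, default 0.95
#' @return TRUE iff the observed overlap exceeds the null bound
#' @export
conservationVerdict <- function(observed, null, level = 0.95) {
    excessTest(observed, null, level)
}

#' Ortholog matching by bidirectional hit rate (BHR)
#'
#' For directed similarity score tables between species A and B (best
#' available score per directed gene pair, e.g. BLASTP bit scores), the
#' forward ratio \code{Rf(a, b)} is the score of (a, b) divided by a's best
#' forward score, and the reverse ratio \code{Rr(a, b)} is the score of
#' (b, a) divided by b's best reverse score; \code{BHR = Rf * Rr}. A pair is
#' reported iff \code{BHR >= threshold}. Mutual best hits have BHR = 1; the
#' ratio form also admits near-co-optimal hits that a strict reciprocal-best
#' rule would discard. Genes with no hit in one direction cannot be scored
#' and are excluded.
#'
#' @param forwardScores data.frame \code{query, subject, score} for A
#'   against B (scores > 0)
#' @param reverseScores data.frame \code{query, subject, score} for B
#'   against A
#' @param threshold minimum BHR, default 0.95
#' @return data.frame \code{gene_a, gene_b, Rf, Rr, bhr}, sorted by gene_a
#' @export
bhrMatch <- function(forwardScores, reverseScores, threshold = 0.95) {
    need <- c("query", "subject", "score")
    stopifnot(all(need %in% colnames(forwardScores)),
              all(need %in% colnames(reverseScores)))
    if (any(forwardScores$score <= 0) || any(reverseScores$score <= 0))
        stop("scores must be positive")
    dedup <- function(df) {
        # keep the best score per directed pair
        df <- df[order(df$query, df$subject, -df$score), ]
        df[!duplicated(df[, c("query", "subject")]), ]
    }
    fwd <- dedup(forwardScores)
    rev <- dedup(reverseScores)
    fwd$Rf <- fwd$score / stats::ave(fwd$score, fwd$query, FUN = max)
    rev$Rr <- rev$score / stats::ave(rev$score, rev$query, FUN = max)
    merged <- merge(fwd[, c("query", "subject", "Rf")],
                    rev[, c("query", "subject", "Rr")],
                    by.x = c("query", "subject"),
                    by.y = c("subject", "query"))
    merged$bhr <- merged$Rf * merged$Rr
    out <- merged[merged$bhr >= threshold,
                  c("query", "subject", "Rf", "Rr", "bhr")]
    names(out)[1:2] <- c("gene_a", "gene_b")
    out <- out[order(out$gene_a, out$gene_b), ]
    rownames(out) <- NULL
    out
}
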