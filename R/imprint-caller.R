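#' The chi-square critical value used by the caller
#'
#' The exact df = 1, alpha = 0.05 chi-square quantile (about 3.841); a gene's
#' statistic must strictly exceed it to count as significant.
#'
#' @return a single numeric value
#' @export
chi2Critical <- function() stats::qchisq(0.95, df = 1)

#' Pearson chi-square ratio test of maternal:paternal allele counts
#'
#' Tests whether the observed maternal/paternal split of a gene's
#' allele-specific reads deviates from the expected maternal share: 2/3 in
#' the triploid endosperm (2m:1p) or 1/2 in the diploid embryo (1m:1p).
#' One-degree-of-freedom Pearson statistic on expected counts
#' \code{(m+p)*share} and \code{(m+p)*(1-share)}, no continuity correction;
#' significance is \code{chi2 > critical}. A gene with \code{m + p = 0} is
#' not testable: its statistic is \code{NA} and it is never significant (the
#' detectability ledger routes such genes to no_ASR).
#'
#' Vectorised over \code{m} and \code{p}.
#'
#' @param m,p maternal and paternal ASR counts (non-negative integers)
#' @param expectedMShare expected maternal share under no imprinting: 2/3
#'   (endosperm) or 1/2 (embryo)
#' @param critical significance cutoff; default the df = 1, alpha = 0.05
#'   quantile
#' @return data.frame with columns \code{chi2} and \code{significant}
#' @examples
#' chiSquareRatioTest(100, 100, 2/3)   # chi2 = 25, significant
#' chiSquareRatioTest(200, 100, 2/3)   # chi2 = 0
#' @export
chiSquareRatioTest <- function(m, p, expectedMShare,
                               critical = chi2Critical()) {
    if (any(m < 0) || any(p < 0)) stop("counts must be non-negative")
    if (any(expectedMShare <= 0) || any(expectedMShare >= 1))
        stop("'expectedMShare' must be in (0, 1)")
    n <- m + p
    em <- n * expectedMShare
    ep <- n * (1 - expectedMShare)
    chi2 <- ifelse(n == 0, NA_real_, (m - em)^2 / em + (p - ep)^2 / ep)
    data.frame(chi2 = chi2,
               significant = !is.na(chi2) & chi2 > critical)
}

#' Maternal/paternal fold changes
#'
#' \code{fold_mp = m/p} and \code{fold_pm = p/m}; a zero denominator yields
#' \code{Inf}, which passes any finite threshold. Vectorised. Requires
#' \code{m + p > 0}.
#'
#' @param m,p maternal and paternal ASR counts
#' @return data.frame with columns \code{fold_mp} and \code{fold_pm}
#' @export
foldChange <- function(m, p) {
    if (any(m < 0) || any(p < 0)) stop("counts must be non-negative")
    if (any(m + p == 0)) stop("fold change undefined for m + p = 0")
    data.frame(fold_mp = ifelse(p == 0, Inf, m / p),
               fold_pm = ifelse(m == 0, Inf, p / m))
}

# Per-tissue fold thresholds of the MEG/PEG rules.
.default_thresholds <- function() {
    list(meg_fold_endosperm = 4, meg_fold_embryo = 2,
         peg_fold_endosperm = 1, peg_fold_embryo = 2)
}

#' Call imprinted genes from reciprocal-cross ASR counts
#'
#' The core caller. Replicate samples of the same cross and tissue are pooled
#' by summation; each gene is then tested per tissue against the parental
#' expectation (2m:1p in endosperm, 1m:1p in embryo) with the Pearson
#' chi-square test, in each cross of the reciprocal pair separately. A gene
#' is a MEG if, in \emph{both} crosses, the test is significant and the
#' maternal fold change exceeds the tissue threshold (m/p > 4 in endosperm,
#' or m/p > 2 in embryo); a PEG if, in both crosses, the test is significant
#' and the paternal fold change exceeds the tissue threshold (p/m > 1 in
#' endosperm, or p/m > 2 in embryo). Endosperm and embryo evidence are
#' combined by OR, and \code{tissue_evidence} records which tissue(s)
#' satisfied the rule. No call is ever made from a single cross; a gene whose
#' pooled ASR total falls below \code{minTotalAsr} in either cross of a
#' tissue is not testable in that tissue.
#'
#' The endosperm PEG fold rule is deliberately literal: p/m > 1 already marks
#' a strong deviation from the expected 1:2 paternal:maternal ratio. Set
#' \code{thresholds$peg_fold_endosperm} to change it.
#'
#' @param records ASR count table: \code{gene_id, sample_id, cross_id,
#'   tissue, maternal_asr, paternal_asr}
#' @param design a [CrossDesign-class]
#' @param minTotalAsr minimum pooled ASR per cross for a gene to be testable
#' @param critical chi-square significance cutoff (strict >)
#' @param thresholds list of per-tissue fold thresholds, see
#'   \code{.default_thresholds}; partial lists are completed with defaults
#' @return data.frame with one row per gene x pair:
#'   \code{gene_id, pair_id, class} ("MEG", "PEG" or "none"),
#'   \code{tissue_evidence} ("endosperm", "embryo", "both" or NA), a
#'   \code{testable} flag, and per-tissue, per-cross statistics
#'   (\code{m_endosperm_1, p_endosperm_1, chi2_endosperm_1,
#'   fold_mp_endosperm_1}, ... and the embryo analogues)
#' @export
callImprinting <- function(records, design, minTotalAsr = 10,
                           critical = chi2Critical(),
                           thresholds = list()) {
    stopifnot(is(design, "CrossDesign"))
    th <- utils::modifyList(.default_thresholds(), thresholds)
    sa <- merge(sampleTable(design), crossTable(design), by = "cross_id",
                sort = FALSE)
    if (!all(records$sample_id %in% sa$sample_id))
        stop("unknown sample_id in records: ",
             setdiff(records$sample_id, sa$sample_id)[1])
    x <- merge(records, sa[, c("sample_id", "pair_id")], by = "sample_id",
               sort = FALSE)
    # pool replicates: one m/p per gene x cross x tissue
    pooled <- stats::aggregate(
        cbind(m = x$maternal_asr, p = x$paternal_asr),
        by = list(gene_id = x$gene_id, pair_id = x$pair_id,
                  cross_id = x$cross_id, tissue = x$tissue),
        FUN = sum)
    cr <- crossTable(design)
    out <- list()
    for (pair in unique(cr$pair_id)) {
        crosses <- cr$cross_id[cr$pair_id == pair]   # cross 1, cross 2
        pp <- pooled[pooled$pair_id == pair, , drop = FALSE]
        genes <- sort(unique(pp$gene_id))
        res <- data.frame(gene_id = genes, pair_id = pair)
        qual <- list()
        for (tissue in c("endosperm", "embryo")) {
            share <- if (tissue == "endosperm") 2 / 3 else 1 / 2
            meg_thr <- th[[paste0("meg_fold_", tissue)]]
            peg_thr <- th[[paste0("peg_fold_", tissue)]]
            stats_by_cross <- vector("list", 2L)
            for (k in 1:2) {
                sub <- pp[pp$cross_id == crosses[k] & pp$tissue == tissue, ]
                m <- sub$m[match(genes, sub$gene_id)]
                p <- sub$p[match(genes, sub$gene_id)]
                m[is.na(m)] <- 0L; p[is.na(p)] <- 0L
                test <- chiSquareRatioTest(m, p, share, critical)
                fold <- data.frame(fold_mp = ifelse(p == 0 & m == 0, NA_real_,
                                             ifelse(p == 0, Inf, m / p)),
                                   fold_pm = ifelse(p == 0 & m == 0, NA_real_,
                                             ifelse(m == 0, Inf, p / m)))
                stats_by_cross[[k]] <- data.frame(
                    m = m, p = p, total = m + p,
                    chi2 = test$chi2, significant = test$significant,
                    fold_mp = fold$fold_mp, fold_pm = fold$fold_pm)
                for (col in c("m", "p", "chi2", "fold_mp", "fold_pm"))
                    res[[sprintf("%s_%s_%d", col, tissue, k)]] <-
                        stats_by_cross[[k]][[col]]
            }
            s1 <- stats_by_cross[[1]]; s2 <- stats_by_cross[[2]]
            testable <- s1$total >= minTotalAsr & s2$total >= minTotalAsr
            res[[paste0("testable_", tissue)]] <- testable
            qual[[paste0("MEG_", tissue)]] <- testable &
                s1$significant & s2$significant &
                !is.na(s1$fold_mp) & s1$fold_mp > meg_thr &
                !is.na(s2$fold_mp) & s2$fold_mp > meg_thr
            qual[[paste0("PEG_", tissue)]] <- testable &
                s1$significant & s2$significant &
                !is.na(s1$fold_pm) & s1$fold_pm > peg_thr &
                !is.na(s2$fold_pm) & s2$fold_pm > peg_thr
        }
        meg <- qual$MEG_endosperm | qual$MEG_embryo
        peg <- qual$PEG_endosperm | qual$PEG_embryo
        class <- ifelse(meg & !peg, "MEG", ifelse(peg & !meg, "PEG", "none"))
        evid <- function(a, b) ifelse(a & b, "both",
                               ifelse(a, "endosperm",
                               ifelse(b, "embryo", NA_character_)))
        res$class <- class
        res$tissue_evidence <- ifelse(class == "MEG",
                                      evid(qual$MEG_endosperm, qual$MEG_embryo),
                               ifelse(class == "PEG",
                                      evid(qual$PEG_endosperm, qual$PEG_embryo),
                                      NA_character_))
        res$testable <- res$testable_endosperm | res$testable_embryo
        out[[pair]] <- res
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    front <- c("gene_id", "pair_id", "class", "tissue_evidence", "testable")
    res[, c(front, setdiff(names(res), front))]
}

#' Summarise imprinting calls per pair and tissue
#'
#' Counts MEGs and PEGs by the tissue whose evidence supported the call
#' (genes with evidence in both tissues are counted in both rows);
#' \code{MEG + PEG = total} in every row.
#'
#' @param calls output of [callImprinting()]
#' @return data.frame \code{pair_id, tissue, total, MEG, PEG}
#' @export
summarizeCalls <- function(calls) {
    out <- list()
    for (pair in unique(calls$pair_id)) {
        pc <- calls[calls$pair_id == pair, ]
        for (tissue in c("endosperm", "embryo")) {
            in_tissue <- !is.na(pc$tissue_evidence) &
                pc$tissue_evidence %in% c(tissue, "both")
            n_meg <- sum(pc$class == "MEG" & in_tissue)
            n_peg <- sum(pc$class == "PEG" & in_tissue)
            out[[paste(pair, tissue)]] <- data.frame(
                pair_id = pair, tissue = tissue,
                total = n_meg + n_peg, MEG = n_meg, PEG = n_peg)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
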