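#' Hundred- and thousand-grain weight
#'
#' \code{HGW = weight / grains * 100}; \code{TGW = weight / grains * 1000}.
#' The phenotyping summary used when scoring grain-filling of imprinted-gene
#' mutants.
#'
#' @param totalWeight total grain weight in grams (>= 0)
#' @param nGrains number of grains (> 0)
#' @return list with \code{total_weight, n_grains, hgw, tgw}
#' @examples
#' grainWeight(50, 2000)  # tgw 25 g
#' @export
grainWeight <- function(totalWeight, nGrains) {
    if (!is.numeric(nGrains) || nGrains <= 0)
        stop("'nGrains' must be positive")
    if (!is.numeric(totalWeight) || totalWeight < 0)
        stop("'totalWeight' must be non-negative")
    per <- totalWeight / nGrains
    list(total_weight = totalWeight, n_grains = nGrains,
         hgw = per * 100, tgw = per * 1000)
}

.default_config <- function() {
    list(
        seed = 1L,
        simulation = list(
            n_chromosomes = 2L, genes_per_chromosome = 250L,
            mean_gene_length = 2000, mean_intergenic_gap = 1000,
            p_gene_has_snp = 0.6, mean_snps_per_gene = 2, indel_rate = 0.1,
            n_meg = 20L, n_peg = 5L, n_cluster_pairs = 2L,
            meg_maternal_fraction = 0.95, peg_maternal_fraction = 0.10,
            mean_depth = 100, dispersion = 10, p_no_asr_given_snp = 0.05,
            pairs = list(c("9311", "Nip")), replicates = 1L),
        thresholds = list(
            fpkm = 0.5, min_total_asr = 10,
            chi2_critical = stats::qchisq(0.95, 1),
            meg_fold_endosperm = 4, meg_fold_embryo = 2,
            peg_fold_endosperm = 1, peg_fold_embryo = 2,
            bhr = 0.95),
        nulls = list(neighbor_reps = 10000L, overlap_reps = 10000L,
                     background_n = NULL))
}

# recursive modifyList; only named lists merge, anything else replaces
.merge_config <- function(base, override) {
    named <- function(x) is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))
    for (nm in names(override)) {
        if (named(override[[nm]]) && named(base[[nm]]))
            base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
        else base[[nm]] <- override[[nm]]
    }
    base
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the imprinting-detection pipeline end to end
#'
#' Orchestrates the stages into one configured, seeded, reproducible run:
#' simulate (or load) a genome, parental variants, cross design and
#' allele-specific counts; call MEGs/PEGs; build the detectability ledger;
#' detect mini clusters and their neighbor-permutation null; when several
#' reciprocal pairs are present, compute observed imprinted-set overlaps and
#' their permutation nulls; and, when score tables are configured, match
#' cross-species orthologs by BHR. All thresholds come from one config
#' object whose defaults are the standard constants of the method (FPKM 0.5,
#' chi-square critical 3.84, fold thresholds 4/2/1/2, BHR 0.95, 10,000
#' permutation replicates).
#'
#' Given the same config (including seed), two runs produce byte-identical
#' reports. Every report directory carries a machine-readable
#' \code{manifest.json} with the thresholds, derived stage seeds, config
#' hash and file inventory.
#'
#' @param config a nested list, or the path of a YAML file with the same
#'   structure; unspecified entries fall back to defaults. To analyse
#'   existing data instead of a simulation, supply
#'   \code{config$inputs = list(counts =, crosses =, samples =, genes =,
#'   vcf =)} (TSV/TSV/TSV/BED-or-GFF3/VCF paths).
#' @param outDir output directory, created if needed
#' @return the manifest, invisibly
#' @export
runPipeline <- function(config = list(), outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    cfg <- .merge_config(.default_config(), config)
    th <- cfg$thresholds
    seed <- as.integer(cfg$seed)

    # ---- startup validation: fail before any output is written
    if (!is.null(cfg$inputs)) {
        needed <- unlist(cfg$inputs[c("counts", "crosses", "samples",
                                      "genes", "vcf")])
        missing <- needed[!file.exists(needed)]
        if (length(missing))
            stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
    for (side in c("forward", "reverse"))
        if (!is.null(cfg$bhr[[side]]) && !file.exists(cfg$bhr[[side]]))
            stop("BHR score table not found: ", cfg$bhr[[side]])

    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(
        tool = "ImprintScan",
        version = as.character(utils::packageVersion("ImprintScan")),
        seed = seed,
        stage_seeds = list(genome = derive_seed(seed, "genome"),
                           variants = derive_seed(seed, "variants"),
                           truth = derive_seed(seed, "truth"),
                           counts = derive_seed(seed, "counts"),
                           neighbor = derive_seed(seed, "neighbor"),
                           overlap = derive_seed(seed, "overlap")),
        thresholds = th,
        config_md5 = NA_character_,
        stages = list(), files = character())
    cfg_path <- file.path(outDir, "config.json")
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    emit <- function(name) manifest$files <<- c(manifest$files, name)

    # ---- acquire inputs
    if (is.null(cfg$inputs)) {
        sim <- cfg$simulation
        genome <- .stage("simulate_genome", simulateGenome(
            sim$n_chromosomes, sim$genes_per_chromosome, sim$mean_gene_length,
            sim$mean_intergenic_gap, seed = derive_seed(seed, "genome")))
        variants <- .stage("simulate_variants", simulateVariants(
            genome, sim$p_gene_has_snp, sim$mean_snps_per_gene, sim$indel_rate,
            seed = derive_seed(seed, "variants")))
        truth <- .stage("plant_truth", plantTruth(
            genome, sim$n_meg, sim$n_peg, sim$n_cluster_pairs,
            sim$meg_maternal_fraction, sim$peg_maternal_fraction,
            seed = derive_seed(seed, "truth")))
        design <- .stage("cross_design", do.call(combineCrossDesigns, lapply(
            sim$pairs, function(p) reciprocalCrossDesign(
                p[[1]], p[[2]], replicates = sim$replicates))))
        records <- .stage("simulate_counts", simulateAsrCounts(
            genome, variants, truth, design, sim$mean_depth, sim$dispersion,
            sim$p_no_asr_given_snp, seed = derive_seed(seed, "counts")))
        utils::write.table(truth, file.path(outDir, "truth.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit("truth.tsv")
        writeAsrTable(records, file.path(outDir, "asr.tsv")); emit("asr.tsv")
        manifest$stages$input <- list(mode = "synthetic",
                                      n_genes = nGenes(genome))
    } else {
        genome <- .stage("read_genes", readGeneModels(cfg$inputs$genes))
        variants <- .stage("read_vcf", readVariantsVcf(cfg$inputs$vcf, genome))
        design <- .stage("read_design", readCrossDesign(cfg$inputs$crosses,
                                                        cfg$inputs$samples))
        records <- .stage("read_counts", readAsrTable(cfg$inputs$counts))
        manifest$stages$input <- list(mode = "files", n_genes = nGenes(genome))
    }

    # ---- imprinting calls and ledger
    calls <- .stage("call_imprinting", callImprinting(
        records, design, minTotalAsr = th$min_total_asr,
        critical = th$chi2_critical,
        thresholds = th[c("meg_fold_endosperm", "meg_fold_embryo",
                          "peg_fold_endosperm", "peg_fold_embryo")]))
    utils::write.table(calls, file.path(outDir, "calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("calls.tsv")
    utils::write.table(summarizeCalls(calls),
                       file.path(outDir, "calls_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("calls_summary.tsv")
    ledger <- .stage("ledger", detectabilityLedger(genome, variants, records,
                                                   calls, design))
    utils::write.table(ledger, file.path(outDir, "ledger.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("ledger.tsv")
    utils::write.table(summarizeLedger(ledger),
                       file.path(outDir, "ledger_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("ledger_summary.tsv")
    manifest$stages$calls <- list(
        n_records = nrow(records),
        n_imprinted = sum(calls$class != "none"))

    # ---- mini clusters + neighbor null, per pair
    pair_ids <- unique(crossTable(design)$pair_id)
    cluster_rows <- list(); neighbor_report <- list()
    for (pair in pair_ids) {
        imp <- calls[calls$pair_id == pair & calls$class != "none",
                     c("gene_id", "class")]
        cl <- .stage("clusters", findMiniClusters(imp, genome))
        if (nrow(cl)) {
            cl <- cbind(pair_id = pair, cl)
            cluster_rows[[pair]] <- cl
        }
        if (nrow(imp) >= 2L) {
            null <- .stage("neighbor_null", neighborNull(
                genome, nrow(imp), reps = cfg$nulls$neighbor_reps,
                seed = derive_seed(seed, "neighbor")))
            obs <- clusteredFraction(cl, nrow(imp))
            neighbor_report[[pair]] <- list(
                n_imprinted = nrow(imp), observed_fraction = obs,
                reps = nullReps(null),
                null_mean = mean(nullValues(null)),
                null_p95 = nullQuantile(null, 0.95),
                exceeds = excessTest(obs, null))
        }
    }
    clusters <- if (length(cluster_rows)) do.call(rbind, cluster_rows)
                else data.frame(pair_id = character(), cluster_id = character(),
                                chrom = character(), members = character(),
                                size = integer(), cluster_type = character())
    utils::write.table(clusters, file.path(outDir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("clusters.tsv")
    jsonlite::write_json(neighbor_report, file.path(outDir, "neighbor_null.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    emit("neighbor_null.json")

    # ---- conservation across pairs
    if (length(pair_ids) >= 2L) {
        sets <- lapply(pair_ids, function(pair)
            calls$gene_id[calls$pair_id == pair & calls$class != "none"])
        names(sets) <- pair_ids
        ok <- lengths(sets) >= 1L
        if (sum(ok) >= 2L) {
            sets <- sets[ok]
            bg <- cfg$nulls$background_n
            if (is.null(bg)) bg <- nGenes(genome)
            obs <- overlapCounts(sets)
            pair_combos <- utils::combn(names(sets), 2L, simplify = FALSE)
            ov <- lapply(pair_combos, function(nmx) {
                null <- .stage("overlap_null", overlapNull(
                    lengths(sets[nmx]), bg, reps = cfg$nulls$overlap_reps,
                    seed = derive_seed(seed, "overlap")))
                o <- obs$pairwise[[paste(nmx, collapse = ":")]]
                list(sets = nmx, observed = o, reps = nullReps(null),
                     null_p95 = nullQuantile(null, 0.95),
                     exceeds = conservationVerdict(o, null))
            })
            report <- list(background_n = bg, sizes = as.list(obs$sizes),
                           pairwise = ov)
            if (length(sets) >= 3L) {
                null3 <- .stage("overlap_null", overlapNull(
                    lengths(sets), bg, reps = cfg$nulls$overlap_reps,
                    seed = derive_seed(seed, "overlap"), statistic = "kway"))
                report$kway <- list(observed = obs$kway,
                                    null_p95 = nullQuantile(null3, 0.95),
                                    exceeds = conservationVerdict(obs$kway, null3))
            }
            jsonlite::write_json(report, file.path(outDir, "overlap.json"),
                                 auto_unbox = TRUE, pretty = TRUE, digits = NA)
            emit("overlap.json")
        }
    }

    # ---- cross-species BHR
    if (!is.null(cfg$bhr$forward) && !is.null(cfg$bhr$reverse)) {
        pairs <- .stage("bhr", bhrMatch(readScoreTable(cfg$bhr$forward),
                                        readScoreTable(cfg$bhr$reverse),
                                        threshold = th$bhr))
        utils::write.table(pairs, file.path(outDir, "bhr_pairs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit("bhr_pairs.tsv")
        manifest$stages$bhr <- list(status = "run", n_pairs = nrow(pairs))
    } else {
        manifest$stages$bhr <- list(status = "skipped",
                                    reason = "no score tables configured")
    }

    emit("config.json")
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}
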