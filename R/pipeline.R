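#' @include AllClasses.R simulate.R scoring.R orthology.R aggregate.R
NULL

.stop2 <- function(class, ...) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = paste0(...), call = sys.call(-1))))
}

#' Assemble and validate a pipeline run configuration
#'
#' A run is configured by a flat key-value list (or a YAML file of the same
#' keys). Paths follow the fixture-bundle layout: one
#' \code{expr/<species>/<sample>.quant.sf} file per sample, a tab-separated
#' pair manifest, and per-species hit tables
#' \code{hits/hub__to__<sp>.tsv} / \code{hits/<sp>__to__hub.tsv}.
#'
#' Keys (defaults in parentheses): \code{input_dir} — bundle-layout
#' directory holding \code{expr/}, \code{hits/} and \code{manifest.tsv};
#' \code{hub_species} — which species anchors consolidation;
#' \code{out_dir} — report destination; \code{annotation} — optional TSV
#' \code{hub_id reference_id score}; \code{format} ("quant_sf");
#' \code{pseudocount} (0.01); \code{fold_threshold} (5);
#' \code{threshold_fraction} (0.2); \code{evalue_max} (1e-3);
#' \code{missing} ("error"); \code{strict} (FALSE).
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list.
#' @export
runConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config))
            .stop2("ioscore_validation_error",
                   "config file not found: '", config, "'")
        config <- yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    defaults <- list(format = "quant_sf", pseudocount = 0.01,
                     fold_threshold = 5, threshold_fraction = 0.2,
                     evalue_max = 1e-3, missing = "error", strict = FALSE,
                     annotation = NULL)
    for (k in names(defaults))
        if (is.null(config[[k]])) config[k] <- defaults[k]
    for (k in c("input_dir", "hub_species", "out_dir"))
        if (is.null(config[[k]]))
            .stop2("ioscore_validation_error",
                   "config key '", k, "' is required")
    if (!dir.exists(config$input_dir))
        .stop2("ioscore_validation_error",
               "input_dir does not exist: '", config$input_dir, "'")
    for (sub in c("expr", "hits"))
        if (!dir.exists(file.path(config$input_dir, sub)))
            .stop2("ioscore_validation_error",
                   "input_dir lacks the '", sub, "/' directory")
    if (!file.exists(file.path(config$input_dir, "manifest.tsv")))
        .stop2("ioscore_validation_error",
               "input_dir lacks manifest.tsv")
    if (!is.null(config$annotation) && !file.exists(config$annotation))
        .stop2("ioscore_validation_error",
               "annotation table not found: '", config$annotation, "'")
    if (config$pseudocount <= 0)
        .stop2("ioscore_validation_error", "pseudocount must be > 0")
    if (config$fold_threshold <= 1)
        .stop2("ioscore_validation_error", "fold_threshold must be > 1")
    if (config$threshold_fraction <= 0 || config$threshold_fraction > 1)
        .stop2("ioscore_validation_error",
               "threshold_fraction must be in (0, 1]")
    if (!config$missing %in% c("error", "zero"))
        .stop2("ioscore_validation_error",
               "missing policy must be 'error' or 'zero'")
    config
}

#' Run the full scoring pipeline on a bundle-layout directory
#'
#' Orchestrates the analysis end to end: per-species expression ingestion
#' and pair scoring, the pooled ratio-SD diagnostic, reciprocal-best-hit
#' resolution against the hub, consolidation into common ortholog groups,
#' total IO-score aggregation, threshold derivation and DEG calling, and
#' (optionally) reference-symbol annotation. All tables, a run log with
#' per-stage record counts, the effective configuration, and a
#' \code{summary.json} are written under \code{out_dir}. The pipeline is
#' deterministic: identical inputs and configuration give identical
#' outputs.
#'
#' @param config See \code{\link{runConfig}}.
#' @return Invisibly, a list with the per-species
#'   \linkS4class{IOScoreTable}s, \linkS4class{RBHMap}s, the
#'   \linkS4class{OrthologSet}, the called \linkS4class{TotalScoreResult},
#'   and the summary list.
#' @export
runPipeline <- function(config) {
    config <- runConfig(config)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(config$out_dir, "run.log")
    cat(sprintf("IOscore %s run started %s\n",
                as.character(utils::packageVersion("IOscore")),
                format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        file = logfile)
    logmsg <- function(...) {
        line <- paste0(...)
        cat(line, "\n", file = logfile, sep = "", append = TRUE)
        message(line)
    }
    cfg_echo <- config
    cfg_echo$strict <- isTRUE(config$strict)
    yaml::write_yaml(cfg_echo[order(names(cfg_echo))],
                     file.path(config$out_dir, "effective_config.yaml"))

    params <- scoringParams(config$pseudocount, config$fold_threshold)
    manifest <- readPairManifest(file.path(config$input_dir,
                                           "manifest.tsv"))
    species <- unique(manifest$species)
    if (!config$hub_species %in% species)
        .stop2("ioscore_validation_error", "hub species '",
               config$hub_species, "' absent from the manifest")
    logmsg("stage manifest: ", nrow(manifest), " pairs over ",
           length(species), " species (hub ", config$hub_species, ")")

    scoreTables <- list()
    sd_rows <- list()
    for (s in species) {
        sdir <- file.path(config$input_dir, "expr", s)
        files <- list.files(sdir, pattern = "\\.quant\\.sf$|\\.tsv$",
                            full.names = TRUE)
        if (!length(files))
            .stop2("ioscore_data_error",
                   "no expression files for species '", s, "' under '",
                   sdir, "'")
        names(files) <- sub("\\.(quant\\.sf|tsv)$", "", basename(files))
        tpm <- readExpression(files, format = config$format,
                              missing = config$missing)
        pr <- manifest[manifest$species == s, , drop = FALSE]
        absent <- setdiff(c(pr$intersexual_sample, pr$ovary_sample),
                          colnames(tpm))
        if (length(absent))
            .stop2("ioscore_data_error", "species '", s,
                   "': manifest sample(s) without expression files: ",
                   paste(absent, collapse = ", "))
        ps <- IOPairSet(tpm, pr, species = s)
        scoreTables[[s]] <- scoreSpecies(ps, params)
        diag <- ratioSdDiagnostic(scoreTables[[s]])
        sd_rows[[s]] <- data.frame(species = s, n_ratios = diag$n,
                                   mean = round(diag$mean, 6),
                                   sd = round(diag$sd, 6),
                                   fold_at_2sd = round(diag$fold_at_2sd,
                                                       6))
        logmsg("stage score [", s, "]: ", nrow(tpm), " transcripts x ",
               nrow(pr), " pairs")
    }

    others <- setdiff(species, config$hub_species)
    rbhMaps <- list()
    for (s in others) {
        f_fwd <- file.path(config$input_dir, "hits",
                           sprintf("hub__to__%s.tsv", s))
        f_rev <- file.path(config$input_dir, "hits",
                           sprintf("%s__to__hub.tsv", s))
        if (!file.exists(f_fwd) || !file.exists(f_rev))
            .stop2("ioscore_data_error",
                   "missing hit tables for species '", s, "'")
        fwd <- readHits(f_fwd, config$evalue_max)
        rev <- readHits(f_rev, config$evalue_max)
        rbhMaps[[s]] <- reciprocalBestHits(fwd, rev, species = s)
        logmsg("stage rbh [", s, "]: ", nrow(fwd), "+", nrow(rev),
               " hits in -> ", nrow(rbhPairs(rbhMaps[[s]])), " RBH pairs")
    }

    orthologs <- consolidateOrthologs(rbhMaps,
                                      hubSpecies = config$hub_species)
    n_common <- length(commonOrthologs(orthologs))
    logmsg("stage consolidate: ", nrow(orthologGroups(orthologs)),
           " groups, ", n_common, " common to all species")

    result <- totalIOScore(orthologs, scoreTables,
                           strict = isTRUE(config$strict))
    threshold <- deriveTotalThreshold(nrow(manifest),
                                      config$threshold_fraction)
    result <- callDEGs(result, threshold)
    rec <- totalScores(result)
    logmsg("stage call: threshold +/-", threshold, " -> ",
           sum(rec$call == "up"), " up, ", sum(rec$call == "down"),
           " down, ", sum(rec$call == "unchanged"), " unchanged")

    n_unmapped <- NA_integer_
    if (!is.null(config$annotation)) {
        ann <- data.table::fread(config$annotation, sep = "\t",
                                 data.table = FALSE, showProgress = FALSE)
        result <- annotateRecords(result, ann)
        n_unmapped <- S4Vectors::metadata(totalScores(result))$n_unmapped
        logmsg("stage annotate: ", nrow(rec) - n_unmapped, " mapped, ",
               n_unmapped, " unmapped")
    }

    .write_run_outputs(config$out_dir, scoreTables, sd_rows, rbhMaps,
                       orthologs, result)
    summary <- list(
        species = species, hub_species = config$hub_species,
        n_pairs_total = nrow(manifest),
        pairs_per_species = as.list(table(manifest$species)[species]),
        rbh_per_species = lapply(rbhMaps, function(m)
            nrow(rbhPairs(m))),
        n_groups = nrow(orthologGroups(orthologs)),
        n_common_orthologs = n_common,
        threshold = threshold,
        n_up = sum(rec$call == "up"), n_down = sum(rec$call == "down"),
        n_unchanged = sum(rec$call == "unchanged"),
        n_unmapped = n_unmapped)
    jsonlite::write_json(summary, file.path(config$out_dir,
                                            "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    logmsg("run complete: outputs under ", config$out_dir)
    invisible(list(scoreTables = scoreTables, rbhMaps = rbhMaps,
                   orthologs = orthologs, result = result,
                   summary = summary))
}

.write_run_outputs <- function(out_dir, scoreTables, sd_rows, rbhMaps,
                               orthologs, result) {
    scdir <- file.path(out_dir, "scores")
    dir.create(scdir, showWarnings = FALSE)
    for (s in names(scoreTables)) {
        sc <- as.data.frame(ioScores(scoreTables[[s]]))
        data.table::fwrite(sc, file.path(scdir,
                                         sprintf("%s_scores.tsv", s)),
                           sep = "\t")
        rt <- as.data.frame(ioRatios(scoreTables[[s]]))
        rt$io_ratio <- round(rt$io_ratio, 6)
        data.table::fwrite(rt, file.path(scdir,
                                         sprintf("%s_ratios.tsv", s)),
                           sep = "\t")
    }
    data.table::fwrite(do.call(rbind, c(sd_rows,
                                        make.row.names = FALSE)),
                       file.path(out_dir, "sd_diagnostic.tsv"), sep = "\t")
    rbh <- do.call(rbind, lapply(rbhMaps, function(m) data.frame(
        hub_id = rbhPairs(m)$hub_id, species = speciesName(m),
        member_id = rbhPairs(m)$member_id, stringsAsFactors = FALSE)))
    data.table::fwrite(rbh, file.path(out_dir, "rbh.tsv"), sep = "\t")
    data.table::fwrite(
        data.frame(hub_id = commonOrthologs(orthologs)),
        file.path(out_dir, "common_orthologs.tsv"), sep = "\t")
    rec <- as.data.frame(totalScores(result))
    rec <- rec[order(rec$rank), , drop = FALSE]
    data.table::fwrite(rec, file.path(out_dir, "total_scores.tsv"),
                       sep = "\t")
    data.table::fwrite(compositionTable(result),
                       file.path(out_dir, "composition.tsv"), sep = "\t")
}

#' Produce plot-ready report tables from a completed run
#'
#' Reads the artifacts a \code{\link{runPipeline}} run left under
#' \code{out_dir} and writes \code{rank_table.tsv} — one row per common
#' ortholog in descending total-IO-score order (the scatterplot-ready
#' ranking) — returning the rank, composition and SD-diagnostic tables.
#'
#' @param out_dir A completed run directory.
#' @return Invisibly, list with \code{rank_table}, \code{composition},
#'   \code{sd_diagnostic} data.frames.
#' @export
reportRun <- function(out_dir) {
    need <- c("total_scores.tsv", "composition.tsv", "sd_diagnostic.tsv")
    absent <- need[!file.exists(file.path(out_dir, need))]
    if (length(absent))
        .stop2("ioscore_data_error", "run artifacts missing under '",
               out_dir, "': ", paste(absent, collapse = ", "))
    total <- data.table::fread(file.path(out_dir, "total_scores.tsv"),
                               sep = "\t", data.table = FALSE,
                               showProgress = FALSE)
    rank_table <- total[order(total$rank),
                        c("rank", "hub_id", "total", "call"),
                        drop = FALSE]
    data.table::fwrite(rank_table, file.path(out_dir, "rank_table.tsv"),
                       sep = "\t")
    composition <- data.table::fread(file.path(out_dir,
                                               "composition.tsv"),
                                     sep = "\t", data.table = FALSE,
                                     showProgress = FALSE)
    sd_diag <- data.table::fread(file.path(out_dir, "sd_diagnostic.tsv"),
                                 sep = "\t", data.table = FALSE,
                                 showProgress = FALSE)
    invisible(list(rank_table = rank_table, composition = composition,
                   sd_diagnostic = sd_diag))
}
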