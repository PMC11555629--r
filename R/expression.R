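#' @include AllClasses.R
NULL

.QUANT_SF_COLS <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")

.read_one_expression <- function(path, format) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = TRUE, showProgress = FALSE)
    if (format == "quant_sf") {
        if (!all(.QUANT_SF_COLS %in% colnames(dt)))
            stop("malformed quant.sf header in '", path, "': expected ",
                 paste(.QUANT_SF_COLS, collapse = "\t"))
        out <- dt[, c("Name", "TPM")]
    } else {
        if (!all(c("transcript_id", "tpm") %in% colnames(dt)))
            stop("malformed TSV header in '", path,
                 "': expected transcript_id\ttpm")
        out <- dt[, c("transcript_id", "tpm")]
    }
    names(out) <- c("transcript_id", "tpm")
    if (anyDuplicated(out$transcript_id))
        stop("duplicate transcript id in '", path, "': ",
             out$transcript_id[duplicated(out$transcript_id)][1L])
    if (!is.numeric(out$tpm) || any(!is.finite(out$tpm)))
        stop("non-numeric TPM values in '", path, "'")
    if (any(out$tpm < 0))
        stop("negative TPM in '", path, "'")
    out
}

#' Read per-sample transcript abundance tables into a TPM matrix
#'
#' Ingests one abundance file per sample, either in the \code{quant.sf}
#' dialect (tab-separated with header
#' \code{Name Length EffectiveLength TPM NumReads}; only Name and TPM are
#' used) or as a generic two-column TSV (\code{transcript_id} and
#' \code{tpm}, header required).
#'
#' Transcript sets are expected to agree across the samples of a species
#' (quantification against one merged annotation guarantees this). When they
#' do not, \code{missing = "error"} aborts naming an offending transcript;
#' \code{missing = "zero"} imputes 0 TPM with a warning — the pseudocount
#' keeps downstream log ratios finite.
#'
#' @param files Character vector of file paths; names become sample ids
#'   (defaults to base names without extension).
#' @param format \code{"quant_sf"} or \code{"tsv"}.
#' @param missing Policy for transcripts absent from some samples.
#' @return Numeric matrix, transcripts x samples.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("Name\tLength\tEffectiveLength\tTPM\tNumReads",
#'              "t1\t500\t350\t10\t35", "t2\t800\t650\t0\t0"),
#'            file.path(dir, "s1.quant.sf"))
#' readExpression(c(s1 = file.path(dir, "s1.quant.sf")))
#' @export
readExpression <- function(files, format = c("quant_sf", "tsv"),
                           missing = c("error", "zero")) {
    format <- match.arg(format)
    missing <- match.arg(missing)
    if (!length(files)) stop("no expression files given")
    ids <- names(files)
    if (is.null(ids))
        ids <- sub("\\.(quant\\.sf|sf|tsv|txt)$", "", basename(files))
    tabs <- lapply(files, .read_one_expression, format = format)
    all_tx <- unique(unlist(lapply(tabs, `[[`, "transcript_id")))
    mat <- matrix(NA_real_, nrow = length(all_tx), ncol = length(tabs),
                  dimnames = list(all_tx, ids))
    for (j in seq_along(tabs))
        mat[tabs[[j]]$transcript_id, j] <- tabs[[j]]$tpm
    if (anyNA(mat)) {
        bad <- which(is.na(mat), arr.ind = TRUE)
        ex <- sprintf("'%s' missing from sample '%s'",
                      rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]])
        if (missing == "error")
            stop("transcript sets differ across samples: e.g. ", ex,
                 " (use missing = \"zero\" to impute)")
        warning(sum(is.na(mat)), " missing transcript/sample entries ",
                "imputed as 0 TPM (e.g. ", ex, ")")
        mat[is.na(mat)] <- 0
    }
    mat
}

#' Read a curated sample-pair manifest
#'
#' Tab-separated with header
#' \code{species pair_id intersexual_sample ovary_sample}; each row curates
#' one comparable intersexual-gonad / ovary pair.
#'
#' @param path Manifest file path.
#' @return data.frame with the four manifest columns.
#' @export
readPairManifest <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE, showProgress = FALSE,
                            colClasses = "character")
    need <- c("species", "pair_id", "intersexual_sample", "ovary_sample")
    if (!all(need %in% colnames(dt)))
        stop("malformed manifest header in '", path, "': expected ",
             paste(need, collapse = "\t"))
    if (anyDuplicated(dt[, c("species", "pair_id")]))
        stop("pair_id values must be unique within a species")
    if (any(dt$intersexual_sample == dt$ovary_sample))
        stop("a pair's intersexual and ovary samples must differ")
    dt[, need]
}

#' Construct an IOPairSet
#'
#' Bundles a TPM matrix with its curated pairing into a
#' \linkS4class{IOPairSet} (a \linkS4class{SummarizedExperiment} with a
#' \code{"TPM"} assay).
#'
#' @param tpm Numeric matrix, transcripts x samples, with dimnames.
#' @param pairs data.frame with columns \code{pair_id},
#'   \code{intersexual}/\code{intersexual_sample} and
#'   \code{ovary}/\code{ovary_sample}.
#' @param species Species identifier.
#' @return An \linkS4class{IOPairSet}.
#' @examples
#' tpm <- matrix(c(1, 2, 5, 0.4), 2, 2,
#'               dimnames = list(c("t1", "t2"), c("I1", "O1")))
#' IOPairSet(tpm, data.frame(pair_id = "p1", intersexual = "I1",
#'                           ovary = "O1"), species = "spA")
#' @export
IOPairSet <- function(tpm, pairs, species) {
    pairs <- as.data.frame(pairs)
    if ("intersexual_sample" %in% colnames(pairs))
        pairs$intersexual <- pairs$intersexual_sample
    if ("ovary_sample" %in% colnames(pairs))
        pairs$ovary <- pairs$ovary_sample
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(TPM = tpm))
    new("IOPairSet", se,
        pairs = S4Vectors::DataFrame(
            pairs[, c("pair_id", "intersexual", "ovary")]),
        species = as.character(species))
}
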