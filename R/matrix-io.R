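# Tabular readers/writers for the formats the package touches. Matrices are
# delimited tables with the probe id in the first column and sample ids in
# the header; the delimiter is auto-detected between tab and comma (GEO
# series use both) and written output is always TSV. Lines starting with '#'
# are treated as provenance comments and skipped.

.detectSep <- function(path) {
    con <- file(path, "r"); on.exit(close(con))
    repeat {
        line <- readLines(con, n = 1L)
        if (!length(line)) stop("empty file: ", path)
        if (!startsWith(line, "#")) break
    }
    nt <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
    nc <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
    if (nt >= nc) "\t" else ","
}

.readDelim <- function(path) {
    utils::read.delim(path, sep = .detectSep(path), header = TRUE,
                      comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE)
}

.readNumericMatrix <- function(path) {
    df <- .readDelim(path)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate probe ids in ", path, ": ",
             paste(utils::head(unique(ids[duplicated(ids)]), 5L),
                   collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
}

.fewIds <- function(x, n = 5L) {
    extra <- if (length(x) > n) sprintf(" (+%d more)", length(x) - n) else ""
    paste0(paste(utils::head(x, n), collapse = ", "), extra)
}

.handleMissing <- function(m, dropIncomplete, what) {
    if (!anyNA(m)) return(m)
    if (!dropIncomplete)
        stop(what, " contains missing values; use dropIncomplete = TRUE ",
             "to drop affected probes")
    bad <- rowSums(is.na(m)) > 0
    message("dropping ", sum(bad), " probe(s) with missing values")
    m[!bad, , drop = FALSE]
}

#' Read paired methylated/unmethylated intensity matrices
#'
#' Loads the M and U channel tables, aligns the U channel to the probe and
#' sample order of the M file, and validates non-negativity and
#' completeness.
#'
#' @param pathM,pathU delimited tables (first column probe id, header row
#'   sample ids) for the methylated and unmethylated channels.
#' @param dropIncomplete drop probes carrying any missing intensity instead
#'   of failing (default `FALSE`, strict).
#' @return a [MethylChannels-class] object.
#' @export
readChannelMatrix <- function(pathM, pathU, dropIncomplete = FALSE) {
    M <- .readNumericMatrix(pathM)
    U <- .readNumericMatrix(pathU)
    missP <- setdiff(rownames(M), rownames(U))
    extraP <- setdiff(rownames(U), rownames(M))
    if (length(missP) || length(extraP))
        stop("probe sets differ between channels; missing from U: ",
             .fewIds(missP), "; extra in U: ", .fewIds(extraP))
    missS <- setdiff(colnames(M), colnames(U))
    extraS <- setdiff(colnames(U), colnames(M))
    if (length(missS) || length(extraS))
        stop("sample sets differ between channels; missing from U: ",
             .fewIds(missS), "; extra in U: ", .fewIds(extraS))
    U <- U[rownames(M), colnames(M), drop = FALSE]
    keep <- !(rowSums(is.na(M)) > 0 | rowSums(is.na(U)) > 0)
    if (!all(keep)) {
        if (!dropIncomplete)
            stop("intensity matrices contain missing values; use ",
                 "dropIncomplete = TRUE to drop affected probes")
        message("dropping ", sum(!keep), " probe(s) with missing values")
        M <- M[keep, , drop = FALSE]; U <- U[keep, , drop = FALSE]
    }
    for (nm in c("M", "U")) {
        a <- if (nm == "M") M else U
        if (any(a < 0)) {
            bad <- rownames(a)[rowSums(a < 0) > 0]
            stop("negative intensities in ", nm, " channel at probe(s): ",
                 .fewIds(bad))
        }
    }
    new("MethylChannels",
        SummarizedExperiment(assays = list(M = M, U = U)))
}

#' Read a beta-value matrix
#'
#' @param path delimited table of beta values (first column probe id,
#'   header row sample ids).
#' @inheritParams readChannelMatrix
#' @return a [BetaSet-class].
#' @export
readBetaMatrix <- function(path, dropIncomplete = FALSE) {
    m <- .handleMissing(.readNumericMatrix(path), dropIncomplete,
                        "beta matrix")
    if (any(m < 0) || any(m > 1)) {
        bad <- rownames(m)[rowSums(m < 0 | m > 1) > 0]
        stop("beta values outside [0, 1] at probe(s): ", .fewIds(bad))
    }
    BetaSet(m)
}

#' Construct a BetaSet from a matrix
#'
#' @param beta numeric probes x samples matrix in \eqn{[0,1]} with probe
#'   rownames and sample colnames.
#' @param annotation optional probe-annotation data.frame (see
#'   [readProbeAnnotation()]); rows matching the matrix probes populate
#'   \code{rowData()}.
#' @param sampleSheet optional sample sheet (see [readSampleSheet()]);
#'   rows matching the matrix samples populate \code{colData()}.
#' @return a [BetaSet-class].
#' @export
BetaSet <- function(beta, annotation = NULL, sampleSheet = NULL) {
    if (is.null(colnames(beta)))
        colnames(beta) <- paste0("S", seq_len(ncol(beta)))
    se <- SummarizedExperiment(assays = list(beta = beta))
    x <- new("BetaSet", se)
    if (!is.null(annotation) || !is.null(sampleSheet))
        x <- alignDataset(x, annotation, sampleSheet)
    x
}

#' Construct a SortedReference
#'
#' @param beta numeric probes x samples beta matrix (or a [BetaSet]).
#' @param cellType character/factor of per-sample cell-type labels.
#' @param age optional numeric per-sample ages in years.
#' @return a [SortedReference-class].
#' @export
SortedReference <- function(beta, cellType, age = NULL) {
    b <- .asBetaMatrix(beta)
    cd <- DataFrame(cell_type = as.character(cellType),
                    row.names = colnames(b))
    if (!is.null(age)) cd$age <- as.numeric(age)
    se <- SummarizedExperiment(assays = list(beta = b), colData = cd)
    new("SortedReference", se)
}

#' Read a probe-annotation table
#'
#' Expects columns \code{probe_id} and \code{chromosome} (labels
#' \code{chr1}..\code{chr22}, \code{chrX}, \code{chrY}); optional logical
#' flags \code{snp_at_cpg}, \code{snp_at_sbe}, \code{snp_in_probe} and an
#' optional \code{gene_id} column (multiple genes separated by \code{;}).
#'
#' @param path delimited annotation table.
#' @return validated data.frame, one row per probe.
#' @export
readProbeAnnotation <- function(path) {
    df <- .readDelim(path)
    if (!all(c("probe_id", "chromosome") %in% colnames(df)))
        stop("annotation needs 'probe_id' and 'chromosome' columns")
    if (anyDuplicated(df$probe_id))
        stop("annotation has duplicated probe ids")
    allowed <- c(paste0("chr", 1:22), "chrX", "chrY")
    bad <- setdiff(unique(df$chromosome), allowed)
    if (length(bad))
        stop("unrecognised chromosome label(s): ", .fewIds(bad))
    for (fl in c("snp_at_cpg", "snp_at_sbe", "snp_in_probe"))
        if (fl %in% colnames(df)) df[[fl]] <- as.logical(df[[fl]])
    df
}

#' Read a sample sheet
#'
#' Expects a \code{sample_id} column; optional \code{age} (years),
#' \code{cell_type}, \code{plate} and \code{study} columns.
#'
#' @param path delimited sample-sheet table.
#' @return validated data.frame, one row per sample.
#' @export
readSampleSheet <- function(path) {
    df <- .readDelim(path)
    if (!"sample_id" %in% colnames(df))
        stop("sample sheet needs a 'sample_id' column")
    if (anyDuplicated(df$sample_id))
        stop("sample sheet has duplicated sample ids")
    if ("age" %in% colnames(df)) {
        df$age <- as.numeric(df$age)
        if (any(!is.na(df$age) & df$age < 0))
            stop("sample sheet contains negative ages")
    }
    df
}

#' Align a matrix with its annotation and sample sheet
#'
#' Intersects the probes of `x` with the annotation and its samples with
#' the sample sheet, reports how many were dropped on each side, and
#' attaches the matching rows as `rowData()`/`colData()`. Matrix order is
#' preserved; the operation is idempotent.
#'
#' @param x a [BetaSet] or [MethylChannels] object.
#' @param annotation optional probe-annotation data.frame.
#' @param sampleSheet optional sample-sheet data.frame.
#' @param verbose message the drop counts (default `TRUE`).
#' @return `x` subset to the common probes/samples, with annotation and
#'   sheet attached and drop counts recorded in
#'   `metadata(x)$alignment`.
#' @export
alignDataset <- function(x, annotation = NULL, sampleSheet = NULL,
                         verbose = TRUE) {
    stopifnot(is(x, "SummarizedExperiment"))
    dropped <- c(probes_matrix = 0L, probes_annotation = 0L,
                 samples_matrix = 0L, samples_sheet = 0L)
    if (!is.null(annotation)) {
        keep <- rownames(x) %in% annotation$probe_id
        if (!any(keep)) stop("no probes shared with the annotation")
        dropped["probes_matrix"] <- sum(!keep)
        dropped["probes_annotation"] <-
            sum(!annotation$probe_id %in% rownames(x))
        x <- x[keep, ]
        ann <- annotation[match(rownames(x), annotation$probe_id), ,
                          drop = FALSE]
        rowData(x) <- DataFrame(ann, row.names = rownames(x))
    }
    if (!is.null(sampleSheet)) {
        keep <- colnames(x) %in% sampleSheet$sample_id
        if (!any(keep)) stop("no samples shared with the sample sheet")
        dropped["samples_matrix"] <- sum(!keep)
        dropped["samples_sheet"] <-
            sum(!sampleSheet$sample_id %in% colnames(x))
        x <- x[, keep]
        sh <- sampleSheet[match(colnames(x), sampleSheet$sample_id), ,
                          drop = FALSE]
        colData(x) <- DataFrame(sh, row.names = colnames(x))
    }
    if (verbose && any(dropped > 0))
        message("alignment dropped: ",
                paste(names(dropped)[dropped > 0], dropped[dropped > 0],
                      sep = "=", collapse = ", "))
    metadata(x)$alignment <- as.list(dropped)
    x
}

.writeTsv <- function(df, path, provenance = NULL) {
    con <- file(path, "w"); on.exit(close(con))
    if (!is.null(provenance))
        writeLines(paste0("# ", provenance), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a beta matrix (or any probes x samples matrix) as TSV
#'
#' @param x a [BetaSet], [CellProportions] (normalised copy is written) or
#'   plain matrix.
#' @param path output path; always tab-separated, probe id first column.
#' @param provenance optional character vector written as leading
#'   \code{#} comment lines.
#' @return the path, invisibly.
#' @export
writeBetaMatrix <- function(x, path, provenance = NULL) {
    m <- if (is(x, "BetaSet")) assay(x, "beta") else x
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
    .writeTsv(df, path, provenance)
}
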