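# Gene-set over-representation for CpG lists by observed/expected count
# ratios, counted at the CpG level, before and after composition
# filtering. No ontology database is bundled: sets load from a two-column
# TSV (or GMT), so GO, KEGG or synthetic collections are interchangeable.

#' Read gene sets
#'
#' `readGeneSets()` expects a two-column delimited table `set_id`,
#' `gene_id` (one row per membership) plus an optional metadata table with
#' a `set_id` column (e.g. set names and ontology labels). `readGmt()`
#' accepts the tab-separated GMT convention
#' (set id, description, member genes...).
#'
#' @param path membership table (or GMT file).
#' @param metaPath optional metadata table.
#' @return named list of unique gene-id vectors; metadata, when given, is
#'   attached as the `"meta"` attribute.
#' @export
readGeneSets <- function(path, metaPath = NULL) {
    df <- .readDelim(path)
    if (!all(c("set_id", "gene_id") %in% colnames(df)))
        stop("gene-set table needs 'set_id' and 'gene_id' columns")
    sets <- lapply(split(as.character(df$gene_id), df$set_id), unique)
    if (!is.null(metaPath)) attr(sets, "meta") <- .readDelim(metaPath)
    sets
}

#' @rdname readGeneSets
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(x) unique(x[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, character(1), 1L)
    sets
}

#' Map CpGs to gene ids
#'
#' @param cpgs character vector of CpG/probe ids.
#' @param annotation probe annotation with `probe_id` and `gene_id`
#'   columns; multiple genes per probe may be separated by `;` or `,`.
#'   Empty or missing gene ids count as unmapped.
#' @return list with `map` (data.frame `cpg`, `gene`, one row per pair),
#'   `n_mapped` and `n_unmapped`.
#' @export
mapCpgsToGenes <- function(cpgs, annotation) {
    if (!"gene_id" %in% colnames(annotation))
        stop("annotation has no 'gene_id' column")
    g <- as.character(annotation$gene_id[
        match(cpgs, annotation$probe_id)])
    g[is.na(g) | g == ""] <- NA_character_
    genes <- strsplit(g, "[;,]\\s*")
    n <- lengths(genes); n[is.na(g)] <- 0L
    map <- data.frame(cpg = rep(cpgs, n),
                      gene = unlist(genes[n > 0L], use.names = FALSE),
                      row.names = NULL)
    list(map = map, n_mapped = sum(n > 0L), n_unmapped = sum(n == 0L))
}

#' Observed/expected gene-set enrichment for a CpG list
#'
#' For each gene set with at least `minSetGenes` member genes present in
#' the background gene universe: the observed count is the number of
#' query CpGs mapping to any gene in the set; the expected count is the
#' mapped query size times the background fraction of CpGs in the set
#' (uniform-mapping null); their ratio is the enrichment statistic and a
#' one-sided hypergeometric p value ranks the sets. A CpG mapping to
#' several genes of one set is counted once.
#'
#' @param query character vector of query CpG ids; must be a subset of
#'   the background CpGs.
#' @param backgroundMap CpG-to-gene map for the background, as returned in
#'   `$map` by [mapCpgsToGenes()] (columns `cpg`, `gene`).
#' @param sets named list of gene-id vectors (see [readGeneSets()]).
#' @param minSetGenes minimum genes (present in the background universe)
#'   for a set to be evaluated; default 25.
#' @return data.frame ordered by p value: `set_id`, `set_size` (genes in
#'   background), `n_bg_cpgs`, `observed`, `expected`, `ratio`, `p`,
#'   `rank`.
#' @export
obsExpEnrichment <- function(query, backgroundMap, sets, minSetGenes = 25) {
    bgCpgs <- unique(backgroundMap$cpg)
    out <- setdiff(query, bgCpgs)
    if (length(out))
        stop("query CpGs absent from the background: ", .fewIds(out))
    bgGenes <- unique(backgroundMap$gene)
    qMap <- backgroundMap[backgroundMap$cpg %in% query, , drop = FALSE]
    nBg <- length(bgCpgs)
    nQuery <- length(unique(qMap$cpg))
    rows <- lapply(names(sets), function(s) {
        genes <- intersect(sets[[s]], bgGenes)
        if (length(genes) < minSetGenes) return(NULL)
        inSet <- backgroundMap$gene %in% genes
        nSet <- length(unique(backgroundMap$cpg[inSet]))
        obs <- length(unique(qMap$cpg[qMap$gene %in% genes]))
        expd <- nQuery * nSet / nBg
        data.frame(set_id = s, set_size = length(genes),
                   n_bg_cpgs = nSet, observed = obs, expected = expd,
                   ratio = obs / expd,
                   p = stats::phyper(obs - 1, nSet, nBg - nSet, nQuery,
                                     lower.tail = FALSE),
                   row.names = NULL)
    })
    res <- do.call(rbind, rows)
    if (is.null(res))
        return(data.frame(set_id = character(), set_size = integer(),
                          n_bg_cpgs = integer(), observed = integer(),
                          expected = numeric(), ratio = numeric(),
                          p = numeric(), rank = integer()))
    res <- res[order(res$p, res$set_id), , drop = FALSE]
    res$rank <- rank(res$p, ties.method = "min")
    rownames(res) <- NULL
    res
}

#' Enrichment before and after composition filtering
#'
#' Runs [obsExpEnrichment()] on the raw query and again after removing
#' composition-associated CpGs with [compositionFilter()], and reports the
#' per-set rank shift: immune-driven sets typically fall in rank once
#' composition-associated CpGs are removed, while trait-specific ones
#' rise.
#'
#' @inheritParams obsExpEnrichment
#' @param stats a [compositionAnova()] table covering the query.
#' @param pCut,rangeCut composition-filter thresholds, see
#'   [compositionFilter()].
#' @return list with `before`, `after` (enrichment tables) and
#'   `comparison` (`set_id`, `ratio_before`, `ratio_after`,
#'   `rank_before`, `rank_after`, `rank_shift` = before - after).
#' @export
beforeAfterComparison <- function(query, stats, backgroundMap, sets,
                                  pCut = 1e-4, rangeCut = 0.10,
                                  minSetGenes = 25) {
    filt <- compositionFilter(query, stats, pCut = pCut,
                              rangeCut = rangeCut)
    if (!length(filt$retained))
        stop("composition filtering removed every query CpG; ",
             "nothing to enrich")
    before <- obsExpEnrichment(query, backgroundMap, sets, minSetGenes)
    after <- obsExpEnrichment(filt$retained, backgroundMap, sets,
                              minSetGenes)
    comp <- merge(before[, c("set_id", "ratio", "rank")],
                  after[, c("set_id", "ratio", "rank")],
                  by = "set_id", suffixes = c("_before", "_after"))
    comp$rank_shift <- comp$rank_before - comp$rank_after
    comp <- comp[order(comp$rank_before), , drop = FALSE]
    rownames(comp) <- NULL
    list(before = before, after = after, comparison = comp,
         filter_report = filt$report)
}
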