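.subsetDataset <- function(dataset, keep) {
  rec <- dataset@records[keep, , drop = FALSE]
  rownames(rec) <- NULL
  initialize(dataset, records = rec)
}

#' Extract variants within a cis-window around gene regions
#'
#' Returns the records whose position falls in `[start - flankBp,
#' end + flankBp]` (1-based inclusive) of any of the supplied regions, on
#' the matching chromosome. Overlapping windows are implicitly merged: each
#' variant appears at most once, in its original record order.
#'
#' @param dataset a [SummaryDataset-class].
#' @param region `GRanges` of one or more gene regions.
#' @param flankBp non-negative flank in base pairs added to both ends.
#' @return A [SummaryDataset-class] subset (possibly empty).
#' @export
extractCisWindow <- function(dataset, region, flankBp = 0L) {
  stopifnot(is(dataset, "SummaryDataset"), flankBp >= 0)
  rec <- dataset@records
  if (nrow(rec) == 0L) return(dataset)
  vGr <- GenomicRanges::GRanges(seqnames = rec$chromosome,
                                ranges = IRanges::IRanges(start = rec$position,
                                                          width = 1L))
  win <- suppressWarnings(region + flankBp)  # expands both ends; may clip at 1
  # variants and regions may legitimately cover disjoint chromosomes
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vGr, win))
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  .subsetDataset(dataset, keep)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' `q_(i) = min over j >= i of (m * p_(j) / j)`, capped at 1, returned in
#' the input order.
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @return q-values aligned with the input.
#' @export
bhFdr <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the unremoved variant with the smallest p-value as an
#' index (ties broken by position, then variant id) and removes every
#' unselected variant within `windowKb` of the index whose squared LD
#' correlation with it exceeds `r2Threshold` (strictly). Window distance is
#' measured between variant positions.
#'
#' @param dataset a [SummaryDataset-class]; every variant must appear in
#'   `ld`.
#' @param ld LD correlation matrix with variant-id dimnames.
#' @param r2Threshold removal threshold on r-squared, in [0, 1].
#' @param windowKb clumping window in kilobases.
#' @return The retained [SummaryDataset-class] subset (original record
#'   order); `attr(, "selectionLog")` records every index/removal decision.
#' @export
clumpVariants <- function(dataset, ld, r2Threshold = 0.01, windowKb = 500) {
  stopifnot(is(dataset, "SummaryDataset"),
            r2Threshold >= 0, r2Threshold <= 1)
  checkLdMatrix(ld)
  rec <- dataset@records
  missing <- setdiff(rec$variant_id, rownames(ld))
  if (length(missing))
    stop("variants missing from LD matrix: ", paste(missing, collapse = ", "))

  ord <- order(rec$pvalue, rec$position, rec$variant_id)
  state <- rep("open", nrow(rec))  # open | index | removed
  log <- list()
  for (i in ord) {
    if (state[i] != "open") next
    state[i] <- "index"
    log[[length(log) + 1L]] <- data.frame(variant_id = rec$variant_id[i],
                                          step = "clump", action = "index",
                                          stringsAsFactors = FALSE)
    near <- which(state == "open" &
                    abs(rec$position - rec$position[i]) <= windowKb * 1000)
    if (length(near)) {
      r2 <- ld[rec$variant_id[near], rec$variant_id[i]]^2
      hit <- near[r2 > r2Threshold]
      if (length(hit)) {
        state[hit] <- "removed"
        log[[length(log) + 1L]] <- data.frame(
          variant_id = rec$variant_id[hit], step = "clump",
          action = sprintf("removed_by=%s", rec$variant_id[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- .subsetDataset(dataset, which(state == "index"))
  attr(out, "selectionLog") <- do.call(rbind, c(log, list(make.row.names = FALSE)))
  out
}

.logRows <- function(ids, step, action) {
  if (!length(ids)) return(NULL)
  data.frame(variant_id = ids, step = step, action = action,
             stringsAsFactors = FALSE)
}

.designatedProxySet <- function(dataset, spec) {
  present <- intersect(spec@designatedProxies, dataset@records$variant_id)
  if (!length(present)) return(NULL)
  keep <- dataset@records$variant_id %in% present
  new("InstrumentSet", drugClass = spec@drugClass, mode = "designated_proxy",
      variants = .subsetDataset(dataset, keep), ld = NULL,
      selectionLog = .logRows(present, "designated_proxy", "force_included"))
}

.selectInstruments <- function(dataset, spec, ld, mode, flankBp,
                               keepFun, keepStep, r2Threshold, windowKb,
                               attachLd) {
  cis <- extractCisWindow(dataset, spec@regions, flankBp)
  log <- .logRows(variantIds(cis), "cis_window", "retained")
  if (nVariants(cis) > 0L) {
    keep <- keepFun(cis@records$pvalue)
    log <- rbind(log, .logRows(variantIds(cis)[!keep], keepStep, "removed"))
    cis <- .subsetDataset(cis, keep)
  }
  if (nVariants(cis) > 0L) {
    pal <- isPalindromic(cis@records$effect_allele, cis@records$other_allele)
    log <- rbind(log, .logRows(variantIds(cis)[pal], "palindrome", "removed"))
    cis <- .subsetDataset(cis, !pal)
  }
  if (nVariants(cis) == 0L) return(list(set = NULL, log = log))
  cis <- clumpVariants(cis, ld, r2Threshold = r2Threshold, windowKb = windowKb)
  log <- rbind(log, attr(cis, "selectionLog"))
  ids <- variantIds(cis)
  set <- new("InstrumentSet", drugClass = spec@drugClass, mode = mode,
             variants = cis,
             ld = if (attachLd) ld[ids, ids, drop = FALSE] else NULL,
             selectionLog = log)
  list(set = set, log = log)
}

#' Select discovery-mode genetic instruments for a drug-target gene set
#'
#' Applies the discovery rule sequence: union of cis-windows (default
#' +/- 2500 bp) over the target's encoding genes, Benjamini-Hochberg FDR
#' filter (default q < 0.05, computed within the pooled cis-window set),
#' palindrome exclusion, then greedy LD clumping (default r-squared 0.01,
#' 500 kb window). Designated proxy variants named by the target spec are
#' never merged into the discovery set: whenever present in `dataset` they
#' are emitted as a separate `designated_proxy` instrument set, whether or
#' not they pass the filters.
#'
#' @param dataset exposure-trait [SummaryDataset-class].
#' @param spec a [DrugTargetSpec-class].
#' @param ld LD correlation matrix covering the cis-window variants.
#' @param fdrThreshold strict BH q-value cutoff.
#' @param flankBp cis-window flank in bp.
#' @param r2Threshold,windowKb clumping parameters.
#' @return list with elements `discovery` ([InstrumentSet-class] or `NULL`)
#'   and `designated_proxy` ([InstrumentSet-class] or `NULL`). An error is
#'   raised when nothing survives and no designated proxy is available.
#' @export
selectInstrumentsDiscovery <- function(dataset, spec, ld,
                                       fdrThreshold = 0.05, flankBp = 2500,
                                       r2Threshold = 0.01, windowKb = 500) {
  res <- .selectInstruments(dataset, spec, ld, mode = "discovery",
                            flankBp = flankBp,
                            keepFun = function(p) bhFdr(p) < fdrThreshold,
                            keepStep = "fdr",
                            r2Threshold = r2Threshold, windowKb = windowKb,
                            attachLd = FALSE)
  proxy <- .designatedProxySet(dataset, spec)
  if (is.null(res$set) && is.null(proxy))
    stop("no instruments survive discovery selection for ", spec@drugClass)
  list(discovery = res$set, designated_proxy = proxy)
}

#' Select validation-mode instruments (correlated-instrument rules)
#'
#' Applies the validation rule sequence: union of +/- `flankBp` windows
#' (default 100 kb), strict p-value filter (default p < 1e-5), palindrome
#' exclusion, then clumping at a permissive LD threshold (default removes
#' r-squared > 0.40), leaving instruments in weak mutual LD. The surviving
#' LD submatrix is attached for generalized-least-squares estimation.
#'
#' @inheritParams selectInstrumentsDiscovery
#' @param pThreshold strict p-value cutoff.
#' @return list with elements `validation` and `designated_proxy` as in
#'   [selectInstrumentsDiscovery()].
#' @export
selectInstrumentsValidation <- function(dataset, spec, ld,
                                        pThreshold = 1e-5, flankBp = 100000,
                                        r2Threshold = 0.40, windowKb = 500) {
  res <- .selectInstruments(dataset, spec, ld, mode = "validation",
                            flankBp = flankBp,
                            keepFun = function(p) p < pThreshold,
                            keepStep = "pvalue",
                            r2Threshold = r2Threshold, windowKb = windowKb,
                            attachLd = TRUE)
  proxy <- .designatedProxySet(dataset, spec)
  if (is.null(res$set) && is.null(proxy))
    stop("no instruments survive validation selection for ", spec@drugClass)
  list(validation = res$set, designated_proxy = proxy)
}

#' Write an instrument set as TSV tables
#'
#' Writes the instrument characteristics (variant, alleles, frequency,
#' beta, se, p) and, alongside it, a `<path>.log.tsv` selection log.
#'
#' @param x an [InstrumentSet-class].
#' @param path output TSV path for the instrument table.
#' @export
writeInstrumentSet <- function(x, path) {
  stopifnot(is(x, "InstrumentSet"))
  tab <- records(x)[, c("variant_id", "effect_allele", "other_allele",
                        "eaf", "beta", "se", "pvalue")]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(x@selectionLog))
    write.table(x@selectionLog, paste0(path, ".log.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
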