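#' Read GWAS summary statistics from a tab-delimited file
#'
#' Parses a one-header-row TSV of per-variant association summaries into a
#' [SummaryDataset-class]. A column mapping translates arbitrary headers
#' (biobank- and consortium-style dialects) onto the canonical fields.
#' Rows violating the per-variant invariants (missing/identical alleles,
#' non-positive standard error, p-value outside (0, 1], position < 1) are
#' dropped, with reasons collected in the `exclusions` attribute of the
#' returned object.
#'
#' @param path path to a tab-separated file with one header row.
#' @param columnMap named character vector mapping canonical names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`) to file headers.
#'   `eaf` and `n` entries may be omitted.
#' @param traitName trait label stored on the dataset.
#' @param traitType `"quantitative"` or `"binary"`.
#' @param duplicatePolicy `"error"` (default) aborts on duplicated variant
#'   ids; `"keep_first"` keeps the first occurrence and logs the rest.
#' @return A [SummaryDataset-class]; `attr(, "exclusions")` is a
#'   `data.frame` (`variant_id`, `reason`) of dropped rows.
#' @export
readSummaryStats <- function(path, columnMap = NULL, traitName = "trait",
                             traitType = c("quantitative", "binary"),
                             duplicatePolicy = c("error", "keep_first")) {
  traitType <- match.arg(traitType)
  duplicatePolicy <- match.arg(duplicatePolicy)
  if (!file.exists(path)) stop("cannot read summary statistics: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (is.null(columnMap))
    columnMap <- setNames(.SUMMARY_COLS, .SUMMARY_COLS)
  mandatory <- setdiff(.SUMMARY_COLS, c("eaf", "n"))
  missingMap <- setdiff(mandatory, names(columnMap))
  if (length(missingMap))
    stop("columnMap lacks entries for: ", paste(missingMap, collapse = ", "))
  absent <- setdiff(unname(columnMap[mandatory]), names(raw))
  if (length(absent))
    stop("mandatory column(s) missing from file: ", paste(absent, collapse = ", "))

  rec <- data.frame(variant_id = as.character(raw[[columnMap["variant_id"]]]),
                    chromosome = as.character(raw[[columnMap["chromosome"]]]),
                    position = as.numeric(raw[[columnMap["position"]]]),
                    effect_allele = toupper(as.character(raw[[columnMap["effect_allele"]]])),
                    other_allele = toupper(as.character(raw[[columnMap["other_allele"]]])),
                    eaf = NA_real_, beta = as.numeric(raw[[columnMap["beta"]]]),
                    se = as.numeric(raw[[columnMap["se"]]]),
                    pvalue = as.numeric(raw[[columnMap["pvalue"]]]),
                    n = NA_real_, stringsAsFactors = FALSE)
  if ("eaf" %in% names(columnMap) && columnMap["eaf"] %in% names(raw))
    rec$eaf <- as.numeric(raw[[columnMap["eaf"]]])
  if ("n" %in% names(columnMap) && columnMap["n"] %in% names(raw))
    rec$n <- as.numeric(raw[[columnMap["n"]]])

  dropped <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  ok <- .validVariantRows(rec)
  if (any(!ok)) {
    dropped <- rbind(dropped,
                     data.frame(variant_id = rec$variant_id[!ok],
                                reason = "invalid_record",
                                stringsAsFactors = FALSE))
    rec <- rec[ok, , drop = FALSE]
  }
  dup <- duplicated(rec$variant_id)
  if (any(dup)) {
    if (duplicatePolicy == "error")
      stop("duplicate variant_id in ", path, ": ",
           paste(unique(rec$variant_id[dup]), collapse = ", "))
    dropped <- rbind(dropped,
                     data.frame(variant_id = rec$variant_id[dup],
                                reason = "duplicate_keep_first",
                                stringsAsFactors = FALSE))
    rec <- rec[!dup, , drop = FALSE]
  }
  if (nrow(rec) == 0L)
    stop("no valid summary-statistic rows in ", path)
  if (nrow(dropped))
    message(nrow(dropped), " row(s) dropped while reading ", basename(path))
  ds <- SummaryDataset(rec, traitName = traitName, traitType = traitType)
  attr(ds, "exclusions") <- dropped
  ds
}

#' Write a SummaryDataset to the tab-delimited dialect the readers accept
#'
#' @param x a [SummaryDataset-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(is(x, "SummaryDataset"))
  write.table(x@records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read drug-target gene regions into a GRanges
#'
#' Expects a BED-like TSV with columns `gene`, `chromosome`, `start`, `end`
#' (1-based inclusive coordinates, the GWAS summary-statistic convention).
#' Comment lines starting with `#` are skipped.
#'
#' @param path path to the region table.
#' @return `GRanges` with a `gene` metadata column.
#' @export
readGeneRegions <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "start", "end")
  if (!all(need %in% names(tab)))
    stop("gene-region table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$start > tab$end)) stop("gene region with start > end")
  gr <- GenomicRanges::GRanges(seqnames = as.character(tab$chromosome),
                               ranges = IRanges::IRanges(start = tab$start,
                                                         end = tab$end))
  S4Vectors::mcols(gr)$gene <- tab$gene
  gr
}

#' Check an LD correlation matrix
#'
#' Verifies the invariants of an LD matrix: square, symmetric, unit
#' diagonal, entries in [-1, 1], row/column names present and matching.
#'
#' @param r numeric matrix of pairwise LD correlations.
#' @return `r`, invisibly, if valid; otherwise an error.
#' @export
checkLdMatrix <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    stop("LD matrix must carry matching variant-id dimnames")
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (any(abs(r) > 1 + 1e-8)) stop("LD correlations must lie in [-1, 1]")
  invisible(r)
}

#' Read / write a square LD matrix as labelled TSV
#'
#' @param path file path; the file carries variant ids both as header and
#'   as a leading row-name column.
#' @return `readLdMatrix`: a validated numeric matrix.
#' @export
readLdMatrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                    check.names = FALSE)
  r <- as.matrix(tab)
  checkLdMatrix(r)
  r
}

#' @rdname readLdMatrix
#' @param r labelled square LD matrix.
#' @param path output path.
#' @export
writeLdMatrix <- function(r, path) {
  checkLdMatrix(r)
  out <- data.frame(variant_id = rownames(r), r, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so the effect allele
#' cannot be resolved from summary statistics alone; such variants are
#' excluded during harmonization.
#'
#' @param effectAllele,otherAllele single-base alleles (A/C/G/T, any case);
#'   vectorized.
#' @return logical vector, `TRUE` for A/T or C/G pairs.
#' @export
isPalindromic <- function(effectAllele, otherAllele) {
  ea <- toupper(effectAllele); oa <- toupper(otherAllele)
  if (!all(ea %in% .ALLELES) || !all(oa %in% .ALLELES))
    stop("alleles must be one of A, C, G, T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[ea] == oa)
}

#' Harmonize an exposure/outcome dataset pair onto one effect-allele frame
#'
#' Intersects the two datasets on variant id and orients every outcome
#' association to the exposure's effect allele. Where the outcome's alleles
#' are swapped relative to the exposure, the outcome beta is negated and its
#' effect-allele frequency complemented. Palindromic (A/T, C/G) variants are
#' excluded (reason `"palindromic"`), variants absent from the outcome are
#' excluded (`"missing_in_outcome"`), and allele sets that do not match even
#' after a swap are excluded (`"allele_mismatch"`); strand relabelling is
#' never attempted. Every exposure variant lands either in the harmonized
#' set or in the exclusion log.
#'
#' @param exposure,outcome [SummaryDataset-class] objects.
#' @param ld optional LD correlation matrix covering (at least) the
#'   exposure variants; it is subset and reordered to the survivors.
#' @return A [HarmonizedSet-class].
#' @export
harmonizePair <- function(exposure, outcome, ld = NULL) {
  stopifnot(is(exposure, "SummaryDataset"), is(outcome, "SummaryDataset"))
  ex <- exposure@records
  if (nrow(ex) == 0L) stop("exposure dataset is empty")
  ou <- outcome@records
  idx <- match(ex$variant_id, ou$variant_id)

  reason <- rep(NA_character_, nrow(ex))
  pal <- isPalindromic(ex$effect_allele, ex$other_allele)
  reason[pal] <- "palindromic"
  miss <- is.na(idx) & is.na(reason)
  reason[miss] <- "missing_in_outcome"

  bo <- so <- rep(NA_real_, nrow(ex))
  open <- which(is.na(reason))
  for (i in open) {
    j <- idx[i]
    eaE <- ex$effect_allele[i]; oaE <- ex$other_allele[i]
    eaO <- ou$effect_allele[j]; oaO <- ou$other_allele[j]
    if (eaE == eaO && oaE == oaO) {
      bo[i] <- ou$beta[j]; so[i] <- ou$se[j]
    } else if (eaE == oaO && oaE == eaO) {
      bo[i] <- -ou$beta[j]; so[i] <- ou$se[j]
    } else {
      reason[i] <- "allele_mismatch"
    }
  }

  keep <- is.na(reason)
  if (!any(keep))
    stop("empty intersection after harmonization exclusions")
  ids <- ex$variant_id[keep]
  ldSub <- NULL
  if (!is.null(ld)) {
    checkLdMatrix(ld)
    missingLd <- setdiff(ids, rownames(ld))
    if (length(missingLd))
      stop("variants missing from LD matrix: ",
           paste(missingLd, collapse = ", "))
    ldSub <- ld[ids, ids, drop = FALSE]
  }
  new("HarmonizedSet",
      variantIds = ids,
      betaExposure = ex$beta[keep], seExposure = ex$se[keep],
      betaOutcome = bo[keep], seOutcome = so[keep],
      ld = ldSub,
      exclusions = data.frame(variant_id = ex$variant_id[!keep],
                              reason = reason[!keep],
                              stringsAsFactors = FALSE))
}

#' Assemble a HarmonizedSet from aligned effect vectors
#'
#' Convenience constructor for analyses that already hold aligned
#' SNP-exposure and SNP-outcome effects (simulation harnesses, oracles).
#'
#' @param variantIds variant ids (defaults to `snp1..snpJ`).
#' @param betaExposure,seExposure,betaOutcome,seOutcome aligned vectors.
#' @param ld optional LD matrix (dimnames set to `variantIds` if absent).
#' @return A [HarmonizedSet-class] with an empty exclusion log.
#' @export
harmonizedSet <- function(betaExposure, seExposure, betaOutcome, seOutcome,
                          variantIds = NULL, ld = NULL) {
  J <- length(betaExposure)
  if (is.null(variantIds)) variantIds <- paste0("snp", seq_len(J))
  if (!is.null(ld)) {
    if (is.null(rownames(ld))) dimnames(ld) <- list(variantIds, variantIds)
    checkLdMatrix(ld)
    ld <- ld[variantIds, variantIds, drop = FALSE]
  }
  new("HarmonizedSet", variantIds = variantIds,
      betaExposure = as.numeric(betaExposure),
      seExposure = as.numeric(seExposure),
      betaOutcome = as.numeric(betaOutcome),
      seOutcome = as.numeric(seOutcome), ld = ld,
      exclusions = data.frame(variant_id = character(),
                              reason = character(), stringsAsFactors = FALSE))
}

#' Write an exclusion log
#'
#' @param x a [HarmonizedSet-class] or a `data.frame` with `variant_id` and
#'   `reason` columns.
#' @param path output TSV path.
#' @export
writeExclusionLog <- function(x, path) {
  tab <- if (is(x, "HarmonizedSet")) x@exclusions else x
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
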