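#' @rdname SummaryDataset-class
#' @param x,object an object.
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname SummaryDataset-class
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname SummaryDataset-class
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname SummaryDataset-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname SummaryDataset-class
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname HarmonizedSet-class
#' @param x an object.
#' @export
setGeneric("ldMatrix", function(x) standardGeneric("ldMatrix"))
#' @rdname HarmonizedSet-class
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname InstrumentSet-class
#' @param x an object.
#' @export
setGeneric("selectionLog", function(x) standardGeneric("selectionLog"))
#' @rdname ColocPosterior-class
#' @param x an object.
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))
#' @rdname ColocPosterior-class
#' @export
setGeneric("ppH4", function(x) standardGeneric("ppH4"))

#' @rdname SummaryDataset-class
#' @export
setMethod("traitName", "SummaryDataset", function(x) x@traitName)
#' @rdname SummaryDataset-class
#' @export
setMethod("traitType", "SummaryDataset", function(x) x@traitType)
#' @rdname SummaryDataset-class
#' @export
setMethod("records", "SummaryDataset", function(x) x@records)
#' @rdname SummaryDataset-class
#' @export
setMethod("nVariants", "SummaryDataset", function(x) nrow(x@records))
#' @rdname SummaryDataset-class
#' @export
setMethod("variantIds", "SummaryDataset", function(x) x@records$variant_id)

#' @rdname HarmonizedSet-class
#' @export
setMethod("nVariants", "HarmonizedSet", function(x) length(x@variantIds))
#' @rdname HarmonizedSet-class
#' @export
setMethod("variantIds", "HarmonizedSet", function(x) x@variantIds)
#' @rdname HarmonizedSet-class
#' @export
setMethod("ldMatrix", "HarmonizedSet", function(x) x@ld)
#' @rdname HarmonizedSet-class
#' @export
setMethod("exclusions", "HarmonizedSet", function(x) x@exclusions)

#' @rdname InstrumentSet-class
#' @export
setMethod("ldMatrix", "InstrumentSet", function(x) x@ld)
#' @rdname InstrumentSet-class
#' @export
setMethod("selectionLog", "InstrumentSet", function(x) x@selectionLog)
#' @rdname InstrumentSet-class
#' @export
setMethod("records", "InstrumentSet", function(x) x@variants@records)
#' @rdname InstrumentSet-class
#' @export
setMethod("nVariants", "InstrumentSet", function(x) nrow(x@variants@records))
#' @rdname InstrumentSet-class
#' @export
setMethod("variantIds", "InstrumentSet", function(x) x@variants@records$variant_id)

#' @rdname ColocPosterior-class
#' @export
setMethod("posteriors", "ColocPosterior", function(x) x@pp)
#' @rdname ColocPosterior-class
#' @export
setMethod("ppH4", "ColocPosterior", function(x) unname(x@pp["H4"]))
#' @rdname ColocPosterior-class
#' @export
setMethod("nVariants", "ColocPosterior", function(x) x@nVariants)

#' Tabulate an MrEstimate as a one-row data.frame
#'
#' @param x an [MrEstimate-class].
#' @return one-row `data.frame` with the estimate's fields.
#' @export
setGeneric("asRow", function(x) standardGeneric("asRow"))

#' @rdname asRow
#' @export
setMethod("asRow", "MrEstimate", function(x) {
  data.frame(method = x@method, n_snps = x@nSnps, theta = x@theta,
             se = x@seTheta, se_inflated = x@seThetaInflated,
             ci_low = x@ciLow, ci_high = x@ciHigh,
             or = x@oddsRatio, or_ci_low = x@orCiLow, or_ci_high = x@orCiHigh,
             pvalue = x@pvalue, scale = x@scale, unit_label = x@unitLabel,
             stringsAsFactors = FALSE)
})

setMethod("show", "SummaryDataset", function(object) {
  cat("SummaryDataset:", object@traitName,
      sprintf("(%s), %d variants\n", object@traitType, nrow(object@records)))
  if (nrow(object@records))
    print(utils::head(object@records, 3L))
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %d harmonized variants, %d excluded%s\n",
              length(object@variantIds), nrow(object@exclusions),
              if (is.null(object@ld)) "" else ", LD attached"))
})

setMethod("show", "MrEstimate", function(object) {
  cat(sprintf("MrEstimate [%s, %d SNP%s, %s of %s]\n", object@method,
              object@nSnps, if (object@nSnps > 1L) "s" else "",
              sub("per_unit_", "per ", object@scale), object@unitLabel))
  cat(sprintf("  theta = %.4g (SE %.4g), OR = %.4g (95%% CI %.4g-%.4g), p = %.3g\n",
              object@theta, object@seTheta, object@oddsRatio,
              object@orCiLow, object@orCiHigh, object@pvalue))
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n",
              object@Q, object@df, object@pvalue))
})

setMethod("show", "PleiotropyResult", function(object) {
  cat(sprintf("MR-Egger intercept = %.4g (SE %.4g), t df = %d, p = %.3g\n",
              object@intercept, object@seIntercept, object@df, object@pvalue))
})

setMethod("show", "ColocPosterior", function(object) {
  cat(sprintf("ColocPosterior [%s, %d variants]\n", object@regionLabel,
              object@nVariants))
  print(round(object@pp, 4))
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet: %s (%s), %d variant%s%s\n", object@drugClass,
              object@mode, nVariants(object),
              if (nVariants(object) == 1L) "" else "s",
              if (is.null(object@ld)) "" else ", LD attached"))
})

setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf("SimulatedStudy: %d variants, outcomes: %s\n",
              nVariants(object@exposure),
              paste(names(object@outcomes), collapse = ", ")))
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport (%s): %d MR rows, %d coloc rows, %d control rows\n",
              object@mode, nrow(object@mr), nrow(object@coloc),
              nrow(object@controls)))
  if (length(object@errors))
    cat("  per-class errors:", paste(names(object@errors), collapse = ", "), "\n")
})
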