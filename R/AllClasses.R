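#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats p.adjust pchisq plogis pnorm pt qlogis qnorm qt rbinom
#'   rnorm runif setNames var
#' @importFrom utils read.delim write.table
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

.SUMMARY_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")
.ALLELES <- c("A", "C", "G", "T")

#' GWAS summary statistics for one trait
#'
#' Per-variant association summaries (effect allele, beta, standard error,
#' p-value, allele frequency, sample size) for a single quantitative or
#' binary trait. Records are unique by variant id and each row satisfies the
#' per-variant invariants (distinct A/C/G/T alleles, positive standard
#' error, p-value in (0, 1], position at least 1).
#'
#' @slot traitName single string naming the trait.
#' @slot traitType `"quantitative"` or `"binary"` (betas are log odds
#'   ratios for binary traits).
#' @slot records `data.frame` with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`. `eaf` and `n` may be `NA`.
#'
#' @seealso [readSummaryStats()], [harmonizePair()]
#' @export
setClass("SummaryDataset",
  representation(traitName = "character",
                 traitType = "character",
                 records = "data.frame"))

.validVariantRows <- function(rec) {
  ea <- toupper(rec$effect_allele)
  oa <- toupper(rec$other_allele)
  ok <- ea %in% .ALLELES & oa %in% .ALLELES & ea != oa &
    is.finite(rec$se) & rec$se > 0 &
    is.finite(rec$pvalue) & rec$pvalue > 0 & rec$pvalue <= 1 &
    is.finite(rec$beta) &
    is.finite(rec$position) & rec$position >= 1 &
    (is.na(rec$eaf) | (rec$eaf >= 0 & rec$eaf <= 1)) &
    (is.na(rec$n) | rec$n > 0)
  ok & !is.na(ok)
}

setValidity("SummaryDataset", function(object) {
  rec <- object@records
  msg <- character()
  if (length(object@traitName) != 1L || !nzchar(object@traitName))
    msg <- c(msg, "traitName must be a single non-empty string")
  if (length(object@traitType) != 1L ||
      !object@traitType %in% c("quantitative", "binary"))
    msg <- c(msg, "traitType must be 'quantitative' or 'binary'")
  if (!all(.SUMMARY_COLS %in% names(rec)))
    msg <- c(msg, paste("records must contain columns:",
                        paste(setdiff(.SUMMARY_COLS, names(rec)), collapse = ", ")))
  else {
    if (anyDuplicated(rec$variant_id))
      msg <- c(msg, "duplicate variant_id in records")
    if (nrow(rec) > 0 && !all(.validVariantRows(rec)))
      msg <- c(msg, "one or more records violate per-variant invariants")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SummaryDataset
#'
#' @param records data.frame of per-variant records (see
#'   [SummaryDataset-class] for the required columns).
#' @param traitName trait label.
#' @param traitType `"quantitative"` or `"binary"`.
#' @return A validated [SummaryDataset-class] object.
#' @export
SummaryDataset <- function(records, traitName, traitType = "quantitative") {
  records <- as.data.frame(records)
  for (col in c("eaf", "n"))
    if (!col %in% names(records)) records[[col]] <- NA_real_
  records$effect_allele <- toupper(records$effect_allele)
  records$other_allele <- toupper(records$other_allele)
  records$chromosome <- as.character(records$chromosome)
  records <- records[, .SUMMARY_COLS, drop = FALSE]
  rownames(records) <- NULL
  new("SummaryDataset", traitName = traitName, traitType = traitType,
      records = records)
}

#' Exposure/outcome association pairs on a common effect-allele frame
#'
#' Output of [harmonizePair()]: aligned SNP-exposure and SNP-outcome effects
#' (outcome betas oriented to the exposure effect allele), an optional LD
#' matrix restricted to the surviving variants, and the exclusion log. Every
#' exposure variant appears either in `variantIds` or in `exclusions`.
#'
#' @slot variantIds ordered character vector of surviving variant ids.
#' @slot betaExposure,seExposure,betaOutcome,seOutcome aligned numeric
#'   vectors; standard errors are strictly positive.
#' @slot ld optional correlation matrix (rows/columns named by and ordered
#'   as `variantIds`), or `NULL`.
#' @slot exclusions `data.frame` with columns `variant_id`, `reason`.
#' @export
setClass("HarmonizedSet",
  representation(variantIds = "character",
                 betaExposure = "numeric", seExposure = "numeric",
                 betaOutcome = "numeric", seOutcome = "numeric",
                 ld = "matrixOrNULL", exclusions = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  n <- length(object@variantIds)
  msg <- character()
  lens <- c(length(object@betaExposure), length(object@seExposure),
            length(object@betaOutcome), length(object@seOutcome))
  if (!all(lens == n)) msg <- c(msg, "effect vectors must match variantIds length")
  if (n > 0 && (any(object@seExposure <= 0) || any(object@seOutcome <= 0)))
    msg <- c(msg, "standard errors must be strictly positive")
  if (!is.null(object@ld)) {
    if (!identical(dim(object@ld), c(n, n)) ||
        !identical(rownames(object@ld), object@variantIds))
      msg <- c(msg, "ld must be a square matrix named and ordered by variantIds")
  }
  if (!all(c("variant_id", "reason") %in% names(object@exclusions)))
    msg <- c(msg, "exclusions needs variant_id and reason columns")
  if (length(msg)) msg else TRUE
})

#' A causal-effect estimate from Mendelian randomization
#'
#' @slot method one of `wald_ratio`, `ivw_fixed`, `ivw_random`,
#'   `ivw_correlated`, `egger_slope`.
#' @slot theta causal effect per unit exposure (log odds ratio for binary
#'   outcomes); `seTheta` its standard error.
#' @slot seThetaInflated heterogeneity-inflated standard error (reported for
#'   `ivw_correlated` alongside the model-based one; `NA` otherwise).
#' @slot ciLow,ciHigh 95% confidence bounds on `theta`.
#' @slot oddsRatio,orCiLow,orCiHigh exponentiated scale.
#' @slot pvalue two-sided p-value.
#' @slot nSnps number of instruments used.
#' @slot scale `"per_unit_increment"` or `"per_unit_decrement"`.
#' @slot unitLabel exposure unit, e.g. `"1 mmol/L blood glucose"`.
#' @export
setClass("MrEstimate",
  representation(method = "character", theta = "numeric", seTheta = "numeric",
                 seThetaInflated = "numeric",
                 ciLow = "numeric", ciHigh = "numeric",
                 oddsRatio = "numeric", orCiLow = "numeric", orCiHigh = "numeric",
                 pvalue = "numeric", nSnps = "integer",
                 scale = "character", unitLabel = "character"))

setValidity("MrEstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("wald_ratio", "ivw_fixed", "ivw_random",
                            "ivw_correlated", "egger_slope"))
    msg <- c(msg, "unknown method")
  if (!(object@ciLow <= object@theta && object@theta <= object@ciHigh))
    msg <- c(msg, "theta must lie within [ciLow, ciHigh]")
  if (abs(object@oddsRatio - exp(object@theta)) > 1e-8 * max(1, exp(object@theta)))
    msg <- c(msg, "oddsRatio must equal exp(theta)")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (!object@scale %in% c("per_unit_increment", "per_unit_decrement"))
    msg <- c(msg, "unknown scale")
  if (length(msg)) msg else TRUE
})

#' Cochran's Q heterogeneity test result
#'
#' @slot Q weighted sum of squared deviations of per-SNP ratio estimates
#'   from the pooled estimate.
#' @slot df degrees of freedom (number of instruments minus one).
#' @slot pvalue upper-tail chi-square p-value.
#' @export
setClass("HeterogeneityResult",
  representation(Q = "numeric", df = "integer", pvalue = "numeric"))

setValidity("HeterogeneityResult", function(object) {
  if (object@Q < 0) return("Q must be non-negative")
  if (object@df < 1L) return("df must be >= 1")
  TRUE
})

#' MR-Egger intercept (directional pleiotropy) test result
#'
#' @slot intercept estimated intercept of the weighted Egger regression.
#' @slot seIntercept its standard error.
#' @slot pvalue two-sided p-value (t reference with J - 2 df).
#' @slot df residual degrees of freedom.
#' @export
setClass("PleiotropyResult",
  representation(intercept = "numeric", seIntercept = "numeric",
                 pvalue = "numeric", df = "integer"))

setValidity("PleiotropyResult", function(object) {
  if (object@seIntercept <= 0) return("seIntercept must be positive")
  TRUE
})

#' Priors for five-hypothesis colocalization
#'
#' @slot p1 prior probability a variant is associated with trait 1.
#' @slot p2 same for trait 2.
#' @slot p12 prior probability a variant is associated with both.
#' @export
setClass("ColocPriors",
  representation(p1 = "numeric", p2 = "numeric", p12 = "numeric"))

setValidity("ColocPriors", function(object) {
  if (object@p12 <= 0 || object@p12 > min(object@p1, object@p2))
    return("require 0 < p12 <= min(p1, p2)")
  if (object@p1 + object@p2 + object@p12 >= 1)
    return("p1 + p2 + p12 must be < 1")
  TRUE
})

#' @rdname ColocPriors-class
#' @param p1,p2,p12 prior probabilities (defaults are the conventional
#'   single-variant colocalization priors).
#' @return A `ColocPriors` object.
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  new("ColocPriors", p1 = p1, p2 = p2, p12 = p12)
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' H0: neither trait associated in the region; H1/H2: only trait 1/2;
#' H3: both associated through distinct causal variants; H4: both associated
#' sharing a single causal variant.
#'
#' @slot pp named numeric vector `c(H0=, H1=, H2=, H3=, H4=)` summing to 1.
#' @slot nVariants number of variants in the region.
#' @slot labfTrait1,labfTrait2 per-variant log approximate Bayes factors.
#' @slot regionLabel region annotation.
#' @export
setClass("ColocPosterior",
  representation(pp = "numeric", nVariants = "integer",
                 labfTrait1 = "numeric", labfTrait2 = "numeric",
                 regionLabel = "character"))

setValidity("ColocPosterior", function(object) {
  msg <- character()
  if (length(object@pp) != 5L ||
      !identical(names(object@pp), c("H0", "H1", "H2", "H3", "H4")))
    msg <- c(msg, "pp must be named H0..H4")
  else {
    if (any(object@pp < -1e-12 | object@pp > 1 + 1e-12))
      msg <- c(msg, "posteriors must lie in [0,1]")
    if (abs(sum(object@pp) - 1) > 1e-9)
      msg <- c(msg, "posteriors must sum to 1 within 1e-9")
  }
  if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Drug-target instrument specification
#'
#' Encoding-gene regions for one antidiabetic drug class, optional
#' designated proxy variants (e.g. rs757110 for sulfonylureas), and the
#' expected sign of the glucose-lowering (decrement-scaled) effect on each
#' positive-control trait.
#'
#' @slot drugClass drug class label, e.g. `"sulfonylureas"`.
#' @slot regions `GRanges` of encoding genes (1-based inclusive), with a
#'   `gene` metadata column.
#' @slot designatedProxies character vector of variant ids force-reported as
#'   a separate instrument set (may be empty).
#' @slot expectedDirections named numeric vector of +1/-1 expected signs per
#'   control trait.
#' @export
setClass("DrugTargetSpec",
  representation(drugClass = "character", regions = "GRanges",
                 designatedProxies = "character",
                 expectedDirections = "numeric"))

setValidity("DrugTargetSpec", function(object) {
  msg <- character()
  if (length(object@regions) < 1L) msg <- c(msg, "at least one gene region required")
  if (length(object@expectedDirections) &&
      !all(object@expectedDirections %in% c(-1, 1)))
    msg <- c(msg, "expectedDirections must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' @rdname DrugTargetSpec-class
#' @param drugClass drug class label.
#' @param regions `GRanges` with a `gene` metadata column (see
#'   [readGeneRegions()]).
#' @param designatedProxies optional character vector of variant ids.
#' @param expectedDirections optional named +1/-1 vector.
#' @return A `DrugTargetSpec`.
#' @export
drugTargetSpec <- function(drugClass, regions, designatedProxies = character(),
                           expectedDirections = numeric()) {
  new("DrugTargetSpec", drugClass = drugClass, regions = regions,
      designatedProxies = designatedProxies,
      expectedDirections = expectedDirections)
}

#' A selected set of genetic instruments
#'
#' @slot drugClass drug class the instruments proxy.
#' @slot mode `"discovery"`, `"validation"` or `"designated_proxy"`.
#' @slot variants [SummaryDataset-class] subset passing the mode's filters.
#' @slot ld LD correlation matrix over `variants` (always attached in
#'   validation mode, where instruments may be correlated), or `NULL`.
#' @slot selectionLog `data.frame` with columns `variant_id`, `step`,
#'   `action` tracing every filter decision.
#' @export
setClass("InstrumentSet",
  representation(drugClass = "character", mode = "character",
                 variants = "SummaryDataset", ld = "matrixOrNULL",
                 selectionLog = "data.frame"))

setValidity("InstrumentSet", function(object) {
  msg <- character()
  if (!object@mode %in% c("discovery", "validation", "designated_proxy"))
    msg <- c(msg, "unknown mode")
  if (object@mode == "validation" && is.null(object@ld))
    msg <- c(msg, "validation instrument sets must carry an LD matrix")
  if (length(msg)) msg else TRUE
})

#' Parameterization of a synthetic two-sample GWAS study
#'
#' Defines an LD region with glucose-lowering causal variants, a binary
#' outcome downstream of the exposure, optional direct (pleiotropic)
#' variant effects, a shared- or distinct-causal-variant configuration for
#' colocalization, and positive-control traits with known signed effects.
#'
#' @slot nVariants number of variants in the region.
#' @slot region single-range `GRanges` giving chromosome and span.
#' @slot ldDecay AR(1) haplotype correlation parameter in [0, 1).
#' @slot mafRange minor-allele-frequency interval in (0, 0.5].
#' @slot causalIndices indices of exposure causal variants.
#' @slot causalBetas per-allele effects on the exposure (trait units).
#' @slot theta true causal effect of exposure on outcome (log-OR per
#'   exposure unit increment).
#' @slot nExposure,nOutcome cohort sizes of the two independent samples.
#' @slot outcomePrevalence baseline outcome probability in (0, 1).
#' @slot pleiotropySd sd of direct variant-to-outcome effects (0 = all
#'   instruments valid).
#' @slot sharedCausal if `FALSE`, the outcome's regional signal is moved to
#'   a variant nearly independent (r^2 < 0.05) of the exposure causal one.
#' @slot controlTraits named numeric vector: true effect of the exposure on
#'   each control trait per unit exposure decrement.
#' @slot palindromeFraction fraction of non-causal variants given A/T or
#'   C/G allele pairs.
#' @slot seed integer master seed; all substreams derive from it.
#' @export
setClass("SimulationConfig",
  representation(nVariants = "integer", region = "GRanges", ldDecay = "numeric",
                 mafRange = "numeric", causalIndices = "integer",
                 causalBetas = "numeric", theta = "numeric",
                 nExposure = "integer", nOutcome = "integer",
                 outcomePrevalence = "numeric", pleiotropySd = "numeric",
                 sharedCausal = "logical", controlTraits = "numeric",
                 palindromeFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@ldDecay < 0 || object@ldDecay >= 1)
    msg <- c(msg, "ldDecay must be in [0, 1)")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
    msg <- c(msg, "mafRange must be an increasing interval in (0, 0.5]")
  if (any(object@causalIndices < 1L | object@causalIndices > object@nVariants))
    msg <- c(msg, "causalIndices out of range")
  if (length(object@causalBetas) != length(object@causalIndices))
    msg <- c(msg, "causalBetas must match causalIndices in length")
  if (object@nExposure < 100L || object@nOutcome < 100L)
    msg <- c(msg, "cohort sizes must be >= 100")
  if (object@outcomePrevalence <= 0 || object@outcomePrevalence >= 1)
    msg <- c(msg, "outcomePrevalence must be in (0, 1)")
  if (object@pleiotropySd < 0) msg <- c(msg, "pleiotropySd must be >= 0")
  if (object@palindromeFraction < 0 || object@palindromeFraction > 1)
    msg <- c(msg, "palindromeFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A simulated two-sample study with known ground truth
#'
#' @slot exposure exposure-trait [SummaryDataset-class].
#' @slot outcomes named list of outcome [SummaryDataset-class] objects
#'   sharing the exposure's variant ids and allele frame.
#' @slot ld nominal AR(1) LD correlation matrix over the region.
#' @slot truth list echoing the generating parameters.
#' @export
setClass("SimulatedStudy",
  representation(exposure = "SummaryDataset", outcomes = "list",
                 ld = "matrix", truth = "list"))

#' Full study configuration for the discovery/validation pipelines
#'
#' Inputs may be in-memory objects or file paths (loaded with the packaged
#' readers when character).
#'
#' @slot exposure [SummaryDataset-class] or path to a summary-stat TSV.
#' @slot outcomes named list of stroke-style outcomes (objects or paths).
#' @slot controls named list of positive-control outcomes (objects or
#'   paths); not counted in the Bonferroni family.
#' @slot targets list of [DrugTargetSpec-class] objects.
#' @slot ld LD correlation matrix or path to a square TSV.
#' @slot priors [ColocPriors-class] for colocalization.
#' @slot alpha,m Bonferroni family-wise level and number of outcome tests.
#' @slot params named list of selection thresholds overriding the mode
#'   defaults (`fdrThreshold`, `pThreshold`, `flankBp`, `r2Threshold`,
#'   `windowKb`, `colocFlankBp`).
#' @slot unitLabel exposure unit used when decrement-rescaling estimates.
#' @slot seed integer seed echoed to the run log.
#' @export
setClass("StudyConfig",
  representation(exposure = "ANY", outcomes = "list", controls = "list",
                 targets = "list", ld = "ANY", priors = "ColocPriors",
                 alpha = "numeric", m = "integer", params = "list",
                 unitLabel = "character", seed = "integer"))

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (object@m < 1L) msg <- c(msg, "m must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0,1)")
  if (!length(object@targets)) msg <- c(msg, "at least one DrugTargetSpec required")
  if (length(msg)) msg else TRUE
})

#' Results of a full discovery or validation run
#'
#' @slot mode `"discovery"` or `"validation"`.
#' @slot mr `data.frame`: one row per drug class x outcome x method with
#'   effect estimates (decrement-scaled), diagnostics and Bonferroni flags.
#' @slot coloc `data.frame` of posterior probabilities per drug class x
#'   outcome x gene (present for Bonferroni-flagged classes).
#' @slot controls `data.frame` of positive-control estimates.
#' @slot instruments named list (per drug class) of [InstrumentSet-class]
#'   lists.
#' @slot errors named character vector of per-class failures (the run
#'   continues past them).
#' @slot config echo of the effective configuration.
#' @export
setClass("StudyReport",
  representation(mode = "character", mr = "data.frame", coloc = "data.frame",
                 controls = "data.frame", instruments = "list",
                 errors = "character", config = "list"))
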