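#' Construct a SimulationConfig
#'
#' Defaults describe a desk-scale drug-target locus: a 200-variant region
#' emulating a KCNJ11/ABCC8-like locus on chromosome 11, AR(1) haplotype
#' correlation 0.9, MAF uniform on (0.05, 0.5), one causal variant lowering
#' blood glucose by 0.1 mmol/L per allele against a residual sd of
#' 1 mmol/L, two independent cohorts of 20,000, a binary outcome of
#' baseline prevalence 0.09, and a true log-OR of 0.4 per 1 mmol/L exposure
#' increment. All randomness derives from `seed`.
#'
#' @param nVariants,region,ldDecay,mafRange,causalIndices,causalBetas,theta
#'   see [SimulationConfig-class].
#' @param nExposure,nOutcome,outcomePrevalence,pleiotropySd,sharedCausal
#'   see [SimulationConfig-class].
#' @param controlTraits,palindromeFraction,seed see
#'   [SimulationConfig-class].
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nVariants = 200L,
                             region = GenomicRanges::GRanges("11",
                               IRanges::IRanges(17350000L, 17450000L)),
                             ldDecay = 0.9, mafRange = c(0.05, 0.5),
                             causalIndices = as.integer(ceiling(nVariants / 2)),
                             causalBetas = rep(0.1, length(causalIndices)),
                             theta = 0.4, nExposure = 20000L,
                             nOutcome = 20000L, outcomePrevalence = 0.09,
                             pleiotropySd = 0, sharedCausal = TRUE,
                             controlTraits = numeric(),
                             palindromeFraction = 0.15, seed = 42L) {
  new("SimulationConfig", nVariants = as.integer(nVariants), region = region,
      ldDecay = ldDecay, mafRange = mafRange,
      causalIndices = as.integer(causalIndices), causalBetas = causalBetas,
      theta = theta, nExposure = as.integer(nExposure),
      nOutcome = as.integer(nOutcome), outcomePrevalence = outcomePrevalence,
      pleiotropySd = pleiotropySd, sharedCausal = sharedCausal,
      controlTraits = controlTraits, palindromeFraction = palindromeFraction,
      seed = as.integer(seed))
}

#' Nominal AR(1) LD correlation matrix
#'
#' `r[j, k] = ldDecay^|j - k|`: symmetric, unit diagonal and positive
#' definite for `ldDecay` in [0, 1).
#'
#' @param nVariants matrix dimension.
#' @param ldDecay AR(1) parameter in [0, 1).
#' @param variantIds optional dimnames (default `var1..varN`).
#' @return labelled correlation matrix.
#' @export
simulateLdMatrix <- function(nVariants, ldDecay, variantIds = NULL) {
  if (ldDecay < 0 || ldDecay >= 1) stop("ldDecay must be in [0, 1)")
  idx <- seq_len(nVariants)
  r <- ldDecay^abs(outer(idx, idx, "-"))
  if (is.null(variantIds)) variantIds <- paste0("var", idx)
  dimnames(r) <- list(variantIds, variantIds)
  r
}

# AR(1) standard-normal scores, one row per individual
.ar1Normals <- function(n, p, rho) {
  X <- matrix(rnorm(n * p), n, p)
  if (rho > 0 && p > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:p) X[, j] <- rho * X[, j - 1L] + s * X[, j]
  }
  X
}

# diploid dosages via MAF-quantile thresholding of two correlated haplotypes
.simGenotypes <- function(n, maf, rho) {
  p <- length(maf)
  thr <- qnorm(maf)
  a1 <- sweep(.ar1Normals(n, p, rho), 2L, thr, "<")
  a2 <- sweep(.ar1Normals(n, p, rho), 2L, thr, "<")
  a1 + a2
}

# marginal simple-regression summary stats for a quantitative trait
.olsScan <- function(G, y) {
  n <- length(y)
  Gc <- sweep(G, 2L, colMeans(G))
  yc <- y - mean(y)
  ssg <- colSums(Gc^2)
  ssy <- sum(yc^2)
  beta <- drop(crossprod(Gc, yc)) / ssg
  varres <- pmax((ssy - beta^2 * ssg) / (n - 2), .Machine$double.eps)
  se <- sqrt(varres / ssg)
  list(beta = beta, se = se,
       pvalue = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin))
}

# marginal logistic score-regression summary stats for a binary trait
.scoreScan <- function(G, y) {
  Gc <- sweep(G, 2L, colMeans(G))
  ybar <- mean(y)
  U <- drop(crossprod(Gc, y - ybar))
  V <- ybar * (1 - ybar) * colSums(Gc^2)
  beta <- U / V
  se <- 1 / sqrt(V)
  list(beta = beta, se = se,
       pvalue = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin))
}

.PAL_PAIRS <- list(c("A", "T"), c("C", "G"))
.NONPAL_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))

# deterministic-by-substream variant frame: ids, positions, alleles, mafs
.variantFrame <- function(config) {
  p <- config@nVariants
  maf <- runif(p, config@mafRange[1], config@mafRange[2])
  pal <- runif(p) < config@palindromeFraction
  pal[config@causalIndices] <- FALSE  # causal signal must survive harmonization
  pairIdx <- sample.int(4L, p, replace = TRUE)
  pairs <- lapply(seq_len(p), function(j)
    if (pal[j]) .PAL_PAIRS[[1L + pairIdx[j] %% 2L]] else .NONPAL_PAIRS[[pairIdx[j]]])
  swap <- runif(p) < 0.5
  ea <- vapply(seq_len(p), function(j) pairs[[j]][1 + swap[j]], character(1))
  oa <- vapply(seq_len(p), function(j) pairs[[j]][2 - swap[j]], character(1))
  data.frame(variant_id = sprintf("rs%06d", seq_len(p)),
             chromosome = as.character(GenomicRanges::seqnames(config@region)[1]),
             position = round(seq(GenomicRanges::start(config@region)[1],
                                  GenomicRanges::end(config@region)[1],
                                  length.out = p)),
             effect_allele = ea, other_allele = oa,
             maf = maf, stringsAsFactors = FALSE)
}

.mkRecords <- function(frame, G, scan, n) {
  data.frame(variant_id = frame$variant_id, chromosome = frame$chromosome,
             position = frame$position, effect_allele = frame$effect_allele,
             other_allele = frame$other_allele, eaf = colMeans(G) / 2,
             beta = scan$beta, se = scan$se, pvalue = scan$pvalue,
             n = n, stringsAsFactors = FALSE)
}

# index of a variant with nominal r^2 < maxR2 to every exposure causal one
.distinctCausalIndex <- function(config, maxR2 = 0.05) {
  idx <- seq_len(config@nVariants)
  minDist <- vapply(idx, function(j) min(abs(j - config@causalIndices)), 0)
  r2 <- config@ldDecay^(2 * minDist)
  ok <- which(r2 < maxR2)
  if (!length(ok))
    stop("region too small/too correlated to place a distinct causal variant")
  ok[which.max(minDist[ok])]
}

#' Simulate a two-sample exposure/outcome GWAS study
#'
#' Draws genotype dosages in two independent cohorts (MAF-quantile
#' thresholding of AR(1)-correlated haplotype scores), builds the exposure
#' as genetic value plus unit-variance Gaussian noise, and the binary
#' outcome from a logistic model whose log odds carry
#' `theta * (genetic exposure value)` plus optional direct (pleiotropic)
#' variant effects, with intercept `qlogis(outcomePrevalence)`. Marginal
#' per-variant summary statistics are computed within each cohort (simple
#' regression for the exposure, logistic score regression for the outcome),
#' so effect/se/p columns follow the large-sample summary model. With
#' `sharedCausal = FALSE` the outcome's regional signal is placed on a
#' variant with nominal r-squared < 0.05 to every exposure causal variant.
#'
#' All randomness flows from `config@seed` through fixed substreams
#' (variant frame, exposure cohort, outcome cohort, one per control trait),
#' so repeated calls are bit-identical.
#'
#' @param config a [SimulationConfig-class].
#' @return A [SimulatedStudy-class] with the exposure dataset, an outcome
#'   named `"stroke"`, the nominal AR(1) LD matrix, and the generating
#'   truth.
#' @export
simulateSummaryPair <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  streams <- sample.int(.Machine$integer.max - 1L,
                        4L + length(config@controlTraits))

  set.seed(streams[1]); frame <- .variantFrame(config)
  p <- config@nVariants
  causalVec <- numeric(p)
  causalVec[config@causalIndices] <- config@causalBetas

  set.seed(streams[2])
  Gx <- .simGenotypes(config@nExposure, frame$maf, config@ldDecay)
  xExp <- drop(Gx %*% causalVec) + rnorm(config@nExposure)
  exposure <- SummaryDataset(.mkRecords(frame, Gx, .olsScan(Gx, xExp),
                                        config@nExposure),
                             traitName = "blood_glucose",
                             traitType = "quantitative")

  set.seed(streams[3])
  Gy <- .simGenotypes(config@nOutcome, frame$maf, config@ldDecay)
  outcomeCausal <- NA_integer_
  if (config@sharedCausal) {
    eta <- config@theta * drop(Gy %*% causalVec)
  } else {
    outcomeCausal <- .distinctCausalIndex(config)
    eta <- config@theta * config@causalBetas[1] * Gy[, outcomeCausal]
  }
  if (config@pleiotropySd > 0)
    eta <- eta + drop(Gy %*% rnorm(p, 0, config@pleiotropySd))
  yOut <- rbinom(config@nOutcome, 1L,
                 plogis(qlogis(config@outcomePrevalence) + eta))
  outcome <- SummaryDataset(.mkRecords(frame, Gy, .scoreScan(Gy, yOut),
                                       config@nOutcome),
                            traitName = "stroke", traitType = "binary")

  ld <- simulateLdMatrix(p, config@ldDecay, frame$variant_id)
  truth <- list(theta = config@theta,
                causalIndices = config@causalIndices,
                causalBetas = config@causalBetas,
                causalVariantIds = frame$variant_id[config@causalIndices],
                outcomeCausalIndex = outcomeCausal,
                sharedCausal = config@sharedCausal,
                pleiotropySd = config@pleiotropySd,
                outcomePrevalence = config@outcomePrevalence,
                nExposure = config@nExposure, nOutcome = config@nOutcome,
                seed = config@seed, streams = streams,
                controlTraits = config@controlTraits)
  new("SimulatedStudy", exposure = exposure,
      outcomes = list(stroke = outcome), ld = ld, truth = truth)
}

#' Simulate a drug-target study with positive-control outcomes
#'
#' Extends [simulateSummaryPair()] with one quantitative outcome dataset
#' per control trait. Control effects are specified per unit exposure
#' *decrement* (the drug direction): a trait value of -0.5 for type 2
#' diabetes means a 1-unit glucose decrement lowers the trait by 0.5, so a
#' glucose-raising allele raises it. Each control trait is drawn in its own
#' independent cohort (size `nOutcome`) and substream.
#'
#' @param config a [SimulationConfig-class].
#' @param controlTraits named numeric vector overriding
#'   `config@controlTraits`.
#' @return A [SimulatedStudy-class] whose `outcomes` hold `"stroke"` plus
#'   one dataset per control trait.
#' @export
simulateDrugTargetStudy <- function(config,
                                    controlTraits = config@controlTraits) {
  config@controlTraits <- controlTraits
  study <- simulateSummaryPair(config)
  if (!length(controlTraits)) return(study)
  if (is.null(names(controlTraits)) || any(!nzchar(names(controlTraits))))
    stop("controlTraits must be named")
  streams <- study@truth$streams
  set.seed(streams[1]); frame <- .variantFrame(config)
  causalVec <- numeric(config@nVariants)
  causalVec[config@causalIndices] <- config@causalBetas
  for (k in seq_along(controlTraits)) {
    set.seed(streams[4L + k])
    G <- .simGenotypes(config@nOutcome, frame$maf, config@ldDecay)
    thetaInc <- -controlTraits[k]  # stored per decrement
    y <- thetaInc * drop(G %*% causalVec) + rnorm(config@nOutcome)
    study@outcomes[[names(controlTraits)[k]]] <-
      SummaryDataset(.mkRecords(frame, G, .olsScan(G, y), config@nOutcome),
                     traitName = names(controlTraits)[k],
                     traitType = "quantitative")
  }
  study@truth$controlTraits <- controlTraits
  study
}

#' Write a simulated study to disk
#'
#' Emits the exposure and every outcome in the summary-statistic TSV
#' dialect [readSummaryStats()] accepts, the LD matrix as labelled TSV, and
#' a `truth.json` sidecar with the generating parameters.
#'
#' @param study a [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "SimulatedStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"))
  writeSummaryStats(study@exposure, paths["exposure"])
  for (nm in names(study@outcomes)) {
    paths[nm] <- file.path(dir, paste0(nm, ".tsv"))
    writeSummaryStats(study@outcomes[[nm]], paths[nm])
  }
  paths["ld"] <- file.path(dir, "ld.tsv")
  writeLdMatrix(study@ld, paths["ld"])
  paths["truth"] <- file.path(dir, "truth.json")
  truth <- study@truth
  truth$streams <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
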