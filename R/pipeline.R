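#' Construct a StudyConfig
#'
#' @param exposure [SummaryDataset-class] or path to an exposure
#'   summary-statistic TSV (canonical headers).
#' @param outcomes named list of outcome datasets or paths (read as binary
#'   traits when paths).
#' @param targets list of [DrugTargetSpec-class] objects (a single spec is
#'   wrapped).
#' @param ld LD correlation matrix or path to a labelled square TSV.
#' @param controls named list of positive-control datasets or paths (read
#'   as quantitative traits when paths); excluded from the Bonferroni
#'   family.
#' @param priors a [ColocPriors-class].
#' @param alpha family-wise significance level.
#' @param m number of Bonferroni-corrected outcome tests (defaults to the
#'   number of outcomes).
#' @param params named list of threshold overrides: `fdrThreshold`,
#'   `pThreshold`, `flankBp`, `r2Threshold`, `windowKb`, `colocFlankBp`.
#'   Unset entries take the mode defaults.
#' @param unitLabel exposure unit used for decrement rescaling.
#' @param seed integer echoed to the run log (selection and estimation are
#'   deterministic; the seed matters only for upstream simulation).
#' @return A validated [StudyConfig-class].
#' @export
studyConfig <- function(exposure, outcomes, targets, ld, controls = list(),
                        priors = colocPriors(), alpha = 0.05,
                        m = length(outcomes), params = list(),
                        unitLabel = "1 mmol/L blood glucose", seed = 1L) {
  if (is(targets, "DrugTargetSpec")) targets <- list(targets)
  new("StudyConfig", exposure = exposure, outcomes = outcomes,
      controls = controls, targets = targets, ld = ld, priors = priors,
      alpha = alpha, m = as.integer(m), params = params,
      unitLabel = unitLabel, seed = as.integer(seed))
}

.loadDataset <- function(x, traitName, traitType) {
  if (is(x, "SummaryDataset")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(readSummaryStats(x, traitName = traitName, traitType = traitType))
  stop("expected a SummaryDataset or a file path for ", traitName)
}

.loadLd <- function(x) {
  if (is.null(x))
    stop("study configuration requires an LD matrix (matrix or TSV path)")
  if (is.character(x) && length(x) == 1L) return(readLdMatrix(x))
  checkLdMatrix(x)
  x
}

.param <- function(cfg, name, default) {
  if (!is.null(cfg@params[[name]])) cfg@params[[name]] else default
}

.emptyMr <- function() {
  data.frame(drug_class = character(), outcome = character(),
             instrument_mode = character(), method = character(),
             n_snps = integer(), theta = numeric(), se = numeric(),
             se_inflated = numeric(), ci_low = numeric(), ci_high = numeric(),
             or = numeric(), or_ci_low = numeric(), or_ci_high = numeric(),
             pvalue = numeric(), scale = character(), unit_label = character(),
             Q = numeric(), Q_df = integer(), Q_pvalue = numeric(),
             egger_intercept = numeric(), egger_se = numeric(),
             egger_pvalue = numeric(), bonferroni_threshold = numeric(),
             bonferroni_sig = logical(), stringsAsFactors = FALSE)
}

.emptyColoc <- function() {
  data.frame(drug_class = character(), outcome = character(),
             gene = character(), n_variants = integer(), PP.H0 = numeric(),
             PP.H1 = numeric(), PP.H2 = numeric(), PP.H3 = numeric(),
             PP.H4 = numeric(), shared_variant = logical(),
             stringsAsFactors = FALSE)
}

.mrRow <- function(class, outcomeName, mode, est, het, pleio, thr) {
  row <- cbind(data.frame(drug_class = class, outcome = outcomeName,
                          instrument_mode = mode, stringsAsFactors = FALSE),
               asRow(est))
  names(row)[names(row) == "or"] <- "or"
  row$Q <- if (is.null(het)) NA_real_ else het@Q
  row$Q_df <- if (is.null(het)) NA_integer_ else het@df
  row$Q_pvalue <- if (is.null(het)) NA_real_ else het@pvalue
  row$egger_intercept <- if (is.null(pleio)) NA_real_ else pleio@intercept
  row$egger_se <- if (is.null(pleio)) NA_real_ else pleio@seIntercept
  row$egger_pvalue <- if (is.null(pleio)) NA_real_ else pleio@pvalue
  row$bonferroni_threshold <- thr
  row$bonferroni_sig <- row$pvalue < thr
  row
}

# estimate one instrument set against one outcome; returns a one-row frame
.estimateSet <- function(set, outcomeDs, outcomeName, thr, unitLabel,
                         correlated = FALSE) {
  h <- harmonizePair(set@variants, outcomeDs, ld = set@ld)
  J <- nVariants(h)
  est <- if (J == 1L)
    waldRatio(h@betaExposure, h@seExposure, h@betaOutcome, h@seOutcome)
  else if (correlated) ivwCorrelated(h)
  else ivw(h, mode = "random")
  het <- if (J >= 2L && all(h@betaExposure != 0)) cochranQ(h) else NULL
  pleio <- if (J >= 3L) tryCatch(mrEgger(h)$pleiotropy, error = function(e) NULL)
           else NULL
  est <- rescalePerUnitDecrement(est, unitLabel)
  .mrRow(set@drugClass, outcomeName, set@mode, est, het, pleio, thr)
}

.colocRows <- function(spec, exposure, outcomeDs, outcomeName, flankBp,
                       priors) {
  rows <- .emptyColoc()
  for (g in seq_along(spec@regions)) {
    region <- spec@regions[g]
    gene <- S4Vectors::mcols(spec@regions)$gene[g]
    s1 <- extractCisWindow(exposure, region, flankBp)
    s2 <- extractCisWindow(outcomeDs, region, flankBp)
    common <- intersect(variantIds(s1), variantIds(s2))
    if (!length(common)) next
    r1 <- s1@records[match(common, s1@records$variant_id),
                     c("variant_id", "beta", "se")]
    r2 <- s2@records[match(common, s2@records$variant_id),
                     c("variant_id", "beta", "se")]
    sd1 <- if (exposure@traitType == "binary") 0.20 else 0.15
    sd2 <- if (outcomeDs@traitType == "binary") 0.20 else 0.15
    post <- colocABF(r1, r2, priors = priors, priorSd1 = sd1, priorSd2 = sd2,
                     regionLabel = paste(gene, outcomeName, sep = " / "))
    pp <- posteriors(post)
    rows <- rbind(rows, data.frame(
      drug_class = spec@drugClass, outcome = outcomeName, gene = gene,
      n_variants = nVariants(post), PP.H0 = pp["H0"], PP.H1 = pp["H1"],
      PP.H2 = pp["H2"], PP.H3 = pp["H3"], PP.H4 = pp["H4"],
      shared_variant = classifyColoc(post), stringsAsFactors = FALSE,
      row.names = NULL))
  }
  rows
}

.runAnalysis <- function(cfg, mode) {
  exposure <- .loadDataset(cfg@exposure, "exposure", "quantitative")
  outcomes <- lapply(seq_along(cfg@outcomes), function(i)
    .loadDataset(cfg@outcomes[[i]], names(cfg@outcomes)[i], "binary"))
  names(outcomes) <- names(cfg@outcomes)
  controls <- lapply(seq_along(cfg@controls), function(i)
    .loadDataset(cfg@controls[[i]], names(cfg@controls)[i], "quantitative"))
  names(controls) <- names(cfg@controls)
  ld <- .loadLd(cfg@ld)
  thr <- bonferroniThreshold(cfg@alpha, cfg@m)
  validation <- mode == "validation"
  colocFlank <- .param(cfg, "colocFlankBp", if (validation) 100000 else 2500)

  mr <- .emptyMr(); coloc <- .emptyColoc(); controlRows <- .emptyMr()
  instruments <- list(); errors <- character()

  for (spec in cfg@targets) {
    res <- tryCatch({
      sel <- if (validation)
        selectInstrumentsValidation(exposure, spec, ld,
          pThreshold = .param(cfg, "pThreshold", 1e-5),
          flankBp = .param(cfg, "flankBp", 100000),
          r2Threshold = .param(cfg, "r2Threshold", 0.40),
          windowKb = .param(cfg, "windowKb", 500))
      else
        selectInstrumentsDiscovery(exposure, spec, ld,
          fdrThreshold = .param(cfg, "fdrThreshold", 0.05),
          flankBp = .param(cfg, "flankBp", 2500),
          r2Threshold = .param(cfg, "r2Threshold", 0.01),
          windowKb = .param(cfg, "windowKb", 500))
      sets <- Filter(Negate(is.null), sel)
      classMr <- .emptyMr(); classControls <- .emptyMr()
      for (set in sets) {
        corr <- validation && set@mode == "validation"
        for (nm in names(outcomes))
          classMr <- rbind(classMr,
                           tryCatch(.estimateSet(set, outcomes[[nm]], nm, thr,
                                                 cfg@unitLabel, corr),
                                    error = function(e) .emptyMr()))
        for (nm in names(controls))
          classControls <- rbind(classControls,
                                 tryCatch(.estimateSet(set, controls[[nm]], nm,
                                                       1, cfg@unitLabel, corr),
                                          error = function(e) .emptyMr()))
      }
      classColoc <- .emptyColoc()
      if (any(classMr$bonferroni_sig)) {
        for (nm in unique(classMr$outcome[classMr$bonferroni_sig]))
          classColoc <- rbind(classColoc,
                              .colocRows(spec, exposure, outcomes[[nm]], nm,
                                         colocFlank, cfg@priors))
      }
      list(sets = sets, mr = classMr, controls = classControls,
           coloc = classColoc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[spec@drugClass] <- conditionMessage(res)
      next
    }
    instruments[[spec@drugClass]] <- res$sets
    mr <- rbind(mr, res$mr)
    controlRows <- rbind(controlRows, res$controls)
    coloc <- rbind(coloc, res$coloc)
  }
  rownames(mr) <- rownames(coloc) <- rownames(controlRows) <- NULL
  new("StudyReport", mode = mode, mr = mr, coloc = coloc,
      controls = controlRows, instruments = instruments, errors = errors,
      config = list(alpha = cfg@alpha, m = cfg@m,
                    bonferroni_threshold = thr, params = cfg@params,
                    unit_label = cfg@unitLabel, seed = cfg@seed,
                    outcomes = names(cfg@outcomes),
                    controls = names(cfg@controls),
                    targets = vapply(cfg@targets, function(s) s@drugClass, "")))
}

#' Run the discovery drug-target MR study
#'
#' For each drug class: select discovery instruments (cis-window, FDR,
#' palindrome exclusion, clumping), harmonize against every outcome,
#' estimate the causal effect (Wald ratio for one instrument, random-effects
#' IVW otherwise; designated proxies analyzed as a separate set), attach
#' Cochran's Q and the MR-Egger intercept where the instrument count
#' permits, rescale to the per-unit-decrement drug direction, flag
#' Bonferroni significance at `alpha / m`, and run colocalization inside
#' the target gene regions for every flagged class. Per-class failures are
#' caught and logged; other classes continue.
#'
#' @param cfg a [StudyConfig-class].
#' @return A [StudyReport-class].
#' @export
runDiscoveryAnalysis <- function(cfg) .runAnalysis(cfg, "discovery")

#' Run the validation study with correlated instruments
#'
#' As [runDiscoveryAnalysis()], but instruments follow the validation rules
#' (+/- 100 kb window, p < 1e-5, clumping at r-squared 0.40) and estimation
#' uses generalized least squares with the attached LD matrix
#' ([ivwCorrelated()]); colocalization regions default to +/- 100 kb. When
#' a discovery report is supplied, a per-(class x outcome) direction-
#' consistency table is attached to the returned report's config as
#' `consistency`.
#'
#' @param cfg a [StudyConfig-class] whose exposure is the independent
#'   validation GWAS.
#' @param discovery optional discovery [StudyReport-class] to compare
#'   effect directions against.
#' @return A [StudyReport-class].
#' @export
runValidationAnalysis <- function(cfg, discovery = NULL) {
  report <- .runAnalysis(cfg, "validation")
  if (!is.null(discovery)) {
    stopifnot(is(discovery, "StudyReport"))
    key <- c("drug_class", "outcome", "instrument_mode")
    a <- discovery@mr[, c(key, "theta")]
    b <- report@mr[, c(key, "theta")]
    # align the primary instrument sets across modes; proxies match by name
    a$instrument_mode[a$instrument_mode == "discovery"] <- "primary"
    b$instrument_mode[b$instrument_mode == "validation"] <- "primary"
    names(a)[4] <- "theta_discovery"; names(b)[4] <- "theta_validation"
    cons <- merge(a, b, by = key)
    cons$direction_consistent <-
      sign(cons$theta_discovery) == sign(cons$theta_validation)
    report@config$consistency <- cons
  }
  report
}

#' Check positive-control estimates against expected drug-effect directions
#'
#' For every control trait with an expected sign in the drug-target spec,
#' compares the sign of the decrement-scaled estimate: matching sign with a
#' 95% interval excluding zero is a `"pass"`; matching sign with an
#' interval spanning zero is `"directionally_consistent_ns"` (or `"pass"`
#' when `requireSignificance = FALSE`); a contradicting sign is a
#' `"fail"`. Control traits reported without an expected direction raise an
#' error.
#'
#' @param report a [StudyReport-class] with control-trait estimates.
#' @param spec the [DrugTargetSpec-class] carrying `expectedDirections`.
#' @param requireSignificance demand a zero-excluding interval for a full
#'   pass.
#' @return `data.frame` with columns `drug_class`, `trait`,
#'   `instrument_mode`, `expected_sign`, `estimated_sign`, `significant`,
#'   `status`.
#' @export
positiveControlCheck <- function(report, spec, requireSignificance = TRUE) {
  stopifnot(is(report, "StudyReport"), is(spec, "DrugTargetSpec"))
  rows <- report@controls[report@controls$drug_class == spec@drugClass, ,
                          drop = FALSE]
  if (!nrow(rows)) stop("no control-trait estimates for ", spec@drugClass)
  missing <- setdiff(unique(rows$outcome), names(spec@expectedDirections))
  if (length(missing))
    stop("expected direction missing for control trait(s): ",
         paste(missing, collapse = ", "))
  expected <- spec@expectedDirections[rows$outcome]
  estSign <- sign(rows$theta)
  sig <- rows$ci_low > 0 | rows$ci_high < 0
  status <- ifelse(estSign != expected, "fail",
                   ifelse(sig | !requireSignificance, "pass",
                          "directionally_consistent_ns"))
  data.frame(drug_class = spec@drugClass, trait = rows$outcome,
             instrument_mode = rows$instrument_mode,
             expected_sign = unname(expected), estimated_sign = estSign,
             significant = sig, status = status, stringsAsFactors = FALSE)
}

#' Write a study report to disk
#'
#' Emits `mr_results.tsv`, `coloc_results.tsv`, `control_results.tsv`,
#' per-class selection logs, and `run_log.txt` echoing the effective
#' configuration and seed. Reruns of the same configuration and seed
#' produce byte-identical files.
#'
#' @param report a [StudyReport-class].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
renderReport <- function(report, outdir) {
  stopifnot(is(report, "StudyReport"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mr = file.path(outdir, "mr_results.tsv"),
             coloc = file.path(outdir, "coloc_results.tsv"),
             controls = file.path(outdir, "control_results.tsv"),
             log = file.path(outdir, "run_log.txt"))
  write.table(report@mr, paths["mr"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report@coloc, paths["coloc"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report@controls, paths["controls"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (class in names(report@instruments)) {
    logs <- lapply(report@instruments[[class]], selectionLog)
    logTab <- do.call(rbind, logs)
    if (!is.null(logTab) && nrow(logTab)) {
      p <- file.path(outdir, paste0("selection_log_",
                                    gsub("[^A-Za-z0-9]+", "_", class), ".tsv"))
      write.table(logTab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[paste0("selection_", class)] <- p
    }
  }
  cfg <- report@config
  lines <- c(paste0("mode: ", report@mode),
             paste0("alpha: ", cfg$alpha), paste0("m: ", cfg$m),
             paste0("bonferroni_threshold: ",
                    format(cfg$bonferroni_threshold, digits = 15)),
             paste0("unit_label: ", cfg$unit_label),
             paste0("seed: ", cfg$seed),
             paste0("outcomes: ", paste(cfg$outcomes, collapse = ", ")),
             paste0("controls: ", paste(cfg$controls, collapse = ", ")),
             paste0("targets: ", paste(cfg$targets, collapse = ", ")),
             paste0("params: ", if (length(cfg$params))
               paste(names(cfg$params), unlist(cfg$params), sep = "=",
                     collapse = ", ") else "(defaults)"),
             if (length(report@errors))
               paste0("errors: ", paste(names(report@errors), report@errors,
                                        sep = ": ", collapse = "; "))
             else "errors: none")
  writeLines(lines, paths["log"])
  invisible(paths)
}
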