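test_that("cis-window extraction respects inclusive flanked boundaries", {
  ds <- makeDataset(paste0("rs", 1:4), c(999, 1000, 4500, 4501),
                    beta = 0.1, se = 0.01)
  expect_equal(variantIds(extractCisWindow(ds, region(1000, 2000), 0)), "rs2")
  expect_setequal(variantIds(extractCisWindow(ds, region(1000, 2000), 2500)),
                  c("rs1", "rs2", "rs3"))
  # chromosome must match
  ds2 <- makeDataset("rsX", 1500, 0.1, 0.01, chrom = "2")
  expect_equal(nVariants(extractCisWindow(ds2, region(1000, 2000), 0)), 0L)
})

test_that("overlapping gene windows yield each variant once (set union)", {
  ds <- makeDataset(paste0("rs", 1:10), seq(100, 1000, by = 100), 0.1, 0.01)
  two <- c(geneRegion("g1", 150, 450), geneRegion("g2", 350, 750))
  got <- variantIds(extractCisWindow(ds, two, 0))
  # oracle: union of the two window memberships applied by hand
  pos <- seq(100, 1000, by = 100)
  want <- paste0("rs", which((pos >= 150 & pos <= 450) |
                               (pos >= 350 & pos <= 750)))
  expect_identical(got, want)
  expect_false(anyDuplicated(got) > 0)
})

test_that("BH q-values follow the step-up definition and preserve order", {
  expect_equal(bhFdr(0.01), 0.01)
  # step-up applied by hand: q_(i) = min_{j>=i} m p_(j)/j
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.04, 0.001, 0.9, 0.02)
  q <- bhFdr(p)
  perm <- c(3, 1, 4, 2)
  expect_equal(bhFdr(p[perm]), q[perm])
  expect_true(all(q >= p))
  expect_error(bhFdr(numeric()), "empty")
  expect_error(bhFdr(c(0.5, 0)), "0, 1")
  expect_error(bhFdr(1.2), "0, 1")
})

test_that("greedy clumping matches an exhaustive hand trace", {
  ds <- makeDataset(paste0("rs", 1:3), c(1000, 2000, 3000),
                    beta = 0.1, se = 0.01, pvalue = c(1e-8, 1e-6, 1e-4))
  ld <- diag(3); dimnames(ld) <- list(paste0("rs", 1:3), paste0("rs", 1:3))
  ld[1, 2] <- ld[2, 1] <- sqrt(0.5)
  # trace: rs1 indexes, removes rs2 (r2 0.5 > 0.01); rs3 indexes
  got <- clumpVariants(ds, ld, r2Threshold = 0.01, windowKb = 500)
  expect_equal(variantIds(got), c("rs1", "rs3"))
  log <- attr(got, "selectionLog")
  expect_equal(log$action[log$variant_id == "rs2"], "removed_by=rs1")

  # independence: everything retained
  expect_equal(nVariants(clumpVariants(ds, diag(3) |>
    (\(m) { dimnames(m) <- dimnames(ld); m })(), 0.01, 500)), 3L)

  # perfect proxies: smaller p wins
  ld2 <- matrix(1, 2, 2); dimnames(ld2) <- list(c("rs1", "rs2"), c("rs1", "rs2"))
  ds2 <- makeDataset(c("rs1", "rs2"), c(1000, 1200), 0.1, 0.01,
                     pvalue = c(1e-6, 1e-8))
  expect_equal(variantIds(clumpVariants(ds2, ld2, 0.01, 500)), "rs2")

  # outside the window the LD is ignored
  ds3 <- makeDataset(c("rs1", "rs2"), c(1000, 600000), 0.1, 0.01,
                     pvalue = c(1e-8, 1e-6))
  expect_equal(nVariants(clumpVariants(ds3, ld2 |>
    (\(m) { dimnames(m) <- list(c("rs1", "rs2"), c("rs1", "rs2")); m })(),
    0.01, 500)), 2L)

  expect_error(clumpVariants(ds, ld[1:2, 1:2], 0.01, 500), "missing")
})

test_that("clumping is idempotent and monotone in the r2 threshold", {
  set.seed(11)
  J <- 20
  ld <- simulateLdMatrix(J, 0.85, paste0("rs", 1:J))
  ds <- makeDataset(paste0("rs", 1:J), seq(1e5, 2e5, length.out = J),
                    beta = rnorm(J, 0, 0.05), se = 0.01)
  clumped <- clumpVariants(ds, ld, 0.01, 500)
  again <- clumpVariants(clumped, ld, 0.01, 500)
  expect_identical(variantIds(again), variantIds(clumped))
  expect_true(all(variantIds(clumped) %in% variantIds(ds)))

  sizes <- vapply(c(0, 0.01, 0.1, 0.4, 0.9, 1), function(r2)
    nVariants(clumpVariants(ds, ld, r2, 500)), 0L)
  expect_true(all(diff(sizes) >= 0))  # stricter threshold removes more
})

discoveryFixture <- function() {
  # 8 variants around gene [10000, 20000]; hand-applied rule sequence:
  #   cis +/-2500 -> drops rs8 (pos 30000)
  #   BH FDR(7 p-values) < 0.05 -> keeps rs1, rs2, rs3, rs7 (palindromic)
  #   palindrome -> drops rs7 (A/T)
  #   clump r2>0.01/500kb: rs1 indexes, removes rs2 (r2 0.64); rs3 survives
  # expected discovery set: rs1, rs3
  ids <- paste0("rs", 1:8)
  p <- c(1e-10, 1e-7, 1e-6, 0.2, 0.4, 0.9, 1e-8, 1e-20)
  ds <- SummaryDataset(data.frame(
    variant_id = ids, chromosome = "11",
    position = c(9000, 11000, 15000, 16000, 17000, 22000, 12000, 30000),
    effect_allele = c("A", "C", "G", "A", "C", "G", "A", "A"),
    other_allele = c("G", "T", "A", "C", "A", "T", "T", "G"),
    eaf = 0.3, beta = 0.1, se = 0.01, pvalue = p, n = 1000), "bg")
  ld <- diag(8); dimnames(ld) <- list(ids, ids)
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- 0.8
  list(ds = ds, ld = ld,
       spec = drugTargetSpec("sulfonylureas", geneRegion("KCNJ11", 10000, 20000, "11"),
                             designatedProxies = "rs4"))
}

test_that("discovery selection composes the four filters as hand-applied", {
  fx <- discoveryFixture()
  sel <- selectInstrumentsDiscovery(fx$ds, fx$spec, fx$ld)
  expect_setequal(variantIds(sel$discovery), c("rs1", "rs3"))
  expect_equal(sel$discovery@mode, "discovery")
  log <- selectionLog(sel$discovery)
  expect_true(any(log$variant_id == "rs7" & log$step == "palindrome"))
  expect_true(any(log$variant_id == "rs2" & log$step == "clump"))
  # rs4 fails FDR yet is emitted separately, never merged
  expect_equal(variantIds(sel$designated_proxy), "rs4")
  expect_equal(sel$designated_proxy@mode, "designated_proxy")
  expect_false("rs4" %in% variantIds(sel$discovery))
})

test_that("discovery with nothing significant errors unless a proxy exists", {
  fx <- discoveryFixture()
  rec <- records(fx$ds)
  rec$pvalue <- pmin(rec$pvalue * 1e9, 1)  # nothing passes FDR now
  dsNull <- SummaryDataset(rec, "bg")
  noProxy <- drugTargetSpec("sulfonylureas",
                            geneRegion("KCNJ11", 10000, 20000, "11"))
  expect_error(selectInstrumentsDiscovery(dsNull, noProxy, fx$ld),
               "no instruments")
  sel <- selectInstrumentsDiscovery(dsNull, fx$spec, fx$ld)
  expect_null(sel$discovery)
  expect_equal(variantIds(sel$designated_proxy), "rs4")
})

test_that("filter degeneracy returns the full cis-window set", {
  fx <- discoveryFixture()
  rec <- records(fx$ds)
  rec <- rec[!isPalindromic(rec$effect_allele, rec$other_allele), ]
  ds <- SummaryDataset(rec, "bg")
  sel <- selectInstrumentsDiscovery(ds, fx$spec, fx$ld, fdrThreshold = 1 + 1e-9,
                                    r2Threshold = 1)
  cis <- extractCisWindow(ds, fx$spec@regions, 2500)
  expect_setequal(variantIds(sel$discovery), variantIds(cis))
})

test_that("validation selection uses strict p, permissive LD, attached LD", {
  ids <- paste0("rs", 1:4)
  ds <- SummaryDataset(data.frame(
    variant_id = ids, chromosome = "11",
    position = c(11000, 12000, 13000, 14000),
    effect_allele = "A", other_allele = "G", eaf = 0.3, beta = 0.1,
    se = 0.01, pvalue = c(1e-8, 1e-7, 1e-5, 1e-6), n = 1000), "bg")
  ld <- diag(4); dimnames(ld) <- list(ids, ids)
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- sqrt(0.3)
  ld["rs1", "rs4"] <- ld["rs4", "rs1"] <- sqrt(0.5)
  spec <- drugTargetSpec("sulfonylureas",
                         geneRegion("KCNJ11", 10000, 20000, "11"))
  sel <- selectInstrumentsValidation(ds, spec, ld)
  # rs3 at exactly p = 1e-5 fails the strict cut; rs4 removed at r2 0.5;
  # rs1/rs2 in weak LD (r2 0.3) both retained
  expect_setequal(variantIds(sel$validation), c("rs1", "rs2"))
  expect_equal(sel$validation@mode, "validation")
  ldAtt <- ldMatrix(sel$validation)
  expect_equal(dim(ldAtt), c(2L, 2L))
  expect_equal(ldAtt["rs1", "rs2"]^2, 0.3, tolerance = 1e-12)
})

test_that("validation keeps at least as many instruments as discovery LD rules", {
  set.seed(5)
  J <- 30
  ld <- simulateLdMatrix(J, 0.9, paste0("rs", 1:J))
  ds <- makeDataset(paste0("rs", 1:J), seq(11000, 19000, length.out = J),
                    beta = rnorm(J, 0.1, 0.02), se = 0.01,
                    pvalue = runif(J, 1e-12, 1e-6))
  spec <- drugTargetSpec("x", geneRegion("g", 10000, 20000))
  loose <- selectInstrumentsValidation(ds, spec, ld, r2Threshold = 0.40)
  tight <- selectInstrumentsValidation(ds, spec, ld, r2Threshold = 0.01)
  expect_gte(nVariants(loose$validation), nVariants(tight$validation))
})

test_that("instrument sets write a table plus selection log", {
  fx <- discoveryFixture()
  sel <- selectInstrumentsDiscovery(fx$ds, fx$spec, fx$ld)
  path <- tempfile(fileext = ".tsv")
  writeInstrumentSet(sel$discovery, path)
  tab <- read.delim(path)
  expect_equal(tab$variant_id, c("rs1", "rs3"))
  expect_true(file.exists(paste0(path, ".log.tsv")))
})
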