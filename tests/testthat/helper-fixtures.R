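# fixture builders and independent oracles shared across test files

makeDataset <- function(ids, pos, beta, se, pvalue = NULL, chrom = "1",
                        ea = "A", oa = "G", eaf = 0.3, n = 10000,
                        trait = "exposure", type = "quantitative") {
  k <- length(ids)
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  SummaryDataset(data.frame(variant_id = ids, chromosome = chrom,
                            position = pos,
                            effect_allele = rep_len(ea, k),
                            other_allele = rep_len(oa, k),
                            eaf = rep_len(eaf, k), beta = beta, se = se,
                            pvalue = pvalue, n = rep_len(n, k),
                            stringsAsFactors = FALSE),
                 traitName = trait, traitType = type)
}

region <- function(start, end, chrom = "1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

geneRegion <- function(gene, start, end, chrom = "1") {
  gr <- region(start, end, chrom)
  S4Vectors::mcols(gr)$gene <- gene
  gr
}

# weighted least squares through the origin, explicit sums
oracleIvwFixed <- function(bx, by, sey) {
  w <- 1 / sey^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  list(theta = theta, se = 1 / sqrt(sum(w * bx^2)))
}

# weighted regression with intercept via explicit 2x2 normal equations
oracleEgger <- function(bx, by, sey) {
  flip <- ifelse(bx < 0, -1, 1)
  bx <- bx * flip; by <- by * flip
  w <- 1 / sey^2
  Sw <- sum(w); Swx <- sum(w * bx); Swx2 <- sum(w * bx^2)
  Swy <- sum(w * by); Swxy <- sum(w * bx * by)
  den <- Sw * Swx2 - Swx^2
  slope <- (Sw * Swxy - Swx * Swy) / den
  intercept <- (Swx2 * Swy - Swx * Swxy) / den
  res <- by - intercept - slope * bx
  df <- length(bx) - 2
  sigma2 <- sum(w * res^2) / df
  list(intercept = intercept, slope = slope,
       seIntercept = sqrt(sigma2 * Swx2 / den),
       seSlope = sqrt(sigma2 * Sw / den), df = df)
}

# generalized least squares through the origin via explicit matrix inverse
oracleGls <- function(bx, by, sey, rho) {
  Omega <- outer(sey, sey) * rho
  Oinv <- solve(Omega)
  prec <- drop(t(bx) %*% Oinv %*% bx)
  list(theta = drop(t(bx) %*% Oinv %*% by) / prec, se = sqrt(1 / prec))
}

# brute-force five-hypothesis enumeration with plain products (no log-space)
oracleColoc <- function(beta1, se1, beta2, se2, sd1, sd2,
                        p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  abf <- function(beta, se, W) {
    V <- se^2
    sqrt(V / (V + W)) * exp((beta / se)^2 * W / (2 * (V + W)))
  }
  B1 <- abf(beta1, se1, sd1^2)
  B2 <- abf(beta2, se2, sd2^2)
  n <- length(B1)
  h0 <- 1
  h1 <- p1 * sum(B1)
  h2 <- p2 * sum(B2)
  h3 <- 0
  for (j in seq_len(n)) for (k in seq_len(n))
    if (j != k) h3 <- h3 + B1[j] * B2[k]
  h3 <- p1 * p2 * h3
  h4 <- p12 * sum(B1 * B2)
  tot <- h0 + h1 + h2 + h3 + h4
  c(H0 = h0, H1 = h1, H2 = h2, H3 = h3, H4 = h4) / tot
}

# random positive-definite correlation matrix (AR(1) with random decay)
randomRho <- function(J, seed) {
  set.seed(seed)
  simulateLdMatrix(J, runif(1, 0, 0.8), paste0("snp", seq_len(J)))
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
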