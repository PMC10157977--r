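test_that("ROH-state indicator uses closed intervals per sample", {
  map <- data.frame(marker_id = c("m1", "m2", "m3", "m4"), chrom = 1L,
                    pos_bp = c(1e6, 2e6, 3e6, 3000001), allele_a = "A",
                    allele_b = "B")
  segs <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(start = 1e6, end = 3e6),
    sample_id = "s1", n_snps = 3L, n_het = 0L)
  st <- rohStateMatrix(segs, map, samples = c("s1", "s2"))
  expect_equal(unname(st["s1", ]), c(1L, 1L, 1L, 0L))  # start in, end+1 out
  expect_equal(unname(st["s2", ]), rep(0L, 4))         # no segments
})

test_that("scan coefficients at fixed VC match a dense joint GLS refit", {
  set.seed(21)
  cfg <- simConfig(seed = 21, nBulls = 30, nChrom = 2, nFounders = 20,
                   nGenerationsAncient = 4, recordsPerBull = c(3, 5),
                   chromLengthMb = 40)
  sim <- simulateGenotypes(cfg)
  g <- sim$genotypes
  ph <- simulatePhenotypes(sim, cfg)
  grm <- buildGrm(filterMarkersQC(g))
  base <- fitAnimalModel(ph, grm)
  segs <- detectRoh(g)
  states <- rohStateMatrix(segs, markerMap(g), sampleIds(g))
  sc <- runScan(ph, grm, g, states, base)

  bulls <- sort(unique(ph$bull_id))
  bidx <- match(ph$bull_id, bulls)
  X <- rohdep:::.reduceRank(rohdep:::.buildDesign(ph, NULL))$X
  vc <- unname(varComp(base))
  okIdx <- which(sc$status == "ok")
  for (j in sample(okIdx, 25)) {
    u1 <- dosage(g)[bulls, j]
    u2 <- states[bulls, j]
    Xj <- cbind(X, u1[bidx], u2[bidx])
    or <- denseGls(ph$value, Xj, bidx, grm[bulls, bulls], vc)
    k <- ncol(Xj)
    if (stats::var(u1) > 0) {
      expect_equal(sc$b_add[j], unname(or$beta[k - 1]), tolerance = 1e-8)
    }
    expect_equal(sc$b_roh[j], unname(or$beta[k]), tolerance = 1e-8)
    expect_equal(sc$se_roh[j], unname(sqrt(or$cov[k, k])), tolerance = 1e-8)
  }
})

test_that("scan flags SNPs without usable ROH-state variation", {
  set.seed(22)
  cfg <- simConfig(seed = 22, nBulls = 25, nChrom = 1, nFounders = 15,
                   nGenerationsAncient = 3, recordsPerBull = c(3, 4),
                   chromLengthMb = 30, closeMatingFrac = 0)
  sim <- simulateGenotypes(cfg)
  g <- sim$genotypes
  ph <- simulatePhenotypes(sim, cfg)
  grm <- buildGrm(filterMarkersQC(g))
  base <- fitAnimalModel(ph, grm)
  # an all-zero ROH-state matrix: every SNP lacks variation
  states0 <- matrix(0L, nSamples(g), nMarkers(g),
                    dimnames = list(sampleIds(g),
                                    markerMap(g)$marker_id))
  sc0 <- runScan(ph, grm, g, states0, base)
  expect_true(all(sc0$status == "NA_no_variation"))
  expect_true(all(is.na(sc0$p_roh)))
  # refuse an unconverged VC source
  fakeFit <- base; fakeFit@converged <- FALSE
  expect_error(runScan(ph, grm, g, states0, fakeFit), "not converged")
})

test_that("proportion FDR formula, identity at N = P, and monotonicity", {
  expect_equal(fdrProportion(0.01, 0.5), 0.01 * 0.5 / (0.5 * 0.99))
  expect_equal(fdrProportion(0.01, 0.5), 0.01010101, tolerance = 1e-7)
  expect_equal(fdrProportion(0.037, 0.037), 1.0)
  expect_error(fdrProportion(0, 0.5), "pThreshold")
  expect_error(fdrProportion(0.01, 0), "nProp")
  # increasing in P at fixed N; decreasing in N at fixed P
  P <- seq(0.001, 0.9, length.out = 40)
  expect_true(all(diff(fdrProportion(P, 0.3)) > 0))
  N <- seq(0.01, 1, length.out = 40)
  expect_true(all(diff(fdrProportion(0.05, N)) < 0))
})

test_that("minimum-FDR threshold search honours ties and skips empty candidates", {
  fake <- data.frame(p_roh = c(1e-6, 1e-6, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95),
                     status = "ok")
  res <- minFdrThreshold(fake, c(1e-5))
  expect_equal(res$p_threshold, 1e-5)
  # candidate below every p-value is skipped with a warning
  expect_warning(res2 <- minFdrThreshold(fake, c(1e-8, 1e-5)), "skipped")
  expect_equal(res2$p_threshold, 1e-5)
  # exact tie in FDR: the smaller threshold wins
  # two candidates catching the same 2 SNPs at the same N give different
  # FDR; construct a genuine tie via identical (P, N) pairs instead
  res3 <- minFdrThreshold(fake, c(1e-5, 1e-5))
  expect_equal(res3$p_threshold, 1e-5)
})

test_that("region calling merges by gap, reports windows, and is order-invariant", {
  pos <- c(4.21e6, 4.40e6, 4.66e6, 5.02e6, 5.9e6, 6.74e6, 4.0e7)
  sc <- data.frame(marker_id = sprintf("m%d", seq_along(pos)), chrom = 8L,
                   pos_bp = pos,
                   b_add = 0, b_roh = -1, se_roh = 0.1,
                   p_roh = c(rep(1e-6, 6), 0.5),
                   status = "ok")
  reg1 <- callRegions(sc, 1e-4, mergeGapBp = 1e6)
  expect_length(reg1, 1)  # 0.36 Mb between clusters: merged at 1 Mb
  expect_equal(GenomicRanges::start(reg1), 4.21e6)
  expect_equal(GenomicRanges::end(reg1), 6.74e6)
  reg2 <- callRegions(sc, 1e-4, mergeGapBp = 3e5)
  # 0.36 Mb between the clusters splits them; the sparse right-hand
  # cluster (0.88 Mb internal gaps) splits into singletons too
  expect_length(reg2, 4)
  expect_equal(S4Vectors::mcols(reg2)$n_significant_snps, c(3L, 1L, 1L, 1L))
  # row order does not matter; repeated calling is stable
  shuf <- sc[sample(nrow(sc)), ]
  reg3 <- callRegions(shuf, 1e-4, mergeGapBp = 3e5)
  expect_equal(as.character(reg3), as.character(reg2))
  # nothing significant -> empty; single SNP -> zero-span region
  expect_length(callRegions(sc, 1e-9), 0)
  one <- sc; one$p_roh <- c(1e-6, rep(0.5, 6))
  regOne <- callRegions(one, 1e-4)
  expect_equal(GenomicRanges::width(regOne), 1L)
  # gene windows: +-500 kb lookup
  genes <- GenomicRanges::GRanges(
    "8", IRanges::IRanges(start = c(3.8e6, 7.1e6, 9e6), width = 1e4),
    name = c("NEAR_LEFT", "NEAR_RIGHT", "FAR"))
  regG <- callRegions(sc, 1e-4, mergeGapBp = 1e6, genes = genes)
  expect_equal(S4Vectors::mcols(regG)$genes, "NEAR_LEFT,NEAR_RIGHT",
               ignore_attr = TRUE)
})
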