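test_that("simulation is deterministic in the seed and validates its config", {
  cfg <- simConfig(seed = 5, nBulls = 12, nChrom = 2, nFounders = 10,
                   nGenerationsAncient = 2)
  a <- simulateGenotypes(cfg)
  b <- simulateGenotypes(cfg)
  expect_identical(dosage(a$genotypes), dosage(b$genotypes))
  expect_identical(a$truth$ibdFraction, b$truth$ibdFraction)
  pha <- simulatePhenotypes(a, cfg)
  phb <- simulatePhenotypes(b, cfg)
  expect_identical(pha$value, phb$value)
  expect_error(simConfig(), "seed")
  expect_error(simConfig(seed = 1, nFounders = 2), "nFounders")
  expect_error(simConfig(seed = 1, closeMatingFrac = 1.5),
               "closeMatingFrac")
})

test_that("outbred scenario has near-zero IBD; full-sib offspring approach 0.25", {
  # large founder pool, no burn-in, no close matings: IBD is impossible
  cfg0 <- simConfig(seed = 6, nBulls = 50, nChrom = 2, nFounders = 60,
                    nGenerationsAncient = 0, closeMatingFrac = 0)
  sim0 <- simulateGenotypes(cfg0)
  expect_equal(mean(sim0$truth$ibdFraction), 0)
  segs0 <- detectRoh(sim0$genotypes)
  fr0 <- fRoh(segs0, genomeLength(markerMap(sim0$genotypes)),
              samples = sampleIds(sim0$genotypes))
  expect_lt(mean(fr0), 0.02)  # only chance IBS runs can be called

  # recent-only close matings: expected true IBD fraction 0.25
  cfg1 <- simPreset("recent-only", seed = 7, nBulls = 200, nChrom = 3,
                    nFounders = 50, closeMatingFrac = 1)
  sim1 <- simulateGenotypes(cfg1)
  f <- sim1$truth$ibdFraction
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.25), 3 * se)
})

test_that("called ROH recovers long true IBD and skips sub-1Mb IBD by construction", {
  sim <- midSim()
  truth <- sim$sim$truth
  g <- sim$sim$genotypes
  segs <- detectRoh(g)
  # coverage of true IBD bp in segments >= 2 Mb by called ROH
  long <- truth$segments[truth$segments$length_bp >= 2e6, ]
  if (nrow(long)) {
    tg <- GenomicRanges::GRanges(
      paste0(long$chrom, "_", long$sample_id),
      IRanges::IRanges(long$start_bp, long$end_bp))
    cg <- GenomicRanges::GRanges(
      paste0(as.character(GenomicRanges::seqnames(segs)), "_",
             S4Vectors::mcols(segs)$sample_id),
      IRanges::IRanges(GenomicRanges::start(segs),
                       GenomicRanges::end(segs)))
    ov <- GenomicRanges::intersect(tg, cg)
    recovered <- sum(GenomicRanges::width(ov)) /
      sum(GenomicRanges::width(tg))
    expect_gt(recovered, 0.9)
  }
  # ROH calling thresholds exclude all sub-1 Mb runs
  expect_true(all(GenomicRanges::width(segs) >= 1e6))
})

test_that("phenotypes follow the generative model", {
  # pure-noise config: records are iid standard normal
  cfg <- simConfig(seed = 8, nBulls = 80, nChrom = 1, nFounders = 40,
                   nGenerationsAncient = 0, closeMatingFrac = 0,
                   recordsPerBull = c(5, 5),
                   vcTrue = c(sigma_a2 = 0, sigma_pe2 = 0, sigma_e2 = 1),
                   mu = 0, bAgeTrue = 0, b2True = 0, fixedEffectSd = 0)
  sim <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(sim, cfg)
  expect_equal(nrow(ph), 400)
  expect_gt(ks.test(ph$value, "pnorm")$p.value, 0.01)
  # record counts honoured exactly
  expect_true(all(table(ph$bull_id) == 5))

  # regression of bull-mean phenotype on true IBD recovers b2True
  cfg2 <- simConfig(seed = 9, nBulls = 150, nChrom = 3, nFounders = 40,
                    nGenerationsAncient = 6, recordsPerBull = c(20, 20),
                    vcTrue = c(sigma_a2 = 0, sigma_pe2 = 0,
                               sigma_e2 = 0.5),
                    mu = 0, bAgeTrue = 0, b2True = -5, fixedEffectSd = 0)
  sim2 <- simulateGenotypes(cfg2)
  ph2 <- simulatePhenotypes(sim2, cfg2)
  ym <- tapply(ph2$value, ph2$bull_id, mean)
  fit <- lm(ym[names(sim2$truth$ibdFraction)] ~ sim2$truth$ibdFraction)
  expect_equal(unname(coef(fit)[2]), -5,
               tolerance = 3 * summary(fit)$coefficients[2, 2] / 5 + 0.05)
})

test_that("class-specific and locus-specific effects enter the truth as declared", {
  cfg <- simConfig(seed = 10, nBulls = 60, nChrom = 2, nFounders = 30,
                   nGenerationsAncient = 4,
                   b2ClassTrue = c(0, 0, 0, 0, -10),
                   vcTrue = c(sigma_a2 = 0, sigma_pe2 = 0, sigma_e2 = 1e-4),
                   mu = 0, bAgeTrue = 0, fixedEffectSd = 0,
                   recordsPerBull = c(1, 1))
  sim <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(sim, cfg)
  want <- -10 * sim$truth$classFraction[, "roh_gt16"]
  got <- tapply(ph$value, ph$bull_id, mean)[rownames(sim$truth$classFraction)]
  expect_lt(max(abs(got - want)), 0.05)  # residual sd is 0.01

  # locus effect: only bulls IBD at the marker are shifted
  mk <- markerMap(sim$genotypes)$marker_id[1000]
  cfgL <- simConfig(seed = 10, nBulls = 60, nChrom = 2, nFounders = 30,
                    nGenerationsAncient = 4,
                    locusEffects = data.frame(marker_id = mk, d = -7),
                    vcTrue = c(sigma_a2 = 0, sigma_pe2 = 0,
                               sigma_e2 = 1e-4),
                    mu = 0, bAgeTrue = 0, b2True = 0, fixedEffectSd = 0,
                    recordsPerBull = c(1, 1))
  phL <- simulatePhenotypes(sim, cfgL)
  gotL <- tapply(phL$value, phL$bull_id,
                 mean)[rownames(sim$truth$ibdState)]
  expect_lt(max(abs(gotL - (-7 * sim$truth$ibdState[, mk]))), 0.05)
  expect_error(simulatePhenotypes(
    sim, simConfig(seed = 1, locusEffects = data.frame(marker_id = "nope",
                                                       d = 1))),
    "not in map")
})
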