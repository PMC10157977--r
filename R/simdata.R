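#' Simulation configuration
#'
#' Study conditions for the gene-dropping simulator: a founder population,
#' a small-Ne burn-in producing ancient (short) identity-by-descent, a
#' final generation of bulls of which a fraction come from designed
#' full-sib matings (recent, long IBD), and repeated phenotype records
#' generated under the same fixed-effect / animal / permanent-environment
#' structure that the fitting functions assume.
#'
#' Defaults describe the desk-scale scenario used throughout the tests:
#' 300 bulls, 5 chromosomes of 100 Mb at 50 kb SNP spacing (10,000 SNPs),
#' sperm-concentration-like variance components, and a genome-wide
#' inbreeding-depression slope of -5 trait units per unit F.
#'
#' @param seed integer seed (mandatory); stage-specific substreams are
#'   derived from it so genotypes and phenotypes are independently
#'   reproducible.
#' @param nFounders founder population size (also the burn-in Ne).
#' @param nGenerationsAncient burn-in generations of random mating.
#' @param nBulls genotyped/phenotyped bulls in the final generation.
#' @param nChrom,chromLengthMb,snpSpacingKb genome layout.
#' @param founderMafRange allele-frequency range for founder SNPs.
#' @param recombRateCmPerMb recombination rate (Haldane map function).
#' @param closeMatingFrac fraction of bulls produced by full-sib matings
#'   (expected IBD fraction 0.25 per such bull).
#' @param recordsPerBull integer range (min, max) of records per bull.
#' @param nYearSeason,nCenter,nInterval,nSample fixed-effect level counts.
#' @param ageRangeMonths age range at recording.
#' @param vcTrue true variance components
#'   `c(sigma_a2, sigma_pe2, sigma_e2)`.
#' @param mu overall trait mean; `trait` its label (EV/SC/SM).
#' @param bAgeTrue true age slope (trait units per month).
#' @param b2True true genome-wide inbreeding-depression slope (trait units
#'   per unit IBD fraction).
#' @param b2ClassTrue optional length-5 vector of class-specific slopes
#'   (same length bins as the ROH classes); when given it replaces the
#'   genome-wide `b2True` term with `sum_q b2q * trueClassFraction_q`.
#' @param locusEffects optional `data.frame(marker_id, d)`: additional
#'   depression `d` added when the SNP lies in a true IBD segment.
#' @param fixedEffectSd SD of the categorical level effects; default 20%
#'   of the phenotypic SD.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(seed,
                      nFounders = 150L, nGenerationsAncient = 5L,
                      nBulls = 300L, nChrom = 5L, chromLengthMb = 100,
                      snpSpacingKb = 50, founderMafRange = c(0.05, 0.5),
                      recombRateCmPerMb = 1, closeMatingFrac = 0.3,
                      recordsPerBull = c(6L, 30L),
                      nYearSeason = 12L, nCenter = 4L, nInterval = 4L,
                      nSample = 3L, ageRangeMonths = c(12, 120),
                      vcTrue = c(sigma_a2 = 2.3, sigma_pe2 = 4.5,
                                 sigma_e2 = 14.4),
                      mu = 12.67, trait = "SC", bAgeTrue = 0.02,
                      b2True = -5, b2ClassTrue = NULL,
                      locusEffects = NULL, fixedEffectSd = NULL) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  stopifnot(nFounders >= 4, nGenerationsAncient >= 0, nBulls >= 1,
            nChrom >= 1, chromLengthMb > 0, snpSpacingKb > 0,
            closeMatingFrac >= 0, closeMatingFrac <= 1,
            length(recordsPerBull) == 2,
            recordsPerBull[1] >= 1, recordsPerBull[2] >= recordsPerBull[1],
            all(vcTrue >= 0), all(is.finite(c(mu, bAgeTrue, b2True))),
            founderMafRange[1] > 0, founderMafRange[2] <= 0.5)
  if (!is.null(b2ClassTrue))
    stopifnot(length(b2ClassTrue) == 5, all(is.finite(b2ClassTrue)))
  if (!is.null(locusEffects))
    stopifnot(is.data.frame(locusEffects),
              all(c("marker_id", "d") %in% names(locusEffects)),
              all(is.finite(locusEffects$d)))
  names(vcTrue) <- .vcNames
  if (is.null(fixedEffectSd)) fixedEffectSd <- 0.2 * sqrt(sum(vcTrue))
  cfg <- list(seed = as.integer(seed), nFounders = as.integer(nFounders),
              nGenerationsAncient = as.integer(nGenerationsAncient),
              nBulls = as.integer(nBulls), nChrom = as.integer(nChrom),
              chromLengthMb = chromLengthMb, snpSpacingKb = snpSpacingKb,
              founderMafRange = founderMafRange,
              recombRateCmPerMb = recombRateCmPerMb,
              closeMatingFrac = closeMatingFrac,
              recordsPerBull = as.integer(recordsPerBull),
              nYearSeason = as.integer(nYearSeason),
              nCenter = as.integer(nCenter),
              nInterval = as.integer(nInterval),
              nSample = as.integer(nSample),
              ageRangeMonths = ageRangeMonths, vcTrue = vcTrue, mu = mu,
              trait = trait, bAgeTrue = bAgeTrue, b2True = b2True,
              b2ClassTrue = b2ClassTrue, locusEffects = locusEffects,
              fixedEffectSd = fixedEffectSd)
  class(cfg) <- "SimConfig"
  cfg
}

#' Preset simulation scenarios
#'
#' `"default"`: genome-wide depression only (`b2True = -5`);
#' `"null"`: no inbreeding or locus effects (type-I-error scenario);
#' `"recent-only"`: no burn-in, so the only IBD is recent (long segments)
#' from the designed close matings.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [simConfig()].
#' @return a `SimConfig`.
#' @export
simPreset <- function(name = c("default", "null", "recent-only"), seed,
                      ...) {
  name <- match.arg(name)
  switch(name,
    "default" = simConfig(seed = seed, ...),
    "null" = simConfig(seed = seed, b2True = 0, locusEffects = NULL, ...),
    "recent-only" = simConfig(seed = seed, nGenerationsAncient = 0L, ...))
}

# one meiosis: origins is 2 x S integer; returns the transmitted S-gamete.
# Haldane model: crossover count per chromosome ~ Poisson(length in Morgan),
# positions uniform; the starting strand is fair.
.meiosis <- function(origins, chromIdx, chromLenBp, morgans, pos) {
  gam <- integer(ncol(origins))
  for (c in seq_along(chromIdx)) {
    idx <- chromIdx[[c]]
    k <- rpois(1, morgans[c])
    strand <- sample.int(2L, 1L)
    if (k == 0) {
      gam[idx] <- origins[strand, idx]
    } else {
      br <- sort(runif(k, 0, chromLenBp[c]))
      sw <- (strand - 1L + findInterval(pos[idx], br)) %% 2L + 1L
      gam[idx] <- origins[cbind(sw, idx)]
    }
  }
  gam
}

#' Simulate genotypes by gene dropping
#'
#' Founder haplotypes are drawn per SNP at frequencies from
#' `founderMafRange`; descendants are produced by gamete dropping with
#' Haldane recombination through `nGenerationsAncient` generations of
#' random mating at Ne = `nFounders` (ancient, short IBD), and a final
#' bull generation of which `closeMatingFrac` come from full-sib matings
#' (recent, long IBD). Identity by descent is tracked exactly through
#' founder-haplotype labels, which separates IBD from chance
#' identity-by-state just as ROH analysis assumes.
#'
#' @param cfg a [simConfig()] object.
#' @return list with `genotypes` (a [GenotypeData-class]) and `truth`, a
#'   `SimTruth` list holding per-bull true IBD fractions (`ibdFraction`),
#'   the SNP-level IBD state matrix (`ibdState`), the dropped IBD segment
#'   table (`segments`, with a length-based generation estimate and a
#'   close-mating flag) and `closeMated`.
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  spacing <- cfg$snpSpacingKb * 1000
  perChrom <- floor(cfg$chromLengthMb * 1e6 / spacing)
  if (perChrom < 2) stop("fewer than 2 SNPs per chromosome")
  map <- do.call(rbind, lapply(seq_len(cfg$nChrom), function(ch)
    data.frame(marker_id = sprintf("snp_%d_%d", ch, seq_len(perChrom)),
               chrom = ch, pos_bp = spacing * seq_len(perChrom),
               allele_a = "A", allele_b = "B")))
  S <- nrow(map)
  chromIdx <- split(seq_len(S), map$chrom)
  chromLenBp <- vapply(chromIdx, function(i) max(map$pos_bp[i]),
                       numeric(1))
  morgans <- chromLenBp / 1e6 * cfg$recombRateCmPerMb / 100

  nf <- cfg$nFounders
  p <- runif(S, cfg$founderMafRange[1], cfg$founderMafRange[2])
  hapAllele <- matrix(rbinom(2L * nf * S, 1L, rep(p, each = 2L * nf)),
                      nrow = 2L * nf)
  pop <- lapply(seq_len(nf), function(i)
    rbind(2L * i - 1L, 2L * i))
  pop <- lapply(pop, function(m)
    matrix(rep(as.integer(m), S), nrow = 2L))

  drop1 <- function(par) .meiosis(par, chromIdx, chromLenBp, morgans,
                                  map$pos_bp)
  mate <- function(p1, p2) rbind(drop1(p1), drop1(p2))

  for (gen in seq_len(cfg$nGenerationsAncient)) {
    pop <- lapply(seq_len(nf), function(i) {
      pr <- sample.int(nf, 2L)
      mate(pop[[pr[1]]], pop[[pr[2]]])
    })
  }

  nClose <- round(cfg$closeMatingFrac * cfg$nBulls)
  closeMated <- rep(c(TRUE, FALSE), c(nClose, cfg$nBulls - nClose))
  bulls <- vector("list", cfg$nBulls)
  for (b in seq_len(cfg$nBulls)) {
    pr <- sample.int(nf, 2L)
    if (closeMated[b]) {
      sib1 <- mate(pop[[pr[1]]], pop[[pr[2]]])
      sib2 <- mate(pop[[pr[1]]], pop[[pr[2]]])
      bulls[[b]] <- mate(sib1, sib2)
    } else {
      bulls[[b]] <- mate(pop[[pr[1]]], pop[[pr[2]]])
    }
  }

  ids <- sprintf("bull_%03d", seq_len(cfg$nBulls))
  dose <- matrix(0L, cfg$nBulls, S, dimnames = list(ids, map$marker_id))
  ibdState <- matrix(0L, cfg$nBulls, S, dimnames = list(ids, map$marker_id))
  segs <- vector("list", cfg$nBulls)
  lg <- genomeLength(map)
  for (b in seq_len(cfg$nBulls)) {
    o <- bulls[[b]]
    dose[b, ] <- hapAllele[cbind(o[1L, ], seq_len(S))] +
      hapAllele[cbind(o[2L, ], seq_len(S))]
    ibd <- o[1L, ] == o[2L, ]
    ibdState[b, ] <- as.integer(ibd)
    segRows <- lapply(chromIdx, function(idx) {
      r <- rle(ibd[idx])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      w <- which(r$values)
      if (!length(w)) return(NULL)
      data.frame(chrom = map$chrom[idx[1]],
                 start_bp = map$pos_bp[idx[starts[w]]],
                 end_bp = map$pos_bp[idx[ends[w]]],
                 n_snps = r$lengths[w])
    })
    sr <- do.call(rbind, segRows)
    if (!is.null(sr) && nrow(sr)) {
      sr <- data.frame(sample_id = ids[b], sr,
                       length_bp = sr$end_bp - sr$start_bp + 1)
      sr$gen_estimate <- generationsForLength(pmax(sr$length_bp, 1) / 1e6)
      sr$close_mated <- closeMated[b]
      segs[[b]] <- sr
    }
  }
  segments <- do.call(rbind, segs)
  if (is.null(segments))
    segments <- data.frame(sample_id = character(), chrom = integer(),
                           start_bp = integer(), end_bp = integer(),
                           n_snps = integer(), length_bp = numeric(),
                           gen_estimate = numeric(), close_mated = logical())
  ibdFraction <- tapply(segments$length_bp,
                        factor(segments$sample_id, levels = ids), sum)
  ibdFraction <- setNames(as.numeric(ibdFraction) / lg, ids)
  ibdFraction[is.na(ibdFraction)] <- 0
  # true IBD decomposed over the same length bins as the ROH classes;
  # unlike called-ROH classes this includes segments shorter than 1 Mb
  # (extra first bin), so depression can be injected per class
  binsMb <- c(0, ROH_BREAKS_MB)
  classFraction <- matrix(0, length(ids), 6,
                          dimnames = list(ids, c("lt1", ROH_CLASSES)))
  if (nrow(segments)) {
    cl <- cut(segments$length_bp / 1e6, breaks = binsMb, right = FALSE,
              labels = c("lt1", ROH_CLASSES))
    agg <- tapply(segments$length_bp,
                  list(factor(segments$sample_id, levels = ids), cl), sum)
    agg[is.na(agg)] <- 0
    classFraction[rownames(agg), colnames(agg)] <- agg / lg
  }
  truth <- structure(list(ibdFraction = ibdFraction, ibdState = ibdState,
                          classFraction = classFraction,
                          segments = segments, closeMated = closeMated,
                          l_g = lg, seed = cfg$seed),
                     class = "SimTruth")
  list(genotypes = GenotypeData(dose, map), truth = truth)
}

#' Simulate repeated phenotype records
#'
#' `y = mu + year_season + center + interval + n_sample + bAge * age +
#' b2True * trueIBD + sum(locus d * IBD-at-locus) + a + pe + e`, with
#' `a ~ N(0, G sigma_a2)` drawn through the Cholesky factor of the
#' realised (post-QC) genomic relationship matrix, `pe` per bull and `e`
#' per record. Record counts per bull are uniform on `recordsPerBull`.
#'
#' @param sim output of [simulateGenotypes()] (or a list with `genotypes`
#'   and `truth`).
#' @param cfg the same [simConfig()].
#' @return phenotype `data.frame` in the [readPhenotypes()] layout, with
#'   attributes `expected` (per-record expected value given the realised
#'   random effects... excluded residual), `bullValue` (per-bull genetic +
#'   permanent-environment values) and `trueIbd`.
#' @export
simulatePhenotypes <- function(sim, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  g <- sim$genotypes; truth <- sim$truth
  set.seed(cfg$seed + 97L)
  ids <- sampleIds(g)
  q <- length(ids)
  vc <- cfg$vcTrue

  a <- rep(0, q)
  if (vc["sigma_a2"] > 0) {
    gq <- filterMarkersQC(g)
    if (nMarkers(gq) < 2) stop("too few polymorphic markers for the GRM")
    G <- buildGrm(gq)
    L <- NULL; ridge <- 0
    for (k in 0:6) {
      ridge <- if (k == 0) 0 else 10^(k - 7)
      L <- tryCatch(chol(G + diag(ridge, q)), error = function(e) NULL)
      if (!is.null(L)) break
    }
    if (is.null(L)) stop("realised GRM is not positive definite")
    a <- drop(t(L) %*% rnorm(q)) * sqrt(vc["sigma_a2"])
  }
  pe <- rnorm(q, 0, sqrt(vc["sigma_pe2"]))

  nrec <- if (cfg$recordsPerBull[1] == cfg$recordsPerBull[2])
    rep(cfg$recordsPerBull[1], q)
  else sample(cfg$recordsPerBull[1]:cfg$recordsPerBull[2], q,
              replace = TRUE)
  n <- sum(nrec)
  bull <- rep(ids, nrec)
  bidx <- rep(seq_len(q), nrec)

  lev <- function(k, nm) sprintf("%s%02d", nm, sample.int(k, n,
                                                          replace = TRUE))
  ys <- lev(cfg$nYearSeason, "ys"); ct <- lev(cfg$nCenter, "c")
  iv <- lev(cfg$nInterval, "i"); ns <- lev(cfg$nSample, "s")
  eff <- function(v, k, nm) {
    e <- rnorm(k, 0, cfg$fixedEffectSd)
    names(e) <- sprintf("%s%02d", nm, seq_len(k))
    e[v]
  }
  age <- runif(n, cfg$ageRangeMonths[1], cfg$ageRangeMonths[2])

  locus <- rep(0, q)
  if (!is.null(cfg$locusEffects)) {
    for (r in seq_len(nrow(cfg$locusEffects))) {
      mk <- as.character(cfg$locusEffects$marker_id[r])
      if (!mk %in% colnames(truth$ibdState))
        stop("locus effect marker not in map: ", mk)
      locus <- locus + cfg$locusEffects$d[r] * truth$ibdState[, mk]
    }
  }
  depr <- if (!is.null(cfg$b2ClassTrue))
    drop(truth$classFraction[ids, ROH_CLASSES] %*% cfg$b2ClassTrue)
  else cfg$b2True * truth$ibdFraction[ids]
  bullValue <- a + pe + depr + locus
  mu <- cfg$mu
  expected <- mu + eff(ys, cfg$nYearSeason, "ys") +
    eff(ct, cfg$nCenter, "c") + eff(iv, cfg$nInterval, "i") +
    eff(ns, cfg$nSample, "s") + cfg$bAgeTrue * age + bullValue[bidx]
  y <- expected + rnorm(n, 0, sqrt(vc["sigma_e2"]))

  ph <- data.frame(bull_id = bull, trait = cfg$trait, value = y,
                   year_season = ys, center = ct, interval = iv,
                   n_sample = ns, age_months = age,
                   stringsAsFactors = FALSE)
  attr(ph, "expected") <- unname(expected)
  attr(ph, "bullValue") <- setNames(unname(bullValue), ids)
  attr(ph, "trueIbd") <- truth$ibdFraction[ids]
  ph
}
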