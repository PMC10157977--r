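# fixture builders and independent oracles used across the test files

# GenotypeData from a dosage matrix with evenly spaced SNPs on one or more
# chromosomes
makeGeno <- function(dosage, posBp = NULL, chrom = NULL) {
  s <- ncol(dosage)
  if (is.null(posBp)) posBp <- 1e5 * seq_len(s)
  if (is.null(chrom)) chrom <- rep(1L, s)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%d", seq_len(nrow(dosage)))
  GenotypeData(dosage,
               data.frame(marker_id = sprintf("m%d", seq_len(s)),
                          chrom = chrom, pos_bp = posBp,
                          allele_a = "A", allele_b = "B"))
}

# brute-force ROH oracle: enumerate every interval, keep the valid ones,
# drop intervals contained in a larger valid interval, then pick the
# non-overlapping subset greedily from the left (the reporting rule)
bruteRoh <- function(pos, het, p = rohParams()) {
  n <- length(pos)
  valid <- list()
  for (i in seq_len(n)) for (j in i:n) {
    nsnp <- j - i + 1
    if (nsnp < p$minSnps) next
    span <- pos[j] - pos[i] + 1
    if (span < p$minLengthBp) next
    if (span / nsnp > p$maxDensityBpPerSnp) next
    if (sum(het[i:j]) > p$maxHet) next
    if (nsnp > 1 && max(diff(pos[i:j])) > p$maxGapBp) next
    valid[[length(valid) + 1]] <- c(i, j)
  }
  if (!length(valid)) return(cbind(start = integer(), end = integer()))
  m <- do.call(rbind, valid)
  maximal <- vapply(seq_len(nrow(m)), function(k) {
    !any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
           (m[, 1] < m[k, 1] | m[, 2] > m[k, 2]))
  }, logical(1))
  m <- m[maximal, , drop = FALSE]
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  keep <- logical(nrow(m)); lastEnd <- 0
  for (k in seq_len(nrow(m))) {
    if (m[k, 1] > lastEnd) { keep[k] <- TRUE; lastEnd <- m[k, 2] }
  }
  m <- m[keep, , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

# extract (start, end) SNP-index runs for one sample from detectRoh output
segIdx <- function(segs, sample, pos) {
  sel <- S4Vectors::mcols(segs)$sample_id == sample
  cbind(start = match(GenomicRanges::start(segs)[sel], pos),
        end = match(GenomicRanges::end(segs)[sel], pos))
}

# dense GLS oracle for the animal model at fixed variance components:
# V = sa ZGZ' + sp ZZ' + se I, beta = (X'V^-1X)^-1 X'V^-1 y
denseGls <- function(y, X, bullIdx, G, vc) {
  n <- length(y)
  q <- nrow(G)
  Z <- matrix(0, n, q); Z[cbind(seq_len(n), bullIdx)] <- 1
  V <- vc[1] * Z %*% G %*% t(Z) + vc[2] * tcrossprod(Z) +
    vc[3] * diag(n)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  co <- solve(XtVX)
  list(beta = drop(co %*% t(X) %*% Vi %*% y), cov = co, Vi = Vi)
}

# small repeated-records phenotype table
makePheno <- function(bulls, nrec, values, trait = "SC",
                      age = NULL, ys = "y1", center = "c1",
                      interval = "i1", nsample = "s1") {
  n <- sum(nrec)
  data.frame(bull_id = rep(bulls, nrec), trait = trait, value = values,
             year_season = ys, center = center, interval = interval,
             n_sample = nsample,
             age_months = if (is.null(age)) 60 else age,
             stringsAsFactors = FALSE)
}

# shared desk-scale simulation for the expensive end-to-end tests
# (computed once per test run)
simCache <- local({
  env <- new.env()
  function(name, maker) {
    if (is.null(env[[name]])) env[[name]] <- maker()
    env[[name]]
  }
})

# mid-size scenario shared by the lmm/scan tests
midSim <- function() simCache("mid", function() {
  cfg <- simConfig(seed = 404, nBulls = 120, nChrom = 3, nFounders = 40,
                   nGenerationsAncient = 8, recordsPerBull = c(6, 10))
  s <- simulateGenotypes(cfg)
  list(cfg = cfg, sim = s, ph = simulatePhenotypes(s, cfg),
       grm = buildGrm(filterMarkersQC(s$genotypes)))
})
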