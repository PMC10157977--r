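#' ROH calling parameters
#'
#' Constraint set defining a run of homozygosity: minimum span, minimum SNP
#' count, maximum average marker spacing (density), maximum number of
#' heterozygous calls inside the run, and maximum gap between adjacent SNPs.
#' Defaults are 1 Mb / 15 SNPs / 1 SNP per 100 kb / 1 het / 500 kb.
#'
#' @param minLengthBp minimum segment span in bp (closed interval).
#' @param minSnps minimum number of SNPs in a segment.
#' @param maxDensityBpPerSnp maximum of span / n_snps, in bp per SNP.
#' @param maxHet maximum heterozygous calls inside a segment.
#' @param maxGapBp maximum distance between adjacent SNPs inside a segment.
#' @return a named list of class `ROHParams`.
#' @export
rohParams <- function(minLengthBp = 1e6, minSnps = 15L,
                      maxDensityBpPerSnp = 1e5, maxHet = 1L,
                      maxGapBp = 5e5) {
  stopifnot(minLengthBp >= 1, minSnps >= 1, maxDensityBpPerSnp > 0,
            maxHet >= 0, maxGapBp >= 1)
  structure(list(minLengthBp = minLengthBp, minSnps = as.integer(minSnps),
                 maxDensityBpPerSnp = maxDensityBpPerSnp,
                 maxHet = as.integer(maxHet), maxGapBp = maxGapBp),
            class = "ROHParams")
}

# Maximal valid runs for one individual on one chromosome.
# pos: sorted positions; het: logical. Returns matrix cbind(start, end) of
# SNP indices. A run is valid when it satisfies every constraint; returned
# runs are exactly the valid runs not contained in a larger valid run.
.rohRunsOne <- function(pos, het, p) {
  n <- length(pos)
  if (n == 0) return(cbind(start = integer(), end = integer()))
  if (p$maxHet > 1)
    stop("maxHet > 1 is not supported by the segment search")
  # split at gaps larger than maxGapBp: no valid run crosses them
  cut <- which(diff(pos) > p$maxGapBp)
  blockStart <- c(1L, cut + 1L)
  blockEnd <- c(cut, n)
  out <- vector("list", 0L)
  # density frontier g(x) = pos[x] - dens * x: interval (i, j) satisfies
  # span/n <= dens iff g(j) <= g(i) + dens - 1; an infinite cap disables it
  dens <- if (is.finite(p$maxDensityBpPerSnp)) p$maxDensityBpPerSnp
          else max(pos) + 1
  gfun <- pos - dens * seq_len(n)
  hcum <- c(0L, cumsum(het))
  for (b in seq_along(blockStart)) {
    a <- blockStart[b]; z <- blockEnd[b]
    if (z - a + 1L < p$minSnps) next
    hIdx <- a - 1L + which(het[a:z])
    if (p$maxHet == 0L && length(hIdx)) {
      # homozygous stretches between hets become separate blocks
      bounds <- c(a - 1L, hIdx, z + 1L)
      wins <- cbind(utils::head(bounds, -1) + 1L,
                    utils::tail(bounds, -1) - 1L)
    } else {
      h <- c(a - 1L, hIdx, z + 1L, z + 1L)
      k <- length(hIdx)
      tmax <- max(k - 1L, 0L)
      wins <- cbind(h[seq_len(tmax + 1L)] + 1L,
                    h[seq_len(tmax + 1L) + 2L] - 1L)
    }
    cand <- list()
    for (w in seq_len(nrow(wins))) {
      L <- wins[w, 1L]; R <- wins[w, 2L]
      if (R - L + 1L < p$minSnps) next
      maxEnd <- 0L  # per window: windows overlap, cross-window nesting is
                    # resolved by the global containment filter below
      for (i in L:(R - p$minSnps + 1L)) {
        jlo <- max(maxEnd + 1L, i + p$minSnps - 1L)
        if (jlo > R) break
        thr <- gfun[i] + dens - 1
        j <- R
        while (j >= jlo && gfun[j] > thr) j <- j - 1L
        if (j < jlo) next
        if (pos[j] - pos[i] + 1 < p$minLengthBp) next
        cand[[length(cand) + 1L]] <- c(i, j)
        maxEnd <- j
      }
    }
    if (length(cand)) out <- c(out, cand)
  }
  if (!length(out)) return(cbind(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  m <- m[order(m[, 1L], -m[, 2L]), , drop = FALSE]
  keep <- logical(nrow(m)); runMax <- 0L
  for (r in seq_len(nrow(m))) {
    if (m[r, 2L] > runMax) { keep[r] <- TRUE; runMax <- m[r, 2L] }
  }
  m <- m[keep, , drop = FALSE]
  # the <=1-het rule makes pairs of maximal intervals overlap around a
  # heterozygote (each absorbing it from one side); reported runs must not
  # double-count bp, so the non-overlapping subset is chosen greedily from
  # the left (earliest start, grown to its maximal end)
  sel <- logical(nrow(m)); lastEnd <- 0L
  for (r in seq_len(nrow(m))) {
    if (m[r, 1L] > lastEnd) { sel[r] <- TRUE; lastEnd <- m[r, 2L] }
  }
  m <- m[sel, , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

#' Detect runs of homozygosity
#'
#' Exhaustive maximal-run search: per individual and chromosome, every
#' SNP interval satisfying all of the [rohParams()] constraints and not
#' contained in a larger satisfying interval is enumerated, and the
#' reported runs are the non-overlapping subset grown greedily from the
#' left (earliest start, maximal extension) so that no bp is covered
#' twice. This is a deterministic, exactly specified rule (no
#' sliding-window heuristic), verified against brute-force enumeration in
#' the test suite.
#'
#' @param g a [GenotypeData-class] object (sorted map; no missing genotypes
#'   in strict mode).
#' @param params a [rohParams()] list.
#' @return A `GRanges` (seqnames = chromosome, 1-based closed intervals from
#'   first to last SNP of the run) with metadata columns `sample_id`,
#'   `n_snps`, `n_het`.
#' @export
detectRoh <- function(g, params = rohParams()) {
  stopifnot(is(g, "GenotypeData"))
  validObject(g)
  d <- dosage(g)
  if (g@strict && anyNA(d)) stop("missing genotypes in strict mode")
  map <- markerMap(g)
  chroms <- unique(map$chrom)
  res <- vector("list", 0L)
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    pos <- map$pos_bp[sel]
    sub <- d[, sel, drop = FALSE]
    for (s in seq_len(nrow(sub))) {
      gt <- sub[s, ]
      ok <- !is.na(gt)
      het <- gt == 1L
      if (!all(ok)) { # permissive mode: missing breaks a run
        runs <- .naSplitRuns(pos, het, ok, params)
      } else {
        runs <- .rohRunsOne(pos, het, params)
      }
      if (nrow(runs) == 0) next
      hc <- c(0L, cumsum(het & ok))
      res[[length(res) + 1L]] <- data.frame(
        sample_id = rownames(sub)[s], chrom = ch,
        start_bp = pos[runs[, 1L]], end_bp = pos[runs[, 2L]],
        n_snps = runs[, 2L] - runs[, 1L] + 1L,
        n_het = hc[runs[, 2L] + 1L] - hc[runs[, 1L]])
    }
  }
  df <- if (length(res)) do.call(rbind, res) else
    data.frame(sample_id = character(), chrom = integer(),
               start_bp = integer(), end_bp = integer(),
               n_snps = integer(), n_het = integer())
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start_bp, end = df$end_bp),
    sample_id = df$sample_id, n_snps = df$n_snps, n_het = df$n_het)
  GenomicRanges::sort(gr)
}

# permissive mode: excise missing calls and search the observed SNPs only
.naSplitRuns <- function(pos, het, ok, params) {
  idx <- which(ok)
  runs <- .rohRunsOne(pos[idx], het[idx], params)
  if (nrow(runs)) {
    runs[, 1L] <- idx[runs[, 1L]]
    runs[, 2L] <- idx[runs[, 2L]]
  }
  runs
}

ROH_CLASSES <- c("roh_1_2", "roh_2_4", "roh_4_8", "roh_8_16", "roh_gt16")
ROH_BREAKS_MB <- c(1, 2, 4, 8, 16, Inf)

#' Classify ROH segments into length classes
#'
#' Bins segment lengths into \[1,2), \[2,4), \[4,8), \[8,16), \[16, Inf) Mb
#' (lower-closed bins; a segment of exactly 16 Mb falls in \[16, Inf)) and
#' sums covered bp per sample and class.
#'
#' @param segs `GRanges` from [detectRoh()].
#' @param samples sample ids to report (rows); defaults to those present in
#'   `segs`.
#' @return numeric matrix, samples x 5 classes, of total bp per class.
#' @export
classifyRoh <- function(segs, samples = NULL) {
  sid <- S4Vectors::mcols(segs)$sample_id
  if (is.null(samples)) samples <- sort(unique(sid))
  len <- GenomicRanges::width(segs)
  cls <- cut(len / 1e6, breaks = ROH_BREAKS_MB, right = FALSE,
             labels = ROH_CLASSES)
  out <- matrix(0, nrow = length(samples), ncol = length(ROH_CLASSES),
                dimnames = list(samples, ROH_CLASSES))
  if (length(len)) {
    agg <- tapply(as.numeric(len), list(factor(sid, levels = samples), cls),
                  sum)
    agg[is.na(agg)] <- 0
    out[rownames(agg), colnames(agg)] <- agg
  }
  out
}

#' Write called ROH segments as TSV
#'
#' One row per segment: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#' `n_snps`, `n_het`, `length_bp`, `class`.
#'
#' @param segs `GRanges` from [detectRoh()].
#' @param file output path.
#' @export
writeRohTsv <- function(segs, file) {
  len <- GenomicRanges::width(segs)
  df <- data.frame(
    sample_id = S4Vectors::mcols(segs)$sample_id,
    chrom = as.character(GenomicRanges::seqnames(segs)),
    start_bp = GenomicRanges::start(segs),
    end_bp = GenomicRanges::end(segs),
    n_snps = S4Vectors::mcols(segs)$n_snps,
    n_het = S4Vectors::mcols(segs)$n_het,
    length_bp = len,
    class = as.character(cut(len / 1e6, breaks = ROH_BREAKS_MB,
                             right = FALSE, labels = ROH_CLASSES)))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
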