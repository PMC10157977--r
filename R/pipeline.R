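PIPELINE_KEYS <- c("simulate", "input", "trait", "models", "seed",
                   "out_dir", "qc", "roh", "scan", "log_level")

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> phenotype and marker QC -> ROH
#' calling -> inbreeding coefficients -> genomic-inbreeding regression
#' (models 1 and 2) -> per-SNP ROH-state scan -> region calling, from one
#' configuration, writing deterministic TSV outputs and a machine-readable
#' run manifest.
#'
#' Configuration keys (YAML file or list): exactly one of `simulate`
#' (preset name, or a list of [simConfig()] overrides with `preset`) or
#' `input` (list with `plink` prefix or `dosage`/`map` TSVs, plus
#' `phenotypes` TSV); `trait` (EV/SC/SM); `models` (subset of 1, 2, 3;
#' default all); `seed`; `out_dir`; optional `qc` (maf_min, hwe_p_min),
#' `roh` (rohParams fields), `scan` (p_thresholds, merge_gap_bp,
#' genes_bed). Unknown keys are rejected.
#'
#' @param config list or path to a YAML file.
#' @return the output directory, invisibly; outputs: `inbreeding.tsv`,
#'   `roh.tsv`, `fit_model1.tsv`/`fit_model2.tsv` (+ `varcomp_model*.yaml`),
#'   `scan.tsv`, `manhattan.tsv`, `regions.tsv`, `manifest.yaml`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$simulate) && !is.null(config$input))
    stop("config must give either 'simulate' or 'input', not both")
  if (is.null(config$simulate) && is.null(config$input))
    stop("config must give one of 'simulate' or 'input'")
  if (is.null(config$out_dir)) stop("config key 'out_dir' is required")
  if (is.null(config$seed)) stop("config key 'seed' is required")
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  models <- config$models
  if (is.null(models)) models <- c(1, 2, 3)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    simSpec <- config$simulate
    if (is.character(simSpec)) simSpec <- list(preset = simSpec)
    preset <- simSpec$preset %||% "default"
    over <- simSpec[setdiff(names(simSpec), "preset")]
    cfg <- stage("simulate",
                 do.call(simPreset,
                         c(list(name = preset, seed = config$seed), over)))
    sim <- stage("simulate", simulateGenotypes(cfg))
    geno <- sim$genotypes
    ph <- stage("simulate", simulatePhenotypes(sim, cfg))
    writePlink(geno, file.path(outDir, "simulated"))
    writePhenotypes(ph, file.path(outDir, "simulated_phenotypes.tsv"))
    utils::write.table(
      data.frame(sample_id = names(sim$truth$ibdFraction),
                 true_ibd = as.numeric(sim$truth$ibdFraction)),
      file.path(outDir, "truth_ibd.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  } else {
    inp <- config$input
    geno <- stage("load", if (!is.null(inp$plink)) readPlink(inp$plink)
                  else readGenotypesTsv(inp$dosage, inp$map))
    ph <- stage("load", readPhenotypes(inp$phenotypes))
    missCol <- setdiff(PHENO_COLS, names(ph))
    if (length(missCol))
      stop("phenotype table missing column(s): ",
           paste(missCol, collapse = ", "))
  }

  trait <- config$trait %||% ph$trait[1]
  ph <- stage("qc", filterPhenotypes(ph))
  ph <- ph[ph$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0) stop("no phenotype records for trait ", trait)
  ph <- ph[ph$bull_id %in% sampleIds(geno), , drop = FALSE]

  qcArgs <- config$qc %||% list()
  genoQc <- stage("qc", filterMarkersQC(
    geno, mafMin = qcArgs$maf_min %||% 0.01,
    hwePMin = qcArgs$hwe_p_min %||% 1e-6))

  rohArgs <- config$roh %||% list()
  params <- rohParams(
    minLengthBp = (rohArgs$min_length_kb %||% 1000) * 1000,
    minSnps = rohArgs$min_snps %||% 15L,
    maxDensityBpPerSnp = (rohArgs$density_kb %||% 100) * 1000,
    maxHet = rohArgs$max_het %||% 1L,
    maxGapBp = (rohArgs$max_gap_kb %||% 500) * 1000)
  segs <- stage("roh", detectRoh(geno, params))
  writeRohTsv(segs, file.path(outDir, "roh.tsv"))

  itab <- stage("inbreeding", inbreedingTable(geno, segs))
  writeInbreedingTsv(itab, file.path(outDir, "inbreeding.tsv"))

  grm <- stage("grm", buildGrm(genoQc))
  fr <- setNames(itab$f_roh, itab$sample_id)
  base <- stage("fit", fitAnimalModel(ph, grm))
  writeFitTsv <- function(fit, tag) {
    utils::write.table(coefTable(fit),
                       file.path(outDir, paste0("fit_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(
      list(varcomp = as.list(varComp(fit)),
           h2_r = as.list(heritabilityRepeatability(fit)),
           loglik = restrictedLogLik(fit), converged = isConverged(fit),
           iterations = fit@iterations),
      file.path(outDir, paste0("varcomp_", tag, ".yaml")))
  }
  writeFitTsv(base, "base")
  if (1 %in% models)
    writeFitTsv(stage("fit", fitAnimalModel(ph, grm, inbreeding = fr)),
                "model1")
  if (2 %in% models) {
    cls <- as.matrix(itab[, paste0("f_", ROH_CLASSES)])
    rownames(cls) <- itab$sample_id
    writeFitTsv(stage("fit", fitRohClassModel(ph, grm, cls)), "model2")
  }
  if (3 %in% models) {
    scanArgs <- config$scan %||% list()
    states <- stage("scan",
                    rohStateMatrix(segs, markerMap(geno), sampleIds(geno)))
    sc <- stage("scan", runScan(ph, grm, geno, states, base))
    utils::write.table(sc, file.path(outDir, "scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    man <- data.frame(chrom = sc$chrom, pos_bp = sc$pos_bp,
                      minus_log10_p = -log10(sc$p_roh))
    utils::write.table(man, file.path(outDir, "manhattan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cand <- scanArgs$p_thresholds %||% c(1e-5, 1e-4, 1e-3)
    thr <- tryCatch(suppressWarnings(minFdrThreshold(sc, cand)),
                    error = function(e) NULL)
    pThr <- if (is.null(thr)) min(cand) else thr$p_threshold
    genes <- if (!is.null(scanArgs$genes_bed))
      readGeneBed(scanArgs$genes_bed) else NULL
    reg <- stage("scan", callRegions(
      sc, pThr, mergeGapBp = scanArgs$merge_gap_bp %||% 1e6,
      genes = genes))
    regDf <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(reg)),
      start_bp = GenomicRanges::start(reg),
      end_bp = GenomicRanges::end(reg),
      n_significant_snps = S4Vectors::mcols(reg)$n_significant_snps,
      min_p = S4Vectors::mcols(reg)$min_p)
    if (!is.null(genes)) regDf$genes <- S4Vectors::mcols(reg)$genes
    utils::write.table(regDf, file.path(outDir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(p_threshold = pThr,
                          fdr = if (is.null(thr)) NA else thr$fdr),
                     file.path(outDir, "fdr.yaml"))
  }

  manifest <- list(
    package = "rohdep",
    version = as.character(utils::packageVersion("rohdep")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    date = format(Sys.time(), "%Y-%m-%d"),
    config = rapply(config, as.vector, how = "replace"),
    n_records = nrow(ph), n_bulls = length(unique(ph$bull_id)),
    n_markers = nMarkers(geno), n_markers_qc = nMarkers(genoQc),
    n_roh_segments = length(segs))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
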