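#' Run the full analysis pipeline
#'
#' Chains the stages -- optional read simulation, junction counting,
#' classification, QC, ratio computation, optional profile rendering and
#' group comparison -- writing each stage's table into `outdir` and
#' echoing the effective configuration to `run_config.json`. The panel is
#' loaded and validated before any read is touched; stage errors
#' propagate with the stage name.
#'
#' @param panel a [ProbePanel-class] or a manifest path.
#' @param fastq FASTQ path (ignored when `simSamples` is given).
#' @param outdir output directory.
#' @param simSamples optional list of [sampleSpec()]; reads are simulated
#'   into `outdir/reads.fastq.gz` with ground truth in `truth.tsv`.
#' @param metadata optional sample metadata (data.frame or TSV path with
#'   a `sample` column and group labels) enabling the cohort stage.
#' @param seed seed for simulation (mandatory when simulating).
#' @param qcThreshold,qcMode see [sampleQC()].
#' @param maxMismatchBarcode,maxMismatchProbe see [countReads()].
#' @param errorRate,readsPerMolecule see [simulateReads()].
#' @param grouping,variant see [compareGroups()].
#' @param renderProfiles render one SVG per QC-passing sample and gene.
#' @param displayThreshold see [renderProfile()].
#' @return invisibly, a list with the stage tables and output paths.
#' @export
runPipeline <- function(panel, fastq = NULL, outdir, simSamples = NULL,
                        metadata = NULL, seed = NULL, qcThreshold = 1500L,
                        qcMode = "combined", maxMismatchBarcode = 1L,
                        maxMismatchProbe = 2L, errorRate = 0,
                        readsPerMolecule = 3L, grouping = "tissue",
                        variant = "welch", renderProfiles = FALSE,
                        displayThreshold = 0.001) {
  stage <- "panel"
  wrap <- function(expr) tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  pan <- wrap(if (is.character(panel)) loadPanel(panel) else panel)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    write.table(df, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    file.path(outdir, f)
  }

  cfg <- list(qc_threshold = qcThreshold, qc_mode = qcMode,
              max_mismatch_barcode = maxMismatchBarcode,
              max_mismatch_probe = maxMismatchProbe,
              error_rate = errorRate, reads_per_molecule = readsPerMolecule,
              grouping = grouping, test_variant = variant, seed = seed,
              display_threshold = displayThreshold)
  jsonlite::write_json(cfg, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, null = "null")

  if (!is.null(simSamples)) {
    stage <- "simulate"
    if (is.null(seed)) stopf("stage 'simulate' failed: a seed is mandatory")
    sim <- wrap(simulateReads(pan, simSamples, seed = seed,
                              errorRate = errorRate,
                              readsPerMolecule = readsPerMolecule,
                              out = file.path(outdir, "reads.fastq.gz")))
    wr(sim$truth, "truth.tsv")
    fastq <- sim$fastq
  }
  if (is.null(fastq)) stopf("stage 'count' failed: no FASTQ input")

  stage <- "count"
  counts <- wrap(countReads(fastq, pan, maxMismatchBarcode,
                            maxMismatchProbe))
  wr(counts, "counts.tsv")
  wr(attr(counts, "stats"), "unassigned_stats.tsv")

  stage <- "classify"
  classified <- wrap(classifyJunctions(counts, pan))
  wr(classified, "classified.tsv")

  stage <- "qc"
  qc <- wrap(sampleQC(classified, qcThreshold, qcMode))
  wr(qc, "qc.tsv")

  stage <- "ratios"
  ratios <- wrap(ratioTable(classified, pan))
  wr(ratios, "ratios.tsv")

  profiles <- character(0)
  if (renderProfiles) {
    stage <- "profiles"
    for (s in qc$sample[qc$pass]) for (g in pan@genes) {
      f <- file.path(outdir, sprintf("profile_%s_%s.svg", s, g))
      wrap(renderProfile(classified, pan, s, g, out = f,
                         displayThreshold = displayThreshold))
      profiles <- c(profiles, f)
    }
  }

  cohort <- NULL
  if (!is.null(metadata)) {
    stage <- "cohort"
    md <- wrap(if (is.character(metadata))
      read.delim(metadata, stringsAsFactors = FALSE) else metadata)
    tab <- wrap(buildCohortTable(ratios, md, qc))
    stats <- lapply(pan@genes, function(g)
      tryCatch({
        r <- compareGroups(tab, g, grouping, variant)
        data.frame(gene = g, group1 = r$groups[1], group2 = r$groups[2],
                   mean1 = r$means[1], mean2 = r$means[2], n1 = r$n[1],
                   n2 = r$n[2], t = r$t, df = r$df, p_value = r$p_value,
                   variant = r$variant)
      }, error = function(e) NULL))
    cohort <- do.call(rbind, stats)
    if (!is.null(cohort)) wr(cohort, "cohort_stats.tsv")
  }

  invisible(list(panel = pan, counts = counts, classified = classified,
                 qc = qc, ratios = ratios, cohort = cohort,
                 profiles = profiles, outdir = outdir))
}
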