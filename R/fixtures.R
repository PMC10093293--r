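#' The packaged BRCA1/BRCA2 probe panel
#'
#' Loads the panel fixture shipped with the package: 114 junction probes
#' at the exon boundaries of BRCA1 (legacy exon numbering, no exon 4;
#' alternative boundaries 5q, 8p, 11q, 13p, 14q) and BRCA2 (alternative
#' boundaries 3q, 6q, 12p, 20q), 30 SNP-allele probes (10 SNPs, two
#' allele-specific probes plus one shared partner each) and 3 intronic
#' BRCA1 control probes. Probe and barcode sequences are synthetic
#' placeholders; the design composition is the assay's.
#'
#' @return a [ProbePanel-class].
#' @export
referencePanel <- function() {
  loadPanel(system.file("extdata", "brca_panel", "manifest.yaml",
                        package = "circLigate", mustWork = TRUE))
}

#' Curated circRNA repertoire reference tables
#'
#' The published repertoire of BRCA1/BRCA2 backsplice junctions in normal
#' and tumor breast tissue shipped as a long-format table: per junction
#' and tissue, the relative proportion among the gene's circRNAs, the
#' detection frequency (percent, detected-sample count, group size), the
#' circRNA/mRNA ratio, and the known/novel status. On load every
#' frequency cell is checked against `100 * count / n` (half-up, 2
#' decimals); an inconsistent transcription aborts.
#'
#' @return data.frame with columns `gene`, `name`, `donor`, `acceptor`,
#'   `status`, `section` (`top`/`novel`), `tissue`, `rel_prop_pct`,
#'   `freq_pct`, `freq_count`, `n_group`, `ratio_pct`.
#' @export
referenceCircTables <- function() {
  f <- system.file("extdata", "annotations", "circ_reference.tsv",
                   package = "circLigate", mustWork = TRUE)
  tab <- read.delim(f, stringsAsFactors = FALSE,
                    colClasses = c(donor = "character",
                                   acceptor = "character"))
  chk <- abs(tab$freq_pct - roundHalfUp(100 * tab$freq_count / tab$n_group, 2))
  if (any(chk > 1e-9))
    stopf("reference table inconsistency: frequency cell %s/%s does not equal count/n",
          tab$name[chk > 1e-9][1], tab$tissue[chk > 1e-9][1])
  tab
}

#' QC pass-count reference table
#'
#' Samples passing the 1500-UMI quality threshold per cohort and tissue
#' type, with the originally printed percentages. A `computed_pct` column
#' gives `100 * passed / total` and `printed_matches` flags whether the
#' printed cell equals the recomputed value at 0-2 decimal precision (two
#' printed cells in the source material do not).
#'
#' @return data.frame `cohort`, `tissue_type`, `passed`, `total`,
#'   `printed_pct`, `computed_pct`, `printed_matches`.
#' @export
qcPassCounts <- function() {
  f <- system.file("extdata", "annotations", "qc_pass_counts.tsv",
                   package = "circLigate", mustWork = TRUE)
  tab <- read.delim(f, stringsAsFactors = FALSE)
  tab$computed_pct <- 100 * tab$passed / tab$total
  tab$printed_matches <- vapply(seq_len(nrow(tab)), function(i)
    any(vapply(0:2, function(d)
      isTRUE(all.equal(tab$printed_pct[i],
                       roundHalfUp(tab$computed_pct[i], d))), logical(1))),
    logical(1))
  tab
}

#' Build a cohort-scale simulation scenario
#'
#' Emits a normal/tumor cohort scenario at the molecule-count level: per
#' sample and gene, each canonical linear junction carries
#' `linearJunctionMolecules / n_canonical` molecules, and backsplice
#' molecules are allocated over the gene's reference circRNA repertoire
#' (top-represented junctions, normal-tissue relative proportions as
#' weights) so that the sample's true overall circRNA/mRNA ratio is drawn
#' around the group mean. Defaults mirror a breast cohort: 38 normal vs
#' 90 tumor samples, BRCA1 means 1.89 vs 1.14 per 100 linear junctions,
#' BRCA2 means 0.51 vs 0.23, between-sample SD 0.5 for BRCA1 and scaled
#' proportionally for BRCA2.
#'
#' @param seed integer seed.
#' @param nNormal,nTumor group sizes.
#' @param linearJunctionMolecules total linear junction molecules per
#'   sample and gene (default 1e5).
#' @param means named list, gene -> c(normal=, tumor=) true mean ratios
#'   (per 100).
#' @param sds named numeric, gene -> between-sample SD of the true ratio.
#' @return list of class `CohortScenario` with `samples` (sample, tissue),
#'   `truth` (sample, gene, truth ratio per 100, realized from molecule
#'   counts), `molecules` (input for [simulateCounts()]).
#' @export
buildCohortScenario <- function(seed, nNormal = 38L, nTumor = 90L,
                                linearJunctionMolecules = 1e5,
                                means = list(BRCA1 = c(normal = 1.89,
                                                       tumor = 1.14),
                                             BRCA2 = c(normal = 0.51,
                                                       tumor = 0.23)),
                                sds = c(BRCA1 = 0.5,
                                        BRCA2 = 0.5 * 0.51 / 1.89)) {
  if (missing(seed)) stopf("a seed is mandatory")
  panel <- referencePanel()
  tab <- referenceCircTables()
  withSeed(seed, {
    samples <- data.frame(
      sample = sprintf("%s%03d", rep(c("N", "T"), c(nNormal, nTumor)),
                       c(seq_len(nNormal), seq_len(nTumor))),
      tissue = rep(c("normal", "tumor"), c(nNormal, nTumor)))
    mol <- list()
    truth <- list()
    for (g in names(means)) {
      cj <- panel@canonicalJunctions
      cj <- cj[cj$gene == g, , drop = FALSE]
      nCanon <- nrow(cj)
      mPerJ <- round(linearJunctionMolecules / nCanon)
      L <- mPerJ * nCanon
      rep_ <- tab[tab$gene == g & tab$section == "top" &
                    tab$tissue == "normal", , drop = FALSE]
      w <- rep_$rel_prop_pct / sum(rep_$rel_prop_pct)
      for (i in seq_len(nrow(samples))) {
        s <- samples$sample[i]
        mu <- means[[g]][[samples$tissue[i]]]
        r <- max(0.02, rnorm(1, mu, sds[[g]]))
        circTotal <- round(r / 100 * L)
        circM <- as.integer(stats::rmultinom(1, circTotal, w))
        keep <- circM > 0
        mol[[length(mol) + 1L]] <- rbind(
          data.frame(sample = s, gene = g, donor = cj$donor,
                     acceptor = cj$acceptor, class = "linear_canonical",
                     name = junctionName(panel, g, cj$donor, cj$acceptor,
                                         "linear"),
                     molecules = mPerJ),
          if (any(keep)) data.frame(sample = s, gene = g,
                     donor = rep_$donor[keep], acceptor = rep_$acceptor[keep],
                     class = "backsplice", name = rep_$name[keep],
                     molecules = circM[keep]))
        truth[[length(truth) + 1L]] <- data.frame(
          sample = s, gene = g, tissue = samples$tissue[i],
          truth_ratio = 100 * sum(circM) / L)
      }
    }
    structure(list(samples = samples,
                   truth = do.call(rbind, truth),
                   molecules = do.call(rbind, mol)),
              class = "CohortScenario")
  })
}

#' Per-sample overall ratios from a junction count table
#'
#' Vectorised computation of the gene-wide circRNA/mRNA ratio (per 100
#' linear junctions) for every (sample, gene) in a classified count
#' table, optionally on saturation-corrected counts.
#'
#' @param counts data.frame with `sample`, `gene`, `class`, `umi_count`.
#' @param correctSaturation use [correctSaturation()] estimates.
#' @param umiSpace UMI space size.
#' @return data.frame `sample`, `gene`, `overall_ratio_pct`.
#' @export
cohortRatios <- function(counts, correctSaturation = FALSE,
                         umiSpace = 16384L) {
  u <- as.numeric(counts$umi_count)
  if (correctSaturation) u <- circLigate::correctSaturation(u, umiSpace)
  key <- paste(counts$sample, counts$gene, sep = "\r")
  lin <- tapply(u * (counts$class %in% c("linear_canonical",
                                         "linear_alternative")), key, sum)
  circ <- tapply(u * (counts$class == "backsplice"), key, sum)
  parts <- do.call(rbind, strsplit(names(lin), "\r", fixed = TRUE))
  out <- data.frame(sample = parts[, 1], gene = parts[, 2],
                    overall_ratio_pct = 100 * as.numeric(circ) /
                      as.numeric(lin))
  rownames(out) <- NULL
  out
}
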