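#' Per-sample quality control on UMI totals
#'
#' A sample is interpretable when enough distinct molecules were counted:
#' by default the combined distinct-UMI total across the panel's target
#' genes must reach `threshold` (default 1500, the depth at which
#' alternative transcripts above 1\% remain detectable); mode
#' `"per-gene"` requires every gene to reach the threshold individually.
#' The DNA contamination fraction is the share of intronic-control UMIs in
#' the sample's total.
#'
#' @param classified output of [classifyJunctions()] (any number of
#'   samples).
#' @param threshold minimal distinct-UMI total (default 1500).
#' @param mode `"combined"` (default) or `"per-gene"`.
#' @return data.frame with one row per sample: per-gene UMI totals (wide
#'   columns `umi_<gene>`), `umi_total`, `contamination_fraction`, `pass`.
#' @export
sampleQC <- function(classified, threshold = 1500L,
                     mode = c("combined", "per-gene")) {
  mode <- match.arg(mode)
  cl <- classified
  samples <- unique(cl$sample)
  genes <- sort(unique(cl$gene[!is.na(cl$gene)]))
  rows <- lapply(samples, function(s) {
    sub <- cl[cl$sample == s, , drop = FALSE]
    junc <- sub$class %in% c("linear_canonical", "linear_alternative",
                             "backsplice")
    perGene <- vapply(genes, function(g)
      sum(sub$umi_count[junc & !is.na(sub$gene) & sub$gene == g]),
      numeric(1))
    total <- sum(perGene)
    allUmi <- sum(sub$umi_count)
    contam <- if (allUmi > 0)
      sum(sub$umi_count[sub$class == "intronic_control"]) / allUmi else 0
    pass <- if (mode == "combined") total >= threshold
            else all(perGene >= threshold)
    out <- data.frame(sample = s, umi_total = total,
                      contamination_fraction = contam, pass = pass)
    for (g in genes) out[[paste0("umi_", g)]] <- perGene[[g]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Linear/circular UMI sums for one sample and gene.
.gsums <- function(classified, sample, gene) {
  sub <- classified[classified$sample == sample &
                      !is.na(classified$gene) & classified$gene == gene, ,
                    drop = FALSE]
  list(sub = sub,
       linear = sum(sub$umi_count[sub$class %in%
                      c("linear_canonical", "linear_alternative")]),
       circ = sub[sub$class == "backsplice", , drop = FALSE])
}

#' Relative proportion of each circRNA of a gene
#'
#' Each backsplice junction's distinct-UMI count divided by the sum over
#' every backsplice junction of the gene in that sample.
#'
#' @param classified output of [classifyJunctions()].
#' @param sample,gene which sample and gene.
#' @return named numeric vector (junction name -> proportion, summing to
#'   1); empty with a `note` attribute when the gene has no circular UMIs.
#' @export
relativeProportions <- function(classified, sample, gene) {
  g <- .gsums(classified, sample, gene)
  circ <- g$circ
  tot <- sum(circ$umi_count)
  if (tot == 0) {
    out <- setNames(numeric(0), character(0))
    attr(out, "note") <- sprintf("no circular UMIs for %s in %s", gene, sample)
    return(out)
  }
  setNames(circ$umi_count / tot, circ$name)
}

#' Per-circRNA circRNA/mRNA ratio (percent)
#'
#' The junction-level ratio compares one backsplice junction to the
#' *average* linear junction of its gene:
#' `100 * UMI(circ junction) / (sum UMI over all linear junctions /
#' number of linear canonical junctions)`. The linear sum includes
#' alternative linear junctions; the divisor is the count of canonical
#' junction pairs of the gene in the panel. Within one sample the ratio is
#' proportional to the relative proportion, with a gene-wide constant.
#'
#' @param classified output of [classifyJunctions()].
#' @param panel a [ProbePanel-class].
#' @param sample,gene which sample and gene.
#' @param junction optional junction name(s) (e.g. `"BRCA1_circRNA_20-18"`)
#'   or `NULL` for all backsplices of the gene.
#' @param correctSaturation replace distinct-UMI counts by their
#'   saturation-corrected molecule estimates (see [correctSaturation()]).
#' @param umiSpace UMI space size for the correction.
#' @return named numeric vector of percentages.
#' @export
junctionCircRatio <- function(classified, panel, sample, gene,
                              junction = NULL, correctSaturation = FALSE,
                              umiSpace = 16384L) {
  g <- .gsums(classified, sample, gene)
  nCanon <- sum(panel@canonicalJunctions$gene == gene)
  if (nCanon == 0) stopf("gene %s has no canonical junctions in the panel", gene)
  lin <- g$linear
  circ <- setNames(as.numeric(g$circ$umi_count), g$circ$name)
  if (correctSaturation) {
    linU <- g$sub$umi_count[g$sub$class %in%
                              c("linear_canonical", "linear_alternative")]
    lin <- sum(circLigate::correctSaturation(linU, umiSpace))
    circ[] <- circLigate::correctSaturation(circ, umiSpace)
  }
  if (lin <= 0) stopf("no mRNA signal: zero linear UMIs for %s in %s",
                      gene, sample)
  if (!is.null(junction)) {
    circ <- circ[junction]
    circ[is.na(circ)] <- 0
    names(circ) <- junction
  }
  100 * circ / (lin / nCanon)
}

#' Gene-wide circRNA/mRNA ratio (per 100 linear junctions)
#'
#' `100 * sum(backsplice UMIs) / sum(linear UMIs)` for one sample and
#' gene: how many circular junction molecules are observed per 100 linear
#' junction molecules.
#'
#' @inheritParams junctionCircRatio
#' @return a single percentage.
#' @export
geneCircRatio <- function(classified, sample, gene,
                          correctSaturation = FALSE, umiSpace = 16384L) {
  g <- .gsums(classified, sample, gene)
  lin <- g$linear
  circ <- sum(g$circ$umi_count)
  if (correctSaturation) {
    linU <- g$sub$umi_count[g$sub$class %in%
                              c("linear_canonical", "linear_alternative")]
    lin <- sum(circLigate::correctSaturation(linU, umiSpace))
    circ <- sum(circLigate::correctSaturation(g$circ$umi_count, umiSpace))
  }
  if (lin <= 0) stopf("no mRNA signal: zero linear UMIs for %s in %s",
                      gene, sample)
  100 * circ / lin
}

#' Ratio table for all samples and genes
#'
#' Convenience wrapper building a long table of per-junction relative
#' proportions and ratios plus the per-gene overall ratio.
#'
#' @inheritParams junctionCircRatio
#' @return data.frame `sample`, `gene`, `name`, `umi_count`,
#'   `relative_proportion`, `ratio_junction_pct`, `overall_ratio_pct`,
#'   `n_canonical`.
#' @export
ratioTable <- function(classified, panel, correctSaturation = FALSE,
                       umiSpace = 16384L) {
  rows <- list()
  cl <- classified[!is.na(classified$gene), , drop = FALSE]
  for (s in unique(cl$sample)) for (g in unique(cl$gene[cl$sample == s])) {
    sub <- cl[cl$sample == s & cl$gene == g, , drop = FALSE]
    if (!any(sub$class %in% c("linear_canonical", "linear_alternative")))
      next
    ov <- geneCircRatio(cl, s, g, correctSaturation, umiSpace)
    circ <- sub[sub$class == "backsplice", , drop = FALSE]
    if (!nrow(circ)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = g, name = NA_character_, umi_count = 0L,
        relative_proportion = NA_real_, ratio_junction_pct = NA_real_,
        overall_ratio_pct = ov,
        n_canonical = sum(panel@canonicalJunctions$gene == g))
      next
    }
    rp <- relativeProportions(cl, s, g)
    rj <- junctionCircRatio(cl, panel, s, g, correctSaturation =
                              correctSaturation, umiSpace = umiSpace)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, gene = g, name = circ$name, umi_count = circ$umi_count,
      relative_proportion = as.numeric(rp[circ$name]),
      ratio_junction_pct = as.numeric(rj[circ$name]),
      overall_ratio_pct = ov,
      n_canonical = sum(panel@canonicalJunctions$gene == g))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection frequency of a junction across a sample group
#'
#' A junction counts as detected in a sample when its distinct-UMI count
#' reaches `presenceThreshold` (default 1). The percentage is rounded half
#' away from zero to two decimals, matching printed-table arithmetic.
#'
#' @param classified output of [classifyJunctions()] for a cohort
#'   (QC-passing samples).
#' @param name junction name (as in the `name` column).
#' @param samples character vector defining the group.
#' @param presenceThreshold minimal UMI count for a presence call.
#' @return list with `count` and `percent`.
#' @export
detectionFrequency <- function(classified, name, samples,
                               presenceThreshold = 1L) {
  if (!length(samples)) stopf("empty sample group")
  hit <- classified[!is.na(classified$name) & classified$name == name &
                      classified$umi_count >= presenceThreshold, ,
                    drop = FALSE]
  count <- length(intersect(samples, hit$sample))
  list(count = count,
       percent = roundHalfUp(100 * count / length(samples), 2))
}

#' Allelic imbalance at an assayed SNP
#'
#' Compares the distinct-UMI counts of the two allele-specific probes of a
#' SNP with an exact two-sided binomial test against 0.5. The sample is
#' flagged imbalanced when p < 0.01 *and* the allele fraction falls
#' outside `[0.3, 0.7]` -- imbalance here is an indirect readout of allele
#' loss or nonsense-mediated decay, so a frank deviation is required, not
#' mere statistical detectability. Fewer than 20 informative UMIs yield
#' status `insufficient`.
#'
#' @param classified output of [classifyJunctions()].
#' @param panel a [ProbePanel-class].
#' @param sample sample name.
#' @param snpId SNP identifier.
#' @return list `snp_id`, `a`, `b` (UMI counts of the alphabetically first
#'   and second allele), `fraction`, `p_value`, `imbalanced`, `status`.
#' @export
alleleBalance <- function(classified, panel, sample, snpId) {
  pr <- panel@probes
  al <- pr[pr$kind == "snp_allele" & !is.na(pr$snp_id) & pr$snp_id == snpId &
             !is.na(pr$allele), , drop = FALSE]
  if (nrow(al) != 2L) stopf("unknown snp_id '%s'", snpId)
  al <- al[order(al$allele), ]
  sub <- classified[classified$sample == sample &
                      classified$class == "snp_allele", , drop = FALSE]
  cnt <- function(pid) sum(sub$umi_count[sub$left_probe_id == pid |
                                           sub$right_probe_id == pid])
  a <- cnt(al$probe_id[1])
  b <- cnt(al$probe_id[2])
  n <- a + b
  if (n < 20L)
    return(list(snp_id = snpId, a = a, b = b, fraction = NA_real_,
                p_value = NA_real_, imbalanced = NA, status = "insufficient"))
  p <- stats::binom.test(a, n, p = 0.5, alternative = "two.sided")$p.value
  frac <- a / n
  list(snp_id = snpId, a = a, b = b, fraction = frac, p_value = p,
       imbalanced = p < 0.01 && (frac < 0.3 || frac > 0.7), status = "ok")
}
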