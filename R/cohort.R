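#' Assemble a cohort ratio table
#'
#' Joins per-sample gene-wide circRNA/mRNA ratios with sample metadata and
#' restricts to QC-passing samples.
#'
#' @param ratios data.frame with at least `sample`, `gene`,
#'   `overall_ratio_pct` (e.g. unique rows of [ratioTable()]).
#' @param metadata data.frame with `sample` plus group labels such as
#'   `tissue` (normal/tumor), `subtype`, `grade`, `pair_id`.
#' @param qc optional output of [sampleQC()]; only samples with
#'   `pass == TRUE` are kept.
#' @return merged data.frame, one row per (sample, gene).
#' @export
buildCohortTable <- function(ratios, metadata, qc = NULL) {
  r <- unique(ratios[, c("sample", "gene", "overall_ratio_pct")])
  if (!is.null(qc)) r <- r[r$sample %in% qc$sample[qc$pass], , drop = FALSE]
  merge(r, metadata, by = "sample")
}

#' Compare gene-wide circRNA/mRNA ratios between groups
#'
#' Two-sided two-sample t-test of the per-100 overall ratios between the
#' two levels of a grouping variable. The default is the Welch test
#' (group sizes and variances typically differ between e.g. normal and
#' tumor tissue); `variant = "pooled"` gives the classical equal-variance
#' Student test.
#'
#' @param table output of [buildCohortTable()] (or any data.frame with
#'   `gene`, `overall_ratio_pct` and the grouping column).
#' @param gene gene to test.
#' @param grouping name of the grouping column (default `"tissue"`).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param levels optional two group levels (otherwise the sorted unique
#'   values are used).
#' @return list with `groups`, `means`, `n`, `t`, `df`, `p_value`,
#'   `variant`. Degenerate groups (n < 2 or zero variance in both) raise
#'   an error rather than returning NaN.
#' @examples
#' tab <- data.frame(gene = "G",
#'                   overall_ratio_pct = c(1, 2, 3, 4, 5, 6),
#'                   tissue = rep(c("normal", "tumor"), each = 3))
#' compareGroups(tab, "G", variant = "pooled")$t  # -3.674
#' @export
compareGroups <- function(table, gene, grouping = "tissue",
                          variant = c("welch", "pooled"), levels = NULL) {
  variant <- match.arg(variant)
  sub <- table[table$gene == gene & is.finite(table$overall_ratio_pct), ,
               drop = FALSE]
  gv <- as.character(sub[[grouping]])
  if (is.null(levels)) levels <- sort(unique(gv[!is.na(gv)]))
  if (length(levels) != 2L)
    stopf("grouping '%s' must have exactly 2 levels (got %d)", grouping,
          length(levels))
  x <- sub$overall_ratio_pct[gv %in% levels[1]]
  y <- sub$overall_ratio_pct[gv %in% levels[2]]
  if (length(x) < 2L || length(y) < 2L)
    stopf("degenerate group: fewer than 2 samples in a '%s' level", grouping)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stopf("degenerate group: zero variance in both groups")
  tt <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(groups = levels, means = setNames(c(mean(x), mean(y)), levels),
       n = setNames(c(length(x), length(y)), levels),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, variant = variant)
}
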