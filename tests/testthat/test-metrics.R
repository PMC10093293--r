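mkClassified <- function(gene = "G", sample = "S", linCanon = integer(0),
                         linAlt = integer(0), circ = integer(0),
                         intron = integer(0)) {
  n <- length(linCanon) + length(linAlt) + length(circ) + length(intron)
  data.frame(
    sample = sample, gene = gene,
    left_probe_id = sprintf("L%d", seq_len(n)),
    right_probe_id = sprintf("R%d", seq_len(n)),
    donor = as.character(seq_len(n)), acceptor = as.character(seq_len(n)),
    class = rep(c("linear_canonical", "linear_alternative", "backsplice",
                  "intronic_control"),
                c(length(linCanon), length(linAlt), length(circ),
                  length(intron))),
    name = paste0(gene, "_j", seq_len(n)),
    umi_count = c(linCanon, linAlt, circ, intron),
    read_count = 3L * c(linCanon, linAlt, circ, intron))
}

test_that("QC threshold modes behave as specified", {
  cl <- rbind(mkClassified("BRCA1", linCanon = rep(100L, 10)),
              mkClassified("BRCA2", linCanon = rep(100L, 6)))
  qcC <- sampleQC(cl)                      # 1000 + 600 = 1600 >= 1500
  expect_true(qcC$pass)
  qcP <- sampleQC(cl, mode = "per-gene")   # 600 < 1500
  expect_false(qcP$pass)
  expect_equal(qcC$umi_BRCA1, 1000)
  expect_equal(qcC$umi_BRCA2, 600)
})

test_that("contamination fraction is the intronic share of all UMIs", {
  cl <- mkClassified(linCanon = c(90L), intron = c(10L))
  expect_equal(sampleQC(cl, threshold = 10)$contamination_fraction, 0.1)
})

test_that("QC pass-rate arithmetic reproduces the cohort pass rates", {
  qc <- qcPassCounts()
  res <- qc[qc$cohort == "research", ]
  tum <- res[res$tissue_type == "breast_tumor", ]
  expect_equal(roundHalfUp(100 * tum$passed / tum$total, 1), 94.7)
  nor <- res[res$tissue_type == "breast_normal", ]
  expect_equal(roundHalfUp(100 * nor$passed / nor$total, 1), 40)
})

test_that("relative proportions partition the circular UMI pool", {
  cl <- mkClassified(linCanon = rep(100L, 4), circ = c(50L, 50L))
  rp <- relativeProportions(cl, "S", "G")
  expect_equal(unname(rp), c(0.5, 0.5))
  expect_equal(sum(rp), 1)
  one <- relativeProportions(mkClassified(linCanon = 10L, circ = 7L),
                             "S", "G")
  expect_equal(unname(one), 1)
  none <- relativeProportions(mkClassified(linCanon = 10L), "S", "G")
  expect_length(none, 0)
  expect_match(attr(none, "note"), "no circular UMIs")
})

test_that("per-junction ratio implements the average-linear-junction formula", {
  p <- toyPanel(21)   # 20 canonical junctions
  cl <- mkClassified(linCanon = rep(50L, 20), circ = 5L)
  r <- junctionCircRatio(cl, p, "S", "G")
  expect_equal(unname(r), 100 * 5 / (1000 / 20))  # = 10
  expect_equal(unname(junctionCircRatio(cl, p, "S", "G",
                                        junction = "absent")), 0)
  noLin <- mkClassified(circ = 5L)
  expect_error(junctionCircRatio(noLin, p, "S", "G"), "no mRNA signal")
})

test_that("gene-wide ratio is circular per 100 linear UMIs", {
  cl <- mkClassified(linCanon = rep(250L, 4), circ = 15L)
  expect_equal(geneCircRatio(cl, "S", "G"), 1.5)
  expect_equal(geneCircRatio(mkClassified(linCanon = rep(10L, 3)), "S", "G"),
               0)
})

test_that("junction ratios are proportional to relative proportions", {
  p <- toyPanel(11)
  set.seed(5)
  cl <- mkClassified(linCanon = sample(50:200, 10), linAlt = c(20L, 9L),
                     circ = sample(1:40, 6))
  rj <- junctionCircRatio(cl, p, "S", "G")
  rp <- relativeProportions(cl, "S", "G")
  k <- rj / rp[names(rj)]
  expect_lt(max(k) - min(k), 1e-9)
  # aggregate identity: sum(ratio_j) * (linear / n_canonical) = 100 * circ
  lin <- sum(cl$umi_count[cl$class %in% c("linear_canonical",
                                          "linear_alternative")])
  expect_equal(sum(rj) * lin / 10, 100 * sum(cl$umi_count[cl$class ==
                                                            "backsplice"]),
               tolerance = 1e-9)
})

test_that("the overall ratio is monotone in both UMI pools", {
  base <- mkClassified(linCanon = rep(100L, 5), circ = c(10L, 5L))
  r0 <- geneCircRatio(base, "S", "G")
  moreCirc <- base; moreCirc$umi_count[6] <- 20L
  expect_gt(geneCircRatio(moreCirc, "S", "G"), r0)
  moreLin <- base; moreLin$umi_count[1] <- 200L
  expect_lt(geneCircRatio(moreLin, "S", "G"), r0)
})

test_that("detection frequencies reproduce every reference-table cell", {
  tab <- referenceCircTables()
  for (i in seq_len(nrow(tab))) {
    n <- tab$n_group[i]
    k <- tab$freq_count[i]
    samples <- sprintf("X%03d", seq_len(n))
    cl <- data.frame(sample = samples[seq_len(max(k, 1))][seq_len(k)],
                     name = tab$name[i], umi_count = 1L)
    got <- detectionFrequency(cl, tab$name[i], samples)
    expect_equal(got$count, k)
    expect_equal(got$percent, tab$freq_pct[i])
  }
  expect_equal(detectionFrequency(
    data.frame(sample = "a", name = "x", umi_count = 0L), "x",
    sprintf("X%d", 1:10))$percent, 0)
  expect_error(detectionFrequency(
    data.frame(sample = "a", name = "x", umi_count = 1L), "x",
    character(0)), "empty sample group")
})

test_that("allelic imbalance combines an exact binomial test with an effect floor", {
  p <- toyPanel(3, withExtras = TRUE)
  mk <- function(a, b) data.frame(
    sample = "S", left_probe_id = c("G_snp01_A", "G_snp01_G"),
    right_probe_id = "G_snp01_P", class = "snp_allele",
    umi_count = c(a, b))
  bal <- alleleBalance(mk(50L, 50L), p, "S", "snp01")
  expect_equal(bal$fraction, 0.5)
  expect_equal(bal$p_value, 1)
  expect_false(bal$imbalanced)

  imb <- alleleBalance(mk(95L, 5L), p, "S", "snp01")
  # independent oracle: direct summation of the symmetric binomial tails
  pOracle <- 2 * sum(choose(100, 95:100)) / 2^100
  expect_equal(imb$p_value, pOracle, tolerance = 1e-12)
  expect_true(imb$imbalanced)

  few <- alleleBalance(mk(9L, 5L), p, "S", "snp01")
  expect_equal(few$status, "insufficient")
  expect_error(alleleBalance(mk(5L, 5L), p, "S", "nope"), "unknown snp_id")
})

test_that("simulated allele loss is flagged and a balanced sample is not", {
  p <- toyPanel(3, withExtras = TRUE,
                barcodes = c(T = "AAAAAAAA", N = "CCCCGGGG"))
  specs <- list(
    sampleSpec("T", "AAAAAAAA", list(G = list(linear = 10)),
               snpFractions = c(snp01 = 0.9), snpMolecules = 200),
    sampleSpec("N", "CCCCGGGG", list(G = list(linear = 10)),
               snpFractions = c(snp01 = 0.5), snpMolecules = 200))
  sim <- simulateReads(p, specs, seed = 23)
  cl <- classifyJunctions(countReads(sim, p), p)
  expect_true(alleleBalance(cl, p, "T", "snp01")$imbalanced)
  expect_false(alleleBalance(cl, p, "N", "snp01")$imbalanced)
})

test_that("saturation-corrected ratios recover molecule-level truth", {
  p <- referencePanel()
  cj <- canonicalJunctions(p)
  for (truthRatio in c(0.5, 1.89)) {
    ests <- vapply(1:5, function(s) {
      cjg <- cj[cj$gene == "BRCA1", ]
      mPer <- round(1e5 / nrow(cjg))
      L <- mPer * nrow(cjg)
      circTotal <- round(truthRatio / 100 * L)
      mol <- rbind(
        data.frame(sample = "S", gene = "BRCA1", donor = cjg$donor,
                   acceptor = cjg$acceptor, class = "linear_canonical",
                   molecules = mPer),
        data.frame(sample = "S", gene = "BRCA1", donor = "20",
                   acceptor = "18", class = "backsplice",
                   molecules = circTotal))
      cnt <- simulateCounts(mol, seed = 900 + s)
      tr <- 100 * circTotal / L
      cohortRatios(cnt, correctSaturation = TRUE)$overall_ratio_pct - tr
    }, numeric(1))
    expect_lt(abs(mean(ests)), 0.05)
  }
})
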