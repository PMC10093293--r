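mkCounts <- function(left, right, umi = 10L) {
  data.frame(sample = "S", left_probe_id = left, right_probe_id = right,
             umi_count = umi, read_count = umi * 3L)
}

test_that("the four junction archetypes classify as expected", {
  p <- referencePanel()
  cl <- classifyJunctions(mkCounts(
    c("BRCA1_e17_D", "BRCA1_e20_D", "BRCA2_e9_D", "BRCA1_e7_D"),
    c("BRCA1_e18_A", "BRCA1_e18_A", "BRCA2_e9_A", "BRCA1_e14_A")), p)
  expect_equal(cl$class, c("linear_canonical", "backsplice", "backsplice",
                           "linear_alternative"))
  expect_equal(cl$name[2], "BRCA1_circRNA_20-18")
  expect_equal(cl$name[3], "BRCA2_circRNA_9-9")   # single-exon circle
  expect_equal(cl$name[4], "BRCA1_mRNA_7-14")     # skipping junction
})

test_that("probe sides, genes and kinds drive the special classes", {
  p <- referencePanel()
  # acceptor-side probe on the left: not a valid ligation product
  expect_equal(classifyJunctions(mkCounts("BRCA1_e18_A", "BRCA1_e17_D"),
                                 p)$class, "artifact")
  expect_warning(
    cl <- classifyJunctions(mkCounts("BRCA1_e17_D", "BRCA2_e9_A"), p),
    "cross-gene")
  expect_equal(cl$class, "artifact")
  expect_true(is.na(cl$gene))
  pr <- panelProbes(p)
  snpA <- pr$probe_id[pr$snp_id %in% "snp01" & !is.na(pr$allele)][1]
  cl2 <- classifyJunctions(mkCounts(
    c(snpA, "BRCA1_int1"),
    c("BRCA1_snp01_P", "BRCA1_int2")), p)
  expect_equal(cl2$class, c("snp_allele", "intronic_control"))
  expect_equal(cl2$snp_id[1], "snp01")
})

test_that("alternative-boundary backsplices keep their suffix in the name", {
  p <- referencePanel()
  cl <- classifyJunctions(mkCounts("BRCA1_e5q_D", "BRCA1_e3_A"), p)
  expect_equal(cl$class, "backsplice")
  expect_equal(cl$name, "BRCA1_circRNA_5q-3")
  # ascending use of an alternative boundary is non-canonical linear
  cl2 <- classifyJunctions(mkCounts("BRCA1_e5q_D", "BRCA1_e6_A"), p)
  expect_equal(cl2$class, "linear_alternative")
})

test_that("classification is total, exclusive and UMI-conserving", {
  p <- toyPanel(5, withExtras = TRUE)
  spec <- sampleSpec("S1", "AAAAAAAA",
                     list(G = list(linear = 80, alt = c("1-3" = 9),
                                   circ = c("4-2" = 12))),
                     snpFractions = c(snp01 = 0.5), snpMolecules = 40,
                     dnaContamination = 8)
  sim <- simulateReads(p, list(spec), seed = 13)
  cnt <- countReads(sim, p)
  cl <- classifyJunctions(cnt, p)
  expect_false(anyNA(cl$class))
  expect_equal(sum(cl$umi_count), sum(cnt$umi_count))
  # recovered class equals the simulator's emitted class
  tk <- paste(sim$truth$left_probe_id, sim$truth$right_probe_id)
  ck <- paste(cl$left_probe_id, cl$right_probe_id)
  simClass <- sim$truth$class[match(ck, tk)]
  simClass[simClass == "linear"] <-
    ifelse(paste(cl$gene, cl$donor, cl$acceptor)[simClass == "linear"] %in%
             paste(canonicalJunctions(p)$gene, canonicalJunctions(p)$donor,
                   canonicalJunctions(p)$acceptor),
           "linear_canonical", "linear_alternative")
  expect_equal(cl$class, simClass)
})

test_that("ordinal rule agrees with a brute-force reference over all pairs", {
  p <- referencePanel()
  pr <- panelProbes(p)
  ex <- panelExons(p)
  jp <- pr[pr$kind == "junction", ]
  don <- jp[jp$side == "donor", ]
  acc <- jp[jp$side == "acceptor", ]
  pairs <- expand.grid(li = seq_len(nrow(don)), ri = seq_len(nrow(acc)))
  cnt <- data.frame(sample = "S",
                    left_probe_id = don$probe_id[pairs$li],
                    right_probe_id = acc$probe_id[pairs$ri],
                    umi_count = 1L, read_count = 1L)
  cl <- suppressWarnings(classifyJunctions(cnt, p))
  # independent restatement of the rule: linear iff the acceptor exon
  # follows the donor exon, circular otherwise; canonical = adjacent in
  # the canonical transcript
  expected <- vapply(seq_len(nrow(cnt)), function(i) {
    g1 <- don$gene[pairs$li[i]]; g2 <- acc$gene[pairs$ri[i]]
    if (g1 != g2) return("artifact")
    o <- function(lab) ex$ordinal[ex$gene == g1 & ex$label == lab]
    od <- o(don$exon_label[pairs$li[i]])
    oa <- o(acc$exon_label[pairs$ri[i]])
    if (oa <= od) return("backsplice")
    cj <- canonicalJunctions(p)
    if (any(cj$gene == g1 & cj$donor == don$exon_label[pairs$li[i]] &
              cj$acceptor == acc$exon_label[pairs$ri[i]]))
      "linear_canonical" else "linear_alternative"
  }, character(1))
  expect_equal(cl$class, expected)
})

test_that("anomaly detection respects the relative-abundance threshold", {
  p <- toyPanel(6)
  cj <- canonicalJunctions(p)
  base <- data.frame(sample = "S",
                     left_probe_id = sprintf("G_e%s_D", cj$donor),
                     right_probe_id = sprintf("G_e%s_A", cj$acceptor),
                     umi_count = 1000L, read_count = 3000L)
  withAlt <- rbind(base, data.frame(sample = "S", left_probe_id = "G_e2_D",
                                    right_probe_id = "G_e5_A",
                                    umi_count = 5L, read_count = 15L))
  cl <- classifyJunctions(withAlt, p)
  # 5/1000 = 0.5%: below the default 1% threshold, above 0.1%
  expect_equal(nrow(detectAnomalies(cl, p)), 0L)
  an <- detectAnomalies(cl, p, minRelAbundance = 0.001)
  expect_equal(nrow(an), 1L)
  expect_equal(an$kind, "skipping")
  expect_equal(c(an$donor, an$acceptor), c("2", "5"))

  clean <- classifyJunctions(base, p)
  expect_equal(nrow(detectAnomalies(clean, p)), 0L)
})

test_that("heterozygous exon skipping is recovered from simulated reads", {
  p <- toyPanel(7)
  # one allele splices 4->6 (skipping exon 5) in half of the transcripts
  spec <- sampleSpec("S1", "AAAAAAAA",
                     list(G = list(linear = 200, alt = c("4-6" = 100))))
  sim <- simulateReads(p, list(spec), seed = 17)
  cl <- classifyJunctions(countReads(sim, p), p)
  an <- detectAnomalies(cl, p)
  expect_equal(nrow(an), 1L)
  expect_equal(an$kind, "skipping")
  expect_gt(an$relative_abundance, 0.3)
})

test_that("tandem-duplication pseudo-circles are flagged without altering counts", {
  p <- referencePanel()
  cnt <- mkCounts(c("BRCA1_e13_D", "BRCA1_e20_D", "BRCA1_e17_D"),
                  c("BRCA1_e13_A", "BRCA1_e18_A", "BRCA1_e15_A"),
                  umi = c(40L, 30L, 20L))
  cl <- classifyJunctions(cnt, p)
  dup <- data.frame(gene = "BRCA1", first_exon = c("13", "18"),
                    last_exon = c("13", "20"))
  fl <- annotatePseudoCirc(cl, dup)
  expect_equal(fl$pseudo_circ, c(TRUE, TRUE, FALSE))
  expect_equal(fl$umi_count, cl$umi_count)
  expect_false(any(annotatePseudoCirc(cl, NULL)$pseudo_circ))
})
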