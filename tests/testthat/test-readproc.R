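test_that("demultiplexing assigns exact and 1-mismatch barcodes", {
  p <- toyPanel(3)
  spec <- list(sampleSpec("S1", "AAAAAAAA", list(G = list(linear = 5))),
               sampleSpec("S2", "CCCCGGGG", list(G = list(linear = 5))))
  sim <- simulateReads(p, spec, seed = 4, readsPerMolecule = 1)
  reads <- sim$reads
  dm <- demultiplex(reads, p)
  expect_equal(dm$sample, sub(".*SM:", "", reads$id))

  mut <- reads
  mut$id <- sub("BC:AAAAAAAA", "BC:AAAAAAAT", mut$id)   # 1 substitution
  dm1 <- demultiplex(mut, p, maxMismatch = 1)
  expect_true(all(dm1$sample[grepl("SM:S1", mut$id)] == "S1"))

  far <- reads
  far$id <- sub("BC:AAAAAAAA", "BC:AATTAATT", far$id)   # 4 substitutions
  dmf <- demultiplex(far, p, maxMismatch = 1)
  expect_true(all(is.na(dmf$sample[grepl("SM:S1", far$id)])))
  expect_equal(attr(dmf, "unassigned")$reads, sum(grepl("SM:S1", far$id)))
})

test_that("barcodes appended to the read are recognised and trimmed", {
  p <- toyPanel(3)
  spec <- sampleSpec("S1", "AAAAAAAA", list(G = list(linear = 10)))
  sim <- simulateReads(p, list(spec), seed = 6, barcodeInRead = TRUE,
                       readsPerMolecule = 1)
  cnt <- countReads(sim, p, barcodeInRead = TRUE)
  expect_equal(sum(cnt$umi_count), sum(sim$truth$distinct_umis))
})

test_that("probe matching recovers the simulated pair and UMI exactly", {
  p <- toyPanel(4)
  spec <- sampleSpec("S1", "AAAAAAAA",
                     list(G = list(linear = 20, circ = c("3-2" = 5))))
  sim <- simulateReads(p, list(spec), seed = 8, readsPerMolecule = 1)
  pm <- matchProbes(sim$reads$seq, p)
  expect_true(all(pm$status == "assigned"))
  expect_equal(pm$umi, substr(sim$reads$seq, 1, 7))
})

test_that("three substitutions in a probe exceed the default tolerance", {
  p <- toyPanel(3)
  sim <- simulateReads(p, sampleSpec("S1", "AAAAAAAA",
                                     list(G = list(linear = 1))),
                       seed = 3, readsPerMolecule = 1)
  r <- sim$reads$seq[1]
  flip <- function(s, i) {
    ch <- strsplit(s, "")[[1]]
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  mut <- flip(flip(flip(r, 8), 12), 16)   # 3 errors inside the left probe
  pm <- matchProbes(c(r, mut), p)
  expect_equal(pm$status, c("assigned", "no_probe_match"))
  pm1 <- matchProbes(mut, p, maxMismatch = 3)
  expect_equal(pm1$status, "assigned")
})

test_that("equidistant probes yield an ambiguous call", {
  A24 <- strrep("A", 24)
  p2seq <- paste0(strrep("A", 20), "TTTT")
  ex <- data.frame(gene = "G", label = c("1", "2"), ordinal = 1:2,
                   in_canonical = TRUE)
  pr <- data.frame(
    probe_id = c("G_e1_D", "G_e2_D", "G_e2_A"), gene = "G",
    exon_label = c("1", "2", "2"), side = c("donor", "donor", "acceptor"),
    kind = "junction",
    sequence = c(A24, p2seq, strrep("C", 24)))
  p <- probePanel(ex, pr, c(S1 = "GGGGGGGG"))
  # left segment at Hamming distance 2 from both donor probes
  left <- paste0(strrep("A", 20), "TTAA")
  read <- paste0("ACGTACG", left, strrep("C", 24))
  pm <- matchProbes(read, p)
  expect_equal(pm$status, "ambiguous")
})

test_that("UMI collapse counts distinct UMIs and preserves reads", {
  a <- data.frame(sample = "S", left_probe_id = "L", right_probe_id = "R",
                  umi = c("AAAAAAA", "AAAAAAA", "AAAAAAA"))
  c1 <- collapseUMIs(a)
  expect_equal(c1$umi_count, 1L)
  expect_equal(c1$read_count, 3L)
  a$umi <- c("AAAAAAA", "CCCCCCC", "GGGGGGG")
  expect_equal(collapseUMIs(a)$umi_count, 3L)
})

test_that("UMI collapse is idempotent and order-independent", {
  set.seed(31)
  a <- data.frame(sample = sample(c("S1", "S2"), 200, TRUE),
                  left_probe_id = sample(c("L1", "L2"), 200, TRUE),
                  right_probe_id = "R",
                  umi = replicate(200, paste(sample(c("A", "C", "G", "T"),
                                                    7, TRUE), collapse = "")))
  c1 <- collapseUMIs(a)
  c2 <- collapseUMIs(a[sample(nrow(a)), ])
  expect_identical(c1, c2)
})

test_that("directional UMI merge follows the 2n-1 parent rule", {
  mk <- function(n1, n2) data.frame(
    sample = "S", left_probe_id = "L", right_probe_id = "R",
    umi = c(rep("AAAAAAA", n1), rep("AAAAAAT", n2)))
  expect_equal(collapseUMIs(mk(5, 2), directional = TRUE)$umi_count, 1L)
  expect_equal(collapseUMIs(mk(5, 4), directional = TRUE)$umi_count, 2L)
  expect_equal(collapseUMIs(mk(5, 2), directional = FALSE)$umi_count, 2L)
})

test_that("error-free pipeline recovers truth UMI counts exactly", {
  p <- toyPanel(5, withExtras = TRUE)
  specs <- list(
    sampleSpec("S1", "AAAAAAAA",
               list(G = list(linear = 100, alt = c("2-4" = 10),
                             circ = c("4-2" = 20, "3-3" = 5))),
               snpFractions = c(snp01 = 0.3), snpMolecules = 50,
               dnaContamination = 12),
    sampleSpec("S2", "CCCCGGGG", list(G = list(linear = 60))))
  sim <- simulateReads(p, specs, seed = 21)
  cnt <- countReads(sim, p)
  st <- attr(cnt, "stats")
  expect_equal(st$assigned, st$total)
  cmp <- truthVsCounts(sim, cnt)
  expect_equal(cmp$recovered, cmp$truth)
  expect_equal(nrow(cnt), nrow(sim$truth))
})

test_that("noisy reads stay assignable and never create phantom junctions", {
  p <- toyPanel(4)
  for (s in 1:3) {
    spec <- sampleSpec("S1", "AAAAAAAA",
                       list(G = list(linear = 150, circ = c("3-2" = 15))))
    sim <- simulateReads(p, list(spec), seed = 400 + s, errorRate = 0.005)
    cnt <- countReads(sim, p)
    st <- attr(cnt, "stats")
    expect_gte(st$assigned / st$total, 0.99)
    tk <- paste(sim$truth$left_probe_id, sim$truth$right_probe_id)
    ck <- paste(cnt$left_probe_id, cnt$right_probe_id)
    expect_true(all(ck %in% tk))
  }
})
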