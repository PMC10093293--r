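# In-code toy panel builder: one gene, `nExons` exons, donor + acceptor
# junction probes on every exon, deterministic synthetic sequences.
toyPanel <- function(nExons = 4L, gene = "G",
                     barcodes = c(S1 = "AAAAAAAA", S2 = "CCCCGGGG"),
                     withExtras = FALSE, probeLen = 24L) {
  set.seed(nExons * 1000L + probeLen)
  seqs <- character(0)
  nextSeq <- function() {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), probeLen, replace = TRUE),
                 collapse = "")
      if (!s %in% seqs) { seqs <<- c(seqs, s); return(s) }
    }
  }
  ex <- data.frame(gene = gene, label = as.character(seq_len(nExons)),
                   ordinal = seq_len(nExons), in_canonical = TRUE)
  rows <- list()
  for (i in seq_len(nExons)) {
    rows[[length(rows) + 1]] <- data.frame(
      probe_id = sprintf("%s_e%d_A", gene, i), gene = gene,
      exon_label = as.character(i), side = "acceptor", kind = "junction",
      snp_id = NA, allele = NA, sequence = nextSeq())
    rows[[length(rows) + 1]] <- data.frame(
      probe_id = sprintf("%s_e%d_D", gene, i), gene = gene,
      exon_label = as.character(i), side = "donor", kind = "junction",
      snp_id = NA, allele = NA, sequence = nextSeq())
  }
  if (withExtras) {
    for (a in c("A", "G"))
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = paste0(gene, "_snp01_", a), gene = gene,
        exon_label = "2", side = "donor", kind = "snp_allele",
        snp_id = "snp01", allele = a, sequence = nextSeq())
    rows[[length(rows) + 1]] <- data.frame(
      probe_id = paste0(gene, "_snp01_P"), gene = gene, exon_label = "2",
      side = "acceptor", kind = "snp_allele", snp_id = "snp01",
      allele = NA, sequence = nextSeq())
    for (j in 1:3)
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = sprintf("%s_int%d", gene, j), gene = gene,
        exon_label = NA, side = c("donor", "acceptor", "donor")[j],
        kind = "intronic", snp_id = NA, allele = NA, sequence = nextSeq())
  }
  probePanel(ex, do.call(rbind, rows), barcodes)
}

# Truth vs recovered per-junction UMI counts, joined on the probe pair.
truthVsCounts <- function(sim, counts) {
  tr <- sim$truth
  tk <- paste(tr$sample, tr$left_probe_id, tr$right_probe_id)
  ck <- paste(counts$sample, counts$left_probe_id, counts$right_probe_id)
  data.frame(truth = tr$distinct_umis,
             recovered = counts$umi_count[match(tk, ck)])
}
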