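#' Describe one sample's transcript mixture for simulation
#'
#' A declarative description of what a simulated sample contains: canonical
#' linear transcript molecules per gene, extra non-canonical linear
#' junction molecules, circRNA (backsplice) molecules, SNP allele fractions
#' and genomic-DNA contaminant molecules (which carry intronic probes).
#'
#' @param name sample name.
#' @param barcode sample barcode (must exist in the panel used).
#' @param genes named list (one entry per gene) of lists with elements:
#'   `linear` (count of canonical-transcript molecules; each emits one
#'   ligation product per canonical junction), `alt` (named numeric vector,
#'   `"donor-acceptor"` -> molecule count for non-canonical linear
#'   junctions), `circ` (named numeric vector, `"donor-acceptor"` ->
#'   backsplice molecule count), `circ_internal_linear` (flag; if `TRUE`
#'   each circRNA molecule also emits its internal canonical linear
#'   junctions; default `FALSE`, matching the convention that all
#'   linear-ordered junctions are attributed to mRNA).
#' @param snpFractions named numeric vector, `snp_id` -> fraction of the
#'   alphabetically first allele.
#' @param snpMolecules molecules assayed per SNP (default 0).
#' @param dnaContamination count of genomic-DNA contaminant molecules,
#'   emitted as ligations of intronic control probes.
#' @return an object of class `SampleSpec` (a validated list).
#' @export
sampleSpec <- function(name, barcode, genes, snpFractions = numeric(0),
                       snpMolecules = 0L, dnaContamination = 0L) {
  for (g in names(genes)) {
    gs <- genes[[g]]
    cnt <- c(gs$linear, gs$alt, gs$circ)
    if (length(cnt) && any(cnt < 0))
      stopf("sample %s, gene %s: molecule counts must be >= 0", name, g)
  }
  if (length(snpFractions) && any(snpFractions < 0 | snpFractions > 1))
    stopf("sample %s: SNP allele fractions must lie in [0, 1]", name)
  structure(list(name = name, barcode = barcode, genes = genes,
                 snpFractions = snpFractions,
                 snpMolecules = as.integer(snpMolecules),
                 dnaContamination = as.integer(dnaContamination)),
            class = "SampleSpec")
}

# Find the donor/acceptor junction probes for a (gene, donor, acceptor)
# pair, or fail before any output is produced.
.junctionProbes <- function(panel, gene, donor, acceptor) {
  pr <- panel@probes
  d <- pr$probe_id[pr$gene == gene & pr$kind == "junction" &
                     pr$side == "donor" & pr$exon_label %in% donor]
  a <- pr$probe_id[pr$gene == gene & pr$kind == "junction" &
                     pr$side == "acceptor" & pr$exon_label %in% acceptor]
  if (length(d) != 1L || length(a) != 1L)
    stopf("junction %s %s-%s lacks a probe on both sides", gene, donor, acceptor)
  c(d, a)
}

# Expand a SampleSpec into one row per (junction-like event) with its
# molecule count and probe pair.
.productPlan <- function(panel, spec) {
  pr <- panel@probes
  ex <- panel@exons
  rows <- list()
  add <- function(gene, left, right, donor, acceptor, class, m) {
    if (m > 0)
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = gene, left_probe_id = left, right_probe_id = right,
        donor = donor, acceptor = acceptor, class = class,
        molecules = as.integer(m))
  }
  for (g in names(spec$genes)) {
    gs <- spec$genes[[g]]
    cj <- panel@canonicalJunctions
    cj <- cj[cj$gene == g, , drop = FALSE]
    lin <- if (is.null(gs$linear)) 0L else gs$linear
    if (lin > 0)
      for (i in seq_len(nrow(cj))) {
        p <- .junctionProbes(panel, g, cj$donor[i], cj$acceptor[i])
        add(g, p[1], p[2], cj$donor[i], cj$acceptor[i], "linear", lin)
      }
    for (j in names(gs$alt)) {
      da <- strsplit(j, "-", fixed = TRUE)[[1]]
      p <- .junctionProbes(panel, g, da[1], da[2])
      add(g, p[1], p[2], da[1], da[2], "linear", gs$alt[[j]])
    }
    internal <- isTRUE(gs$circ_internal_linear)
    for (j in names(gs$circ)) {
      da <- strsplit(j, "-", fixed = TRUE)[[1]]
      p <- .junctionProbes(panel, g, da[1], da[2])
      add(g, p[1], p[2], da[1], da[2], "backsplice", gs$circ[[j]])
      if (internal) {
        eg <- ex[ex$gene == g, ]
        lo <- eg$ordinal[eg$label == da[2]]
        hi <- eg$ordinal[eg$label == da[1]]
        ok <- cj[eg$ordinal[match(cj$donor, eg$label)] >= lo &
                   eg$ordinal[match(cj$acceptor, eg$label)] <= hi, ,
                 drop = FALSE]
        for (i in seq_len(nrow(ok))) {
          p2 <- .junctionProbes(panel, g, ok$donor[i], ok$acceptor[i])
          add(g, p2[1], p2[2], ok$donor[i], ok$acceptor[i], "linear",
              gs$circ[[j]])
        }
      }
    }
  }
  for (s in names(spec$snpFractions)) {
    sp <- pr[pr$kind == "snp_allele" & !is.na(pr$snp_id) & pr$snp_id == s, ]
    if (!nrow(sp)) stopf("unknown snp_id '%s'", s)
    al <- sp[!is.na(sp$allele), ]
    al <- al[order(al$allele), ]
    partner <- sp$probe_id[is.na(sp$allele)][1]
    m <- spec$snpMolecules
    if (m > 0) {
      a <- rbinom(1, m, spec$snpFractions[[s]])
      add(al$gene[1], al$probe_id[1], partner, NA, NA, "snp_allele", a)
      add(al$gene[1], al$probe_id[2], partner, NA, NA, "snp_allele", m - a)
    }
  }
  if (spec$dnaContamination > 0) {
    ip <- pr[pr$kind == "intronic", ]
    dn <- ip$probe_id[ip$side == "donor"]
    ac <- ip$probe_id[ip$side == "acceptor"]
    if (!length(dn) || !length(ac))
      stopf("panel lacks intronic probe pairs for contamination simulation")
    pairs <- expand.grid(left = dn, right = ac, stringsAsFactors = FALSE)
    m <- spec$dnaContamination
    base <- m %/% nrow(pairs)
    extra <- m %% nrow(pairs)
    for (i in seq_len(nrow(pairs)))
      add(ip$gene[1], pairs$left[i], pairs$right[i], NA, NA,
          "intronic_control", base + (i <= extra))
  }
  if (!length(rows))
    return(data.frame(gene = character(0), left_probe_id = character(0),
                      right_probe_id = character(0), donor = character(0),
                      acceptor = character(0), class = character(0),
                      molecules = integer(0)))
  plan <- do.call(rbind, rows)
  # merge duplicate junction rows (e.g. canonical junctions emitted both by
  # linear molecules and by circRNA interiors)
  key <- paste(plan$gene, plan$left_probe_id, plan$right_probe_id, plan$class)
  if (anyDuplicated(key)) {
    m <- tapply(plan$molecules, key, sum)
    plan <- plan[!duplicated(key), , drop = FALSE]
    plan$molecules <- as.integer(m[paste(plan$gene, plan$left_probe_id,
                                         plan$right_probe_id, plan$class)])
  }
  plan[order(plan$gene, plan$left_probe_id, plan$right_probe_id), ,
       drop = FALSE]
}

#' Simulate ligation-probe sequencing reads with ground truth
#'
#' Generates reads with the assay's layout -- `UMI ++ donor-probe sequence
#' ++ acceptor-probe sequence` -- from a declarative description of each
#' sample's transcript mixture. Each molecule yields one ligation product
#' per junction it spans; each product receives an independent uniform UMI
#' and is replicated `readsPerMolecule` times with the *same* UMI (PCR
#' duplication); per-base substitution noise is applied independently to
#' every read. The sample barcode is recorded in the read identifier
#' (`|BC:<barcode>|SM:<sample>`) or appended to the read sequence when
#' `barcodeInRead = TRUE`. Output is fully reproducible from `seed`.
#'
#' @param panel a [ProbePanel-class].
#' @param samples list of [sampleSpec()] objects.
#' @param seed integer seed (mandatory).
#' @param errorRate per-base substitution probability, in `[0, 0.1]`.
#' @param readsPerMolecule PCR duplication factor (default 3).
#' @param efficiency ligation capture efficiency in `(0, 1]`; products are
#'   thinned independently (default 1, every molecule observed).
#' @param barcodeInRead append the barcode to the read sequence instead of
#'   the header.
#' @param out optional FASTQ path (`.gz` supported); if `NULL` reads stay
#'   in memory.
#' @return a list of class `SimResult` with `reads` (data.frame `id`,
#'   `seq`), `truth` (per sample/junction: probe pair, labels, class,
#'   `molecules`, `distinct_umis`), `fastq` (path or `NA`).
#' @examples
#' ex <- data.frame(gene = "G", label = c("1", "2"), ordinal = 1:2,
#'                  in_canonical = TRUE)
#' pr <- data.frame(probe_id = c("G_e1_D", "G_e2_A"), gene = "G",
#'                  exon_label = c("1", "2"), side = c("donor", "acceptor"),
#'                  kind = "junction",
#'                  sequence = c(strrep("ACGTG", 5), strrep("TTGCA", 5)))
#' p <- probePanel(ex, pr, c(S1 = "ACGTACGT"))
#' sim <- simulateReads(p, list(sampleSpec("S1", "ACGTACGT",
#'   list(G = list(linear = 1)))), seed = 1, readsPerMolecule = 1)
#' nchar(sim$reads$seq)  # 7 + 25 + 25
#' @export
simulateReads <- function(panel, samples, seed, errorRate = 0,
                          readsPerMolecule = 3L, efficiency = 1,
                          barcodeInRead = FALSE, out = NULL) {
  if (missing(seed)) stopf("a seed is mandatory")
  if (errorRate < 0 || errorRate > 0.1)
    stopf("errorRate must lie in [0, 0.1]")
  if (efficiency <= 0 || efficiency > 1)
    stopf("efficiency must lie in (0, 1]")
  if (inherits(samples, "SampleSpec")) samples <- list(samples)
  for (s in samples) {
    if (!s$barcode %in% panel@barcodes)
      stopf("sample %s: barcode %s not in panel", s$name, s$barcode)
    # demultiplexing reports panel sample names, so the pair must agree
    if (!identical(unname(panel@barcodes[s$name]), s$barcode))
      stopf("sample %s: panel assigns barcode %s to a different name",
            s$name, s$barcode)
  }

  withSeed(seed, {
    seqs <- setNames(panel@probes$sequence, panel@probes$probe_id)
    truth <- list()
    ids <- list()
    rds <- list()
    for (s in samples) {
      plan <- .productPlan(panel, s)
      if (!nrow(plan)) next
      m <- plan$molecules
      if (efficiency < 1) m <- rbinom(nrow(plan), m, efficiency)
      n <- sum(m)
      idx <- rep.int(seq_len(nrow(plan)), m)
      umi <- randomDNA(n, panel@umiLength)
      plan$molecules <- m
      plan$distinct_umis <- vapply(
        split(umi, factor(idx, levels = seq_len(nrow(plan)))),
        function(u) length(unique(u)), integer(1))
      truth[[length(truth) + 1L]] <- cbind(sample = s$name, plan)

      body <- paste0(umi, seqs[plan$left_probe_id][idx],
                     seqs[plan$right_probe_id][idx])
      body <- rep(body, each = readsPerMolecule)
      if (barcodeInRead) body <- paste0(body, s$barcode)
      if (errorRate > 0) body <- .addErrors(body, errorRate)
      rds[[length(rds) + 1L]] <- body
      ids[[length(ids) + 1L]] <-
        sprintf("%s_r%07d|BC:%s|SM:%s", s$name, seq_along(body),
                s$barcode, s$name)
    }
    reads <- data.frame(id = unlist(ids), seq = unlist(rds))
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    res <- structure(list(reads = reads, truth = truth, fastq = NA_character_),
                     class = "SimResult")
    if (!is.null(out)) {
      writeFastq(reads, out)
      res$fastq <- out
    }
    res
  })
}

# Independent per-base substitutions at rate `e` on a character vector.
.addErrors <- function(body, e) {
  len <- nchar(body)
  nerr <- rbinom(length(body), len, e)
  hit <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(len[i], nerr[i])
    ch <- strsplit(body[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    body[i] <- paste(ch, collapse = "")
  }
  body
}

#' Write simulated reads as FASTQ
#'
#' Standard 4-line FASTQ records with a constant quality (`I`, Q40), via
#' Biostrings. Gzip output is selected by a `.gz` extension.
#'
#' @param reads data.frame with `id` and `seq` (as in `SimResult$reads`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into an id/sequence table
#'
#' @param path FASTQ(.gz) path.
#' @return data.frame with `id` and `seq`.
#' @export
readFastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(dna), seq = as.character(dna))
}

## ---- UMI occupancy ---------------------------------------------------------

#' Expected number of distinct UMIs for m molecules
#'
#' With `m` molecules drawing UMIs uniformly from a space of size `N`
#' (`4^umiLength`, 16384 for 7-base UMIs), the expected number of distinct
#' UMIs observed is `N (1 - (1 - 1/N)^m)` -- the classical occupancy mean.
#' `varDistinctUMIs` gives the exact occupancy variance.
#'
#' @param m molecule count (vectorised).
#' @param umiSpace UMI space size `N` (default `4^7`).
#' @return expected (or variance of) distinct-UMI count.
#' @export
expectedDistinctUMIs <- function(m, umiSpace = 16384L) {
  umiSpace * (1 - (1 - 1 / umiSpace)^m)
}

#' @rdname expectedDistinctUMIs
#' @export
varDistinctUMIs <- function(m, umiSpace = 16384L) {
  N <- umiSpace
  N * (1 - 1 / N)^m + N^2 * (1 - 1 / N) * (1 - 2 / N)^m -
    N^2 * (1 - 1 / N)^(2 * m)
}

#' Saturation-corrected molecule estimate from a distinct-UMI count
#'
#' Inverts the occupancy mean exactly: `m_hat = log(1 - k/N) /
#' log(1 - 1/N)`. Useful when per-junction molecule numbers approach the
#' UMI space size; raw distinct-UMI counts are the default currency
#' everywhere else.
#'
#' @param k observed distinct-UMI count.
#' @param umiSpace UMI space size (default `4^7`).
#' @return estimated molecule count.
#' @export
correctSaturation <- function(k, umiSpace = 16384L) {
  log1p(-k / umiSpace) / log1p(-1 / umiSpace)
}

# Sample distinct-UMI counts for molecule counts `m`: exact multinomial
# occupancy for small m, normal approximation with exact occupancy
# mean/variance for large m.
rDistinctUMIs <- function(m, umiSpace = 16384L, exactMax = 3000L) {
  k <- numeric(length(m))
  small <- which(m <= exactMax)
  for (i in small)
    k[i] <- length(unique(sample.int(umiSpace, m[i], replace = TRUE)))
  big <- which(m > exactMax)
  if (length(big)) {
    mu <- expectedDistinctUMIs(m[big], umiSpace)
    sd <- sqrt(pmax(varDistinctUMIs(m[big], umiSpace), 0))
    k[big] <- pmin(pmax(round(rnorm(length(big), mu, sd)), 1), umiSpace)
  }
  as.integer(k)
}

#' Simulate junction-level distinct-UMI counts without generating reads
#'
#' Molecule-count-level counterpart of [simulateReads()]: for each row of a
#' molecule-count table, draws the number of distinct UMIs that tagging the
#' molecules with independent uniform UMIs would produce (exact occupancy
#' sampling for small counts, a normal approximation with the exact
#' occupancy mean and variance for large ones). Used for cohort-scale
#' studies where read-level simulation would be wasteful.
#'
#' @param molecules data.frame with columns `sample`, `gene`, `donor`,
#'   `acceptor`, `class`, `molecules`.
#' @param seed integer seed.
#' @param umiSpace UMI space size (default `4^7`).
#' @return the input with an added `umi_count` column.
#' @export
simulateCounts <- function(molecules, seed, umiSpace = 16384L) {
  if (missing(seed)) stopf("a seed is mandatory")
  withSeed(seed, {
    molecules$umi_count <- rDistinctUMIs(molecules$molecules, umiSpace)
    molecules
  })
}
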