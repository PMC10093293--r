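# Read structure is positionally rigid: UMI, then the left (donor-side)
# probe, then the right (acceptor-side) probe. Matching is therefore
# fixed-offset Hamming comparison, not alignment; indels are out of scope.

# Best probe match at a fixed offset. Returns id (NA if none within
# maxMismatch), distance, and a tie flag (two probes equally close).
.matchAtOffset <- function(seqs, offsets, probes, maxMismatch) {
  n <- length(seqs)
  bestD <- rep(Inf, n)
  bestId <- rep(NA_character_, n)
  tie <- logical(n)
  plen <- nchar(probes$sequence)
  for (L in sort(unique(plen))) {
    sub <- substr(seqs, offsets, offsets + L - 1L)
    ok <- nchar(sub) == L
    pn <- probes[plen == L, , drop = FALSE]
    # exact fast path: probe sequences are unique, so distance 0 is final
    hit <- match(sub, pn$sequence)
    ex <- ok & !is.na(hit)
    upd <- ex & bestD > 0
    bestD[upd] <- 0
    bestId[upd] <- pn$probe_id[hit[upd]]
    tie[upd] <- FALSE
    rest <- which(ok & bestD > 0)
    if (!length(rest)) next
    for (j in seq_len(nrow(pn))) {
      d <- hammingToTarget(sub[rest], pn$sequence[j])
      lt <- d < bestD[rest]
      eq <- d == bestD[rest] & d > 0
      tie[rest[eq]] <- TRUE
      w <- rest[lt]
      bestD[w] <- d[lt]
      bestId[w] <- pn$probe_id[j]
      tie[w] <- FALSE
    }
  }
  miss <- bestD > maxMismatch
  bestId[miss] <- NA_character_
  tie[miss] <- FALSE
  list(id = bestId, dist = bestD, tie = tie)
}

#' Identify the ligated probe pair and UMI of each read
#'
#' The UMI is the first `umiLength(panel)` bases; the left probe is matched
#' at the following offset and the right probe immediately after the left
#' probe's end, each by Hamming distance over all panel probes of
#' compatible length. A unique best match within `maxMismatch` is required;
#' an exact tie yields status `ambiguous`, no probe within tolerance yields
#' `no_probe_match`.
#'
#' @param seqs character vector of read sequences.
#' @param panel a [ProbePanel-class].
#' @param maxMismatch maximum Hamming distance per probe (default 2).
#' @return data.frame with `umi`, `left_probe_id`, `right_probe_id`,
#'   `status` (`assigned`, `no_probe_match` or `ambiguous`).
#' @export
matchProbes <- function(seqs, panel, maxMismatch = 2L) {
  u <- panel@umiLength
  pr <- panel@probes
  umi <- substr(seqs, 1L, u)
  n <- length(seqs)
  left <- .matchAtOffset(seqs, rep(u + 1L, n), pr, maxMismatch)
  leftLen <- nchar(pr$sequence)[match(left$id, pr$probe_id)]
  right <- list(id = rep(NA_character_, n), tie = logical(n))
  hasLeft <- which(!is.na(left$id) & !left$tie)
  if (length(hasLeft)) {
    off2 <- u + 1L + leftLen[hasLeft]
    for (o in unique(off2)) {
      g <- hasLeft[off2 == o]
      r <- .matchAtOffset(seqs[g], rep(o, length(g)), pr, maxMismatch)
      right$id[g] <- r$id
      right$tie[g] <- r$tie
    }
  }
  status <- rep("assigned", n)
  status[is.na(left$id) | is.na(right$id)] <- "no_probe_match"
  status[left$tie | right$tie] <- "ambiguous"
  ok <- status == "assigned"
  data.frame(umi = umi,
             left_probe_id = ifelse(ok, left$id, NA_character_),
             right_probe_id = ifelse(ok, right$id, NA_character_),
             status = status)
}

#' Demultiplex reads by sample barcode
#'
#' Assigns each read to the unique barcode within `maxMismatch`
#' substitutions. Barcodes are taken from the `|BC:<seq>|` field of the
#' read identifier (the simulator's default) or, with
#' `barcodeInRead = TRUE`, from the last `nchar(barcode)` bases of the
#' read (which are then trimmed). The panel's barcode distance floor
#' (pairwise Hamming >= 2 * tolerance + 1) makes the assignment
#' unambiguous.
#'
#' @param reads data.frame with `id` and `seq` (see [readFastq()]).
#' @param panel a [ProbePanel-class].
#' @param maxMismatch barcode mismatch tolerance (default 1).
#' @param barcodeInRead barcode appended to the read sequence instead of
#'   the header.
#' @return the reads with a `sample` column (NA for status `no_barcode`)
#'   and an attribute `unassigned` tallying unassignable reads.
#' @export
demultiplex <- function(reads, panel, maxMismatch = 1L,
                        barcodeInRead = FALSE) {
  bc <- panel@barcodes
  if (!length(bc)) stopf("panel has no barcodes")
  blen <- nchar(bc[1])
  if (barcodeInRead) {
    obs <- substr(reads$seq, nchar(reads$seq) - blen + 1L, nchar(reads$seq))
    reads$seq <- substr(reads$seq, 1L, nchar(reads$seq) - blen)
  } else {
    obs <- sub(".*\\|BC:([ACGTN]+)\\|.*", "\\1", reads$id)
  }
  sample <- names(bc)[match(obs, bc)]
  todo <- which(is.na(sample) & nchar(obs) == blen)
  if (length(todo)) {
    d <- vapply(bc, function(b) hammingToTarget(obs[todo], b),
                integer(length(todo)))
    d <- matrix(d, nrow = length(todo))
    best <- apply(d, 1L, which.min)
    ok <- d[cbind(seq_along(todo), best)] <= maxMismatch
    sample[todo[ok]] <- names(bc)[best[ok]]
  }
  reads$sample <- sample
  attr(reads, "unassigned") <-
    data.frame(status = "no_barcode", reads = sum(is.na(sample)))
  reads
}

#' Collapse read-level assignments to distinct-UMI junction counts
#'
#' Per (sample, left probe, right probe), counts the number of distinct
#' UMIs -- the molecular count, since PCR duplicates carry the molecule's
#' UMI -- and the total read count. UMI distinctness is scoped per
#' junction, not per sample. An optional directional single-mismatch merge
#' absorbs a UMI into a Hamming-1 neighbour when
#' `count(parent) >= 2 * count(child) - 1` (off by default; raw distinct
#' counts are the reported currency).
#'
#' @param assignments data.frame with `sample`, `left_probe_id`,
#'   `right_probe_id`, `umi` (rows with other statuses are ignored if a
#'   `status` column is present).
#' @param directional apply the directional Hamming-1 UMI merge.
#' @return data.frame `sample`, `left_probe_id`, `right_probe_id`,
#'   `umi_count`, `read_count`, ordered deterministically.
#' @export
collapseUMIs <- function(assignments, directional = FALSE) {
  a <- assignments
  if (!is.null(a$status)) a <- a[a$status == "assigned", , drop = FALSE]
  if (!is.null(a$sample)) a <- a[!is.na(a$sample), , drop = FALSE]
  if (!nrow(a))
    return(data.frame(sample = character(0), left_probe_id = character(0),
                      right_probe_id = character(0), umi_count = integer(0),
                      read_count = integer(0)))
  key <- paste(a$sample, a$left_probe_id, a$right_probe_id, sep = "\r")
  cnt <- function(u) {
    if (!directional) return(length(unique(u)))
    .directionalCount(u)
  }
  umiN <- tapply(a$umi, key, cnt)
  readN <- tapply(a$umi, key, length)
  parts <- do.call(rbind, strsplit(names(umiN), "\r", fixed = TRUE))
  out <- data.frame(sample = parts[, 1], left_probe_id = parts[, 2],
                    right_probe_id = parts[, 3],
                    umi_count = as.integer(umiN),
                    read_count = as.integer(readN))
  out <- out[order(out$sample, out$left_probe_id, out$right_probe_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Directional single-mismatch UMI network count: a UMI is merged into a
# more abundant Hamming-1 neighbour when parent >= 2 * child - 1.
.directionalCount <- function(umis) {
  tab <- sort(table(umis), decreasing = TRUE)
  u <- names(tab)
  n <- as.integer(tab)
  if (length(u) <= 1L) return(length(u))
  alive <- rep(TRUE, length(u))
  lookup <- setNames(seq_along(u), u)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(u)) {
    if (!alive[i]) next
    ch <- strsplit(u[i], "")[[1]]
    for (p in seq_along(ch)) for (b in setdiff(bases, ch[p])) {
      v <- ch; v[p] <- b
      j <- lookup[paste(v, collapse = "")]
      if (!is.na(j) && j > i && alive[j] && n[i] >= 2L * n[j] - 1L)
        alive[j] <- FALSE
    }
  }
  sum(alive)
}

#' Count junctions from FASTQ reads
#'
#' Full read-processing stage: demultiplex by barcode, match the ligated
#' probe pair, extract the UMI and collapse to distinct-UMI counts per
#' (sample, probe pair).
#'
#' @param reads a FASTQ path, a data.frame from [readFastq()], or a
#'   `SimResult` from [simulateReads()].
#' @param panel a [ProbePanel-class].
#' @param maxMismatchBarcode,maxMismatchProbe Hamming tolerances
#'   (defaults 1 and 2).
#' @param directional directional UMI merge, see [collapseUMIs()].
#' @param barcodeInRead see [demultiplex()].
#' @return a junction count table as from [collapseUMIs()], with an
#'   attribute `stats` (reads total / assigned / no_barcode /
#'   no_probe_match / ambiguous).
#' @export
countReads <- function(reads, panel, maxMismatchBarcode = 1L,
                       maxMismatchProbe = 2L, directional = FALSE,
                       barcodeInRead = FALSE) {
  if (inherits(reads, "SimResult")) reads <- reads$reads
  if (is.character(reads)) reads <- readFastq(reads)
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  dm <- demultiplex(reads, panel, maxMismatchBarcode, barcodeInRead)
  pm <- matchProbes(dm$seq, panel, maxMismatchProbe)
  pm$sample <- dm$sample
  pm$status[is.na(dm$sample)] <- "no_barcode"
  out <- collapseUMIs(pm)
  attr(out, "stats") <- data.frame(
    total = nrow(pm),
    assigned = sum(pm$status == "assigned" & !is.na(pm$sample)),
    no_barcode = sum(is.na(dm$sample)),
    no_probe_match = sum(pm$status == "no_probe_match"),
    ambiguous = sum(pm$status == "ambiguous"))
  out
}
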