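#' Classify counted probe pairs into junction classes
#'
#' The probe order encodes the transcript topology: a donor-side (3' exon
#' boundary) probe ligated to the acceptor-side (5' boundary) probe of a
#' *downstream* exon is a linear splice; ligated to the acceptor probe of
#' the *same or an upstream* exon it is a backsplice (equality being a
#' single-exon circle). Classes are a pure function of the probe pair and
#' the panel:
#'
#' * any intronic probe involved -> `intronic_control`
#' * any SNP-allele probe involved -> `snp_allele`
#' * probes from different genes -> `artifact` (with a warning; fusion
#'   detection is out of scope)
#' * left probe not donor-side or right probe not acceptor-side ->
#'   `artifact`
#' * acceptor ordinal > donor ordinal -> `linear_canonical` if the pair is
#'   a canonical junction of the panel, else `linear_alternative`
#' * acceptor ordinal <= donor ordinal -> `backsplice`
#'
#' @param counts junction count table from [countReads()] /
#'   [collapseUMIs()].
#' @param panel a [ProbePanel-class].
#' @return the counts with added columns `gene`, `donor`, `acceptor`,
#'   `class`, `name` (junction name for linear/backsplice rows),
#'   `snp_id`, `allele`.
#' @examples
#' # donor ex20 ligated to acceptor ex18 -> backsplice "..._circRNA_20-18"
#' @export
classifyJunctions <- function(counts, panel) {
  pr <- panel@probes
  ex <- panel@exons
  li <- match(counts$left_probe_id, pr$probe_id)
  ri <- match(counts$right_probe_id, pr$probe_id)
  if (anyNA(li) || anyNA(ri))
    stopf("count table references probes absent from the panel (%s)",
          c(counts$left_probe_id[is.na(li)], counts$right_probe_id[is.na(ri)])[1])
  exKey <- paste(ex$gene, ex$label)
  ordOf <- function(g, lab) ex$ordinal[match(paste(g, lab), exKey)]

  n <- nrow(counts)
  class <- rep(NA_character_, n)
  gene <- pr$gene[li]
  donor <- pr$exon_label[li]
  acceptor <- pr$exon_label[ri]
  snp <- ifelse(is.na(pr$snp_id[li]), pr$snp_id[ri], pr$snp_id[li])
  allele <- pr$allele[li]

  intronic <- pr$kind[li] == "intronic" | pr$kind[ri] == "intronic"
  snpish <- !intronic & (pr$kind[li] == "snp_allele" | pr$kind[ri] == "snp_allele")
  cross <- !intronic & !snpish & pr$gene[li] != pr$gene[ri]
  badside <- !intronic & !snpish & !cross &
    (pr$side[li] != "donor" | pr$side[ri] != "acceptor")
  class[intronic] <- "intronic_control"
  class[snpish] <- "snp_allele"
  class[cross] <- "artifact"
  class[badside] <- "artifact"
  if (any(cross))
    warning(sprintf("%d cross-gene probe pair(s) classified as artifact",
                    sum(cross)), call. = FALSE)

  rest <- which(is.na(class))
  if (length(rest)) {
    dOrd <- ordOf(gene[rest], donor[rest])
    aOrd <- ordOf(gene[rest], acceptor[rest])
    lin <- aOrd > dOrd
    canonKey <- paste(panel@canonicalJunctions$gene,
                      panel@canonicalJunctions$donor,
                      panel@canonicalJunctions$acceptor)
    isCanon <- paste(gene[rest], donor[rest], acceptor[rest]) %in% canonKey
    class[rest] <- ifelse(lin,
                          ifelse(isCanon, "linear_canonical",
                                 "linear_alternative"),
                          "backsplice")
  }

  out <- counts
  out$gene <- gene
  out$gene[cross] <- NA_character_
  out$donor <- donor
  out$acceptor <- acceptor
  out$class <- class
  out$snp_id <- ifelse(class == "snp_allele", snp, NA_character_)
  out$allele <- ifelse(class == "snp_allele", allele, NA_character_)
  nm <- rep(NA_character_, n)
  jx <- class %in% c("linear_canonical", "linear_alternative", "backsplice")
  if (any(jx))
    nm[jx] <- junctionName(panel, gene[jx], donor[jx], acceptor[jx],
                           ifelse(class[jx] == "backsplice", "backsplice",
                                  "linear"))
  out$name <- nm
  out
}

#' Per-gene linear and circular UMI totals
#'
#' Sums distinct-UMI counts per sample and gene over the linear classes
#' (`linear_canonical` + `linear_alternative`) and over backsplices.
#' SNP-allele and intronic-control UMIs measure alleles and contamination,
#' not junction abundance, and are excluded from both totals.
#'
#' @param classified output of [classifyJunctions()].
#' @return data.frame `sample`, `gene`, `umi_linear_total`,
#'   `umi_circ_total`.
#' @export
geneTotals <- function(classified) {
  cl <- classified[!is.na(classified$gene), , drop = FALSE]
  key <- paste(cl$sample, cl$gene, sep = "\r")
  lin <- tapply(cl$umi_count * (cl$class %in%
           c("linear_canonical", "linear_alternative")), key, sum)
  circ <- tapply(cl$umi_count * (cl$class == "backsplice"), key, sum)
  parts <- do.call(rbind, strsplit(names(lin), "\r", fixed = TRUE))
  data.frame(sample = parts[, 1], gene = parts[, 2],
             umi_linear_total = as.integer(lin),
             umi_circ_total = as.integer(circ), row.names = NULL)
}

#' Detect splicing anomalies
#'
#' Flags non-canonical linear junctions and unannotated backsplices whose
#' abundance relative to the gene's mean canonical-junction UMI count
#' reaches `minRelAbundance` (default 1\%, the level at which all known
#' alternative transcripts are detectable at assay depth). Kinds:
#' `skipping` (linear junction jumping over at least one exon, i.e.
#' acceptor ordinal > donor ordinal + 1), `novel` (other non-canonical
#' linear junctions, e.g. alternative-boundary usage), and
#' `unexpected_backsplice` (backsplices absent from `known`).
#'
#' @param classified output of [classifyJunctions()], one sample.
#' @param panel a [ProbePanel-class].
#' @param minRelAbundance relative-abundance threshold (fraction of the
#'   mean canonical UMI count; default 0.01).
#' @param known optional annotation data.frame with `gene`, `donor`,
#'   `acceptor` (and optionally `status`) of known junctions; defaults to
#'   the packaged circRNA reference repertoire.
#' @return data.frame `sample`, `gene`, `donor`, `acceptor`, `kind`,
#'   `umi_count`, `relative_abundance`, `status` (known/novel with respect
#'   to the annotation), sorted by descending relative abundance.
#' @export
detectAnomalies <- function(classified, panel, minRelAbundance = 0.01,
                            known = referenceCircTables()) {
  cl <- classified[!is.na(classified$gene), , drop = FALSE]
  res <- list()
  for (s in unique(cl$sample)) for (g in unique(cl$gene[cl$sample == s])) {
    sub <- cl[cl$sample == s & cl$gene == g, , drop = FALSE]
    canon <- sub$umi_count[sub$class == "linear_canonical"]
    if (!length(canon) || sum(canon) == 0)
      stopf("cannot normalize: no canonical-junction UMIs for %s in %s", g, s)
    denom <- mean(canon)
    cand <- sub[sub$class %in% c("linear_alternative", "backsplice"), ,
                drop = FALSE]
    if (!nrow(cand)) next
    knownKey <- paste(known$gene, known$donor, known$acceptor)
    isKnown <- paste(cand$gene, cand$donor, cand$acceptor) %in% knownKey
    keep <- cand$class == "linear_alternative" |
      (cand$class == "backsplice" & !isKnown)
    cand <- cand[keep, , drop = FALSE]
    isKnown <- isKnown[keep]
    if (!nrow(cand)) next
    rel <- cand$umi_count / denom
    sel <- rel >= minRelAbundance
    if (!any(sel)) next
    cand <- cand[sel, , drop = FALSE]
    ex <- panel@exons[panel@exons$gene == g, ]
    dOrd <- ex$ordinal[match(cand$donor, ex$label)]
    aOrd <- ex$ordinal[match(cand$acceptor, ex$label)]
    kind <- ifelse(cand$class == "backsplice", "unexpected_backsplice",
                   ifelse(aOrd > dOrd + 1L, "skipping", "novel"))
    res[[length(res) + 1L]] <- data.frame(
      sample = s, gene = g, donor = cand$donor, acceptor = cand$acceptor,
      kind = kind, umi_count = cand$umi_count,
      relative_abundance = rel[sel],
      status = ifelse(isKnown[sel], "known", "novel"))
  }
  if (!length(res))
    return(data.frame(sample = character(0), gene = character(0),
                      donor = character(0), acceptor = character(0),
                      kind = character(0), umi_count = integer(0),
                      relative_abundance = numeric(0), status = character(0)))
  out <- do.call(rbind, res)
  out <- out[order(-out$relative_abundance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag backsplice junctions explained by genomic tandem duplications
#'
#' A tandem duplication of exons `first..last` produces, by purely linear
#' splicing across the duplicated segment, a junction of the donor of
#' `last` to the acceptor of the duplicated `first` -- indistinguishable
#' from a backsplice at the read level. Given germline duplication
#' annotations (which cannot be inferred from counts alone), matching
#' backsplice rows receive a `pseudo_circ` flag; counts are never altered,
#' and flagged rows stay in circRNA tallies unless explicitly excluded
#' downstream.
#'
#' @param classified output of [classifyJunctions()].
#' @param duplications data.frame with `gene`, `first_exon`, `last_exon`
#'   (may be empty or NULL).
#' @return `classified` with a logical `pseudo_circ` column.
#' @export
annotatePseudoCirc <- function(classified, duplications = NULL) {
  out <- classified
  out$pseudo_circ <- FALSE
  if (is.null(duplications) || !nrow(duplications)) return(out)
  key <- paste(duplications$gene, duplications$last_exon,
               duplications$first_exon)
  hit <- out$class == "backsplice" &
    paste(out$gene, out$donor, out$acceptor) %in% key
  out$pseudo_circ[hit & !is.na(hit)] <- TRUE
  out
}
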