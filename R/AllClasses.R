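#' @import methods
NULL

#' ProbePanel: a targeted exon-boundary ligation probe design
#'
#' An S4 container for a ligation-probe panel: the ordered exon models of the
#' targeted genes (including alternative exon boundaries such as `"5q"` or
#' `"8p"`), the probe set (junction, SNP-allele and intronic-control probes),
#' the sample barcodes and the UMI length. The canonical splice junctions of
#' each gene (adjacent exon pairs of the canonical transcript) are derived
#' from the exon table and stored explicitly.
#'
#' @slot genes character vector of gene identifiers.
#' @slot exons data.frame with columns `gene`, `label`, `ordinal`,
#'   `in_canonical`. Ordinals are unique within a gene and order the exons
#'   5' to 3'; alternative-boundary exons (p/q suffix) occupy ordinals
#'   adjacent to their parent exon.
#' @slot probes data.frame with columns `probe_id`, `gene`, `exon_label`,
#'   `side` (`"donor"` = 3' exon boundary, `"acceptor"` = 5' boundary),
#'   `kind` (`"junction"`, `"snp_allele"`, `"intronic"`), `snp_id`,
#'   `allele`, `sequence` (DNA, 20-30 nt).
#' @slot canonicalJunctions data.frame with columns `gene`, `donor`,
#'   `acceptor`: the ordered adjacent exon pairs of each canonical
#'   transcript.
#' @slot barcodes named character vector mapping sample name to barcode.
#' @slot umiLength integer, length of the unique molecular identifier
#'   (default 7, giving 4^7 = 16384 distinct UMIs).
#'
#' @seealso [loadPanel()], [panelSummary()], [junctionName()]
#' @export
setClass("ProbePanel",
  representation(
    genes = "character",
    exons = "data.frame",
    probes = "data.frame",
    canonicalJunctions = "data.frame",
    barcodes = "character",
    umiLength = "integer"
  )
)

setValidity("ProbePanel", function(object) {
  ex <- object@exons
  pr <- object@probes
  msgs <- character(0)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      msgs <<- c(msgs, sprintf("schema error: %s lacks column(s) %s",
                               what, paste(miss, collapse = ", ")))
  }
  need(ex, c("gene", "label", "ordinal", "in_canonical"), "exon table")
  need(pr, c("probe_id", "gene", "exon_label", "side", "kind", "sequence"),
       "probe table")
  if (length(msgs)) return(msgs)

  for (g in object@genes) {
    o <- ex$ordinal[ex$gene == g]
    if (anyDuplicated(o))
      msgs <- c(msgs, sprintf("schema error: duplicated exon ordinals in %s", g))
  }

  if (anyDuplicated(pr$probe_id))
    msgs <- c(msgs, "schema error: duplicated probe_id")
  dup <- pr$sequence[duplicated(pr$sequence)]
  if (length(dup))
    msgs <- c(msgs, sprintf("ambiguous panel: duplicate probe sequence shared by %s",
      paste(pr$probe_id[pr$sequence %in% dup[1]], collapse = "/")))
  # a probe that is a proper prefix of another cannot be matched uniquely at
  # its fixed read offset
  sq <- sort(unique(pr$sequence))
  if (length(sq) > 1) {
    pre <- startsWith(sq[-1], sq[-length(sq)])
    if (any(pre))
      msgs <- c(msgs, sprintf("ambiguous panel: probe sequence is a prefix of another (%s)",
        pr$probe_id[match(sq[-length(sq)][pre][1], pr$sequence)]))
  }

  len <- nchar(pr$sequence)
  bad <- len < 20 | len > 30
  if (any(bad))
    msgs <- c(msgs, sprintf("schema error: probe %s length %d outside [20, 30]",
                            pr$probe_id[bad][1], len[bad][1]))

  if (!all(pr$side %in% c("donor", "acceptor")))
    msgs <- c(msgs, "schema error: probe side must be donor or acceptor")
  if (!all(pr$kind %in% c("junction", "snp_allele", "intronic")))
    msgs <- c(msgs, "schema error: unknown probe kind")

  key <- paste(ex$gene, ex$label)
  ref <- pr$kind != "intronic"
  dangling <- ref & !(paste(pr$gene, pr$exon_label) %in% key)
  if (any(dangling))
    msgs <- c(msgs, sprintf("schema error: probe %s references unknown exon '%s' in %s",
      pr$probe_id[dangling][1], pr$exon_label[dangling][1], pr$gene[dangling][1]))
  if (any(pr$kind == "intronic" & !is.na(pr$exon_label) & nzchar(pr$exon_label)))
    msgs <- c(msgs, "schema error: intronic probe must not reference an exon")

  cj <- object@canonicalJunctions
  for (i in seq_len(nrow(cj))) {
    d <- pr$probe_id[pr$gene == cj$gene[i] & pr$exon_label %in% cj$donor[i] &
                       pr$side == "donor" & pr$kind == "junction"]
    a <- pr$probe_id[pr$gene == cj$gene[i] & pr$exon_label %in% cj$acceptor[i] &
                       pr$side == "acceptor" & pr$kind == "junction"]
    if (!length(d) || !length(a)) {
      msgs <- c(msgs, sprintf("schema error: canonical junction %s %s-%s lacks a %s probe",
        cj$gene[i], cj$donor[i], cj$acceptor[i],
        if (!length(d)) "donor" else "acceptor"))
      break
    }
  }

  bc <- object@barcodes
  if (length(bc)) {
    if (length(unique(nchar(bc))) != 1L)
      msgs <- c(msgs, "schema error: barcodes must share one length")
    else if (length(bc) > 1) {
      cmb <- utils::combn(length(bc), 2)
      for (j in seq_len(ncol(cmb))) {
        d <- hammingDist(bc[cmb[1, j]], bc[cmb[2, j]])
        if (d < 3) {  # 2 * tolerance + 1 with tolerance = 1
          msgs <- c(msgs, sprintf("barcode collision: %s/%s at Hamming distance %d",
            names(bc)[cmb[1, j]], names(bc)[cmb[2, j]], d))
          break
        }
      }
    }
  }

  if (length(object@umiLength) != 1L || object@umiLength < 1L)
    msgs <- c(msgs, "schema error: umiLength must be a positive integer")

  if (length(msgs)) msgs else TRUE
})
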