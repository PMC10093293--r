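#' Construct a ProbePanel from its component tables
#'
#' Builds and validates a [ProbePanel-class] object. Canonical splice
#' junctions are derived from the exon table as adjacent pairs of exons
#' flagged `in_canonical`, taken in ordinal order.
#'
#' @param exons data.frame with `gene`, `label`, `ordinal`, `in_canonical`.
#' @param probes data.frame with `probe_id`, `gene`, `exon_label`, `side`,
#'   `kind`, optional `snp_id`/`allele`, `sequence`.
#' @param barcodes named character vector (sample name -> barcode), or a
#'   data.frame with columns `sample` and `barcode`.
#' @param umiLength UMI length in bases (default 7).
#' @return a validated `ProbePanel`.
#' @examples
#' ex <- data.frame(gene = "G", label = c("1", "2"), ordinal = 1:2,
#'                  in_canonical = TRUE)
#' pr <- data.frame(probe_id = c("G_e1_D", "G_e2_A"), gene = "G",
#'                  exon_label = c("1", "2"), side = c("donor", "acceptor"),
#'                  kind = "junction",
#'                  sequence = c(strrep("ACGTG", 5), strrep("TTGCA", 5)))
#' probePanel(ex, pr, c(S1 = "ACGTACGT"))
#' @export
probePanel <- function(exons, probes, barcodes = character(0), umiLength = 7L) {
  if (is.data.frame(barcodes))
    barcodes <- setNames(as.character(barcodes$barcode),
                         as.character(barcodes$sample))
  exons <- as.data.frame(exons)
  probes <- as.data.frame(probes)
  exons$label <- as.character(exons$label)
  exons$ordinal <- as.integer(exons$ordinal)
  exons$in_canonical <- as.logical(exons$in_canonical)
  probes$exon_label <- as.character(probes$exon_label)
  if (is.null(probes$snp_id)) probes$snp_id <- NA_character_
  if (is.null(probes$allele)) probes$allele <- NA_character_
  probes$exon_label[!nzchar(probes$exon_label) | is.na(probes$exon_label)] <-
    NA_character_
  probes$snp_id[!is.na(probes$snp_id) & !nzchar(probes$snp_id)] <- NA_character_
  probes$allele[!is.na(probes$allele) & !nzchar(probes$allele)] <- NA_character_
  genes <- unique(exons$gene)

  cj <- do.call(rbind, lapply(genes, function(g) {
    e <- exons[exons$gene == g & exons$in_canonical, , drop = FALSE]
    e <- e[order(e$ordinal), , drop = FALSE]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene = g, donor = e$label[-nrow(e)], acceptor = e$label[-1])
  }))
  if (is.null(cj))
    cj <- data.frame(gene = character(0), donor = character(0),
                     acceptor = character(0))

  obj <- new("ProbePanel", genes = genes, exons = exons, probes = probes,
             canonicalJunctions = cj, barcodes = barcodes,
             umiLength = as.integer(umiLength))
  validObject(obj)
  obj
}

#' Load a probe panel from a manifest
#'
#' Reads a YAML manifest pointing at tab-separated `exons`, `probes` and
#' `barcodes` tables (paths relative to the manifest), validates every panel
#' invariant, and returns a [ProbePanel-class]. Validation failures abort
#' with a diagnostic naming the offending record (duplicate probe sequences
#' are reported as an ambiguous panel, barcode pairs below the distance
#' floor as a barcode collision, dangling references as schema errors).
#'
#' @param manifest path to the panel `manifest.yaml`.
#' @return a validated `ProbePanel`.
#' @examples
#' p <- loadPanel(system.file("extdata/brca_panel/manifest.yaml",
#'                            package = "circLigate"))
#' panelSummary(p)
#' @export
loadPanel <- function(manifest) {
  if (!file.exists(manifest))
    stopf("schema error: panel manifest '%s' not found", manifest)
  cfg <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  rd <- function(key) {
    f <- file.path(dir, cfg$files[[key]])
    if (is.null(cfg$files[[key]]) || !file.exists(f))
      stopf("schema error: panel file for '%s' missing", key)
    read.delim(f, stringsAsFactors = FALSE, colClasses = "character")
  }
  exons <- rd("exons")
  probes <- rd("probes")
  bc <- rd("barcodes")
  probePanel(exons, probes, bc,
             umiLength = if (is.null(cfg$umi_length)) 7L else cfg$umi_length)
}

#' Serialize a panel back to manifest + TSV tables
#'
#' Inverse of [loadPanel()]: writes `manifest.yaml`, `exons.tsv`,
#' `probes.tsv` and `barcodes.tsv` into `dir` such that reloading yields an
#' identical panel.
#'
#' @param panel a `ProbePanel`.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
writePanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE, na = "")
  wr(panel@exons, "exons.tsv")
  wr(panel@probes, "probes.tsv")
  wr(data.frame(sample = names(panel@barcodes), barcode = panel@barcodes),
     "barcodes.tsv")
  mf <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(panel = "exported", umi_length = panel@umiLength,
                        files = list(exons = "exons.tsv", probes = "probes.tsv",
                                     barcodes = "barcodes.tsv")), mf)
  invisible(mf)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn probePanel gene identifiers of a panel
#' @param panel a `ProbePanel`.
#' @export
panelGenes <- function(panel) panel@genes

#' @describeIn probePanel exon table of a panel
#' @export
panelExons <- function(panel) panel@exons

#' @describeIn probePanel probe table of a panel
#' @export
panelProbes <- function(panel) panel@probes

#' @describeIn probePanel named barcode vector of a panel
#' @export
panelBarcodes <- function(panel) panel@barcodes

#' @describeIn probePanel UMI length of a panel
#' @export
umiLength <- function(panel) panel@umiLength

#' @describeIn probePanel canonical (adjacent, reference-transcript) splice
#'   junctions, as a data.frame of `gene`, `donor`, `acceptor`
#' @export
canonicalJunctions <- function(panel) panel@canonicalJunctions

#' Summarise a probe panel
#'
#' Counts probes per category and canonical junctions per gene.
#'
#' @param panel a `ProbePanel`.
#' @return a list with `n_junction`, `n_snp`, `n_intronic`, `n_total`,
#'   `n_canonical` (named per gene), `n_exons` (named per gene) and
#'   `umi_space` (number of distinct UMIs, `4^umiLength`).
#' @export
panelSummary <- function(panel) {
  pr <- panel@probes
  cj <- panel@canonicalJunctions
  list(
    n_junction = sum(pr$kind == "junction"),
    n_snp = sum(pr$kind == "snp_allele"),
    n_intronic = sum(pr$kind == "intronic"),
    n_total = nrow(pr),
    n_canonical = vapply(panel@genes, function(g) sum(cj$gene == g), integer(1)),
    n_exons = vapply(panel@genes, function(g) sum(panel@exons$gene == g),
                     integer(1)),
    umi_space = as.integer(4^panel@umiLength)
  )
}

setMethod("show", "ProbePanel", function(object) {
  s <- panelSummary(object)
  cat("ProbePanel:", paste(object@genes, collapse = ", "), "\n")
  cat(sprintf("  probes: %d (%d junction, %d snp_allele, %d intronic)\n",
              s$n_total, s$n_junction, s$n_snp, s$n_intronic))
  cat(sprintf("  canonical junctions: %s\n",
              paste(sprintf("%s=%d", names(s$n_canonical), s$n_canonical),
                    collapse = ", ")))
  cat(sprintf("  samples: %d barcodes; UMI length %d (%d combinations)\n",
              length(object@barcodes), object@umiLength, s$umi_space))
})

## ---- junction naming -------------------------------------------------------

#' Canonical name of a splice or backsplice junction
#'
#' Backsplice junctions are named `<gene>_circRNA_<donor>-<acceptor>`
#' (e.g. `BRCA1_circRNA_20-18`), linear junctions
#' `<gene>_mRNA_<donor>-<acceptor>`. The mapping is deterministic and
#' injective within a class.
#'
#' @param panel a `ProbePanel`.
#' @param gene gene identifier.
#' @param donor,acceptor exon labels (must exist in the gene).
#' @param class `"backsplice"` or a linear class.
#' @return the junction name string (vectorised over its arguments).
#' @examples
#' p <- loadPanel(system.file("extdata/brca_panel/manifest.yaml",
#'                            package = "circLigate"))
#' junctionName(p, "BRCA1", "20", "18", "backsplice")
#' @export
junctionName <- function(panel, gene, donor, acceptor, class = "backsplice") {
  key <- paste(panel@exons$gene, panel@exons$label)
  for (nm in c(donor, acceptor)) {
    bad <- !(paste(gene, c(donor, acceptor)) %in% key)
    if (any(bad))
      stopf("unknown exon label '%s' in gene %s",
            c(donor, acceptor)[bad][1], gene[1])
  }
  mid <- ifelse(class == "backsplice", "circRNA", "mRNA")
  sprintf("%s_%s_%s-%s", gene, mid, donor, acceptor)
}
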