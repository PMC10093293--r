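# Schematic splicing/backsplicing profile: exon boxes on a baseline,
# linear splice arcs above in green, backsplice arcs below in red,
# intronic-control signals as blue marks. Written as hand-assembled SVG so
# that identical inputs yield byte-identical documents (no timestamps,
# fixed element ordering, fixed number formatting).

.fmt <- function(x) sprintf("%.2f", x)

#' Render the splicing/backsplicing profile of a sample
#'
#' Draws the gene track (numbered exon boxes in ordinal order; alternative
#' exons unnumbered), linear splice junctions as green arcs above the
#' baseline, backsplices as red arcs below, and intronic-control signals
#' as blue marks, with arc apex heights scaled to the distinct-UMI counts
#' (square-root scaling by default). Junctions below `displayThreshold`
#' (relative to the gene's mean canonical UMI count) are suppressed from
#' the drawing but listed in the returned `suppressed` table -- nothing is
#' dropped silently.
#'
#' @param classified output of [classifyJunctions()].
#' @param panel a [ProbePanel-class].
#' @param sample,gene which sample and gene.
#' @param out optional SVG output path.
#' @param scale height scaling: `"sqrt"` (default), `"linear"` or `"log"`.
#' @param displayThreshold minimal relative abundance drawn (default
#'   0.001; set to 0 to draw everything).
#' @return invisibly, a list with `svg` (the document as one string),
#'   `arcs` (drawn junctions) and `suppressed` (junctions below the
#'   display threshold).
#' @export
renderProfile <- function(classified, panel, sample, gene, out = NULL,
                          scale = c("sqrt", "linear", "log"),
                          displayThreshold = 0.001) {
  scale <- match.arg(scale)
  ex <- panel@exons[panel@exons$gene == gene, , drop = FALSE]
  if (!nrow(ex)) stopf("unknown gene '%s'", gene)
  ex <- ex[order(ex$ordinal), , drop = FALSE]
  sub <- classified[classified$sample == sample &
                      !is.na(classified$gene) & classified$gene == gene, ,
                    drop = FALSE]

  boxW <- 26; gap <- 10; mar <- 30; boxH <- 18
  baseY <- 150; maxH <- 110
  x0 <- mar + (seq_len(nrow(ex)) - 1) * (boxW + gap)
  xl <- setNames(x0, ex$label)                 # left edge (acceptor side)
  xr <- setNames(x0 + boxW, ex$label)          # right edge (donor side)

  jx <- sub[sub$class %in% c("linear_canonical", "linear_alternative",
                             "backsplice"), , drop = FALSE]
  canon <- jx$umi_count[jx$class == "linear_canonical"]
  denom <- if (length(canon) && sum(canon) > 0) mean(canon) else NA_real_
  rel <- if (is.na(denom)) rep(1, nrow(jx)) else jx$umi_count / denom
  shown <- rel >= displayThreshold
  arcs <- jx[shown, , drop = FALSE]
  suppressed <- jx[!shown, , drop = FALSE]

  hFun <- switch(scale, sqrt = sqrt, linear = identity,
                 log = function(x) log1p(x))
  hRaw <- hFun(arcs$umi_count)
  h <- if (length(hRaw) && max(hRaw) > 0) maxH * hRaw / max(hRaw) else hRaw

  ord <- order(arcs$class, arcs$donor, arcs$acceptor)
  arcs <- arcs[ord, , drop = FALSE]
  h <- h[ord]

  intr <- sub[sub$class == "intronic_control", , drop = FALSE]
  width <- mar * 2 + nrow(ex) * (boxW + gap) + 60

  el <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="300" viewBox="0 0 %d 300">',
                  ceiling(width), ceiling(width)),
          sprintf('<title>%s %s splicing profile</title>', sample, gene))
  # gene track
  for (i in seq_len(nrow(ex))) {
    el <- c(el, sprintf('<rect x="%s" y="%s" width="%d" height="%d" fill="#d9d9d9" stroke="#333"/>',
                        .fmt(x0[i]), .fmt(baseY - boxH / 2), boxW, boxH))
    if (ex$in_canonical[i])
      el <- c(el, sprintf('<text x="%s" y="%s" font-size="9" text-anchor="middle">%s</text>',
                          .fmt(x0[i] + boxW / 2), .fmt(baseY + 4), ex$label[i]))
  }
  # arcs: linear above (green), backsplice below (red)
  for (i in seq_len(nrow(arcs))) {
    lin <- arcs$class[i] != "backsplice"
    xa <- xr[[arcs$donor[i]]]
    xb <- xl[[arcs$acceptor[i]]]
    apex <- if (lin) baseY - boxH / 2 - h[i] else baseY + boxH / 2 + h[i]
    y0 <- if (lin) baseY - boxH / 2 else baseY + boxH / 2
    col <- if (lin) "#1a9641" else "#d7191c"
    el <- c(el, sprintf('<path d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-width="1.2"><title>%s UMI=%d</title></path>',
                        .fmt(xa), .fmt(y0), .fmt((xa + xb) / 2), .fmt(apex),
                        .fmt(xb), .fmt(y0), col, arcs$name[i],
                        arcs$umi_count[i]))
  }
  # intronic-control signals, blue marks right of the track
  if (nrow(intr)) {
    intr <- intr[order(intr$left_probe_id, intr$right_probe_id), ,
                 drop = FALSE]
    for (i in seq_len(nrow(intr))) {
      x <- max(xr) + 14 + (i - 1) * 8
      hh <- hFun(intr$umi_count[i])
      hh <- if (hh > 0) min(maxH, 6 * hh) else 0
      el <- c(el, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#2c7fb8" stroke-width="3"><title>intronic %s/%s UMI=%d</title></line>',
                          .fmt(x), .fmt(baseY - boxH / 2),
                          .fmt(x), .fmt(baseY - boxH / 2 - hh),
                          intr$left_probe_id[i], intr$right_probe_id[i],
                          intr$umi_count[i]))
    }
  }
  # legend
  el <- c(el,
    '<text x="10" y="16" font-size="10" fill="#1a9641">splicing (above)</text>',
    '<text x="10" y="28" font-size="10" fill="#d7191c">backsplicing (below)</text>',
    '<text x="10" y="40" font-size="10" fill="#2c7fb8">intronic control</text>',
    sprintf('<text x="10" y="290" font-size="10">%s | %s | scale=%s</text>',
            sample, gene, scale),
    '</svg>')
  svg <- paste(el, collapse = "\n")
  if (!is.null(out)) writeLines(svg, out)
  invisible(list(svg = svg, arcs = arcs, suppressed = suppressed))
}
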