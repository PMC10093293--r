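panel: brca_circ_v1
description: >
  Exon-boundary ligation probe panel for BRCA1/BRCA2 linear and
  backsplice junction profiling. Probe and barcode sequences are
  SYNTHETIC placeholders; exon structure and probe composition mirror
  the assay design (114 junction, 30 SNP-allele, 3 intronic probes).
umi_length: 7
files:
  exons: exons.tsv
  probes: probes.tsv
  barcodes: barcodes.tsv
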