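# Signature registry: the two gene signatures under comparison plus the
# luminal/basal marker panels used for marker-separation scoring.

# 12 PCS1-specific genes (proliferation / cell-cycle program of the
# aggressive luminal subtype). This block is fixed by the source
# publications of the PCS scheme.
.PCS1_GENES <- c("STMN1", "MCM4", "CCNB1", "CDC6", "CDKN3", "EZH2",
                 "TPX2", "FOXM1", "KIF11", "HMMR", "MKI67", "KNTC1")

# The PCS2 (androgen-response luminal) and PCS3 (basal) blocks of the
# 37-gene signature. The full membership of these two blocks is not
# publicly printed alongside the PCS1 block; the lists below are a
# SYNTHETIC reconstruction from canonical prostate luminal
# (androgen-regulated) and basal lineage genes, chosen to preserve the
# documented signature structure: 37 genes total, three class-specific
# blocks, and an intersection with PAM50 of exactly CCNB1/CDC6/MKI67.
.PCS2_GENES <- c("KLK3", "KLK2", "NKX3-1", "TMPRSS2", "FOLH1", "NDRG1",
                 "ABCC4", "PMEPA1", "FKBP5", "SPDEF", "GNMT", "NANS",
                 "TRIM36")
.PCS3_GENES <- c("TP63", "KRT15", "DST", "COL17A1", "GPX2", "SNAI2",
                 "MYLK", "VCL", "ACTG2", "MYH11", "TAGLN", "LAMB3")

# Canonical 50-gene PAM50 panel (modern HGNC symbols: NDC80 = KNTC2,
# ORC6 = ORC6L).
.PAM50_GENES <- c(
  "ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1", "CCNE1",
  "CDC20", "CDC6", "CDH3", "CENPF", "CEP55", "CXXC5", "EGFR", "ERBB2",
  "ESR1", "EXO1", "FGFR4", "FOXA1", "FOXC1", "GPR160", "GRB7", "KIF2C",
  "KRT14", "KRT17", "KRT5", "MAPT", "MDM2", "MELK", "MIA", "MKI67",
  "MLPH", "MMP11", "MYBL2", "MYC", "NAT1", "NDC80", "NUF2", "ORC6",
  "PGR", "PHGDH", "PTTG1", "RRM2", "SFRP1", "SLC39A6", "TMEM45B",
  "TYMS", "UBE2C", "UBE2T")

# Class annotation of PAM50 genes used only by the synthetic generator to
# plant class-specific expression blocks (proliferation -> LumB, luminal
# differentiation -> LumA, basal lineage -> Basal).
.PAM50_LUMB_BLOCK <- c("ANLN", "BIRC5", "CCNB1", "CCNE1", "CDC20", "CDC6",
                       "CENPF", "CEP55", "EXO1", "KIF2C", "MELK", "MKI67",
                       "MYBL2", "NDC80", "NUF2", "ORC6", "PTTG1", "RRM2",
                       "TYMS", "UBE2C", "UBE2T")
.PAM50_LUMA_BLOCK <- c("BAG1", "BCL2", "BLVRA", "CXXC5", "ERBB2", "ESR1",
                       "FGFR4", "FOXA1", "GPR160", "GRB7", "MAPT", "MDM2",
                       "MLPH", "MMP11", "NAT1", "PGR", "SLC39A6",
                       "TMEM45B")
.PAM50_BASAL_BLOCK <- c("ACTR3B", "CDH3", "EGFR", "FOXC1", "KRT14",
                        "KRT17", "KRT5", "MIA", "MYC", "PHGDH", "SFRP1")

# Epithelial lineage marker panels for luminal/basal separation scoring.
.LUMINAL_MARKERS <- c("AR", "KLK3", "KLK2", "NKX3-1", "TMPRSS2", "FOLH1",
                      "MSMB", "ACPP")
.BASAL_MARKERS <- c("KRT5", "KRT14", "KRT17", "TP63", "ITGA6", "CD44",
                    "KIT", "DST")

#' Construct a gene signature object
#'
#' @param name signature name (e.g. `"PCS37"`).
#' @param genes character vector of unique gene symbols.
#' @param classes class labels the signature targets, ordered from most to
#'   least aggressive (the order is used as the deterministic argmax
#'   tie-break downstream).
#' @param gene_class optional named character vector annotating genes with
#'   a class-specific block.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, classes, gene_class = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(.norm_symbol(genes)))
    stop("duplicate gene symbols in signature '", name, "'")
  if (anyDuplicated(classes))
    stop("duplicate class labels in signature '", name, "'")
  structure(list(name = name, genes = genes, classes = classes,
                 gene_class = gene_class),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$genes), " genes, classes ",
      paste(x$classes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Built-in signature registry
#'
#' Returns the two subtyping signatures under comparison and the
#' luminal/basal epithelial marker panels:
#' \describe{
#'   \item{PCS37}{37 genes; classes PCS1 (aggressive luminal), PCS2
#'     (luminal), PCS3 (basal). The 12 PCS1-specific proliferation genes
#'     are the published block; the PCS2/PCS3 blocks are a synthetic
#'     reconstruction from canonical prostate luminal and basal genes
#'     (see the methods vignette).}
#'   \item{PAM50}{the canonical 50-gene panel, collapsed to the three
#'     classes retained in prostate cancer: LumB (aggressive luminal),
#'     LumA, Basal.}
#'   \item{luminal_markers / basal_markers}{epithelial lineage markers
#'     used by [marker_separation()].}
#' }
#'
#' Class label order encodes clinical aggressiveness (most aggressive
#' first) and is used as the deterministic tie-break in
#' [assign_subtypes()].
#'
#' @return named list with elements `PCS37`, `PAM50` (both
#'   `gene_signature`), `luminal_markers`, `basal_markers`.
#' @export
#' @examples
#' reg <- builtin_signatures()
#' length(reg$PCS37$genes)  # 37
#' signature_overlap(reg$PCS37, reg$PAM50)
builtin_signatures <- function() {
  pcs_genes <- c(.PCS1_GENES, .PCS2_GENES, .PCS3_GENES)
  pcs_ann <- setNames(rep(c("PCS1", "PCS2", "PCS3"),
                          c(length(.PCS1_GENES), length(.PCS2_GENES),
                            length(.PCS3_GENES))), pcs_genes)
  pam_ann <- setNames(rep(c("LumB", "LumA", "Basal"),
                          c(length(.PAM50_LUMB_BLOCK),
                            length(.PAM50_LUMA_BLOCK),
                            length(.PAM50_BASAL_BLOCK))),
                      c(.PAM50_LUMB_BLOCK, .PAM50_LUMA_BLOCK,
                        .PAM50_BASAL_BLOCK))
  list(
    PCS37 = gene_signature("PCS37", pcs_genes,
                           classes = c("PCS1", "PCS2", "PCS3"),
                           gene_class = pcs_ann),
    PAM50 = gene_signature("PAM50", .PAM50_GENES,
                           classes = c("LumB", "LumA", "Basal"),
                           gene_class = pam_ann[.PAM50_GENES]),
    luminal_markers = .LUMINAL_MARKERS,
    basal_markers = .BASAL_MARKERS
  )
}

#' Shared genes between two signatures
#'
#' Case-insensitive symbol intersection, returned sorted using the
#' casing of the first signature.
#'
#' @param sig_a,sig_b `gene_signature` objects.
#' @return sorted character vector of shared gene symbols.
#' @export
signature_overlap <- function(sig_a, sig_b) {
  a <- sig_a$genes
  shared <- a[.norm_symbol(a) %in% .norm_symbol(sig_b$genes)]
  sort(shared)
}
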