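#' Classify variants as pathogenic (P-SNV)
#'
#' A variant is a P-SNV iff its ClinVar label is pathogenic or likely
#' pathogenic, OR its OncoKB label is oncogenic, likely oncogenic or
#' predicted oncogenic (case-insensitive; spaces and slashes are
#' normalized to underscores). The annotation table is joined on
#' (gene, protein_change) with a genomic (chrom, pos, ref, alt)
#' fallback; unknown variants are `not_classified`.
#'
#' @param variants Table with gene and either protein_change or
#'   chrom/pos/ref/alt columns.
#' @param table Pathogenicity table: gene, protein_change, chrom, pos,
#'   ref, alt, clinvar_label, oncokb_label.
#' @return The variants table with added `clinvar_label`,
#'   `oncokb_label` and `pathogenic` (logical) columns.
#' @export
classify_pathogenic <- function(variants, table) {
  v <- data.table::copy(data.table::as.data.table(variants))
  tb <- data.table::as.data.table(table)
  norm <- function(x) gsub("[ /]+", "_", tolower(trimws(as.character(x))))
  clin_path <- c("pathogenic", "likely_pathogenic",
                 "pathogenic_likely_pathogenic")
  onco_path <- c("oncogenic", "likely_oncogenic", "predicted_oncogenic")

  cl <- rep(NA_character_, nrow(v)); ok <- rep(NA_character_, nrow(v))
  if (nrow(tb) > 0) {
    if (all(c("gene", "protein_change") %in% names(v)) &&
        all(c("gene", "protein_change") %in% names(tb))) {
      m <- match(paste(v$gene, v$protein_change),
                 paste(tb$gene, tb$protein_change))
      cl[!is.na(m)] <- as.character(tb$clinvar_label)[m[!is.na(m)]]
      ok[!is.na(m)] <- as.character(tb$oncokb_label)[m[!is.na(m)]]
    }
    gcols <- c("chrom", "pos", "ref", "alt")
    if (all(gcols %in% names(v)) && all(gcols %in% names(tb))) {
      todo <- is.na(cl) & is.na(ok)
      m <- match(paste(v$chrom, v$pos, v$ref, v$alt)[todo],
                 paste(tb$chrom, tb$pos, tb$ref, tb$alt))
      cl[todo][!is.na(m)] <- as.character(tb$clinvar_label)[m[!is.na(m)]]
      ok[todo][!is.na(m)] <- as.character(tb$oncokb_label)[m[!is.na(m)]]
    }
  }
  v[, clinvar_label := cl]
  v[, oncokb_label := ok]
  v[, pathogenic := (!is.na(cl) & norm(cl) %in% clin_path) |
      (!is.na(ok) & norm(ok) %in% onco_path)]
  v[]
}

#' Consensus candidate-deleterious rule for exome predictors
#'
#' TRUE only when all four in-silico predictors agree: PolyPhen-2
#' possibly/probably damaging AND SIFT deleterious AND CADD-MSC high
#' AND FATHMM-XF pathogenic. Any missing predictor fails the rule.
#'
#' @param scores A list or one-row data.frame with elements `polyphen`,
#'   `sift`, `cadd_msc`, `fathmm` (any may be missing/NA).
#' @return Logical scalar.
#' @export
classify_candidate_deleterious <- function(scores) {
  g <- function(k) {
    x <- scores[[k]]
    if (is.null(x) || length(x) == 0L || is.na(x)) return(NA_character_)
    gsub("[ /]+", "_", tolower(trimws(as.character(x))))
  }
  pp <- g("polyphen"); sf <- g("sift"); cd <- g("cadd_msc"); fm <- g("fathmm")
  !is.na(pp) && pp %in% c("possibly_damaging", "probably_damaging") &&
    !is.na(sf) && sf == "deleterious" &&
    !is.na(cd) && cd == "high" &&
    !is.na(fm) && fm == "pathogenic"
}

#' Default gene-set catalog
#'
#' Named gene sets used for pathway tagging and enrichment. The
#' classical MAPK set is the 15 RASopathy genes; the CML set is the
#' panel-relevant chronic-myeloid-leukemia members (the mutated MAPK
#' genes plus TEK, SMAD5, TP53); small DNA-repair and chromatin sets
#' cover the remaining recurrently hit pathways. Symbols are upper-cased
#' and deduplicated; user sets can be added or read from GMT.
#'
#' @param extra Optional named list of additional sets.
#' @return Named list of character vectors, class `gene_set_catalog`.
#' @export
gene_set_catalog <- function(extra = NULL) {
  sets <- list(
    classical_MAPK = classical_mapk_genes(),
    CML_KEGG = c("CBL", "BRAF", "RIT1", "NF1", "PTPN11", "KRAS",
                 "TEK", "SMAD5", "TP53"),
    DNA_repair = c("ATR", "SMC1A", "TP53", "BRCA1", "BRCA2", "ATM"),
    chromatin = c("TET2", "IDH2", "PBRM1", "DNMT3A", "EZH2"))
  if (!is.null(extra)) sets <- c(sets, extra)
  sets <- lapply(sets, function(g) unique(toupper(g)))
  structure(sets, class = "gene_set_catalog")
}

#' Read a gene-set catalog from a GMT file
#'
#' Standard GMT: one set per line, tab-separated: name, description,
#' then member genes.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_catalog`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(toupper(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  structure(sets, class = "gene_set_catalog")
}

#' Gene-set membership tags for a gene
#'
#' @param gene Gene symbol (case-insensitive).
#' @param catalog A [gene_set_catalog()].
#' @return Character vector of catalog set names containing the gene.
#' @export
assign_gene_sets <- function(gene, catalog = gene_set_catalog()) {
  g <- toupper(gene)
  names(catalog)[vapply(catalog, function(set) g %in% set, logical(1))]
}

#' Per-sample mutational burden (variants per Mb)
#'
#' Burden is the count of retained calls matching the selector divided
#' by the sample's sequenced footprint in Mb. Samples with no matching
#' calls get burden 0 (every sample in the metadata yields a row).
#'
#' @param callset Filtered, annotated call table (needs `retained`; the
#'   P_SNV selector needs `pathogenic`; gene-set selectors need `gene`).
#' @param samples Per-sample metadata with sample_id, donor_id,
#'   cell_type and panel_mb columns.
#' @param subset `"all_SNV"` (default), `"P_SNV"`, or a gene-set name
#'   from `catalog`.
#' @param catalog Optional [gene_set_catalog()] for gene-set selectors.
#' @param gene_list Optional explicit gene restriction applied on top of
#'   `subset` (e.g. genes expressed in the cell type of interest).
#' @return data.table: sample_id, donor_id, cell_type, subset,
#'   n_variants, panel_mb, burden.
#' @export
sample_burden <- function(callset, samples, subset = "all_SNV",
                          catalog = gene_set_catalog(), gene_list = NULL) {
  meta <- data.table::as.data.table(samples)
  if (any(meta$panel_mb <= 0))
    stop("panel footprint must be > 0", call. = FALSE)
  calls <- data.table::as.data.table(callset)
  if (nrow(calls) > 0 && "retained" %in% names(calls))
    calls <- calls[retained == TRUE]
  if (subset == "P_SNV") {
    calls <- calls[pathogenic == TRUE]
  } else if (subset != "all_SNV") {
    if (!subset %in% names(catalog))
      stop("unknown subset selector: ", subset, call. = FALSE)
    calls <- calls[pathogenic == TRUE & toupper(gene) %in% catalog[[subset]]]
  }
  if (!is.null(gene_list))
    calls <- calls[toupper(gene) %in% toupper(gene_list)]
  cnt <- calls[, .(n_variants = .N), by = sample_id]
  out <- merge(meta[, .(sample_id, donor_id, cell_type, panel_mb)],
               cnt, by = "sample_id", all.x = TRUE)
  out[is.na(n_variants), n_variants := 0L]
  subset_label <- subset
  out[, subset := subset_label]
  out[, burden := n_variants / panel_mb]
  data.table::setcolorder(out, c("sample_id", "donor_id", "cell_type",
                                 "subset", "n_variants", "panel_mb",
                                 "burden"))
  out[]
}

#' Donor-level burden: mean over a donor's samples per cell type
#'
#' Arithmetic mean of sample burdens within (donor, cell type, subset);
#' groups with no samples are simply absent.
#'
#' @param records Output of [sample_burden()].
#' @return data.table: donor_id, cell_type, subset, n_samples, burden.
#' @export
donor_burden <- function(records) {
  r <- data.table::as.data.table(records)
  out <- r[, .(n_samples = .N, burden = mean(burden)),
           by = .(donor_id, cell_type, subset)]
  out[]
}
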