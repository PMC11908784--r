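#' Write a pipeline artifact as TSV with a provenance header
#'
#' Tables are UTF-8, tab-separated, with a header row; lines starting
#' with `#` carry tool version, seed and config hash and are skipped on
#' read.
#'
#' @param x A data.frame/data.table.
#' @param path Output path.
#' @param seed Seed recorded in the header (may be NA).
#' @param config_hash Config hash recorded in the header (may be NA).
#' @return `path`, invisibly.
#' @export
write_artifact <- function(x, path, seed = NA, config_hash = NA) {
  hdr <- c(
    paste0("# mosaicall ", as.character(utils::packageVersion("mosaicall"))),
    paste0("# seed: ", seed),
    paste0("# config_hash: ", config_hash))
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(x, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a pipeline artifact written by [write_artifact()]
#'
#' @param path Path to the TSV.
#' @param required_cols Optional column names that must be present; a
#'   violation names the file and the first missing column.
#' @return A data.table.
#' @export
read_artifact <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 1L)
    stop("schema error in ", path, ": no header row", call. = FALSE)
  dt <- data.table::fread(text = paste(body, collapse = "\n"), sep = "\t")
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(dt))
    if (length(missing) > 0)
      stop("schema error in ", path, ": missing column '", missing[1], "'",
           call. = FALSE)
  }
  dt
}

# stable hash of a configuration (md5 of its deparsed form)
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Load and validate pipeline inputs from files
#'
#' Reads the pileup, metadata and auxiliary tables of the TSV dialect
#' written by [write_cohort()], checks required columns and the 1-based
#' coordinate convention, and assembles an in-memory bundle.
#'
#' @param dir Directory containing pileups.tsv, samples.tsv, and
#'   optionally pathogenicity.tsv, pop_af.tsv, indel_sites.tsv,
#'   truth.tsv.
#' @return A list shaped like a `cohort_bundle` (without config).
#' @export
load_inputs <- function(dir) {
  pu <- read_artifact(file.path(dir, "pileups.tsv"),
                      c("site_id", "chrom", "pos", "ref", "alt",
                        "sample_id", "depth_fwd", "depth_rev",
                        "alt_fwd", "alt_rev"))
  if (nrow(pu) == 0L) stop("no sites in pileup file", call. = FALSE)
  if (any(pu$pos < 1)) stop("coordinates must be 1-based", call. = FALSE)
  samples <- read_artifact(file.path(dir, "samples.tsv"),
                           c("sample_id", "donor_id", "cell_type",
                             "region", "age", "sex", "status", "panel_mb"))
  sites <- unique(pu[, .(site_id, chrom, pos, ref, alt)])
  if ("gene" %in% names(pu))
    sites <- unique(pu[, .(site_id, chrom, pos, ref, alt, gene)])
  pileups <- structure(list(
    counts = pu[, .(site_id, sample_id, depth_fwd, depth_rev,
                    alt_fwd, alt_rev)],
    sites = sites, samples = samples), class = "pileup_set")
  opt <- function(f, cols) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_artifact(p, cols) else NULL
  }
  list(pileups = pileups, samples = samples,
       pathogenicity = opt("pathogenicity.tsv",
                           c("gene", "clinvar_label", "oncokb_label")),
       pop_af = opt("pop_af.tsv", c("chrom", "pos", "ref", "alt", "af")),
       indel_sites = opt("indel_sites.tsv", c("chrom", "pos")),
       truth = opt("truth.tsv", c("site_id", "category")))
}

#' Write a cohort bundle to a directory of TSV artifacts
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- bundle$config$seed
  h <- .config_hash(bundle$config)
  pu <- merge(bundle$pileups$counts, bundle$pileups$sites, by = "site_id",
              sort = FALSE)
  data.table::setcolorder(pu, c("site_id", "chrom", "pos", "ref", "alt",
                                "gene", "sample_id", "depth_fwd",
                                "depth_rev", "alt_fwd", "alt_rev"))
  data.table::setorder(pu, sample_id, pos)
  write_artifact(pu, file.path(dir, "pileups.tsv"), seed, h)
  write_artifact(bundle$samples, file.path(dir, "samples.tsv"), seed, h)
  write_artifact(bundle$truth, file.path(dir, "truth.tsv"), seed, h)
  write_artifact(bundle$pathogenicity, file.path(dir, "pathogenicity.tsv"),
                 seed, h)
  write_artifact(bundle$pop_af, file.path(dir, "pop_af.tsv"), seed, h)
  write_artifact(bundle$indel_sites, file.path(dir, "indel_sites.tsv"),
                 seed, h)
  invisible(dir)
}

#' Run the full analysis pipeline on a cohort bundle
#'
#' Stages: call -> filter -> annotate -> burden -> group statistics ->
#' mixed model -> enrichment. Writes calls.tsv, filtered_calls.tsv,
#' annotated_calls.tsv, burden_samples.tsv, burden_donors.tsv,
#' stats.json and manifest.json under `outdir`. Re-running with the
#' same bundle and seed reproduces identical tables.
#'
#' @param bundle A `cohort_bundle` (from [simulate_cohort()] or
#'   [load_inputs()] plus a config).
#' @param outdir Output directory.
#' @param design A [background_design()].
#' @param fconfig A [filter_config()].
#' @param catalog A [gene_set_catalog()].
#' @param q_cutoff Calling FDR threshold.
#' @return Invisibly, a list with the in-memory stage results
#'   (`calls`, `filtered`, `annotated`, `burden_samples`,
#'   `burden_donors`, `stats`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(bundle, outdir, design = background_design(),
                         fconfig = filter_config(),
                         catalog = gene_set_catalog(),
                         q_cutoff = 0.01) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(bundle$config)) bundle$config$seed else NA
  h <- if (!is.null(bundle$config)) .config_hash(bundle$config) else NA
  manifest <- list(seed = seed, config_hash = h,
                   version = as.character(utils::packageVersion("mosaicall")),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      completed = TRUE,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    r
  }

  calls <- t_stage("call", call_variants(bundle$pileups, design, q_cutoff))
  filtered <- t_stage("filter", apply_filters(
    calls, bundle$pileups, fconfig, bundle$pop_af, bundle$indel_sites))
  annotated <- t_stage("annotate",
                       classify_pathogenic(filtered, bundle$pathogenicity))
  bs <- t_stage("burden", {
    rbind(sample_burden(annotated, bundle$samples, "all_SNV"),
          sample_burden(annotated, bundle$samples, "P_SNV", catalog))
  })
  bd <- donor_burden(bs)

  stats_out <- t_stage("stats", {
    meta <- data.table::as.data.table(bundle$samples)
    ct <- if (!is.null(bundle$config)) bundle$config$clone_cell_type else
      "microglia"
    bsx <- merge(bs[subset == "P_SNV" & cell_type == ct],
                 unique(meta[, .(donor_id, age, sex, status)]),
                 by = "donor_id")
    bdx <- merge(bd[subset == "P_SNV" & cell_type == ct],
                 unique(meta[, .(donor_id, age, sex, status)]),
                 by = "donor_id")
    grp <- split(bdx$burden, bdx$status)
    two_group <- if (length(grp) == 2L) compare_groups(grp) else NULL
    carriers <- bdx[, .(donor_id, status, age, sex,
                        carrier = burden > 0)]
    logistic <- tryCatch(carrier_logistic(carriers),
                         error = function(e) conditionMessage(e))
    mixed <- tryCatch(burden_mixed_model(bsx),
                      error = function(e) conditionMessage(e))
    list(two_group = two_group, logistic = logistic, mixed = mixed)
  })

  enr <- t_stage("enrich", {
    hits <- unique(annotated[retained == TRUE & pathogenic == TRUE,
                             toupper(gene)])
    bg <- unique(toupper(bundle$pileups$sites$gene))
    if (length(hits) > 0) enrich_pathways(hits, catalog, bg) else NULL
  })

  t_stage("write", {
    write_artifact(calls, file.path(outdir, "calls.tsv"), seed, h)
    write_artifact(filtered, file.path(outdir, "filtered_calls.tsv"),
                   seed, h)
    write_artifact(annotated, file.path(outdir, "annotated_calls.tsv"),
                   seed, h)
    write_artifact(bs, file.path(outdir, "burden_samples.tsv"), seed, h)
    write_artifact(bd, file.path(outdir, "burden_donors.tsv"), seed, h)
    if (!is.null(enr))
      write_artifact(enr, file.path(outdir, "enrichment.tsv"), seed, h)
    sj <- list(
      two_group = if (!is.null(stats_out$two_group))
        stats_out$two_group[c("method", "statistic", "p")] else NULL,
      logistic = if (inherits(stats_out$logistic, "logistic_result"))
        stats_out$logistic$coefficients else stats_out$logistic,
      mixed = if (inherits(stats_out$mixed, "mixed_model_result"))
        list(fixed_effects = as.list(stats_out$mixed$fixed_effects),
             conditional_r2 = stats_out$mixed$conditional_r2,
             lrt = stats_out$mixed$lrt) else stats_out$mixed)
    jsonlite::write_json(sj, file.path(outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE)
  invisible(list(calls = calls, filtered = filtered, annotated = annotated,
                 burden_samples = bs, burden_donors = bd,
                 stats = stats_out, enrichment = enr, manifest = manifest))
}
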