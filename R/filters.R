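#' Post-calling filter thresholds
#'
#' The fixed cascade applied after calling: germline removal by pooled
#' VAF (> 20% of all reads across the pooling scope), minimum coverage
#' 50x, VAF window (0.3%, 35%], at least 4 alt reads, at least one
#' supporting read on each strand, no indel within 10 bp, population
#' minor allele frequency below 0.01, and q <= 0.01.
#'
#' @param germline_pooled_vaf_max Pooled-VAF germline threshold (0.20).
#' @param min_coverage Minimum depth at the call (50).
#' @param max_vaf Maximum VAF retained (0.35).
#' @param min_vaf Minimum VAF retained (0.003).
#' @param min_alt_reads Minimum alt reads (4).
#' @param require_both_strands Require >= 1 alt read per strand (TRUE).
#' @param indel_window Exclusion window around indels, bp, inclusive (10).
#' @param pop_af_max Population-AF cutoff (0.01).
#' @param q_max FDR cutoff (0.01).
#' @param germline_scope `"donor"` (default) pools reads across the
#'   call's donor's samples for the germline rule; `"cohort"` pools
#'   across all samples.
#' @return A validated list of class `filter_config`.
#' @export
filter_config <- function(germline_pooled_vaf_max = 0.20,
                          min_coverage = 50, max_vaf = 0.35,
                          min_vaf = 0.003, min_alt_reads = 4,
                          require_both_strands = TRUE,
                          indel_window = 10, pop_af_max = 0.01,
                          q_max = 0.01,
                          germline_scope = c("donor", "cohort")) {
  germline_scope <- match.arg(germline_scope)
  if (!(min_vaf > 0 && min_vaf < max_vaf && max_vaf <= 1))
    stop("need 0 < min_vaf < max_vaf <= 1", call. = FALSE)
  if (min_coverage < 1) stop("min_coverage must be >= 1", call. = FALSE)
  if (indel_window < 0) stop("indel_window must be >= 0", call. = FALSE)
  structure(list(germline_pooled_vaf_max = germline_pooled_vaf_max,
                 min_coverage = min_coverage, max_vaf = max_vaf,
                 min_vaf = min_vaf, min_alt_reads = min_alt_reads,
                 require_both_strands = require_both_strands,
                 indel_window = indel_window, pop_af_max = pop_af_max,
                 q_max = q_max, germline_scope = germline_scope),
            class = "filter_config")
}

#' Pooled variant allele fraction at a site
#'
#' Total alt reads over total depth across samples (all samples, or a
#' subset given by `sample_ids`); 0 when total depth is 0.
#'
#' @param pileups A `pileup_set`.
#' @param site A site_id present in the pileups.
#' @param sample_ids Optional subset of samples to pool over.
#' @return A proportion.
#' @export
pooled_vaf <- function(pileups, site, sample_ids = NULL) {
  counts <- pileups$counts
  rows <- counts[site_id == site]
  if (nrow(rows) == 0L) stop("unknown site: ", site, call. = FALSE)
  if (!is.null(sample_ids)) rows <- rows[sample_id %in% sample_ids]
  tot <- sum(rows$depth_fwd + rows$depth_rev)
  if (tot == 0) return(0)
  sum(rows$alt_fwd + rows$alt_rev) / tot
}

#' Is a position within `window` bp of an indel?
#'
#' Inclusive at exactly `window` bp; both coordinates 1-based on the
#' same contig.
#'
#' @param pos Position(s) to test.
#' @param indel_pos Indel positions on the same contig (any order).
#' @param window Window in bp.
#' @return Logical vector.
#' @export
near_indel <- function(pos, indel_pos, window = 10) {
  if (length(indel_pos) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) min(abs(p - indel_pos)) <= window, logical(1))
}

#' Apply the post-calling filter cascade
#'
#' Annotates every call with the full set of filter flags it fails
#' (`germline`, `low_coverage`, `high_vaf`, `low_vaf`, `few_alt_reads`,
#' `strand`, `near_indel`, `common_population_allele`, `fdr`); the
#' retained set is exactly the calls with an empty flag set. Flags are
#' computed independently, so evaluation order is irrelevant. Calls at
#' sites absent from the population-AF table are treated as AF 0.
#'
#' @param callset Call table from [call_variants()] or [merge_callsets()].
#' @param pileups The `pileup_set` the calls came from (for pooled VAF).
#' @param config A [filter_config()].
#' @param pop_af Optional table chrom/pos/ref/alt/af.
#' @param indel_sites Optional table chrom/pos of indel positions.
#' @return The call table with added `filter_flags` (semicolon-joined,
#'   "" when clean) and logical `retained` columns.
#' @export
apply_filters <- function(callset, pileups, config = filter_config(),
                          pop_af = NULL, indel_sites = NULL) {
  calls <- data.table::copy(data.table::as.data.table(callset))
  if (nrow(calls) == 0L) {
    calls[, `:=`(filter_flags = character(0), retained = logical(0))]
    return(calls[])
  }
  if (any(!calls$site_id %in% pileups$sites$site_id))
    stop("call at a site absent from the pileups", call. = FALSE)

  counts <- pileups$counts
  # pooled VAF per site within the configured scope
  if (config$germline_scope == "donor") {
    smeta <- pileups$samples[, .(sample_id, donor_id)]
    cc <- merge(counts, smeta, by = "sample_id")
    pool <- cc[, .(pv = {
      tot <- sum(depth_fwd + depth_rev)
      if (tot == 0) 0 else sum(alt_fwd + alt_rev) / tot
    }), by = .(site_id, donor_id)]
    calls <- merge(calls, smeta, by = "sample_id", all.x = TRUE,
                   sort = FALSE, suffixes = c("", ".meta"))
    if (!"donor_id" %in% names(calls))
      stop("donor-scope germline rule needs sample metadata", call. = FALSE)
    calls <- merge(calls, pool, by = c("site_id", "donor_id"),
                   all.x = TRUE, sort = FALSE)
  } else {
    pool <- counts[, .(pv = {
      tot <- sum(depth_fwd + depth_rev)
      if (tot == 0) 0 else sum(alt_fwd + alt_rev) / tot
    }), by = site_id]
    calls <- merge(calls, pool, by = "site_id", all.x = TRUE, sort = FALSE)
  }
  calls[is.na(pv), pv := 0]

  af <- rep(0, nrow(calls))
  if (!is.null(pop_af) && nrow(pop_af) > 0) {
    pa <- data.table::as.data.table(pop_af)
    key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
    m <- match(key, paste(pa$chrom, pa$pos, pa$ref, pa$alt))
    af[!is.na(m)] <- pa$af[m[!is.na(m)]]
  }
  near <- rep(FALSE, nrow(calls))
  if (!is.null(indel_sites) && nrow(indel_sites) > 0) {
    ind <- data.table::as.data.table(indel_sites)
    for (ch in unique(calls$chrom)) {
      sel <- calls$chrom == ch
      near[sel] <- near_indel(calls$pos[sel], ind[chrom == ch, pos],
                              config$indel_window)
    }
  }

  flag <- list(
    germline = calls$pv > config$germline_pooled_vaf_max,
    low_coverage = calls$depth < config$min_coverage,
    high_vaf = calls$vaf > config$max_vaf,
    low_vaf = calls$vaf <= config$min_vaf,
    few_alt_reads = calls$alt_reads < config$min_alt_reads,
    strand = if (config$require_both_strands)
      (calls$alt_fwd < 1 | calls$alt_rev < 1) else rep(FALSE, nrow(calls)),
    near_indel = near,
    common_population_allele = af >= config$pop_af_max,
    fdr = if ("q" %in% names(calls))
      (!is.na(calls$q) & calls$q > config$q_max) else rep(FALSE, nrow(calls)))
  fm <- do.call(cbind, flag)
  fm[is.na(fm)] <- FALSE
  calls[, filter_flags := apply(fm, 1L, function(r)
    paste(names(flag)[r], collapse = ";"))]
  calls[, retained := filter_flags == ""]
  calls[, pv := NULL]
  calls[]
}

#' Merge call sets from two callers
#'
#' Union on the call identity key (sample_id, chrom, pos, ref, alt) with
#' a `provenance` field ("A", "B" or "both"); per-call statistics are
#' kept from caller A when both called. Two calls sharing
#' (sample, chrom, pos, alt) but disagreeing on the reference allele are
#' a data-integrity error.
#'
#' @param a,b Call tables.
#' @param labels Length-2 provenance labels (default `c("A", "B")`).
#' @return Merged call table with a `provenance` column.
#' @export
merge_callsets <- function(a, b, labels = c("A", "B")) {
  a <- data.table::copy(data.table::as.data.table(a))
  b <- data.table::copy(data.table::as.data.table(b))
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt)
  loose <- function(d) paste(d$sample_id, d$chrom, d$pos, d$alt)
  ka <- key(a); kb <- key(b)
  if (any(loose(b) %in% loose(a) & !(kb %in% ka)))
    stop("data-integrity error: conflicting ref alleles at the same key",
         call. = FALSE)
  a[, provenance := ifelse(ka %in% kb, "both", labels[1])]
  bonly <- b[!(kb %in% ka)]
  if (nrow(bonly) > 0) bonly[, provenance := labels[2]]
  out <- data.table::rbindlist(list(a, bonly), fill = TRUE)
  out[]
}
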