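#' Background design: which cell types form each test's "normal" panel
#'
#' Each sorted population is tested against a pool of the *other*
#' populations, mirroring the design used with brain-sorted nuclei
#' (microglia vs neurons+glia, glia vs neurons+microglia, neurons vs
#' microglia+glia, blood vs neurons+glia). A test cell type must never
#' appear in its own background pool.
#'
#' @param design Named list mapping each test cell type to the character
#'   vector of cell types pooled as its background. Default: the
#'   four-population brain/blood design above.
#' @return A validated list of class `background_design`.
#' @export
background_design <- function(design = list(
    microglia = c("neuron", "glia"),
    glia = c("neuron", "microglia"),
    neuron = c("microglia", "glia"),
    blood = c("neuron", "glia"))) {
  if (is.null(names(design)) || any(names(design) == ""))
    stop("design must be a named list", call. = FALSE)
  for (ct in names(design)) {
    if (ct %in% design[[ct]])
      stop("cell type '", ct, "' is a member of its own background pool",
           call. = FALSE)
  }
  structure(design, class = "background_design")
}

# site x sample matrices of combined-strand alt counts and depths
.pileup_matrices <- function(pileups) {
  counts <- pileups$counts
  site_ids <- pileups$sites$site_id
  sample_ids <- pileups$samples$sample_id
  si <- match(counts$site_id, site_ids)
  sj <- match(counts$sample_id, sample_ids)
  S <- length(site_ids); M <- length(sample_ids)
  X <- matrix(0, S, M, dimnames = list(site_ids, sample_ids))
  N <- matrix(0, S, M, dimnames = list(site_ids, sample_ids))
  X[cbind(si, sj)] <- counts$alt_fwd + counts$alt_rev
  N[cbind(si, sj)] <- counts$depth_fwd + counts$depth_rev
  list(X = X, N = N)
}

#' Call somatic variants with the site-specific error model
#'
#' For each cell-type batch, fits the per-site beta-binomial background
#' error model on the pooled "normal" samples and tests every
#' (site, test sample) for an excess of alt reads by a one-sided
#' likelihood-ratio test; p-values are Benjamini-Hochberg adjusted
#' within the batch (all site x sample tests of one cell type form one
#' family) and calls with `q <= q_cutoff` are emitted.
#'
#' The default `method = "fast"` path estimates per-site rho by maximum
#' likelihood on the background pool with pooled-proportion plug-in rate
#' estimates (the estimator used by deep error-model callers in this
#' field); rho is shared between null and alternative so the statistic
#' is referred to chi-square with 1 df, halved for one-sidedness. In the
#' rho -> 0 limit this is exactly the binomial likelihood-ratio test.
#' `method = "full"` instead calls [lrt_one_sample()] per test (full
#' joint ML; exact but slow, intended for small data and cross-checks).
#'
#' @param pileups A `pileup_set`.
#' @param design A [background_design()].
#' @param q_cutoff FDR threshold for emitting calls (default 0.01).
#' @param method `"fast"` (default) or `"full"`; see Details.
#' @param keep_all If `TRUE`, return all tests (with their p and q),
#'   not only those passing `q_cutoff`. Used for calibration checks.
#' @return A `data.table` call set: site_id, chrom, pos, ref, alt,
#'   sample_id, vaf, alt_reads, depth, alt_fwd, alt_rev, lambda, p, q,
#'   caller.
#' @export
call_variants <- function(pileups, design = background_design(),
                          q_cutoff = 0.01,
                          method = c("fast", "full"),
                          keep_all = FALSE) {
  method <- match.arg(method)
  samples <- pileups$samples
  sites <- pileups$sites
  mats <- .pileup_matrices(pileups)
  X <- mats$X; N <- mats$N
  test_types <- intersect(names(design), unique(samples$cell_type))

  res <- list()
  for (ct in test_types) {
    test_ids <- samples[cell_type == ct, sample_id]
    bg_ids <- samples[cell_type %in% design[[ct]], sample_id]
    if (length(bg_ids) < 2L)
      stop("configuration error: background pool for cell type '", ct,
           "' has fewer than 2 samples", call. = FALSE)
    ti <- match(test_ids, colnames(X)); bi <- match(bg_ids, colnames(X))

    if (method == "fast") {
      b <- .bb_call_batch_cpp(X, N, bi - 1L, ti - 1L)
      lam <- b$lambda; pv <- b$p; mut <- b$mu_test; mub <- b$mu_bg
    } else {
      S <- nrow(X)
      lam <- pv <- mut <- mub <- matrix(NA_real_, S, length(ti))
      for (s in seq_len(S)) {
        for (t in seq_along(ti)) {
          r <- lrt_one_sample(X[s, ti[t]], N[s, ti[t]], X[s, bi], N[s, bi])
          lam[s, t] <- r$lambda; pv[s, t] <- r$p
          mut[s, t] <- if (is.na(r$mu_hat_test)) 0 else r$mu_hat_test
          mub[s, t] <- r$mu_hat_background
        }
      }
    }
    q <- matrix(bh_adjust(as.vector(pv)), nrow = nrow(pv))
    dt <- data.table::data.table(
      site_id = rep(rownames(X), times = length(ti)),
      sample_id = rep(test_ids, each = nrow(X)),
      vaf = as.vector(X[, ti, drop = FALSE] / pmax(N[, ti, drop = FALSE], 1)),
      alt_reads = as.vector(X[, ti, drop = FALSE]),
      depth = as.vector(N[, ti, drop = FALSE]),
      lambda = as.vector(lam), p = as.vector(pv), q = as.vector(q))
    res[[ct]] <- if (keep_all) dt else dt[q <= q_cutoff]
  }
  calls <- data.table::rbindlist(res)
  if (nrow(calls) == 0L) {
    calls <- data.table::data.table(
      site_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), sample_id = character(),
      vaf = numeric(), alt_reads = numeric(), depth = numeric(),
      alt_fwd = numeric(), alt_rev = numeric(), lambda = numeric(),
      p = numeric(), q = numeric(), caller = character())
    return(calls[])
  }
  calls <- merge(calls, sites, by = "site_id", sort = FALSE)
  strands <- pileups$counts[, .(site_id, sample_id, alt_fwd, alt_rev)]
  calls <- merge(calls, strands, by = c("site_id", "sample_id"),
                 all.x = TRUE, sort = FALSE)
  calls[, caller := "error_model"]
  data.table::setcolorder(calls, c("site_id", "chrom", "pos", "ref", "alt",
                                   "sample_id", "vaf", "alt_reads", "depth",
                                   "alt_fwd", "alt_rev", "lambda", "p", "q",
                                   "caller"))
  data.table::setorder(calls, sample_id, pos)
  calls[]
}
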