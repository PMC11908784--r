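# Fixture builders; everything is generated in code at test time.

# a pileup_set built directly from alt/depth matrices (sites x samples);
# strand counts split deterministically (ceiling/floor) unless alt == 1,
# which goes to the forward strand
make_pileups <- function(X, N, cell_types, donors = NULL) {
  S <- nrow(X); M <- ncol(X)
  site_ids <- sprintf("S%03d", seq_len(S))
  sample_ids <- sprintf("SAMP%02d", seq_len(M))
  if (is.null(donors)) donors <- sprintf("D%02d", seq_len(M))
  sites <- data.table::data.table(
    site_id = site_ids, chrom = "chr1", pos = 1000L + 50L * seq_len(S),
    ref = "A", alt = "T", gene = rep(c("BRAF", "PANEL0001"),
                                     length.out = S))
  samples <- data.table::data.table(
    sample_id = sample_ids, donor_id = donors, cell_type = cell_types,
    region = "cortex", age = 70, sex = "F", status = "case",
    panel_mb = 3.44)
  idx <- expand.grid(s = seq_len(S), m = seq_len(M))
  alt <- X[cbind(idx$s, idx$m)]
  dep <- N[cbind(idx$s, idx$m)]
  af <- ceiling(alt / 2)
  dfwd <- pmax(ceiling(dep / 2), af)  # fwd depth always >= fwd alt
  counts <- data.table::data.table(
    site_id = site_ids[idx$s], sample_id = sample_ids[idx$m],
    depth_fwd = dfwd, depth_rev = dep - dfwd,
    alt_fwd = af, alt_rev = alt - af)
  structure(list(counts = counts, sites = sites, samples = samples),
            class = "pileup_set")
}

# small cohort config used by several files; overridable
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_donors_case = 4L, n_donors_control = 3L,
                   samples_per_donor = 1L, n_sites = 200L,
                   mean_depth = 1000, seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}
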