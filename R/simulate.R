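#' Configuration for a synthetic deep-sequencing cohort
#'
#' Describes the stated world the generator emulates: a case/control
#' cohort of donors, each contributing sorted cell populations
#' (microglia, neurons, glia, blood) deep-sequenced (~1100x) over a
#' targeted gene panel, with per-site error rates drawn from a beta
#' prior, germline heterozygous sites shared within a donor, and somatic
#' clones (VAF window 0.3--35%, defaults 1--6%) planted with cell-type
#' specificity and a case/control carrier effect.
#'
#' @param n_donors_case,n_donors_control Donors per arm (defaults 45/27,
#'   the AD/control split of the cohort this generator emulates).
#' @param cell_types Sorted populations per donor.
#' @param samples_per_donor Samples per donor per cell type (e.g. two
#'   brain regions).
#' @param n_sites Panel sites simulated.
#' @param n_genes Genes the sites are spread over (default 716; the
#'   first 15 genes are the classical MAPK set).
#' @param panel_footprint_mb Sequenced footprint per sample, Mb.
#' @param mean_depth Mean coverage (default 1100).
#' @param depth_dispersion Excess depth dispersion d: depth is negative
#'   binomial with variance `m + d * m^2`; 0 means constant depth.
#' @param error_prior_mean,error_prior_dispersion Mean (in (0, 0.01])
#'   and overdispersion of the beta prior from which per-site error
#'   rates are drawn.
#' @param error_site_dispersion Between-sample beta-binomial
#'   overdispersion of alt counts at a site (0 = pure binomial).
#' @param germline_het_fraction Fraction of sites that are common-SNP
#'   positions at which donors may be heterozygous.
#' @param clone_vaf_range Planted somatic-clone VAF window (low, high).
#' @param carrier_prob_case,carrier_prob_control Probability that a
#'   donor in each arm carries pathogenic clone(s).
#' @param clones_per_carrier Integer range (lo, hi) of clones per
#'   carrier donor.
#' @param clone_cell_type Cell type in which pathogenic clones are
#'   planted (default microglia).
#' @param mapk_fraction Probability that a planted clone falls in a
#'   classical-MAPK-pathway gene.
#' @param strand_bias Offset added to the fair 0.5 forward-strand
#'   probability of alt reads (default 0; used to exercise the strand
#'   filter).
#' @param age_range Donor ages are uniform on this interval (years).
#' @param seed Integer RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_donors_case = 45L, n_donors_control = 27L,
                              cell_types = c("microglia", "neuron",
                                             "glia", "blood"),
                              samples_per_donor = 2L,
                              n_sites = 2000L, n_genes = 716L,
                              panel_footprint_mb = 3.44,
                              mean_depth = 1100, depth_dispersion = 0.28,
                              error_prior_mean = 1e-3,
                              error_prior_dispersion = 2e-3,
                              error_site_dispersion = 0,
                              germline_het_fraction = 0.05,
                              clone_vaf_range = c(0.01, 0.06),
                              carrier_prob_case = 0.44,
                              carrier_prob_control = 0.15,
                              clones_per_carrier = c(1L, 3L),
                              clone_cell_type = "microglia",
                              mapk_fraction = 0.5,
                              strand_bias = 0,
                              age_range = c(60, 95),
                              seed = 1L) {
  cfg <- list(n_donors_case = as.integer(n_donors_case),
              n_donors_control = as.integer(n_donors_control),
              cell_types = cell_types,
              samples_per_donor = as.integer(samples_per_donor),
              n_sites = as.integer(n_sites), n_genes = as.integer(n_genes),
              panel_footprint_mb = panel_footprint_mb,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              error_prior_mean = error_prior_mean,
              error_prior_dispersion = error_prior_dispersion,
              error_site_dispersion = error_site_dispersion,
              germline_het_fraction = germline_het_fraction,
              clone_vaf_range = clone_vaf_range,
              carrier_prob_case = carrier_prob_case,
              carrier_prob_control = carrier_prob_control,
              clones_per_carrier = as.integer(clones_per_carrier),
              clone_cell_type = clone_cell_type,
              mapk_fraction = mapk_fraction,
              strand_bias = strand_bias,
              age_range = age_range, seed = as.integer(seed))
  probs <- c(cfg$carrier_prob_case, cfg$carrier_prob_control,
             cfg$germline_het_fraction, cfg$mapk_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  if (cfg$panel_footprint_mb <= 0)
    stop("panel_footprint_mb must be > 0", call. = FALSE)
  if (cfg$error_prior_mean <= 0 || cfg$error_prior_mean > 0.01)
    stop("error_prior_mean must be in (0, 0.01]", call. = FALSE)
  if (length(cfg$clone_vaf_range) != 2L ||
      cfg$clone_vaf_range[1] > cfg$clone_vaf_range[2] ||
      cfg$clone_vaf_range[1] < 0 || cfg$clone_vaf_range[2] > 1)
    stop("clone_vaf_range must be (low, high) within [0, 1]", call. = FALSE)
  if (!cfg$clone_cell_type %in% cfg$cell_types)
    stop("clone_cell_type must be one of cell_types", call. = FALSE)
  if (cfg$depth_dispersion < 0 || cfg$error_site_dispersion < 0)
    stop("dispersions must be >= 0", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Classical MAPK pathway (RASopathy) gene set
#'
#' The 15 genes recurrently mutated in RASopathies, used as the default
#' "classical MAPK" gene set and as the preferred target of planted
#' pathogenic clones in the synthetic cohort.
#' @return Character vector of gene symbols.
#' @export
classical_mapk_genes <- function() {
  c("BRAF", "CBL", "KRAS", "MAP2K1", "NF1", "PTPN11", "SOS1", "RIT1",
    "SHOC2", "NRAS", "RAF1", "RASA1", "HRAS", "MAP2K2", "SPRED1")
}

.sim_gene_names <- function(n_genes) {
  mapk <- classical_mapk_genes()
  if (n_genes <= length(mapk)) return(mapk[seq_len(n_genes)])
  c(mapk, sprintf("PANEL%04d", seq_len(n_genes - length(mapk))))
}

# deterministic sample/site scaffolds (no RNG)
.sim_samples <- function(cfg) {
  donors <- c(sprintf("CASE%03d", seq_len(cfg$n_donors_case)),
              sprintf("CTRL%03d", seq_len(cfg$n_donors_control)))
  status <- rep(c("case", "control"),
                c(cfg$n_donors_case, cfg$n_donors_control))
  grid <- data.table::CJ(donor_id = donors, cell_type = cfg$cell_types,
                         rep = seq_len(cfg$samples_per_donor),
                         sorted = FALSE)
  grid[, sample_id := paste(donor_id, cell_type, rep, sep = "_")]
  grid <- merge(grid, data.table::data.table(donor_id = donors,
                                             status = status),
                by = "donor_id", sort = FALSE)
  data.table::setcolorder(grid, c("sample_id", "donor_id", "cell_type",
                                  "rep", "status"))
  grid[]
}

.sim_sites <- function(cfg) {
  genes <- .sim_gene_names(cfg$n_genes)
  bases <- c("A", "C", "G", "T")
  i <- seq_len(cfg$n_sites)
  ref <- bases[((i - 1L) %% 4L) + 1L]
  alt <- bases[(i %% 4L) + 1L]
  data.table::data.table(
    site_id = sprintf("S%06d", i), chrom = "chr1",
    pos = 1000000L + 50L * i, ref = ref, alt = alt,
    gene = rep(genes, length.out = cfg$n_sites))
}

#' Draw per-site background error rates from a beta prior
#'
#' @param n_sites Number of sites.
#' @param prior_mean Mean error rate, in (0, 0.01].
#' @param prior_dispersion Overdispersion rho of the beta prior
#'   (shape `a = mean * (1/rho - 1)`); must be > 0. Values below 1e-12
#'   behave as a point mass at `prior_mean`.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Numeric vector of `n_sites` error rates in (0, 1).
#' @export
simulate_error_profile <- function(n_sites, prior_mean, prior_dispersion,
                                   seed = NULL) {
  if (n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  if (prior_mean <= 0 || prior_mean > 0.01)
    stop("prior_mean must be in (0, 0.01]", call. = FALSE)
  if (prior_dispersion <= 0)
    stop("prior_dispersion must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (prior_dispersion < 1e-12) return(rep(prior_mean, n_sites))
  s <- 1 / prior_dispersion - 1
  stats::rbeta(n_sites, prior_mean * s, (1 - prior_mean) * s)
}

#' Simulate background pileup counts for a cohort
#'
#' For each (site, sample): total depth is negative binomial around
#' `mean_depth`; alt reads are beta-binomial at the site's error rate
#' (between-sample overdispersion `error_site_dispersion`); every read
#' is assigned a strand by a fair coin (plus optional `strand_bias` for
#' alt reads), so per-strand alt never exceeds per-strand depth.
#'
#' @param error_profile Per-site error rates
#'   (length `sim_config$n_sites`).
#' @param sim_config A [simulation_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A `pileup_set`: list with `counts` (long data.table of
#'   per-site, per-sample strand counts), `sites`, and `samples` tables.
#' @export
simulate_pileups <- function(error_profile, sim_config, seed = NULL) {
  cfg <- sim_config
  if (length(error_profile) != cfg$n_sites)
    stop("error profile length must equal n_sites", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  samples <- .sim_samples(cfg)
  sites <- .sim_sites(cfg)
  ns <- nrow(sites); nsam <- nrow(samples)
  m <- ns * nsam

  depth <- if (cfg$depth_dispersion == 0) {
    rep(as.integer(round(cfg$mean_depth)), m)
  } else {
    stats::rnbinom(m, mu = cfg$mean_depth, size = 1 / cfg$depth_dispersion)
  }
  e <- rep(error_profile, times = nsam)
  p <- if (cfg$error_site_dispersion == 0) e else {
    s <- 1 / cfg$error_site_dispersion - 1
    ifelse(e <= 0, 0, stats::rbeta(m, e * s, pmax((1 - e) * s, 1e-12)))
  }
  alt <- stats::rbinom(m, depth, p)
  alt_fwd <- stats::rbinom(m, alt, min(max(0.5 + cfg$strand_bias, 0), 1))
  ref_fwd <- stats::rbinom(m, depth - alt, 0.5)
  counts <- data.table::data.table(
    site_id = rep(sites$site_id, times = nsam),
    sample_id = rep(samples$sample_id, each = ns),
    depth_fwd = alt_fwd + ref_fwd,
    depth_rev = (depth - alt) - ref_fwd + (alt - alt_fwd),
    alt_fwd = alt_fwd,
    alt_rev = alt - alt_fwd)
  structure(list(counts = counts, sites = sites, samples = samples,
                 error_profile = error_profile),
            class = "pileup_set")
}

# redraw alt reads at a target rate for selected (site, sample) pairs,
# replacing the background draw so the expected VAF is exact
.redraw_alt <- function(counts, idx, rate, strand_p = 0.5) {
  depth <- counts$depth_fwd[idx] + counts$depth_rev[idx]
  alt <- stats::rbinom(length(idx), depth, rate)
  alt_fwd <- stats::rbinom(length(idx), alt, strand_p)
  ref_fwd <- stats::rbinom(length(idx), depth - alt, 0.5)
  data.table::set(counts, idx, "alt_fwd", alt_fwd)
  data.table::set(counts, idx, "alt_rev", alt - alt_fwd)
  data.table::set(counts, idx, "depth_fwd", alt_fwd + ref_fwd)
  data.table::set(counts, idx, "depth_rev", depth - alt_fwd - ref_fwd)
  invisible(counts)
}

#' Plant germline heterozygous sites and somatic clones
#'
#' Germline: a fixed subset of sites are common-SNP positions with a
#' population allele frequency drawn uniform on (0.1, 0.5); each donor
#' is heterozygous there with probability `2 p (1 - p)`, and a
#' heterozygous donor shows VAF ~= 0.5 in every one of their samples.
#' Somatic: each donor is a pathogenic-clone carrier with probability
#' `carrier_prob_case` / `carrier_prob_control` by arm; carriers get
#' 1--3 clones, each at a VAF drawn from `clone_vaf_range`, restricted
#' to the donor's samples of `clone_cell_type`, preferentially (with
#' probability `mapk_fraction`) in classical-MAPK genes. Alt counts at
#' affected entries are redrawn binomially at the target rate, so the
#' expected VAF equals the planted VAF exactly.
#'
#' @param pileups A `pileup_set` from [simulate_pileups()].
#' @param sim_config The matching [simulation_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return List with elements `pileups` (modified copy) and `truth`
#'   (data.table of planted records: donor_id, sample_ids, site_id, alt,
#'   true_vaf, category, pathogenic_flag, gene, plus pop_af for
#'   germline sites).
#' @export
plant_clones <- function(pileups, sim_config, seed = NULL) {
  cfg <- sim_config
  if (!is.null(seed)) set.seed(seed)
  counts <- data.table::copy(pileups$counts)
  sites <- pileups$sites
  samples <- pileups$samples
  data.table::setkey(counts, site_id, sample_id)
  donors <- unique(samples[, .(donor_id, status)])

  truth <- list()

  # germline heterozygous common-SNP sites
  n_het_sites <- round(cfg$germline_het_fraction * cfg$n_sites)
  het_sites <- if (n_het_sites > 0)
    sort(sample(cfg$n_sites, n_het_sites)) else integer(0)
  het_maf <- stats::runif(length(het_sites), 0.1, 0.5)
  for (k in seq_along(het_sites)) {
    sid <- sites$site_id[het_sites[k]]
    het <- donors$donor_id[stats::runif(nrow(donors)) <
                             2 * het_maf[k] * (1 - het_maf[k])]
    for (d in het) {
      sam <- samples[donor_id == d, sample_id]
      idx <- counts[.(sid, sam), which = TRUE]
      .redraw_alt(counts, idx, 0.5)
      truth[[length(truth) + 1L]] <- data.table::data.table(
        donor_id = d, sample_ids = paste(sam, collapse = ","),
        site_id = sid, alt = sites$alt[het_sites[k]],
        true_vaf = 0.5, category = "germline_het",
        pathogenic_flag = FALSE, gene = sites$gene[het_sites[k]],
        pop_af = het_maf[k])
    }
  }

  # somatic clones in carrier donors
  mapk_sites <- setdiff(which(sites$gene %in% classical_mapk_genes()),
                        het_sites)
  other_sites <- setdiff(seq_len(cfg$n_sites),
                         c(het_sites, mapk_sites))
  carrier_p <- ifelse(donors$status == "case",
                      cfg$carrier_prob_case, cfg$carrier_prob_control)
  is_carrier <- stats::runif(nrow(donors)) < carrier_p
  for (i in which(is_carrier)) {
    d <- donors$donor_id[i]
    k <- sample(seq(cfg$clones_per_carrier[1], cfg$clones_per_carrier[2]), 1L)
    sam <- samples[donor_id == d & cell_type == cfg$clone_cell_type,
                   sample_id]
    if (length(sam) == 0L) next
    for (j in seq_len(k)) {
      use_mapk <- length(mapk_sites) > 0 &&
        stats::runif(1) < cfg$mapk_fraction
      pool <- if (use_mapk) mapk_sites else other_sites
      if (length(pool) == 0L) pool <- other_sites
      si <- pool[sample(length(pool), 1L)]
      vaf <- stats::runif(1, cfg$clone_vaf_range[1], cfg$clone_vaf_range[2])
      if (vaf > 1) stop("clone VAF above 1", call. = FALSE)
      sid <- sites$site_id[si]
      idx <- counts[.(sid, sam), which = TRUE]
      .redraw_alt(counts, idx, vaf,
                  strand_p = min(max(0.5 + cfg$strand_bias, 0), 1))
      truth[[length(truth) + 1L]] <- data.table::data.table(
        donor_id = d, sample_ids = paste(sam, collapse = ","),
        site_id = sid, alt = sites$alt[si], true_vaf = vaf,
        category = "somatic_clone", pathogenic_flag = TRUE,
        gene = sites$gene[si], pop_af = 0)
    }
  }
  truth <- if (length(truth)) data.table::rbindlist(truth) else
    data.table::data.table(donor_id = character(), sample_ids = character(),
                           site_id = character(), alt = character(),
                           true_vaf = numeric(), category = character(),
                           pathogenic_flag = logical(), gene = character(),
                           pop_af = numeric())
  out <- pileups
  out$counts <- counts
  list(pileups = out, truth = truth)
}

#' Simulate a complete synthetic cohort bundle
#'
#' Runs the full generator under one seed: donor metadata (age uniform
#' on `age_range`, sex, case/control status), per-site error profile,
#' background pileups, planted germline hets and somatic clones, plus
#' the auxiliary tables the downstream pipeline consumes (pathogenicity
#' annotations for planted clones with decoy rows, population allele
#' frequencies for germline sites, indel positions near a few sites,
#' panel definition). Identical config implies byte-identical tables.
#'
#' @param sim_config A [simulation_config()].
#' @return A list of class `cohort_bundle`: `pileups`, `truth`,
#'   `samples` (per-sample metadata incl. age/sex/status/region/panel_mb),
#'   `donors`, `pathogenicity`, `pop_af`, `indel_sites`, `config`.
#' @export
simulate_cohort <- function(sim_config) {
  cfg <- sim_config
  if (cfg$n_donors_case + cfg$n_donors_control < 1L)
    stop("configuration error: zero donors in both arms", call. = FALSE)
  set.seed(cfg$seed)

  profile <- simulate_error_profile(cfg$n_sites, cfg$error_prior_mean,
                                    cfg$error_prior_dispersion)
  pileups <- simulate_pileups(profile, cfg)
  planted <- plant_clones(pileups, cfg)
  pileups <- planted$pileups
  truth <- planted$truth

  donors <- unique(pileups$samples[, .(donor_id, status)])
  donors[, age := stats::runif(.N, cfg$age_range[1], cfg$age_range[2])]
  donors[, sex := sample(c("M", "F"), .N, replace = TRUE)]
  samples <- merge(pileups$samples, donors[, .(donor_id, age, sex)],
                   by = "donor_id", sort = FALSE)
  samples[, region := ifelse(cell_type == "blood", "blood",
                             c("cortex", "hippocampus")[(rep - 1L) %% 2L + 1L])]
  samples[, panel_mb := cfg$panel_footprint_mb]
  data.table::setcolorder(samples, c("sample_id", "donor_id", "cell_type",
                                     "region", "age", "sex", "status",
                                     "panel_mb"))
  pileups$samples <- samples

  sites <- pileups$sites
  # pathogenicity annotations: planted clones -> pathogenic labels,
  # plus benign/VUS decoys at random unplanted sites
  planted_somatic <- unique(truth[category == "somatic_clone", site_id])
  pato <- merge(data.table::data.table(site_id = planted_somatic),
                sites, by = "site_id")
  pato <- pato[, .(gene, protein_change = paste0("p.", ref, pos %% 997 + 1,
                                                 alt),
                   chrom, pos, ref, alt,
                   clinvar_label = "Pathogenic", oncokb_label = "")]
  decoy_pool <- setdiff(sites$site_id, c(planted_somatic,
                                         unique(truth$site_id)))
  n_decoy <- min(length(decoy_pool), 50L)
  if (n_decoy > 0) {
    dec <- merge(data.table::data.table(
      site_id = sample(decoy_pool, n_decoy)), sites, by = "site_id")
    dec <- dec[, .(gene, protein_change = paste0("p.", ref, pos %% 997 + 1,
                                                 alt),
                   chrom, pos, ref, alt,
                   clinvar_label = sample(c("Benign",
                                            "Uncertain_significance"),
                                          .N, replace = TRUE),
                   oncokb_label = "")]
    pato <- rbind(pato, dec)
  }

  pop_af <- merge(unique(truth[category == "germline_het",
                               .(site_id, af = pop_af)]),
                  sites, by = "site_id")[, .(chrom, pos, ref, alt, af)]

  # indel positions planted 5 bp from a few non-planted sites so that
  # the proximity filter has true work to do
  indel_pool <- setdiff(sites$site_id, unique(truth$site_id))
  n_indel <- min(length(indel_pool), max(1L, round(0.005 * cfg$n_sites)))
  indel_sites <- merge(data.table::data.table(
    site_id = sample(indel_pool, n_indel)), sites,
    by = "site_id")[, .(chrom, pos = pos + 5L)]

  structure(list(pileups = pileups, truth = truth, samples = samples,
                 donors = donors, pathogenicity = pato, pop_af = pop_af,
                 indel_sites = indel_sites, config = cfg),
            class = "cohort_bundle")
}
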