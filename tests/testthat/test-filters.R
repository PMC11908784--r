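test_that("pooled_vaf arithmetic", {
  X <- matrix(c(50, 50, 0, 0, 10, 0), nrow = 3, byrow = TRUE)
  N <- matrix(c(100, 100, 100, 300, 100, 300), nrow = 3, byrow = TRUE)
  pu <- make_pileups(X, N, cell_types = c("microglia", "neuron"))
  expect_equal(pooled_vaf(pu, "S001"), 0.5)
  expect_equal(pooled_vaf(pu, "S002"), 0)
  expect_equal(pooled_vaf(pu, "S003"), 10 / 400)
  expect_error(pooled_vaf(pu, "S999"), "unknown site")
})

test_that("near_indel boundary convention is inclusive", {
  expect_true(near_indel(100, 110, 10))
  expect_false(near_indel(100, 111, 10))
  expect_identical(near_indel(c(5, 100), integer(0), 10), c(FALSE, FALSE))
})

test_that("filter thresholds flag the worked examples", {
  # one call per threshold violation, one clean call
  X <- matrix(2, 6, 4); N <- matrix(1000, 6, 4)
  X[1, 1] <- 4;  N[1, 1] <- 40    # low coverage (depth 40 < 50)
  X[2, 1] <- 400; N[2, 1] <- 1000 # VAF 0.40 > 0.35
  X[3, 1] <- 3                    # 3 alt reads < 4
  X[4, 1] <- 2; N[4, 1] <- 1000   # VAF 0.002 <= 0.003
  X[5, 1] <- 30                   # clean: VAF 0.03, both strands
  X[6, 1] <- 30                   # will be near an indel
  pu <- make_pileups(X, N, cell_types = c("microglia", rep("neuron", 3)))
  calls <- data.table::data.table(
    site_id = sprintf("S%03d", 1:6), chrom = "chr1",
    pos = pu$sites$pos, ref = "A", alt = "T",
    sample_id = "SAMP01",
    vaf = X[, 1] / N[, 1], alt_reads = X[, 1], depth = N[, 1],
    alt_fwd = ceiling(X[, 1] / 2), alt_rev = floor(X[, 1] / 2),
    q = 1e-5)
  indels <- data.table::data.table(chrom = "chr1",
                                   pos = pu$sites$pos[6] + 10L)
  f <- apply_filters(calls, pu, filter_config(), indel_sites = indels)
  flags <- setNames(f$filter_flags, f$site_id)
  expect_match(flags[["S001"]], "low_coverage")
  expect_match(flags[["S002"]], "high_vaf")
  expect_match(flags[["S003"]], "few_alt_reads")
  expect_match(flags[["S004"]], "low_vaf")
  expect_identical(flags[["S005"]], "")
  expect_match(flags[["S006"]], "near_indel")
  expect_identical(f[f$site_id == "S005"]$retained, TRUE)
})

test_that("germline rule uses pooled VAF and strand rule needs both strands", {
  # site 1: VAF 0.5 in all samples of the donor -> germline
  # site 2: all alt reads on one strand -> strand flag
  X <- matrix(0, 2, 4); N <- matrix(1000, 2, 4)
  X[1, ] <- 500
  X[2, 1] <- 9
  pu <- make_pileups(X, N, cell_types = c("microglia", rep("neuron", 3)),
                     donors = rep("D01", 4))
  # force single-strand support at site 2
  pu$counts[site_id == "S002" & sample_id == "SAMP01",
            `:=`(alt_fwd = 9L, alt_rev = 0L)]
  calls <- data.table::data.table(
    site_id = c("S001", "S002"), chrom = "chr1", pos = pu$sites$pos,
    ref = "A", alt = "T", sample_id = "SAMP01",
    vaf = c(0.5, 0.009), alt_reads = c(500, 9), depth = 1000,
    alt_fwd = c(250L, 9L), alt_rev = c(250L, 0L), q = 1e-6)
  f <- apply_filters(calls, pu, filter_config())
  expect_match(f$filter_flags[f$site_id == "S001"], "germline")
  expect_match(f$filter_flags[f$site_id == "S002"], "strand")
})

test_that("population-AF filter; missing entries treated as AF 0", {
  X <- matrix(0, 2, 4); N <- matrix(1000, 2, 4); X[, 1] <- 30
  pu <- make_pileups(X, N, cell_types = c("microglia", rep("neuron", 3)))
  calls <- data.table::data.table(
    site_id = c("S001", "S002"), chrom = "chr1", pos = pu$sites$pos,
    ref = "A", alt = "T", sample_id = "SAMP01", vaf = 0.03,
    alt_reads = 30, depth = 1000, alt_fwd = 15L, alt_rev = 15L, q = 1e-6)
  pop <- data.table::data.table(chrom = "chr1", pos = pu$sites$pos[1],
                                ref = "A", alt = "T", af = 0.05)
  f <- apply_filters(calls, pu, filter_config(), pop_af = pop)
  expect_match(f$filter_flags[f$site_id == "S001"],
               "common_population_allele")
  expect_identical(f$filter_flags[f$site_id == "S002"], "")
})

test_that("apply_filters equals the brute-force predicate conjunction", {
  set.seed(31)
  cfg <- filter_config()
  for (rep in 1:5) {
    S <- 15; M <- 6
    X <- matrix(rbinom(S * M, 500, 0.02), S, M)
    N <- matrix(sample(c(30, 400, 1200), S * M, replace = TRUE), S, M)
    X <- pmin(X, N)
    pu <- make_pileups(X, N, cell_types = rep(c("microglia", "neuron"),
                                              each = 3),
                       donors = rep(c("D01", "D02"), 3))
    j <- 1L
    calls <- data.table::data.table(
      site_id = pu$sites$site_id, chrom = "chr1", pos = pu$sites$pos,
      ref = "A", alt = "T", sample_id = "SAMP01",
      vaf = X[, j] / N[, j], alt_reads = X[, j], depth = N[, j],
      alt_fwd = ceiling(X[, j] / 2), alt_rev = floor(X[, j] / 2),
      q = runif(S)^2)
    indels <- data.table::data.table(
      chrom = "chr1", pos = sample(pu$sites$pos, 3) + sample(0:15, 3))
    pop <- data.table::data.table(
      chrom = "chr1", pos = sample(pu$sites$pos, 4), ref = "A", alt = "T",
      af = runif(4, 0, 0.03))
    f <- apply_filters(calls, pu, cfg, pop, indels)

    # independent predicate-by-predicate evaluation
    don <- pu$samples$donor_id[match("SAMP01", pu$samples$sample_id)]
    dsam <- pu$samples$sample_id[pu$samples$donor_id == don]
    for (i in seq_len(S)) {
      sid <- pu$sites$site_id[i]
      pv <- pooled_vaf(pu, sid, dsam)
      afv <- pop$af[match(pu$sites$pos[i], pop$pos)]
      afv <- if (is.na(afv)) 0 else afv
      want <- c(
        germline = pv > cfg$germline_pooled_vaf_max,
        low_coverage = N[i, j] < cfg$min_coverage,
        high_vaf = X[i, j] / N[i, j] > cfg$max_vaf,
        low_vaf = X[i, j] / N[i, j] <= cfg$min_vaf,
        few_alt_reads = X[i, j] < cfg$min_alt_reads,
        strand = ceiling(X[i, j] / 2) < 1 || floor(X[i, j] / 2) < 1,
        near_indel = near_indel(pu$sites$pos[i], indels$pos,
                                cfg$indel_window),
        common_population_allele = afv >= cfg$pop_af_max,
        fdr = calls$q[i] > cfg$q_max)
      got <- strsplit(f$filter_flags[f$site_id == sid], ";")[[1]]
      expect_setequal(got, names(want)[want])
      expect_identical(f$retained[f$site_id == sid], !any(want))
    }
  }
})

test_that("loosening a single threshold never removes a retained call", {
  set.seed(32)
  S <- 20
  X <- matrix(rbinom(S * 4, 800, 0.01), S, 4)
  N <- matrix(800, S, 4)
  pu <- make_pileups(X, N, cell_types = c("microglia", rep("neuron", 3)))
  calls <- data.table::data.table(
    site_id = pu$sites$site_id, chrom = "chr1", pos = pu$sites$pos,
    ref = "A", alt = "T", sample_id = "SAMP01",
    vaf = X[, 1] / N[, 1], alt_reads = X[, 1], depth = N[, 1],
    alt_fwd = ceiling(X[, 1] / 2), alt_rev = floor(X[, 1] / 2),
    q = runif(S)^3)
  base <- apply_filters(calls, pu, filter_config())
  looser <- list(filter_config(min_coverage = 10),
                 filter_config(min_alt_reads = 1),
                 filter_config(max_vaf = 0.9),
                 filter_config(min_vaf = 1e-4),
                 filter_config(q_max = 0.5),
                 filter_config(germline_pooled_vaf_max = 0.5))
  for (cfg in looser) {
    f <- apply_filters(calls, pu, cfg)
    expect_true(all(f$retained[base$retained]))
  }
})

test_that("merge_callsets reproduces the union arithmetic", {
  mk <- function(n, offset) data.table::data.table(
    sample_id = "SAMP01", chrom = "chr1",
    pos = offset + seq_len(n), ref = "A", alt = "T", vaf = 0.01)
  overlap <- 111; onlyA <- 428 - overlap; onlyB <- 509 - overlap
  a <- rbind(mk(onlyA, 0), mk(overlap, 10000))
  b <- rbind(mk(onlyB, 50000), mk(overlap, 10000))
  m <- merge_callsets(a, b)
  expect_equal(nrow(m), 826)
  expect_equal(sum(m$provenance == "both"), 111)
  expect_equal(nrow(a) + nrow(b) - overlap, nrow(m))

  # disjoint and identical sets
  expect_equal(nrow(merge_callsets(mk(5, 0), mk(7, 1000))), 12)
  mm <- merge_callsets(mk(5, 0), mk(5, 0))
  expect_equal(nrow(mm), 5)
  expect_true(all(mm$provenance == "both"))

  # conflicting ref at the same key
  b2 <- mk(3, 0); b2$ref <- "G"
  expect_error(merge_callsets(mk(3, 0), b2), "integrity")
})
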