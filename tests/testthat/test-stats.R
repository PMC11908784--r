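test_that("Mann-Whitney exact worked examples", {
  r <- compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)

  ri <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ri$p, 1)
})

test_that("Mann-Whitney exact p equals permutation enumeration", {
  set.seed(41)
  for (rep in 1:8) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    v <- sample(1:100, n1 + n2)  # distinct values, no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    r <- compare_groups(list(x = x, y = y))
    expect_equal(r$p, mw_exact_enum(x, y), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis on two groups matches the z^2 identity", {
  set.seed(42)
  x <- rnorm(12); y <- rnorm(15) + 0.5
  kd <- compare_groups(list(a = x, b = y), method = "kruskal_dunn")
  # chi-square_1 = z^2 relation between KW and the normal-approx MW
  z <- sqrt(kd$statistic)
  expect_equal(kd$pairwise$p[1], 2 * pnorm(-z), tolerance = 1e-9)
  expect_equal(kd$p, pchisq(z^2, 1, lower.tail = FALSE), tolerance = 1e-9)
})

test_that("group comparison input validation", {
  expect_error(compare_groups(list(a = 1:3)), "2 groups")
  expect_error(compare_groups(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("correlate: perfect monotone association and oracle check", {
  expect_equal(correlate(1:10, (1:10)^3)$coefficient, 1)
  expect_equal(correlate(1:10, -(1:10)^3)$coefficient, -1)
  x <- c(1, 2, 2, 4, 5); y <- c(2, 1, 4, 4, 7)
  r <- correlate(x, y)
  expect_equal(r$coefficient, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "constant")
  rp <- correlate(1:8, c(2, 1, 4, 3, 6, 5, 8, 7), method = "pearson")
  expect_equal(rp$coefficient, cor(1:8, c(2, 1, 4, 3, 6, 5, 8, 7)))
})

test_that("carrier logistic reproduces the closed-form 2x2 odds ratio", {
  mk <- function(case_c, case_n, ctrl_c, ctrl_n) data.table::data.table(
    status = rep(c("case", "control"), c(case_c + case_n, ctrl_c + ctrl_n)),
    carrier = c(rep(c(TRUE, FALSE), c(case_c, case_n)),
                rep(c(TRUE, FALSE), c(ctrl_c, ctrl_n))))
  d <- mk(20, 25, 4, 23)
  fit <- carrier_logistic(d, status ~ carrier)
  or <- fit$coefficients[term == "carrierTRUE"]$or
  expect_equal(or, (20 * 23) / (25 * 4), tolerance = 1e-6)
  expect_equal(or, 4.6, tolerance = 1e-6)
  lo <- fit$coefficients[term == "carrierTRUE"]$ci_lo
  hi <- fit$coefficients[term == "carrierTRUE"]$ci_hi
  expect_true(lo <= or && or <= hi)

  # random 2x2 tables without separation
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(5:30, 4, replace = TRUE)
    d <- mk(n[1], n[2], n[3], n[4])
    fit <- carrier_logistic(d, status ~ carrier)
    expect_equal(fit$coefficients[term == "carrierTRUE"]$estimate,
                 log((n[1] * n[4]) / (n[2] * n[3])), tolerance = 1e-6)
  }
})

test_that("balanced carriers give OR ~ 1; separation raises an error", {
  set.seed(45)
  d <- data.table::data.table(
    status = rep(c("case", "control"), each = 40),
    carrier = rep(c(TRUE, FALSE), 40),
    age = runif(80, 60, 90), sex = sample(c("M", "F"), 80, TRUE))
  fit <- carrier_logistic(d)
  expect_equal(fit$coefficients[term == "carrierTRUE"]$or, 1,
               tolerance = 0.3)
  dsep <- data.table::data.table(
    status = rep(c("case", "control"), each = 20),
    carrier = rep(c(TRUE, FALSE), each = 20))
  expect_error(carrier_logistic(dsep, status ~ carrier), "separation")
})

test_that("mixed model recovers a noise-free planted structure", {
  d <- data.table::CJ(donor_id = sprintf("d%02d", 1:20), rep = 1:2)
  d[, status := rep(c(1, 0), each = 20)]
  d[, age := 0]
  d[, burden := 0.1 + 0.2 * status]
  # noise-free data: lmer convergence checks warn about the singular fit
  m <- suppressWarnings(burden_mixed_model(d, fixed = c("status", "age")))
  expect_equal(unname(m$fixed_effects["(Intercept)"]), 0.1,
               tolerance = 1e-6)
  expect_equal(unname(m$fixed_effects["status"]), 0.2, tolerance = 1e-6)
  expect_lt(m$ranef_sd, 1e-4)
  expect_true(m$lrt[term == "status"]$significant)
  expect_error(burden_mixed_model(d[donor_id == "d01"]), "2 donors")
})

test_that("mixed-model LRT is invariant to affine rescaling of age", {
  set.seed(46)
  d <- data.table::CJ(donor_id = sprintf("d%02d", 1:24), rep = 1:2)
  d[, status := rep(c(1, 0), each = 24)]
  d[, age := rep(runif(24, 60, 95), each = 2)]
  d[, burden := 0.1 + 0.1 * status + 0.002 * age +
      rep(rnorm(24, 0, 0.05), each = 2) + rnorm(.N, 0, 0.05)]
  m1 <- burden_mixed_model(d)
  d2 <- data.table::copy(d)[, age := 10 * age + 5]
  m2 <- burden_mixed_model(d2)
  expect_equal(m1$lrt$statistic, m2$lrt$statistic, tolerance = 1e-4)
  expect_true(m1$conditional_r2 >= 0 && m1$conditional_r2 <= 1)
})

test_that("mixed-model disease LRT holds its nominal type-I error", {
  set.seed(47)
  nrep <- 500
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    d <- data.table::CJ(donor_id = sprintf("d%02d", 1:36), rep = 1:2)
    d[, status := rep(c(1, 0), each = 36)]
    d[, age := 0]
    d[, burden := 0.1 + rep(rnorm(36, 0, 0.05), each = 2) +
        rnorm(.N, 0, 0.05)]
    m <- burden_mixed_model(d, fixed = "status")
    rej[r] <- m$lrt[term == "status"]$p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("hypergeometric enrichment matches enumeration and flag rules", {
  bg <- sprintf("G%02d", 1:20)
  cat <- structure(list(setA = bg[1:5]), class = "gene_set_catalog")
  hits <- c(bg[1:3], bg[10:12])  # overlap 3 of 6 hits
  r <- enrich_pathways(hits, cat, bg)
  expect_equal(r$p, 5090 / 38760, tolerance = 1e-12)
  expect_equal(r$p, hyper_tail_enum(3, 5, 20, 6), tolerance = 1e-12)
  expect_equal(r$p, 1 - phyper(2, 5, 15, 6), tolerance = 1e-12)
  expect_equal(r$enrichment_factor, 3 / (6 * 5 / 20))
  expect_false(r$reported)  # k and factor qualify but p = 0.131 >= 0.05
})

test_that("enrichment reported flag needs p, count and factor together", {
  bg <- sprintf("G%02d", 1:40)
  cat <- structure(list(setA = bg[1:4], setB = bg[5:20]),
                   class = "gene_set_catalog")
  # overlap 0 -> p = 1
  r0 <- enrich_pathways(bg[21:24], cat, bg)
  expect_true(all(r0$p[r0$k == 0] == 1))
  # overlap 2 with small p still not reported (minimum count 3)
  r2 <- enrich_pathways(bg[c(1, 2, 30)], cat, bg)
  row <- r2[r2$set == "setA"]
  expect_equal(row$k, 2)
  expect_lt(row$p, 0.05)
  expect_false(row$reported)
  expect_error(enrich_pathways("G01", cat, character(0)), "background")
  expect_warning(enrich_pathways(c("G01", "NOTINBG"), cat, bg), "dropped")
})
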