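#' Nonparametric group comparisons
#'
#' Two groups: unpaired two-tailed Mann-Whitney U (exact when the
#' combined sample size is <= 20 and there are no ties, normal
#' approximation with tie correction otherwise). More than two groups
#' (or `method = "kruskal_dunn"`): Kruskal-Wallis plus Dunn pairwise
#' z-tests with Benjamini-Hochberg adjustment.
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param method `"mann_whitney"` or `"kruskal_dunn"`.
#' @return For Mann-Whitney: list with `method`, `statistic` (U), `p`,
#'   `group_sizes`, `direction`. For Kruskal-Dunn: list with the
#'   Kruskal-Wallis `statistic`, `df`, `p`, and a `pairwise` data.table
#'   (group1, group2, z, p, q).
#' @export
compare_groups <- function(values_by_group,
                           method = c("mann_whitney", "kruskal_dunn")) {
  method <- match.arg(method)
  if (length(values_by_group) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(values_by_group, length, integer(1)) == 0L))
    stop("invalid input: a group is empty", call. = FALSE)
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("g", seq_along(values_by_group))

  if (method == "mann_whitney") {
    if (length(values_by_group) != 2L)
      stop("mann_whitney needs exactly 2 groups", call. = FALSE)
    x <- values_by_group[[1]]; y <- values_by_group[[2]]
    n <- length(x) + length(y)
    ties <- anyDuplicated(c(x, y)) > 0L
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = (n <= 20 && !ties),
                         correct = TRUE))
    list(method = "mann_whitney", statistic = unname(wt$statistic),
         p = wt$p.value,
         group_sizes = vapply(values_by_group, length, integer(1)),
         direction = sign(stats::median(x) - stats::median(y)))
  } else {
    g <- rep(names(values_by_group),
             vapply(values_by_group, length, integer(1)))
    v <- unlist(values_by_group, use.names = FALSE)
    kw <- stats::kruskal.test(v, factor(g))
    pw <- .dunn_test(v, g)
    list(method = "kruskal_dunn", statistic = unname(kw$statistic),
         df = unname(kw$parameter), p = kw$p.value, pairwise = pw)
  }
}

# Dunn's pairwise z-tests on joint ranks with tie correction, BH-adjusted
.dunn_test <- function(v, g) {
  r <- rank(v)
  N <- length(v)
  tie_tab <- table(v)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  groups <- unique(g)
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  cmb <- utils::combn(groups, 2L)
  z <- p <- numeric(ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- (mean_r[[a]] - mean_r[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.table::data.table(group1 = cmb[1, ], group2 = cmb[2, ],
                         z = z, p = p, q = bh_adjust(p))
}

#' Correlation with p-value
#'
#' Spearman rank or Pearson product-moment correlation with the
#' t-approximation p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `coefficient` and `p`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  rho <- stats::cor(x, y)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(coefficient = rho, p = p)
}

#' Carrier logistic regression
#'
#' Multivariate logistic regression of disease status on carrier state
#' with age and sex as covariates (default `status ~ carrier + age +
#' sex`), maximum likelihood, reporting per-term odds ratios, Wald 95%
#' CIs and Wald p-values. Complete or quasi-complete separation raises
#' an explicit error rather than returning a degenerate fit.
#'
#' @param cohort Data with a binary outcome column, a carrier flag, and
#'   any covariates in `formula`.
#' @param formula Model formula; default `status ~ carrier + age + sex`.
#' @param outcome_case Level of the outcome treated as 1 (default
#'   `"case"`; ignored for already-numeric outcomes).
#' @return List of class `logistic_result`: `coefficients` data.table
#'   (term, estimate, or, ci_lo, ci_hi, p), `n`, `fit`.
#' @export
carrier_logistic <- function(cohort,
                             formula = status ~ carrier + age + sex,
                             outcome_case = "case") {
  d <- data.table::as.data.table(cohort)
  out_var <- all.vars(formula)[1]
  y <- d[[out_var]]
  if (!is.numeric(y)) d[[out_var]] <- as.integer(y == outcome_case)
  fit <- stats::glm(formula, data = d, family = stats::binomial())
  pr <- fit$fitted.values
  if (!fit$converged || any(pr > 1 - 1e-8) || any(pr < 1e-8))
    stop("separation error: the logistic fit is degenerate ",
         "(consider a penalized fallback)", call. = FALSE)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zcrit <- stats::qnorm(0.975)
  tab <- data.table::data.table(
    term = names(est), estimate = unname(est),
    or = exp(unname(est)),
    ci_lo = exp(unname(est) - zcrit * se),
    ci_hi = exp(unname(est) + zcrit * se),
    p = 2 * stats::pnorm(-abs(unname(est) / se)))
  structure(list(coefficients = tab, n = nrow(d), fit = fit),
            class = "logistic_result")
}

#' Mixed-effects model of sample-level burden
#'
#' ML fit of `burden ~ status + age + (1 | donor_id)` (configurable
#' fixed effects): burden per sample, donor as random intercept. Each
#' fixed effect is assessed by a likelihood-ratio test against the
#' nested model dropping that term (chi-square, 1 df). Conditional R^2
#' follows the variance-partition definition: (fixed-effect variance +
#' random-intercept variance) / total variance.
#'
#' @param samples Sample-level table with burden, the fixed-effect
#'   covariates, and donor_id.
#' @param fixed Character vector of fixed-effect terms
#'   (default `c("status", "age")`).
#' @param response Response column name (default `"burden"`).
#' @return List of class `mixed_model_result`: `fixed_effects` (named
#'   estimates), `ranef_sd`, `resid_sd`, `loglik`, `conditional_r2`,
#'   `lrt` data.table (term, statistic, df, p, significant), `fit`.
#' @export
burden_mixed_model <- function(samples, fixed = c("status", "age"),
                               response = "burden") {
  d <- data.table::as.data.table(samples)
  if (length(unique(d$donor_id)) < 2L)
    stop("random effect unidentifiable: need >= 2 donors", call. = FALSE)
  rhs <- paste(c(fixed, "(1 | donor_id)"), collapse = " + ")
  full_form <- stats::as.formula(paste(response, "~", rhs))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lme4::lmer(full_form, data = d, REML = FALSE, control = ctrl)

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_ranef <- vc$vcov[vc$grp == "donor_id"][1]
  var_resid <- vc$vcov[vc$grp == "Residual"][1]
  var_fixed <- stats::var(as.vector(
    stats::model.matrix(fit) %*% lme4::fixef(fit)))
  r2c <- (var_fixed + var_ranef) / (var_fixed + var_ranef + var_resid)

  lrt <- data.table::rbindlist(lapply(fixed, function(term) {
    red <- paste(c(setdiff(fixed, term), "(1 | donor_id)"), collapse = " + ")
    red_form <- stats::as.formula(paste(response, "~", red))
    fit0 <- lme4::lmer(red_form, data = d, REML = FALSE, control = ctrl)
    stat <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                          as.numeric(stats::logLik(fit0))))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    data.table::data.table(term = term, statistic = stat, df = 1,
                           p = p, significant = p < 0.05)
  }))
  structure(list(fixed_effects = lme4::fixef(fit),
                 ranef_sd = sqrt(var_ranef), resid_sd = sqrt(var_resid),
                 loglik = as.numeric(stats::logLik(fit)),
                 conditional_r2 = r2c, lrt = lrt, fit = fit),
            class = "mixed_model_result")
}

#' Hypergeometric gene-set enrichment against a custom background
#'
#' For each catalog set (intersected with the background first): k =
#' overlap of hit genes with the set, K = set size within background,
#' n = number of hits, N = background size; p is the upper-tail
#' cumulative hypergeometric P(X >= k); expected = n K / N; enrichment
#' factor = k / expected. A set is `reported` when p < 0.05, k >= 3 and
#' enrichment factor > 1.5. Hits outside the background are dropped
#' with a warning.
#'
#' @param hit_genes Character vector of hit gene symbols.
#' @param catalog A [gene_set_catalog()].
#' @param background Character vector of background gene symbols (e.g.
#'   the full targeted panel).
#' @return data.table sorted by p: set, k, K, n, N, expected,
#'   enrichment_factor, p, reported.
#' @export
enrich_pathways <- function(hit_genes, catalog = gene_set_catalog(),
                            background) {
  if (length(background) == 0L)
    stop("invalid input: empty background", call. = FALSE)
  background <- unique(toupper(background))
  hits <- unique(toupper(hit_genes))
  outside <- setdiff(hits, background)
  if (length(outside) > 0) {
    warning(length(outside), " hit gene(s) outside the background dropped")
    hits <- intersect(hits, background)
  }
  N <- length(background); n <- length(hits)
  rows <- lapply(names(catalog), function(nm) {
    set <- intersect(catalog[[nm]], background)
    K <- length(set)
    k <- length(intersect(hits, set))
    expected <- n * K / N
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ef <- if (expected > 0) k / expected else NA_real_
    data.table::data.table(set = nm, k = k, K = K, n = n, N = N,
                           expected = expected, enrichment_factor = ef,
                           p = min(p, 1),
                           reported = (p < 0.05 & k >= 3 &
                                         !is.na(ef) & ef > 1.5))
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, p)
  out[]
}
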