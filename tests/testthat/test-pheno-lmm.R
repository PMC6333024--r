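# one-way layout: n_g genotypes x n_years records, only genotype + residual
# identifiable (family = individual, single pop type, one plot per plant)
oneway_table <- function(n_g, n_years, sg2, se2, seed, year_means = rep(10, n_years)) {
  set.seed(seed)
  ind <- sprintf("g%02d", seq_len(n_g))
  g <- stats::rnorm(n_g, 0, sqrt(sg2))
  d <- expand.grid(individual = ind, year = seq_len(n_years),
                   stringsAsFactors = FALSE)
  d$family <- d$individual
  d$pop_type <- "A"
  d$plot <- d$individual
  d$trait <- "t"
  d$value <- year_means[d$year] + g[match(d$individual, ind)] +
    stats::rnorm(nrow(d), 0, sqrt(se2))
  d
}

test_that("build_design enumerates records and drops confounded terms", {
  d <- simulate_lmm_records(c(genotype = 0.4, permanent = 0, poptype = 0.02,
                              plot = 0.05, interaction = 0.1, residual = 0.43),
                            seed = 1)
  des <- build_design(d, "sim")
  expect_equal(length(des$y), 585)
  expect_equal(ncol(des$X), 3)
  expect_setequal(names(des$terms), c("genotype", "poptype", "plot", "interaction"))
  expect_equal(des$dropped, "permanent")  # same incidence as individual genotype

  # family-level genetic effect keeps the plant (permanent) term
  des_f <- build_design(d, "sim", genotype = "family")
  expect_true(all(c("genotype", "permanent") %in% names(des_f$terms)))
  expect_equal(nlevels(des_f$terms$genotype), 13)

  d2 <- d[-1, ]
  expect_equal(length(build_design(d2, "sim")$y), 584)
  expect_error(build_design(d[d$year == 1, ], "sim"), "2 years")
  expect_error(build_design(d, "absent"), "not found")
})

test_that("EM-REML equals the ANOVA estimator on a balanced one-way design", {
  d <- oneway_table(20, 3, sg2 = 2, se2 = 1, seed = 42)
  des <- build_design(d, "t")
  expect_equal(names(des$terms), "genotype")
  vc <- reml_fit(des, max_iter = 5000, tol = 1e-12)
  # method-of-moments oracle from the two-way ANOVA (year fixed, genotype random)
  a <- stats::anova(stats::lm(value ~ factor(year) + individual, d))
  ms_g <- a["individual", "Mean Sq"]; ms_e <- a["Residuals", "Mean Sq"]
  expect_equal(vc$sigma2[["genotype"]], (ms_g - ms_e) / 3, tolerance = 1e-6)
  expect_equal(vc$sigma2[["residual"]], ms_e, tolerance = 1e-6)
  expect_true(vc$converged)
})

test_that("EM-REML agrees with lme4 on an unbalanced six-effect dataset", {
  skip_if_not_installed("lme4")
  d <- simulate_lmm_records(c(genotype = 0.5, permanent = 0, poptype = 0.1,
                              plot = 0.2, interaction = 0.15, residual = 0.4),
                            n_genotypes = 120, n_families = 12, seed = 9)
  d <- d[-sample(nrow(d), 40), ]  # unbalance
  des <- build_design(d, "sim")
  vc <- reml_fit(des, max_iter = 3000, tol = 1e-10)
  d$famyear <- paste(d$family, d$year, sep = ":")
  lf <- lme4::lmer(value ~ 0 + factor(year) + (1 | individual) + (1 | pop_type) +
                     (1 | plot) + (1 | famyear), data = d,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  vl <- as.data.frame(lme4::VarCorr(lf))
  ref <- stats::setNames(vl$vcov, vl$grp)
  expect_equal(vc$sigma2[["genotype"]], ref[["individual"]], tolerance = 1e-3)
  expect_equal(vc$sigma2[["plot"]], ref[["plot"]], tolerance = 1e-3)
  expect_equal(vc$sigma2[["interaction"]], ref[["famyear"]], tolerance = 1e-3)
  expect_equal(vc$sigma2[["residual"]], ref[["Residual"]], tolerance = 1e-3)
})

test_that("restricted log-likelihood is non-decreasing across EM iterations", {
  d <- simulate_lmm_records(c(genotype = 0.3, permanent = 0, poptype = 0.05,
                              plot = 0.1, interaction = 0.1, residual = 0.45),
                            n_genotypes = 30, n_families = 6, seed = 3)
  des <- build_design(d, "sim")
  vc <- reml_fit(des, max_iter = 200, tol = 1e-8, keep_loglik = TRUE)
  expect_gt(length(vc$loglik), 2)
  expect_true(all(diff(vc$loglik) > -1e-8))
})

test_that("a null genotype variance is estimated as (near) zero", {
  med <- sapply(1:20, function(s) {
    d <- simulate_lmm_records(c(genotype = 0, permanent = 0, poptype = 0.02,
                                plot = 0.05, interaction = 0.1, residual = 0.83),
                              n_genotypes = 60, n_families = 6, seed = 1000 + s)
    vc <- reml_fit(build_design(d, "sim"), max_iter = 400, tol = 1e-6)
    vc$sigma2[["genotype"]] / sum(vc$sigma2)
  })
  expect_lt(stats::median(med), 1e-3)
})

test_that("BLUPs match a dense generalized-least-squares oracle", {
  d <- oneway_table(8, 3, sg2 = 1.5, se2 = 0.8, seed = 5,
                    year_means = c(9, 10, 12))
  des <- build_design(d, "t")
  comp <- c(genotype = 1.5, permanent = 0, poptype = 0, plot = 0,
            interaction = 0, residual = 0.8)
  fit <- blup_solve(des, comp)
  Z <- stats::model.matrix(~ 0 + individual, d)
  X <- stats::model.matrix(~ 0 + factor(year), d)
  V <- 1.5 * tcrossprod(Z) + diag(0.8, nrow(d))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$value)
  u <- 1.5 * t(Z) %*% Vi %*% (d$value - X %*% beta)
  expect_equal(unname(fit$fixed), unname(drop(beta)), tolerance = 1e-10)
  expect_equal(unname(fit$blups$genotype), unname(drop(u)), tolerance = 1e-10)
  # PEV against the brute-force joint covariance
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  pev_oracle <- diag(diag(1.5, 8) - 1.5 * t(Z) %*% P %*% Z * 1.5)
  expect_equal(unname(fit$pev), unname(pev_oracle), tolerance = 1e-10)
  # BLUPs shrink toward zero relative to raw mean deviations and sum to ~0
  raw_dev <- tapply(d$value - ave(d$value, d$year), d$individual, mean)
  expect_true(all(abs(fit$blups$genotype) <= abs(raw_dev[names(fit$blups$genotype)]) + 1e-10))
  expect_lt(abs(sum(fit$blups$genotype)), 1e-8)
})

test_that("all-zero random variances give all-zero BLUPs", {
  d <- oneway_table(6, 2, sg2 = 1, se2 = 1, seed = 6)
  des <- build_design(d, "t")
  fit <- blup_solve(des, c(genotype = 0, permanent = 0, poptype = 0,
                           plot = 0, interaction = 0, residual = 1))
  expect_true(all(fit$blups$genotype == 0))
})

test_that("phenotypic accuracy behaves at its limits and tracks sqrt(h2)", {
  # strong genotype signal, many effective reps: r_yy near 1
  d <- oneway_table(25, 3, sg2 = 10, se2 = 0.1, seed = 7)
  des <- build_design(d, "t")
  vc <- reml_fit(des, max_iter = 2000, tol = 1e-9)
  acc <- phenotypic_accuracy(des, vc)
  expect_gt(acc$r_yy, 0.97)
  # zero genotype variance reports zero accuracy
  acc0 <- phenotypic_accuracy(des, structure(list(sigma2 = c(
    genotype = 0, permanent = 0, poptype = 0, plot = 0, interaction = 0,
    residual = 1)), class = "variance_components"))
  expect_equal(acc0$r_yy, 0)
  # mean-level h2 ~ 0.9 gives r_yy ~ 0.95, for both definitions
  d2 <- simulate_lmm_records(c(genotype = 0.8, permanent = 0, poptype = 0,
                               plot = 0, interaction = 0, residual = 0.27),
                             seed = 8)
  des2 <- build_design(d2, "sim")
  vc2 <- reml_fit(des2, max_iter = 500, tol = 1e-7)
  acc2 <- phenotypic_accuracy(des2, vc2)
  expect_equal(acc2$h2_phen, 0.9, tolerance = 0.07)
  expect_equal(acc2$r_yy, 0.95, tolerance = 0.05)
  acc2b <- phenotypic_accuracy(des2, vc2, method = "sqrt_h2")
  expect_equal(acc2$r_yy, acc2b$r_yy, tolerance = 0.03)
})

test_that("correct_phenotypes removes year offsets and plot/interaction BLUPs", {
  # pure year offsets and genotype: corrected value = centered genotype mean
  d <- oneway_table(10, 3, sg2 = 2, se2 = 0, seed = 11,
                    year_means = c(5, 50, 500))
  des <- build_design(d, "t")
  comp <- c(genotype = 2, permanent = 0, poptype = 0, plot = 0,
            interaction = 0, residual = 1e-6)
  fit <- blup_solve(des, comp)
  yc <- correct_phenotypes(des, fit)
  raw <- tapply(d$value, d$individual, mean)
  # year offsets removed exactly: corrected equals the centered raw means
  # (the estimated year means absorb the population mean of the genotypes)
  expect_equal(unname(yc), as.numeric(raw[names(yc)] - mean(raw)),
               tolerance = 1e-6)
  # record order must not matter
  d_perm <- d[sample(nrow(d)), ]
  des_p <- build_design(d_perm, "t")
  fit_p <- blup_solve(des_p, comp)
  expect_equal(correct_phenotypes(des_p, fit_p), yc, tolerance = 1e-9)
})

test_that("individual heritability is the exact component ratio", {
  expect_equal(individual_h2(c(genotype = 1, permanent = 0.2, poptype = 0.2,
                               plot = 0.2, interaction = 0.2, residual = 0.2)),
               0.5)
  expect_equal(individual_h2(c(genotype = 0, permanent = 1, poptype = 0,
                               plot = 0, interaction = 0, residual = 1)), 0)
  expect_equal(individual_h2(c(genotype = 0.26, permanent = 0.1, poptype = 0.1,
                               plot = 0.1, interaction = 0.2, residual = 0.24)),
               0.26)
  expect_error(individual_h2(c(genotype = 0, permanent = 0, poptype = 0,
                               plot = 0, interaction = 0, residual = 0)),
               "zero")
})
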