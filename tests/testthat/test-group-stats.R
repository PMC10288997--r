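test_that("summary t-test reproduces the published demographic example", {
  # age row, eye-level n: printed two-sided p = 0.904
  for (v in c("welch", "pooled")) {
    r <- t_test_summary(47.36, 13.21, 50, 47.68, 12.48, 44, variant = v)
    expect_lt(abs(r$p - 0.904), 0.005)
  }
})

test_that("summary t-test handles degenerate inputs per contract", {
  r0 <- t_test_summary(5, 0, 10, 5, 0, 12)
  expect_identical(r0$p, 1)
  expect_identical(r0$t, 0)
  r1 <- t_test_summary(5, 0, 10, 6, 0, 12)
  expect_identical(r1$p, 0)
  expect_true(r1$degenerate)
  ri <- t_test_summary(3, 1, 5, 3, 1, 5)
  expect_identical(ri$t, 0)
  expect_identical(ri$p, 1)
  expect_error(t_test_summary(1, 1, 1, 2, 1, 5))
})

test_that("summary t-test p matches a numerically integrated t oracle", {
  set.seed(7)
  for (i in 1:200) {
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
    s1 <- runif(1, 0.5, 4); s2 <- runif(1, 0.5, 4)
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    r <- t_test_summary(m1, s1, n1, m2, s2, n2)
    # quadrature oracle: integrate the t density over the rejection tail
    p_or <- 2 * stats::integrate(function(x) stats::dt(x, r$df),
                                 abs(r$t), Inf, rel.tol = 1e-12)$value
    expect_lt(abs(r$p - p_or), 1e-6)
  }
})

test_that("sample t-test agrees with the summary form to 1e-12", {
  set.seed(8)
  for (i in 1:50) {
    x1 <- rnorm(sample(5:60, 1), runif(1, -2, 2), runif(1, 0.5, 3))
    x2 <- rnorm(sample(5:60, 1), runif(1, -2, 2), runif(1, 0.5, 3))
    for (v in c("welch", "pooled")) {
      a <- t_test_samples(x1, x2, v)
      b <- t_test_summary(mean(x1), sd(x1), length(x1),
                          mean(x2), sd(x2), length(x2), v)
      expect_lt(abs(a$t - b$t), 1e-12)
      expect_lt(abs(a$p - b$p), 1e-12)
      expect_lt(abs(a$df - b$df), 1e-12)
    }
  }
  expect_error(t_test_samples(1, rnorm(5)), "at least 2")
})

test_that("t p-value agrees with a permutation oracle on Gaussian data", {
  set.seed(9)
  x1 <- rnorm(30, 0.4); x2 <- rnorm(35, 0)
  p_t <- t_test_samples(x1, x2)$p
  pooled <- c(x1, x2); n1 <- length(x1)
  obs <- abs(mean(x1) - mean(x2))
  perm <- replicate(1e4, {
    idx <- sample(length(pooled), n1)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("IRLS logistic matches glm and the 2x2 closed form", {
  set.seed(10)
  d <- data.frame(group = rep(c("HC", "NMOSD"), each = 60),
                  m = c(rnorm(60), rnorm(60, 0.7)),
                  age = rnorm(120, 47, 13))
  lr <- logistic_adjusted(d, "m", "age")
  gm <- stats::glm(I(group != "HC") ~ scale(m) + scale(age),
                   stats::binomial, d)
  expect_lt(max(abs(lr$coef - stats::coef(gm))), 1e-8)
  expect_true(lr$converged)
  expect_true(lr$CI95[1] <= lr$OR && lr$OR <= lr$CI95[2])
  # Wald p close to the likelihood-ratio p at this n
  lrt <- stats::anova(stats::glm(I(group != "HC") ~ scale(age),
                                 stats::binomial, d),
                      gm, test = "LRT")
  expect_lt(abs(lr$p - lrt$`Pr(>Chi)`[2]), 0.01)

  # binary metric, no covariates: cross-product odds ratio
  set.seed(11)
  d2 <- data.frame(group = rep(c("HC", "NMOSD"), each = 100),
                   b = stats::rbinom(200, 1, rep(c(0.3, 0.6), each = 100)))
  lr2 <- logistic_adjusted(d2, "b", covariates = character(0),
                           standardized = FALSE)
  tab <- table(d2$b, d2$group)
  expect_lt(abs(lr2$OR - (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])),
            1e-6)
})

test_that("logistic fit flags separation and constant covariates", {
  d <- data.frame(group = rep(c("HC", "NMOSD"), each = 20),
                  m = c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)))
  lr <- logistic_adjusted(d, "m", covariates = character(0))
  expect_true(lr$separation)
  expect_true(is.infinite(lr$OR) || lr$OR == 0)

  # all-female cohort: a constant gender covariate is dropped with a warning
  d$gender <- 1
  expect_warning(logistic_adjusted(d, "m", covariates = "gender"),
                 "constant")
  expect_error(logistic_adjusted(d[d$group == "HC", ], "m",
                                 covariates = character(0)), "both classes")
})

test_that("logistic regression recovers a known effect size", {
  # cases shifted by +1 SD: raw-unit log-OR equals the shift (LDA identity)
  set.seed(12)
  ors <- replicate(200, {
    d <- data.frame(group = rep(c("HC", "NMOSD"), each = 500),
                    m = c(rnorm(500, 0, 1), rnorm(500, 1, 1)))
    logistic_adjusted(d, "m", covariates = character(0),
                      standardized = FALSE)$OR
  })
  expect_lt(abs(stats::median(ors) - exp(1)) / exp(1), 0.15)
})

test_that("logistic null CIs cover 1 near the nominal rate (small check)", {
  set.seed(13)
  cov <- 0
  for (r in 1:200) {
    d <- data.frame(group = rep(c("HC", "NMOSD"), c(50, 44)),
                    m = rnorm(94), age = rnorm(94, 47, 13))
    lr <- logistic_adjusted(d, "m", "age")
    if (lr$CI95[1] <= 1 && lr$CI95[2] >= 1) cov <- cov + 1
  }
  expect_gte(cov / 200, 0.90)
})

test_that("significance categories are a pure closed-boundary threshold", {
  p <- c(a = 0.0005, b = 0.001, c = 0.03, d = 0.05, e = 0.5)
  m <- significance_map(p)
  expect_identical(as.character(m),
                   c("P<=0.001", "P<=0.001", "P<=0.05", "P<=0.05", "P>0.05"))
  # monotone in p and idempotent category boundaries
  ps <- sort(runif(50))
  cats <- as.integer(significance_map(ps))
  expect_true(all(diff(cats) >= 0))
  expect_error(significance_map(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cohort analysis driver emits the full report structure", {
  tab <- simulate_cohort(cohort_preset("table5"), seed = 21)
  res <- run_cohort_analysis(tab, "ON-vs-HC")
  expect_equal(nrow(res$t_tests), 3 * 12)
  expect_equal(nrow(res$logistic), 3 * 12)
  expect_true(all(res$t_tests$p >= 0 & res$t_tests$p <= 1))
  expect_error(run_cohort_analysis(tab, "nonON-vs-HC"), "empty group")

  # sector-level maps + files
  set.seed(22)
  st <- expand.grid(group = c("HC", "ON"), plexus = c("SVC", "DVC"),
                    sector = c("SI", "TI"), rep = 1:20,
                    stringsAsFactors = FALSE)
  st$VAD <- rnorm(nrow(st), ifelse(st$group == "ON", 13, 15.5), 2.5)
  st$VLD <- rnorm(nrow(st), 5, 1)
  out <- withr::local_tempdir()
  res2 <- run_cohort_analysis(tab, "ON-vs-HC", sector_table = st,
                              out_dir = out)
  expect_true(all(c("plexus", "sector", "metric", "p", "category") %in%
                    names(res2$sector_maps)))
  expect_true(file.exists(file.path(out, "t_tests.csv")))
  expect_true(file.exists(file.path(out, "significance_SVC.png")))

  # optional BH correction never increases the significant-sector count
  res3 <- run_cohort_analysis(tab, "ON-vs-HC", sector_table = st,
                              adjust = "BH")
  n_sig <- function(r) sum(r$sector_maps$category != "P>0.05")
  expect_lte(n_sig(res3), n_sig(res2))
})

test_that("null contrasts keep the type-I error near nominal", {
  # both arms drawn from the HC summaries: fraction of p < 0.05 across all
  # plexus x metric tests stays in a band around 0.05
  rows <- octa_summary_table()
  hc <- rows[rows$table == "nmosd_vs_hc" & rows$group == "HC",
             c("plexus", "metric", "mean", "sd")]
  spec <- cohort_spec(list(
    list(name = "HC", n_eyes = 50, covariates = list(), metrics = hc),
    list(name = "NMOSD", n_eyes = 44, covariates = list(), metrics = hc)))
  hits <- 0; total <- 0
  for (r in 1:100) {
    tb <- simulate_cohort(spec, seed = 3000 + r)
    for (px in c("SVC", "DVC", "IVC")) {
      d <- tb[tb$plexus == px, ]
      for (m in METRIC_NAMES) {
        p <- t_test_samples(d[[m]][d$group == "NMOSD"],
                            d[[m]][d$group == "HC"])$p
        total <- total + 1
        if (p < 0.05) hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.01)
  expect_lte(hits / total, 0.12)
})
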