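#' @title Group comparison statistics
#' @name group_stats
#' @description Two-sample t-tests from raw samples or printed summary
#'   statistics, covariate-adjusted logistic regression with odds ratios and
#'   Wald 95% confidence intervals, three-level sector significance maps,
#'   and the cohort-level analysis driver.
NULL

#' Two-sample t-test from summary statistics
#'
#' Computes t, degrees of freedom (Welch-Satterthwaite or pooled
#' `n1 + n2 - 2`) and the two-sided p-value directly from group means, SDs
#' and sizes, as needed to reproduce tests on published summaries.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @param variant `"welch"` (unequal variances, default) or `"pooled"`.
#' @return A `group_comparison` list: means, sds, n, `t`, `df`, `p`,
#'   `degenerate` flag.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  degenerate <- FALSE
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      t <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      t <- Inf * sign(mean1 - mean2); df <- n1 + n2 - 2; p <- 0
      degenerate <- TRUE
    }
  } else if (variant == "welch") {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(mean = c(mean1, mean2), sd = c(sd1, sd2), n = c(n1, n2),
                 t = t, df = df, p = p, variant = variant,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' Two-sample t-test from raw samples
#'
#' Delegates to [stats::t.test()]; consistent with [t_test_summary()]
#' applied to the samples' own mean/SD/n.
#'
#' @param x1,x2 numeric sample vectors (each of length >= 2).
#' @inheritParams t_test_summary
#' @export
t_test_samples <- function(x1, x2, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x1) < 2 || length(x2) < 2) {
    stop("each sample needs at least 2 observations")
  }
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
    return(t_test_summary(mean(x1), 0, length(x1), mean(x2), 0, length(x2),
                          variant))
  }
  ht <- stats::t.test(x1, x2, var.equal = (variant == "pooled"))
  structure(list(mean = c(mean(x1), mean(x2)), sd = c(stats::sd(x1), stats::sd(x2)),
                 n = c(length(x1), length(x2)),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, variant = variant, degenerate = FALSE),
            class = "group_comparison")
}

#' Covariate-adjusted logistic regression for one biomarker
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (Newton scoring; convergence when the maximum absolute score falls below
#' `tol` or after `max_iter` iterations). The outcome is case (non-HC)
#' versus control (HC). With `standardized = TRUE` (default) the metric and
#' covariates are z-scored so the odds ratio is per 1 SD of the biomarker;
#' otherwise per raw unit. Constant covariates (e.g. gender in an
#' all-female cohort) are dropped with a warning. Perfect separation is
#' flagged and reported with an infinite-OR sentinel rather than an error.
#'
#' @param table cohort data frame with columns `group`, the metric and the
#'   covariates (e.g. from [simulate_cohort()]), one row per eye (filter to
#'   one plexus first).
#' @param metric metric column name.
#' @param covariates covariate column names to adjust for.
#' @param standardized z-score predictors before fitting.
#' @param max_iter,tol IRLS controls.
#' @return A `logistic_result`: `metric`, `OR`, `CI95`, `p`, `coef`, `se`,
#'   `covariates`, `standardized`, `converged`, `separation`.
#' @export
logistic_adjusted <- function(table, metric, covariates = c("age"),
                              standardized = TRUE, max_iter = 100L,
                              tol = 1e-8) {
  y <- as.integer(table$group != "HC")
  if (all(y == 0) || all(y == 1)) stop("outcome must contain both classes")
  vars <- c(metric, covariates)
  if (any(!vars %in% names(table))) {
    stop("missing columns: ", paste(setdiff(vars, names(table)), collapse = ", "))
  }
  X <- as.matrix(table[, vars, drop = FALSE])
  if (anyNA(X)) stop("missing values in metric/covariates")
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    vars <- vars[keep]
  }
  if (!metric %in% vars) stop("metric column is constant")
  if (standardized) X <- scale(X)
  X <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
  }
  eta <- drop(X %*% beta)
  p_hat <- stats::plogis(eta)
  separation <- all(abs(y - p_hat) < 1e-6) || max(abs(beta)) > 30
  w <- pmax(p_hat * (1 - p_hat), 1e-10)
  H <- crossprod(X * w, X)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, ncol(X)))
  names(beta) <- names(se) <- colnames(X)
  b <- beta[metric]; s <- se[metric]
  if (separation) {
    OR <- if (b > 0) Inf else 0
    ci <- c(0, Inf); pval <- NA_real_
  } else {
    OR <- exp(b)
    ci <- exp(b + c(-1, 1) * stats::qnorm(0.975) * s)
    pval <- 2 * stats::pnorm(-abs(b / s))
  }
  structure(list(metric = metric, OR = unname(OR),
                 CI95 = unname(ci), p = unname(pval),
                 coef = beta, se = se, covariates = setdiff(vars, metric),
                 standardized = standardized, converged = converged,
                 separation = separation),
            class = "logistic_result")
}

#' Three-level significance categories for sector p-values
#'
#' Categories are `P<=0.001`, `P<=0.05` and `P>0.05`, closed on the
#' boundary (p = 0.001 falls in the strongest class). A pure threshold
#' function: idempotent and monotone in p.
#'
#' @param p_values named numeric vector of p-values in `[0, 1]`.
#' @param thresholds the two category boundaries.
#' @return factor with levels `P<=0.001`, `P<=0.05`, `P>0.05`.
#' @export
significance_map <- function(p_values, thresholds = c(0.001, 0.05)) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  lv <- c(sprintf("P<=%g", thresholds[1]), sprintf("P<=%g", thresholds[2]),
          sprintf("P>%g", thresholds[2]))
  cat <- ifelse(p_values <= thresholds[1], lv[1],
                ifelse(p_values <= thresholds[2], lv[2], lv[3]))
  factor(stats::setNames(cat, names(p_values)), levels = lv)
}

#' Full cohort analysis for one contrast
#'
#' For each plexus and metric, a two-sample t-test and a covariate-adjusted
#' logistic regression of case versus HC; optionally, per plexus, sector and
#' sub-regional metric, a t-test with its three-level significance category.
#' Results can be written as CSVs plus a three-colour significance grid PNG
#' per plexus (yellow `P<=0.001`, red `P<=0.05`, green `P>0.05`).
#'
#' @param table per-eye cohort table (columns `group`, `plexus`, metric
#'   columns, covariates), e.g. [simulate_cohort()] on a [cohort_preset()].
#' @param contrast `"NMOSD-vs-HC"`, `"ON-vs-HC"` or `"nonON-vs-HC"`.
#' @param sector_table optional sector-level table (columns `group`,
#'   `plexus`, `sector`, sub-regional metric columns).
#' @param covariates covariates for the logistic model.
#' @param variant t-test variant.
#' @param adjust `"none"` (default, matching the study) or `"BH"` for
#'   Benjamini-Hochberg correction of the sector p-values.
#' @param out_dir optional output directory for CSVs/PNGs.
#' @return list: `t_tests`, `logistic`, `sector_maps` (or `NULL`).
#' @export
run_cohort_analysis <- function(table,
                                contrast = c("NMOSD-vs-HC", "ON-vs-HC",
                                             "nonON-vs-HC"),
                                sector_table = NULL, covariates = c("age"),
                                variant = "welch", adjust = "none",
                                out_dir = NULL) {
  contrast <- match.arg(contrast)
  case <- switch(contrast, "NMOSD-vs-HC" = "NMOSD", "ON-vs-HC" = "ON",
                 "nonON-vs-HC" = "NON_ON")
  sub <- table[table$group %in% c(case, "HC"), , drop = FALSE]
  if (!any(sub$group == case) || !any(sub$group == "HC")) {
    stop("contrast ", contrast, " has an empty group")
  }
  metrics <- intersect(METRIC_NAMES, names(sub))
  plexuses <- if ("plexus" %in% names(sub)) unique(sub$plexus) else NA_character_
  tt <- list(); lg <- list()
  for (px in plexuses) {
    d <- if (is.na(px[1])) sub else sub[sub$plexus == px, , drop = FALSE]
    for (m in metrics) {
      r <- t_test_samples(d[[m]][d$group == case], d[[m]][d$group == "HC"],
                          variant)
      tt[[length(tt) + 1L]] <- data.frame(
        plexus = px, metric = m, mean_case = r$mean[1], sd_case = r$sd[1],
        mean_hc = r$mean[2], sd_hc = r$sd[2], t = r$t, df = r$df, p = r$p,
        stringsAsFactors = FALSE)
      lr <- logistic_adjusted(d, m, covariates)
      lg[[length(lg) + 1L]] <- data.frame(
        plexus = px, metric = m, OR = lr$OR, CI_low = lr$CI95[1],
        CI_high = lr$CI95[2], p = lr$p, converged = lr$converged,
        separation = lr$separation, stringsAsFactors = FALSE)
    }
  }
  t_tests <- do.call(rbind, tt)
  logistic <- do.call(rbind, lg)
  sector_maps <- NULL
  if (!is.null(sector_table)) {
    ssub <- sector_table[sector_table$group %in% c(case, "HC"), , drop = FALSE]
    smetrics <- intersect(c("VAD", "VLD", "FD", "tortuosity", "B_num"),
                          names(ssub))
    sm <- list()
    for (px in unique(ssub$plexus)) {
      for (sec in unique(ssub$sector)) {
        d <- ssub[ssub$plexus == px & ssub$sector == sec, , drop = FALSE]
        for (m in smetrics) {
          r <- t_test_samples(d[[m]][d$group == case],
                              d[[m]][d$group == "HC"], variant)
          sm[[length(sm) + 1L]] <- data.frame(
            plexus = px, sector = sec, metric = m, p = r$p,
            stringsAsFactors = FALSE)
        }
      }
    }
    sector_maps <- do.call(rbind, sm)
    p_use <- if (identical(adjust, "BH")) {
      stats::ave(sector_maps$p, sector_maps$plexus, sector_maps$metric,
                 FUN = function(p) stats::p.adjust(p, "BH"))
    } else sector_maps$p
    sector_maps$category <- as.character(significance_map(p_use))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(t_tests, file.path(out_dir, "t_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(logistic, file.path(out_dir, "logistic.csv"),
                     row.names = FALSE)
    if (!is.null(sector_maps)) {
      utils::write.csv(sector_maps, file.path(out_dir, "sector_maps.csv"),
                       row.names = FALSE)
      for (px in unique(sector_maps$plexus)) {
        render_significance_grid(
          sector_maps[sector_maps$plexus == px, ],
          file.path(out_dir, paste0("significance_", px, ".png")))
      }
    }
  }
  list(contrast = contrast, t_tests = t_tests, logistic = logistic,
       sector_maps = sector_maps)
}

# Three-colour grid (rows = sectors, cols = metrics) written as PNG.
render_significance_grid <- function(sector_maps, path, cell_px = 24L) {
  secs <- unique(sector_maps$sector)
  mets <- unique(sector_maps$metric)
  cols <- list("P<=0.001" = c(1, 0.9, 0),    # yellow
               "P<=0.05" = c(0.9, 0.1, 0.1), # red
               "P>0.05" = c(0.1, 0.7, 0.2))  # green
  arr <- array(1, dim = c(length(secs) * cell_px, length(mets) * cell_px, 3))
  for (i in seq_along(secs)) for (j in seq_along(mets)) {
    row <- sector_maps[sector_maps$sector == secs[i] &
                       sector_maps$metric == mets[j], ]
    if (!nrow(row)) next
    rgb <- cols[[row$category[1]]]
    rs <- ((i - 1) * cell_px + 2):(i * cell_px - 1)
    cs <- ((j - 1) * cell_px + 2):(j * cell_px - 1)
    for (k in 1:3) arr[rs, cs, k] <- rgb[k]
  }
  png::writePNG(arr, path)
  invisible(path)
}
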