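#' Fit the coating-by-time regression for one outcome
#'
#' Each outcome (an index or the myotube count, one value per well) is
#' modeled by least squares on categorical coating and day effects, with the
#' reference coating being matrigel and the earliest modeled day the
#' reference day. The coating-by-day interaction is included only when it
#' significantly improves the fit: the additive and interaction models are
#' compared by a partial F-test at `alpha` (default 0.05). For outcomes where
#' the earliest time point is uninformative (myotube number and the
#' differentiation index, which are essentially zero at day 1), day-1 rows
#' can be excluded before fitting.
#'
#' On noiseless data the additive model may fit with zero residual variance;
#' the partial F-statistic is then indeterminate and the interaction is
#' considered a significant improvement whenever it still reduces the
#' residual sum of squares by more than a relative tolerance.
#'
#' @param table tidy analysis table (`coating`, `day`, `well`, `outcome`,
#'   `value`), as from [build_analysis_table()].
#' @param outcome which outcome to model.
#' @param exclude_day1 drop day-1 rows before fitting.
#' @param ref_coating reference coating label (must be present).
#' @param alpha significance level for the interaction F-test.
#' @return object of class `regression_fit`: `outcome`, `fit` (the selected
#'   `lm`), `interaction_included`, `anova_p`, `excluded_days`, `days`,
#'   `coatings`, `ref_coating`, and `contrasts` (the full
#'   [contrasts_vs_reference()] table).
#' @export
fit_outcome_model <- function(table, outcome, exclude_day1 = FALSE,
                              ref_coating = "matrigel", alpha = 0.05) {
  d <- table[table$outcome == outcome & !is.na(table$value), , drop = FALSE]
  if (nrow(d) == 0) stop_param("no data for outcome '", outcome, "'")
  excluded <- integer(0)
  if (exclude_day1) {
    excluded <- 1L
    d <- d[d$day != 1, , drop = FALSE]
  }
  if (!ref_coating %in% d$coating)
    stop_param("reference coating '", ref_coating, "' absent from the data")
  coats <- unique(as.character(d$coating))
  days <- sort(unique(d$day))
  if (length(coats) < 2)
    stop_param("need at least 2 coatings to fit coating contrasts (got ",
               length(coats), ")")
  if (length(days) < 2)
    stop_param("need at least 2 days to fit time effects (got ",
               length(days), ")")
  d$coating <- factor(d$coating,
                      levels = c(ref_coating, setdiff(sort(coats), ref_coating)))
  d$day <- factor(d$day, levels = days)
  fit_add <- lm(value ~ coating + day, data = d)
  fit_int <- lm(value ~ coating * day, data = d)
  n_par_int <- length(coef(fit_int))
  if (nrow(d) - n_par_int < 0)
    stop_param("fewer observations than interaction-model parameters for '",
               outcome, "'")
  rss_add <- sum(residuals(fit_add)^2)
  rss_int <- sum(residuals(fit_int)^2)
  if (rss_int <= 1e-10 * max(rss_add, 1)) {
    # (near-)saturated noiseless fit: F is indeterminate; count the
    # interaction as an improvement iff it actually reduced the RSS
    p_int <- if (rss_add - rss_int > 1e-10 * max(rss_add, 1)) 0 else 1
  } else {
    av <- anova(fit_add, fit_int)
    p_int <- av[2, "Pr(>F)"]
    if (is.na(p_int)) p_int <- 1  # no extra df estimable
  }
  include <- p_int < alpha
  fit <- if (include) fit_int else fit_add
  out <- structure(list(outcome = outcome, fit = fit,
                        interaction_included = include, anova_p = p_int,
                        excluded_days = excluded, days = days,
                        coatings = levels(d$coating),
                        ref_coating = ref_coating, alpha = alpha),
                   class = "regression_fit")
  out$contrasts <- contrasts_vs_reference(out)
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("<regression_fit> outcome:", x$outcome,
      if (x$interaction_included) "(coating x day interaction)"
      else "(additive coating + day)", "\n")
  cat("  interaction F-test p =", format(x$anova_p, digits = 3), "\n")
  if (length(x$excluded_days))
    cat("  excluded days:", paste(x$excluded_days, collapse = ", "), "\n")
  sig <- x$contrasts[x$contrasts$significant, , drop = FALSE]
  cat("  significant contrasts vs", x$ref_coating, ":", nrow(sig), "\n")
  invisible(x)
}

#' Model-estimated coating contrasts versus the reference at each day
#'
#' For every non-reference coating and requested day, the model-estimated
#' difference (coating minus reference at that day) with its standard error
#' and two-sided p-value. Under the additive model the estimate is identical
#' across days; under the interaction model it equals the cell-mean
#' difference.
#'
#' @param fit a `regression_fit`.
#' @param days days at which to evaluate (defaults to all modeled days).
#' @return data frame: `outcome`, `coating`, `day`, `estimate`, `se`,
#'   `p_value`, `significant` (at the fit's alpha).
#' @export
contrasts_vs_reference <- function(fit, days = NULL) {
  stopifnot(inherits(fit, "regression_fit"))
  if (is.null(days)) days <- fit$days
  if (!all(days %in% fit$days))
    stop_param("day(s) ", paste(setdiff(days, fit$days), collapse = ", "),
               " not in the modeled days (", paste(fit$days, collapse = ", "), ")")
  m <- fit$fit
  tt <- delete.response(terms(m))
  xlev <- m$xlevels
  beta <- coef(m)
  df_res <- m$df.residual
  sigma2 <- sum(residuals(m)^2) / max(df_res, 1)
  # on a noiseless fit the covariance is not needed (and summary.lm warns)
  V <- if (sigma2 < 1e-12) matrix(0, length(beta), length(beta)) else vcov(m)
  rows <- list()
  for (co in setdiff(fit$coatings, fit$ref_coating)) {
    for (dy in days) {
      nd1 <- data.frame(coating = factor(co, levels = xlev$coating),
                        day = factor(dy, levels = xlev$day))
      nd0 <- data.frame(coating = factor(fit$ref_coating,
                                         levels = xlev$coating),
                        day = factor(dy, levels = xlev$day))
      L <- model.matrix(tt, nd1) - model.matrix(tt, nd0)
      est <- drop(L %*% beta)
      se <- sqrt(drop(L %*% V %*% t(L)))
      if (sigma2 < 1e-12) {
        # noiseless fit: the estimate is exact; p reflects only whether the
        # difference is nonzero
        p <- if (abs(est) > 1e-10) 0 else 1
        se <- 0
      } else if (se > 0) {
        p <- 2 * pt(-abs(est / se), df_res)
      } else {
        p <- NA_real_
      }
      rows[[length(rows) + 1L]] <-
        data.frame(outcome = fit$outcome, coating = co, day = dy,
                   estimate = est, se = se, p_value = p,
                   significant = !is.na(p) & p < fit$alpha)
    }
  }
  do.call(rbind, rows)
}

#' Agreement statistics between manual and automated counts
#'
#' Validation statistics for automated counting against a manual reference:
#' Pearson correlation, a two-sided paired t-test on the per-image
#' differences, and the signed mean difference (manual minus automated).
#' When a second automated run of the same images is supplied, the duplicate
#' measurement error (SD of the run-to-run differences) is reported; a fully
#' deterministic pipeline yields 0.
#'
#' A constant nonzero difference has zero variance, making the t statistic
#' infinite; this exact-difference case is reported as p = 0 (p = 1 when the
#' vectors are identical). Zero variance in either count vector leaves the
#' correlation undefined (`NA`) with a warning.
#'
#' @param manual,automated equal-length numeric vectors (length >= 3) of
#'   per-image counts.
#' @param duplicates optional second automated run on the same images.
#' @return list of class `agreement_stats`: `pearson_r`, `paired_t_p`,
#'   `mean_difference`, `n`, `duplicate_error`.
#' @export
validate_counts <- function(manual, automated, duplicates = NULL) {
  if (length(manual) != length(automated))
    stop_param("manual and automated vectors differ in length")
  if (length(manual) < 3)
    stop_param("need at least 3 paired counts")
  r <- if (sd(manual) == 0 || sd(automated) == 0) {
    warning("zero variance in a count vector: correlation undefined")
    NA_real_
  } else {
    cor(manual, automated)
  }
  diffs <- manual - automated
  if (sd(diffs) == 0) {
    p <- if (mean(diffs) == 0) 1 else 0
  } else {
    p <- t.test(manual, automated, paired = TRUE)$p.value
  }
  dup <- if (!is.null(duplicates)) {
    if (length(duplicates) != length(automated))
      stop_param("duplicates vector differs in length")
    sd(automated - duplicates)
  } else {
    NA_real_
  }
  structure(list(pearson_r = r, paired_t_p = p,
                 mean_difference = mean(diffs), n = length(manual),
                 duplicate_error = dup),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("<agreement_stats> n =", x$n, "\n")
  cat("  Pearson r =", format(x$pearson_r, digits = 4),
      " paired-t p =", format(x$paired_t_p, digits = 3),
      " mean diff =", format(x$mean_difference, digits = 4), "\n")
  if (!is.na(x$duplicate_error))
    cat("  duplicate error =", format(x$duplicate_error, digits = 4), "\n")
  invisible(x)
}
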