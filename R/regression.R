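#' Parental-age trend on scaled phased DNM counts
#'
#' Ordinary least-squares regression of the scaled phased count (phased
#' fraction times total DNM count) on the parent's age at conception, with
#' Wald 95% confidence interval and the Pearson correlation p-value. Children
#' with no phased DNMs have an undefined scaled count and are excluded.
#'
#' @param rows Cohort tibble with `father_age`/`mother_age` and
#'   `scaled_paternal`/`scaled_maternal` columns (see [build_cohort_table()]).
#' @param parent `"father"` or `"mother"`.
#' @param response Response column; defaults to the scaled phased count of
#'   the matching parent.
#' @return A `dnm_fit` object.
#' @export
fit_age_trend <- function(rows, parent = c("father", "mother"),
                          response = NULL) {
  parent <- match.arg(parent)
  age_col <- paste0(parent, "_age")
  response <- response %||%
    if (parent == "father") "scaled_paternal" else "scaled_maternal"
  d <- tibble::tibble(age = rows[[age_col]], y = rows[[response]])
  d <- d[complete.cases(d), ]
  if (nrow(d) < 3) abort("need at least 3 complete rows",
                         class = "dnmtrio_input_error")
  if (sd(d$age) == 0) abort("degenerate (constant) predictor",
                            class = "dnmtrio_input_error")
  fit <- lm(y ~ age, data = d)
  ci <- stats::confint(fit)["age", ]
  p <- if (sd(d$y) == 0) 1 else cor.test(d$age, d$y)$p.value
  new_dnm_fit(
    model = paste0("linear-", parent, "-age"),
    slope = unname(coef(fit)["age"]),
    intercept = unname(coef(fit)[1]),
    conf_low = ci[1], conf_high = ci[2],
    p_value = p, n = nrow(d), fit = fit
  )
}

#' Identity-link Poisson regression of DNM count on paternal age
#'
#' Maximum-likelihood Poisson fit with identity link, so the slope reads
#' directly as additional DNMs per year of father's age. Starting values come
#' from an OLS pre-fit; if the identity-link IRLS fails or produces
#' non-positive fitted means, a damped-slope restart is attempted before
#' giving up with a convergence error. With `interaction = TRUE` the model
#' adds a family term and a family-by-age interaction on families with at
#' least `min_offspring` children, returning per-family slopes and a
#' likelihood-ratio test against the no-interaction model on the same rows.
#'
#' @param rows Cohort tibble with `dnm_count`, `father_age`, `family_id`.
#' @param interaction Fit per-family intercepts and slopes.
#' @param min_offspring Family-size cutoff for the interaction model.
#' @return A `dnm_fit` object; with interaction, `per_family` is a tibble of
#'   per-family slopes with Wald intervals, `slope` the average per-family
#'   slope, and `lrt_p` the likelihood-ratio p-value.
#' @export
fit_poisson_identity <- function(rows, interaction = FALSE,
                                 min_offspring = 4) {
  d <- rows[complete.cases(rows[, c("dnm_count", "father_age")]), ]
  if (any(d$dnm_count < 0)) abort("negative counts",
                                  class = "dnmtrio_input_error")
  if (interaction) {
    sizes <- dplyr::count(d, .data$family_id)
    big <- sizes$family_id[sizes$n >= min_offspring]
    if (length(big) < 2) {
      abort(paste("interaction model needs >= 2 families with >=",
                  min_offspring, "children"),
            class = "dnmtrio_input_error")
    }
    d <- d[d$family_id %in% big, ]
    d$family_id <- factor(d$family_id)
  }
  if (sd(d$father_age) == 0) abort("degenerate (constant) predictor",
                                   class = "dnmtrio_input_error")

  glm_identity <- function(formula, data, start) {
    for (damp in c(1, 0.5, 0.1, 0)) {
      st <- start
      st[-1] <- st[-1] * damp
      fit <- tryCatch(
        suppressWarnings(glm(formula, data = data,
                             family = poisson(link = "identity"),
                             start = st,
                             control = list(maxit = 100))),
        error = function(e) NULL
      )
      if (!is.null(fit) && fit$converged && all(fit$fitted.values > 0)) {
        return(fit)
      }
    }
    abort("identity-link Poisson fit did not converge",
          class = "dnmtrio_convergence_error")
  }

  ols <- lm(dnm_count ~ father_age, data = d)
  st0 <- coef(ols)
  if (min(st0[1] + st0[2] * range(d$father_age)) <= 0) {
    st0 <- c(mean(d$dnm_count), 0)
  }
  null_fit <- glm_identity(dnm_count ~ father_age, d, st0)

  if (!interaction) {
    ci <- stats::confint.default(null_fit)["father_age", ]
    s <- summary(null_fit)$coefficients
    return(new_dnm_fit(
      model = "poisson-identity", slope = unname(coef(null_fit)["father_age"]),
      intercept = unname(coef(null_fit)[1]),
      conf_low = ci[1], conf_high = ci[2],
      p_value = s["father_age", 4], n = nrow(d), fit = null_fit
    ))
  }

  k <- nlevels(d$family_id)
  start_int <- c(tapply(d$dnm_count, d$family_id, mean), rep(0, k))
  int_fit <- glm_identity(dnm_count ~ 0 + family_id + family_id:father_age,
                          d, start_int)
  cf <- coef(int_fit)
  slope_idx <- grep(":father_age$", names(cf))
  se <- sqrt(diag(stats::vcov(int_fit)))[slope_idx]
  per_family <- tibble::tibble(
    family_id = sub("^family_id(.*):father_age$", "\\1", names(cf)[slope_idx]),
    slope = unname(cf[slope_idx]),
    conf_low = unname(cf[slope_idx] - 1.96 * se),
    conf_high = unname(cf[slope_idx] + 1.96 * se)
  )
  lrt_df <- length(coef(int_fit)) - length(coef(null_fit))
  lrt_stat <- null_fit$deviance - int_fit$deviance
  lrt_p <- pchisq(lrt_stat, lrt_df, lower.tail = FALSE)
  avg <- mean(per_family$slope)
  se_avg <- sd(per_family$slope) / sqrt(nrow(per_family))
  new_dnm_fit(
    model = "poisson-identity-by-family", slope = avg,
    intercept = NA_real_,
    conf_low = avg - 1.96 * se_avg, conf_high = avg + 1.96 * se_avg,
    p_value = lrt_p, n = nrow(d), fit = int_fit,
    per_family = per_family, lrt_p = lrt_p
  )
}

#' Family-size effect on per-child DNM count
#'
#' Least-squares slope of DNM count on the number of offspring in the
#' family. Sharing of missed parental heterozygotes across siblings makes
#' this slope negative: every extra sequenced sibling gives the
#' sibling-sharing filter another chance to expose an artifact.
#'
#' @param rows Cohort tibble with `dnm_count`, `n_offspring`.
#' @return A `dnm_fit` object.
#' @export
family_size_effect <- function(rows) {
  d <- rows[complete.cases(rows[, c("dnm_count", "n_offspring")]), ]
  if (length(unique(d$n_offspring)) < 2) {
    abort("need at least two distinct family sizes",
          class = "dnmtrio_input_error")
  }
  fit <- lm(dnm_count ~ n_offspring, data = d)
  ci <- stats::confint(fit)["n_offspring", ]
  new_dnm_fit(
    model = "family-size", slope = unname(coef(fit)["n_offspring"]),
    intercept = unname(coef(fit)[1]),
    conf_low = ci[1], conf_high = ci[2],
    p_value = if (sd(d$dnm_count) == 0) 1
              else cor.test(d$n_offspring, d$dnm_count)$p.value,
    n = nrow(d), fit = fit
  )
}

#' Residualize a response on a covariate
#'
#' Adds the residuals of the least-squares fit of `response` on `covariate`
#' as a new column `<response>_resid`; group comparisons on the residuals are
#' the "corrected for" analyses (e.g. DNM count corrected for father's age).
#'
#' @param rows Cohort tibble.
#' @param response,covariate Column names.
#' @return `rows` with the residual column added (rows with a missing
#'   covariate get `NA`).
#' @export
residualize <- function(rows, response = "dnm_count",
                        covariate = "father_age") {
  if (!covariate %in% names(rows) || !response %in% names(rows)) {
    abort("response or covariate column missing",
          class = "dnmtrio_input_error")
  }
  d <- tibble::tibble(y = rows[[response]], x = rows[[covariate]])
  ok <- complete.cases(d)
  fit <- lm(y ~ x, data = d[ok, ])
  res <- rep(NA_real_, nrow(rows))
  res[ok] <- resid(fit)
  rows[[paste0(response, "_resid")]] <- res
  rows
}

#' Pairwise group comparisons
#'
#' Two-sample Student t-tests for every pair of groups, optionally
#' Bonferroni-corrected (each p multiplied by the number of pairs, capped at
#' 1). Groups with fewer than two members are skipped with a message.
#'
#' @param rows Cohort tibble.
#' @param value Name of the numeric column to compare.
#' @param group Name of the grouping column.
#' @param correction `"bonferroni"` or `"none"`.
#' @return Tibble: `group1`, `group2`, `n1`, `n2`, `estimate` (mean
#'   difference), `p_value`, `p_adjusted`.
#' @export
compare_groups <- function(rows, value, group,
                           correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  d <- tibble::tibble(y = rows[[value]], g = as.character(rows[[group]]))
  d <- d[complete.cases(d), ]
  sizes <- table(d$g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    inform(paste("skipping groups with < 2 members:",
                 paste(small, collapse = ", ")))
  }
  groups <- sort(names(sizes)[sizes >= 2])
  if (length(groups) < 2) {
    abort("need at least two groups with two or more members",
          class = "dnmtrio_input_error")
  }
  pairs <- utils::combn(groups, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    y1 <- d$y[d$g == g1]; y2 <- d$y[d$g == g2]
    p <- if (sd(c(y1, y2)) == 0) 1 else t.test(y1, y2, var.equal = TRUE)$p.value
    tibble::tibble(group1 = g1, group2 = g2,
                   n1 = length(y1), n2 = length(y2),
                   estimate = mean(y1) - mean(y2), p_value = p)
  })
  out <- dplyr::bind_rows(out)
  out$p_adjusted <- if (correction == "bonferroni") {
    pmin(out$p_value * nrow(out), 1)
  } else {
    out$p_value
  }
  out
}

#' Compare deleteriousness-score profiles across groups
#'
#' For each child, the fraction of its DNMs exceeding each configured score
#' threshold (CADD, GERP, pLI, or any numeric annotation); fractions are then
#' compared between groups with pairwise t-tests.
#'
#' @param dnms Annotated DNM tibble with `child_id` and the score columns.
#' @param cohort Cohort tibble with `child_id` and the grouping column.
#' @param thresholds Named list mapping score columns to cutoffs, e.g.
#'   `list(cadd = 20, gerp = 2)`.
#' @param group Grouping column in `cohort`.
#' @param correction Multiple-testing correction for [compare_groups()].
#' @return List with `fractions` (per child per score) and `tests` (pairwise
#'   p-values per score).
#' @export
score_profile_compare <- function(dnms, cohort, thresholds, group,
                                  correction = "bonferroni") {
  if (length(thresholds) == 0) abort("empty threshold list",
                                     class = "dnmtrio_input_error")
  fracs <- purrr::imap(thresholds, function(cut, col) {
    dplyr::summarise(
      dplyr::group_by(dnms, .data$child_id),
      score = col,
      fraction = mean(.data[[col]] > cut, na.rm = TRUE),
      .groups = "drop"
    )
  })
  fracs <- dplyr::bind_rows(fracs)
  joined <- dplyr::inner_join(fracs, cohort, by = "child_id")
  tests <- purrr::map(unique(fracs$score), function(sc) {
    sub <- joined[joined$score == sc, ]
    dplyr::mutate(compare_groups(sub, "fraction", group, correction),
                  score = sc, .before = 1)
  })
  list(fractions = fracs, tests = dplyr::bind_rows(tests))
}

# ---- fit container + broom-style methods ----

new_dnm_fit <- function(model, slope, intercept, conf_low, conf_high,
                        p_value, n, fit, per_family = NULL, lrt_p = NULL) {
  structure(
    list(model = model, slope = unname(slope), intercept = intercept,
         conf_low = unname(conf_low), conf_high = unname(conf_high),
         p_value = unname(p_value), n = n, fit = fit,
         per_family = per_family, lrt_p = lrt_p),
    class = "dnm_fit"
  )
}

#' @export
print.dnm_fit <- function(x, ...) {
  cat("<dnm_fit>", x$model, "\n")
  cat(sprintf("  slope %.3f (95%% CI %.3f to %.3f), p = %.3g, n = %d\n",
              x$slope, x$conf_low, x$conf_high, x$p_value, x$n))
  if (!is.null(x$per_family)) {
    cat("  per-family slopes:", nrow(x$per_family), "families, range",
        sprintf("%.2f to %.2f", min(x$per_family$slope),
                max(x$per_family$slope)), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DNM regression fit
#'
#' @param x A `dnm_fit` object.
#' @param ... Unused.
#' @return One row per slope term (per family for the interaction model):
#'   `model`, `term`, `estimate`, `conf.low`, `conf.high`, `p.value`.
#' @method tidy dnm_fit
#' @export
tidy.dnm_fit <- function(x, ...) {
  if (!is.null(x$per_family)) {
    return(tibble::tibble(
      model = x$model,
      term = paste0("father_age:", x$per_family$family_id),
      estimate = x$per_family$slope,
      conf.low = x$per_family$conf_low,
      conf.high = x$per_family$conf_high,
      p.value = NA_real_
    ))
  }
  tibble::tibble(
    model = x$model, term = "slope", estimate = x$slope,
    conf.low = x$conf_low, conf.high = x$conf_high, p.value = x$p_value
  )
}

#' One-row summary of a DNM regression fit
#'
#' @param x A `dnm_fit` object.
#' @param ... Unused.
#' @return Tibble: `model`, `slope`, `conf.low`, `conf.high`, `p.value`,
#'   `n`.
#' @method glance dnm_fit
#' @export
glance.dnm_fit <- function(x, ...) {
  tibble::tibble(model = x$model, slope = x$slope, conf.low = x$conf_low,
                 conf.high = x$conf_high, p.value = x$p_value, n = x$n)
}
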