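#' Kaplan-Meier curves of continued residence
#'
#' Product-limit estimate of the probability of continued residence,
#' optionally stratified by a flag (e.g. kin presence). Right censoring
#' only; computed via [survival::survfit()].
#'
#' @param records a data.frame of residence records with
#'   `duration_months` and `censored` columns.
#' @param group_by optional name of a flag column to stratify by.
#' @return A list of per-stratum data.frames (`time`, `n_risk`,
#'   `n_event`, `surv`), class `km_curve`; the underlying `survfit`
#'   object is kept as an attribute for plotting.
#' @export
km_curve <- function(records, group_by = NULL) {
  records <- as.data.frame(records)
  ev <- !records$censored
  if (is.null(group_by)) {
    f <- survival::survfit(
      survival::Surv(records$duration_months, ev) ~ 1)
    strata_names <- "all"
    idx <- list(seq_along(f$time))
  } else {
    g <- records[[group_by]]
    if (is.null(g)) stop("unknown stratum column: ", group_by)
    if (any(table(g) == 0L)) stop("empty stratum in ", group_by)
    f <- survival::survfit(
      survival::Surv(records$duration_months, ev) ~ g)
    if (is.null(f$strata)) {
      strata_names <- as.character(unique(g))
      idx <- list(seq_along(f$time))
    } else {
      strata_names <- sub("^g=", "", names(f$strata))
      ends <- cumsum(f$strata)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      idx <- Map(seq, starts, ends)
    }
  }
  out <- Map(function(nm, ii) {
    data.frame(time = f$time[ii], n_risk = f$n.risk[ii],
               n_event = f$n.event[ii], surv = f$surv[ii])
  }, strata_names, idx)
  structure(out, class = "km_curve", survfit = f, group_by = group_by)
}

#' @export
print.km_curve <- function(x, ...) {
  for (nm in names(x)) {
    cat("Stratum", nm, ":", nrow(x[[nm]]), "time points, final S(t) =",
        format(min(x[[nm]]$surv), digits = 4), "\n")
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "months since group entry",
                          ylab = "probability of continued residence", ...) {
  f <- attr(x, "survfit")
  graphics::plot(f, lty = seq_along(x), xlab = xlab, ylab = ylab, ...)
  if (length(x) > 1L) {
    graphics::legend("topright", legend = names(x), lty = seq_along(x))
  }
  invisible(x)
}

# shared result container for the residence-time and tenure fits
.residence_fit <- function(model, coefficients, chi2_lr, df_lr, n, n_events,
                           n_excluded = 0L, converged = TRUE, notes = NULL) {
  structure(list(model = model, coefficients = coefficients,
                 chi2_lr = chi2_lr, df_lr = df_lr,
                 p_lr = stats::pchisq(chi2_lr, df_lr, lower.tail = FALSE),
                 n = n, n_events = n_events, n_excluded = n_excluded,
                 converged = converged, notes = notes),
            class = "residence_fit")
}

#' @export
print.residence_fit <- function(x, ...) {
  cat(x$model, "fit: n =", x$n, ", events =", x$n_events)
  if (x$n_excluded > 0L) cat(" (", x$n_excluded, "records excluded )")
  cat("\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("LR chi2(%d) = %.3f, p = %.4g\n", x$df_lr, x$chi2_lr, x$p_lr))
  if (!x$converged) cat("WARNING: fit did not converge cleanly:", x$notes, "\n")
  invisible(x)
}

#' @export
coef.residence_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' Cox proportional-hazards fit of residence time
#'
#' Partial-likelihood fit (Breslow ties by default) of the hazard of
#' leaving a group on one or more flags, e.g. kin presence and dispersal
#' type with their interaction. The likelihood-ratio statistic compares
#' the full model against the covariate-free null. A monotone likelihood
#' (complete separation) is flagged in the result rather than raised.
#'
#' @param records residence records (`duration_months`, `censored`, and
#'   the covariate columns).
#' @param covariates character vector of covariate column names.
#' @param interaction optional length-2 character vector naming two
#'   covariates whose interaction is added.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `residence_fit` with per-covariate `beta`, `se`, `z`, `p`
#'   and the model LR chi-square.
#' @export
cox_fit <- function(records, covariates, interaction = NULL,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  records <- as.data.frame(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  ev <- !records$censored
  if (!any(ev)) stop("no events: Cox fit undefined")
  terms <- covariates
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2L, all(interaction %in% covariates))
    terms <- c(terms, paste(interaction, collapse = ":"))
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(duration_months, .event) ~", paste(terms, collapse = " + ")))
  dat <- records
  dat$.event <- ev
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- data.frame(term = rownames(s$coefficients),
                   beta = s$coefficients[, "coef"],
                   se = s$coefficients[, "se(coef)"],
                   z = s$coefficients[, "z"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL)
  bad <- !is.null(warn) && grepl("infinite|converge|beta may be", warn,
                                 ignore.case = TRUE)
  bad <- bad || any(!is.finite(co$beta)) || any(abs(co$beta) > 15)
  .residence_fit("Cox (ties = breslow)" , co,
                 chi2_lr = 2 * (fit$loglik[2] - fit$loglik[1]),
                 df_lr = length(stats::coef(fit)),
                 n = nrow(dat), n_events = sum(ev),
                 converged = !bad, notes = warn)
}

#' Likelihood-ratio test of staying one year
#'
#' Logistic regression of the indicator "resided at least 12 months" on a
#' presence flag, tested against the intercept-only null by a maximum
#' likelihood-ratio chi-square. Records censored before month 12 carry no
#' information about the outcome and are excluded (the count is
#' reported). Perfect separation is flagged in the result.
#'
#' @param records residence records.
#' @param predictor name of the flag column.
#' @return A `residence_fit`.
#' @export
stay_one_year_test <- function(records, predictor) {
  records <- as.data.frame(records)
  if (!predictor %in% names(records)) stop("unknown predictor: ", predictor)
  drop <- records$censored & records$duration_months < 12
  d <- records[!drop, , drop = FALSE]
  y <- d$duration_months >= 12
  if (length(unique(y)) < 2L) {
    stop("all outcomes identical: one-year-stay test undefined")
  }
  x <- d[[predictor]]
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  chi2 <- fit$null.deviance - fit$deviance
  s <- summary(fit)$coefficients
  co <- data.frame(term = c("(Intercept)", predictor),
                   beta = s[, "Estimate"], se = s[, "Std. Error"],
                   z = s[, "z value"], p = s[, "Pr(>|z|)"],
                   row.names = NULL)
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 15)
  .residence_fit("Logistic (stay >= 12 months)", co,
                 chi2_lr = chi2, df_lr = 1L,
                 n = nrow(d), n_events = sum(y), n_excluded = sum(drop),
                 converged = !sep,
                 notes = if (sep) {
                   "perfect separation: beta unbounded; interpret via the LR statistic (a median-unbiased/penalized fit would bound it)"
                 })
}

#' Linear model of high-rank tenure
#'
#' Compares high-rank tenure (months at rank 1-3) between males with and
#' without co-resident related males, after the eligibility filter: a
#' male's tenure counts if his best rank was 1-3, tightened to 1-2 when
#' fewer than five non-natal males resided in the group. Ordinary least
#' squares with a Gaussian likelihood-ratio chi-square against the
#' intercept-only null.
#'
#' @param records residence records with `high_rank_tenure_months`,
#'   `max_rank` and `group_n_nonnatal_males`.
#' @param predictor name of the flag column.
#' @param min_males_rule apply the small-group rank-1-2 tightening
#'   (default `TRUE`).
#' @return A `residence_fit`.
#' @export
tenure_model <- function(records, predictor, min_males_rule = TRUE) {
  records <- as.data.frame(records)
  if (!predictor %in% names(records)) stop("unknown predictor: ", predictor)
  eligible <- !is.na(records$high_rank_tenure_months) &
    records$max_rank <= 3L &
    (!min_males_rule | records$group_n_nonnatal_males >= 5L |
       records$max_rank <= 2L)
  d <- records[eligible, , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("fewer than 3 records eligible after the high-rank filter ",
         "(rank <= 3, or <= 2 in groups with < 5 non-natal males)")
  }
  x <- d[[predictor]]
  fit <- stats::lm(high_rank_tenure_months ~ x, data = d)
  fit0 <- stats::lm(high_rank_tenure_months ~ 1, data = d)
  n <- nrow(d)
  chi2 <- n * (log(sum(stats::resid(fit0)^2)) - log(sum(stats::resid(fit)^2)))
  s <- summary(fit)$coefficients
  co <- data.frame(term = c("(Intercept)", predictor),
                   beta = s[, "Estimate"], se = s[, "Std. Error"],
                   z = s[, "t value"], p = s[, "Pr(>|t|)"],
                   row.names = NULL)
  .residence_fit("OLS (high-rank tenure)", co,
                 chi2_lr = chi2, df_lr = 1L,
                 n = n, n_events = n,
                 n_excluded = nrow(records) - n)
}

#' Cluster bootstrap over males
#'
#' Resamples whole males (all their records) with replacement and refits,
#' giving a percentile confidence interval and bootstrap SE for the
#' predictor effect. This propagates within-male dependence into interval
#' estimates and stands in for a random intercept per male, which is
#' weakly identified with only a couple of spells per male.
#'
#' @param records residence records.
#' @param fit_fun a function `records -> residence_fit` (e.g.
#'   `function(d) cox_fit(d, "kin_at_entry")`), or one of the names
#'   `"cox_fit"`, `"stay_one_year_test"`, `"tenure_model"` (then
#'   `predictor` is passed through).
#' @param predictor predictor name when `fit_fun` is given by name.
#' @param cluster_key column identifying the cluster (default `male_id`).
#' @param n_boot bootstrap replicates (>= 200).
#' @param conf confidence level for the percentile interval.
#' @param seed optional integer seed.
#' @return List with `beta` (original-fit effect), `boot_se`, `ci`
#'   (percentile), `n_boot`, `failure_rate`; class `cluster_bootstrap`.
#'   A refit-failure rate above 10% triggers a warning.
#' @export
cluster_bootstrap <- function(records, fit_fun, predictor = NULL,
                              cluster_key = "male_id", n_boot = 500L,
                              conf = 0.95, seed = NULL) {
  stopifnot(n_boot >= 200L)
  records <- as.data.frame(records)
  if (is.character(fit_fun)) {
    nm <- match.arg(fit_fun, c("cox_fit", "stay_one_year_test", "tenure_model"))
    if (is.null(predictor)) stop("predictor required when fit_fun is a name")
    fit_fun <- switch(nm,
      cox_fit = function(d) cox_fit(d, predictor),
      stay_one_year_test = function(d) stay_one_year_test(d, predictor),
      tenure_model = function(d) tenure_model(d, predictor))
  }
  eff <- function(f) {
    b <- f$coefficients$beta
    b[length(b)]  # the (last) predictor term; intercept first where present
  }
  base <- fit_fun(records)
  clusters <- unique(records[[cluster_key]])
  with_seed(seed, {
    bs <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      pick <- sample(clusters, length(clusters), replace = TRUE)
      d <- do.call(rbind, lapply(seq_along(pick), function(j) {
        rows <- records[records[[cluster_key]] == pick[j], , drop = FALSE]
        rows[[cluster_key]] <- paste0(rows[[cluster_key]], ".b", j)
        rows
      }))
      bs[b] <- tryCatch(eff(fit_fun(d)), error = function(e) NA_real_)
    }
    fail <- mean(!is.finite(bs))
    if (fail > 0.10) {
      warning(sprintf("bootstrap refit failure rate %.1f%% exceeds 10%%",
                      100 * fail))
    }
    okv <- bs[is.finite(bs)]
    a <- (1 - conf) / 2
    structure(list(beta = eff(base), boot_se = stats::sd(okv),
                   ci = stats::quantile(okv, c(a, 1 - a), names = FALSE),
                   conf = conf, n_boot = n_boot, failure_rate = fail),
              class = "cluster_bootstrap")
  })
}

#' @export
print.cluster_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Cluster bootstrap (%d reps): beta = %.3f, boot SE = %.3f, %.0f%% CI [%.3f, %.3f]\n",
    x$n_boot, x$beta, x$boot_se, 100 * x$conf, x$ci[1], x$ci[2]))
  if (x$failure_rate > 0) {
    cat(sprintf("refit failures: %.1f%%\n", 100 * x$failure_rate))
  }
  invisible(x)
}
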