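# Outcome association: group comparisons, Kaplan-Meier / log-rank, and
# Cox proportional hazards with the clinical covariate set (age group,
# sex, TNM stage). Fits are backed by the survival package; behaviour is
# pinned by hand-worked oracles in the test suite.

#' Compare two groups of continuous measurements
#'
#' Unpaired data are compared with the Wilcoxon rank-sum test (exact p
#' when both arms are small and tie-free, tie-corrected normal
#' approximation otherwise); matched samples with a paired t-test. Both
#' tests are two-sided. The reported statistic is signed (the centred
#' rank sum `W - n1*n2/2`, or the paired t statistic), so swapping the
#' arms flips its sign and leaves p unchanged.
#'
#' Two degenerate paired cases are distinguished: all differences exactly
#' zero returns statistic 0 with p = 1; identical nonzero differences
#' (zero variance, nonzero effect) is an error.
#'
#' @param values_a,values_b Numeric vectors (>= 2 observations each;
#'   paired arms must have equal length).
#' @param paired Logical.
#'
#' @return Object of class `group_comparison`: `statistic`, `p.value`,
#'   `method`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least 2 observations per arm", call. = FALSE)
  if (paired) {
    if (length(values_a) != length(values_b))
      stop("paired arms must have equal length", call. = FALSE)
    d <- values_a - values_b
    if (all(d == 0)) {
      res <- list(statistic = 0, p.value = 1,
                  method = "Paired t-test (identical samples)")
    } else if (diff(range(d)) <= 1e-12 * max(abs(d))) {
      stop("degenerate paired differences: identical nonzero values (zero variance)",
           call. = FALSE)
    } else {
      ht <- t.test(values_a, values_b, paired = TRUE)
      res <- list(statistic = unname(ht$statistic), p.value = ht$p.value,
                  method = "Paired t-test")
    }
  } else {
    ht <- suppressWarnings(wilcox.test(values_a, values_b))
    res <- list(statistic = unname(ht$statistic) -
                  length(values_a) * length(values_b) / 2,
                p.value = ht$p.value,
                method = "Wilcoxon rank-sum test (centred statistic)")
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p.value))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test for a dichotomised feature
#'
#' Splits the cohort into low/high strata at the median of the feature
#' (or an explicit value); ties go to the low group. Overall survival is
#' estimated per stratum by the Kaplan-Meier method and the strata
#' compared with the two-group log-rank test (1 df chi-square, two-sided
#' p). A stratum without events is analysed but flagged with a warning.
#'
#' @param cohort Data frame with `os_time` (> 0), `event` (0/1) and the
#'   feature column.
#' @param feature Name of the feature column.
#' @param cutpoint_rule `"median"` or `"value"`.
#' @param cutpoint_value Cut value when `cutpoint_rule = "value"`.
#'
#' @return Object of class `km_logrank`: `feature`, `cutpoint`,
#'   group sizes `n`, `chisq`, `p`, and the `survfit` object `fit`.
#' @export
km_logrank <- function(cohort, feature,
                       cutpoint_rule = c("median", "value"),
                       cutpoint_value = NULL) {
  cutpoint_rule <- match.arg(cutpoint_rule)
  if (!feature %in% names(cohort))
    stop(sprintf("feature '%s' not in cohort table", feature), call. = FALSE)
  v <- cohort[[feature]]
  cut <- if (cutpoint_rule == "median") median(v, na.rm = TRUE)
         else cutpoint_value %||% stop_config("cutpoint_value required")
  group <- factor(ifelse(v <= cut, "low", "high"),
                  levels = c("low", "high"))
  if (any(table(group) == 0L))
    stop("a stratum is empty after the split", call. = FALSE)
  df <- data.frame(os_time = cohort$os_time, event = cohort$event,
                   group = group)
  ev <- tapply(df$event, df$group, sum)
  if (any(ev == 0))
    warning(sprintf("stratum without events: %s",
                    paste(names(ev)[ev == 0], collapse = ", ")),
            call. = FALSE)
  fit <- survival::survfit(survival::Surv(os_time, event) ~ group,
                           data = df)
  sdf <- survival::survdiff(survival::Surv(os_time, event) ~ group,
                            data = df)
  chisq <- unname(sdf$chisq)
  structure(list(feature = feature, cutpoint = cut,
                 n = as.integer(table(group)), chisq = chisq,
                 p = pchisq(chisq, df = 1, lower.tail = FALSE),
                 fit = fit, data = df),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Kaplan-Meier / log-rank for '%s' (cut at %.4g)\n",
              x$feature, x$cutpoint))
  cat(sprintf("  n(low/high) = %d/%d, chi-square = %.4g, p = %.4g\n",
              x$n[1], x$n[2], x$chisq, x$p))
  invisible(x)
}

#' @export
plot.km_logrank <- function(x, ...) {
  plot(x$fit, col = c("steelblue", "firebrick"), xlab = "time (months)",
       ylab = "overall survival",
       main = sprintf("%s (log-rank p = %.3g)", x$feature, x$p), ...)
  legend("bottomleft", c("low", "high"), lty = 1,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Cox proportional-hazards association of features with survival
#'
#' Fits, per feature, a Cox model (partial likelihood, Efron tie
#' handling) of overall survival on the feature — univariate, or adjusted
#' for the clinical covariates (multivariate). TNM stage is encoded
#' ordinally (I-IV as 1-4) by default, or as dummy variables. With
#' `joint = TRUE` all features enter a single model together.
#'
#' Non-convergence or monotone likelihood (separation) is reported as an
#' explicit failed fit (`fit_failed = TRUE`, NA estimates), never as
#' silent numbers.
#'
#' @param cohort Data frame with `os_time`, `event`, the features, and
#'   (for multivariate fits) `age_group`, `sex`, `tnm_stage`.
#' @param features Character vector of feature column names.
#' @param covariates Clinical adjustment set (multivariate mode).
#' @param multivariate Logical; `FALSE` drops the covariates.
#' @param joint Logical; fit all features in one model.
#' @param stage_coding `"ordinal"` or `"dummy"`.
#'
#' @return Object of class `cox_result`: a data frame with one row per
#'   model term (`feature`, `term`, `loghr`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`, `n_events`, `fit_failed`).
#' @export
cox_model <- function(cohort, features,
                      covariates = c("age_group", "sex", "tnm_stage"),
                      multivariate = TRUE, joint = FALSE,
                      stage_coding = c("ordinal", "dummy")) {
  stage_coding <- match.arg(stage_coding)
  miss <- setdiff(c(features, if (multivariate) covariates), names(cohort))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  n_events <- sum(cohort$event)
  if (n_events < 10L)
    stop(sprintf("too few events for a Cox fit (%d < 10)", n_events),
         call. = FALSE)
  df <- cohort
  if (multivariate && "tnm_stage" %in% covariates &&
      stage_coding == "ordinal")
    df$tnm_stage <- as.integer(factor(df$tnm_stage,
                                      levels = c("I", "II", "III", "IV")))
  terms_of <- function(fs) c(fs, if (multivariate) covariates)
  check_constant <- function(fs) {
    for (v in terms_of(fs)) {
      x <- df[[v]]
      if (length(unique(x[!is.na(x)])) < 2L)
        stop(sprintf("constant covariate: %s", v), call. = FALSE)
    }
  }
  fit_one <- function(fs) {
    check_constant(fs)
    fml <- as.formula(paste("survival::Surv(os_time, event) ~",
                            paste(terms_of(fs), collapse = " + ")))
    failed <- FALSE
    fit <- withCallingHandlers(
      tryCatch(survival::coxph(fml, data = df, ties = "efron"),
               error = function(e) { failed <<- TRUE; NULL }),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be infinite|out of iterations",
                  conditionMessage(w), ignore.case = TRUE))
          failed <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!failed && !is.null(fit) &&
        (any(is.na(coef(fit))) || any(abs(coef(fit)) > 15)))
      failed <- TRUE
    lab <- paste(fs, collapse = "+")
    if (failed || is.null(fit)) {
      return(data.frame(feature = lab, term = terms_of(fs),
                        loghr = NA_real_, se = NA_real_, hr = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        p = NA_real_, n_events = n_events,
                        fit_failed = TRUE, stringsAsFactors = FALSE))
    }
    b <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    z <- qnorm(0.975)
    data.frame(feature = lab, term = names(b), loghr = unname(b),
               se = unname(se), hr = exp(unname(b)),
               ci_lower = exp(unname(b) - z * se),
               ci_upper = exp(unname(b) + z * se),
               p = 2 * stats::pnorm(-abs(unname(b) / se)),
               n_events = n_events, fit_failed = FALSE,
               stringsAsFactors = FALSE)
  }
  res <- if (joint) fit_one(features)
         else do.call(rbind, lapply(features, fit_one))
  structure(res, class = c("cox_result", "data.frame"))
}

#' @export
`[.cox_result` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%d events)\n", x$n_events[1L]))
  df <- data.frame(feature = x$feature, term = x$term,
                   HR = sprintf("%.3f", x$hr),
                   `95% CI` = sprintf("[%.3f, %.3f]", x$ci_lower,
                                      x$ci_upper),
                   p = sprintf("%.4g", x$p), check.names = FALSE)
  df$HR[x$fit_failed] <- "fit failed"
  print(df, row.names = FALSE)
  invisible(x)
}
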