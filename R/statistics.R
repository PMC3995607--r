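# Outcome-analysis battery for symptomatic (grade >= 2) radiation
# pneumonitis: association tests, logistic and Cox modelling with
# backward-AIC selection, Holm adjustment, Nagelkerke R2, ROC with DeLong
# CI and the Youden cutpoint, depth-2 recursive partitioning, Kaplan-Meier
# terciles and Bland-Altman inter-reader limits of agreement.

.Z95 <- 1.96  # fixed z-multiplier for all reported 95% intervals

#' Association test between a covariate and the symptomatic outcome
#'
#' Categorical covariates use Pearson's chi-squared test (with Yates
#' continuity correction on 2 x 2 tables); continuous covariates use the
#' two-sided Mann-Whitney U test.
#'
#' @param data data frame of patient records.
#' @param covariate column name to test.
#' @param outcome logical/binary outcome column (default `"symptomatic"`).
#' @return list with `covariate`, `test`, `statistic`, `df` (chi-squared
#'   only) and two-sided `p_value`.
#' @export
association_tests <- function(data, covariate, outcome = "symptomatic") {
  x <- data[[covariate]]
  y <- as.logical(data[[outcome]])
  if (is.null(x)) stop("no column `", covariate, "`")
  if (is.character(x) || is.factor(x) || is.logical(x)) {
    fx <- if (is.factor(x)) x else factor(x)   # keep declared (unused) levels
    tab <- table(fx, factor(y, levels = c(FALSE, TRUE)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0))
      stop("expected cell count of 0 for `", covariate,
           "`; merge sparse categories before testing")
    ct <- suppressWarnings(chisq.test(tab))  # Yates-corrected iff 2 x 2
    list(covariate = covariate, test = "chi-squared",
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(x[y], x[!y], exact = FALSE))
    list(covariate = covariate, test = "mann-whitney",
         statistic = unname(wt$statistic), df = NA_real_,
         p_value = wt$p.value)
  }
}

#' Nagelkerke's coefficient of determination
#'
#' `R2 = (1 - exp((2/n) (LL0 - LL1))) / (1 - exp((2/n) LL0))`, the
#' Cox-Snell ratio rescaled to \[0, 1\].
#'
#' @param loglik fitted-model log-likelihood.
#' @param null_loglik intercept-only log-likelihood over the same records.
#' @param n number of records.
#' @return value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik, null_loglik, n) {
  if (loglik < null_loglik - 1e-8)
    stop("fitted log-likelihood below the null; models are not nested on the same records")
  r2 <- (1 - exp((2 / n) * (null_loglik - loglik))) /
    (1 - exp((2 / n) * null_loglik))
  min(max(r2, 0), 1)
}

coef_table <- function(est, se, ratio_name = "or") {
  z <- est / se
  out <- data.frame(term = names(est), coef = unname(est), se = unname(se),
                    z = unname(z),
                    p = unname(2 * pnorm(-abs(z))),
                    stringsAsFactors = FALSE)
  out[[ratio_name]] <- exp(out$coef)
  out[[paste0(ratio_name, "_lo")]] <- exp(out$coef - .Z95 * out$se)
  out[[paste0(ratio_name, "_hi")]] <- exp(out$coef + .Z95 * out$se)
  rownames(out) <- NULL
  out
}

check_fit_sane <- function(est, se, what = "logistic") {
  bad <- !is.finite(est) | !is.finite(se) | se > 1e3 | abs(est) > 50
  if (any(bad))
    stop(what, " fit did not converge (possible complete separation); ",
         "offending term(s): ", paste(names(est)[bad], collapse = ", "))
}

#' Fit a logistic regression for symptomatic pneumonitis
#'
#' Maximum-likelihood logistic regression (IRLS, tolerance 1e-8, at most
#' 100 iterations) with two-sided Wald tests, odds ratios
#' `exp(coef)` with `exp(coef +/- 1.96 se)` intervals, and Nagelkerke R2.
#'
#' @param formula model formula with a logical/binary response, or a
#'   character vector of predictor terms when `response` is given.
#' @param data data frame of patient records (>= 10 complete rows).
#' @param response response column name when `formula` is a term vector.
#' @return an object of class `rp_logit` with a coefficient `table`,
#'   `loglik`, `null_loglik`, `aic`, `nagelkerke_r2`, `n` and the
#'   underlying `glm` fit.
#' @export
fit_logistic <- function(formula, data, response = "symptomatic") {
  if (is.character(formula))
    formula <- as.formula(paste(response, "~", paste(formula, collapse = " + ")))
  mf <- stats::model.frame(formula, data)
  if (nrow(mf) < 10) stop("need at least 10 complete records")
  y <- mf[[1]]
  if (length(unique(as.numeric(y))) < 2)
    stop("outcome is constant; logistic model is undefined")
  fit <- withCallingHandlers(
    glm(formula, data = mf, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      # separation shows up as this warning; it is re-raised as an error below
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged) stop("IRLS did not converge within 100 iterations")
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  check_fit_sane(est, se, "logistic")
  null_fit <- update(fit, . ~ 1)
  ll1 <- as.numeric(logLik(fit)); ll0 <- as.numeric(logLik(null_fit))
  structure(list(table = coef_table(est, se, "or"),
                 loglik = ll1, null_loglik = ll0,
                 aic = stats::AIC(fit),
                 nagelkerke_r2 = nagelkerke_r2(ll1, ll0, nrow(mf)),
                 n = nrow(mf), fit = fit, formula = formula),
            class = "rp_logit")
}

#' @export
print.rp_logit <- function(x, ...) {
  cat(sprintf("Logistic model for symptomatic RP  (n = %d, AIC = %.1f, Nagelkerke R2 = %.3f)\n",
              x$n, x$aic, x$nagelkerke_r2))
  tab <- x$table
  tab$`OR (95% CI)` <- sprintf("%.2f (%.2f, %.2f)", tab$or, tab$or_lo, tab$or_hi)
  print(data.frame(term = tab$term, coef = round(tab$coef, 3),
                   se = round(tab$se, 3), `OR (95% CI)` = tab$`OR (95% CI)`,
                   p = signif(tab$p, 3), check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.rp_logit <- function(object, ...) coef(object$fit)

#' @export
summary.rp_logit <- function(object, ...) object$table

#' @export
predict.rp_logit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  predict(object$fit, newdata = newdata, type = match.arg(type))
}

#' Holm (sequentially rejective Bonferroni) adjustment
#'
#' Step-down procedure: sort the p-values ascending, compare the i-th
#' against `alpha / (m - i + 1)`, stop at the first failure.  Adjusted
#' p-values are monotone and never smaller than the raw ones.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha familywise error rate (default 0.05).
#' @return data frame with `p`, `p_adjusted` and `reject`, in input order.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "holm")
  data.frame(p = p, p_adjusted = adj, reject = adj <= alpha)
}

#' Backward model selection by AIC
#'
#' Starts from the full model over `candidates` and repeatedly drops the
#' single term whose removal lowers the AIC the most, stopping when no drop
#' improves it.  Deterministic given the data.  For `family = "cox"` the
#' partial-likelihood AIC is used.
#'
#' @param data data frame of patient records, complete for all candidates.
#' @param candidates character vector of candidate terms.
#' @param family `"logistic"` or `"cox"`.
#' @param response outcome column (logistic) .
#' @param time,event time/status columns (cox).
#' @return list with `selected` (character vector, possibly empty) and
#'   `fit` (an `rp_logit`/`rp_cox` refit on the selected terms, or `NULL`
#'   if the final model is empty).
#' @export
backward_aic_select <- function(data, candidates,
                                family = c("logistic", "cox"),
                                response = "symptomatic",
                                time = "time_days", event = "event") {
  family <- match.arg(family)
  if (!length(candidates)) stop("candidate set is empty")
  cc <- stats::complete.cases(data[, candidates, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  rhs <- paste(candidates, collapse = " + ")
  full <- tryCatch(
    if (family == "logistic") {
      glm(as.formula(paste(response, "~", rhs)), data = data,
          family = binomial(), control = glm.control(epsilon = 1e-8, maxit = 100))
    } else {
      survival::coxph(
        as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", rhs)),
        data = data, ties = "efron")
    },
    error = function(e) stop("full model failed to fit: ", conditionMessage(e)))
  sel <- step(full, direction = "backward", trace = 0,
              scope = list(lower = ~1))
  selected <- attr(stats::terms(sel), "term.labels")
  fit <- if (!length(selected)) NULL
  else if (family == "logistic") fit_logistic(selected, data, response = response)
  else cox_fit(selected, data, time = time, event = event)
  list(selected = selected, fit = fit, family = family,
       aic_full = stats::AIC(full), aic_selected = stats::AIC(sel))
}

#' ROC analysis with DeLong interval and Youden cutpoint
#'
#' AUC by the trapezoidal rule over all unique score thresholds (equal to
#' the Mann-Whitney concordance probability), variance by DeLong's
#' structural components, `CI = AUC +/- 1.96 SE`, and the Youden point
#' maximising `J = sensitivity + specificity - 1` with ties broken toward
#' higher specificity.
#'
#' @param scores numeric risk scores (higher = more likely symptomatic).
#' @param outcomes logical/binary outcomes; both classes must be present.
#' @return an object of class `rp_roc`.
#' @export
roc_delong_youden <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  if (length(scores) != length(y)) stop("scores and outcomes differ in length")
  if (!any(y) || all(y)) stop("both outcome classes must be present")
  if (length(unique(scores)) == 1L) {
    warning("constant scores: AUC 0.5, DeLong interval undefined")
    return(structure(list(thresholds = numeric(), sensitivity = numeric(),
                          specificity = numeric(), auc = 0.5,
                          auc_se = NA_real_, auc_ci_95 = c(NA_real_, NA_real_),
                          ci_defined = FALSE,
                          youden_threshold = NA_real_,
                          youden_sensitivity = NA_real_,
                          youden_specificity = NA_real_,
                          n_pos = sum(y), n_neg = sum(!y)),
                     class = "rp_roc"))
  }
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  # a degenerate (AUC = 1) curve has zero DeLong variance; that is fine here
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  se <- sqrt(v)
  ci <- auc + c(-1, 1) * .Z95 * se
  sens <- r$sensitivities; spec <- r$specificities; thr <- r$thresholds
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]           # ties -> higher specificity
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_se = se,
                 auc_ci_95 = pmin(pmax(ci, 0), 1), ci_defined = TRUE,
                 youden_threshold = thr[best],
                 youden_sensitivity = sens[best],
                 youden_specificity = spec[best],
                 n_pos = sum(y), n_neg = sum(!y)),
            class = "rp_roc")
}

#' @export
print.rp_roc <- function(x, ...) {
  if (isTRUE(x$ci_defined)) {
    cat(sprintf("ROC: AUC = %.3f (DeLong 95%% CI %.3f - %.3f)\n",
                x$auc, x$auc_ci_95[1], x$auc_ci_95[2]))
    cat(sprintf("Youden point: threshold %.4g, sensitivity %.0f%%, specificity %.0f%%\n",
                x$youden_threshold, 100 * x$youden_sensitivity,
                100 * x$youden_specificity))
  } else cat("ROC: constant scores, AUC 0.5 (interval undefined)\n")
  invisible(x)
}

#' @export
plot.rp_roc <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("AUC %.2f (%.2f-%.2f)", x$auc,
                      x$auc_ci_95[1], x$auc_ci_95[2]), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::points(1 - x$youden_specificity, x$youden_sensitivity, pch = 19)
  invisible(x)
}

#' Depth-2 recursive partitioning of the symptomatic outcome
#'
#' Greedy binary splits minimising Gini impurity, maximum depth 2, minimum
#' leaf size `min_leaf`, candidate thresholds at midpoints of consecutive
#' sorted unique values, equal misclassification costs.  If no split
#' reduces impurity the result is a single (majority-class) leaf.
#'
#' @param data data frame of patient records.
#' @param predictors predictor columns (default SUV95 and V30).
#' @param outcome binary outcome column.
#' @param min_leaf minimum observations per leaf (default 5).
#' @param max_depth maximum tree depth (default 2).
#' @return an object of class `rp_partition` with a `splits` table, the
#'   training `sensitivity`/`specificity` of the induced rule, and the
#'   underlying `rpart` tree.
#' @export
recursive_partition <- function(data, predictors = c("suv_p95", "v30"),
                                outcome = "symptomatic",
                                min_leaf = 5, max_depth = 2) {
  if (nrow(data) < 20) stop("need at least 20 records")
  y <- factor(as.logical(data[[outcome]]), levels = c(FALSE, TRUE))
  df <- data[, predictors, drop = FALSE]
  df$.y <- y
  if (length(unique(y)) < 2) {
    pred <- rep(levels(y)[which.max(table(y))], nrow(df))
    return(structure(list(splits = data.frame(variable = character(),
                                              threshold = numeric(),
                                              symptomatic_side = character()),
                          sensitivity = if (any(y == "TRUE")) 1 else NA_real_,
                          specificity = if (any(y == "FALSE")) 1 else NA_real_,
                          tree = NULL, n = nrow(df)),
                     class = "rp_partition"))
  }
  tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                       parms = list(split = "gini"),
                       control = rpart::rpart.control(
                         maxdepth = max_depth, minbucket = min_leaf,
                         minsplit = 2 * min_leaf, cp = 0, xval = 0,
                         maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  fr <- tree$frame
  spl <- tree$splits
  splits <- data.frame(variable = character(), threshold = numeric(),
                       symptomatic_side = character(),
                       stringsAsFactors = FALSE)
  if (!is.null(spl) && nrow(fr) > 1) {
    internal <- which(fr$var != "<leaf>")
    node_no <- as.integer(rownames(fr))
    si <- 0
    for (node in internal) {
      si <- si + 1
      # right child (node 2k+1) holds x >= threshold when ncat = -1
      rc <- match(2L * node_no[node] + 1L, node_no)
      right_class <- levels(y)[fr$yval[rc]]
      high_is_right <- spl[si, "ncat"] < 0
      splits <- rbind(splits, data.frame(
        variable = as.character(fr$var[node]),
        threshold = spl[si, "index"],
        symptomatic_side = if ((right_class == "TRUE") == high_is_right)
          "high" else "low",
        stringsAsFactors = FALSE))
    }
  }
  pred <- predict(tree, type = "class")
  sens <- mean(pred[y == "TRUE"] == "TRUE")
  spec <- mean(pred[y == "FALSE"] == "FALSE")
  structure(list(splits = splits, sensitivity = sens, specificity = spec,
                 tree = tree, n = nrow(df)),
            class = "rp_partition")
}

#' @export
print.rp_partition <- function(x, ...) {
  cat(sprintf("Recursive partition (depth <= 2, n = %d): %d split(s)\n",
              x$n, nrow(x$splits)))
  if (nrow(x$splits))
    for (i in seq_len(nrow(x$splits)))
      cat(sprintf("  %s > %.4g\n", x$splits$variable[i], x$splits$threshold[i]))
  cat(sprintf("  training sensitivity %.0f%%, specificity %.0f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Kaplan-Meier curves across SUV95 terciles
#'
#' Product-limit curves of time to symptomatic pneumonitis stratified by
#' SUV95 tercile.  Boundaries are the empirical terciles of `by` unless
#' `paper_compat = TRUE` (pins them at 0.99 and 1.2) or explicit
#' `boundaries` are given.  The per-stratum median is the earliest time at
#' which survival drops to 0.5 or below (absent if never reached).
#'
#' @param data data frame of patient records.
#' @param time,event time (days, > 0) and event-indicator columns.
#' @param by grouping biomarker column (default `"suv_p95"`).
#' @param boundaries optional length-2 tercile boundaries.
#' @param paper_compat pin the boundaries at `c(0.99, 1.2)`.
#' @return an object of class `rp_km` with the `survfit`, the boundaries,
#'   per-stratum medians and pairwise tercile hazard ratios versus the
#'   lowest tercile.
#' @export
km_fit <- function(data, time = "time_days", event = "event",
                   by = "suv_p95", boundaries = NULL, paper_compat = FALSE) {
  tt <- data[[time]]; ev <- as.logical(data[[event]]); x <- data[[by]]
  if (any(tt <= 0)) stop("times must be > 0")
  if (is.null(boundaries))
    boundaries <- if (paper_compat) c(0.99, 1.2)
    else unname(quantile(x, c(1, 2) / 3, type = 7))
  tercile <- cut(x, c(-Inf, boundaries, Inf),
                 labels = c("T1", "T2", "T3"), right = FALSE)
  df <- data.frame(t = tt, e = as.integer(ev), g = tercile)
  sf <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  med <- summary(sf)$table
  medians <- if (is.matrix(med)) med[, "median"] else med["median"]
  hr <- NULL
  if (sum(ev) > 0 && length(unique(tercile[ev])) >= 1 &&
      nlevels(droplevels(tercile)) > 1) {
    cx <- tryCatch(survival::coxph(survival::Surv(t, e) ~ g, data = df,
                                   ties = "efron"),
                   error = function(e) NULL)
    if (!is.null(cx)) {
      est <- coef(cx); se <- sqrt(diag(vcov(cx)))
      hr <- coef_table(est, se, "hr")
    }
  }
  structure(list(survfit = sf, boundaries = boundaries,
                 tercile = tercile, medians = medians,
                 tercile_hr = hr, n = nrow(df), n_events = sum(ev)),
            class = "rp_km")
}

#' @export
print.rp_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier terciles (boundaries %.3g, %.3g; %d events / %d patients)\n",
              x$boundaries[1], x$boundaries[2], x$n_events, x$n))
  print(round(x$medians, 1))
  if (!is.null(x$tercile_hr)) {
    cat("Tercile hazard ratios vs T1:\n")
    print(data.frame(term = x$tercile_hr$term,
                     `HR (95% CI)` = sprintf("%.2f (%.2f, %.2f)",
                                             x$tercile_hr$hr,
                                             x$tercile_hr$hr_lo,
                                             x$tercile_hr$hr_hi),
                     check.names = FALSE), row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.rp_km <- function(x, ...) {
  plot(x$survfit, mark.time = TRUE, col = 1:3, lty = 1,
       xlab = "days from start of RT", ylab = "symptom-free fraction", ...)
  graphics::legend("bottomleft", bty = "n", col = 1:3, lty = 1,
                   legend = sprintf("T%d", 1:3))
  invisible(x)
}

#' Cox proportional-hazards regression for time to symptoms
#'
#' Partial-likelihood maximisation with Efron tie handling; hazard ratios
#' `exp(coef)` with `exp(coef +/- 1.96 se)` intervals.
#'
#' @param formula model terms: character vector of predictors or a formula
#'   with a `survival::Surv` response.
#' @param data data frame of patient records (>= 10 events).
#' @param time,event column names used when `formula` is a term vector.
#' @return an object of class `rp_cox` with a coefficient `table`,
#'   `loglik`, `aic`, `n`, `n_events` and the underlying `coxph` fit.
#' @export
cox_fit <- function(formula, data, time = "time_days", event = "event") {
  if (is.character(formula))
    formula <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                                 paste(formula, collapse = " + ")))
  n_events <- sum(as.logical(data[[event]]), na.rm = TRUE)
  if (n_events < 10) stop("need at least 10 events for a Cox fit")
  fit <- survival::coxph(formula, data = data, ties = "efron")
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  check_fit_sane(est, se, "Cox")
  structure(list(table = coef_table(est, se, "hr"),
                 loglik = fit$loglik[2], aic = stats::AIC(fit),
                 n = fit$n, n_events = fit$nevent, fit = fit,
                 formula = formula),
            class = "rp_cox")
}

#' @export
print.rp_cox <- function(x, ...) {
  cat(sprintf("Cox model for time to RP symptoms  (%d events / %d patients, AIC = %.1f)\n",
              x$n_events, x$n, x$aic))
  tab <- x$table
  print(data.frame(term = tab$term, coef = round(tab$coef, 3),
                   se = round(tab$se, 3),
                   `HR (95% CI)` = sprintf("%.2f (%.2f, %.2f)",
                                           tab$hr, tab$hr_lo, tab$hr_hi),
                   p = signif(tab$p, 3), check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.rp_cox <- function(object, ...) coef(object$fit)

#' @export
summary.rp_cox <- function(object, ...) object$table

#' Bland-Altman limits of agreement from repeated readings
#'
#' Per-reading percent deviation from the subject mean, a one-way ANOVA
#' with subject as the grouping factor, and limits of agreement
#' `mean deviation +/- 1.96 sqrt(within-subject mean square)`.  Subjects
#' with a single reading are excluded with a warning.
#'
#' @param readings numeric matrix, subjects x readers; all values > 0.
#' @return an object of class `rp_agreement` with the `deviations_pct`
#'   matrix, `mean_deviation_pct`, `within_ms`, and `loa_pct` (the +/-
#'   half-width).
#' @export
bland_altman_loa <- function(readings) {
  readings <- as.matrix(readings)
  keep <- rowSums(!is.na(readings)) >= 2
  if (any(!keep)) {
    warning(sum(!keep), " subject(s) with fewer than 2 readings excluded")
    readings <- readings[keep, , drop = FALSE]
  }
  if (nrow(readings) < 2 || ncol(readings) < 2)
    stop("need at least 2 subjects and 2 readers")
  if (any(readings <= 0, na.rm = TRUE)) stop("all readings must be > 0")
  subj_mean <- rowMeans(readings, na.rm = TRUE)
  dev <- 100 * sweep(readings, 1, subj_mean, "-") / subj_mean
  long <- data.frame(dev = as.vector(dev),
                     subject = factor(rep(seq_len(nrow(dev)), ncol(dev))))
  long <- long[!is.na(long$dev), ]
  ms_within <- anova(aov(dev ~ subject, data = long))["Residuals", "Mean Sq"]
  md <- mean(long$dev)
  structure(list(deviations_pct = dev, mean_deviation_pct = md,
                 within_ms = ms_within,
                 loa_pct = .Z95 * sqrt(ms_within),
                 n_subjects = nrow(dev), n_readers = ncol(dev)),
            class = "rp_agreement")
}

#' @export
print.rp_agreement <- function(x, ...) {
  cat(sprintf(
    "Inter-reader agreement (%d subjects x %d readers): LoA = %.2f%% +/- %.2f%%\n",
    x$n_subjects, x$n_readers, x$mean_deviation_pct, x$loa_pct))
  invisible(x)
}

#' @export
plot.rp_agreement <- function(x, ...) {
  plot(rep(seq_len(x$n_subjects), x$n_readers), as.vector(x$deviations_pct),
       xlab = "subject", ylab = "% deviation from subject mean", ...)
  graphics::abline(h = x$mean_deviation_pct + c(-1, 0, 1) * x$loa_pct,
                   lty = c(2, 1, 2))
  invisible(x)
}
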