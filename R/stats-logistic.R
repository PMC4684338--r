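#' Univariate logistic regression with odds ratio
#'
#' Maximum-likelihood fit of logit P(y = 1) = b0 + b1 x; reports the
#' per-unit odds ratio exp(b1) with a Wald 95% CI and two-sided Wald
#' p-value. A predictor with no variance returns the null result
#' (b1 = 0, OR = 1, p = 1). Complete or quasi-complete separation is
#' flagged and the CI reported as unbounded.
#'
#' @param x numeric predictor
#' @param y outcome: 0/1 numeric, or factor/character with the positive
#'   class named by `positive`
#' @param positive label coded as 1 when `y` is not numeric
#' @param conf confidence level for the Wald interval
#' @return list of class `LogisticResult`: `coefficient`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `separation`
#' @examples
#' co <- generateCohort(CohortSpec(seed = 4))
#' univariateLogistic(co$pct_augc, co$outcome, positive = "SF")
#' @export
univariateLogistic <- function(x, y, positive = "SF", conf = 0.95) {
  yy <- codeOutcome(y, positive)
  stopIfNot(length(x) == length(yy), "x and y must have equal length")
  keep <- is.finite(x) & !is.na(yy)
  x <- x[keep]; yy <- yy[keep]
  n <- length(x)
  stopIfNot(n >= 10, "need at least 10 observations")
  stopIfNot(length(unique(yy)) == 2, "both outcome classes must be present")

  if (stats::var(x) == 0) {
    return(structure(list(coefficient = 0, odds_ratio = 1,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = 1, n = n, separation = FALSE),
                     class = "LogisticResult"))
  }
  fit <- suppressWarnings(stats::glm(yy ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  b <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  sep <- !fit$converged || se > 100 || abs(b) > 50 ||
    all(abs(fit$fitted.values - yy) < 1e-8)
  ci <- if (sep) c(0, Inf) else exp(b + c(-1, 1) * z * se)
  structure(list(coefficient = b, odds_ratio = exp(b),
                 ci_low = ci[1], ci_high = ci[2],
                 p_value = co["x", "Pr(>|z|)"], n = n, separation = sep),
            class = "LogisticResult")
}

#' @export
print.LogisticResult <- function(x, ...) {
  cat("Logistic regression (n = ", x$n, "): OR ", signif(x$odds_ratio, 4),
      " (95% CI ", signif(x$ci_low, 4), "-", signif(x$ci_high, 4),
      "), p = ", signif(x$p_value, 3),
      if (x$separation) " [separation]", "\n", sep = "")
  invisible(x)
}

codeOutcome <- function(y, positive) {
  if (is.numeric(y)) {
    stopIfNot(all(y %in% c(0, 1)), "numeric y must be coded 0/1")
    return(as.integer(y))
  }
  as.integer(as.character(y) == positive)
}

#' Stepwise multivariate logistic regression
#'
#' Forward stepwise selection on likelihood-ratio tests with entry
#' p < `pEnter` and removal p >= `pRemove` (the conventional 0.05 / 0.10
#' pair). After selection, the adjusted odds ratios of the selected
#' predictors are refit with the stated confounders included in the
#' model. An empty selection is a legitimate result, not an error.
#'
#' @param data data.frame holding predictors and outcome
#' @param candidates names of candidate predictor columns (typically those
#'   with univariate p < 0.05)
#' @param outcome name of the outcome column
#' @param confounders names of confounder columns for the adjusted model
#' @param positive outcome label coded 1
#' @param pEnter,pRemove entry and removal thresholds on LRT p-values
#' @return list with `selected` (character), `adjusted` (data.frame of
#'   adjusted OR/CI/p per selected predictor) and `model` (the final glm,
#'   or NULL)
#' @export
stepwiseMultivariate <- function(data, candidates, outcome = "outcome",
                                 confounders = character(0),
                                 positive = "SF",
                                 pEnter = 0.05, pRemove = 0.10) {
  stopIfNot(length(candidates) >= 1, "need at least one candidate")
  yy <- codeOutcome(data[[outcome]], positive)
  df <- data[, unique(c(candidates, confounders)), drop = FALSE]
  df$.y <- yy

  lrtP <- function(small, big) {
    stats::anova(small, big, test = "Chisq")$`Pr(>Chi)`[2]
  }
  fitWith <- function(terms) {
    fml <- if (length(terms)) stats::reformulate(terms, response = ".y")
           else .y ~ 1
    suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
  }

  selected <- character(0)
  repeat {
    changed <- FALSE
    cur <- fitWith(selected)
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      ps <- vapply(remaining, function(v) lrtP(cur, fitWith(c(selected, v))),
                   numeric(1))
      ps[is.na(ps)] <- 1
      if (min(ps) < pEnter) {
        selected <- c(selected, remaining[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(selected) > 1) {
      full <- fitWith(selected)
      drp <- vapply(selected, function(v)
        lrtP(fitWith(setdiff(selected, v)), full), numeric(1))
      drp[is.na(drp)] <- 1
      if (max(drp) >= pRemove) {
        selected <- setdiff(selected, selected[which.max(drp)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (!length(selected)) {
    return(list(selected = character(0),
                adjusted = data.frame(term = character(0),
                                      odds_ratio = numeric(0),
                                      ci_low = numeric(0),
                                      ci_high = numeric(0),
                                      p_value = numeric(0)),
                model = NULL))
  }
  final <- fitWith(c(selected, confounders))
  co <- summary(final)$coefficients
  z <- stats::qnorm(0.975)
  rows <- lapply(selected, function(v) {
    rn <- grep(paste0("^", v), rownames(co), value = TRUE)[1]
    b <- co[rn, "Estimate"]; se <- co[rn, "Std. Error"]
    data.frame(term = v, odds_ratio = exp(b),
               ci_low = exp(b - z * se), ci_high = exp(b + z * se),
               p_value = co[rn, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  list(selected = selected, adjusted = do.call(rbind, rows), model = final)
}

#' Paired t-test on pre/post parameter values
#'
#' Two-sided paired t-test on the differences post - pre. Zero variance
#' of the differences is degenerate: all-zero differences give t = 0,
#' p = 1; a constant nonzero shift gives an infinite statistic with p = 0,
#' both flagged.
#'
#' @param pre,post paired measurements, equal length, n >= 2
#' @return list with `t`, `df`, `p_value`, `mean_difference`, `degenerate`
#' @export
pairedTTest <- function(pre, post) {
  stopIfNot(length(pre) == length(post), "pre and post must have equal length")
  stopIfNot(length(pre) >= 2, "need at least two pairs")
  d <- post - pre
  if (stats::sd(d) <= .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    zero <- isTRUE(all.equal(mean(d), 0))
    return(list(t = if (zero) 0 else Inf * sign(mean(d)),
                df = length(d) - 1,
                p_value = if (zero) 1 else 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d), degenerate = FALSE)
}
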