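#' @include AllClasses.R
NULL

#' Greedy Spearman redundancy filter
#'
#' Scans the feature columns in their fixed order and drops any feature
#' whose absolute Spearman correlation with an already-kept feature exceeds
#' the threshold; the result is deterministic for a given column order.
#' Constant features (undefined correlation) are dropped first with a
#' warning.
#'
#' @param X numeric matrix or data.frame of features (no missing values).
#' @param threshold absolute correlation above which a feature is
#'   redundant (default 0.9).
#' @return Character vector of kept feature names.
#' @export
spearmanFilter <- function(X, threshold = 0.9) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (anyNA(X)) stop("missing values are not allowed")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped (undefined rank correlation)")
    X <- X[, sds > 0, drop = FALSE]
  }
  p <- ncol(X)
  if (p <= 1L) return(colnames(X))
  rho <- abs(cor(X, method = "spearman"))
  keep <- logical(p)
  for (j in seq_len(p)) {
    keep[j] <- !any(rho[j, keep] > threshold)
  }
  colnames(X)[keep]
}

#' Fit a penalized Cox model with cross-validated alpha and lambda
#'
#' Standardizes the features (training mean/sd), then for each elastic-net
#' mixing value `alpha` in the grid fits the regularization path of a
#' penalized Cox proportional-hazards model and selects the strength by
#' k-fold cross-validated partial likelihood; the best `(alpha, lambda)`
#' pair by CV deviance wins. `alpha = 1` is the LASSO, `alpha = 0` ridge,
#' intermediate values the elastic net. Features with nonzero coefficients
#' are reported as selected, and the risk-score dichotomization threshold
#' is frozen from the training scores.
#'
#' @param X numeric matrix of features (rows = subjects).
#' @param time,event survival time (> 0) and event indicator (1 = death).
#' @param alphaGrid elastic-net mixing values to search
#'   (default `seq(0, 1, by = 0.02)`).
#' @param nFolds folds for cross-validation (default 5).
#' @param seed seed controlling the fold assignment.
#' @param thresholdRule `"median"` (default) or `"mean"` of the training
#'   risk scores.
#' @return A [RampCoxFit-class].
#' @export
fitPenalizedCox <- function(X, time, event, alphaGrid = seq(0, 1, by = 0.02),
                            nFolds = 5L, seed = 1L,
                            thresholdRule = c("median", "mean")) {
  thresholdRule <- match.arg(thresholdRule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(time) != n || length(event) != n)
    stop("time/event length must match rows of X")
  if (any(time <= 0)) stop("survival times must be positive")
  if (!any(event == 1)) stop("no events: Cox partial likelihood undefined")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  if (any(scl == 0)) stop("constant features must be removed before fitting")
  Xs <- scale(X, center = ctr, scale = scl)
  y <- survival::Surv(time, event)
  set.seed(seed)
  foldid <- sample(rep(seq_len(nFolds), length.out = n))
  cvs <- lapply(alphaGrid, function(a) {
    glmnet::cv.glmnet(Xs, y, family = "cox", alpha = a, foldid = foldid,
                      standardize = FALSE)
  })
  cvmin <- vapply(cvs, function(cv) min(cv$cvm), numeric(1))
  best <- which.min(cvmin)
  cv <- cvs[[best]]
  beta <- as.numeric(coef(cv, s = "lambda.min"))
  names(beta) <- colnames(X)
  sel <- names(beta)[beta != 0]
  if (!length(sel))
    warning("all coefficients shrunk to zero; the model carries no signal")
  fit <- new("RampCoxFit", features = colnames(X), center = ctr,
             scale = scl, selected = sel, coefficients = beta[sel],
             alpha = alphaGrid[best], lambda = cv$lambda.min,
             threshold = 0, thresholdRule = thresholdRule,
             cvTable = data.frame(alpha = alphaGrid, cvm = cvmin,
                                  lambda = vapply(cvs, function(cv)
                                    cv$lambda.min, numeric(1))))
  scores <- rampScore(fit, X)
  fit@threshold <- if (thresholdRule == "median") median(scores) else
    mean(scores)
  fit
}

#' Compute the continuous radiomic risk score
#'
#' The risk score is the linear combination `sum_z co_z * F_z` of the
#' selected features (standardized with the training parameters) and their
#' fitted Cox coefficients. A model with no selected features scores every
#' subject 0.
#'
#' @param fit a [RampCoxFit-class].
#' @param X feature matrix containing at least the selected features, on
#'   the original (unstandardized) scale.
#' @return Numeric vector of per-subject risk scores.
#' @export
rampScore <- function(fit, X) {
  X <- as.matrix(X)
  if (!length(fit@selected)) return(rep(0, nrow(X)))
  missing <- setdiff(fit@selected, colnames(X))
  if (length(missing))
    stop("selected feature(s) absent from X: ",
         paste(head(missing, 5L), collapse = ", "))
  Xs <- scale(X[, fit@selected, drop = FALSE],
              center = fit@center[fit@selected],
              scale = fit@scale[fit@selected])
  as.numeric(Xs %*% fit@coefficients)
}

#' Dichotomize risk scores into high/low groups
#'
#' Scores above the (training-derived, frozen) threshold are high risk;
#' scores at or below it are low risk.
#'
#' @param scores numeric risk scores.
#' @param threshold frozen threshold from the training fit.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(scores, threshold) {
  g <- factor(ifelse(scores > threshold, "high", "low"),
              levels = c("low", "high"))
  if (length(unique(g[!is.na(g)])) < 2L)
    warning("all subjects fall in a single risk group")
  g
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' Product-limit survival estimate per group and the two-sample log-rank
#' chi-square statistic (1 df for two groups).
#'
#' @param time,event survival data.
#' @param groups factor of group labels (two nonempty groups for the
#'   log-rank test).
#' @return List with `km` (data.frame: group, time, n.risk, n.event,
#'   survival), `chisq`, `df`, and `p`.
#' @export
kmLogrank <- function(time, event, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 1L || any(table(groups) == 0))
    stop("each group must contain at least one subject")
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata <- if (is.null(sf$strata)) setNames(length(sf$time),
                                             levels(groups)[1L]) else
    sf$strata
  km <- data.frame(
    group = rep(sub("^groups=", "", names(strata)), strata),
    time = sf$time, n.risk = sf$n.risk, n.event = sf$n.event,
    survival = sf$surv, stringsAsFactors = FALSE)
  if (nlevels(groups) < 2L)
    return(list(km = km, chisq = NA_real_, df = NA_integer_, p = NA_real_))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1L
  list(km = km, chisq = sd_$chisq, df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Hazard ratio, confidence interval, and concordance index
#'
#' `HR = exp(beta)` from a univariable Cox model on the high-risk indicator
#' (Efron ties) with the Wald 95% CI `exp(beta +/- 1.96 SE)`; Harrell's
#' C-index of the continuous risk score against observed survival (higher
#' score = higher risk = earlier event counts as concordant).
#'
#' @param time,event survival data.
#' @param scores continuous risk scores.
#' @param groups factor from [dichotomize()].
#' @return List with `hr`, `ci` (length 2), `cindex`, and `events` per
#'   group. If a group has no events the HR is reported as `NA`.
#' @export
survivalMetrics <- function(time, event, scores, groups) {
  groups <- as.factor(groups)
  y <- survival::Surv(time, event)
  cidx <- if (length(unique(scores)) <= 1L) 0.5 else
    survival::concordance(y ~ scores, reverse = TRUE)$concordance
  evt <- tapply(event, groups, sum)
  hr <- ci <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (nlevels(droplevels(groups)) == 2L && all(evt > 0, na.rm = TRUE)) {
    cx <- survival::coxph(y ~ I(groups == "high"), ties = "efron")
    b <- coef(cx)[1L]
    se <- sqrt(diag(cx$var))[1L]
    hr <- exp(b)
    ci <- exp(b + c(-1.96, 1.96) * se)
  }
  list(hr = unname(hr), ci = unname(ci), cindex = unname(cidx),
       events = evt)
}

#' Association tests between risk groupings
#'
#' `mcnemar`: McNemar test on the paired 2x2 table of two binary risk
#' labelings, statistic `(b - c)^2 / (b + c)` with a 1-df chi-square p
#' value; with fewer than 25 discordant pairs an exact binomial version is
#' used instead. `chisq`: Pearson chi-square test of independence for a
#' categorical cross-table.
#'
#' @param rampGroups factor of model-derived risk labels.
#' @param clinicalGroups factor of clinical labels (binary for McNemar).
#' @return List with `mcnemar` (statistic, p, b, c, exact flag) and
#'   `chisq` (statistic, df, p).
#' @export
associationTests <- function(rampGroups, clinicalGroups) {
  rampGroups <- as.factor(rampGroups)
  clinicalGroups <- as.factor(clinicalGroups)
  mc <- list(statistic = NA_real_, p = NA_real_, b = NA_integer_,
             c = NA_integer_, exact = FALSE)
  if (nlevels(rampGroups) == 2L && nlevels(clinicalGroups) == 2L) {
    tab <- table(rampGroups, clinicalGroups)
    b <- tab[1L, 2L]
    cc <- tab[2L, 1L]
    if (b + cc == 0) {
      warning("no discordant pairs; McNemar statistic undefined")
    } else if (b + cc < 25) {
      bt <- binom.test(b, b + cc, p = 0.5)
      mc <- list(statistic = (b - cc)^2 / (b + cc), p = bt$p.value,
                 b = b, c = cc, exact = TRUE)
    } else {
      stat <- (b - cc)^2 / (b + cc)
      mc <- list(statistic = stat,
                 p = pchisq(stat, 1L, lower.tail = FALSE),
                 b = b, c = cc, exact = FALSE)
    }
  }
  ct <- suppressWarnings(chisq.test(table(rampGroups, clinicalGroups),
                                    correct = FALSE))
  list(mcnemar = mc,
       chisq = list(statistic = unname(ct$statistic),
                    df = unname(ct$parameter), p = ct$p.value))
}
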