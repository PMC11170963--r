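#' Percentage change of a clinical measure
#'
#' `(post - pre) / pre * 100`; negative values are improvements for glycemic
#' measures.
#'
#' @param pre,post Numeric values (vectors recycle as usual).
#' @return Percentage change.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0, na.rm = TRUE)) {
    stop("pre-treatment value of 0 has no percentage change", call. = FALSE)
  }
  (post - pre) / pre * 100
}

#' Median split into high and low responders
#'
#' High responders (HR) are subjects whose percentage change lies strictly
#' below the median (a larger reduction is a better glycemic response); all
#' others, including exact-median values, are low responders (LR). The
#' tie-to-LR rule makes the split deterministic.
#'
#' @param responses Named numeric vector of per-subject percentage changes.
#' @return Data frame with columns `subject_id`, `response`, `class`
#'   (`"HR"`/`"LR"`); counts in the `"counts"` attribute.
#' @export
stratify_responders <- function(responses) {
  responses <- responses[!is.na(responses)]
  if (length(responses) < 4L) stop("need >= 4 subjects", call. = FALSE)
  if (length(unique(responses)) == 1L) {
    stop("all responses identical; no median split exists", call. = FALSE)
  }
  med <- median(responses)
  cls <- ifelse(responses < med, "HR", "LR")
  out <- data.frame(
    subject_id = names(responses) %||% as.character(seq_along(responses)),
    response = unname(responses), class = unname(cls),
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- c(HR = sum(cls == "HR"), LR = sum(cls == "LR"))
  out
}

#' Partial Spearman screen of baseline features against response
#'
#' For each feature: the feature, the response and the covariates are
#' rank-transformed (mid-ranks), feature and response ranks are
#' residualized on the covariate ranks by linear projection, and the
#' partial correlation is the Pearson correlation of the residuals, with p
#' from the t distribution on `n - 2 - k` degrees of freedom (k
#' covariates). An association is called significant when
#' `|rho| > 0.3` and `p < 0.05` — both strictly.
#'
#' @param features Numeric matrix, features in rows, subjects in columns
#'   (e.g. baseline CLR values or gene RPKM).
#' @param response Numeric vector, one value per subject (column order).
#' @param covariates Data frame of adjustment covariates (e.g. age, sex,
#'   BMI, baseline measure); factors/characters are expanded via
#'   `model.matrix`. `NULL` adjusts for the intercept only.
#' @return Data frame of class `screen_result`: `feature_id`,
#'   `partial_rho`, `p_value`, `significant`, `excluded` (constant
#'   features are excluded with `excluded = TRUE` and `NA` estimates).
#' @export
partial_spearman_screen <- function(features, response, covariates = NULL) {
  stopifnot(is.matrix(features))
  n <- ncol(features)
  if (length(response) != n) {
    stop("response length must match the number of subjects", call. = FALSE)
  }
  if (is.null(covariates)) {
    x <- matrix(1, n, 1)
    k <- 0L
  } else {
    if (nrow(covariates) != n) stop("covariate rows must match subjects",
                                    call. = FALSE)
    if (anyNA(covariates)) {
      stop("covariates must be complete for included subjects", call. = FALSE)
    }
    x <- model.matrix(~ ., data = as.data.frame(covariates))
    # rank-transform the covariates too (mid-ranks), so the projection
    # removes any monotone covariate effect, as in partial Spearman
    if (ncol(x) > 1L) {
      x[, -1] <- apply(x[, -1, drop = FALSE], 2, rank)
    }
    k <- ncol(x) - 1L
  }
  if (n < k + 5L) stop("need n >= number of covariates + 5", call. = FALSE)
  qx <- qr(x)
  resid_on <- function(v) qr.resid(qx, v)
  ry <- resid_on(rank(response))
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    if (var(f) == 0) {
      return(data.frame(feature_id = rownames(features)[i],
                        partial_rho = NA_real_, p_value = NA_real_,
                        significant = FALSE, excluded = TRUE,
                        stringsAsFactors = FALSE))
    }
    rf <- resid_on(rank(f))
    if (sum(rf^2) == 0 || sum(ry^2) == 0) {
      rho <- 0
    } else {
      rho <- sum(rf * ry) / sqrt(sum(rf^2) * sum(ry^2))
    }
    df <- n - 2L - k
    tt <- rho * sqrt(df / max(1 - rho^2, 1e-15))
    p <- 2 * pt(-abs(tt), df = df)
    data.frame(feature_id = rownames(features)[i], partial_rho = rho,
               p_value = p, significant = abs(rho) > 0.3 && p < 0.05,
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Count significant screen associations
#'
#' @param screen A `screen_result` from [partial_spearman_screen()].
#' @return Integer count of features with `significant = TRUE`.
#' @export
count_significant_features <- function(screen) {
  if (!nrow(screen)) return(0L)
  sum(screen$significant, na.rm = TRUE)
}

#' Variance in treatment response explained by baseline features
#'
#' Two-stage estimate: (1) an elastic net (default mixing 0.5) with the
#' penalty chosen by k-fold cross-validation at a fixed seed (default the
#' one-standard-error rule, the sparser conventional CV choice; the
#' CV-minimum is available via `lambda_rule`) selects the features with
#' non-zero coefficients; (2) an ordinary linear model of the
#' response on the selected features is refit, and its in-sample R-squared
#' is reported. A cross-validated R-squared (`1 - cv MSE / var(y)` at the
#' selected penalty) is reported alongside. An empty selection yields
#' R-squared 0.
#'
#' @param features Numeric matrix, features x subjects; standardized
#'   internally.
#' @param response Numeric vector per subject.
#' @param covariates Optional data frame forced into both stages
#'   (unpenalized).
#' @param cv_folds Number of CV folds.
#' @param alpha_mix Elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param lambda_rule Penalty choice from the CV curve: `"lambda.1se"`
#'   (default) or `"lambda.min"`.
#' @param seed RNG seed fixing the fold assignment.
#' @return A `variance_explained_result` list: `selected_features`,
#'   `r_squared` (stage-2 refit), `r_squared_cv`, `coefficients` (refit),
#'   `lambda`, `n`, `seed`.
#' @export
elasticnet_variance_explained <- function(features, response,
                                          covariates = NULL, cv_folds = 5,
                                          alpha_mix = 0.5,
                                          lambda_rule = c("lambda.1se",
                                                          "lambda.min"),
                                          seed = 1) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(is.matrix(features))
  n <- ncol(features)
  if (length(response) != n) stop("response must match subjects", call. = FALSE)
  if (n < 20L) stop("need >= 20 subjects", call. = FALSE)
  if (cv_folds > n) stop("cv_folds exceeds the number of subjects",
                         call. = FALSE)
  x <- t(features)
  keep <- apply(x, 2, var) > 0
  x <- scale(x[, keep, drop = FALSE])
  pf <- rep(1, ncol(x))
  cov_mat <- NULL
  if (!is.null(covariates)) {
    cov_mat <- model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                   drop = FALSE]
    x <- cbind(x, cov_mat)
    pf <- c(pf, rep(0, ncol(cov_mat)))
  }
  foldid <- with_local_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv <- glmnet::cv.glmnet(x, response, alpha = alpha_mix, foldid = foldid,
                          penalty.factor = pf, standardize = FALSE)
  lambda <- if (lambda_rule == "lambda.1se") cv$lambda.1se else cv$lambda.min
  b <- as.matrix(coef(cv, s = lambda))[-1, 1]
  selected <- intersect(names(b)[b != 0], rownames(features)[keep])
  mse_null <- mean((response - mean(response))^2)
  r2_cv <- 1 - cv$cvm[cv$lambda == lambda] / mse_null
  r2_cv <- max(min(r2_cv, 1), 0)
  if (!length(selected)) {
    r2 <- 0
    coefs <- numeric(0)
  } else {
    dat <- data.frame(.y = response,
                      t(features[selected, , drop = FALSE]),
                      check.names = FALSE)
    if (!is.null(cov_mat)) dat <- cbind(dat, as.data.frame(cov_mat))
    fit <- lm(.y ~ ., data = dat)
    r2 <- summary(fit)$r.squared
    coefs <- coef(fit)
  }
  structure(
    list(selected_features = selected, r_squared = r2, r_squared_cv = r2_cv,
         coefficients = coefs, lambda = cv$lambda.min, n = n, seed = seed),
    class = "variance_explained_result"
  )
}

#' Responder odds ratio for one baseline feature
#'
#' Logistic regression of responder class (HR = 1) on a baseline feature,
#' optionally adjusted for covariates. Continuous features are standardized
#' so the odds ratio is per standard deviation; binary features are left on
#' their own scale. Complete separation is detected and flagged, with
#' non-finite estimates replaced by `NA` rather than reported as huge
#' numbers.
#'
#' @param feature Numeric vector of baseline values, one per subject.
#' @param classes Character/factor vector of `"HR"`/`"LR"` per subject (as
#'   from [stratify_responders()]).
#' @param covariates Optional data frame of adjustment covariates.
#' @return A `responder_odds_result` one-row data frame: `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `separation`.
#' @export
responder_logistic <- function(feature, classes, covariates = NULL) {
  classes <- as.character(classes)
  if (!all(classes %in% c("HR", "LR"))) {
    stop("classes must be 'HR'/'LR'", call. = FALSE)
  }
  if (length(unique(classes)) < 2L) {
    stop("both responder classes must be non-empty", call. = FALSE)
  }
  y <- as.integer(classes == "HR")
  n_unique <- length(unique(feature))
  if (n_unique < 2L) stop("feature is constant", call. = FALSE)
  xf <- if (n_unique == 2L) feature else as.numeric(scale(feature))
  dat <- data.frame(.y = y, .x = xf)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  co <- coef(fit)[".x"]
  se <- sqrt(vcov(fit)[".x", ".x"])
  eps <- 1e-8
  separation <- !fit$converged || any(fit$fitted.values < eps) &&
    any(fit$fitted.values > 1 - eps) && abs(co) > 10
  if (!is.finite(co) || !is.finite(se) || abs(co) > 15) separation <- TRUE
  if (separation) {
    out <- data.frame(odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      separation = TRUE)
  } else {
    z <- co / se
    out <- data.frame(
      odds_ratio = exp(co), ci_low = exp(co - qnorm(0.975) * se),
      ci_high = exp(co + qnorm(0.975) * se),
      p_value = 2 * pnorm(-abs(z)), separation = FALSE
    )
  }
  rownames(out) <- NULL
  class(out) <- c("responder_odds_result", "data.frame")
  out
}
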