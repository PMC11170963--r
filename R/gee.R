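#' Longitudinal association by generalized estimating equations
#'
#' Marginal regression of a clinical trajectory on a microbial feature
#' trajectory across timepoints, with within-subject correlation handled by
#' a Gaussian identity-link GEE with exchangeable working correlation and
#' robust (sandwich) standard errors. With one observation per subject the
#' estimates coincide with ordinary least squares.
#'
#' @param feature Numeric vector of the microbial feature (one value per
#'   observation; observations span subjects and timepoints).
#' @param clinical Numeric vector of the clinical outcome, same length.
#' @param subjects Cluster identifier per observation.
#' @param covariates Optional data frame of additional covariates.
#' @param max_iter,tol Fisher-scoring controls.
#' @return A `gee_result` data frame, one row per model term:
#'   `term`, `estimate`, `robust_se`, `z_value`, `p_value`, plus attributes
#'   `converged`, `alpha` (working correlation), `n_clusters`.
#' @export
gee_longitudinal <- function(feature, clinical, subjects, covariates = NULL,
                             max_iter = 50, tol = 1e-10) {
  n <- length(clinical)
  if (length(feature) != n || length(subjects) != n) {
    stop("feature, clinical and subjects must have equal length", call. = FALSE)
  }
  if (var(feature) == 0) stop("feature has zero variance", call. = FALSE)
  dat <- data.frame(feature = feature)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  x <- model.matrix(~ ., data = dat)
  y <- clinical
  id <- as.character(subjects)
  clusters <- split(seq_len(n), id)
  p <- ncol(x)

  beta <- qr.coef(qr(x), y)  # OLS start
  alpha <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- y - as.vector(x %*% beta)
    phi <- sum(e^2) / (n - p)
    # moment estimate of the exchangeable correlation
    num <- 0
    npairs <- 0
    for (idx in clusters) {
      ni <- length(idx)
      if (ni > 1) {
        ei <- e[idx] / sqrt(phi)
        num <- num + (sum(ei)^2 - sum(ei^2)) / 2
        npairs <- npairs + ni * (ni - 1) / 2
      }
    }
    alpha_new <- if (npairs > p) num / (npairs - p) else 0
    alpha_new <- min(max(alpha_new, -0.99), 0.99)
    xtvx <- matrix(0, p, p)
    xtvy <- numeric(p)
    for (idx in clusters) {
      ni <- length(idx)
      r_inv <- solve(matrix(alpha_new, ni, ni) + diag(1 - alpha_new, ni))
      xi <- x[idx, , drop = FALSE]
      xtvx <- xtvx + t(xi) %*% r_inv %*% xi
      xtvy <- xtvy + t(xi) %*% r_inv %*% y[idx]
    }
    beta_new <- solve(xtvx, xtvy)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    alpha <- alpha_new
  }
  # robust sandwich covariance
  e <- y - as.vector(x %*% beta)
  bread <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (idx in clusters) {
    ni <- length(idx)
    r_inv <- solve(matrix(alpha, ni, ni) + diag(1 - alpha, ni))
    xi <- x[idx, , drop = FALSE]
    xv <- t(xi) %*% r_inv
    bread <- bread + xv %*% xi
    s <- xv %*% e[idx]
    meat <- meat + s %*% t(s)
  }
  bi <- solve(bread)
  vc <- bi %*% meat %*% bi
  se <- sqrt(pmax(diag(vc), 0))
  z <- as.vector(beta) / se
  out <- data.frame(
    term = colnames(x), estimate = as.vector(beta), robust_se = se,
    z_value = z, p_value = 2 * pnorm(-abs(z)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!converged) warning("GEE did not converge in ", max_iter, " iterations")
  attr(out, "converged") <- converged
  attr(out, "alpha") <- alpha
  attr(out, "n_clusters") <- length(clusters)
  class(out) <- c("gee_result", "data.frame")
  out
}
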