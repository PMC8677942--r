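#' Fit a linear generalized estimating equation
#'
#' Linear mean model for clustered observations (two eyes and repeated
#' recordings per subject) with a working correlation of `"exchangeable"`
#' (default; constant intra-cluster correlation) or `"independence"`, and a
#' robust (sandwich) covariance estimate, so inference is valid even when the
#' working correlation is misspecified.
#'
#' Estimation iterates generalized least squares with moment estimates of the
#' scale and of the exchangeable correlation from Pearson residuals. The
#' sandwich is `A^-1 B A^-1` with `A = sum_i X_i' V_i^-1 X_i` and
#' `B = sum_i X_i' V_i^-1 r_i r_i' V_i^-1 X_i`. With one observation per
#' cluster and independence working correlation the fit reduces exactly to
#' ordinary least squares.
#'
#' @param response Numeric response vector (no missing values; apply listwise
#'   deletion upstream).
#' @param design Numeric design matrix including an intercept column.
#' @param cluster Cluster identifiers (one per observation), e.g. subject
#'   IDs.
#' @param corstr Working correlation structure.
#' @param maxit,tol Iteration control.
#' @param model_label Optional label stored with the fit.
#' @return A [GEEFit-class].
#' @export
fitLinearGEE <- function(response, design, cluster,
                         corstr = c("exchangeable", "independence"),
                         maxit = 25L, tol = 1e-10, model_label = "") {
  corstr <- match.arg(corstr)
  y <- as.numeric(response)
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  cluster <- as.character(cluster)
  if (length(y) != nrow(X) || length(cluster) != length(y))
    stop("response, design and cluster must align")
  if (anyNA(y) || anyNA(X))
    stop("missing values are not allowed; apply listwise deletion first")
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design matrix")
  cl <- split(seq_len(n), cluster)
  K <- length(cl)
  if (K < 2) stop("at least 2 clusters are required")

  beta <- qr.solve(X, y)  # OLS start
  alpha <- NA_real_
  sigma2 <- NA_real_
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    r <- y - X %*% beta
    sigma2 <- sum(r^2) / (n - p)
    if (corstr == "independence") {
      beta_new <- beta  # OLS is the fixed point
      converged <- TRUE
      beta <- beta_new
      break
    }
    # moment estimator of the exchangeable correlation
    num <- 0; npairs <- 0
    for (idx in cl) {
      ni <- length(idx)
      if (ni > 1) {
        ri <- r[idx]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        npairs <- npairs + ni * (ni - 1) / 2
      }
    }
    if (npairs <= p) {
      alpha <- 0
    } else {
      alpha <- num / sigma2 / (npairs - p)
      nmax <- max(lengths(cl))
      alpha <- min(max(alpha, -1 / (nmax - 1) + 1e-6), 1 - 1e-6)
    }
    # GLS step with V_i = sigma2 * [(1 - alpha) I + alpha J]
    XtVX <- matrix(0, p, p); XtVy <- numeric(p)
    for (idx in cl) {
      ni <- length(idx)
      Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
      # closed-form inverse of the exchangeable correlation matrix
      c1 <- 1 / (1 - alpha)
      c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      XtVX <- XtVX + c1 * crossprod(Xi) + c2 * tcrossprod(colSums(Xi))
      XtVy <- XtVy + c1 * crossprod(Xi, yi) + c2 * colSums(Xi) * sum(yi)
    }
    beta_new <- solve(XtVX, XtVy)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  r <- as.numeric(y - X %*% beta)
  sigma2 <- sum(r^2) / (n - p)

  # sandwich covariance
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (idx in cl) {
    ni <- length(idx)
    Xi <- X[idx, , drop = FALSE]; ri <- r[idx]
    if (corstr == "independence") {
      XtVi <- t(Xi)  # V^-1 proportional to identity; scale cancels in A^-1 B A^-1
    } else {
      c1 <- 1 / (1 - alpha)
      c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      XtVi <- c1 * t(Xi) + c2 * tcrossprod(colSums(Xi), rep(1, ni))
    }
    A <- A + XtVi %*% Xi
    u <- XtVi %*% ri
    B <- B + tcrossprod(u)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  se <- sqrt(diag(V))
  z <- as.numeric(beta) / se
  pv <- 2 * pnorm(-abs(z))
  beta <- as.numeric(beta)
  names(beta) <- names(se) <- names(z) <- names(pv) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  new("GEEFit", coefficients = beta, robust_se = se, wald_z = z, p_values = pv,
      vcov_robust = V, corstr = corstr,
      alpha = if (corstr == "exchangeable") alpha else NA_real_,
      scale = sigma2, n_clusters = as.integer(K), n_obs = as.integer(n),
      converged = converged, model_label = as.character(model_label))
}

#' @describeIn fitLinearGEE Coefficients of a fit.
#' @param object A `GEEFit`.
#' @param ... Ignored.
#' @export
setMethod("coef", "GEEFit", function(object, ...) object@coefficients)

#' Robust standard errors of a GEE fit
#' @param object A [GEEFit-class].
#' @return Named numeric vector.
#' @export
robustSE <- function(object) { stopifnot(is(object, "GEEFit")); object@robust_se }

#' Two-sided Wald p-values of a GEE fit
#' @param object A [GEEFit-class].
#' @return Named numeric vector.
#' @export
pValues <- function(object) { stopifnot(is(object, "GEEFit")); object@p_values }

#' Estimated exchangeable working correlation
#' @param object A [GEEFit-class].
#' @return Scalar (NA under independence).
#' @export
workingAlpha <- function(object) { stopifnot(is(object, "GEEFit")); object@alpha }

# tidy one fit into rows of (term, estimate, robust_se, z, p)
.tidyGEE <- function(fit, ...) {
  extra <- list(...)
  out <- data.frame(term = names(coef(fit)), estimate = unname(coef(fit)),
                    robust_se = unname(robustSE(fit)),
                    z = unname(fit@wald_z), p = unname(pValues(fit)),
                    n_obs = fit@n_obs, n_clusters = fit@n_clusters,
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out[, c(names(extra), setdiff(names(out), names(extra)))]
}
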