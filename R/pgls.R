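## Phylogenetic generalised least squares with Pagel's lambda.
## The GLS algebra is kept explicit (Cholesky solves) so that lambda = 0
## reduces exactly to OLS and lambda = 1 to Brownian GLS; tests hold both
## routes against independent oracles.

#' Brownian phylogenetic covariance matrix
#'
#' Under Brownian trait evolution the expected covariance between two tips
#' equals the branch length shared from the root to their most recent
#' common ancestor; the diagonal holds root-to-tip depths (constant for an
#' ultrametric tree).
#'
#' @param tree a rooted `phylo` object with branch lengths, or a path to a
#'   Newick file.
#' @return Object of class `"phylo_cov"`: list with `C` (n x n labelled
#'   matrix), `tip_order` (character) and `tree`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' brownian_covariance(tr)$C
#' @export
brownian_covariance <- function(tree) {
  if (is.character(tree)) tree <- read_newick(tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv.phylo(tree)
  if (max(diag(C)) <= 0) stop("tree has zero depth")
  structure(list(C = C, tip_order = rownames(C), tree = tree),
            class = "phylo_cov")
}

## V(lambda): off-diagonal shared branch lengths scaled by lambda,
## diagonal kept.
.pagel_V <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

## GLS solve for fixed V via Cholesky; returns everything summary needs.
.gls_solve <- function(X, y, V) {
  n <- nrow(X); p <- ncol(X)
  L <- tryCatch(chol(V), error = function(e)
    stop("phylogenetic covariance is singular (condition number ",
         format(kappa(V), digits = 3), ")"))
  ## whiten: solve L' z = . (V = L'L with R's upper-tri chol)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  rownames(beta) <- colnames(X)
  resid <- y - X %*% beta
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  sigma2 <- rss / (n - p)
  vcov_beta <- sigma2 * solve(XtX)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  ## ML log-likelihood at the ML variance scale (rss/n)
  logdetV <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi * rss / n) + logdetV + n)
  ## generalized R^2 against the GLS intercept-only model
  ones <- matrix(1, n, 1)
  ow <- backsolve(L, ones, transpose = TRUE)
  mu <- sum(ow * yw) / sum(ow^2)
  tss <- sum((yw - ow * mu)^2)
  list(beta = drop(beta), vcov = vcov_beta, sigma2 = sigma2,
       rss = rss, logLik = ll, df.residual = n - p,
       residuals = drop(resid), fitted = drop(X %*% beta),
       r.squared.gls = 1 - rss / tss,
       r.squared.ols = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

#' Phylogenetically controlled regression (PGLS with Pagel's lambda)
#'
#' Fits a linear model by generalised least squares with residual
#' covariance `V(lambda) = lambda * C` off the diagonal and `diag(C)` on
#' it, where `C` is the Brownian covariance of the tree and Pagel's
#' `lambda` in \[0, 1\] measures phylogenetic signal in the residuals
#' (0 = star phylogeny / OLS, 1 = full Brownian covariance). `lambda` may
#' be fixed or profiled by maximum likelihood.
#'
#' @param formula model formula; variables are looked up in `data`.
#' @param data data frame with a `species` column matching the tree tips
#'   (spaces and underscores are interchangeable, matching is
#'   case-insensitive), or rows already ordered to `cov$tip_order`.
#' @param cov a `"phylo_cov"` from [brownian_covariance()], a `phylo`
#'   tree, or `NULL` for an ordinary (non-phylogenetic) least-squares fit.
#' @param lambda `"ML"` (default) to profile the likelihood on \[0, 1\], or
#'   a fixed value in \[0, 1\].
#' @return Object of class `"pgls"` with `coefficients`, `se`, `tstat`,
#'   `pvalue`, `vcov`, `lambda`, `logLik`, `r.squared` (generalized) and
#'   `r.squared.ols`, `residuals`, `fitted`, `df.residual`, `n`.
#' @examples
#' tr <- ape::rcoal(8)
#' d <- data.frame(species = tr$tip.label, x = rnorm(8))
#' d$y <- 2 * d$x + rnorm(8, sd = 0.1)
#' pgls(y ~ x, d, cov = tr, lambda = 0)
#' @export
pgls <- function(formula, data, cov = NULL, lambda = "ML") {
  cl <- match.call()
  if (inherits(cov, "phylo")) cov <- brownian_covariance(cov)
  if (!is.null(cov)) {
    data <- align_to_tips(data, cov$tip_order)
    C <- cov$C
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 species")
  if (is.null(cov)) {
    C <- diag(n)
    lambda <- 0
  }

  fit_at <- function(lam) .gls_solve(X, y, .pagel_V(C, lam))
  ll_at <- function(lam) tryCatch(fit_at(lam)$logLik,
                                  error = function(e) -Inf)
  if (identical(lambda, "ML")) {
    opt <- optimize(ll_at, c(0, 1), maximum = TRUE, tol = 1e-8)
    ## the optimum may sit on a boundary optimize() cannot touch
    cand <- c(opt$maximum, 0, 1)
    lls <- vapply(cand, ll_at, numeric(1))
    lambda_hat <- cand[which.max(lls)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("'lambda' must be \"ML\" or a number in [0, 1]")
    lambda_hat <- lambda
  }
  g <- fit_at(lambda_hat)
  se <- sqrt(diag(g$vcov))
  tstat <- g$beta / se
  pval <- 2 * pt(-abs(tstat), g$df.residual)
  structure(
    list(coefficients = g$beta, se = se, tstat = tstat, pvalue = pval,
         vcov = g$vcov, sigma2 = g$sigma2, lambda = lambda_hat,
         lambda_mode = if (identical(lambda, "ML")) "ML" else "fixed",
         logLik = g$logLik, r.squared = g$r.squared.gls,
         r.squared.ols = g$r.squared.ols,
         residuals = g$residuals, fitted = g$fitted,
         df.residual = g$df.residual, n = n,
         formula = formula, call = cl,
         terms = attr(mf, "terms")),
    class = "pgls"
  )
}

#' Match species labels in a trait table to tree tip labels
#'
#' Labels are compared after replacing spaces with underscores and case
#' folding. Species absent from the tree are dropped with a warning, never
#' silently; tips absent from the table are ignored.
#'
#' @param data data frame with a `species` column.
#' @param tip_order character vector of tip labels defining the row order.
#' @return `data` reordered to `tip_order` (matched rows only).
#' @export
align_to_tips <- function(data, tip_order) {
  if (is.null(data$species)) {
    if (nrow(data) == length(tip_order)) return(data)
    stop("'data' needs a species column to align to the tree")
  }
  norm <- function(x) tolower(gsub(" ", "_", trimws(x)))
  idx <- match(norm(tip_order), norm(data$species))
  if (all(is.na(idx))) stop("no species in common between data and tree")
  if (anyNA(idx)) {
    missing_tips <- tip_order[is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  dropped <- data$species[!norm(data$species) %in% norm(tip_order)]
  if (length(dropped))
    warning("species not in tree, dropped: ", paste(dropped, collapse = ", "))
  out <- data[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("  lambda =", format(x$lambda, digits = digits),
      sprintf("(%s), n = %d\n", x$lambda_mode, x$n))
  print(round(rbind(estimate = x$coefficients, se = x$se), digits))
  cat("  R2 (generalized) =", format(x$r.squared, digits = digits),
      " R2 (OLS-style) =", format(x$r.squared.ols, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tstat, `Pr(>|t|)` = object$pvalue)
  structure(list(call = object$call, coefficients = tab,
                 lambda = object$lambda, lambda_mode = object$lambda_mode,
                 r.squared = object$r.squared,
                 r.squared.ols = object$r.squared.ols,
                 df.residual = object$df.residual, n = object$n,
                 logLik = object$logLik),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, digits = 4, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d, residual df = %d, lambda = %s (%s)\n",
              x$n, x$df.residual, format(x$lambda, digits = digits),
              x$lambda_mode))
  stats::printCoefmat(x$coefficients, digits = digits)
  cat("R2 (generalized):", format(x$r.squared, digits = digits),
      "  R2 (OLS-style):", format(x$r.squared.ols, digits = digits),
      "  logLik:", format(x$logLik, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 2,
            nobs = object$n, class = "logLik")
}

#' @export
predict.pgls <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  drop(X %*% object$coefficients)
}

#' @export
confint.pgls <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  a <- (1 - level) / 2
  q <- qt(c(a, 1 - a), object$df.residual)
  out <- cbind(cf[parm] + q[1] * object$se[parm],
               cf[parm] + q[2] * object$se[parm])
  colnames(out) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  out
}
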