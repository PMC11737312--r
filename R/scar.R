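## Power-law prediction of bite force from the adductor mandibulae
## externus scar on the mandible: an osteological proxy usable on dry or
## museum skulls where dissection is impossible.

new_scar_model <- function(log_intercept, log_slope, fit = NULL) {
  coefficient <- 10^log_intercept
  if (coefficient <= 0 || !is.finite(coefficient))
    stop("invalid scar model coefficient")
  structure(list(coefficient = coefficient, exponent = log_slope,
                 log_intercept = log_intercept, log_slope = log_slope,
                 fit = fit),
            class = "scar_model")
}

#' Fit the scar-length power law
#'
#' Fits `log10(bite force) = a + b log10(scar length)` (via [pgls()] when a
#' tree is given, plain least squares otherwise) and expresses it as the
#' power law `bite force = 10^a * scar_length^b`.
#'
#' @param scar_length_mm scar lengths, mm (> 0).
#' @param bite_force_N matching bite forces, N (> 0).
#' @param cov optional phylogeny / `"phylo_cov"`; requires `species`.
#' @param species species labels (needed only with `cov`).
#' @param lambda passed to [pgls()].
#' @return Object of class `"scar_model"`: `coefficient` (N mm^-exponent),
#'   `exponent`, `log_intercept`, `log_slope` and the underlying `fit`.
#' @examples
#' m <- fit_scar_model(c(2, 4, 8, 16), 2 * c(2, 4, 8, 16)^3)
#' coef(m) # coefficient 2, exponent 3
#' @export
fit_scar_model <- function(scar_length_mm, bite_force_N, cov = NULL,
                           species = NULL, lambda = "ML") {
  keep <- !is.na(scar_length_mm) & !is.na(bite_force_N)
  x <- scar_length_mm[keep]; y <- bite_force_N[keep]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(x <= 0)) stop("invalid row: non-positive scar length")
  if (any(y <= 0)) stop("invalid row: non-positive bite force")
  d <- data.frame(log_scar = log10(x), log_bf = log10(y))
  if (!is.null(cov)) {
    if (is.null(species)) stop("'species' required with a phylogeny")
    d$species <- species[keep]
  }
  fit <- pgls(log_bf ~ log_scar, d, cov = cov,
              lambda = if (is.null(cov)) 0 else lambda)
  new_scar_model(unname(fit$coefficients[1]), unname(fit$coefficients[2]),
                 fit = fit)
}

#' A scar model from published log-log coefficients
#'
#' Builds a [fit_scar_model()]-style object directly from an intercept and
#' slope on the log10 scale, e.g. to apply a published prediction equation
#' to new skulls.
#'
#' @param log_intercept intercept of the log10-log10 fit.
#' @param log_slope slope (the power-law exponent).
#' @return A `"scar_model"` object (with no `fit` component).
#' @examples
#' scar_power_law(-0.026, 2.195)$coefficient # ~0.94
#' @export
scar_power_law <- function(log_intercept, log_slope) {
  new_scar_model(log_intercept, log_slope)
}

#' Predict bite force from scar length
#'
#' @param object a `"scar_model"`.
#' @param scar_length_mm scar length(s), mm (>= 0); vectorized.
#' @param interval `"none"` (default) or `"prediction"` for a 95%
#'   prediction interval from the fit's residual variance (only available
#'   for fitted models; an add-on beyond the point prediction itself).
#' @param ... unused.
#' @return Predicted bite force, N; with `interval = "prediction"` a data
#'   frame with `fit`, `lwr`, `upr`.
#' @export
predict.scar_model <- function(object, scar_length_mm,
                               interval = c("none", "prediction"), ...) {
  interval <- match.arg(interval)
  if (any(scar_length_mm < 0, na.rm = TRUE))
    stop("scar length must be >= 0")
  fit_val <- object$coefficient * scar_length_mm^object$exponent
  if (interval == "none") return(fit_val)
  if (is.null(object$fit))
    stop("prediction intervals need a fitted model, not published coefficients")
  f <- object$fit
  s <- sqrt(f$sigma2)
  q <- qt(0.975, f$df.residual)
  lx <- log10(scar_length_mm)
  half <- q * s * sqrt(1 + 1 / f$n)   # ignores leverage: diagnostic only
  data.frame(fit = fit_val,
             lwr = 10^(object$log_intercept + object$log_slope * lx - half),
             upr = 10^(object$log_intercept + object$log_slope * lx + half))
}

#' Scar length implied by a bite force
#'
#' Inverse of [predict.scar_model()]: scar = (BF / coefficient)^(1 /
#' exponent). Round-tripping through the prediction is the identity.
#'
#' @param object a `"scar_model"`.
#' @param bite_force_N bite force(s), N (>= 0).
#' @return Scar length, mm.
#' @export
invert_prediction <- function(object, bite_force_N) {
  stopifnot(inherits(object, "scar_model"))
  if (any(bite_force_N < 0, na.rm = TRUE)) stop("bite force must be >= 0")
  (bite_force_N / object$coefficient)^(1 / object$exponent)
}

#' @export
coef.scar_model <- function(object, ...) {
  c(coefficient = object$coefficient, exponent = object$exponent)
}

#' @export
print.scar_model <- function(x, digits = 4, ...) {
  cat(sprintf("Scar power law: bite force (N) = %.*g x scar length (mm)^%.*g\n",
              digits, x$coefficient, digits, x$exponent))
  if (!is.null(x$fit))
    cat(sprintf("  log10-log10 fit: intercept %.4g (se %.3g), slope %.4g (se %.3g), R2 %.3g, lambda %.3g, n %d\n",
                x$fit$coefficients[1], x$fit$se[1], x$fit$coefficients[2],
                x$fit$se[2], x$fit$r.squared, x$fit$lambda, x$fit$n))
  invisible(x)
}
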