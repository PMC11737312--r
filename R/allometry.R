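#' Log10-transform a species trait table
#'
#' All morphometric analyses run on base-10 logarithms. Positive-valued
#' trait columns are transformed in place; a non-positive value in a
#' transformed column is an error naming the species and field. Missing
#' optional columns are left alone so that rows are dropped per
#' relationship, not globally.
#'
#' @param traits species trait data frame (see [read_traits()]).
#' @param columns character vector of columns to transform; defaults to
#'   the morphometric columns present among `body_mass_g`, `skull_mass_g`,
#'   `skull_length_mm`, `jaw_muscle_mass_g`, `bite_force_N`,
#'   `scar_length_mm`.
#' @return The data frame with the selected columns replaced by their
#'   base-10 logs (column names prefixed `log_`).
#' @export
log10_table <- function(traits, columns = NULL) {
  stopifnot(is.data.frame(traits))
  if (is.null(columns))
    columns <- intersect(c("body_mass_g", "skull_mass_g", "skull_length_mm",
                           "jaw_muscle_mass_g", "bite_force_N",
                           "scar_length_mm"),
                         names(traits))
  out <- traits
  for (cl in columns) {
    v <- traits[[cl]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      who <- if (!is.null(traits$species)) traits$species[bad] else bad
      stop("invalid row: non-positive '", cl, "' for ",
           paste(who, collapse = ", "))
    }
    out[[paste0("log_", cl)]] <- log10(v)
    out[[cl]] <- NULL
  }
  out
}

#' Isometric scaling expectations
#'
#' Under geometric similarity a force scales as mass^(2/3) (areas scale as
#' the 2/3 power of volumes/masses) and as length^2. The conventional
#' two-decimal exponent 0.66 is used for mass-like predictors, and 2.0 for
#' length-like predictors (skull length, scar length).
#'
#' @return Named numeric vector of expected log-log slopes.
#' @export
isometric_exponents <- function() {
  c(body_mass = 0.66, skull_mass = 0.66, jaw_muscle_mass = 0.66,
    skull_length = 2.0, scar_length = 2.0)
}

#' One-sample t-test of a fitted exponent against isometry
#'
#' t = (slope - expected) / SE, two-sided p from a t-distribution.
#'
#' @param slope fitted log-log slope.
#' @param slope_se its standard error.
#' @param expected expected isometric exponent.
#' @param df degrees of freedom for the reference distribution.
#' @return List with `t`, `p`, `df`, `expected`.
#' @examples
#' isometry_t_test(2.574, 0.191, 2.0, 18) # positively allometric
#' @export
isometry_t_test <- function(slope, slope_se, expected, df) {
  stopifnot(slope_se > 0, df >= 1)
  t <- (slope - expected) / slope_se
  list(t = t, p = 2 * pt(-abs(t), df), df = df, expected = expected)
}

#' Allometry of bite force against body-size traits
#'
#' Fits the log10-log10 relationship of bite force against each available
#' predictor with [pgls()] (or OLS when no tree is supplied), and tests
#' each fitted exponent against its isometric expectation.
#'
#' @param traits species trait table with `bite_force_N` and at least one
#'   of `body_mass_g`, `skull_mass_g`, `skull_length_mm`,
#'   `jaw_muscle_mass_g`, `scar_length_mm`.
#' @param cov phylogeny / covariance passed to [pgls()], or `NULL` for OLS.
#' @param lambda passed to [pgls()].
#' @param isometry named expectations, see [isometric_exponents()].
#' @return Data frame, one row per relationship: `predictor`, `n`,
#'   `intercept`, `intercept_se`, `slope`, `slope_se`, `t_slope`,
#'   `p_slope`, `r_squared`, `r_squared_ols`, `lambda`, `t_isometry`,
#'   `p_isometry`, `expected_exponent`, `verdict` ("isometric",
#'   "positively allometric" or "negatively allometric" at alpha = 0.05).
#' @export
allometry_report <- function(traits, cov = NULL, lambda = "ML",
                             isometry = isometric_exponents()) {
  preds <- c(body_mass = "body_mass_g", skull_mass = "skull_mass_g",
             skull_length = "skull_length_mm",
             jaw_muscle_mass = "jaw_muscle_mass_g",
             scar_length = "scar_length_mm")
  preds <- preds[preds %in% names(traits)]
  if (!length(preds) || is.null(traits$bite_force_N))
    stop("traits table must contain bite_force_N and at least one predictor")
  rows <- lapply(names(preds), function(nm) {
    col <- preds[[nm]]
    keep <- !is.na(traits[[col]]) & !is.na(traits$bite_force_N)
    d <- traits[keep, , drop = FALSE]
    ld <- log10_table(d, columns = c(col, "bite_force_N"))
    f <- stats::as.formula(paste("log_bite_force_N ~ log_", col, sep = ""))
    fit <- pgls(f, ld, cov = cov, lambda = lambda)
    exp_b <- isometry[[nm]]
    iso <- isometry_t_test(fit$coefficients[2], fit$se[2], exp_b, fit$n - 1)
    verdict <- if (iso$p >= 0.05) "isometric" else if (iso$t > 0)
      "positively allometric" else "negatively allometric"
    data.frame(predictor = nm, n = fit$n,
               intercept = unname(fit$coefficients[1]),
               intercept_se = unname(fit$se[1]),
               slope = unname(fit$coefficients[2]),
               slope_se = unname(fit$se[2]),
               t_slope = unname(fit$tstat[2]),
               p_slope = unname(fit$pvalue[2]),
               r_squared = fit$r.squared,
               r_squared_ols = fit$r.squared.ols,
               lambda = fit$lambda,
               expected_exponent = exp_b,
               t_isometry = iso$t, p_isometry = iso$p,
               verdict = verdict)
  })
  do.call(rbind, rows)
}

#' Bite force to body mass ratio
#'
#' A size-relative performance measure, N/g.
#'
#' @param bite_force_N bite force, N.
#' @param body_mass_g body mass, g.
#' @return Ratio, N/g.
#' @export
bf_bm_ratio <- function(bite_force_N, body_mass_g) {
  if (any(body_mass_g <= 0, na.rm = TRUE)) stop("body mass must be > 0")
  bite_force_N / body_mass_g
}
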