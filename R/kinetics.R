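#' Michaelis-Menten kinetics and inhibition-mechanism classification
#'
#' Apparent (Vmax, Km) are estimated per inhibitor concentration by
#' nonlinear least squares on `v = Vmax [S] / (Km + [S])`; the
#' double-reciprocal Lineweaver-Burk line is produced for display and
#' verification only, because the reciprocal transform distorts the error
#' structure.  The mechanism call follows explicit trend rules on the
#' apparent parameters across inhibitor levels: competitive inhibition
#' raises apparent Km at constant Vmax, non-competitive inhibition lowers
#' apparent Vmax at constant Km, and uncompetitive inhibition lowers both
#' while preserving the Km/Vmax ratio.
#'
#' @name enzyme_kinetics
NULL

#' Fit the Michaelis-Menten rate law
#'
#' @param S substrate concentrations (micromolar, > 0).
#' @param v measured rates (arbitrary linear units).
#' @return object of class `mm_fit` with `vmax`, `km` (uM), standard
#'   errors, `rss` and a `non_saturating` warning flag (max tested [S]
#'   below half the Km estimate).
#' @export
fit_michaelis_menten <- function(S, v) {
  stopifnot(length(S) == length(v), all(is.finite(S)), all(is.finite(v)),
            all(S > 0))
  if (length(unique(S)) < 3L) {
    stop("need at least 3 distinct substrate concentrations", call. = FALSE)
  }
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  fit <- minpack.lm::nlsLM(
    v ~ vmax * S / (km + S),
    data = data.frame(S = S, v = v),
    start = list(vmax = vmax0, km = max(km0, min(S))),
    lower = c(vmax = 1e-12, km = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(vmax = NA_real_, km = NA_real_))
  structure(list(
    vmax = cf[["vmax"]], km = cf[["km"]],
    vmax_se = se[["vmax"]], km_se = se[["km"]],
    rss = sum(stats::residuals(fit)^2),
    non_saturating = max(S) < cf[["km"]] / 2,
    model = fit, data = data.frame(S = S, v = v)
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax = %s, Km = %s uM%s\n",
              format(x$vmax, digits = digits), format(x$km, digits = digits),
              if (x$non_saturating) " (warning: non-saturating data)" else ""))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(vmax = object$vmax, km = object$km)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else newdata$S
  object$vmax * S / (object$km + S)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$data$v - predict(object)
}

#' @export
plot.mm_fit <- function(x, ...) {
  plot(x$data$S, x$data$v, xlab = "[S] (uM)", ylab = "rate", ...)
  Ss <- seq(0, max(x$data$S), length.out = 100)
  graphics::lines(Ss, x$vmax * Ss / (x$km + Ss))
  invisible(x)
}

#' Lineweaver-Burk double-reciprocal line
#'
#' Ordinary least squares of 1/v on 1/[S]; on noise-free Michaelis-Menten
#' data the slope is Km/Vmax and the intercept 1/Vmax.
#'
#' @param S substrate concentrations (> 0).
#' @param v rates (> 0; reciprocals are undefined otherwise).
#' @return list with `slope`, `intercept`, `r_squared` and the `lm` fit.
#' @export
lineweaver_burk <- function(S, v) {
  stopifnot(length(S) == length(v), all(S > 0))
  if (any(v <= 0)) {
    stop("all rates must be positive for the reciprocal transform",
         call. = FALSE)
  }
  d <- data.frame(inv_S = 1 / S, inv_v = 1 / v)
  m <- stats::lm(inv_v ~ inv_S, data = d)
  cf <- stats::coef(m)
  list(slope = cf[["inv_S"]], intercept = cf[["(Intercept)"]],
       r_squared = suppressWarnings(summary(m)$r.squared), model = m)
}

# trend of a fitted parameter across inhibitor levels: regress log(param)
# on [I]; relative change over the tested range plus a monotonicity p-value
param_trend <- function(I, param) {
  m <- stats::lm(log(param) ~ I)
  slope <- stats::coef(m)[["I"]]
  # noise-free data gives an exact fit; the p-value is still well-defined
  p <- suppressWarnings(summary(m)$coefficients["I", "Pr(>|t|)"])
  if (!is.finite(p)) p <- 1
  rel_change <- exp(slope * (max(I) - min(I))) - 1
  d <- diff(param[order(I)])
  monotone <- all(d > 0) || all(d < 0)
  list(rel_change = rel_change, slope = slope, p_value = p,
       monotone = monotone)
}

# a parameter "changes" only when the trend is practically large (fitted
# relative change beyond +/-20% over the inhibitor range) AND supported
# ordinally: either monotone at 95% confidence by the regression t-test, or
# strictly monotone across every inhibitor level (the exact-trend fallback,
# which matters for designs with so few levels that the t-test has almost no
# power). Requiring practical size keeps spuriously significant near-zero
# slopes classified as "flat".
trend_flag <- function(tr, rel_tol = 0.20, alpha = 0.05) {
  if (abs(tr$rel_change) > rel_tol && (tr$p_value < alpha || tr$monotone)) {
    if (tr$rel_change > 0) "up" else "down"
  } else {
    "flat"
  }
}

#' Classify the inhibition mechanism from kinetics data
#'
#' Fits apparent (Vmax, Km) at each inhibitor concentration, computes trend
#' statistics of both parameters (and of their ratio) across the inhibitor
#' range, and classifies: competitive (Km up, Vmax unchanged),
#' non-competitive (Vmax down, Km unchanged), uncompetitive (both down,
#' Km/Vmax ratio unchanged), mixed (both changing otherwise), indeterminate
#' (no parameter responds).  The per-[I] table is always reported so the
#' call is auditable.
#'
#' @param data data frame with columns `S_uM`, `I_uM` and `rate` (optional
#'   `replicate`); must contain at least 2 inhibitor levels including
#'   `I_uM == 0`, and at least 3 distinct substrate levels per inhibitor
#'   level.
#' @param s_range optional length-2 numeric: only substrate concentrations
#'   inside `[s_range[1], s_range[2]]` are fitted; excluded points are
#'   listed in the result (point-windowing is never silent).
#' @return object of class `mechanism_call`.
#' @export
classify_mechanism <- function(data, s_range = NULL) {
  stopifnot(is.data.frame(data),
            all(c("S_uM", "I_uM", "rate") %in% names(data)))
  excluded <- data[0, , drop = FALSE]
  if (!is.null(s_range)) {
    stopifnot(length(s_range) == 2L)
    keep <- data$S_uM >= s_range[1] & data$S_uM <= s_range[2]
    excluded <- data[!keep, , drop = FALSE]
    data <- data[keep, , drop = FALSE]
  }
  data <- data[data$S_uM > 0, , drop = FALSE]
  levels_I <- sort(unique(data$I_uM))
  if (length(levels_I) < 2L) {
    stop("need at least 2 inhibitor levels", call. = FALSE)
  }
  if (!0 %in% levels_I) {
    stop("kinetics data must include the uninhibited ([I] = 0) condition",
         call. = FALSE)
  }
  fits <- lapply(levels_I, function(I) {
    d <- data[data$I_uM == I, , drop = FALSE]
    fit_michaelis_menten(d$S_uM, d$rate)
  })
  tab <- data.frame(
    I_uM = levels_I,
    vmax = vapply(fits, `[[`, numeric(1), "vmax"),
    vmax_se = vapply(fits, `[[`, numeric(1), "vmax_se"),
    km = vapply(fits, `[[`, numeric(1), "km"),
    km_se = vapply(fits, `[[`, numeric(1), "km_se")
  )
  tr_km <- param_trend(tab$I_uM, tab$km)
  tr_vmax <- param_trend(tab$I_uM, tab$vmax)
  tr_ratio <- param_trend(tab$I_uM, tab$km / tab$vmax)
  fk <- trend_flag(tr_km)
  fv <- trend_flag(tr_vmax)
  fr <- trend_flag(tr_ratio)
  mechanism <- if (fk == "flat" && fv == "flat") {
    "indeterminate"
  } else if (fk == "up" && fv == "flat") {
    "competitive"
  } else if (fk == "flat" && fv == "down") {
    "non-competitive"
  } else if (fk == "down" && fv == "down" && fr == "flat") {
    "uncompetitive"
  } else {
    "mixed"
  }
  structure(list(
    mechanism = mechanism,
    table = tab,
    trends = list(km = tr_km, vmax = tr_vmax, ratio = tr_ratio),
    flags = c(km = fk, vmax = fv, ratio = fr),
    fits = fits,
    excluded_points = excluded
  ), class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, digits = 4, ...) {
  cat(sprintf("Inhibition mechanism: %s\n", x$mechanism))
  cat(sprintf("  Km trend %s (%+.1f%%), Vmax trend %s (%+.1f%%)\n",
              x$flags[["km"]], 100 * x$trends$km$rel_change,
              x$flags[["vmax"]], 100 * x$trends$vmax$rel_change))
  print(x$table, digits = digits)
  if (nrow(x$excluded_points)) {
    cat(sprintf("  (%d points excluded by substrate windowing)\n",
                nrow(x$excluded_points)))
  }
  invisible(x)
}

#' Convert a peptide mass concentration to molarity
#'
#' The polymeric kinase substrate is dosed by mass; molarity assumes an
#' average polymer mass (default 12.5 kDa).
#'
#' @param mg_ml mass concentration in mg/mL.
#' @param mass_kda average molecular mass in kDa (default 12.5).
#' @return concentration in micromolar.
#' @export
peptide_conc_uM <- function(mg_ml, mass_kda = 12.5) {
  stopifnot(mg_ml >= 0, mass_kda > 0)
  mg_ml / mass_kda * 1000
}
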