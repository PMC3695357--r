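#' Dilution schemes, constrained IC50 fitting and selectivity ratios
#'
#' Dose-response curves of percent activity are fitted with the constrained
#' variable-slope sigmoid
#' \deqn{\%A(c) = 100 / (1 + (c/IC_{50})^h)}
#' i.e. a four-parameter logistic with the top fixed at 100\% and the bottom
#' at 0\%, so the only free parameters are the IC50 and the Hill slope h.
#'
#' @name dose_response
NULL

#' Define a serial-dilution scheme
#'
#' @param top_stock top stock concentration (micromolar).
#' @param fold serial dilution factor (default 2).
#' @param n_points number of points (at least 2).
#' @param transfer_dilution fold dilution from stock into the assay
#'   (default 100).
#' @return list of class `dilution_scheme`.
#' @export
dilution_scheme <- function(top_stock, fold = 2, n_points,
                            transfer_dilution = 100) {
  stopifnot(top_stock > 0, fold > 1, n_points >= 2, transfer_dilution > 0)
  structure(list(top_stock = top_stock, fold = fold,
                 n_points = as.integer(n_points),
                 transfer_dilution = transfer_dilution),
            class = "dilution_scheme")
}

#' Compute a serial dilution series
#'
#' Stock concentrations are `top_stock / fold^(i-1)`; final (in-assay)
#' concentrations divide each stock by the transfer dilution.
#'
#' @param s a `dilution_scheme`.
#' @return data frame with columns `point`, `stock_uM`, `final_uM`.
#' @export
dilution_series <- function(s) {
  stopifnot(inherits(s, "dilution_scheme"))
  i <- seq_len(s$n_points)
  stock <- s$top_stock / s$fold^(i - 1)
  data.frame(point = i, stock_uM = stock,
             final_uM = stock / s$transfer_dilution)
}

ic50_model <- function(conc, log10ic50, hill) {
  100 / (1 + 10^(hill * (log10(conc) - log10ic50)))
}

#' Fit a constrained sigmoidal dose-response curve
#'
#' Least-squares fit of `%A(c) = 100 / (1 + (c/IC50)^h)` over (IC50, h).
#' Replicates enter the loss individually.  The IC50 is initialized at the
#' tested concentration whose mean response is nearest 50\% and the Hill
#' slope at 1; bounds are IC50 in [1e-4, 1e6] uM and h in [0.2, 10].  The
#' convergence flag is FALSE when the optimizer hits a bound or when all
#' responses lie on one side of 50\% (no transition observed); the fit is
#' still returned for inspection.  `censored_at_top` marks IC50 estimates at
#' or beyond the highest tested concentration (reported as "~top" values).
#'
#' @param data data frame with columns `conc_uM` and `activity` (percent),
#'   one row per replicate measurement.
#' @return object of class `ic50_fit` with components `ic50` (uM), `hill`,
#'   `rss`, `converged`, `censored_at_top`, `ci_halfwidth` (uM, from the
#'   fit's curvature; reported, not guaranteed calibrated) and `model` (the
#'   underlying `nls` object or NULL).
#' @export
fit_ic50 <- function(data) {
  stopifnot(is.data.frame(data), all(c("conc_uM", "activity") %in% names(data)))
  data <- data[is.finite(data$conc_uM) & is.finite(data$activity) &
                 data$conc_uM > 0, , drop = FALSE]
  concs <- sort(unique(data$conc_uM))
  if (length(concs) < 4L) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  means <- vapply(split(data$activity, data$conc_uM), mean, numeric(1))
  init_conc <- as.numeric(names(means))[which.min(abs(means - 50))]
  one_sided <- all(means > 50) || all(means < 50)

  lo <- c(log10ic50 = -4, hill = 0.2)
  hi <- c(log10ic50 = 6, hill = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      activity ~ ic50_model(conc_uM, log10ic50, hill),
      data = data,
      start = list(log10ic50 = log10(init_conc), hill = 1),
      lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, rss = NA_real_,
                          converged = FALSE, censored_at_top = NA,
                          ci_halfwidth = NA_real_, model = NULL,
                          data = data),
                     class = "ic50_fit"))
  }
  cf <- stats::coef(fit)
  at_bound <- any(abs(cf - lo) < 1e-8) || any(abs(cf - hi) < 1e-8)
  ic50 <- 10^cf[["log10ic50"]]
  se_log <- tryCatch(sqrt(diag(stats::vcov(fit)))[["log10ic50"]],
                     error = function(e) NA_real_)
  # delta-method half-width of a 95% interval on the IC50 scale
  ci_hw <- if (is.finite(se_log)) 1.96 * se_log * log(10) * ic50 else NA_real_
  structure(list(
    ic50 = ic50,
    hill = cf[["hill"]],
    rss = sum(stats::residuals(fit)^2),
    converged = !at_bound && !one_sided,
    censored_at_top = ic50 >= max(concs),
    ci_halfwidth = ci_hw,
    model = fit,
    data = data
  ), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  cat("Constrained sigmoidal dose-response fit (top 100%, bottom 0%)\n")
  cat(sprintf("  IC50: %s uM%s   Hill slope: %s\n",
              format(x$ic50, digits = digits),
              if (isTRUE(x$censored_at_top)) " (censored at top conc)" else "",
              format(x$hill, digits = digits)))
  cat(sprintf("  RSS: %s   converged: %s\n",
              format(x$rss, digits = digits), x$converged))
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc_uM else newdata$conc_uM
  ic50_model(conc, log10(object$ic50), object$hill)
}

#' @export
residuals.ic50_fit <- function(object, ...) {
  object$data$activity - predict(object)
}

#' @export
summary.ic50_fit <- function(object, ...) {
  cat(sprintf(
    "IC50 %.4g uM (95%% half-width %.3g), hill %.3g, RSS %.4g, n = %d\n",
    object$ic50, object$ci_halfwidth, object$hill, object$rss,
    nrow(object$data)))
  if (!is.null(object$model)) print(summary(object$model))
  invisible(object)
}

#' @export
plot.ic50_fit <- function(x, ...) {
  d <- x$data
  plot(d$conc_uM, d$activity, log = "x",
       xlab = "concentration (uM)", ylab = "% activity", ...)
  cs <- exp(seq(log(min(d$conc_uM)), log(max(d$conc_uM)), length.out = 100))
  graphics::lines(cs, ic50_model(cs, log10(x$ic50), x$hill))
  graphics::abline(v = x$ic50, lty = 2)
  invisible(x)
}

#' Selectivity ratio between two kinase IC50s
#'
#' Reports the InsR/IGF1R IC50 ratio: above 1 the compound is
#' IGF1R-selective (lower IGF1R IC50), below 1 it is InsR-selective.
#'
#' @param ic50_igf1r,ic50_insr IC50 values in the same unit (both positive).
#' @param tol relative tolerance for calling a compound nonselective
#'   (default 1e-6, i.e. only exactly equal IC50s).
#' @return list of class `selectivity_ratio`: `ratio` (InsR/IGF1R), `fold`
#'   (the ratio in the selective direction, always >= 1) and `direction`.
#' @export
selectivity_ratio <- function(ic50_igf1r, ic50_insr, tol = 1e-6) {
  if (!is.finite(ic50_igf1r) || !is.finite(ic50_insr) ||
      ic50_igf1r <= 0 || ic50_insr <= 0) {
    stop("IC50 values must be positive and finite", call. = FALSE)
  }
  ratio <- ic50_insr / ic50_igf1r
  direction <- if (abs(ratio - 1) <= tol) {
    "nonselective"
  } else if (ratio > 1) {
    "IGF1R-selective"
  } else {
    "InsR-selective"
  }
  structure(list(ratio = ratio, fold = max(ratio, 1 / ratio),
                 direction = direction),
            class = "selectivity_ratio")
}

#' @export
print.selectivity_ratio <- function(x, ...) {
  cat(sprintf("<%.3g-fold %s (InsR/IGF1R = %.3g)>\n",
              x$fold, x$direction, x$ratio))
  invisible(x)
}
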