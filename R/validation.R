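#' Four-parameter logistic dose-response fit
#'
#' Fits response = bottom + (top - bottom) / (1 + (conc / ic50)^hill) by
#' Levenberg-Marquardt least squares, with IC50 parameterized on the log10
#' scale for stability. The reported IC50 is the relative IC50 — the
#' curve's inflection point — and the maximum inhibition is
#' 100 x (top - bottom) / top percent; fits with maximum inhibition below
#' `partial_threshold` are flagged as partial inhibitors. Responses are
#' fractional activity (1 = uninhibited control).
#'
#' @param concentrations inhibitor concentrations in uM (>= 5 points
#'   spanning the inflection; conc = 0 points anchor the top asymptote).
#' @param responses fractional activities, same length.
#' @param partial_threshold max-inhibition percentage below which the
#'   compound is flagged partial (default 80).
#' @return object of class `del_ic50_fit`: ic50, ic50_se, hill, top,
#'   bottom, max_inhibition (percent), partial, converged, residual_sd,
#'   and the data.
#' @examples
#' conc <- 10^seq(-1, 3, length.out = 8)
#' resp <- 0.05 + 0.95 / (1 + (conc / 7))
#' fit_ic50(conc, resp)$ic50  # 7
#' @export
fit_ic50 <- function(concentrations, responses, partial_threshold = 80) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 5L) {
    stop("need >= 5 concentration points")
  }
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  df <- data.frame(conc = concentrations, resp = responses)
  pos <- df$conc > 0
  if (sum(pos) < 4L) stop("need >= 4 non-zero concentrations")
  # starting values from the data
  top0 <- max(df$resp)
  bot0 <- min(df$resp)
  mid <- (top0 + bot0) / 2
  lic0 <- log10(df$conc[pos][which.min(abs(df$resp[pos] - mid))])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - lic))),
      data = df[pos, ],
      start = list(top = top0, bottom = bot0, hill = 1, lic = lic0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(ic50 = NA_real_, ic50_se = NA_real_, hill = NA_real_,
                top = NA_real_, bottom = NA_real_,
                max_inhibition = NA_real_, partial = NA, converged = FALSE,
                residual_sd = NA_real_, data = df)
    class(out) <- "del_ic50_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  ic50 <- 10^cf[["lic"]]
  ic50_se <- log(10) * ic50 * se[["lic"]]
  top <- cf[["top"]]; bottom <- cf[["bottom"]]
  max_inh <- 100 * (top - bottom) / top
  max_inh <- min(max(max_inh, 0), 100)
  out <- list(
    ic50 = ic50, ic50_se = ic50_se, hill = cf[["hill"]], top = top,
    bottom = bottom, max_inhibition = max_inh,
    partial = max_inh < partial_threshold, converged = TRUE,
    residual_sd = stats::sigma(fit), data = df
  )
  class(out) <- "del_ic50_fit"
  out
}

#' @export
print.del_ic50_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "4PL fit: relative IC50 = %.3g +/- %.2g uM, hill = %.2f, max inhibition %.0f%%%s\n",
    x$ic50, x$ic50_se, x$hill, x$max_inhibition,
    if (isTRUE(x$partial)) " (partial inhibitor)" else ""))
  invisible(x)
}

#' Plot a fitted dose-response curve
#'
#' @param x a `del_ic50_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.del_ic50_fit <- function(x, ...) {
  df <- x$data[x$data$conc > 0, ]
  graphics::plot(df$conc, df$resp, log = "x", xlab = "[I] (uM)",
                 ylab = "fractional activity", ylim = c(0, 1.05), ...)
  if (x$converged) {
    cc <- 10^seq(log10(min(df$conc)), log10(max(df$conc)), length.out = 200)
    yy <- x$bottom + (x$top - x$bottom) /
      (1 + 10^(x$hill * (log10(cc) - log10(x$ic50))))
    graphics::lines(cc, yy)
    graphics::abline(v = x$ic50, lty = 3)
  }
  invisible(x)
}

#' Score recovery of planted actives from a dose-comparison report
#'
#' Precision and recall of the planted warm building blocks within the
#' high-priority tier, plus the Spearman rank correlation between planted
#' series potency (-log10 of the series mean IC50) and combined cumulative
#' k over the series observed in the report.
#'
#' @param report a `del_dose_report`.
#' @param truth the `del_activity_map` the screens were simulated from.
#' @return list of class `del_recovery`: precision, recall, spearman,
#'   n_planted, n_high_priority, flagged (TRUE when either metric is
#'   undefined).
#' @export
score_recovery <- function(report, truth) {
  stopifnot(inherits(report, "del_dose_report"),
            inherits(truth, "del_activity_map"))
  planted <- truth$series$bb_id
  hp <- report$bb$bb_id[report$bb$tier == "high_priority"]
  precision <- if (length(hp)) mean(hp %in% planted) else NA_real_
  recall <- if (length(planted)) mean(planted %in% hp) else NA_real_
  obs <- report$bb[report$bb$bb_id %in% planted, , drop = FALSE]
  spearman <- NA_real_
  if (nrow(obs) >= 3L) {
    pot <- -log10(truth$series$mean_ic50[match(obs$bb_id,
                                               truth$series$bb_id)])
    spearman <- suppressWarnings(
      stats::cor(pot, obs$k_high + obs$k_low, method = "spearman"))
  }
  structure(list(
    precision = precision, recall = recall, spearman = spearman,
    n_planted = length(planted), n_high_priority = length(hp),
    flagged = is.na(precision) || is.na(recall)
  ), class = "del_recovery")
}

#' @export
print.del_recovery <- function(x, ...) {
  cat(sprintf(
    "Recovery: precision %.2f, recall %.2f, potency-k Spearman %.2f (%d planted, %d high-priority)%s\n",
    x$precision, x$recall, x$spearman, x$n_planted, x$n_high_priority,
    if (x$flagged) " [flagged: undefined metric]" else ""))
  invisible(x)
}

#' Dose-comparison scatter of building-block enrichment
#'
#' Cumulative k at the low dose against cumulative k at the high dose, one
#' point per observed building block, shaped by tier.
#'
#' @param x a `del_dose_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.del_dose_report <- function(x, ...) {
  pch <- c(high_priority = 19, dose_limited = 17, noise = 1,
           unobserved = 4)[x$bb$tier]
  graphics::plot(x$bb$k_high, x$bb$k_low, pch = pch,
                 xlab = sprintf("cumulative k (%s)", x$labels[["high"]]),
                 ylab = sprintf("cumulative k (%s)", x$labels[["low"]]),
                 ...)
  graphics::abline(h = x$min_k, v = x$min_k, lty = 3)
  graphics::legend("topleft", legend = names(pch)[!duplicated(pch)],
                   pch = pch[!duplicated(pch)], bty = "n")
  invisible(x)
}
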