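#' DPP-IV inhibition percentage from plate readings
#'
#' DI\% = \[1 - (A_S - A_SC) / (A_NR - A_NC)\] x 100, where A_S is the
#' absorbance with peptide, enzyme and substrate; A_SC the sample control
#' (enzyme replaced by buffer); A_NR the uninhibited reaction; and A_NC the
#' no-enzyme, no-peptide control. Values below 0 or above 100 are retained
#' as-is with a warning — clipping would bias downstream curve fits.
#'
#' @param a_s,a_sc,a_nr,a_nc Numeric vectors of plate readings (absorbance
#'   or fluorescence), recycled to a common length.
#' @return Numeric vector of inhibition percentages.
#' @examples
#' inhibition_percent(0.8, 0.2, 1.0, 0.2)  # 25
#' @export
inhibition_percent <- function(a_s, a_sc, a_nr, a_nc) {
  if (any(!is.finite(c(a_s, a_sc, a_nr, a_nc)))) {
    stop("plate readings must be finite", call. = FALSE)
  }
  if (any(a_nr == a_nc)) {
    stop("A_NR equals A_NC: inhibition undefined (degenerate denominator)",
         call. = FALSE)
  }
  di <- (1 - (a_s - a_sc) / (a_nr - a_nc)) * 100
  if (any(di < 0 | di > 100)) {
    warning("inhibition outside [0, 100]% reported as-is", call. = FALSE)
  }
  di
}

#' Cell viability percentage
#'
#' Viability\% = (OD_test - OD_blank) / (OD_control - OD_blank) x 100.
#'
#' @param od_test,od_blank,od_control Numeric vectors of optical densities.
#' @return Numeric vector of viability percentages.
#' @export
viability_percent <- function(od_test, od_blank, od_control) {
  if (any(od_control == od_blank)) {
    stop("OD_control equals OD_blank: viability undefined", call. = FALSE)
  }
  (od_test - od_blank) / (od_control - od_blank) * 100
}

# 4PL response at concentration conc (hill > 0: response rises with dose)
.fourpl <- function(conc, bottom, top, logic50, hill) {
  bottom + (top - bottom) / (1 + 10^((logic50 - log10(conc)) * hill))
}

#' Fit a four-parameter logistic dose-response curve (IC50)
#'
#' Least-squares fit of response = bottom + (top - bottom) /
#' (1 + 10^((log10(IC50) - log10(conc)) * hill)) on the log10 concentration
#' axis; IC50 is the inflection concentration. Initialisation is fixed and
#' deterministic — bottom/top from the per-dose mean extremes, log-IC50 by
#' linear interpolation between the doses bracketing the half-maximal
#' response (nearest dose when nothing brackets), hill = 1 — so identical
#' input always yields the identical fit. `nls` (port algorithm) is tried
#' first with a box constraint keeping hill positive; on failure an
#' L-BFGS-B least-squares fallback runs from the same start.
#'
#' @param concentration Strictly positive dose vector (>= 4 distinct values),
#'   in the unit of `unit`.
#' @param response Response vector (inhibition \%), same length.
#' @param fix_bottom,fix_top Optionally pin the asymptotes (e.g. 0 and 100).
#' @param unit Concentration unit label, `"uM"` or `"mg_ml"`; with
#'   `"mg_ml"` and `mass_da` supplied the reported IC50 is also converted
#'   to uM.
#' @param mass_da Peptide monoisotopic mass, for the mg/mL-to-uM conversion.
#' @return An object of class `ic50_fit` with coefficients `bottom`, `top`,
#'   `ic50`, `hill`, plus residual diagnostics; see [coef()], [predict()],
#'   [plot()] and [summary()] methods.
#' @examples
#' d <- gen_dose_response(ic50 = 200, doses = 10^seq(0, 3, length.out = 7),
#'                        noise_sd = 0, seed = 1)
#' fit <- fit_ic50(d$concentration, d$response)
#' coef(fit)[["ic50"]]
#' @export
fit_ic50 <- function(concentration, response, fix_bottom = NULL,
                     fix_top = NULL, unit = c("uM", "mg_ml"),
                     mass_da = NULL) {
  unit <- match.arg(unit)
  stopifnot(length(concentration) == length(response))
  if (any(concentration <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (length(unique(concentration)) < 4) {
    stop("at least 4 distinct concentrations required", call. = FALSE)
  }
  if (length(unique(response)) == 1) {
    stop("all responses identical: curve unidentifiable", call. = FALSE)
  }
  dat <- data.frame(conc = concentration, resp = response)
  means <- tapply(dat$resp, dat$conc, mean)
  doses <- as.numeric(names(means))
  ord <- order(doses)
  doses <- doses[ord]; means <- as.numeric(means)[ord]
  b0 <- if (is.null(fix_bottom)) min(means) else fix_bottom
  t0 <- if (is.null(fix_top)) max(means) else fix_top
  mid <- (b0 + t0) / 2
  # deterministic log-IC50 start: interpolate across the bracketing doses
  above <- means >= mid
  li0 <- log10(doses[which.min(abs(means - mid))])
  cross <- which(above[-1] != above[-length(above)])
  if (length(cross) > 0) {
    i <- cross[1]
    f <- (mid - means[i]) / (means[i + 1] - means[i])
    li0 <- log10(doses[i]) + f * (log10(doses[i + 1]) - log10(doses[i]))
  }
  start <- list(logic50 = li0, hill = 1)
  lower <- c(logic50 = -Inf, hill = 1e-3)
  upper <- c(logic50 = Inf, hill = 50)
  if (is.null(fix_bottom)) {
    start$bottom <- b0; lower <- c(lower, bottom = -Inf)
    upper <- c(upper, bottom = Inf)
  }
  if (is.null(fix_top)) {
    start$top <- t0; lower <- c(lower, top = -Inf)
    upper <- c(upper, top = Inf)
  }
  model_fun <- function(p, conc) {
    .fourpl(conc,
            bottom = if (is.null(fix_bottom)) p[["bottom"]] else fix_bottom,
            top = if (is.null(fix_top)) p[["top"]] else fix_top,
            logic50 = p[["logic50"]], hill = p[["hill"]])
  }
  form <- resp ~ .fourpl(conc,
    bottom = if (is.null(fix_bottom)) bottom else fix_bottom,
    top = if (is.null(fix_top)) top else fix_top,
    logic50 = logic50, hill = hill)
  fit <- tryCatch(
    nls(form, data = dat, start = start, algorithm = "port",
        lower = lower[names(start)], upper = upper[names(start)],
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    sse <- function(pv) {
      p <- setNames(pv, names(start))
      sum((dat$resp - model_fun(p, dat$conc))^2)
    }
    op <- optim(unlist(start), sse, method = "L-BFGS-B",
                lower = lower[names(start)], upper = upper[names(start)],
                control = list(maxit = 500))
    if (op$convergence != 0) {
      stop("IC50 fit did not converge (nls: ",
           conditionMessage(fit), "; optim code ", op$convergence, ")",
           call. = FALSE)
    }
    pars <- setNames(op$par, names(start))
    fitted_vals <- model_fun(pars, dat$conc)
    method <- "optim/L-BFGS-B"
  } else {
    pars <- coef(fit)
    fitted_vals <- as.numeric(fitted(fit))
    method <- "nls/port"
  }
  bottom <- if (is.null(fix_bottom)) pars[["bottom"]] else fix_bottom
  top <- if (is.null(fix_top)) pars[["top"]] else fix_top
  if (bottom > top) {  # reflected solution: swap and flip the slope sign
    tmp <- bottom; bottom <- top; top <- tmp
  }
  ic50 <- 10^pars[["logic50"]]
  res <- dat$resp - fitted_vals
  out <- list(
    coefficients = c(bottom = bottom, top = top, ic50 = ic50,
                     hill = pars[["hill"]]),
    unit = unit, data = dat, fitted = fitted_vals, residuals = res,
    rss = sum(res^2),
    sigma = sqrt(sum(res^2) / max(1, nrow(dat) - length(start))),
    method = method, fixed = list(bottom = fix_bottom, top = fix_top))
  if (unit == "mg_ml" && !is.null(mass_da)) {
    out$ic50_um <- convert_ic50_units(ic50, mass_da)
  }
  structure(out, class = "ic50_fit")
}

#' Convert an IC50 from mg/mL to uM
#'
#' IC50(uM) = IC50(mg/mL) x 10^6 / mass(Da).
#'
#' @param ic50_mg_ml IC50 in mg/mL.
#' @param mass_da Peptide mass in Da (see [monoisotopic_mass()]).
#' @return IC50 in uM.
#' @export
convert_ic50_units <- function(ic50_mg_ml, mass_da) {
  ic50_mg_ml * 1e6 / mass_da
}

#' @export
coef.ic50_fit <- function(object, ...) object$coefficients

#' @export
residuals.ic50_fit <- function(object, ...) object$residuals

#' @export
fitted.ic50_fit <- function(object, ...) object$fitted

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else {
    if (is.data.frame(newdata)) newdata$conc else newdata
  }
  p <- object$coefficients
  .fourpl(conc, p[["bottom"]], p[["top"]], log10(p[["ic50"]]), p[["hill"]])
}

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  p <- x$coefficients
  cat(sprintf("4PL dose-response fit (%s)\n", x$method))
  cat(sprintf("  IC50 = %s %s, hill = %s, bottom = %s, top = %s\n",
              signif(p[["ic50"]], digits), x$unit,
              signif(p[["hill"]], digits), signif(p[["bottom"]], digits),
              signif(p[["top"]], digits)))
  if (!is.null(x$ic50_um)) {
    cat(sprintf("  IC50 = %s uM (converted)\n", signif(x$ic50_um, digits)))
  }
  cat(sprintf("  residual SE %s on %d points\n", signif(x$sigma, 3),
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.ic50_fit <- function(object, ...) {
  print(object)
  cat("residual quartiles:\n")
  print(signif(quantile(object$residuals), 3))
  invisible(object)
}

#' @export
plot.ic50_fit <- function(x, n_curve = 100, ...) {
  p <- x$coefficients
  plot(x$data$conc, x$data$resp, log = "x",
       xlab = paste0("concentration (", x$unit, ")"),
       ylab = "response (%)", ...)
  cc <- 10^seq(log10(min(x$data$conc)), log10(max(x$data$conc)),
               length.out = n_curve)
  lines(cc, predict(x, cc))
  points(p[["ic50"]], .fourpl(p[["ic50"]], p[["bottom"]], p[["top"]],
                              log10(p[["ic50"]]), p[["hill"]]), pch = 4)
  invisible(x)
}

#' Mean and standard deviation of replicate IC50 estimates
#'
#' @param values Numeric vector of at least two replicate IC50 estimates.
#' @return Named numeric vector `c(mean, sd)` (sample SD, n - 1
#'   denominator).
#' @export
summarize_ic50 <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("at least 2 replicate IC50 estimates required", call. = FALSE)
  }
  c(mean = mean(values), sd = sd(values))
}
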