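#' Abbott's control correction of a response proportion
#'
#' Rescales an observed response proportion by the response observed on
#' untreated control diet: \eqn{(p - c) / (1 - c)}, clipped below at 0.
#'
#' @param p observed response proportion(s), in \[0, 1\].
#' @param control control response proportion, in \[0, 1).
#' @return corrected proportion(s); a logical \code{clipped} attribute
#'   marks values that were negative before clipping.
#' @export
abbott_correct <- function(p, control) {
  if (any(control >= 1)) stop("control response of 1 leaves no signal")
  stopifnot(all(p >= 0), all(p <= 1), all(control >= 0))
  raw <- (p - control) / (1 - control)
  out <- pmax(0, raw)
  attr(out, "clipped") <- raw < 0
  out
}

#' Maximum-likelihood probit fit of a dose-response table
#'
#' Fits a binomial probit regression of response on log10 concentration
#' by iteratively reweighted least squares. If the table contains a
#' control row (concentration 0), all treated proportions are first
#' Abbott-corrected by the pooled control response. The EC50 is
#' \eqn{10^{-\alpha/\beta}} with a 95\% CI obtained by the delta method
#' on \eqn{\log_{10} EC_{50}}. Complete separation (no concentration with
#' a partial response) yields a non-converged fit whose EC50 and CI are
#' the interval estimate bracketed by the highest all-survive and lowest
#' all-respond concentrations.
#'
#' @param table data.frame with columns \code{concentration}, \code{n},
#'   \code{responded}; a row with concentration 0 is treated as the
#'   control.
#' @return object of class \code{probit_fit}: intercept, slope,
#'   slope_se, ec50, ci (lower, upper), log10_ec50, log10_ec50_se,
#'   loglik, converged, control_response, n_total.
#' @export
fit_probit <- function(table) {
  need <- c("concentration", "n", "responded")
  if (!all(need %in% names(table)))
    stop("dose-response table needs columns: ", paste(need, collapse = ", "))
  if (any(table$responded < 0 | table$responded > table$n))
    stop("responded must lie in [0, n]")
  ctrl <- table$concentration == 0
  control_response <- if (any(ctrl))
    sum(table$responded[ctrl]) / sum(table$n[ctrl]) else 0
  tr <- table[!ctrl, , drop = FALSE]
  if (length(unique(tr$concentration)) < 3L)
    stop("need at least 3 distinct positive concentrations")
  p_obs <- tr$responded / tr$n
  p_corr <- as.numeric(abbott_correct(p_obs, control_response))
  lc <- log10(tr$concentration)
  partial <- p_corr > 0 & p_corr < 1
  n_total <- sum(tr$n)
  if (!any(partial)) {
    lo <- suppressWarnings(max(tr$concentration[p_corr == 0]))
    hi <- suppressWarnings(min(tr$concentration[p_corr == 1]))
    if (!is.finite(lo)) lo <- min(tr$concentration)
    if (!is.finite(hi)) hi <- max(tr$concentration)
    out <- list(intercept = NA_real_, slope = NA_real_,
                slope_se = NA_real_,
                ec50 = sqrt(lo * hi), ci = c(lo, hi),
                log10_ec50 = log10(sqrt(lo * hi)),
                log10_ec50_se = NA_real_, loglik = NA_real_,
                converged = FALSE, control_response = control_response,
                n_total = n_total)
    class(out) <- "probit_fit"
    return(out)
  }
  fit <- suppressWarnings(
    glm(p_corr ~ lc, family = binomial(link = "probit"), weights = tr$n,
        control = list(maxit = 100L, epsilon = 1e-10)))
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  V <- vcov(fit)
  slope_se <- sqrt(V[2, 2])
  mu <- pmin(1 - 1e-12, pmax(1e-12, pnorm(a + b * lc)))
  loglik <- sum(tr$n * (p_corr * log(mu) + (1 - p_corr) * log(1 - mu)))
  converged <- fit$converged && b > 0
  log10_ec50 <- -a / b
  grad <- c(-1 / b, a / b^2)
  log10_se <- sqrt(drop(t(grad) %*% V %*% grad))
  ci <- 10^(log10_ec50 + c(-1, 1) * qnorm(0.975) * log10_se)
  out <- list(intercept = a, slope = b, slope_se = slope_se,
              ec50 = 10^log10_ec50, ci = ci, log10_ec50 = log10_ec50,
              log10_ec50_se = log10_se, loglik = loglik,
              converged = converged, control_response = control_response,
              n_total = n_total)
  class(out) <- "probit_fit"
  out
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("probit fit: EC50 = %.4g (95%% CI %.4g-%.4g), slope = %.3g +/- %.2g%s\n",
              x$ec50, x$ci[1], x$ci[2], x$slope, x$slope_se,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Predicted response proportion of a probit fit at given concentrations
#'
#' @param object a \code{probit_fit}.
#' @param conc concentrations (> 0).
#' @param ... unused.
#' @return predicted response proportions.
#' @export
predict.probit_fit <- function(object, conc, ...) {
  stopifnot(all(conc > 0))
  pnorm(object$intercept + object$slope * log10(conc))
}

#' Geometric dose series bracketing an anticipated EC50
#'
#' Standard bioassay design when the EC50 is approximately known: a
#' geometric dilution series centred on it. The default factor of 1.35
#' concentrates observations near the EC50, where they carry the most
#' information about it, rather than in the saturated tails.
#'
#' @param ec50 anticipated EC50 (> 0).
#' @param fold dilution factor between adjacent doses (> 1).
#' @param n_doses number of doses (even, default 6).
#' @return concentrations in ascending order.
#' @export
ec50_dose_series <- function(ec50, fold = 1.35, n_doses = 6L) {
  stopifnot(ec50 > 0, fold > 1, n_doses >= 2)
  ec50 * fold^(seq_len(n_doses) - (n_doses + 1) / 2)
}

#' Resistance ratio of two EC50s
#'
#' @param ec50_test EC50 of the tested strain or cross.
#' @param ec50_reference EC50 of the susceptible reference strain (> 0).
#' @return the quotient, reported to 3 significant figures.
#' @export
resistance_ratio <- function(ec50_test, ec50_reference) {
  if (ec50_reference <= 0) stop("reference EC50 must be > 0")
  signif(ec50_test / ec50_reference, 3)
}

#' Fit a multi-strain bioassay table and report EC50s and ratios
#'
#' @param table data.frame with columns strain, concentration, n,
#'   responded (control rows have concentration 0).
#' @param reference strain whose EC50 divides the others for the
#'   resistance ratio (default \code{"SS"}).
#' @return data.frame: strain, n, ec50, ci_lower, ci_upper, slope,
#'   slope_se, rr, converged.
#' @export
fit_probit_table <- function(table, reference = "SS") {
  stopifnot("strain" %in% names(table))
  strains <- unique(table$strain)
  fits <- lapply(strains, function(s)
    fit_probit(table[table$strain == s, , drop = FALSE]))
  names(fits) <- strains
  ref_ec50 <- if (reference %in% strains) fits[[reference]]$ec50 else NA
  out <- do.call(rbind, lapply(strains, function(s) {
    f <- fits[[s]]
    data.frame(strain = s, n = f$n_total, ec50 = f$ec50,
               ci_lower = f$ci[1], ci_upper = f$ci[2],
               slope = f$slope, slope_se = f$slope_se,
               rr = if (is.na(ref_ec50)) NA_real_
                    else resistance_ratio(f$ec50, ref_ec50),
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  attr(out, "fits") <- fits
  out
}
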