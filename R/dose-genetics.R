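#' Dominance of resistance at one concentration
#'
#' \eqn{h = (Z - X) / (Y - X)} where X, Y and Z are the survival
#' proportions of the susceptible strain, the resistant strain and their
#' F1 progeny at the same concentration. h = 0 is completely recessive,
#' h = 1 completely dominant. Values outside \[0, 1\] (possible with
#' sampling noise) are returned unclipped with an \code{out_of_range}
#' attribute.
#'
#' @param x,y,z survival proportions (susceptible, resistant, F1), each
#'   in \[0, 1\].
#' @return h, with attribute \code{out_of_range}.
#' @export
dominance_h <- function(x, y, z) {
  stopifnot(all(c(x, y, z) >= 0), all(c(x, y, z) <= 1))
  if (any(y == x)) stop("h is undefined when resistant and susceptible survival are equal")
  h <- (z - x) / (y - x)
  attr(h, "out_of_range") <- h < 0 | h > 1
  h
}

#' Dominance across a concentration series
#'
#' @param table data.frame with columns \code{concentration}, \code{x},
#'   \code{y}, \code{z}: survival of the susceptible strain, resistant
#'   strain and F1 at each concentration.
#' @return data.frame: concentration, h, out_of_range. Monotonicity of h
#'   in concentration is reported via the \code{decreasing} attribute,
#'   not enforced.
#' @export
dominance_curve <- function(table) {
  need <- c("concentration", "x", "y", "z")
  if (!all(need %in% names(table)))
    stop("dominance table needs columns: ", paste(need, collapse = ", "))
  h <- dominance_h(table$x, table$y, table$z)
  out <- data.frame(concentration = table$concentration,
                    h = as.numeric(h),
                    out_of_range = attr(h, "out_of_range"))
  out <- out[order(out$concentration), , drop = FALSE]
  attr(out, "decreasing") <- !is.unsorted(rev(out$h))
  out
}

#' Survival by genotype under a shared-slope probit model
#'
#' Helper for constructing dominance curves from strain parameters:
#' survival = \eqn{1 - \Phi(\beta(\log_{10} c - \log_{10} EC_{50}))}.
#'
#' @param slope probit slope.
#' @param ec50 strain EC50.
#' @param conc concentrations (> 0).
#' @return survival proportions.
#' @export
survival_from_probit <- function(slope, ec50, conc) {
  stopifnot(slope > 0, ec50 > 0, all(conc > 0))
  1 - pnorm(slope * (log10(conc) - log10(ec50)))
}

#' Expected mortality under a one-locus recessive resistance model
#'
#' At a concentration where resistance is completely recessive only RR
#' homozygotes survive, so expected mortality is one minus the Mendelian
#' RR fraction: 0.50 for the backcross of F1 to the resistant strain,
#' 0.75 for the F2 intercross, and 1.00 for F1 progeny (all
#' heterozygous).
#'
#' @param cross \code{"backcross"}, \code{"F2"} or \code{"F1"}.
#' @return expected mortality proportion.
#' @export
monogenic_expectation <- function(cross = c("backcross", "F2", "F1")) {
  cross <- match.arg(cross)
  switch(cross, backcross = 0.5, F2 = 0.75, F1 = 1.0)
}

## log-sum-exp over a vector of log probabilities
lse <- function(lp) {
  if (length(lp) == 0L) return(-Inf)
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' all tables no more probable than the observed one (with a relative
#' tolerance of 1e-7 for ties), working in log space so that p-values far
#' below double precision of the individual terms remain accurate. If a
#' row or column margin is zero the p-value is 1 by convention and
#' flagged.
#'
#' @param tab 2x2 matrix (or something coercible) of non-negative
#'   integer counts.
#' @return list: p (two-sided p-value), log10_p, odds_ratio (sample odds
#'   ratio ad/bc), degenerate (TRUE for a zero margin).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(p = 1, log10_p = 0, odds_ratio = or, degenerate = TRUE))
  x <- max(0, c1 - r2):min(r1, c1)
  lp <- dhyper(x, r1, r2, c1, log = TRUE)
  lobs <- dhyper(tab[1, 1], r1, r2, c1, log = TRUE)
  sel <- lp <= lobs + log(1 + 1e-7)
  lp_two <- lse(lp[sel])
  list(p = exp(lp_two), log10_p = lp_two / log(10),
       odds_ratio = or, degenerate = FALSE)
}

#' Test observed mortality against a Mendelian expectation
#'
#' Builds a 2x2 table of observed (responders, survivors) against the
#' expected counts (n * p rounded half-to-even) and applies
#' [fisher_exact()]; the exact binomial test of the observed count
#' against the expected proportion is always reported alongside, since
#' the construction of the contingency table from an expectation involves
#' a rounding convention.
#'
#' @param n larvae tested.
#' @param observed observed responders (0..n).
#' @param expected expected response proportion (0 < expected < 1).
#' @return list: fisher (from [fisher_exact()]), binomial_p, table,
#'   observed_prop, expected_prop.
#' @export
observed_vs_expected_test <- function(n, observed, expected) {
  stopifnot(observed >= 0, observed <= n, expected > 0, expected < 1)
  exp_resp <- round(n * expected)
  tab <- rbind(observed = c(observed, n - observed),
               expected = c(exp_resp, n - exp_resp))
  list(fisher = fisher_exact(tab),
       binomial_p = binom.test(observed, n, expected)$p.value,
       table = tab,
       observed_prop = observed / n,
       expected_prop = expected)
}
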