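#' Relative transcript abundance from qPCR cycle thresholds
#'
#' For each sample and target assay, \eqn{\Delta Ct = Ct_{target} -
#' Ct_{reference}} and the raw abundance is \eqn{2^{-\Delta Ct}}. Folds
#' are then normalized per assay to the calibrator group so that the
#' calibrator group's geometric mean fold is exactly 1 (the geometric
#' mean is the natural aggregator for log-scale Ct data; an
#' arithmetic-mean option is provided). Samples lacking a reference-gene
#' Ct are dropped with a warning.
#'
#' @param records data.frame with columns \code{sample}, \code{group},
#'   \code{assay}, \code{ct}.
#' @param calibrator calibrator group name (must be present).
#' @param reference_assay name of the reference-gene assay
#'   (default \code{"reference"}).
#' @param aggregate \code{"geometric"} (default) or \code{"arithmetic"}
#'   mean of the calibrator group's \eqn{2^{-\Delta Ct}}.
#' @return data.frame: sample, group, assay, dct, fold.
#' @export
rel_abundance <- function(records, calibrator,
                          reference_assay = "reference",
                          aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  need <- c("sample", "group", "assay", "ct")
  if (!all(need %in% names(records)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (!calibrator %in% records$group)
    stop("calibrator group '", calibrator, "' absent from the table")
  ref <- records[records$assay == reference_assay, c("sample", "ct")]
  if (nrow(ref) == 0L) stop("no reference-assay rows found")
  ref_ct <- setNames(ref$ct, ref$sample)
  tg <- records[records$assay != reference_assay, , drop = FALSE]
  has_ref <- tg$sample %in% names(ref_ct)
  if (any(!has_ref)) {
    warning(sum(!has_ref), " row(s) dropped: no reference Ct for sample(s) ",
            paste(unique(tg$sample[!has_ref]), collapse = ", "))
    tg <- tg[has_ref, , drop = FALSE]
  }
  tg$dct <- tg$ct - ref_ct[tg$sample]
  tg$raw <- 2^(-tg$dct)
  out <- lapply(unique(tg$assay), function(a) {
    sub <- tg[tg$assay == a, , drop = FALSE]
    cal <- sub$raw[sub$group == calibrator]
    if (length(cal) == 0L)
      stop("calibrator group has no rows for assay ", a)
    denom <- if (aggregate == "geometric") exp(mean(log(cal))) else mean(cal)
    data.frame(sample = sub$sample, group = sub$group, assay = a,
               dct = sub$dct, fold = sub$raw / denom,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group means and standard errors of fold values
#'
#' @param folds data.frame from [rel_abundance()].
#' @return data.frame: group, assay, n, mean, sem.
#' @export
fold_summary <- function(folds) {
  agg <- aggregate(folds$fold,
                   by = list(group = folds$group, assay = folds$assay),
                   FUN = function(v) c(length(v), mean(v),
                                       stats::sd(v) / sqrt(length(v))))
  data.frame(group = agg$group, assay = agg$assay,
             n = as.integer(agg$x[, 1]), mean = agg$x[, 2],
             sem = agg$x[, 3], stringsAsFactors = FALSE)
}

#' Mutant transcript fraction from total and wild-type fold values
#'
#' In a strain where a transposon-disrupted allele produces transcripts
#' that the wild-type-specific assay cannot amplify, the mutant fraction
#' is (total - wildtype) / total. A wild-type fold exceeding the total
#' (possible with assay noise) is flagged and the fraction reported as 0.
#'
#' @param total total-transcript fold value (> 0).
#' @param wildtype wild-type-transcript fold value (>= 0).
#' @return fraction in \[0, 1\], with a \code{flagged} attribute when
#'   wildtype exceeded total.
#' @export
mutant_fraction <- function(total, wildtype) {
  stopifnot(total > 0, wildtype >= 0)
  flagged <- wildtype > total
  out <- ifelse(flagged, 0, (total - wildtype) / total)
  attr(out, "flagged") <- flagged
  out
}

#' Two-sample t statistic from printed means and standard errors
#'
#' \eqn{t = |m_2 - m_1| / \sqrt{SEM_1^2 + SEM_2^2}} with
#' \eqn{df = n_1 + n_2 - 2} (unpooled standard error with additive
#' degrees of freedom — the combination that reproduces published
#' summary-statistic t tests); the Welch–Satterthwaite df is reported as
#' an alternative.
#'
#' @param mean1,sem1,n1 first group: mean, standard error of the mean,
#'   sample size (n >= 2).
#' @param mean2,sem2,n2 second group.
#' @return list: t, df, welch_df, p (two-sided, on df).
#' @export
summary_t <- function(mean1, sem1, n1, mean2, sem2, n2) {
  stopifnot(sem1 >= 0, sem2 >= 0, n1 >= 2, n2 >= 2)
  if (sem1 == 0 && sem2 == 0) {
    if (mean1 == mean2)
      return(list(t = 0, df = n1 + n2 - 2, welch_df = NA_real_, p = 1))
    stop("both SEMs are zero with unequal means: t is infinite")
  }
  se <- sqrt(sem1^2 + sem2^2)
  t <- abs(mean2 - mean1) / se
  df <- n1 + n2 - 2
  welch_df <- se^4 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  list(t = t, df = df, welch_df = welch_df,
       p = 2 * stats::pt(-t, df))
}
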