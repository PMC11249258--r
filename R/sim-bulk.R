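#' Phenotype progeny at two doses and form phenotype-selected bulks
#'
#' Progeny are split at random into two disjoint dose arms. Each individual
#' responds (dies or fails to advance) with the probit probability its
#' causal genotype implies at its arm's concentration. The resistant bulk
#' is drawn from the \emph{non}-responders on the high dose; the
#' susceptible bulk from the responders on the low dose. Requested bulk
#' sizes are truncated to availability with a warning.
#'
#' @param pop a \code{cross_pop} from [simulate_cross()].
#' @param model a [phenotype_model()].
#' @param high_dose,low_dose concentrations for the two arms (> 0).
#' @param bulk_sizes integer pair: target sizes of the (resistant,
#'   susceptible) bulks.
#' @param seed integer seed.
#' @param arm_sizes integer pair: individuals assigned to the (high, low)
#'   dose arms; default splits the progeny in half.
#'
#' @return list with elements \code{resistant} and \code{susceptible}
#'   (each a \code{cross_pop} subset) plus an \code{assignment}
#'   data.frame recording arm, response and bulk membership per individual.
#' @export
phenotype_and_bulk <- function(pop, model, high_dose, low_dose, bulk_sizes,
                               seed, arm_sizes = NULL) {
  stopifnot(inherits(pop, "cross_pop"), inherits(model, "phenotype_model"),
            high_dose > 0, low_dose > 0, length(bulk_sizes) == 2L)
  n <- length(pop$id)
  if (is.null(arm_sizes)) {
    arm_sizes <- c(floor(n / 2), n - floor(n / 2))
  }
  if (sum(arm_sizes) > n) stop("arm_sizes exceed available progeny")
  withr::with_seed(as.integer(seed), {
    ord <- sample.int(n)
    high_idx <- ord[seq_len(arm_sizes[1])]
    low_idx <- ord[arm_sizes[1] + seq_len(arm_sizes[2])]
    p_high <- response_prob(model, high_dose)[causal_genotype(pop)[high_idx]]
    p_low <- response_prob(model, low_dose)[causal_genotype(pop)[low_idx]]
    resp_high <- runif(length(high_idx)) < p_high
    resp_low <- runif(length(low_idx)) < p_low
    surv_high <- high_idx[!resp_high]
    dead_low <- low_idx[resp_low]
    if (length(surv_high) == 0L)
      stop("no survivors at the high dose (", high_dose,
           "): resistant bulk would be empty")
    if (length(dead_low) == 0L)
      stop("no responders at the low dose (", low_dose,
           "): susceptible bulk would be empty")
    sizes <- bulk_sizes
    if (sizes[1] > length(surv_high)) {
      warning("resistant bulk truncated to ", length(surv_high),
              " available survivors")
      sizes[1] <- length(surv_high)
    }
    if (sizes[2] > length(dead_low)) {
      warning("susceptible bulk truncated to ", length(dead_low),
              " available responders")
      sizes[2] <- length(dead_low)
    }
    r_idx <- sort(sample(surv_high, sizes[1]))
    s_idx <- sort(sample(dead_low, sizes[2]))
    assignment <- data.frame(
      id = pop$id,
      arm = NA_character_, responded = NA,
      bulk = NA_character_, stringsAsFactors = FALSE)
    assignment$arm[high_idx] <- "high"; assignment$arm[low_idx] <- "low"
    assignment$responded[high_idx] <- resp_high
    assignment$responded[low_idx] <- resp_low
    assignment$bulk[r_idx] <- "resistant"
    assignment$bulk[s_idx] <- "susceptible"
    list(resistant = subset_pop(pop, r_idx),
         susceptible = subset_pop(pop, s_idx),
         assignment = assignment)
  })
}

#' Sample pooled sequencing allele counts over a bulk
#'
#' Emulates pooled DNA sequencing of a bulk: per marker the read depth is
#' Poisson(\code{mean_depth}) and the number of R-origin reads is binomial
#' with the bulk's true R-allele frequency. No base-call errors are
#' modelled; mismatch tolerance lives in the junction-read matcher, and
#' the BSA statistic only consumes counts.
#'
#' @param bulk a \code{cross_pop} (typically one bulk from
#'   [phenotype_and_bulk()]).
#' @param mean_depth mean read depth per marker (>= 0).
#' @param seed integer seed.
#' @param bulk_label label recorded in the output
#'   (\code{"resistant"}/\code{"susceptible"}).
#'
#' @return data.frame: chrom, pos, bulk, r_count, s_count, depth.
#' @export
sample_pool_counts <- function(bulk, mean_depth, seed,
                               bulk_label = "resistant") {
  stopifnot(inherits(bulk, "cross_pop"), mean_depth >= 0)
  truth <- marker_rfreq(bulk)
  withr::with_seed(as.integer(seed), {
    depth <- rpois(nrow(truth), mean_depth)
    r_count <- rbinom(nrow(truth), depth, truth$freq_r)
  })
  data.frame(chrom = truth$chrom, pos = truth$pos, bulk = bulk_label,
             r_count = r_count, s_count = depth - r_count, depth = depth,
             stringsAsFactors = FALSE)
}

#' Simulate a dose-response bioassay table from probit parameters
#'
#' Draws binomial responder counts at each concentration from
#' \eqn{\Phi(\beta(\log_{10} c - \log_{10} EC_{50}))}.
#'
#' @param doses concentrations (> 0).
#' @param n larvae tested per dose (recycled).
#' @param slope probit slope (per log10 concentration).
#' @param ec50 true EC50.
#' @param seed integer seed.
#' @param strain strain label for the output table.
#' @return data.frame: strain, concentration, n, responded.
#' @export
simulate_bioassay <- function(doses, n, slope, ec50, seed, strain = "sim") {
  stopifnot(all(doses > 0), slope > 0, ec50 > 0)
  n <- rep_len(n, length(doses))
  p <- pnorm(slope * (log10(doses) - log10(ec50)))
  responded <- withr::with_seed(as.integer(seed),
                                rbinom(length(doses), n, p))
  data.frame(strain = strain, concentration = doses, n = n,
             responded = responded, stringsAsFactors = FALSE)
}

#' Simulate qPCR cycle-threshold tables with known fold changes
#'
#' For each group and assay, the target Ct of a sample is the reference
#' gene Ct minus log2 of the group's true fold value, plus Gaussian noise;
#' the reference assay Ct is emitted unchanged. Recovering folds with
#' [rel_abundance()] at zero noise therefore inverts the construction
#' exactly.
#'
#' @param fold_design data.frame with columns \code{group}, \code{assay}
#'   and \code{fold} (true fold change of each group/assay relative to the
#'   calibrator group, > 0). The calibrator group should have fold 1.
#' @param ref_ct reference-gene Ct value (cycles).
#' @param noise_sd standard deviation of the Ct noise (>= 0).
#' @param n_per_group samples per group (>= 1).
#' @param seed integer seed.
#' @param reference_assay name of the reference assay row emitted per
#'   sample (default \code{"reference"}).
#'
#' @return data.frame: sample, group, assay, ct — the input format of
#'   [rel_abundance()].
#' @export
simulate_ct <- function(fold_design, ref_ct = 20, noise_sd = 0.2,
                        n_per_group = 4L, seed = 1L,
                        reference_assay = "reference") {
  stopifnot(is.data.frame(fold_design),
            all(c("group", "assay", "fold") %in% names(fold_design)),
            all(fold_design$fold > 0), n_per_group >= 1, noise_sd >= 0)
  groups <- unique(fold_design$group)
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (g in groups) {
      des <- fold_design[fold_design$group == g, , drop = FALSE]
      for (i in seq_len(n_per_group)) {
        smp <- paste0(g, "_", i)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, group = g, assay = reference_assay, ct = ref_ct)
        for (j in seq_len(nrow(des))) {
          ct <- ref_ct - log2(des$fold[j]) + rnorm(1L, 0, noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = smp, group = g, assay = des$assay[j], ct = ct)
        }
      }
    }
    do.call(rbind, rows)
  })
}
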