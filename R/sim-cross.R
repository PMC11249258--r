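#' Define the genome coordinate frame for a simulated cross
#'
#' A genome specification carries the chromosome lengths, the informative
#' marker positions (SNPs fixed for different alleles in the two parental
#' strains), the position of the single causal resistance locus, and a
#' constant recombination rate. Physical distance is converted to genetic
#' distance at \code{rate_cM_Mb} centimorgans per megabase and recombination
#' fractions follow Haldane's map function (no interference).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param markers named list (same names) of strictly increasing 1-based
#'   marker positions per chromosome. Every chromosome must carry at least
#'   one marker.
#' @param causal_chrom,causal_pos chromosome name and 1-based position of the
#'   causal locus; the position must lie within its chromosome.
#' @param rate_cM_Mb recombination rate, cM per Mb (> 0). Default 3, a
#'   typical lepidopteran genome-wide average.
#'
#' @return an object of class \code{genome_spec}.
#' @seealso [simulate_cross()]
#' @export
genome_spec <- function(chrom_lengths, markers, causal_chrom, causal_pos,
                        rate_cM_Mb = 3) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  if (!setequal(names(markers), names(chrom_lengths)))
    stop("markers must be a list named by chromosome")
  for (ch in names(chrom_lengths)) {
    pos <- markers[[ch]]
    if (length(pos) == 0L)
      stop("chromosome ", ch, " has zero markers")
    if (any(diff(pos) <= 0))
      stop("marker positions on ", ch, " must be strictly increasing")
    if (any(pos < 1) || any(pos > chrom_lengths[[ch]]))
      stop("marker positions on ", ch, " fall outside the chromosome")
  }
  if (!causal_chrom %in% names(chrom_lengths))
    stop("causal_chrom not among chromosomes")
  if (causal_pos < 1 || causal_pos > chrom_lengths[[causal_chrom]])
    stop("causal position outside its chromosome")
  if (rate_cM_Mb <= 0) stop("rate_cM_Mb must be > 0")
  structure(
    list(chrom_lengths = chrom_lengths,
         markers = markers[names(chrom_lengths)],
         causal_chrom = causal_chrom,
         causal_pos = as.numeric(causal_pos),
         rate_cM_Mb = rate_cM_Mb),
    class = "genome_spec")
}

#' Describe a cross producing the progeny to simulate
#'
#' @param type one of \code{"F1"}, \code{"F2"}, \code{"backcross"}
#'   (F1 x resistant homozygote) or \code{"intercross"} (advanced
#'   intercross maintained by random pan-mixis).
#' @param n_progeny number of progeny to generate (> 0).
#' @param generations for \code{"intercross"}: the generation index of the
#'   progeny (>= 2; e.g. 7 for an F7 screen).
#' @param n_pairs breeding pairs maintained per intermediate intercross
#'   generation (default 50).
#'
#' @return an object of class \code{cross_design}.
#' @export
cross_design <- function(type = c("F1", "F2", "backcross", "intercross"),
                         n_progeny, generations = NULL, n_pairs = 50L) {
  type <- match.arg(type)
  if (n_progeny <= 0) stop("n_progeny must be > 0")
  if (type == "intercross") {
    if (is.null(generations) || generations < 2)
      stop("intercross requires generations >= 2")
  }
  structure(list(type = type, n_progeny = as.integer(n_progeny),
                 generations = if (is.null(generations)) NULL
                               else as.integer(generations),
                 n_pairs = as.integer(n_pairs)),
            class = "cross_design")
}

#' Probit phenotype model for the three causal genotypes
#'
#' The probability that an individual "responds" (dies or fails to reach
#' third instar at the scoring day) at concentration \eqn{c} is
#' \eqn{\Phi(\alpha_g + \beta_g \log_{10} c)} for its causal genotype
#' \eqn{g \in \{SS, RS, RR\}}. Genotype EC50s (\eqn{10^{-\alpha/\beta}})
#' must be ordered RR >= RS >= SS and all slopes must be positive.
#'
#' @param intercepts,slopes numeric vectors named \code{SS}, \code{RS},
#'   \code{RR}: probit intercepts and slopes (probit units per log10
#'   concentration).
#'
#' @return an object of class \code{phenotype_model} with an
#'   \code{ec50} element giving the implied genotype EC50s.
#' @export
phenotype_model <- function(intercepts, slopes) {
  gt <- c("SS", "RS", "RR")
  if (!all(gt %in% names(intercepts)) || !all(gt %in% names(slopes)))
    stop("intercepts and slopes must be named SS, RS, RR")
  intercepts <- intercepts[gt]; slopes <- slopes[gt]
  if (any(slopes <= 0)) stop("slopes must be > 0")
  ec50 <- 10^(-intercepts / slopes)
  if (!(ec50[["RR"]] >= ec50[["RS"]] && ec50[["RS"]] >= ec50[["SS"]]))
    stop("genotype EC50s must be ordered RR >= RS >= SS")
  structure(list(intercepts = intercepts, slopes = slopes, ec50 = ec50),
            class = "phenotype_model")
}

#' Convenience constructor from genotype EC50s and a shared slope
#'
#' @param ec50_ss,ec50_rs,ec50_rr genotype EC50s (concentration units).
#' @param slope shared probit slope (> 0).
#' @return a [phenotype_model()].
#' @export
phenotype_model_from_ec50 <- function(ec50_ss, ec50_rs, ec50_rr, slope) {
  phenotype_model(
    intercepts = c(SS = -slope * log10(ec50_ss),
                   RS = -slope * log10(ec50_rs),
                   RR = -slope * log10(ec50_rr)),
    slopes = c(SS = slope, RS = slope, RR = slope))
}

#' Probability of responding for each causal genotype at a concentration
#'
#' @param model a [phenotype_model()].
#' @param conc concentration (> 0).
#' @return named numeric vector (SS, RS, RR) of response probabilities.
#' @export
response_prob <- function(model, conc) {
  stopifnot(inherits(model, "phenotype_model"), conc > 0)
  pnorm(model$intercepts + model$slopes * log10(conc))
}

## recombination fractions between adjacent loci, Haldane map function
haldane_r <- function(pos_bp, rate_cM_Mb) {
  if (length(pos_bp) < 2L) return(numeric(0))
  d_morgan <- diff(pos_bp) / 1e6 * rate_cM_Mb / 100
  0.5 * (1 - exp(-2 * d_morgan))
}

## Augmented locus table: markers plus (if absent) the causal position,
## so the causal allele is transmitted through the same meioses.
augmented_loci <- function(genome) {
  out <- lapply(names(genome$chrom_lengths), function(ch) {
    pos <- genome$markers[[ch]]
    is_marker <- rep(TRUE, length(pos))
    if (ch == genome$causal_chrom && !genome$causal_pos %in% pos) {
      pos <- c(pos, genome$causal_pos)
      is_marker <- c(is_marker, FALSE)
      o <- order(pos)
      pos <- pos[o]; is_marker <- is_marker[o]
    }
    data.frame(chrom = ch, pos = pos, is_marker = is_marker,
               is_causal = (ch == genome$causal_chrom &
                            pos == genome$causal_pos))
  })
  do.call(rbind, out)
}

## Draw G gametes from parents indexed by parent_idx.
## hap1/hap2: n_parents x n_loci 0/1 matrices (1 = R-origin).
## loci: augmented locus table; rate: cM/Mb. Returns G x n_loci matrix.
##
## Under Haldane's map function crossovers form a Poisson process along
## the genetic map (no interference), so each meiosis draws a Poisson
## number of crossover positions uniform in map distance; the haplotype
## transmitted at a locus follows the parity of crossovers before it.
## This reproduces the pairwise recombination fraction
## r = (1 - exp(-2d))/2 for loci d Morgans apart.
draw_gametes <- function(hap1, hap2, parent_idx, loci, rate_cM_Mb) {
  G <- length(parent_idx)
  out <- matrix(0L, G, nrow(loci))
  for (ch in unique(loci$chrom)) {
    cols <- which(loci$chrom == ch)
    cm <- loci$pos[cols] / 1e6 * rate_cM_Mb / 100  # Morgans
    span <- cm[length(cm)] - cm[1]
    n_xo <- rpois(G, span)
    start <- sample.int(2L, G, replace = TRUE) - 1L
    for (j in seq_len(G)) {
      parity <- if (n_xo[j] > 0L) {
        xo <- sort(runif(n_xo[j], cm[1], cm[length(cm)]))
        (start[j] + findInterval(cm, xo)) %% 2L
      } else rep.int(start[j], length(cols))
      p <- parent_idx[j]
      h1 <- hap1[p, cols]; h2 <- hap2[p, cols]
      out[j, cols] <- h1 + (h2 - h1) * parity
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Simulate progeny of a cross between a resistant and a susceptible strain
#'
#' The resistant parent is homozygous for the R-origin allele at every
#' marker and at the causal locus; the susceptible parent is homozygous
#' S-origin. Meioses place crossovers between adjacent loci with Haldane
#' recombination fractions derived from the genome's cM/Mb rate; there is
#' no crossover interference. The causal locus is transmitted through the
#' same meioses as the markers, so causal genotype and flanking-marker
#' genotypes are consistent by construction.
#'
#' @param genome a [genome_spec()].
#' @param design a [cross_design()].
#' @param seed integer seed; identical seeds reproduce identical progeny.
#'
#' @return an object of class \code{cross_pop} representing the progeny
#'   collection: marker coordinates (\code{$map}), two haplotype matrices
#'   (\code{$hap1}, \code{$hap2}; individuals x markers; 1 = R-origin
#'   allele), per-individual causal allele counts (\code{$causal_dose},
#'   0/1/2 copies of R) and ids.
#' @export
simulate_cross <- function(genome, design, seed) {
  stopifnot(inherits(genome, "genome_spec"), inherits(design, "cross_design"))
  loci <- augmented_loci(genome)
  n_loci <- nrow(loci)
  n <- design$n_progeny
  withr::with_seed(as.integer(seed), {
    f1_h1 <- matrix(1L, 1L, n_loci)  # R-origin haplotype
    f1_h2 <- matrix(0L, 1L, n_loci)  # S-origin haplotype
    if (design$type == "F1") {
      hap1 <- matrix(1L, n, n_loci); hap2 <- matrix(0L, n, n_loci)
    } else if (design$type == "F2") {
      hap1 <- draw_gametes(f1_h1, f1_h2, rep(1L, n), loci, genome$rate_cM_Mb)
      hap2 <- draw_gametes(f1_h1, f1_h2, rep(1L, n), loci, genome$rate_cM_Mb)
    } else if (design$type == "backcross") {
      hap1 <- draw_gametes(f1_h1, f1_h2, rep(1L, n), loci, genome$rate_cM_Mb)
      hap2 <- matrix(1L, n, n_loci)  # resistant parent contributes R
    } else { # advanced intercross
      np <- design$n_pairs
      pop1 <- matrix(1L, 2L * np, n_loci)
      pop2 <- matrix(0L, 2L * np, n_loci)
      rounds <- design$generations - 1L
      for (g in seq_len(rounds)) {
        last <- (g == rounds)
        n_out <- if (last) n else 2L * np
        perm <- sample.int(nrow(pop1))
        mothers <- perm[seq_len(np)]
        fathers <- perm[np + seq_len(np)]
        pair <- sample.int(np, n_out, replace = TRUE)
        h1 <- draw_gametes(pop1, pop2, mothers[pair], loci, genome$rate_cM_Mb)
        h2 <- draw_gametes(pop1, pop2, fathers[pair], loci, genome$rate_cM_Mb)
        pop1 <- h1; pop2 <- h2
      }
      hap1 <- pop1; hap2 <- pop2
    }
    mk <- loci$is_marker
    causal_dose <- hap1[, loci$is_causal] + hap2[, loci$is_causal]
    structure(
      list(map = loci[mk, c("chrom", "pos")],
           hap1 = hap1[, mk, drop = FALSE],
           hap2 = hap2[, mk, drop = FALSE],
           causal_dose = as.integer(causal_dose),
           id = sprintf("ind%05d", seq_len(n)),
           genome = genome, design = design, seed = as.integer(seed)),
      class = "cross_pop")
  })
}

#' @export
print.cross_pop <- function(x, ...) {
  cat("<cross_pop> ", x$design$type, " progeny: n = ", length(x$id),
      ", markers = ", nrow(x$map), "\n", sep = "")
  cat("causal genotype counts:\n")
  print(table(causal_genotype(x)))
  invisible(x)
}

#' Causal genotype labels of simulated progeny
#'
#' @param pop a \code{cross_pop}.
#' @return character vector: \code{"SS"}, \code{"RS"} or \code{"RR"}.
#' @export
causal_genotype <- function(pop) {
  stopifnot(inherits(pop, "cross_pop"))
  c("SS", "RS", "RR")[pop$causal_dose + 1L]
}

#' Per-marker R-origin allele frequency in a progeny set
#'
#' @param pop a \code{cross_pop}.
#' @param subset optional integer index of individuals.
#' @return data.frame chrom, pos, freq_r.
#' @export
marker_rfreq <- function(pop, subset = NULL) {
  stopifnot(inherits(pop, "cross_pop"))
  i <- if (is.null(subset)) seq_along(pop$id) else subset
  f <- (colMeans(pop$hap1[i, , drop = FALSE]) +
        colMeans(pop$hap2[i, , drop = FALSE])) / 2
  data.frame(chrom = pop$map$chrom, pos = pop$map$pos, freq_r = f)
}

## internal: subset a cross_pop, keeping truth
subset_pop <- function(pop, idx) {
  out <- pop
  out$hap1 <- pop$hap1[idx, , drop = FALSE]
  out$hap2 <- pop$hap2[idx, , drop = FALSE]
  out$causal_dose <- pop$causal_dose[idx]
  out$id <- pop$id[idx]
  out
}
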