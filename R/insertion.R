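#' Build junction reference constructs for a transposon insertion allele
#'
#' An LTR-retrotransposon insertion creates a target site duplication
#' (TSD): the last bases of the upstream flank are repeated immediately
#' after the element. Writing the wild-type locus as \code{L | R} with the
#' TSD forming the tail of \code{L}, the inserted allele is
#' \code{L | element | TSD | R}. Three detection constructs are assembled,
#' each \code{2 * flank} bp with the junction at offset \code{flank}:
#' \itemize{
#'   \item wild-type: last \code{flank} bp of \code{L} + first
#'     \code{flank} bp of \code{R};
#'   \item upstream insertion: last \code{flank} bp of \code{L} + first
#'     \code{flank} bp of the element;
#'   \item downstream insertion: last \code{flank} bp of the element +
#'     first \code{flank} bp of \code{TSD + R}.
#' }
#'
#' @param locus wild-type locus sequence (character or
#'   [Biostrings::DNAString]).
#' @param insertion_point 1-based position of the last base of \code{L}
#'   (the final TSD base); the element is inserted immediately after it.
#' @param element element sequence (>= \code{flank} bp).
#' @param tsd target site duplication sequence; must match the locus
#'   immediately upstream of the insertion point.
#' @param flank flank length per side (default 300, giving 600-bp
#'   constructs).
#'
#' @return object of class \code{junction_refs}: a
#'   [Biostrings::DNAStringSet] \code{$constructs} named
#'   \code{wildtype}, \code{upstream}, \code{downstream}, plus
#'   \code{$junction_offset} (= \code{flank}) and \code{$tsd}.
#' @export
build_junction_refs <- function(locus, insertion_point, element, tsd,
                                flank = 300L) {
  locus <- Biostrings::DNAString(as.character(locus))
  element <- Biostrings::DNAString(as.character(element))
  tsd <- toupper(as.character(tsd))
  p <- as.integer(insertion_point)
  flank <- as.integer(flank)
  if (p < flank)
    stop("flank (", flank, ") overruns the locus 5' end: insertion point ", p)
  if (length(locus) - p < flank)
    stop("flank (", flank, ") overruns the locus 3' end: insertion point ",
         p, " of ", length(locus))
  if (length(element) < flank)
    stop("element (", length(element),
         " bp) shorter than the flank (", flank, " bp)")
  if (nchar(tsd) >= 1) {
    up_tail <- as.character(Biostrings::subseq(locus, p - nchar(tsd) + 1L, p))
    if (up_tail != tsd)
      stop("locus does not end with the TSD (", tsd,
           ") at the insertion point: found ", up_tail)
  }
  left <- Biostrings::subseq(locus, p - flank + 1L, p)
  right <- Biostrings::subseq(locus, p + 1L, p + flank)
  tsd_right <- Biostrings::DNAString(paste0(tsd, as.character(right)))
  constructs <- Biostrings::DNAStringSet(c(
    wildtype = paste0(as.character(left), as.character(right)),
    upstream = paste0(as.character(left),
                      as.character(Biostrings::subseq(element, 1L, flank))),
    downstream = paste0(
      as.character(Biostrings::subseq(element,
                                      length(element) - flank + 1L,
                                      length(element))),
      as.character(Biostrings::subseq(tsd_right, 1L, flank)))))
  structure(list(constructs = constructs, junction_offset = flank,
                 tsd = tsd, flank = flank),
            class = "junction_refs")
}

#' Count reads spanning each junction construct
#'
#' A read supports a construct when it aligns ungapped (at most
#' \code{max_mismatch} mismatches, either strand) at a position straddling
#' the junction with at least \code{min_overlap} bases on each side. Each
#' read is counted at most once per construct. The default
#' \code{min_overlap} of 20 bp exceeds typical TSD lengths, so a read can
#' never support both the wild-type and an insertion junction.
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of reads.
#' @param refs a [build_junction_refs()] result.
#' @param min_overlap minimum bases on each side of the junction (>= 1).
#' @param max_mismatch mismatches tolerated in an ungapped alignment.
#'
#' @return object of class \code{read_support}: named integer vector with
#'   elements \code{wildtype}, \code{upstream}, \code{downstream}.
#' @export
count_junction_support <- function(reads, refs, min_overlap = 20L,
                                   max_mismatch = 2L) {
  stopifnot(inherits(refs, "junction_refs"), min_overlap >= 1)
  if (any(Biostrings::width(refs$constructs) == 0L))
    stop("empty reference construct")
  reads <- Biostrings::DNAStringSet(reads)
  jx <- refs$junction_offset
  support <- setNames(integer(3L), names(refs$constructs))
  if (length(reads) == 0L) return(structure(support, class = "read_support"))
  rc <- Biostrings::reverseComplement(reads)
  for (k in seq_along(refs$constructs)) {
    construct <- refs$constructs[[k]]
    hit <- logical(length(reads))
    for (i in seq_along(reads)) {
      for (rd in list(reads[[i]], rc[[i]])) {
        if (length(rd) > length(construct)) next
        m <- Biostrings::matchPattern(rd, construct,
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        s <- Biostrings::start(m); e <- Biostrings::end(m)
        if (any(jx - s + 1L >= min_overlap & e - jx >= min_overlap)) {
          hit[i] <- TRUE
          break
        }
      }
    }
    support[k] <- sum(hit)
  }
  structure(support, class = "read_support")
}

#' @export
print.read_support <- function(x, ...) {
  cat("junction support: wildtype =", x[["wildtype"]],
      " upstream =", x[["upstream"]],
      " downstream =", x[["downstream"]], "\n")
  invisible(x)
}

#' Call insertion status and genotype for one sample
#'
#' A sample is \emph{positive} when either insertion junction is covered
#' by at least \code{min_reads} spanning reads (the "more than 3 reads"
#' rule with the default of 4). Genotype classes refine the
#' positive/negative status using the wild-type junction: a positive
#' sample with zero wild-type support is called homozygous for the
#' insertion; positive with wild-type support at threshold is
#' heterozygous; negative with wild-type support at threshold is
#' wild-type; anything else is indeterminate.
#'
#' @param support a \code{read_support} from [count_junction_support()].
#' @param min_reads minimum spanning reads for a junction to count as
#'   covered (default 4, i.e. strictly more than 3).
#' @param sample_id sample identifier carried into the call.
#'
#' @return data.frame (class \code{insertion_call}): sample, wildtype /
#'   upstream / downstream read support, status, genotype.
#' @export
call_sample <- function(support, min_reads = 4L, sample_id = "sample") {
  stopifnot(inherits(support, "read_support"))
  ins_pos <- max(support[["upstream"]], support[["downstream"]]) >= min_reads
  wt_pos <- support[["wildtype"]] >= min_reads
  status <- if (ins_pos) "positive" else "negative"
  genotype <- if (ins_pos && support[["wildtype"]] == 0L) {
    "homozygous-insertion"
  } else if (ins_pos && wt_pos) {
    "heterozygous"
  } else if (!ins_pos && wt_pos) {
    "wild-type"
  } else "indeterminate"
  out <- data.frame(sample = sample_id,
                    wildtype = support[["wildtype"]],
                    upstream = support[["upstream"]],
                    downstream = support[["downstream"]],
                    status = status, genotype = genotype,
                    stringsAsFactors = FALSE)
  class(out) <- c("insertion_call", class(out))
  out
}

#' Summarize insertion calls across a cohort
#'
#' @param calls a data.frame of row-bound [call_sample()] results.
#' @return list with \code{$by_status} and \code{$by_genotype} count
#'   tables and the per-sample table \code{$calls}.
#' @export
screen_cohort <- function(calls) {
  stopifnot(is.data.frame(calls), nrow(calls) >= 1)
  if (anyDuplicated(calls$sample))
    stop("duplicate sample ids: ",
         paste(unique(calls$sample[duplicated(calls$sample)]),
               collapse = ", "))
  list(by_status = table(factor(calls$status,
                                levels = c("positive", "negative"))),
       by_genotype = table(factor(calls$genotype,
                                  levels = c("homozygous-insertion",
                                             "heterozygous", "wild-type",
                                             "indeterminate"))),
       calls = as.data.frame(calls))
}

#' Allele frequency of the insertion in a screened cohort
#'
#' @param n_hom,n_het numbers of homozygous and heterozygous carriers.
#' @param n_individuals individuals screened (>= 1).
#' @return allele frequency (2 * hom + het) / (2 * individuals).
#' @export
allele_frequency <- function(n_hom, n_het, n_individuals) {
  stopifnot(n_individuals >= 1, n_hom >= 0, n_het >= 0,
            n_hom + n_het <= n_individuals)
  (2 * n_hom + n_het) / (2 * n_individuals)
}

#' Probability that a founding sample carried at least one allele copy
#'
#' For a diploid allele at frequency \eqn{q}, a sample of \eqn{n} founders
#' carries \eqn{2n} allele draws, so the probability of at least one copy
#' is \eqn{1 - (1 - q)^{2n}}.
#'
#' @param frequency allele frequency in the source population (0..1).
#' @param n_founders founding individuals (>= 1).
#' @return probability in \[0, 1\].
#' @export
founder_probability <- function(frequency, n_founders) {
  stopifnot(frequency >= 0, frequency <= 1, n_founders >= 1)
  1 - (1 - frequency)^(2 * n_founders)
}
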