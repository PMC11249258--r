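#' Simulate error-free short reads over junction constructs
#'
#' Generates single-end reads drawn uniformly from the constructs carried
#' by a sample's alleles: wild-type samples read from the wild-type
#' construct only; homozygous-insertion samples from the two insertion
#' constructs; heterozygotes from all three, with half the coverage per
#' allele. Read starts are uniform over the valid start positions and the
#' read count per construct is Poisson with mean
#' \code{coverage * (L - read_length + 1) / read_length} (halved per
#' allele for heterozygotes), so per-base coverage at interior positions
#' — including the junction — is the nominal fold coverage, and the
#' expected number of reads straddling a junction with
#' \code{min_overlap} bases on each side is
#' \code{coverage * (read_length - 2 * min_overlap + 1) / read_length}.
#'
#' @param genotype \code{"wild-type"}, \code{"heterozygous"} or
#'   \code{"homozygous-insertion"}.
#' @param refs a [build_junction_refs()] result.
#' @param coverage fold coverage (>= 0).
#' @param read_length read length in bp (< construct length).
#' @param seed integer seed.
#'
#' @return a [Biostrings::DNAStringSet] of reads (possibly empty).
#' @export
simulate_junction_reads <- function(genotype = c("wild-type",
                                                 "heterozygous",
                                                 "homozygous-insertion"),
                                    refs, coverage, read_length, seed) {
  genotype <- match.arg(genotype)
  stopifnot(inherits(refs, "junction_refs"))
  if (coverage < 0) stop("coverage must be >= 0")
  widths <- Biostrings::width(refs$constructs)
  if (read_length >= min(widths))
    stop("read_length must be shorter than the constructs")
  cov_per <- switch(genotype,
    "wild-type" = c(wildtype = coverage, upstream = 0, downstream = 0),
    "heterozygous" = c(wildtype = coverage / 2, upstream = coverage / 2,
                       downstream = coverage / 2),
    "homozygous-insertion" = c(wildtype = 0, upstream = coverage,
                               downstream = coverage))
  withr::with_seed(as.integer(seed), {
    reads <- character(0)
    for (k in names(refs$constructs)) {
      cv <- cov_per[[k]]
      if (cv <= 0) next
      L <- widths[[which(names(refs$constructs) == k)]]
      n <- rpois(1L, cv * (L - read_length + 1L) / read_length)
      if (n == 0L) next
      starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
      seqs <- substring(as.character(refs$constructs[[k]]),
                        starts, starts + read_length - 1L)
      flip <- runif(n) < 0.5
      if (any(flip)) {
        seqs[flip] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[flip])))
      }
      reads <- c(reads, seqs)
    }
    out <- Biostrings::DNAStringSet(reads)
    if (length(out))
      names(out) <- sprintf("read%05d", seq_along(out))
    out
  })
}

#' Write reads to a FASTQ file with uniform quality
#'
#' @param reads a [Biostrings::DNAStringSet].
#' @param path output path.
#' @param qual quality character applied to every base (default "I").
#' @return the path, invisibly.
#' @export
write_reads_fastq <- function(reads, path, qual = "I") {
  reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads)) && length(reads))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  quals <- Biostrings::BStringSet(vapply(
    Biostrings::width(reads),
    function(w) paste(rep(qual, w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read single-end reads from a FASTQ file
#'
#' @param path FASTQ path (gzip allowed).
#' @return a [Biostrings::DNAStringSet].
#' @export
read_reads_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
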