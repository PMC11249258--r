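## Variant-table ingestion and the informative-SNP filter.
##
## Canonical variant table (one row per site):
##   chrom, pos           coordinates (1-based)
##   gt_r, gt_s           parental genotype strings, e.g. "A/A"
##   rb, sb               per-bulk allele depth strings, e.g. "A:12,G:30"

parse_gt <- function(gt, line) {
  m <- regmatches(gt, regexec("^([ACGTN])/([ACGTN])$", gt))[[1]]
  if (length(m) != 3L)
    stop("malformed genotype string '", gt, "' at line ", line)
  m[2:3]
}

parse_depths <- function(txt, line) {
  if (is.na(txt) || txt == "" || txt == ".") return(setNames(integer(0), character(0)))
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexec("^([ACGTN]):([0-9]+)$", parts))
  if (any(lengths(kv) != 3L))
    stop("malformed allele depth string '", txt, "' at line ", line)
  setNames(vapply(kv, function(x) as.integer(x[3]), integer(1)),
           vapply(kv, function(x) x[2], character(1)))
}

#' Read a variant table in the simplified TSV dialect
#'
#' Expected tab-separated columns (with header): \code{chrom}, \code{pos},
#' \code{gt_r}, \code{gt_s} (parental genotypes as \code{"A/G"} strings)
#' and \code{rb}, \code{sb} (resistant- and susceptible-bulk allele depths
#' as \code{"A:12,G:30"} strings).
#'
#' @param path file path.
#' @return data.frame in the canonical variant-table layout.
#' @export
read_variant_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "gt_r", "gt_s", "rb", "sb")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df
}

#' Read parent and bulk genotypes from a VCF into the variant-table layout
#'
#' Uses the \pkg{vcfR} parser; only CHROM, POS, REF, ALT and the GT and AD
#' fields of the four named samples are consumed. Multi-allelic sites are
#' kept (all ALT alleles enter the depth strings) so the
#' origin-attribution filter can act on them.
#'
#' @param path VCF path.
#' @param parent_r,parent_s,bulk_r,bulk_s sample names in the VCF.
#' @return data.frame in the canonical variant-table layout.
#' @export
read_vcf_variants <- function(path, parent_r, parent_s, bulk_r, bulk_s) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  for (s in c(parent_r, parent_s, bulk_r, bulk_s))
    if (!s %in% samples) stop("sample ", s, " absent from ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  if (all(is.na(ad[, bulk_r])) || all(is.na(ad[, bulk_s])))
    stop("bulk sample lacks AD field in ", path)
  ref <- vcfR::getREF(v); alt <- vcfR::getALT(v)
  alleles <- mapply(function(r, a) c(r, strsplit(a, ",")[[1]]),
                    ref, alt, SIMPLIFY = FALSE)
  gt_to_bases <- function(g, al) {
    if (is.na(g)) return(NA_character_)
    idx <- as.integer(strsplit(g, "[/|]")[[1]]) + 1L
    paste(al[idx], collapse = "/")
  }
  ad_to_string <- function(a, al) {
    if (is.na(a)) return("")
    d <- as.integer(strsplit(a, ",")[[1]])
    paste(paste0(al[seq_along(d)], ":", d), collapse = ",")
  }
  n <- nrow(v@fix)
  data.frame(
    chrom = vcfR::getCHROM(v), pos = as.integer(vcfR::getPOS(v)),
    gt_r = vapply(seq_len(n), function(i)
      gt_to_bases(gt[i, parent_r], alleles[[i]]), character(1)),
    gt_s = vapply(seq_len(n), function(i)
      gt_to_bases(gt[i, parent_s], alleles[[i]]), character(1)),
    rb = vapply(seq_len(n), function(i)
      ad_to_string(ad[i, bulk_r], alleles[[i]]), character(1)),
    sb = vapply(seq_len(n), function(i)
      ad_to_string(ad[i, bulk_s], alleles[[i]]), character(1)),
    stringsAsFactors = FALSE)
}

#' Filter variant sites down to informative origin-labelled markers
#'
#' Removes sites with (a) read support below \code{min_depth} in either
#' bulk, (b) no genotype difference between the two parents, or (c) bulk
#' alleles that cannot be attributed to either parent. Heterozygous or
#' missing parental genotypes are also removed: the parent of origin of a
#' bulk allele is only defined when both parents are homozygous for
#' different alleles. Survivors become markers whose R- and S-origin
#' alleles are the resistant and susceptible parents' alleles, with the
#' per-bulk origin-labelled depths attached.
#'
#' @param variants canonical variant table (see [read_variant_table()]).
#' @param min_depth minimum total read support per bulk per site
#'   (default 4; sites below it in \emph{either} bulk are removed).
#'
#' @return data.frame of markers: chrom, pos, allele_r, allele_s, rb_r,
#'   rb_s, sb_r, sb_s. A \code{filter_reasons} attribute tabulates removals.
#' @export
filter_snps <- function(variants, min_depth = 4L) {
  need <- c("chrom", "pos", "gt_r", "gt_s", "rb", "sb")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(variants)
  keep <- logical(n)
  reason <- character(n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    gr <- variants$gt_r[i]; gs <- variants$gt_s[i]
    if (is.na(gr) || is.na(gs)) { reason[i] <- "missing_parent_gt"; next }
    ar <- parse_gt(gr, i); as_ <- parse_gt(gs, i)
    if (ar[1] != ar[2] || as_[1] != as_[2]) {
      reason[i] <- "parent_heterozygous"; next
    }
    if (ar[1] == as_[1]) { reason[i] <- "parents_identical"; next }
    rb <- parse_depths(variants$rb[i], i)
    sb <- parse_depths(variants$sb[i], i)
    if (sum(rb) < min_depth || sum(sb) < min_depth) {
      reason[i] <- "low_depth"; next
    }
    parental <- c(ar[1], as_[1])
    foreign <- function(d) any(d > 0 & !names(d) %in% parental)
    if (foreign(rb) || foreign(sb)) {
      reason[i] <- "non_parental_allele"; next
    }
    getd <- function(d, a) if (a %in% names(d)) unname(d[[a]]) else 0L
    keep[i] <- TRUE
    out[[i]] <- data.frame(
      chrom = variants$chrom[i], pos = as.integer(variants$pos[i]),
      allele_r = ar[1], allele_s = as_[1],
      rb_r = getd(rb, ar[1]), rb_s = getd(rb, as_[1]),
      sb_r = getd(sb, ar[1]), sb_s = getd(sb, as_[1]),
      stringsAsFactors = FALSE)
  }
  res <- if (any(keep)) do.call(rbind, out[keep]) else
    data.frame(chrom = character(0), pos = integer(0),
               allele_r = character(0), allele_s = character(0),
               rb_r = integer(0), rb_s = integer(0),
               sb_r = integer(0), sb_s = integer(0))
  attr(res, "filter_reasons") <- table(reason[!keep])
  res
}

#' Read pooled allele counts in the 8-column TSV dialect
#'
#' Columns (with header): chrom, pos, allele_r, allele_s, bulk
#' (\code{resistant}/\code{susceptible}), r_count, s_count, depth.
#'
#' @param path file path.
#' @return data.frame of pooled counts (long format, one row per marker
#'   per bulk).
#' @export
read_bsa_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "allele_r", "allele_s", "bulk",
            "r_count", "s_count", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("BSA TSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$bulk %in% c("resistant", "susceptible"))
  if (length(bad))
    stop("unknown bulk label at data line ", bad[1], ": ", df$bulk[bad[1]])
  df
}
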