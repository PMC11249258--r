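# Shared fixtures, all built in code.

# Two-chromosome genome mirroring the mapping-study layout: a 15-Mb
# chromosome carrying the causal locus at 8.4 Mb plus a 10-Mb null
# chromosome. Marker spacing configurable for speed.
study_genome <- function(spacing = 2e3) {
  genome_spec(c(chr1 = 15e6, chr2 = 10e6),
              list(chr1 = seq(spacing, 15e6, by = spacing),
                   chr2 = seq(spacing, 10e6, by = spacing)),
              causal_chrom = "chr1", causal_pos = 8.4e6, rate_cM_Mb = 3)
}

# Small genome for fast unit tests; causal locus on a marker position.
small_genome <- function() {
  genome_spec(c(chrA = 10e6),
              list(chrA = c(1e6, 3e6, 5e6, 7e6, 9e6)),
              causal_chrom = "chrA", causal_pos = 5e6, rate_cM_Mb = 3)
}

# Strain phenotype model matching the published strain EC50s with a
# shared slope.
study_model <- function() {
  phenotype_model_from_ec50(ec50_ss = 0.077, ec50_rs = 0.27,
                            ec50_rr = 428, slope = 4.7)
}

# Sharply discriminating model: heterozygotes and SS respond with
# probability numerically 1 at dose 1, RR respond with probability ~0;
# nobody responds at dose 1e-4.
strict_recessive_model <- function() {
  phenotype_model_from_ec50(ec50_ss = 0.01, ec50_rs = 0.02, ec50_rr = 100,
                            slope = 10)
}

# Deterministic toy junction reference set (flank 10, 20-bp element,
# GAAGG TSD) whose constructs can be verified by string concatenation.
toy_refs <- function() {
  left <- "ACGTACGTACGTACG"            # 15 bp, upstream of TSD
  tsd <- "GAAGG"
  right <- "TTGCATTGCATTGCATTGCA"      # 20 bp downstream
  element <- "CCCCAAAATTTTGGGGCCAA"    # 20 bp
  locus <- paste0(left, tsd, right)
  list(refs = build_junction_refs(locus, insertion_point = 20L,
                                  element = element, tsd = tsd,
                                  flank = 10L),
       left = left, tsd = tsd, right = right, element = element,
       locus = locus)
}

# Random junction reference set at full scale (600-bp constructs).
random_refs <- function(seed = 1, flank = 300L, tsd = "GAAGG") {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    left <- paste(sample(bases, flank + 40L, replace = TRUE), collapse = "")
    right <- paste(sample(bases, flank + 40L, replace = TRUE), collapse = "")
    element <- paste(sample(bases, 2L * flank, replace = TRUE),
                     collapse = "")
    locus <- paste0(left, tsd, right)
    build_junction_refs(locus, insertion_point = nchar(left) + nchar(tsd),
                        element = element, tsd = tsd, flank = flank)
  })
}

# Canonical variant-table row builder for filter tests.
variant_row <- function(chrom = "chr1", pos = 100L, gt_r = "A/A",
                        gt_s = "G/G", rb = "A:10,G:10", sb = "A:10,G:10") {
  data.frame(chrom = chrom, pos = pos, gt_r = gt_r, gt_s = gt_s,
             rb = rb, sb = sb, stringsAsFactors = FALSE)
}
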