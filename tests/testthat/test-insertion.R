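test_that("junction constructs are exact concatenations with the TSD geometry", {
  t <- toy_refs()
  cs <- as.character(t$refs$constructs)
  left10 <- substr(t$locus, 11, 20)   # last 10 bp up to the insertion point
  right10 <- substr(t$right, 1, 10)
  expect_equal(unname(cs["wildtype"]), paste0(left10, right10))
  expect_equal(unname(cs["upstream"]),
               paste0(left10, substr(t$element, 1, 10)))
  expect_equal(unname(cs["downstream"]),
               paste0(substr(t$element, 11, 20),
                      substr(paste0(t$tsd, t$right), 1, 10)))
  expect_equal(t$refs$junction_offset, 10L)
  # TSD sits immediately left of the upstream junction and immediately
  # right of the downstream junction
  expect_equal(unname(substr(cs["upstream"], 6, 10)), "GAAGG")
  expect_equal(unname(substr(cs["downstream"], 11, 15)), "GAAGG")
})

test_that("full-scale constructs are 600 bp and invalid geometry is rejected", {
  refs <- random_refs(seed = 51)
  expect_equal(unname(Biostrings::width(refs$constructs)), rep(600L, 3))
  t <- toy_refs()
  expect_error(build_junction_refs(t$locus, 20, substr(t$element, 1, 8),
                                   t$tsd, flank = 10),
               "shorter than the flank")
  expect_error(build_junction_refs(t$locus, 5, t$element, t$tsd, flank = 10),
               "overruns")
  expect_error(build_junction_refs(t$locus, 21, t$element, t$tsd,
                                   flank = 10),
               "TSD")
})

test_that("support counting honours the straddle and mismatch contracts", {
  refs <- random_refs(seed = 52)
  wt <- as.character(refs$constructs[["wildtype"]])
  expect_equal(unclass(count_junction_support(character(0), refs)),
               c(wildtype = 0L, upstream = 0L, downstream = 0L))
  # read entirely inside one flank: no support
  inside <- substr(wt, 1, 120)
  # read straddling the junction (construct positions 251..350)
  strad <- substr(wt, 251, 350)
  sup <- count_junction_support(c(inside, strad), refs)
  expect_equal(sup[["wildtype"]], 1L)
  # reverse complement of a straddling read still counts
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(strad)))
  expect_equal(count_junction_support(rc, refs)[["wildtype"]], 1L)
  # two mismatches tolerated, three not
  mm <- strad
  substr(mm, 10, 10) <- "N"; substr(mm, 40, 40) <- "N"
  expect_equal(count_junction_support(mm, refs,
                                      max_mismatch = 2)[["wildtype"]], 1L)
  substr(mm, 70, 70) <- "N"
  expect_equal(count_junction_support(mm, refs,
                                      max_mismatch = 2)[["wildtype"]], 0L)
  # marginal overlap: 20 bases right of the junction qualifies, 19 does not
  r20 <- substr(wt, 221, 320)  # spans junction at 300 with 20 on the right
  r19 <- substr(wt, 220, 319)
  expect_equal(count_junction_support(r20, refs,
                                      min_overlap = 20)[["wildtype"]], 1L)
  expect_equal(count_junction_support(r19, refs,
                                      min_overlap = 20)[["wildtype"]], 0L)
})

test_that("no read can support both the wild-type and an insertion junction", {
  # min_overlap (8) exceeds the 5-bp TSD; enumerate every read on a toy set
  refs <- random_refs(seed = 53, flank = 30L)
  rl <- 20L
  for (k in seq_along(refs$constructs)) {
    cseq <- as.character(refs$constructs[[k]])
    reads <- substring(cseq, 1:(nchar(cseq) - rl + 1L),
                       rl:nchar(cseq))
    for (rd in reads) {
      sup <- count_junction_support(rd, refs, min_overlap = 8L,
                                    max_mismatch = 0L)
      expect_false(sup[["wildtype"]] > 0 &&
                   (sup[["upstream"]] > 0 || sup[["downstream"]] > 0))
    }
  }
})

test_that("the read-count rule calls the published support patterns", {
  mk_sup <- function(wt, up, down)
    structure(c(wildtype = wt, upstream = up, downstream = down),
              class = "read_support")
  gdjm14 <- call_sample(mk_sup(0L, 4L, 6L), sample_id = "GDJM14")
  expect_equal(gdjm14$status, "positive")
  expect_equal(gdjm14$genotype, "homozygous-insertion")
  neg <- call_sample(mk_sup(12L, 0L, 0L))
  expect_equal(neg$status, "negative")
  expect_equal(neg$genotype, "wild-type")
  # threshold is strictly more than 3 reads
  three <- call_sample(mk_sup(0L, 3L, 3L))
  expect_equal(three$status, "negative")
  expect_equal(three$genotype, "indeterminate")
  het <- call_sample(mk_sup(8L, 5L, 4L))
  expect_equal(het$genotype, "heterozygous")
})

test_that("adding reads never flips a positive call negative", {
  mk_sup <- function(wt, up, down)
    structure(c(wildtype = wt, upstream = up, downstream = down),
              class = "read_support")
  for (up in 0:8) {
    st <- vapply(up:12, function(u)
      call_sample(mk_sup(2L, u, 0L))$status, character(1))
    first_pos <- match("positive", st)
    if (!is.na(first_pos))
      expect_true(all(st[first_pos:length(st)] == "positive"))
  }
})

test_that("error-free wild-type samples never produce a positive call", {
  refs <- random_refs(seed = 54)
  reads <- simulate_junction_reads("wild-type", refs, 100, 150, seed = 55)
  sup <- count_junction_support(reads, refs)
  call <- call_sample(sup)
  expect_equal(call$status, "negative")
  expect_equal(call$genotype, "wild-type")
  expect_equal(sup[["upstream"]] + sup[["downstream"]], 0L)
})

test_that("cohort screening tabulates one carrier among 540 samples", {
  calls <- do.call(rbind, lapply(1:540, function(i) {
    sup <- if (i == 277)
      structure(c(wildtype = 0L, upstream = 7L, downstream = 5L),
                class = "read_support")
    else
      structure(c(wildtype = 11L, upstream = 0L, downstream = 0L),
                class = "read_support")
    call_sample(sup, sample_id = sprintf("s%03d", i))
  }))
  sm <- screen_cohort(calls)
  expect_equal(as.integer(sm$by_status[c("positive", "negative")]),
               c(1L, 539L))
  expect_equal(as.integer(sm$by_genotype[["homozygous-insertion"]]), 1L)
  # duplicate ids rejected; all-carrier cohorts count everyone
  calls2 <- calls; calls2$sample[2] <- calls2$sample[1]
  expect_error(screen_cohort(calls2), "duplicate")
  allpos <- calls[calls$status == "positive", ][rep(1, 3), ]
  allpos$sample <- paste0("c", 1:3)
  expect_equal(as.integer(screen_cohort(allpos)$by_status[["positive"]]), 3L)
})

test_that("cohort allele frequency and founder probability match the field-screen arithmetic", {
  expect_equal(signif(allele_frequency(1, 0, 158), 3), 0.00633)
  expect_equal(allele_frequency(0, 0, 50), 0)
  expect_equal(allele_frequency(0, 1, 100), 0.005)
  expect_equal(round(founder_probability(0.00633, 100), 2), 0.72)
  expect_equal(founder_probability(0, 10), 0)
  expect_equal(founder_probability(1, 1), 1)
  # strictly increasing in both arguments
  fr <- seq(0.001, 0.2, length.out = 20)
  expect_false(is.unsorted(founder_probability(fr, 10), strictly = TRUE))
  expect_false(is.unsorted(vapply(1:20, founder_probability,
                                  numeric(1), frequency = 0.01),
                           strictly = TRUE))
})
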