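mk_counts <- function(r, s, pos = seq_along(r) * 100, chrom = "c1") {
  data.frame(chrom = chrom, pos = pos, rb_r = r, rb_s = s)
}

test_that("delta-SNP reproduces fixation, balance and the clipping rule", {
  d <- delta_snp(mk_counts(c(10, 5, 2), c(0, 5, 8)))
  expect_equal(d$delta, c(1, 0, 0))
  expect_equal(d$raw, c(1, 0, -0.6))
  expect_identical(d$clipped, c(FALSE, FALSE, TRUE))
  expect_identical(attr(d, "mode"), "single")
})

test_that("zero-depth markers are skipped with a message, never NaN", {
  expect_message(d <- delta_snp(mk_counts(c(10, 0), c(10, 0))), "skipped")
  expect_equal(nrow(d), 1L)
  expect_false(anyNA(d$delta))
})

test_that("two-bulk mode subtracts susceptible-bulk allele frequency", {
  m <- mk_counts(c(90, 50), c(10, 50))
  expect_error(delta_snp(m, mode = "two-bulk"), "susceptible")
  m$sb_r <- c(30, 50); m$sb_s <- c(70, 50)
  d <- delta_snp(m, mode = "two-bulk")
  expect_equal(d$raw, c(0.9 - 0.3, 0))
})

test_that("windows use the half-open tiling convention", {
  rec <- data.frame(chrom = "c1", pos = c(100, 900, 1000),
                    delta = c(0.4, 0.6, 0.9))
  w <- window_index(rec, 1000)
  expect_equal(w$start, c(0, 1000))
  expect_equal(w$index, c(0.5, 0.9))
  expect_equal(w$end - w$start, c(1000, 1000))
  expect_equal(w$n_snps, c(2L, 1L))
})

test_that("window index equals the brute-force grouping oracle and is order-invariant", {
  withr::with_seed(101, {
    rec <- data.frame(
      chrom = sample(c("c1", "c2"), 10000, replace = TRUE),
      pos = sample.int(2e6, 10000, replace = TRUE),
      delta = runif(10000))
  })
  w <- window_index(rec, 1000)
  # oracle: explicit group-then-average
  key <- paste(rec$chrom, (rec$pos %/% 1000) * 1000)
  omean <- tapply(rec$delta, key, mean)
  ocount <- tapply(rec$delta, key, length)
  wkey <- paste(w$chrom, w$start)
  expect_setequal(wkey, names(omean))
  expect_equal(w$index, as.numeric(omean[wkey]), tolerance = 0)
  expect_equal(w$n_snps, as.integer(ocount[wkey]))
  # window index bounded by member deltas
  omin <- tapply(rec$delta, key, min); omax <- tapply(rec$delta, key, max)
  expect_true(all(w$index >= as.numeric(omin[wkey]) - 1e-12 &
                  w$index <= as.numeric(omax[wkey]) + 1e-12))
  # invariance to input row order
  shuf <- rec[withr::with_seed(102, sample.int(nrow(rec))), ]
  expect_equal(window_index(shuf, 1000), w, ignore_attr = TRUE)
})

test_that("local regression is exact on constants and lines", {
  w <- data.frame(chrom = "c1", start = (0:99) * 1000, end = (1:100) * 1000,
                  index = rep(0.3, 100), n_snps = 1L)
  expect_equal(loess_smooth(w, 0.2)$smoothed, rep(0.3, 100))
  w$index <- 0.001 * (1:100) + 0.05
  expect_equal(loess_smooth(w, 0.2)$smoothed, w$index, tolerance = 1e-6)
})

test_that("local regression matches a pointwise weighted-least-squares oracle", {
  withr::with_seed(103, {
    n <- 120
    x <- sort(runif(n, 0, 1e5))
    y <- ifelse(x > 5e4, 0.8, 0.2) + rnorm(n, 0, 0.05)
  })
  w <- data.frame(chrom = "c1", start = x - 50, end = x + 50,
                  index = y, n_snps = 1L)
  sm <- loess_smooth(w, span = 0.25)$smoothed
  k <- ceiling(0.25 * n)
  oracle <- vapply(seq_len(n), function(i) {
    dx <- abs(x - x[i])
    nb <- order(dx)[seq_len(k)]
    df <- data.frame(xx = x[nb], yy = y[nb],
                     wt = (1 - (dx[nb] / max(dx[nb]))^3)^3)
    fit <- lm(yy ~ xx, data = df, weights = wt)
    unname(predict(fit, newdata = data.frame(xx = x[i])))
  }, numeric(1))
  expect_equal(sm, oracle, tolerance = 1e-8)
})

test_that("chromosomes with too few windows fall back to unsmoothed values", {
  w <- data.frame(chrom = "c1", start = (0:4) * 1000, end = (1:5) * 1000,
                  index = runif(5), n_snps = 1L)
  expect_warning(out <- loess_smooth(w, 0.5), "fewer than 10")
  expect_equal(out$smoothed, out$index)
})

test_that("top-percentile threshold matches a sort-and-interpolate oracle", {
  expect_equal(top_percentile_threshold(rep(0.7, 25)), 0.7)
  expect_equal(top_percentile_threshold(0.42), 0.42)
  # oracle: linear interpolation between order statistics at rank (n-1)p+1
  q_oracle <- function(v, p) {
    s <- sort(v)
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    if (lo == length(v)) s[lo]
    else s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }
  expect_equal(top_percentile_threshold(1:100), q_oracle(1:100, 0.99))
  withr::with_seed(104, v <- rnorm(537))
  expect_equal(top_percentile_threshold(v, 95), q_oracle(v, 0.95))
})

test_that("candidate regions are maximal runs with gap tolerance", {
  w <- data.frame(chrom = "c1", start = (0:9) * 1000, end = (1:10) * 1000,
                  index = c(0.1, 0.9, 0.9, 0.1, 0.9, 0.9, 0.1, 0.1, 0.9, 0.1),
                  n_snps = 1L)
  expect_equal(nrow(call_candidate_regions(w, threshold = 2)), 0L)
  r0 <- call_candidate_regions(w, threshold = 0.5, max_gap = 0)
  expect_equal(nrow(r0), 3L)
  expect_equal(r0$start[1], 1000); expect_equal(r0$end[1], 3000)
  r1 <- call_candidate_regions(w, threshold = 0.5, max_gap = 1)
  expect_equal(nrow(r1), 2L)
  expect_equal(r1$end[1], 6000)  # one-gap bridge joins the first two runs
  # five contiguous above-threshold windows form a single region
  w5 <- data.frame(chrom = "c1", start = (0:4) * 1000, end = (1:5) * 1000,
                   index = 0.9, n_snps = 1L)
  r5 <- call_candidate_regions(w5, threshold = 0.5)
  expect_equal(nrow(r5), 1L)
  expect_equal(c(r5$start, r5$end), c(0, 5000))
  expect_equal(r5$n_windows, 5L)
})

test_that("fine-mapping tallies count genotypes and flag complete linkage", {
  g <- data.frame(phenotype = c(rep("resistant", 4), rep("susceptible", 2)),
                  m1 = c("rr", "rr", "rr", "rr", "rs", "ss"),
                  m2 = c("rr", "rr", "rs", "rs", "ss", "ss"),
                  stringsAsFactors = FALSE)
  t <- finemap_tally(g)
  r1 <- t[t$marker == "m1" & t$phenotype == "resistant", ]
  expect_equal(r1$het_fraction, 0)
  expect_true(r1$fully_linked)
  r2 <- t[t$marker == "m2" & t$phenotype == "resistant", ]
  expect_equal(r2$het_fraction, 0.5)
  expect_false(r2$fully_linked)
  g$m1[1] <- "xx"
  expect_error(finemap_tally(g), "unknown genotype code")
})

test_that("resistant-class heterozygosity grows with distance from the causal locus", {
  g <- genome_spec(c(c1 = 10e6),
                   list(c1 = c(5e6, 5.5e6, 7e6, 9e6)),
                   "c1", 5e6, rate_cM_Mb = 3)
  het <- matrix(NA_real_, 100, 4)
  for (rep in 1:100) {
    pop <- simulate_cross(g, cross_design("F2", 60), seed = 200 + rep)
    res <- which(causal_genotype(pop) == "RR")
    h1 <- pop$hap1[res, , drop = FALSE]; h2 <- pop$hap2[res, , drop = FALSE]
    het[rep, ] <- colMeans(h1 != h2)
  }
  m <- colMeans(het)
  expect_false(is.unsorted(m))  # non-decreasing with distance
  expect_lt(m[1], 0.01)         # at the causal marker: no heterozygotes
})

test_that("null-chromosome raw delta-SNP is centred on zero", {
  g <- genome_spec(c(c1 = 2e6), list(c1 = seq(2e3, 2e6, by = 2e3)),
                   "c1", 1e6)
  f1 <- simulate_cross(g, cross_design("F1", 30), seed = 300)
  counts <- sample_pool_counts(f1, 100, seed = 301)
  d <- delta_snp(pool_counts_to_markers(counts))
  se <- sd(d$raw) / sqrt(nrow(d))
  expect_lt(abs(mean(d$raw)), 3 * se)
  expect_true(all(d$delta >= 0 & d$delta <= 1))
})
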