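## Delta-SNP statistic, windowing, smoothing, threshold and region calls.

#' Combine per-bulk pooled counts into the wide marker-count layout
#'
#' @param resistant,susceptible data.frames from [sample_pool_counts()]
#'   (chrom, pos, r_count, s_count); \code{susceptible} may be NULL.
#' @return data.frame: chrom, pos, rb_r, rb_s, sb_r, sb_s.
#' @export
pool_counts_to_markers <- function(resistant, susceptible = NULL) {
  out <- data.frame(chrom = resistant$chrom, pos = resistant$pos,
                    rb_r = resistant$r_count, rb_s = resistant$s_count,
                    sb_r = NA_integer_, sb_s = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(susceptible)) {
    key <- paste(out$chrom, out$pos)
    skey <- paste(susceptible$chrom, susceptible$pos)
    m <- match(key, skey)
    out$sb_r <- susceptible$r_count[m]
    out$sb_s <- susceptible$s_count[m]
  }
  out
}

#' Per-marker delta-SNP from origin-labelled pooled counts
#'
#' The default (\code{"single"}) mode works within the resistant bulk:
#' delta = frequency of R-origin reads minus frequency of S-origin reads
#' (equal to \eqn{2 f_R - 1}), which is 1 at a recessive causal locus
#' fixed in the bulk and 0 in expectation at unlinked markers. The
#' \code{"two-bulk"} mode subtracts the R-allele frequency in the
#' susceptible bulk from that in the resistant bulk. In both modes
#' negative raw values are clipped to 0 and flagged (so the statistic
#' spans 0..1), and markers with zero usable depth are skipped with a
#' message rather than producing NaN.
#'
#' @param markers wide marker-count data.frame with columns rb_r, rb_s
#'   (and sb_r, sb_s for two-bulk mode): from [filter_snps()] or
#'   [pool_counts_to_markers()].
#' @param mode \code{"single"} or \code{"two-bulk"}.
#'
#' @return data.frame: chrom, pos, delta, raw, depth, clipped; the mode is
#'   recorded in the \code{mode} attribute.
#' @export
delta_snp <- function(markers, mode = c("single", "two-bulk")) {
  mode <- match.arg(mode)
  rdepth <- markers$rb_r + markers$rb_s
  if (mode == "single") {
    usable <- rdepth >= 1
    raw <- (markers$rb_r - markers$rb_s) / rdepth
    depth <- rdepth
  } else {
    if (!all(c("sb_r", "sb_s") %in% names(markers)) ||
        anyNA(markers$sb_r))
      stop("two-bulk mode requires susceptible-bulk counts")
    sdepth <- markers$sb_r + markers$sb_s
    usable <- rdepth >= 1 & sdepth >= 1
    raw <- markers$rb_r / rdepth - markers$sb_r / sdepth
    depth <- rdepth + sdepth
  }
  if (any(!usable))
    message(sum(!usable), " marker(s) skipped for zero depth")
  out <- data.frame(chrom = markers$chrom[usable], pos = markers$pos[usable],
                    delta = pmax(0, raw[usable]), raw = raw[usable],
                    depth = depth[usable], clipped = raw[usable] < 0,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Mean delta-SNP per fixed genomic window
#'
#' Windows tile each chromosome as half-open intervals
#' \code{[k*w, (k+1)*w)} over 1-based positions, so a SNP at exactly
#' position \code{w} falls in the second window. Windows containing no
#' SNP are omitted.
#'
#' @param records data.frame from [delta_snp()] (chrom, pos, delta).
#' @param window window size in bp (default 1000).
#' @return data.frame ordered by (chrom, start): chrom, start, end,
#'   index (mean delta), n_snps.
#' @export
window_index <- function(records, window = 1000L) {
  stopifnot(window >= 1)
  if (nrow(records) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), index = numeric(0),
                      n_snps = integer(0)))
  start <- (records$pos %/% window) * window
  agg <- aggregate(records$delta,
                   by = list(chrom = records$chrom, start = start),
                   FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(chrom = agg$chrom, start = agg$start,
                    end = agg$start + window,
                    index = agg$x[, 1], n_snps = as.integer(agg$x[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

## tricube local linear regression at the observed points; the k nearest
## neighbours of a point in sorted x form a contiguous block, tracked
## with a monotone two-pointer sweep
tricube_local_fit <- function(x, y, span) {
  n <- length(x)
  k <- max(2L, min(n, ceiling(span * n)))
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  fit <- numeric(n)
  lo <- 1L
  for (i in seq_len(n)) {
    lo <- max(lo, i - k + 1L)
    lo_max <- min(i, n - k + 1L)
    while (lo < lo_max && xs[lo + k] - xs[i] < xs[i] - xs[lo])
      lo <- lo + 1L
    idx <- lo:(lo + k - 1L)
    dx <- abs(xs[idx] - xs[i])
    dmax <- max(dx)
    if (dmax == 0) { fit[i] <- mean(ys[idx]); next }
    w <- (1 - (dx / dmax)^3)^3
    sw <- sum(w)
    xw <- xs[idx]; yw <- ys[idx]
    xb <- sum(w * xw) / sw; yb <- sum(w * yw) / sw
    sxx <- sum(w * (xw - xb)^2)
    b <- if (sxx > 0) sum(w * (xw - xb) * (yw - yb)) / sxx else 0
    fit[i] <- yb + b * (xs[i] - xb)
  }
  fit[o] <- fit
  fit
}

#' Smooth the window index with tricube local linear regression
#'
#' Per chromosome, each window's smoothed value is the prediction at its
#' midpoint of a degree-1 weighted least-squares fit over the
#' \code{ceiling(span * n)} nearest windows, with tricube weights and no
#' robustness iterations. Chromosomes with fewer than 10 windows fall
#' back to the unsmoothed index with a warning.
#'
#' @param windows data.frame from [window_index()].
#' @param span neighbourhood fraction in (0, 1] (default 0.1).
#' @return the input with a \code{smoothed} column appended.
#' @export
loess_smooth <- function(windows, span = 0.1) {
  stopifnot(span > 0, span <= 1)
  windows$smoothed <- NA_real_
  for (ch in unique(windows$chrom)) {
    i <- which(windows$chrom == ch)
    if (length(i) < 10L) {
      warning("chromosome ", ch, " has fewer than 10 windows; ",
              "returning unsmoothed values")
      windows$smoothed[i] <- windows$index[i]
      next
    }
    mid <- (windows$start[i] + windows$end[i]) / 2
    windows$smoothed[i] <- tricube_local_fit(mid, windows$index[i], span)
  }
  windows
}

#' Top-percentile threshold of the window index
#'
#' The 99th (by default) percentile of the supplied values, computed by
#' linear interpolation between order statistics
#' (\code{quantile type 7}), genome-wide over all emitted windows.
#'
#' @param values numeric vector (>= 1 value).
#' @param percentile percentile in (0, 100\] (default 99).
#' @return the threshold value.
#' @export
top_percentile_threshold <- function(values, percentile = 99) {
  stopifnot(length(values) >= 1, percentile > 0, percentile <= 100)
  quantile(values, percentile / 100, type = 7, names = FALSE)
}

#' Call candidate regions from above-threshold windows
#'
#' Scans the emitted windows of each chromosome in positional order and
#' reports maximal runs of windows whose value reaches the threshold,
#' allowing up to \code{max_gap} consecutive below-threshold windows
#' inside a run. The region spans from the first to the last qualifying
#' window; the peak is the window with the largest value.
#'
#' @param windows data.frame from [window_index()] /[loess_smooth()].
#' @param threshold index threshold (e.g. [top_percentile_threshold()]).
#' @param max_gap below-threshold windows tolerated inside a run
#'   (default 0).
#' @param value which column to compare against the threshold:
#'   \code{"index"} (default) or \code{"smoothed"}.
#' @return data.frame: chrom, start, end, peak_start, peak_value,
#'   n_windows, threshold.
#' @export
call_candidate_regions <- function(windows, threshold, max_gap = 0L,
                                   value = c("index", "smoothed")) {
  value <- match.arg(value)
  if (value == "smoothed" && !"smoothed" %in% names(windows))
    stop("windows carry no smoothed column")
  v <- windows[[value]]
  above <- v >= threshold
  regions <- list()
  for (ch in unique(windows$chrom)) {
    i <- which(windows$chrom == ch)
    i <- i[order(windows$start[i])]
    idx_above <- i[above[i]]
    if (length(idx_above) == 0L) next
    pos_in_chr <- match(idx_above, i)
    if (length(pos_in_chr) > 1L) {
      gaps <- diff(pos_in_chr) - 1L
      breaks <- which(gaps > max_gap)
      starts <- c(1L, breaks + 1L)
      ends <- c(breaks, length(pos_in_chr))
    } else { starts <- 1L; ends <- 1L }
    for (r in seq_along(starts)) {
      mem <- idx_above[starts[r]:ends[r]]
      peak <- mem[which.max(v[mem])]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch,
        start = min(windows$start[mem]),
        end = max(windows$end[mem]),
        peak_start = windows$start[peak],
        peak_value = v[peak],
        n_windows = length(mem),
        threshold = threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(regions) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_start = numeric(0),
                      peak_value = numeric(0), n_windows = integer(0),
                      threshold = numeric(0)))
  do.call(rbind, regions)
}

#' Run the full delta-SNP-index scan
#'
#' Convenience wrapper chaining [delta_snp()], [window_index()],
#' [loess_smooth()], [top_percentile_threshold()] and
#' [call_candidate_regions()].
#'
#' @param markers wide marker-count data.frame (see [delta_snp()]).
#' @param mode delta-SNP mode.
#' @param window window size (bp).
#' @param span smoothing span.
#' @param percentile threshold percentile.
#' @param max_gap region gap tolerance in windows.
#' @param flag_value column the threshold is computed over and compared
#'   against for region calls: \code{"index"} (default; the top-percentile
#'   line is drawn over the raw window index, the smoothed curve being for
#'   presentation) or \code{"smoothed"}. One quantity serves for both the
#'   threshold and the flags so the top-percentile rule is self-consistent.
#' @return list: records, windows (with smoothed values), threshold,
#'   regions (ordered by peak value, then width).
#' @export
bsa_scan <- function(markers, mode = "single", window = 1000L, span = 0.1,
                     percentile = 99, max_gap = 0L,
                     flag_value = "index") {
  records <- delta_snp(markers, mode = mode)
  windows <- window_index(records, window = window)
  windows <- loess_smooth(windows, span = span)
  threshold <- top_percentile_threshold(windows[[flag_value]], percentile)
  regions <- call_candidate_regions(windows, threshold, max_gap = max_gap,
                                    value = flag_value)
  if (nrow(regions) > 1L)
    regions <- regions[order(-regions$peak_value, -regions$n_windows), ,
                       drop = FALSE]
  list(records = records, windows = windows, threshold = threshold,
       regions = regions)
}

#' Tally fine-mapping genotypes by phenotype class
#'
#' @param genotypes data.frame with a \code{phenotype} column and one
#'   column per marker holding codes \code{"rr"}, \code{"rs"} or
#'   \code{"ss"}.
#' @param resistant_class label of the resistant phenotype class used for
#'   the complete-linkage flag (default \code{"resistant"}).
#' @return data.frame, one row per marker per phenotype class: marker,
#'   phenotype, rr, rs, ss, het_fraction, fully_linked (TRUE when every
#'   resistant-class individual is rr at that marker).
#' @export
finemap_tally <- function(genotypes, resistant_class = "resistant") {
  stopifnot("phenotype" %in% names(genotypes))
  markers <- setdiff(names(genotypes), "phenotype")
  if (length(markers) == 0L) stop("no marker columns")
  codes <- unlist(genotypes[markers], use.names = FALSE)
  bad <- setdiff(unique(codes), c("rr", "rs", "ss"))
  if (length(bad))
    stop("unknown genotype code(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (m in markers) {
    full <- all(genotypes[[m]][genotypes$phenotype == resistant_class]
                == "rr")
    for (cl in unique(genotypes$phenotype)) {
      g <- genotypes[[m]][genotypes$phenotype == cl]
      n_rr <- sum(g == "rr"); n_rs <- sum(g == "rs"); n_ss <- sum(g == "ss")
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, phenotype = cl, rr = n_rr, rs = n_rs, ss = n_ss,
        het_fraction = n_rs / (n_rr + n_rs + n_ss),
        fully_linked = full, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write windows (or regions) as BED and TSV
#'
#' BED output is 0-based half-open, converted from the internal 1-based
#' position convention (a window starting at internal coordinate s covers
#' 1-based positions max(1, s)..s+w-1, i.e. BED \[max(0, s-1), s+w-1)).
#'
#' @param df windows or regions data.frame with chrom/start/end.
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @param score optional column name written in BED column 5.
#' @return invisibly, the paths written.
#' @export
write_bsa_output <- function(df, bed_path = NULL, tsv_path = NULL,
                             score = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = df$chrom,
                      start = pmax(0, df$start - 1),
                      end = df$end - 1,
                      name = sprintf("%s_%d", df$chrom, as.integer(df$start)),
                      score = if (!is.null(score)) df[[score]] else 0)
    write.table(format(bed, scientific = FALSE, trim = TRUE), bed_path,
                sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
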