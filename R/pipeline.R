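## End-to-end orchestration: simulate -> BSA -> dose-response ->
## insertion screen -> qPCR, with a JSON run manifest.

pipeline_stages <- c("simulate", "bsa", "dose", "insertion", "qpcr")

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "bsamap_run",
    stages = pipeline_stages,
    simulate = list(
      chrom_lengths = c(chr1 = 15e6, chr2 = 10e6),
      marker_spacing = 1e4,
      causal_chrom = "chr1", causal_pos = 8.4e6,
      rate_cM_Mb = 3,
      n_progeny = 960L, arm_sizes = c(480L, 480L),
      bulk_sizes = c(89L, 75L),
      high_dose = 4.0, low_dose = 0.1,
      ec50 = c(SS = 0.077, RS = 0.27, RR = 428), slope = 4.7,
      mean_depth = 100,
      bioassay_fold = 1.35,
      bioassay_n = 24L,
      tsd = "GAAGG", flank = 100L, read_length = 75L, coverage = 30,
      insertion_genotypes = c("wild-type", "heterozygous",
                              "homozygous-insertion"),
      ct_folds = data.frame(
        group = c("SS", "SS", "R", "R"),
        assay = c("total", "wildtype", "total", "wildtype"),
        fold = c(1, 1, 1.8, 0.08)),
      ct_n = 4L, ct_sd = 0.2),
    bsa = list(window = 1000L, span = 0.1, percentile = 99,
               max_gap = 0L, mode = "single", flag_value = "index"),
    dose = list(reference = "SS"),
    insertion = list(min_reads = 4L, min_overlap = 20L, max_mismatch = 2L),
    qpcr = list(calibrator = "SS", reference_assay = "reference"))
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", k)
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.data.frame(base[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' Unknown keys are rejected by name; values not present fall back to
#' the built-in defaults, which encode the study conditions of the
#' bundled demonstration (an F2 of 960 progeny, 480 per dose arm, bulks
#' of 89 and 75, pooled depth 100x).
#'
#' @param path configuration file; format chosen by extension
#'   (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return a complete configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("unknown config format: ", path)
  merge_config(default_config(), user)
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the simulation-to-report pipeline
#'
#' Executes the selected stages in dependency order, writing each
#' stage's outputs before the next starts: \code{simulate} generates the
#' cross, bulks, pooled counts (8-column TSV dialect), a bioassay table,
#' junction constructs (FASTA) with per-genotype read sets (FASTQ) and a
#' Ct table; \code{bsa} scans the pooled counts into windows and
#' candidate regions (TSV + BED); \code{dose} produces the per-strain
#' probit fit table; \code{insertion} screens the read sets;
#' \code{qpcr} computes fold values and group summaries. All randomness
#' derives from \code{config$seed}; re-running with an identical
#' configuration reproduces byte-identical outputs, which the manifest
#' records as md5 checksums.
#'
#' @param config configuration list (see [read_run_config()]) or a path
#'   to a YAML/JSON configuration file.
#' @return the run manifest (list), invisibly; also written to
#'   \code{manifest.json} in the output directory.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_config(), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(tool = "bsamapr",
                   version = as.character(utils::packageVersion("bsamapr")),
                   config_hash = md5_of(config), seed = config$seed,
                   stages = list())
  files <- list()
  for (stage in intersect(pipeline_stages, config$stages)) {
    t0 <- proc.time()[["elapsed"]]
    written <- switch(stage,
      simulate = stage_simulate(config, out),
      bsa = stage_bsa(config, out),
      dose = stage_dose(config, out),
      insertion = stage_insertion(config, out),
      qpcr = stage_qpcr(config, out))
    files[[stage]] <- written
    manifest$stages[[stage]] <- list(
      outputs = as.list(setNames(tools::md5sum(written),
                                 basename(written))),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    stage_log(stage, "done (", length(written), " file(s))")
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

sim_genome_from_config <- function(sc) {
  mk <- lapply(sc$chrom_lengths, function(L)
    seq(sc$marker_spacing, L, by = sc$marker_spacing))
  genome_spec(sc$chrom_lengths, mk, sc$causal_chrom, sc$causal_pos,
              sc$rate_cM_Mb)
}

stage_simulate <- function(config, out) {
  sc <- config$simulate
  seed <- as.integer(config$seed)
  genome <- sim_genome_from_config(sc)
  model <- phenotype_model_from_ec50(sc$ec50[["SS"]], sc$ec50[["RS"]],
                                     sc$ec50[["RR"]], sc$slope)
  pop <- simulate_cross(genome, cross_design("F2", sc$n_progeny),
                        seed = seed)
  bulks <- phenotype_and_bulk(pop, model, sc$high_dose, sc$low_dose,
                              sc$bulk_sizes, seed = seed + 1L,
                              arm_sizes = sc$arm_sizes)
  counts_r <- sample_pool_counts(bulks$resistant, sc$mean_depth,
                                 seed = seed + 2L, "resistant")
  counts_s <- sample_pool_counts(bulks$susceptible, sc$mean_depth,
                                 seed = seed + 3L, "susceptible")
  long <- rbind(counts_r, counts_s)
  long$allele_r <- "A"; long$allele_s <- "G"
  long <- long[, c("chrom", "pos", "allele_r", "allele_s", "bulk",
                   "r_count", "s_count", "depth")]
  f_counts <- out("pool_counts.tsv")
  write.table(long, f_counts, sep = "\t", quote = FALSE, row.names = FALSE)
  f_assign <- out("bulk_assignment.tsv")
  write.table(bulks$assignment, f_assign, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ## bioassay tables for SS-like, RR-like and F1-like strains
  rows <- list()
  for (g in c("SS", "RS", "RR")) {
    strain <- c(SS = "SS", RS = "F1", RR = "R")[[g]]
    doses <- ec50_dose_series(sc$ec50[[g]], sc$bioassay_fold)
    rows[[g]] <- simulate_bioassay(doses, sc$bioassay_n,
                                   sc$slope, sc$ec50[[g]],
                                   seed = seed + 10L + match(g, names(sc$ec50)),
                                   strain = strain)
  }
  f_bio <- out("bioassay.tsv")
  write.table(do.call(rbind, rows), f_bio, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ## junction constructs and per-genotype read sets
  jr <- sim_demo_locus(sc$tsd, sc$flank, seed = seed + 20L)
  f_fa <- out("junction_constructs.fasta")
  Biostrings::writeXStringSet(jr$constructs, f_fa)
  f_reads <- character(0)
  for (g in sc$insertion_genotypes) {
    reads <- simulate_junction_reads(g, jr, sc$coverage, sc$read_length,
                                     seed = seed + 30L +
                                       match(g, sc$insertion_genotypes))
    f <- out(paste0("reads_", gsub("[^a-z]+", "_", g), ".fastq"))
    write_reads_fastq(reads, f)
    f_reads <- c(f_reads, f)
  }
  ## Ct table
  ct <- simulate_ct(as.data.frame(sc$ct_folds), noise_sd = sc$ct_sd,
                    n_per_group = sc$ct_n, seed = seed + 40L)
  f_ct <- out("ct_table.tsv")
  write.table(ct, f_ct, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, causal = list(chrom = sc$causal_chrom,
                                    pos = sc$causal_pos)),
    out("simulate_truth.json"), auto_unbox = TRUE, digits = NA)
  c(f_counts, f_assign, f_bio, f_fa, f_reads, f_ct,
    out("simulate_truth.json"))
}

## deterministic toy locus + element for the demo insertion screen
sim_demo_locus <- function(tsd, flank, seed) {
  withr::with_seed(as.integer(seed), {
    bases <- c("A", "C", "G", "T")
    left <- paste(sample(bases, flank + 50L, replace = TRUE), collapse = "")
    right <- paste(sample(bases, flank + 50L, replace = TRUE), collapse = "")
    element <- paste(sample(bases, 4L * flank, replace = TRUE),
                     collapse = "")
    locus <- paste0(left, tsd, right)
    build_junction_refs(locus, insertion_point = nchar(left) + nchar(tsd),
                        element = element, tsd = tsd, flank = flank)
  })
}

stage_bsa <- function(config, out) {
  bc <- config$bsa
  long <- read_bsa_tsv(out("pool_counts.tsv"))
  res <- long[long$bulk == "resistant", ]
  sus <- long[long$bulk == "susceptible", ]
  markers <- pool_counts_to_markers(res, sus)
  scan <- bsa_scan(markers, mode = bc$mode, window = bc$window,
                   span = bc$span, percentile = bc$percentile,
                   max_gap = bc$max_gap, flag_value = bc$flag_value)
  scan$windows$threshold <- scan$threshold
  write_bsa_output(scan$windows, out("windows.bed"), out("windows.tsv"),
                   score = "index")
  write_bsa_output(scan$regions, out("regions.bed"), out("regions.tsv"),
                   score = "peak_value")
  unname(vapply(c("windows.bed", "windows.tsv", "regions.bed",
                  "regions.tsv"), out, character(1)))
}

stage_dose <- function(config, out) {
  table <- read.table(out("bioassay.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  fits <- fit_probit_table(table, reference = config$dose$reference)
  f <- out("probit_fits.tsv")
  write.table(fits, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

stage_insertion <- function(config, out) {
  ic <- config$insertion
  constructs <- Biostrings::readDNAStringSet(out("junction_constructs.fasta"))
  refs <- structure(list(constructs = constructs,
                         junction_offset = Biostrings::width(constructs)[1] %/% 2L,
                         tsd = config$simulate$tsd,
                         flank = Biostrings::width(constructs)[1] %/% 2L),
                    class = "junction_refs")
  fq <- list.files(config$out_dir, pattern = "^reads_.*\\.fastq$",
                   full.names = TRUE)
  calls <- do.call(rbind, lapply(fq, function(f) {
    reads <- read_reads_fastq(f)
    sup <- count_junction_support(reads, refs, ic$min_overlap,
                                  ic$max_mismatch)
    call_sample(sup, ic$min_reads,
                sample_id = sub("^reads_(.*)\\.fastq$", "\\1", basename(f)))
  }))
  summary <- screen_cohort(calls)
  f1 <- out("insertion_calls.tsv")
  write.table(summary$calls, f1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  f2 <- out("insertion_summary.tsv")
  write.table(data.frame(status = names(summary$by_status),
                         n = as.integer(summary$by_status)),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  c(f1, f2)
}

stage_qpcr <- function(config, out) {
  qc <- config$qpcr
  ct <- read.table(out("ct_table.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  folds <- rel_abundance(ct, calibrator = qc$calibrator,
                         reference_assay = qc$reference_assay)
  f1 <- out("qpcr_folds.tsv")
  write.table(folds, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- out("qpcr_summary.tsv")
  write.table(fold_summary(folds), f2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(f1, f2)
}

#' Validate pipeline input files against their schemas
#'
#' @param paths character vector of file paths.
#' @param schemas matching character vector of schema names:
#'   \code{"bioassay"}, \code{"ct"}, \code{"bsa_tsv"},
#'   \code{"variant_tsv"} or \code{"vcf"}.
#' @return data.frame: path, schema, ok, detail (first offending line or
#'   sample for failures).
#' @export
validate_inputs <- function(paths, schemas) {
  stopifnot(length(paths) == length(schemas))
  check_one <- function(path, schema) {
    if (!file.exists(path)) return(paste("missing file:", path))
    tryCatch({
      if (schema == "bioassay") {
        df <- read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
        need <- c("strain", "concentration", "n", "responded")
        miss <- setdiff(need, names(df))
        if (length(miss))
          return(paste("missing column(s):", paste(miss, collapse = ", ")))
        bad <- which(df$responded > df$n | df$responded < 0)
        if (length(bad))
          return(paste("responded > tested at data row", bad[1]))
      } else if (schema == "ct") {
        df <- read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
        need <- c("sample", "group", "assay", "ct")
        miss <- setdiff(need, names(df))
        if (length(miss))
          return(paste("missing column(s):", paste(miss, collapse = ", ")))
        if (any(df$ct <= 0))
          return(paste("non-positive Ct at data row",
                       which(df$ct <= 0)[1]))
      } else if (schema == "bsa_tsv") {
        read_bsa_tsv(path)
      } else if (schema == "variant_tsv") {
        read_variant_table(path)
      } else if (schema == "vcf") {
        if (!requireNamespace("vcfR", quietly = TRUE))
          return("vcfR not available")
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        ad <- vcfR::extract.gt(v, element = "AD")
        no_ad <- colnames(ad)[apply(is.na(ad), 2, all)]
        if (length(no_ad))
          return(paste("sample lacks AD:", no_ad[1]))
      } else return(paste("unknown schema:", schema))
      "ok"
    }, error = function(e) conditionMessage(e))
  }
  detail <- mapply(check_one, paths, schemas)
  data.frame(path = paths, schema = schemas, ok = detail == "ok",
             detail = ifelse(detail == "ok", "", detail),
             row.names = NULL, stringsAsFactors = FALSE)
}
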