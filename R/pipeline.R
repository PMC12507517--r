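# Pipeline orchestration: run a subcommand from a configuration list or a
# plain-text key: value config file, write versioned outputs plus a
# machine-readable manifest (inputs, parameters, seed, checksums) and a
# human-readable log. Outputs are fully determined by the configuration and
# seed; manifests carry no timestamps so identical runs are byte-identical.

#' Default pipeline configuration
#'
#' @return Named list of defaults; see [run_pipeline()] for the meaning of
#'   each field.
#' @export
default_config <- function() {
  list(
    subcommand = "all",
    out_dir = "kbscan_out",
    seed = 1L,
    # scanning
    consensus = "GGGRNNYYCC", max_mismatches = 3L, strong_threshold = 6,
    scan_both_strands = TRUE,
    # windows
    window_min = 10L, window_max = 500L, window_step = 10L,
    report_windows = c(50L, 150L, 500L),
    # simulate
    n_peaks = 100L, table_entries = 200L, span_bp = 150,
    n_weak_min = 2L, n_weak_max = 8L, background_gc = 0.45,
    alpha = 1, noise_sd = 5,
    # occupancy
    conc_nM = c(100, 200, 250), kd_nM = c(27, 250, 1500, 3000),
    # pulldown
    min_total = 5, z_margin = 0.5, kmeans_k = NA,
    # input paths (scan / correlate / pulldown on real data)
    fasta = NULL, peaks = NULL, peak_format = "narrowPeak",
    zscore_table = NULL, counts = NULL, design = NULL
  )
}

#' Read a pipeline configuration file
#'
#' Plain-text `key: value` format (a YAML subset); unknown keys are
#' rejected so typos fail fast.
#'
#' @param path config file path.
#' @return Configuration list merged over [default_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

# internal: scan config from a pipeline config
config_scan <- function(cfg) {
  scan_config(consensus = cfg$consensus, max_mismatches = cfg$max_mismatches,
              strong_threshold = cfg$strong_threshold,
              scan_both_strands = cfg$scan_both_strands)
}

#' Run the analysis pipeline
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate`}{generate a Z-score table and a synthetic peak cohort;
#'     write FASTA, narrowPeak, the table and the planted truth.}
#'   \item{`scan`}{designate kB sites in the input FASTA against the input
#'     Z-score table; write a site TSV and BED.}
#'   \item{`correlate`}{scan peak-region sequences, compute per-peak
#'     cumulative Z-scores and weak-site counts, the correlation-vs-window
#'     curve, and the ranked-halves comparison.}
#'   \item{`occupancy`}{write the equilibrium occupancy grid over the
#'     configured concentrations and dissociation constants.}
#'   \item{`pulldown`}{run the enrichment pipeline on a count matrix.}
#'   \item{`all`}{`simulate`, then `correlate` and `occupancy` on the
#'     simulated files (round-tripped through disk).}
#' }
#' Every run writes `manifest.json` (subcommand, parameters, seed, input and
#' output MD5 checksums, per-stage counts) and `run.log`.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   of a `key: value` config file.
#' @return Invisibly, the manifest list. Errors propagate as R conditions
#'   with actionable messages; the command-line wrapper maps them to a
#'   nonzero exit status.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)
  sub <- match.arg(cfg$subcommand,
                   c("all", "simulate", "scan", "correlate", "occupancy",
                     "pulldown"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  inputs <- character(0)
  outputs <- character(0)
  stats <- list()

  path_in <- function(p) file.path(cfg$out_dir, p)

  if (sub %in% c("simulate", "all")) {
    note("simulate: %d peaks, %d-entry table, seed %d", cfg$n_peaks,
         cfg$table_entries, cfg$seed)
    tbl <- gen_zscore_table(cfg$table_entries, seed = cfg$seed,
                            consensus = cfg$consensus)
    spec <- cohort_spec(cfg$n_peaks, span_bp = cfg$span_bp,
                        n_weak_range = c(cfg$n_weak_min, cfg$n_weak_max),
                        background_gc = cfg$background_gc, alpha = cfg$alpha,
                        noise_sd = cfg$noise_sd, seed = cfg$seed)
    cohort <- gen_peak_cohort(spec, tbl, config_scan(cfg))
    seqs <- vapply(cohort$peaks, `[[`, character(1), "sequence")
    names(seqs) <- vapply(cohort$peaks, `[[`, character(1), "region_id")
    f_fa <- path_in("regions.fa"); write_fasta(seqs, f_fa)
    pk_df <- data.frame(
      chrom = names(seqs), start = 0L,
      end = nchar(seqs),
      region_id = names(seqs),
      chip_score = vapply(cohort$peaks, `[[`, numeric(1), "chip_score"),
      strand = ".",
      summit = round(vapply(cohort$peaks, `[[`, numeric(1), "anchor_offset")),
      stringsAsFactors = FALSE)
    f_np <- path_in("peaks.narrowPeak"); write_narrowpeak(pk_df, f_np)
    f_zt <- path_in("zscore_table.tsv"); write_zscore_table(tbl, f_zt)
    f_ts <- path_in("truth_sites.tsv")
    write.table(cohort$truth$sites, f_ts, sep = "\t", quote = FALSE,
                row.names = FALSE)
    f_tp <- path_in("truth_peaks.tsv")
    write.table(cohort$truth$peaks, f_tp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs <- c(outputs, f_fa, f_np, f_zt, f_ts, f_tp)
    stats$simulate <- list(
      n_peaks = cfg$n_peaks, table_entries = length(tbl),
      planted_sites = sum(cohort$truth$sites$planted),
      incidental_sites = sum(!cohort$truth$sites$planted))
    note("simulate: %d planted + %d incidental designated sites",
         stats$simulate$planted_sites, stats$simulate$incidental_sites)
    if (sub == "all") {
      cfg$fasta <- f_fa
      cfg$peaks <- f_np
      cfg$peak_format <- "narrowPeak"
      cfg$zscore_table <- f_zt
    }
  }

  if (sub == "scan") {
    if (is.null(cfg$fasta) || is.null(cfg$zscore_table))
      stop("`scan` needs config entries `fasta` and `zscore_table`")
    seqs <- read_fasta(cfg$fasta)
    tbl <- read_zscore_table(cfg$zscore_table)
    inputs <- c(inputs, cfg$fasta, cfg$zscore_table)
    sc <- config_scan(cfg)
    all_sites <- do.call(rbind, lapply(names(seqs), function(nm) {
      s <- designate_sites(seqs[[nm]], tbl, sc)
      if (nrow(s)) s$chrom <- nm
      s
    }))
    f_tsv <- path_in("sites.tsv")
    f_bed <- path_in("sites.bed")
    if (is.null(all_sites) || !nrow(all_sites)) {
      note("scan: no sites designated")
      all_sites <- data.frame()
      file.create(f_tsv, f_bed)
    } else {
      sp <- split(all_sites, all_sites$chrom)
      first <- TRUE
      for (nm in names(sp)) {
        tmp_bed <- tempfile(); tmp_tsv <- tempfile()
        write_sites(sp[[nm]], nm, bed_path = tmp_bed, tsv_path = tmp_tsv)
        bl <- readLines(tmp_bed); tl <- readLines(tmp_tsv)
        cat(bl, file = f_bed, sep = "\n", append = !first)
        cat("\n", file = f_bed, append = TRUE)
        cat(if (first) tl else tl[-1], file = f_tsv, sep = "\n",
            append = !first)
        cat("\n", file = f_tsv, append = TRUE)
        unlink(c(tmp_bed, tmp_tsv))
        first <- FALSE
      }
    }
    outputs <- c(outputs, f_tsv, f_bed)
    stats$scan <- list(n_sequences = length(seqs),
                       n_sites = nrow(all_sites))
    note("scan: designated %d sites in %d sequences", nrow(all_sites),
         length(seqs))
  }

  if (sub %in% c("correlate", "all")) {
    if (is.null(cfg$fasta) || is.null(cfg$peaks) || is.null(cfg$zscore_table))
      stop("`correlate` needs config entries `fasta`, `peaks` and `zscore_table`")
    seqs <- read_fasta(cfg$fasta)
    pk <- read_peaks(cfg$peaks, cfg$peak_format)
    tbl <- read_zscore_table(cfg$zscore_table)
    if (sub == "correlate")
      inputs <- c(inputs, cfg$fasta, cfg$peaks, cfg$zscore_table)
    missing_seq <- setdiff(pk$region_id, names(seqs))
    if (length(missing_seq))
      stop("no FASTA record for region(s): ",
           paste(utils::head(missing_seq, 3), collapse = ", "))
    sc <- config_scan(cfg)
    peaks <- lapply(seq_len(nrow(pk)), function(i) {
      summit <- if ("summit" %in% names(pk)) pk$summit[i] else NA
      peak_region(pk$region_id[i], chip_score = pk$chip_score[i],
                  sequence = seqs[[pk$region_id[i]]], table = tbl,
                  config = sc,
                  region_center = if (!is.na(summit)) summit else NULL)
    })
    windows <- seq(cfg$window_min, cfg$window_max, by = cfg$window_step)
    curve <- correlation_curve(peaks, windows)
    f_curve <- path_in("correlation_curve.tsv"); write_curve(curve, f_curve)
    halves <- compare_ranked_halves(peaks)
    rep_w <- cfg$report_windows
    report <- halves$assignment
    for (L in rep_w)
      report[[sprintf("cum_z_%d", L)]] <-
        vapply(peaks, cumulative_z, numeric(1), window_length = L)
    f_rep <- path_in("peak_report.tsv")
    write.table(report, f_rep, sep = "\t", quote = FALSE, row.names = FALSE)
    f_half <- path_in("ranked_halves.json")
    jsonlite::write_json(halves[c("mean_top", "mean_bottom", "t_statistic",
                                  "p_value")],
                         f_half, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f_curve, f_rep, f_half)
    stats$correlate <- list(
      n_peaks = length(peaks), n_windows = length(windows),
      n_sites = sum(vapply(peaks, function(p) nrow(p$sites), numeric(1))),
      ranked_halves_p = halves$p_value)
    note("correlate: %d peaks, %d windows; ranked-halves p = %.3g",
         length(peaks), length(windows), halves$p_value)
  }

  if (sub %in% c("occupancy", "all")) {
    grid <- occupancy_table(cfg$conc_nM, cfg$kd_nM)
    f_occ <- path_in("occupancy.tsv")
    df <- data.frame(conc_nM = as.numeric(rownames(grid)), grid,
                     check.names = FALSE)
    write.table(df, f_occ, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f_occ)
    stats$occupancy <- list(n_conc = length(cfg$conc_nM),
                            n_kd = length(cfg$kd_nM))
    note("occupancy: %d x %d grid", length(cfg$conc_nM), length(cfg$kd_nM))
  }

  if (sub == "pulldown") {
    if (is.null(cfg$counts) || is.null(cfg$design))
      stop("`pulldown` needs config entries `counts` and `design`")
    pm <- read_pulldown(cfg$counts, cfg$design)
    inputs <- c(inputs, cfg$counts, cfg$design)
    k <- if (is.na(cfg$kmeans_k)) NULL else as.integer(cfg$kmeans_k)
    res <- pulldown_enrichment(pm, min_total = cfg$min_total,
                               z_margin = cfg$z_margin, k = k,
                               seed = cfg$seed)
    f_enr <- path_in("enrichment.tsv")
    write_enrichment(res, f_enr)
    outputs <- c(outputs, f_enr)
    stats$pulldown <- list(n_input = nrow(pm$counts),
                           n_retained = nrow(res$matrix$counts),
                           n_passed = sum(res$passed))
    note("pulldown: %d/%d proteins retained, %d enriched",
         stats$pulldown$n_retained, stats$pulldown$n_input,
         sum(res$passed))
  }

  # manifests must be identical for identical runs regardless of where the
  # output directory lives: record file names, not absolute paths
  rel_sum <- function(paths) {
    s <- tools::md5sum(paths)
    names(s) <- basename(names(s))
    as.list(s)
  }
  params <- cfg[setdiff(names(cfg), "out_dir")]
  for (key in c("fasta", "peaks", "zscore_table", "counts", "design"))
    if (!is.null(params[[key]])) params[[key]] <- basename(params[[key]])
  manifest <- list(
    tool = "kbscan",
    version = as.character(utils::packageVersion("kbscan")),
    subcommand = sub,
    seed = cfg$seed,
    parameters = params,
    inputs = rel_sum(inputs),
    outputs = rel_sum(outputs),
    stats = stats)
  f_manifest <- path_in("manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  writeLines(log_lines, path_in("run.log"))
  invisible(manifest)
}
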