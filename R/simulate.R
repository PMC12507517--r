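# Synthetic inputs with planted ground truth: Z-score tables, peak cohorts
# with clustered strong/weak sites, and pulldown count matrices. All
# randomness flows from a single seed through named substreams so each
# component can be regenerated independently.

#' Generate a synthetic affinity Z-score table
#'
#' Emits `n_entries` distinct 10-mers, each within three mismatches of the
#' kB consensus GGGRNNYYCC, with positive right-skewed Z-scores (log-normal,
#' median ~4) so that most entries are weak and a minority exceed the
#' strong boundary of 6 — the shape of measured kB affinity spectra. The
#' table always contains the two benchmark sites GGGAAATTCC (Z = 14, the
#' strong A-centric reference) and GGGAAGTTCC (Z = 5.8, the weak G-centric
#' reference) when `n_entries` permits.
#'
#' @param n_entries number of table entries (>= 1).
#' @param seed integer seed; the table is deterministic per seed.
#' @param consensus degenerate consensus the emitted kmers stay within 3
#'   mismatches of.
#' @return A [zscore_table()].
#' @export
gen_zscore_table <- function(n_entries, seed = 1L,
                             consensus = "GGGRNNYYCC") {
  n_entries <- as.integer(n_entries)
  if (is.na(n_entries) || n_entries < 1L) stop("n_entries must be >= 1")
  capacity <- count_compatible_kmers(consensus, max_mismatches = 3L)
  if (n_entries > capacity)
    stop("n_entries (", n_entries, ") exceeds the ", capacity,
         " 10-mers within 3 mismatches of ", consensus)
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  allowed <- IUPAC_SETS[cons]
  mutable <- which(lengths(allowed) < 4L)  # N positions cannot mismatch

  sentinels <- c(GGGAAATTCC = 14.0, GGGAAGTTCC = 5.8)
  sentinels <- sentinels[seq_len(min(2L, n_entries))]

  withr::with_seed(as.integer(substream_seed(seed, "zscore_table")), {
    kmers <- names(sentinels)
    attempts <- 0L
    while (length(kmers) < n_entries && attempts < 10000L * n_entries) {
      attempts <- attempts + 1L
      bases <- vapply(allowed, function(a) sample(a, 1L), character(1))
      d <- sample(0:3, 1L)
      if (d > 0L) {
        pos <- sample(mutable, min(d, length(mutable)))
        for (p in pos) {
          disallowed <- setdiff(c("A", "C", "G", "T"), allowed[[p]])
          bases[p] <- sample(disallowed, 1L)
        }
      }
      km <- paste(bases, collapse = "")
      if (!km %in% kmers) kmers <- c(kmers, km)
    }
    if (length(kmers) < n_entries)
      stop("failed to draw ", n_entries, " distinct compatible 10-mers")
    n_extra <- n_entries - length(sentinels)
    z_extra <- round(rlnorm(n_extra, meanlog = log(4), sdlog = 0.65), 3)
    z <- c(unname(sentinels), z_extra)
  })
  zscore_table(kmers, z, source_label = sprintf("synthetic (seed %s)", seed))
}

# internal: number of 10-mers within max_mismatches of a degenerate
# consensus, by convolution of per-position (allowed, mismatch) choices
count_compatible_kmers <- function(consensus, max_mismatches = 3L) {
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  allowed <- lengths(IUPAC_SETS[cons])
  poly <- 1
  for (a in allowed) poly <- convolve_poly(poly, c(a, 4 - a))
  sum(poly[seq_len(min(length(poly), max_mismatches + 1L))])
}

convolve_poly <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) for (j in seq_along(q))
    out[i + j - 1L] <- out[i + j - 1L] + p[i] * q[j]
  out
}

#' Specification of a synthetic peak cohort
#'
#' Describes the study conditions a cohort emulates: per peak, a 1001-bp
#' background sequence carries one strong site at its center surrounded by
#' several weak sites planted within a span of ~150 bp (the width kB-site
#' clusters, and the open chromatin they sit in, typically occupy), and the
#' ChIP score is a noisy linear function of the planted cumulative Z.
#'
#' @param n_peaks number of peaks (>= 4).
#' @param span_bp planted cluster span in bp (<= 500; default 150).
#' @param n_weak_range integer interval for the per-peak weak-site count
#'   planted within the cluster span (default 2..8; induced chemokine
#'   promoters carry on the order of 8-13 weak sites across the full
#'   +/-500 bp region, with the cluster core holding a subset — and 8
#'   non-overlapping 10-bp sites approach the packing limit of a 150-bp
#'   span).
#' @param strong_z_range,weak_z_range Z intervals the planted strong/weak
#'   kmers are drawn from (defaults `[6, 15]` and `[1, 6)`); the weak range
#'   must lie strictly below the strong threshold.
#' @param background_gc GC fraction of the i.i.d. background (default 0.45,
#'   typical of murine promoter neighbourhoods).
#' @param alpha slope of chip score versus planted cumulative Z.
#' @param noise_sd standard deviation of the additive Gaussian chip-score
#'   noise (scores are floored at 0).
#' @param seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_peaks, span_bp = 150, n_weak_range = c(2L, 8L),
                        strong_z_range = c(6, 15), weak_z_range = c(1, 6),
                        background_gc = 0.45, alpha = 1, noise_sd = 5,
                        seed = 1L) {
  n_peaks <- as.integer(n_peaks)
  if (is.na(n_peaks) || n_peaks < 4L) stop("n_peaks must be >= 4")
  if (span_bp > 500 || span_bp < 10) stop("span_bp must be in [10, 500]")
  n_weak_range <- as.integer(n_weak_range)
  if (length(n_weak_range) != 2L || any(n_weak_range < 0) ||
      n_weak_range[1] > n_weak_range[2])
    stop("n_weak_range must be a non-decreasing pair of non-negative integers")
  if (weak_z_range[2] > strong_z_range[1])
    stop("weak_z_range must lie strictly below the strong threshold")
  if (background_gc <= 0 || background_gc >= 1)
    stop("background_gc must be in (0, 1)")
  structure(list(n_peaks = n_peaks, span_bp = span_bp,
                 n_weak_range = n_weak_range,
                 strong_z_range = strong_z_range,
                 weak_z_range = weak_z_range,
                 background_gc = background_gc, alpha = alpha,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic peak cohort with planted kB-site clusters
#'
#' Per peak: a 1001-bp i.i.d. background at the requested GC content; one
#' strong site (kmer drawn from the table's strong entries) planted at the
#' region center on a random strand; `n_weak` weak sites (count uniform in
#' `n_weak_range`, kmers from the table's weak entries) planted at centers
#' uniform within `span_bp / 2` of the anchor, non-overlapping (collisions
#' resampled up to 1000 times). The chip score is
#' `alpha * (planted cumulative Z at span_bp) + N(0, noise_sd)`, floored at
#' zero. Each region is then re-scanned with [designate_sites()], so
#' background windows that accidentally qualify become part of the region's
#' designated sites; they are recorded in the truth as incidental.
#'
#' @param spec a [cohort_spec()].
#' @param table a [zscore_table()] containing at least one strong and one
#'   weak entry within the requested Z ranges.
#' @param config a [scan_config()] used for the re-scan.
#' @return A list: `peaks` (list of [peak_region()]) and `truth`, itself a
#'   list with `sites` (planted and incidental sites, flag `planted`),
#'   `peaks` (per-peak `true_cum_z` at `span_bp`, `noiseless_chip`,
#'   `chip_score`, planted weak count) and the `spec`.
#' @export
gen_peak_cohort <- function(spec, table, config = scan_config()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(table, "zscore_table"))
  z <- table$entries
  strong_pool <- names(z)[z >= spec$strong_z_range[1] & z <= spec$strong_z_range[2]]
  weak_pool <- names(z)[z >= spec$weak_z_range[1] & z < spec$weak_z_range[2]]
  if (!length(strong_pool)) stop("table has no entry in strong_z_range")
  if (!length(weak_pool) && spec$n_weak_range[2] > 0)
    stop("table has no entry in weak_z_range")

  len <- 1001L
  anchor_start <- 495L            # 0-based; center 499.5
  anchor_center <- anchor_start + 4.5
  half_span <- spec$span_bp / 2
  probs <- c((1 - spec$background_gc) / 2, spec$background_gc / 2,
             spec$background_gc / 2, (1 - spec$background_gc) / 2)

  seq_seed <- substream_seed(spec$seed, "sequence")
  place_seed <- substream_seed(spec$seed, "placement")
  noise_seed <- substream_seed(spec$seed, "noise")

  backgrounds <- withr::with_seed(as.integer(seq_seed), {
    lapply(seq_len(spec$n_peaks), function(i)
      sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs))
  })

  planted <- withr::with_seed(as.integer(place_seed), {
    lapply(seq_len(spec$n_peaks), function(i) {
      strong_kmer <- strong_pool[sample.int(length(strong_pool), 1L)]
      n_range <- seq(spec$n_weak_range[1], spec$n_weak_range[2])
      n_weak <- n_range[sample.int(length(n_range), 1L)]
      starts <- anchor_start
      kmers <- strong_kmer
      strands <- sample(c("+", "-"), 1L)
      tries <- 0L
      while (length(starts) < n_weak + 1L) {
        tries <- tries + 1L
        if (tries > 1000L)
          stop("could not place ", n_weak, " non-overlapping weak sites in a ",
               spec$span_bp, "-bp span; widen span_bp or reduce n_weak_range")
        d <- sample(seq(-floor(half_span), floor(half_span)), 1L)
        s0 <- anchor_start + d
        if (s0 < 0L || s0 + 10L > len) next
        if (any(abs(s0 - starts) < 10L)) next
        starts <- c(starts, s0)
        kmers <- c(kmers, weak_pool[sample.int(length(weak_pool), 1L)])
        strands <- c(strands, sample(c("+", "-"), 1L))
      }
      data.frame(start = starts, strand = strands, kmer = kmers,
                 stringsAsFactors = FALSE)
    })
  })

  noise <- withr::with_seed(as.integer(noise_seed),
                            rnorm(spec$n_peaks, 0, spec$noise_sd))

  peaks <- vector("list", spec$n_peaks)
  truth_sites <- vector("list", spec$n_peaks)
  truth_peaks <- vector("list", spec$n_peaks)
  for (i in seq_len(spec$n_peaks)) {
    id <- sprintf("peak_%03d", i)
    bases <- backgrounds[[i]]
    pl <- planted[[i]]
    for (j in seq_len(nrow(pl))) {
      ins <- if (pl$strand[j] == "+") pl$kmer[j] else rev_comp(pl$kmer[j])
      bases[(pl$start[j] + 1L):(pl$start[j] + 10L)] <-
        strsplit(ins, "", fixed = TRUE)[[1]]
    }
    sequence <- paste(bases, collapse = "")
    pl$z_score <- zscore_lookup(table, pl$kmer)
    pl$site_class <- classify_site(pl$z_score, config$strong_threshold)
    pl$center <- pl$start + 4.5
    in_span <- abs(pl$center - anchor_center) <= half_span
    true_cum <- sum(pl$z_score[in_span])
    noiseless <- spec$alpha * true_cum
    chip <- max(0, noiseless + noise[i])
    pk <- peak_region(id, chip_score = chip, sequence = sequence,
                      table = table, config = config)
    peaks[[i]] <- pk
    des <- pk$sites
    des$planted <- des$start %in% pl$start
    des$region_id <- id
    ts <- des[, c("region_id", "start", "center", "strand", "kmer", "z_score",
                  "site_class", "planted")]
    rownames(ts) <- NULL
    truth_sites[[i]] <- ts
    truth_peaks[[i]] <- data.frame(
      region_id = id, true_cum_z = true_cum, noiseless_chip = noiseless,
      chip_score = chip, n_weak_planted = sum(pl$site_class == "weak"),
      stringsAsFactors = FALSE)
  }
  list(peaks = peaks,
       truth = list(sites = do.call(rbind, truth_sites),
                    peaks = do.call(rbind, truth_peaks),
                    planted = planted, spec = spec))
}

#' Generate a synthetic pulldown count matrix with planted enrichment
#'
#' Baseline counts are Poisson with protein-specific log-normal rates; a
#' planted subset of proteins has its rate multiplied by `effect_size` in
#' the experimental columns only. Experimental columns cycle through
#' probe x timepoint conditions (two probes, two stimulation timepoints);
#' controls share one control-DNA condition.
#'
#' @param n_proteins number of proteins.
#' @param n_experimental,n_control numbers of experimental / control
#'   pulldown columns (each >= 1).
#' @param n_enriched number of planted enriched proteins
#'   (`<= n_proteins`).
#' @param effect_size multiplicative rate increase in experimental columns
#'   (1 = null model, no systematic enrichment).
#' @param seed integer seed; the matrix is deterministic per seed.
#' @return A list: `matrix` (a [pulldown_matrix()]) and `enriched`
#'   (character vector of planted protein identifiers).
#' @export
gen_pulldown <- function(n_proteins, n_experimental = 4L, n_control = 2L,
                         n_enriched = 0L, effect_size = 1, seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  n_experimental <- as.integer(n_experimental)
  n_control <- as.integer(n_control)
  n_enriched <- as.integer(n_enriched)
  if (n_experimental < 1L || n_control < 1L)
    stop("need at least one experimental and one control column")
  if (n_enriched > n_proteins) stop("n_enriched must be <= n_proteins")
  if (effect_size <= 0) stop("effect_size must be positive")

  proteins <- sprintf("protein_%03d", seq_len(n_proteins))
  conditions <- rep(c("Cxcl2_30min", "Cxcl2_180min",
                      "Ccl2_30min", "Ccl2_180min"),
                    length.out = n_experimental)
  design <- data.frame(
    label = c(sprintf("exp_%02d", seq_len(n_experimental)),
              sprintf("ctrl_%02d", seq_len(n_control))),
    class = c(rep("experimental", n_experimental),
              rep("control", n_control)),
    condition = c(conditions, rep("control_DM", n_control)),
    replicate = c(as.integer(stats::ave(seq_len(n_experimental),
                                        conditions, FUN = seq_along)),
                  seq_len(n_control)),
    stringsAsFactors = FALSE)

  counts_seed <- substream_seed(seed, "counts")
  withr::with_seed(as.integer(counts_seed), {
    rates <- rlnorm(n_proteins, meanlog = log(10), sdlog = 0.8)
    enriched <- sample(proteins, n_enriched)
    rate_mat <- matrix(rates, nrow = n_proteins,
                       ncol = n_experimental + n_control)
    rate_mat[proteins %in% enriched, seq_len(n_experimental)] <-
      rate_mat[proteins %in% enriched, seq_len(n_experimental)] * effect_size
    counts <- matrix(rpois(length(rate_mat), rate_mat),
                     nrow = n_proteins,
                     dimnames = list(proteins, design$label))
  })
  list(matrix = pulldown_matrix(counts, design), enriched = sort(enriched))
}
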