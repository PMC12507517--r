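# Cumulative Z-scores of kB-site clusters in dynamic windows around the
# strongest motif of each ChIP peak, and cohort-level comparisons.

#' Select the anchor (strongest) motif of a region
#'
#' The anchor is the designated site with the maximal Z-score. Ties are
#' broken by proximity of the site center to the region center, then by the
#' smaller start, so the choice is deterministic.
#'
#' @param sites data.frame of sites as returned by [designate_sites()].
#' @param region_center offset (same coordinate system as `sites$start`) of
#'   the region midpoint used for tie-breaking.
#' @return The single anchor row of `sites`.
#' @export
select_anchor <- function(sites, region_center) {
  if (is.null(sites) || nrow(sites) == 0L)
    stop("no designated kB site in region")
  center <- if ("center" %in% names(sites)) sites$center else sites$start + 4.5
  ord <- order(-sites$z_score, abs(center - region_center), sites$start)
  sites[ord[1], , drop = FALSE]
}

#' Construct a ChIP peak region
#'
#' A `peak_region` bundles the +/- 500 bp sequence context of a ChIP peak
#' (1001 bp nominal; shorter at contig edges), its occupancy score, the kB
#' sites designated within it, and the anchor — the strongest designated
#' motif, around whose center all dynamic analysis windows are placed.
#' Either supply `sequence` plus a Z-score `table` (the region is scanned),
#' or a precomputed `sites` data.frame.
#'
#' @param region_id identifier (e.g. the associated gene or peak name).
#' @param chip_score non-negative ChIP occupancy score (tag count / peak
#'   intensity), accepted as provided.
#' @param sequence DNA string, or `NULL` when `sites` is given.
#' @param sites optional precomputed data.frame in [designate_sites()]
#'   layout with coordinates relative to the region.
#' @param table,config used to scan `sequence` when `sites` is `NULL`.
#' @param region_length region length when no sequence is supplied
#'   (defaults to `max(site end, 1001)`).
#' @param region_center offset used for anchor tie-breaking; defaults to
#'   the sequence midpoint, but a peak-summit offset can be supplied.
#' @return An object of class `peak_region` with fields `region_id`,
#'   `sequence`, `chip_score`, `sites`, `anchor`, `anchor_offset` (center of
#'   the anchor motif within the region).
#' @export
peak_region <- function(region_id, chip_score, sequence = NULL, sites = NULL,
                        table = NULL, config = scan_config(),
                        region_length = NULL, region_center = NULL) {
  if (!is.finite(chip_score) || chip_score < 0)
    stop("chip_score must be a finite non-negative number")
  if (is.null(sites)) {
    if (is.null(sequence) || is.null(table))
      stop("supply either `sites` or both `sequence` and `table`")
    sites <- designate_sites(sequence, table, config)
  }
  len <- if (!is.null(sequence)) nchar(sequence)
         else region_length %||% max(1001, if (nrow(sites)) max(sites$start) + 10 else 0)
  if (!"center" %in% names(sites)) sites$center <- sites$start + 4.5
  anchor <- select_anchor(sites, region_center = region_center %||% (len - 1) / 2)
  structure(list(region_id = as.character(region_id), sequence = sequence,
                 chip_score = as.numeric(chip_score), sites = sites,
                 anchor = anchor, anchor_offset = anchor$center,
                 region_length = len),
            class = "peak_region")
}

#' @export
print.peak_region <- function(x, ...) {
  cat(sprintf(
    "Peak region '%s': chip_score %.3g, %d kB site(s) (%d strong, %d weak),\n",
    x$region_id, x$chip_score, nrow(x$sites),
    sum(x$sites$site_class == "strong"), sum(x$sites$site_class == "weak")))
  cat(sprintf("  anchor %s (Z = %.2f) centered at offset %.1f of %d bp\n",
              x$anchor$kmer, x$anchor$z_score, x$anchor_offset,
              x$region_length))
  invisible(x)
}

#' Cumulative Z-score of a peak's kB cluster in a dynamic window
#'
#' Sums the affinity Z-scores of all designated sites whose center lies
#' within the symmetric window `[anchor_center - L/2, anchor_center + L/2]`.
#' With `include_weak = FALSE`, weak-class sites contribute zero, but the
#' anchor always contributes its own Z regardless of class — exclusion never
#' re-anchors the window.
#'
#' @param peak a [peak_region()].
#' @param window_length window length L in bp (>= 1).
#' @param include_weak include contributions of weak-class sites?
#' @return Cumulative Z (Z-units). Non-decreasing in `window_length` because
#'   designation requires Z > 0.
#' @export
cumulative_z <- function(peak, window_length, include_weak = TRUE) {
  stopifnot(inherits(peak, "peak_region"))
  if (!is.finite(window_length) || window_length < 1)
    stop("window_length must be >= 1 bp")
  drop(cumulative_z_profile(peak, window_length, include_weak))
}

# internal: cumulative Z at each of several window lengths at once
cumulative_z_profile <- function(peak, window_lengths, include_weak = TRUE) {
  s <- peak$sites
  d <- abs(s$center - peak$anchor_offset)
  contrib <- s$z_score
  if (!include_weak) contrib[s$site_class == "weak"] <- 0
  is_anchor <- s$start == peak$anchor$start & s$strand == peak$anchor$strand
  contrib[is_anchor] <- s$z_score[is_anchor]  # anchor always counts in full
  vapply(window_lengths, function(L) sum(contrib[d <= L / 2]), numeric(1))
}

#' Count weak kB sites around the anchor
#'
#' Number of weak-class designated sites whose center lies within
#' `window_length / 2` bp of the anchor center. If the anchor itself is
#' weak it is included in the count.
#'
#' @inheritParams cumulative_z
#' @return Non-negative integer.
#' @export
count_weak_sites <- function(peak, window_length = 500) {
  stopifnot(inherits(peak, "peak_region"))
  s <- peak$sites
  sum(s$site_class == "weak" &
        abs(s$center - peak$anchor_offset) <= window_length / 2)
}

#' Correlation between ChIP occupancy and cumulative Z across window lengths
#'
#' For each window length L, computes the Pearson correlation r between the
#' peaks' ChIP scores and their cumulative Z-scores at L — once with all
#' designated sites (`r_all`) and once with weak sites' contributions zeroed
#' (`r_strong_only`). A window where either vector has zero variance yields
#' `NA` and is flagged via the `undefined_windows` attribute (never silently
#' dropped).
#'
#' @param peaks list of [peak_region()] objects (>= 3).
#' @param window_lengths strictly increasing integer window lengths in bp
#'   (default 10, 20, ..., 500).
#' @param log1p_score correlate `log1p(chip_score)` instead of the raw
#'   score (off by default; the raw score is what occupancy curves use).
#' @return A data.frame of class `correlation_curve` with columns
#'   `window_length`, `r_all`, `r_strong_only`; attributes `n_peaks` and
#'   `undefined_windows`.
#' @export
correlation_curve <- function(peaks, window_lengths = seq(10L, 500L, by = 10L),
                              log1p_score = FALSE) {
  if (length(peaks) < 3L) stop("need at least 3 peaks for a correlation curve")
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_region")))
  window_lengths <- as.numeric(window_lengths)
  if (is.unsorted(window_lengths, strictly = TRUE))
    stop("window_lengths must be strictly increasing")
  scores <- vapply(peaks, `[[`, numeric(1), "chip_score")
  if (any(!is.finite(scores))) stop("all peaks need a finite chip_score")
  if (log1p_score) scores <- log1p(scores)
  cz_all <- do.call(rbind, lapply(peaks, cumulative_z_profile,
                                  window_lengths = window_lengths,
                                  include_weak = TRUE))
  cz_str <- do.call(rbind, lapply(peaks, cumulative_z_profile,
                                  window_lengths = window_lengths,
                                  include_weak = FALSE))
  safe_r <- function(x, y) {
    if (isTRUE(sd(x) > 0) && isTRUE(sd(y) > 0)) cor(x, y) else NA_real_
  }
  r_all <- apply(cz_all, 2, safe_r, x = scores)
  r_str <- apply(cz_str, 2, safe_r, x = scores)
  out <- data.frame(window_length = window_lengths, r_all = r_all,
                    r_strong_only = r_str)
  undef <- window_lengths[is.na(r_all) | is.na(r_str)]
  if (length(undef))
    message("correlation undefined (zero variance) at window length(s): ",
            paste(undef, collapse = ", "))
  structure(out, n_peaks = length(peaks), undefined_windows = undef,
            class = c("correlation_curve", "data.frame"))
}

#' Compare weak-site abundance between occupancy-ranked peak halves
#'
#' Ranks peaks by ChIP score (ties broken lexically by `region_id` so the
#' split is deterministic), assigns the top `floor(n/2)` peaks to the top
#' half (odd n puts the extra peak in the bottom half), and compares the
#' per-peak weak-site counts between halves with a two-sided Student's
#' t-test (pooled variance by default; Welch via `var_equal = FALSE`).
#' When both halves are constant with identical means the test degenerates
#' to t = 0, p = 1; constant halves with unequal means give t = +/-Inf,
#' p = 0.
#'
#' @param peaks list of [peak_region()] (>= 4).
#' @param window_length window (bp) passed to [count_weak_sites()].
#' @param var_equal pooled-variance t-test (TRUE, default) or Welch.
#' @return A list: `mean_top`, `mean_bottom`, `t_statistic`, `p_value`,
#'   plus the per-half count vectors `counts_top`, `counts_bottom` and the
#'   data.frame `assignment` (region_id, chip_score, half).
#' @export
compare_ranked_halves <- function(peaks, window_length = 500,
                                  var_equal = TRUE) {
  if (length(peaks) < 4L) stop("need at least 4 peaks to compare halves")
  scores <- vapply(peaks, `[[`, numeric(1), "chip_score")
  ids <- vapply(peaks, `[[`, character(1), "region_id")
  ord <- order(-scores, ids)
  n_top <- length(peaks) %/% 2L
  half <- rep("bottom", length(peaks))
  half[ord[seq_len(n_top)]] <- "top"
  counts <- vapply(peaks, count_weak_sites, numeric(1),
                   window_length = window_length)
  top <- counts[half == "top"]
  bottom <- counts[half == "bottom"]
  if (var(top) == 0 && var(bottom) == 0) {
    delta <- mean(top) - mean(bottom)
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
    p_val <- if (delta == 0) 1 else 0
  } else {
    tt <- t.test(top, bottom, var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  }
  list(mean_top = mean(top), mean_bottom = mean(bottom),
       t_statistic = t_stat, p_value = p_val,
       counts_top = unname(top), counts_bottom = unname(bottom),
       assignment = data.frame(region_id = ids, chip_score = scores,
                               weak_sites = unname(counts), half = half,
                               stringsAsFactors = FALSE))
}
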