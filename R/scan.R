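# Designation of kB sites: table membership + degenerate-consensus matching.

# IUPAC subset used by the kB consensus
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T")
)

#' Scanning configuration
#'
#' Parameters governing kB-site designation. The defaults encode the
#' classical kB consensus GGGRNNYYCC (R = A/G, Y = C/T, N = any), tolerance
#' of up to three consensus deviations, and the strong/weak affinity
#' boundary at Z = 6 (corresponding to an in vitro dissociation constant of
#' roughly 300 nM in the calibration this boundary derives from).
#'
#' @param consensus degenerate 10-mer over A/C/G/T/R/Y/N.
#' @param max_mismatches maximum tolerated consensus deviations (>= 0).
#' @param strong_threshold Z-score at and above which a site is "strong".
#' @param scan_both_strands scan the reverse complement as well?
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(consensus = "GGGRNNYYCC", max_mismatches = 3L,
                        strong_threshold = 6.0, scan_both_strands = TRUE) {
  consensus <- toupper(consensus)
  check_kmer(consensus, alphabet = names(IUPAC_SETS), what = "consensus")
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0L)
    stop("max_mismatches must be a non-negative integer")
  if (!is.finite(strong_threshold)) stop("strong_threshold must be finite")
  structure(list(consensus = consensus, max_mismatches = max_mismatches,
                 strong_threshold = as.numeric(strong_threshold),
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "scan_config")
}

#' Count deviations of a 10-mer from a degenerate consensus
#'
#' A position counts as a mismatch when the 10-mer base is outside the set
#' the consensus symbol allows (R = \{A,G\}, Y = \{C,T\}, N = any base).
#'
#' @param kmer character vector of 10-mers over A/C/G/T.
#' @param consensus degenerate 10-mer over A/C/G/T/R/Y/N.
#' @return Integer vector of mismatch counts.
#' @examples
#' consensus_mismatches("GGGAAATTCC")              # 0: consensus-conformant
#' consensus_mismatches("GGGCTTTTCC")              # 1: C at the R position
#' @export
consensus_mismatches <- function(kmer, consensus = "GGGRNNYYCC") {
  consensus <- toupper(consensus)
  check_kmer(consensus, alphabet = names(IUPAC_SETS), what = "consensus")
  kmer <- toupper(kmer)
  for (k in kmer) check_kmer(k)
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  allowed <- IUPAC_SETS[cons]
  vapply(kmer, function(k) {
    bases <- strsplit(k, "", fixed = TRUE)[[1]]
    sum(vapply(seq_len(10L), function(i) !(bases[i] %in% allowed[[i]]),
               logical(1)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Classify a site Z-score as strong or weak
#'
#' Sites at or above the boundary are strong; the boundary itself is
#' assigned to the strong class so that the strong set is closed.
#'
#' @param z_score finite numeric vector of affinity Z-scores.
#' @param strong_threshold the strong/weak boundary (default 6 Z-units).
#' @return Character vector, `"strong"` or `"weak"`.
#' @examples
#' classify_site(c(14, 5.8, 6))   # strong, weak, strong
#' @export
classify_site <- function(z_score, strong_threshold = 6.0) {
  if (any(!is.finite(z_score))) stop("z_score must be finite")
  if (!is.finite(strong_threshold)) stop("strong_threshold must be finite")
  ifelse(z_score >= strong_threshold, "strong", "weak")
}

# internal: fast vectorised mismatch count for candidate kmers only;
# assumes kmers already validated (came out of the scanned sequence)
mismatches_fast <- function(kmers, cons_chars, allowed) {
  if (!length(kmers)) return(integer(0))
  m <- matrix(unlist(strsplit(kmers, "", fixed = TRUE), use.names = FALSE),
              nrow = length(kmers), byrow = TRUE)
  mm <- integer(length(kmers))
  for (i in seq_len(10L)) mm <- mm + !(m[, i] %in% allowed[[i]])
  mm
}

#' Designate kB sites in a DNA sequence
#'
#' Every 10-bp window on the plus strand (and, by default, its reverse
#' complement) is tested. A window is designated a kB site when its 10-mer
#' is present in the affinity table with Z > 0 and deviates from the
#' degenerate consensus at no more than `max_mismatches` positions. Windows
#' containing N are skipped. When both strands of the same window qualify,
#' the strand with the larger Z is reported (ties go to the plus strand), so
#' near-palindromic sites are not double-counted. Overlapping sites at
#' different starts are all reported.
#'
#' @param sequence DNA string over A/C/G/T/N (case-insensitive).
#' @param table a [zscore_table()].
#' @param config a [scan_config()].
#' @return A data.frame with one row per designated site, sorted by `start`:
#'   `start` (0-based, half-open `[start, start+10)`), `center`
#'   (`start + 4.5`), `strand`, `kmer` (as read 5'->3' on its strand),
#'   `z_score`, `mismatches`, `site_class`.
#' @examples
#' tbl <- zscore_table("GGGAAATTCC", 14)
#' designate_sites(paste0(strrep("T", 8), "GGGAAATTCC", strrep("T", 8)), tbl)
#' @export
designate_sites <- function(sequence, table, config = scan_config()) {
  stopifnot(inherits(table, "zscore_table"), inherits(config, "scan_config"))
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L) stop("`sequence` must be a single string")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0)
    stop("illegal character '", substr(sequence, bad, bad),
         "' at position ", bad, " of sequence")
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), center = numeric(0),
                      strand = character(0), kmer = character(0),
                      z_score = numeric(0), mismatches = integer(0),
                      site_class = character(0), stringsAsFactors = FALSE)
  if (n < 10L || !length(table$entries)) return(empty)

  starts0 <- 0:(n - 10L)
  win_p <- substring(sequence, starts0 + 1L, starts0 + 10L)
  clean <- !grepl("N", win_p, fixed = TRUE)

  ent <- table$entries
  cons_chars <- strsplit(config$consensus, "", fixed = TRUE)[[1]]
  allowed <- IUPAC_SETS[cons_chars]

  score_strand <- function(wins) {
    z <- unname(ent[match(wins, names(ent))])
    cand <- clean & !is.na(z) & z > 0
    if (any(cand)) {
      mm <- rep(NA_integer_, length(wins))
      mm[cand] <- mismatches_fast(wins[cand], cons_chars, allowed)
      cand <- cand & !is.na(mm) & mm <= config$max_mismatches
    } else mm <- rep(NA_integer_, length(wins))
    list(z = z, mm = mm, ok = cand)
  }

  p <- score_strand(win_p)
  if (config$scan_both_strands) {
    rc_seq <- rev_comp(sequence)
    # reverse complement of the window [i, i+10) in 1-based rc coordinates
    win_m <- substring(rc_seq, n - starts0 - 9L, n - starts0)
    m <- score_strand(win_m)
  } else {
    m <- list(z = rep(NA_real_, length(win_p)),
              mm = rep(NA_integer_, length(win_p)),
              ok = rep(FALSE, length(win_p)))
    win_m <- rep(NA_character_, length(win_p))
  }

  take_p <- p$ok & (!m$ok | p$z >= m$z)
  take_m <- m$ok & !take_p
  keep <- take_p | take_m
  if (!any(keep)) return(empty)

  strand <- ifelse(take_p[keep], "+", "-")
  kmer <- ifelse(take_p[keep], win_p[keep], win_m[keep])
  z <- ifelse(take_p[keep], p$z[keep], m$z[keep])
  mm <- ifelse(take_p[keep], p$mm[keep], m$mm[keep])
  out <- data.frame(start = starts0[keep], center = starts0[keep] + 4.5,
                    strand = strand, kmer = kmer, z_score = z,
                    mismatches = as.integer(mm),
                    site_class = classify_site(z, config$strong_threshold),
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}
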