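# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the package internals: their own
# reverse complement, their own IUPAC matching, plain-loop arithmetic.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_mismatches <- function(kmer, consensus = "GGGRNNYYCC") {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T"))
  kb <- strsplit(kmer, "")[[1]]
  cb <- strsplit(consensus, "")[[1]]
  n <- 0L
  for (i in 1:10) if (!(kb[i] %in% sets[[cb[i]]])) n <- n + 1L
  n
}

# brute-force window enumeration applying the membership / positivity /
# mismatch rules and the larger-Z strand collapse (tie -> plus strand)
oracle_designate <- function(sequence, entries, max_mismatches = 3L,
                             strong_threshold = 6, both_strands = TRUE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  rows <- list()
  if (n >= 10) for (s0 in 0:(n - 10)) {
    w <- substr(sequence, s0 + 1, s0 + 10)
    if (grepl("N", w, fixed = TRUE)) next
    zp <- unname(entries[w])
    ok_p <- !is.na(zp) && zp > 0 && oracle_mismatches(w) <= max_mismatches
    wm <- oracle_revcomp(w)
    zm <- unname(entries[wm])
    ok_m <- both_strands && !is.na(zm) && zm > 0 &&
      oracle_mismatches(wm) <= max_mismatches
    if (!ok_p && !ok_m) next
    if (ok_p && (!ok_m || zp >= zm)) {
      rows[[length(rows) + 1]] <- data.frame(
        start = s0, strand = "+", kmer = w, z_score = zp,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        start = s0, strand = "-", kmer = wm, z_score = zm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), strand = character(0),
                      kmer = character(0), z_score = numeric(0),
                      site_class = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$site_class <- ifelse(out$z_score >= strong_threshold, "strong", "weak")
  out[order(out$start), ]
}

# textbook Pearson correlation from sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# brute-force enrichment pipeline on a plain count matrix
oracle_enriched <- function(counts, classes, min_total = 5, z_margin = 0.5) {
  keep <- apply(counts, 1, sum) >= min_total
  m <- counts[keep, , drop = FALSE]
  norm <- m
  for (j in seq_len(ncol(m))) norm[, j] <- m[, j] / sum(m[, j])
  z <- norm
  for (i in seq_len(nrow(norm))) {
    mu <- mean(norm[i, ])
    s <- sqrt(sum((norm[i, ] - mu)^2) / (ncol(norm) - 1))
    z[i, ] <- if (s == 0) 0 else (norm[i, ] - mu) / s
  }
  score <- numeric(nrow(z))
  for (i in seq_len(nrow(z)))
    score[i] <- mean(z[i, classes == "experimental"]) -
      mean(z[i, classes == "control"])
  names(score) <- rownames(m)
  list(retained = rownames(m), score = score, passed = score > z_margin)
}

# peak built from a bare site list (no sequence), for hand-constructed cases
make_peak <- function(starts, z, chip_score, id = "pk", strand = NULL,
                      len = 1001, strong_threshold = 6) {
  sites <- data.frame(
    start = starts, center = starts + 4.5,
    strand = strand %||% rep("+", length(starts)),
    kmer = rep("GGGAAATTCC", length(starts)),
    z_score = z, mismatches = 0L,
    site_class = ifelse(z >= strong_threshold, "strong", "weak"),
    stringsAsFactors = FALSE)
  peak_region(id, chip_score = chip_score, sites = sites, region_length = len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
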