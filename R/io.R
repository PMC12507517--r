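# Readers and writers for the plain-text interchange formats: FASTA,
# narrowPeak/BED6, Z-score tables, site tables, curves, pulldown matrices.
# All genomic coordinates on disk are 0-based half-open, matching the
# in-memory convention bit for bit.

#' Read named DNA sequences from a FASTA file
#'
#' Sequences are uppercased; lowercase input and CRLF line endings are
#' tolerated. Only A/C/G/T/N are accepted.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("FASTA file is empty: ", path)
  seqs <- toupper(gsub("[\r ]", "", as.character(set)))
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms))
    stop("duplicate FASTA record name: ", nms[duplicated(nms)][1])
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[i])
    if (bad > 0)
      stop("record '", nms[i], "' has illegal character '",
           substr(seqs[i], bad, bad), "' at position ", bad)
  }
  names(seqs) <- nms
  seqs
}

#' Write named DNA sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(toupper(sequences))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read ChIP peak regions from narrowPeak or BED6
#'
#' Both formats are tab-separated with 0-based half-open intervals; the
#' score column (5) carries the occupancy score. In narrowPeak, a summit
#' offset (column 10) of -1 means "no summit" and is returned as `NA`.
#'
#' @param path file path.
#' @param format `"narrowPeak"` (10 columns) or `"bed6"` (6 columns).
#' @return data.frame with `region_id`, `chrom`, `start`, `end`,
#'   `chip_score`, `strand`, and (narrowPeak only) `summit`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("peak file is empty: ", path)
  ncol_need <- if (format == "narrowPeak") 10L else 6L
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (length(f) < ncol_need)
      stop("line ", i, ": expected ", ncol_need, " tab-separated fields, got ",
           length(f))
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    score <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end))
      stop("line ", i, ": non-numeric interval bounds")
    if (start >= end)
      stop("line ", i, ": start (", f[2], ") must be < end (", f[3], ")")
    if (is.na(score))
      stop("line ", i, ": non-numeric score '", f[5], "'")
    row <- data.frame(region_id = f[4], chrom = f[1], start = start,
                      end = end, chip_score = score, strand = f[6],
                      stringsAsFactors = FALSE)
    if (format == "narrowPeak") {
      summit <- suppressWarnings(as.numeric(f[10]))
      if (is.na(summit)) stop("line ", i, ": non-numeric summit '", f[10], "'")
      row$summit <- if (summit < 0) NA_real_ else summit
    }
    row
  })
  do.call(rbind, out)
}

#' Write peak regions as narrowPeak
#'
#' @param peaks data.frame with at least `chrom`, `start`, `end`,
#'   `region_id`, `chip_score`; optional `strand` and `summit` (`NA`
#'   written as -1).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  strand <- peaks$strand %||% rep(".", nrow(peaks))
  summit <- peaks$summit %||% rep(NA_real_, nrow(peaks))
  summit[is.na(summit)] <- -1
  df <- data.frame(peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), peaks$region_id,
                   peaks$chip_score, strand, 0, -1, -1, as.integer(summit))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an affinity Z-score table from TSV
#'
#' Expects a header line `kmer<TAB>zscore`.
#'
#' @param path TSV path.
#' @param source_label provenance tag (defaults to the file name).
#' @return A [zscore_table()].
#' @export
read_zscore_table <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("Z-score table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("kmer", "zscore") %in% names(df)))
    stop("Z-score table needs columns 'kmer' and 'zscore'")
  zscore_table(df$kmer, df$zscore, source_label = source_label)
}

#' Write an affinity Z-score table to TSV
#'
#' @param table a [zscore_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zscore_table <- function(table, path) {
  stopifnot(inherits(table, "zscore_table"))
  df <- data.frame(kmer = names(table$entries),
                   zscore = unname(table$entries))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export designated sites as BED6 and as a rich TSV
#'
#' The BED score column is the Z-score linearly rescaled to 0-1000
#' (`round(50 * z)`, capped), since BED scores are integer-bounded; the
#' companion TSV keeps the exact values.
#'
#' @param sites data.frame from [designate_sites()].
#' @param chrom chromosome / sequence name for the BED lines.
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip).
#' @param offset value added to `start` to lift region-relative coordinates
#'   to chromosome coordinates (default 0).
#' @return Invisibly, a list of the written paths.
#' @export
write_sites <- function(sites, chrom, bed_path = NULL, tsv_path = NULL,
                        offset = 0) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom, as.integer(sites$start + offset),
                      as.integer(sites$start + offset + 10L), sites$kmer,
                      pmin(1000L, pmax(0L, as.integer(round(50 * sites$z_score)))),
                      sites$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    df <- sites
    df$chrom <- chrom
    df$start <- df$start + offset
    df <- df[, c("chrom", "start", "strand", "kmer", "z_score",
                 "mismatches", "site_class")]
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}

#' Write a correlation curve to TSV
#'
#' Columns `window_length`, `r_all`, `r_strong_only`, `n`; undefined
#' correlations are written as `NA`, never dropped.
#'
#' @param curve a [correlation_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  df$n <- attr(curve, "n_peaks")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pulldown count matrix and its experiment design from TSV
#'
#' @param counts_path TSV: first column protein ID (header `protein`),
#'   remaining columns one per experiment label.
#' @param design_path TSV with columns `label`, `class`, `condition`,
#'   `replicate`.
#' @return A [pulldown_matrix()].
#' @export
read_pulldown <- function(counts_path, design_path) {
  cdf <- read.delim(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(cdf)[1] != "protein")
    stop("first column of the count matrix must be 'protein'")
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$protein
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  pulldown_matrix(counts, design)
}

#' Write a pulldown matrix and design to TSV
#'
#' @param matrix a [pulldown_matrix()].
#' @param counts_path,design_path output paths.
#' @return Invisibly, a list of the written paths.
#' @export
write_pulldown <- function(matrix, counts_path, design_path) {
  stopifnot(inherits(matrix, "pulldown_matrix"))
  cdf <- data.frame(protein = rownames(matrix$counts), matrix$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cdf, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(matrix$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(counts = counts_path, design = design_path))
}

#' Write the full enrichment result to TSV
#'
#' One row per retained protein: normalized counts, Z-scores, enrichment
#' score, pass flag, and (when clustered) the cluster label.
#'
#' @param result an `enrichment_result` from [pulldown_enrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  stopifnot(inherits(result, "enrichment_result"))
  labs <- colnames(result$normalized)
  df <- data.frame(protein = rownames(result$normalized),
                   stringsAsFactors = FALSE)
  norm <- result$normalized
  colnames(norm) <- paste0("norm_", labs)
  zs <- result$zscores
  colnames(zs) <- paste0("z_", labs)
  df <- cbind(df, norm, zs)
  df$enrichment_score <- unname(result$enrichment_score)
  df$passed <- unname(result$passed)
  if (!is.null(result$clusters)) df$cluster <- unname(result$clusters)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
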