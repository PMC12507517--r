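#' Affinity Z-score lookup table for 10-mers
#'
#' A `zscore_table` maps 10-bp sequences (uppercase A/C/G/T, read 5'->3') to
#' dimensionless binding-affinity Z-scores of the kind measured for kB sites
#' in protein-binding-microarray experiments. A 10-mer and its reverse
#' complement may both be present (the two strands of a site need not score
#' equally); each 10-mer appears at most once. Entries with Z <= 0 are kept
#' in the table but are never designated as sites by [designate_sites()].
#'
#' @param kmers character vector of 10-mers (case-insensitive, A/C/G/T only).
#' @param z_scores numeric vector of affinity Z-scores, same length.
#' @param source_label free-text provenance tag stored with the table.
#' @return An object of class `zscore_table` with elements `entries`
#'   (named numeric vector) and `source_label`.
#' @examples
#' tbl <- zscore_table(c("GGGAAATTCC", "GGGAAGTTCC"), c(14, 5.8))
#' zscore_lookup(tbl, "GGGAAATTCC")
#' @export
zscore_table <- function(kmers, z_scores, source_label = "user") {
  kmers <- toupper(as.character(kmers))
  z_scores <- as.numeric(z_scores)
  if (length(kmers) != length(z_scores))
    stop("`kmers` and `z_scores` must have equal length")
  for (i in seq_along(kmers)) check_kmer(kmers[i], what = sprintf("kmer %d", i))
  if (anyDuplicated(kmers))
    stop("duplicate 10-mer in table: ", kmers[duplicated(kmers)][1])
  if (any(!is.finite(z_scores)))
    stop("all z_scores must be finite")
  entries <- z_scores
  names(entries) <- kmers
  structure(list(entries = entries, source_label = as.character(source_label)),
            class = "zscore_table")
}

# internal: validate a fixed-width kmer over an alphabet, naming the first
# offending position in the error
check_kmer <- function(kmer, width = 10L, alphabet = c("A", "C", "G", "T"),
                       what = "kmer") {
  if (!is.character(kmer) || length(kmer) != 1L || is.na(kmer))
    stop(what, " must be a single string")
  if (nchar(kmer) != width)
    stop(what, " '", kmer, "' has length ", nchar(kmer), ", expected ", width)
  bases <- strsplit(kmer, "", fixed = TRUE)[[1]]
  bad <- which(!bases %in% alphabet)
  if (length(bad))
    stop(what, " '", kmer, "' has illegal symbol '", bases[bad[1]],
         "' at position ", bad[1])
  invisible(kmer)
}

#' @export
print.zscore_table <- function(x, ...) {
  cat("Affinity Z-score table (", length(x$entries), " 10-mers, source: ",
      x$source_label, ")\n", sep = "")
  z <- x$entries
  cat(sprintf("  Z range: %.2f .. %.2f; %d entries with Z > 0\n",
              min(z), max(z), sum(z > 0)))
  invisible(x)
}

#' @export
length.zscore_table <- function(x) length(x$entries)

#' Look up the Z-score of one or more 10-mers
#'
#' @param table a [zscore_table()].
#' @param kmers character vector of 10-mers.
#' @return Numeric vector; `NA` where a 10-mer is absent from the table.
#' @export
zscore_lookup <- function(table, kmers) {
  stopifnot(inherits(table, "zscore_table"))
  unname(table$entries[match(toupper(kmers), names(table$entries))])
}
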