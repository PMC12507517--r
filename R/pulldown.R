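# Enrichment scoring of DNA-pulldown mass-spectrometry peptide counts:
# low-count exclusion, per-pulldown normalization, per-protein Z-scores,
# filtering against the control-DNA pulldown, optional k-means row clusters.

#' Construct a DNA-pulldown peptide-count matrix
#'
#' @param counts numeric matrix of total peptide counts, proteins in rows
#'   (rownames = protein identifiers), pulldown experiments in columns
#'   (colnames = experiment labels). Counts must be non-negative; averaged
#'   replicates may be fractional.
#' @param design data.frame with one row per experiment: `label` (matching
#'   the column names), `class` (`"experimental"` or `"control"`),
#'   `condition` (e.g. probe x timepoint) and `replicate` (index). At least
#'   one control experiment is required.
#' @return An object of class `pulldown_matrix`.
#' @export
pulldown_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have protein rownames and experiment colnames")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate protein identifier: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate experiment label: ",
         colnames(counts)[duplicated(colnames(counts))][1])
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("label", "class", "condition", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(design$label, colnames(counts)))
    stop("design labels must match count-matrix column names")
  design <- design[match(colnames(counts), design$label), , drop = FALSE]
  if (!all(design$class %in% c("experimental", "control")))
    stop("design class must be 'experimental' or 'control'")
  if (!any(design$class == "control"))
    stop("at least one control-tagged experiment is required")
  structure(list(counts = counts, design = design), class = "pulldown_matrix")
}

#' @export
print.pulldown_matrix <- function(x, ...) {
  cat(sprintf("Pulldown matrix: %d proteins x %d experiments (%d experimental, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$design$class == "experimental"),
              sum(x$design$class == "control")))
  invisible(x)
}

#' Exclude proteins with low total peptide counts
#'
#' Removes proteins whose peptide count summed over all experiments is
#' below `min_total` ("fewer than five" by default; a total of exactly five
#' is retained). Row order of survivors is preserved, and the operation is
#' idempotent.
#'
#' @param matrix a [pulldown_matrix()].
#' @param min_total minimum retained total count (default 5).
#' @return A filtered `pulldown_matrix`.
#' @export
filter_low_counts <- function(matrix, min_total = 5) {
  stopifnot(inherits(matrix, "pulldown_matrix"))
  keep <- rowSums(matrix$counts) >= min_total
  if (!any(keep))
    stop("all proteins fall below the total-count threshold of ", min_total)
  pulldown_matrix(matrix$counts[keep, , drop = FALSE], matrix$design)
}

#' Normalize peptide counts within each pulldown experiment
#'
#' Divides each column by its total so each experiment's normalized counts
#' sum to 1 over the retained proteins.
#'
#' @param matrix a [pulldown_matrix()].
#' @return Numeric matrix of fractions, same dimnames as the counts.
#' @export
normalize_counts <- function(matrix) {
  stopifnot(inherits(matrix, "pulldown_matrix"))
  totals <- colSums(matrix$counts)
  zero <- totals == 0
  if (any(zero))
    stop("experiment '", colnames(matrix$counts)[zero][1],
         "' has a zero peptide total; cannot normalize")
  sweep(matrix$counts, 2, totals, "/")
}

#' Per-protein Z-scores of normalized peptide counts
#'
#' By default each protein (row) is standardized across all experiments:
#' `z = (x - row mean) / row sd`, with the sample standard deviation
#' (denominator n - 1). Rows with zero variance become all-zero and are
#' flagged via the `constant_proteins` attribute. Per-experiment (column)
#' standardization is available with `by = "experiment"` but is not the
#' default reading of a "Z-score value for each protein".
#'
#' @param normalized matrix of normalized counts (from [normalize_counts()]).
#' @param by `"protein"` (row-wise, default) or `"experiment"` (column-wise).
#' @return Matrix of Z-scores with attribute `constant_proteins` (character
#'   vector of zero-variance rows, possibly empty).
#' @export
protein_zscores <- function(normalized, by = c("protein", "experiment")) {
  by <- match.arg(by)
  normalized <- as.matrix(normalized)
  if (ncol(normalized) < 2L)
    stop("Z-scores need at least 2 experiments")
  if (by == "experiment") normalized <- t(normalized)
  mu <- rowMeans(normalized)
  s <- apply(normalized, 1, sd)
  flat <- s == 0
  s[flat] <- 1  # constant rows map to zero
  z <- (normalized - mu) / s
  if (by == "experiment") z <- t(z)
  constant <- if (is.null(rownames(normalized))) as.character(which(flat))
              else rownames(normalized)[flat]
  if (any(flat))
    message("zero-variance row(s) set to Z = 0: ",
            paste(constant, collapse = ", "))
  structure(z, constant_proteins = constant)
}

#' Select proteins enriched in experimental versus control pulldowns
#'
#' The enrichment score of a protein is its mean Z over the experimental
#' pulldowns minus its mean Z over the control pulldowns; a protein passes
#' when the score strictly exceeds `z_margin` (a score of exactly the
#' margin does not pass).
#'
#' @param zscores matrix from [protein_zscores()].
#' @param design experiment design data.frame (see [pulldown_matrix()]),
#'   rows matching the columns of `zscores`.
#' @param z_margin enrichment margin (default 0.5).
#' @return List with `enrichment_score` (named numeric), `passed` (named
#'   logical) and `params`.
#' @export
select_enriched <- function(zscores, design, z_margin = 0.5) {
  zscores <- as.matrix(zscores)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (nrow(design) != ncol(zscores))
    stop("design must describe every z-score column")
  exp_cols <- design$class == "experimental"
  ctl_cols <- design$class == "control"
  if (!any(exp_cols)) stop("no experimental-tagged experiment")
  if (!any(ctl_cols)) stop("no control-tagged experiment")
  score <- rowMeans(zscores[, exp_cols, drop = FALSE]) -
    rowMeans(zscores[, ctl_cols, drop = FALSE])
  list(enrichment_score = score, passed = score > z_margin,
       params = list(z_margin = z_margin))
}

#' k-means clustering of protein Z-score rows
#'
#' Clusters the rows of a Z-score matrix with Euclidean k-means (up to 100
#' random restarts, seeded for reproducibility), as used to order heatmap
#' rows.
#'
#' @param zscores matrix of per-protein Z-scores.
#' @param k number of clusters, `1 <= k <= nrow(zscores)`.
#' @param seed integer seed for the restarts.
#' @param nstart number of restarts (capped at 100).
#' @return Integer cluster labels named by protein, with attributes
#'   `withinss` (per-cluster within sum of squares) and `tot_withinss`.
#' @export
cluster_rows <- function(zscores, k, seed = 1L, nstart = 100L) {
  zscores <- as.matrix(zscores)
  if (!is.finite(k) || k < 1L || k > nrow(zscores))
    stop("k must be between 1 and the number of proteins (", nrow(zscores), ")")
  nstart <- min(as.integer(nstart), 100L)
  if (k == nrow(zscores)) {
    # every row its own cluster: zero scatter, no iteration needed
    labels <- seq_len(nrow(zscores))
    names(labels) <- rownames(zscores)
    return(structure(labels, withinss = rep(0, k), tot_withinss = 0))
  }
  km <- withr::with_seed(as.integer(seed),
                         kmeans(zscores, centers = k, nstart = nstart))
  structure(km$cluster, withinss = km$withinss,
            tot_withinss = km$tot.withinss)
}

#' Average replicate pulldowns within each condition
#'
#' Collapses replicate columns of the same (class, condition) group by
#' averaging their raw counts — averaging happens before normalization, so
#' the collapsed matrix flows through the same pipeline. Averaged counts
#' may be fractional.
#'
#' @param matrix a [pulldown_matrix()].
#' @return A `pulldown_matrix` with one column per (class, condition) group
#'   and `replicate` set to 1.
#' @export
average_replicates <- function(matrix) {
  stopifnot(inherits(matrix, "pulldown_matrix"))
  d <- matrix$design
  grp <- paste(d$class, d$condition, sep = "|")
  groups <- unique(grp)
  counts <- vapply(groups, function(g)
    rowMeans(matrix$counts[, grp == g, drop = FALSE]),
    numeric(nrow(matrix$counts)))
  colnames(counts) <- vapply(groups, function(g)
    d$condition[grp == g][1], character(1))
  design <- data.frame(label = colnames(counts),
                       class = vapply(groups, function(g)
                         d$class[grp == g][1], character(1)),
                       condition = colnames(counts),
                       replicate = 1L, stringsAsFactors = FALSE)
  pulldown_matrix(counts, design)
}

#' Full pulldown-enrichment pipeline
#'
#' Runs the fixed pipeline: low-count exclusion, per-experiment
#' normalization, per-protein Z-scores, enrichment selection against the
#' control pulldown, and (optionally) k-means row clustering.
#'
#' @param matrix a [pulldown_matrix()].
#' @param min_total low-count exclusion threshold (default 5).
#' @param z_margin enrichment margin (default 0.5, strict).
#' @param by Z-score orientation, see [protein_zscores()].
#' @param k optional number of k-means clusters (default `NULL`: no
#'   clustering).
#' @param seed seed for the clustering restarts.
#' @return An object of class `enrichment_result`: `matrix` (filtered),
#'   `normalized`, `zscores`, `enrichment_score`, `passed`, `clusters`
#'   (or `NULL`), `params`.
#' @export
pulldown_enrichment <- function(matrix, min_total = 5, z_margin = 0.5,
                                by = "protein", k = NULL, seed = 1L) {
  filtered <- filter_low_counts(matrix, min_total)
  normalized <- normalize_counts(filtered)
  zs <- protein_zscores(normalized, by = by)
  sel <- select_enriched(zs, filtered$design, z_margin)
  clusters <- if (!is.null(k)) cluster_rows(zs, k, seed = seed) else NULL
  structure(list(matrix = filtered, normalized = normalized, zscores = zs,
                 enrichment_score = sel$enrichment_score, passed = sel$passed,
                 clusters = clusters,
                 params = list(min_total = min_total, z_margin = z_margin,
                               by = by, k = k, seed = seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Pulldown enrichment: %d proteins retained (total count >= %s), %d passed (score > %s)\n",
    nrow(x$matrix$counts), x$params$min_total, sum(x$passed),
    x$params$z_margin))
  invisible(x)
}
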