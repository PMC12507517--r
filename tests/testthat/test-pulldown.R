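# Pulldown enrichment: filtering, normalization, Z-scores, selection,
# clustering.

toy_matrix <- function() {
  counts <- matrix(c(10, 30,  5,  2,
                     20, 10,  8,  1,
                      8,  9, 12,  1,
                      2,  1,  1,  0),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("prot", 1:4),
                                   c("e1", "e2", "c1", "c2")))
  design <- data.frame(label = c("e1", "e2", "c1", "c2"),
                       class = c("experimental", "experimental",
                                 "control", "control"),
                       condition = c("Cxcl2", "Ccl2", "DM", "DM"),
                       replicate = c(1L, 1L, 1L, 2L),
                       stringsAsFactors = FALSE)
  pulldown_matrix(counts, design)
}

test_that("proteins with total counts fewer than the threshold are excluded", {
  pm <- toy_matrix()
  filt <- filter_low_counts(pm)          # prot4 totals 4 < 5
  expect_identical(rownames(filt$counts), paste0("prot", 1:3))
  # a total of exactly 5 is not 'fewer than five'
  counts5 <- matrix(c(5, 0, 0), nrow = 1,
                    dimnames = list("p", c("e1", "c1", "c2")))
  pm5 <- pulldown_matrix(counts5, data.frame(
    label = c("e1", "c1", "c2"), class = c("experimental", "control", "control"),
    condition = c("x", "DM", "DM"), replicate = c(1L, 1L, 2L)))
  expect_identical(rownames(filter_low_counts(pm5)$counts), "p")
  # min_total = 0 is the identity; filtering is idempotent
  expect_identical(filter_low_counts(pm, 0)$counts, pm$counts)
  expect_identical(filter_low_counts(filt)$counts, filt$counts)
  expect_error(filter_low_counts(pm, 1000), "below the total-count threshold")
})

test_that("normalization divides each pulldown by its peptide total", {
  pm <- toy_matrix()
  norm <- normalize_counts(pm)
  expect_equal(unname(norm[, "e1"]), c(10, 20, 8, 2) / 40)
  expect_equal(unname(colSums(norm)), rep(1, 4), tolerance = 1e-12)
  one <- pulldown_matrix(matrix(c(7, 3), nrow = 1,
                                dimnames = list("p", c("e1", "c1"))),
                         data.frame(label = c("e1", "c1"),
                                    class = c("experimental", "control"),
                                    condition = c("x", "DM"),
                                    replicate = 1L))
  expect_equal(unname(normalize_counts(one)[1, ]), c(1, 1))
  zero <- pulldown_matrix(matrix(c(1, 0), nrow = 1,
                                 dimnames = list("p", c("e1", "c1"))),
                          data.frame(label = c("e1", "c1"),
                                     class = c("experimental", "control"),
                                     condition = c("x", "DM"),
                                     replicate = 1L))
  expect_error(normalize_counts(zero), "'c1'")
})

test_that("per-protein Z-scores standardize rows with the sample sd", {
  z <- protein_zscores(matrix(c(0.1, 0.3), nrow = 1,
                              dimnames = list("p", c("a", "b"))))
  expect_equal(unname(z[1, ]), c(-0.7071068, 0.7071068), tolerance = 1e-6)
  # z-rows are centered
  m <- matrix(runif(12), nrow = 3,
              dimnames = list(paste0("p", 1:3), paste0("e", 1:4)))
  zz <- protein_zscores(m)
  expect_equal(unname(rowSums(zz)), rep(0, 3), tolerance = 1e-12)
  # constant rows flatten to zero and are flagged
  cm <- rbind(m, pflat = rep(0.25, 4))
  expect_message(zc <- protein_zscores(cm), "pflat")
  expect_equal(unname(zc["pflat", ]), rep(0, 4))
  expect_identical(attr(zc, "constant_proteins"), "pflat")
  expect_error(protein_zscores(m[, 1, drop = FALSE]), "at least 2")
})

test_that("enrichment is mean experimental Z minus mean control Z, strict margin", {
  z <- matrix(c(0.8, 0.8, 0.1, 0.1,
                0.6, 0.9, 0.2, 0.3), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("e1", "e2", "c1", "c2")))
  design <- toy_matrix()$design
  sel <- select_enriched(z, design)
  expect_equal(unname(sel$enrichment_score), c(0.7, 0.5))
  expect_identical(unname(sel$passed), c(TRUE, FALSE))  # 0.5 is not > 0.5
  bad <- design; bad$class <- "control"
  expect_error(select_enriched(z, bad), "experimental")
})

test_that("the full pipeline equals a brute-force recomputation on small matrices", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      np <- sample(4:10, 1)
      ne <- sample(2:4, 1); nc <- sample(1:2, 1)
      counts <- matrix(rpois(np * (ne + nc), 6), nrow = np,
                       dimnames = list(paste0("p", seq_len(np)),
                                       paste0("x", seq_len(ne + nc))))
      classes <- c(rep("experimental", ne), rep("control", nc))
      design <- data.frame(label = colnames(counts), class = classes,
                           condition = classes, replicate = 1L)
      pm <- pulldown_matrix(counts, design)
      res <- try(suppressMessages(pulldown_enrichment(pm)), silent = TRUE)
      want <- oracle_enriched(counts, classes)
      if (inherits(res, "try-error")) {
        expect_identical(length(want$retained), 0L)
      } else {
        expect_identical(rownames(res$matrix$counts), want$retained)
        expect_equal(res$enrichment_score, want$score, tolerance = 1e-12)
        expect_identical(res$passed, want$passed)
      }
    }
  })
})

test_that("planted enriched proteins are exactly the ones selected", {
  gp <- gen_pulldown(50, n_experimental = 4, n_control = 2,
                     n_enriched = 5, effect_size = 20, seed = 3)
  res <- pulldown_enrichment(gp$matrix)
  expect_identical(sort(names(res$passed)[res$passed]), gp$enriched)
})

test_that("k-means on separated centroids recovers the planted partition", {
  withr::with_seed(5, {
    a <- matrix(rnorm(5 * 4, mean = 3, sd = 0.1), nrow = 5)
    b <- matrix(rnorm(6 * 4, mean = -3, sd = 0.1), nrow = 6)
  })
  z <- rbind(a, b)
  rownames(z) <- paste0("p", 1:11)
  labels <- cluster_rows(z, k = 2, seed = 1)
  expect_identical(length(unique(labels[1:5])), 1L)
  expect_identical(length(unique(labels[6:11])), 1L)
  expect_false(labels[1] == labels[6])
  # singleton clusters have zero scatter
  single <- cluster_rows(z, k = 11, seed = 1)
  expect_equal(attr(single, "tot_withinss"), 0)
  whole <- cluster_rows(z, k = 1, seed = 1)
  expect_equal(attr(whole, "tot_withinss"),
               sum(scale(z, scale = FALSE)^2))
  expect_error(cluster_rows(z, k = 12), "between 1 and")
  expect_error(cluster_rows(z, k = 0), "between 1 and")
})

test_that("replicate averaging collapses conditions before normalization", {
  pm <- toy_matrix()
  avg <- average_replicates(pm)
  expect_identical(ncol(avg$counts), 3L)  # Cxcl2, Ccl2, DM
  expect_equal(unname(avg$counts[, "DM"]),
               unname(rowMeans(pm$counts[, c("c1", "c2")])))
  expect_identical(avg$design$class[avg$design$condition == "DM"], "control")
})
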