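# Cumulative Z-scores in dynamic windows, correlation curves, ranked halves.

test_that("the anchor is the maximal-Z site with deterministic tie-breaks", {
  sites <- data.frame(start = c(100, 300), center = c(104.5, 304.5),
                      strand = "+", kmer = "GGGAAATTCC",
                      z_score = c(14, 5.8), mismatches = 0L,
                      site_class = c("strong", "weak"),
                      stringsAsFactors = FALSE)
  expect_equal(select_anchor(sites, 250)$z_score, 14)
  tie <- data.frame(start = c(100, 260), center = c(104.5, 264.5),
                    strand = "+", kmer = "GGGAAATTCC", z_score = c(7, 7),
                    mismatches = 0L, site_class = "strong",
                    stringsAsFactors = FALSE)
  expect_equal(select_anchor(tie, 250)$start, 260)  # closer to center
  equi <- tie; equi$center <- c(240.5, 259.5)       # equidistant from 250
  expect_equal(select_anchor(equi, 250)$start, 100) # then smaller start
  expect_error(select_anchor(tie[0, ], 250), "no designated kB site")
})

test_that("cumulative Z sums site Z over the symmetric window", {
  # anchor Z=14 at center 499.5; weak Z=5.8 at +40 bp; weak Z=3.1 at +220 bp
  pk <- make_peak(starts = c(495, 535, 715), z = c(14, 5.8, 3.1),
                  chip_score = 10)
  expect_equal(cumulative_z(pk, 100), 19.8)   # only the +40 site is in +/-50
  expect_equal(cumulative_z(pk, 500), 22.9)   # all three
  expect_equal(cumulative_z(pk, 500, include_weak = FALSE), 14.0)
  expect_equal(cumulative_z(pk, 10), 14.0)    # anchor alone
  expect_error(cumulative_z(pk, 0), ">= 1")
})

test_that("a weak anchor always contributes, even with weak sites excluded", {
  pk <- make_peak(starts = c(495, 535), z = c(4, 3), chip_score = 1)
  expect_equal(pk$anchor$z_score, 4)
  expect_equal(cumulative_z(pk, 500, include_weak = FALSE), 4)
})

test_that("cumulative Z is monotone in window length and nested by class", {
  tbl <- gen_zscore_table(150, seed = 11)
  co <- gen_peak_cohort(cohort_spec(25, seed = 11), tbl)
  Ls <- seq(10, 500, by = 10)
  for (pk in co$peaks) {
    prof_all <- vapply(Ls, function(L) cumulative_z(pk, L), numeric(1))
    prof_str <- vapply(Ls, function(L) cumulative_z(pk, L, FALSE), numeric(1))
    expect_true(all(diff(prof_all) >= 0))
    expect_true(all(diff(prof_str) >= 0))
    expect_true(all(prof_str <= prof_all + 1e-12))
  }
})

test_that("weak sites around the anchor are counted within the window", {
  pk <- make_peak(starts = c(495, 505, 520), z = c(14, 3, 2), chip_score = 5)
  expect_identical(count_weak_sites(pk), 2L)
  solo <- make_peak(starts = 495, z = 14, chip_score = 5)
  expect_identical(count_weak_sites(solo), 0L)
  # 8 weak planted inside +/-250 of the anchor, 2 outside
  inside <- 495 + c(-120, -90, -60, -30, 30, 60, 90, 120)
  outside <- 495 + c(-300, 300)
  pk8 <- make_peak(starts = c(495, inside, outside),
                   z = c(14, rep(3, 10)), chip_score = 5)
  expect_identical(count_weak_sites(pk8, 500), 8L)
  expect_identical(count_weak_sites(pk8, 1000), 10L)
  # a weak anchor counts itself
  wpk <- make_peak(starts = c(495, 505), z = c(4, 3), chip_score = 1)
  expect_identical(count_weak_sites(wpk), 2L)
})

test_that("correlation curves match a textbook Pearson computation", {
  tbl <- gen_zscore_table(150, seed = 3)
  co <- gen_peak_cohort(cohort_spec(30, seed = 3, noise_sd = 3), tbl)
  Ls <- c(10, 150, 400)
  curve <- correlation_curve(co$peaks, Ls)
  scores <- vapply(co$peaks, `[[`, numeric(1), "chip_score")
  for (i in seq_along(Ls)) {
    cz <- vapply(co$peaks, cumulative_z, numeric(1), window_length = Ls[i])
    expect_equal(curve$r_all[i], oracle_pearson(scores, cz),
                 tolerance = 1e-12)
    cz_s <- vapply(co$peaks, cumulative_z, numeric(1),
                   window_length = Ls[i], include_weak = FALSE)
    expect_equal(curve$r_strong_only[i], oracle_pearson(scores, cz_s),
                 tolerance = 1e-12)
  }
  expect_identical(attr(curve, "n_peaks"), length(co$peaks))
})

test_that("perfect linear relation gives r = 1; zero variance gives NA", {
  pks <- lapply(1:6, function(i) {
    make_peak(starts = c(495, 495 + 20 * i), z = c(8 + i, 3), chip_score = 1,
              id = sprintf("p%d", i))
  })
  pks <- lapply(pks, function(p) {
    p$chip_score <- cumulative_z(p, 150)
    p
  })
  curve <- correlation_curve(pks, c(150))
  expect_equal(curve$r_all[1], 1, tolerance = 1e-12)
  flat <- lapply(pks, function(p) { p$chip_score <- 7; p })
  expect_message(curve_flat <- correlation_curve(flat, c(10, 150)),
                 "zero variance")
  expect_true(all(is.na(curve_flat$r_all)))
  expect_identical(attr(curve_flat, "undefined_windows"), c(10, 150))
  expect_error(correlation_curve(pks[1:2], c(150)), "at least 3")
  expect_error(correlation_curve(pks, c(150, 100)), "strictly increasing")
})

test_that("signal concentrated at the planted span is recovered at that span", {
  tbl <- gen_zscore_table(150, seed = 1)
  co <- gen_peak_cohort(cohort_spec(60, seed = 1, noise_sd = 0, span_bp = 150),
                        tbl)
  curve <- correlation_curve(co$peaks, c(10, 150))
  expect_true(curve$r_all[curve$window_length == 150] >=
                curve$r_all[curve$window_length == 10])
})

test_that("ranked-halves comparison reproduces the pooled-variance t-test", {
  # identical groups: degenerate t = 0, p = 1
  same <- lapply(1:4, function(i)
    make_peak(starts = c(495, 505, 515, 525), z = c(14, 3, 3, 3),
              chip_score = i, id = sprintf("p%d", i)))
  res <- compare_ranked_halves(same)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  # counts top {5,6,7} vs bottom {1,2,3}: hand-computed pooled t with 4 d.f.
  mk <- function(n_weak, chip, id)
    make_peak(starts = c(495, 495 + seq_len(n_weak) * 12),
              z = c(14, rep(3, n_weak)), chip_score = chip, id = id)
  pks <- list(mk(5, 30, "a"), mk(6, 20, "b"), mk(7, 10, "c"),
              mk(1, 3, "d"), mk(2, 2, "e"), mk(3, 1, "f"))
  res2 <- compare_ranked_halves(pks)
  expect_equal(res2$mean_top, 6)
  expect_equal(res2$mean_bottom, 2)
  expect_equal(res2$t_statistic, 4.899, tolerance = 1e-3)
  expect_lt(res2$p_value, 0.01)
  expect_equal(res2$p_value, 2 * pt(-abs(res2$t_statistic), df = 4),
               tolerance = 1e-6)
  expect_error(compare_ranked_halves(pks[1:3]), "at least 4")
})

test_that("score ties split deterministically and odd n favours the bottom half", {
  mk <- function(n_weak, chip, id)
    make_peak(starts = c(495, 495 + seq_len(n_weak) * 12),
              z = c(14, rep(3, n_weak)), chip_score = chip, id = id)
  pks <- list(mk(1, 5, "a"), mk(2, 5, "b"), mk(3, 5, "c"),
              mk(4, 5, "d"), mk(5, 5, "e"))
  res <- compare_ranked_halves(pks)
  # all scores tie: lexical order on region_id puts a,b on top; c,d,e bottom
  expect_identical(sum(res$assignment$half == "top"), 2L)
  expect_identical(res$assignment$half[res$assignment$region_id %in%
                                         c("a", "b")], rep("top", 2))
  expect_identical(res$counts_bottom, c(3, 4, 5))
})

test_that("planted weak-site excess in high-score peaks is detected", {
  tbl <- gen_zscore_table(150, seed = 7)
  co <- gen_peak_cohort(cohort_spec(60, seed = 7, noise_sd = 5), tbl)
  res <- compare_ranked_halves(co$peaks)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$mean_top, res$mean_bottom)
})
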