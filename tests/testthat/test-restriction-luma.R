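# Digestion forward model, virtual gels, pyrogram peaks and the LUMA
# estimator.

test_that("find_sites matches hand scans and an independent scanner", {
  expect_identical(find_sites("AAACCGGTT", "CCGG"), 3L)
  expect_identical(find_sites("CCGGCCGG", "CCGG"), c(0L, 4L))
  expect_identical(find_sites("ATATAT", "CCGG"), integer(0))
  # overlapping occurrences
  expect_identical(find_sites("AAAA", "AA"), c(0L, 1L, 2L))
  expect_error(find_sites("ACGT", "CN"), "motif")
  set.seed(13)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    expect_identical(find_sites(s, "CCGG"), brute_find_sites(s, "CCGG"))
  }
})

test_that("digestion reproduces hand-computed cuts and fragments", {
  g <- "AAACCGGAAACCGGAAA"             # CCGG at 3 and 10, length 17
  d <- digest(g, "MspI")
  expect_identical(d$cut_positions, c(4L, 11L))
  expect_identical(d$fragment_lengths, c(4L, 7L, 6L))

  meth_first <- structure(data.frame(pos = c(3L, 10L),
                                     methylated = c(TRUE, FALSE)),
                          class = c("methylome", "data.frame"))
  dh <- digest(g, "HpaII", meth_first)
  expect_identical(dh$cut_positions, 11L)
  expect_identical(dh$fragment_lengths, c(11L, 6L))

  expect_identical(digest("ATATATAT", "MspI")$fragment_lengths, 8L)

  bad <- structure(data.frame(pos = 5L, methylated = TRUE),
                   class = c("methylome", "data.frame"))
  expect_error(digest(g, "HpaII", bad), "not CCGG")
})

test_that("digestion conserves mass and nests HpaII cuts within MspI", {
  for (i in 1:100) {
    g <- simulate_genome_with_sites(2000, sample(0:20, 1), sample(0:10, 1),
                                    gc = 0.45, seed = 1000 + i)
    m <- assign_ccgg_methylation(g, runif(1), seed = 2000 + i)
    for (enz in c("HpaII", "MspI", "EcoRI", "HpaII+EcoRI", "MspI+EcoRI")) {
      d <- digest(g, enz, m)
      expect_identical(sum(d$fragment_lengths), g$length)
      expect_identical(length(d$fragment_lengths),
                       length(d$cut_positions) + 1L)
    }
    dh <- digest(g, "HpaII", m)
    dm <- digest(g, "MspI", m)
    expect_true(all(dh$cut_positions %in% dm$cut_positions))
    if (!any(m$methylated))
      expect_identical(dh$cut_positions, dm$cut_positions)
  }
})

test_that("virtual gel conserves mass and separates methylated genomes", {
  d <- digest("AAACCGGAAACCGGAAA", "MspI")
  gel <- virtual_gel(d, n_bins = 5)
  expect_equal(sum(gel$mass_per_bin), 17)
  expect_length(gel$bin_edges, 6L)

  one <- digest("ATATATAT", "MspI")
  g1 <- virtual_gel(one, n_bins = 4)
  expect_equal(sum(g1$mass_per_bin > 0), 1L)

  # fully methylated genome: HpaII mass sits at high MW, MspI spreads low
  g <- simulate_genome_with_sites(50000, 100, 0, seed = 5)
  m <- assign_ccgg_methylation(g, 1, seed = 5)
  mw <- function(enz) {
    fl <- as.numeric(digest(g, enz, m)$fragment_lengths)
    sum(fl * fl) / sum(fl)
  }
  expect_gt(mw("HpaII"), 10 * mw("MspI"))   # mass-weighted fragment size
  expect_error(virtual_gel(d, n_bins = 0), "n_bins")
})

test_that("pyrogram peaks follow the fill-in stoichiometry", {
  g <- simulate_genome_with_sites(2000, 2, 1, seed = 21)
  p <- pyrogram_from_digest(digest(g, "MspI+EcoRI"))
  expect_identical(p$dispensations,
                   c("dATP", "dGTP+dCTP", "dTTP", "H2O", "dGTP+dCTP",
                     "dATP", "dTTP"))
  lab <- p$dispensations
  expect_equal(sum(p$peaks[lab == "dGTP+dCTP"]), 8)   # 2 cuts x 2 ends x (C+G)
  expect_equal(sum(p$peaks[lab == "dATP"]), 4)
  expect_equal(sum(p$peaks[lab == "dTTP"]), 4)
  expect_equal(p$peaks[lab == "H2O"], 0)

  g0 <- simulate_genome_with_sites(2000, 0, 1, seed = 22)
  p0 <- pyrogram_from_digest(digest(g0, "MspI+EcoRI"))
  expect_true(all(p0$peaks[lab == "dGTP+dCTP"] == 0))

  ge <- simulate_genome_with_sites(2000, 2, 0, seed = 23)
  expect_warning(pyrogram_from_digest(digest(ge, "MspI+EcoRI")), "EcoRI")
  expect_error(pyrogram_from_digest(digest(g, "MspI")), "combined")
})

test_that("luma ratio and percent methylation follow the printed formulas", {
  g <- simulate_genome_with_sites(2000, 2, 1, seed = 21)
  p <- pyrogram_from_digest(digest(g, "MspI+EcoRI"))
  expect_equal(luma_ratio(p), 2)           # 8 / mean(4, 4)

  ge <- simulate_genome_with_sites(2000, 2, 0, seed = 23)
  pe <- suppressWarnings(pyrogram_from_digest(digest(ge, "MspI+EcoRI")))
  expect_error(luma_ratio(pe), "EcoRI")

  mk <- function(r_gc, r_at) {
    structure(list(reaction = "MspI+EcoRI",
                   dispensations = c("dATP", "dGTP+dCTP", "dTTP", "H2O",
                                     "dGTP+dCTP", "dATP", "dTTP"),
                   peaks = c(r_at / 2, r_gc / 2, r_at / 2, 0,
                             r_gc / 2, r_at / 2, r_at / 2)),
              class = "pyrogram")
  }
  # HpaII/EcoRI = 0.4, MspI/EcoRI = 2.0 -> 100 x (1 - 0.2) = 80
  res <- luma_percent_methylation(mk(0.8, 2), mk(4, 2))
  expect_equal(res$ratio_hpaii, 0.4)
  expect_equal(res$ratio_mspi, 2.0)
  expect_equal(res$percent_methylation, 80)
  # equal ratios -> 0 %; zero HpaII ratio -> 100 %
  expect_equal(luma_percent_methylation(mk(4, 2), mk(4, 2))$percent_methylation, 0)
  expect_equal(luma_percent_methylation(mk(0, 2), mk(4, 2))$percent_methylation, 100)
  expect_error(luma_percent_methylation(mk(4, 2), mk(0, 2)), "MspI|CCGG")
  # noisy raw percent outside [0, 100] is clamped but retained
  r <- suppressWarnings(luma_percent_methylation(mk(4.4, 2), mk(4, 2)))
  expect_equal(r$percent_methylation, 0)
  expect_lt(r$raw_percent, 0)
  expect_true(r$clamped)
})

test_that("noise-free LUMA chain recovers the methylated fraction exactly", {
  g <- simulate_genome_with_sites(30000, 60, 25, seed = 31)
  for (f in c(0, 0.25, 0.5, 1)) {
    m <- assign_ccgg_methylation(g, f, seed = 32)
    expect_equal(luma_simulate(g, m)$percent_methylation,
                 100 * round(f * 60) / 60)
  }
})

test_that("the estimator is invariant to the EcoRI site count", {
  out <- vapply(c(10L, 150L, 1000L), function(ne) {
    g <- simulate_genome_with_sites(150000, 100, ne, seed = 41)
    m <- assign_ccgg_methylation(g, 0.6, seed = 42)
    luma_simulate(g, m)$percent_methylation
  }, numeric(1))
  expect_equal(out, rep(60, 3))
})

test_that("fold decrease of percent methylation is a plain ratio", {
  expect_equal(fold_decrease(80, 40), 2)
  expect_error(fold_decrease(80, 0), "after")
})
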