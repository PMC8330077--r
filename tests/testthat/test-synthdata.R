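# Generators: determinism, motif exactness, calibration, forward-model
# closed forms.

test_that("transcriptome generator is seeded, sized and validated", {
  tx1 <- simulate_transcriptome(20, c(100, 300), gc = 0.4, target_oe = 0.7,
                                seed = 42)
  tx2 <- simulate_transcriptome(20, c(100, 300), gc = 0.4, target_oe = 0.7,
                                seed = 42)
  expect_identical(tx1, tx2)
  expect_length(tx1, 20L)
  expect_true(all(nchar(tx1) >= 100 & nchar(tx1) <= 300))
  expect_true(all(grepl("^[ACGT]+$", tx1)))
  expect_error(simulate_transcriptome(0, c(100, 300)), "positive")
  expect_error(simulate_transcriptome(5, c(100, 300), target_oe = 0),
               "target_oe")
  # CG transition probability would exceed 1
  expect_error(simulate_transcriptome(5, c(100, 300), gc = 0.9,
                                      target_oe = 3), "exceed|invalid")
})

test_that("transcriptome o/e calibration hits the target within 0.03", {
  for (t in c(0.3, 0.55, 1.0)) {
    tx <- simulate_transcriptome(5000, c(500, 3000), gc = 0.4,
                                 target_oe = t, seed = 100 + round(100 * t))
    oe <- cpg_oe(tx)$oe
    expect_lt(abs(mean(oe) - t), 0.03)
  }
})

test_that("genome generator places exactly the declared sites", {
  g <- simulate_genome_with_sites(200000, 300, 150, gc = 0.4, seed = 1)
  expect_identical(brute_find_sites(substr(g$seq, 1, 5000), "CCGG"),
                   g$ccgg_sites[g$ccgg_sites <= 5000 - 4])
  expect_identical(find_sites(g, "CCGG"), g$ccgg_sites)
  expect_identical(find_sites(g, "GAATTC"), g$ecori_sites)
  expect_length(g$ccgg_sites, 300L)
  expect_length(g$ecori_sites, 150L)

  g0 <- simulate_genome_with_sites(500, 0, 0, seed = 2)
  expect_length(find_sites(g0, "CCGG"), 0L)
  expect_length(find_sites(g0, "GAATTC"), 0L)

  expect_error(simulate_genome_with_sites(10, 3, 0), "placement")
})

test_that("methylation assignment uses exact counts and is seeded", {
  g <- simulate_genome_with_sites(20000, 300, 0, seed = 3)
  m0 <- assign_ccgg_methylation(g, 0, seed = 1)
  expect_equal(sum(m0$methylated), 0L)
  m1 <- assign_ccgg_methylation(g, 1, seed = 1)
  expect_equal(sum(m1$methylated), 300L)
  m8 <- assign_ccgg_methylation(g, 0.8, seed = 1)
  expect_equal(sum(m8$methylated), 240L)   # round(0.8 * 300)
  expect_identical(m8, assign_ccgg_methylation(g, 0.8, seed = 1))
  expect_true(all(m8$pos %in% g$ccgg_sites))
  expect_true(all(diff(m8$pos) > 0))
  expect_error(assign_ccgg_methylation(g, 1.2), "fraction")
})

test_that("bisulfite read simulator follows its closed form", {
  locus <- "AATCGATTCGGATCGAA"   # CpGs at C offsets 3, 8, 13
  rs <- simulate_bisulfite_reads(locus, c(1, 1, 1), 200,
                                 conversion_rate = 1, error_rate = 0,
                                 seed = 5)
  at <- function(reads, off) substr(reads, off + 1, off + 1)
  expect_true(all(at(rs$reads, 3) == "C"))
  rs0 <- simulate_bisulfite_reads(locus, c(0, 0, 0), 200,
                                  conversion_rate = 1, error_rate = 0,
                                  seed = 5)
  expect_true(all(at(rs0$reads, 3) == "T"))
  # expected C fraction (1 - m)(1 - c) + m with m = 0, c = 0.98
  rs2 <- simulate_bisulfite_reads(locus, c(0, 0, 0), 20000,
                                  conversion_rate = 0.98, error_rate = 0,
                                  seed = 6)
  cf <- mean(at(rs2$reads, 8) == "C")
  expect_lt(abs(cf - 0.02), 0.006)
  expect_error(simulate_bisulfite_reads(locus, c(1, 1), 10), "per_cpg_m")
  expect_error(simulate_bisulfite_reads("", c(1), 10), "locus")
})

test_that("pyrogram noise has unit mean, is seeded and clamps at zero", {
  g <- simulate_genome_with_sites(5000, 20, 10, seed = 7)
  p <- pyrogram_from_digest(digest(g, "MspI+EcoRI"))
  expect_identical(add_pyrogram_noise(p, 0, seed = 1)$peaks, p$peaks)
  n1 <- add_pyrogram_noise(p, 0.1, seed = 9)
  expect_identical(n1, add_pyrogram_noise(p, 0.1, seed = 9))
  expect_false(identical(n1$peaks, p$peaks))
  expect_true(all(add_pyrogram_noise(p, 5, seed = 2)$peaks >= 0))
  expect_error(add_pyrogram_noise(p, -0.1), "cv")
})

test_that("repertoire evolution is Dollo-compatible and seeded", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  fam <- paste0("f", 1:6)
  m0 <- simulate_repertoire_evolution(tr, fam, 2L, loss_rate = 0,
                                      dup_rate = 0, seed = 1)
  expect_true(all(m0 == 2L))
  m1 <- simulate_repertoire_evolution(tr, fam, 1L, loss_rate = 0.3,
                                      dup_rate = 0.2, seed = 4)
  expect_identical(m1, simulate_repertoire_evolution(tr, fam, 1L, 0.3, 0.2,
                                                     seed = 4))
  # losses only: Dollo recovers root presence for every family
  m2 <- simulate_repertoire_evolution(tr, fam, 1L, loss_rate = 0.4,
                                      dup_rate = 0, seed = 11)
  root <- length(tr$tip.label) + 1L
  left <- c("A", "B"); right <- c("C", "D", "E")
  for (f in fam) {
    pres <- setNames(m2[, f] >= 1, rownames(m2))
    if (!any(pres)) next
    rec <- dollo_reconstruct(tr, pres)
    # presence surviving on both sides of the root pins the origin (and
    # hence presence) back at the simulated root
    if (any(pres[left]) && any(pres[right])) {
      expect_identical(rec$origin_node, root)
      expect_identical(rec$node_states[root], 1L)
    }
  }
})
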