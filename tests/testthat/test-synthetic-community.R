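test_that("generator is deterministic given a seed and sensitive to it", {
  a <- generate_master_distribution(small_config(seed = 7))
  b <- generate_master_distribution(small_config(seed = 7))
  c <- generate_master_distribution(small_config(seed = 8))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("full detection and deep sequencing recover the whole master pool", {
  cfg <- community_config(n_otus_master = 120, n_replicates = 3,
                          per_replicate_depth = 5e6,
                          replicate_detection_prob = function(x) rep(1, length(x)),
                          seed = 3)
  tab <- generate_master_distribution(cfg)
  s <- summarize_distribution(tab)
  expect_true(all(s$per_replicate$richness == 120))
})

test_that("default calibration hits the sand-community richness targets", {
  # a thinned version of the 20-seed calibration check (full check in the
  # acceptance suite): union within +/-15% of 1200, per-replicate within
  # the reported spread around 543
  sums <- lapply(1:4, function(sd) {
    summarize_distribution(
      generate_master_distribution(community_config(seed = sd)))
  })
  union_mean <- mean(vapply(sums, `[[`, numeric(1), "union_richness"))
  rich_mean <- mean(vapply(sums, `[[`, numeric(1), "mean_richness"))
  expect_gt(union_mean, 1020); expect_lt(union_mean, 1380)
  expect_gt(rich_mean, 390); expect_lt(rich_mean, 696)
})

test_that("summarize_distribution counts richness and normalizes the histogram", {
  tab <- make_otu_table(rbind(c(5, 0), c(3, 2)))
  s <- summarize_distribution(tab)
  expect_equal(s$per_replicate$richness, c(2L, 1L))
  expect_equal(s$union_richness, 2L)
  expect_equal(sum(s$histogram$prop), 1)

  tab0 <- make_otu_table(rbind(c(4, 0), c(1, 0)))
  expect_equal(summarize_distribution(tab0)$per_replicate$richness, c(2L, 0L))
})

test_that("richness is monotone in sequencing depth", {
  mean_rich <- function(depth) {
    mean(vapply(1:6, function(sd) {
      cfg <- community_config(n_otus_master = 300, n_replicates = 2,
                              per_replicate_depth = depth, seed = sd)
      summarize_distribution(generate_master_distribution(cfg))$mean_richness
    }, numeric(1)))
  }
  expect_lte(mean_rich(500), mean_rich(5000))
  expect_lte(mean_rich(5000), mean_rich(50000))
})

test_that("generator rejects invalid configurations", {
  expect_error(community_config(per_replicate_depth = 0), "per_replicate_depth")
  expect_error(community_config(n_otus_master = -5), "n_otus_master")
  expect_error(community_config(lognormal_sigma = 0), "lognormal_sigma")
})

test_that("bead generator respects occupancy and degenerate category mixes", {
  solo <- generate_bead_table(100, occupancy_mix = 1, seed = 2)
  expect_true(all(dplyr::count(solo, bead_id)$n == 1))

  allng <- generate_bead_table(300, occupancy_mix = 0,
                               category_mix = c(1, 0, 0, 0), seed = 2)
  cats <- pair_category_table(pair_pbp(allng))
  expect_equal(cats$category[cats$n > 0], "both_no_growth")
})

test_that("bead generator recovers its category mix within sampling error", {
  mix <- c(both_no_growth = 0.25, one_not_growing = 0.30,
           balanced = 0.25, imbalanced = 0.20)
  beads <- generate_bead_table(5000, occupancy_mix = 0, category_mix = mix,
                               seed = 11)
  cats <- pair_category_table(pair_pbp(beads))
  got <- setNames(cats$pct / 100, cats$category)[names(mix)]
  se <- sqrt(mix * (1 - mix) / 5000)
  expect_true(all(abs(got - mix) < 3 * se))
})

test_that("bead generator validates its mixes", {
  expect_error(generate_bead_table(10, category_mix = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(generate_bead_table(10, occupancy_mix = 1.2), "occupancy_mix")
})

test_that("OTU and bead tables round-trip through TSV", {
  tab <- generate_master_distribution(small_config(seed = 5))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, f1)
  back <- read_otu_table(f1)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(otu_replicates(back), otu_replicates(tab))

  beads <- generate_bead_table(50, seed = 5)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_bead_table(beads, f2)
  back2 <- read_bead_table(f2)
  expect_equal(as.data.frame(back2), as.data.frame(beads), tolerance = 1e-12,
               ignore_attr = TRUE)
})
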