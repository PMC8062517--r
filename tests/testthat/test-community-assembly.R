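test_that("occurrence probabilities follow the percent normalization", {
  expect_equal(otu_probabilities(make_otu_table(cbind(c(50, 50))))$prob_pct,
               c(50, 50))
  expect_equal(otu_probabilities(make_otu_table(cbind(c(1, 3))))$prob_pct,
               c(25, 75))
  expect_equal(otu_probabilities(make_otu_table(cbind(c(1, 0, 0))))$prob_pct,
               c(100, 0, 0))
  p <- otu_probabilities(generate_master_distribution(small_config()), "rep2")
  expect_equal(sum(p$prob_pct), 100, tolerance = 1e-9)
  expect_error(otu_probabilities(make_otu_table(cbind(c(0, 0)))), "zero")
})

test_that("founder sampling matches the probability vector", {
  tab <- make_otu_table(cbind(c(10, 0)))
  p <- otu_probabilities(tab)
  f <- sample_founders(p, 1000, seed = 1)
  expect_true(all(f$otu_id == tab$otu_id[1]))

  p2 <- otu_probabilities(make_otu_table(cbind(c(5, 5))))
  f2 <- sample_founders(p2, 200000, seed = 2)
  freq <- mean(f2$otu_id == "OTU_001")
  se <- sqrt(0.25 / 200000)
  expect_lt(abs(freq - 0.5), 5 * se)

  expect_identical(sample_founders(p2, 500, seed = 9),
                   sample_founders(p2, 500, seed = 9))
  expect_error(sample_founders(p2, 0), "n_cells")
})

test_that("growth rates stay in bounds and are shared within an OTU", {
  tab <- generate_master_distribution(small_config(seed = 2))
  f <- sample_founders(otu_probabilities(tab), 2000, seed = 3)
  for (mode in c("random", "abundance_proportional")) {
    r <- assign_growth_rates(f, tab, mode = mode, seed = 4)
    expect_true(all(r$mu >= 0.01 & r$mu <= 0.6))
    per_otu <- tapply(r$mu, r$otu_id, function(x) length(unique(x)))
    expect_true(all(per_otu == 1))
  }
  expect_error(
    assign_growth_rates(tibble::tibble(otu_id = "nope"), tab),
    "unknown otu_id")
})

test_that("abundance-proportional mode couples rate to abundance", {
  tab <- make_otu_table(cbind(c(100000, 10)))
  f <- tibble::tibble(lineage_id = 1:2, otu_id = tab$otu_id)
  mus <- vapply(1:200, function(sd) {
    r <- assign_growth_rates(f, tab, mode = "abundance_proportional", seed = sd)
    r$mu
  }, numeric(2))
  expect_gt(mean(mus[1, ]), mean(mus[2, ]))
})

test_that("random mode draws a uniform rate distribution", {
  tab <- make_otu_table(cbind(rep(10, 500)))
  f <- tibble::tibble(lineage_id = 1:500, otu_id = tab$otu_id)
  r <- assign_growth_rates(f, tab, mode = "random", seed = 6)
  ks <- suppressWarnings(stats::ks.test(r$mu, "punif", 0.01, 0.6))
  expect_gt(ks$p.value, 0.01)
})

test_that("death models flag the expected lineages", {
  slow <- make_community(rep(0.2, 100))
  d1 <- apply_death(slow, death_model("fast_biased", 0.85, 0.25), seed = 1)
  expect_true(all(d1$alive))

  fast <- make_community(rep(0.5, 10000))
  d2 <- apply_death(fast, death_model("fast_biased", 0.85, 0.25), seed = 2)
  dead_frac <- mean(!d2$alive)
  se <- sqrt(0.85 * 0.15 / 10000)
  expect_lt(abs(dead_frac - 0.85), 3 * se)

  d3 <- apply_death(fast, death_model("random", 0), seed = 3)
  expect_true(all(d3$alive))
  d4 <- apply_death(fast, death_model("none"), seed = 3)
  expect_true(all(d4$alive))
})

test_that("bead partitioning hits the occupancy mix and conserves lineages", {
  lin <- make_community(runif(200000, 0.01, 0.6))
  com <- partition_beads(lin, fraction_single = 0.75, seed = 4)
  occ <- dplyr::count(com, bead_id)
  expect_true(all(occ$n %in% c(1L, 2L)))
  frac_single <- mean(occ$n == 1)
  se <- sqrt(0.75 * 0.25 / nrow(occ))
  expect_lt(abs(frac_single - 0.75), 3 * se)
  # conservation: same lineages, same OTU multiset
  expect_setequal(com$lineage_id, lin$lineage_id)
  expect_equal(sort(com$otu_id), sort(lin$otu_id))

  all_single <- partition_beads(make_community(runif(50, 0.01, 0.6)),
                                fraction_single = 1, seed = 1)
  expect_true(all(dplyr::count(all_single, bead_id)$n == 1))
  expect_error(partition_beads(lin, fraction_single = 1.5), "fraction_single")
})

test_that("assembled communities have the right shape per environment", {
  tab <- generate_master_distribution(small_config(seed = 9))
  liq <- assemble_community(tab, "liquid", n_cells = 1000, seed = 2)
  expect_equal(nrow(liq), 1000)
  expect_equal(community_environment(liq), "liquid")

  bead <- assemble_community(tab, "beads", n_cells = 1000,
                             death = death_model("fast_biased"), seed = 2)
  expect_equal(nrow(bead), 1000)
  expect_true(all(dplyr::count(bead, bead_id)$n %in% 1:2))
  expect_true(all(bead$mu >= 0.01 & bead$mu <= 0.6))
})

test_that("founder communities round-trip through TSV", {
  tab <- generate_master_distribution(small_config(seed = 9))
  com <- assemble_community(tab, "beads", n_cells = 300, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_community(com, f)
  back <- read_community(f)
  expect_equal(community_environment(back), "beads")
  expect_equal(as.data.frame(back), as.data.frame(com), ignore_attr = TRUE)
})
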