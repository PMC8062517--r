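test_that("single-occupancy penalty follows the abundance-inverse reading", {
  expect_equal(single_penalty(0.5, 10^1.2), 0.5)    # boundary: no penalty
  expect_equal(single_penalty(0.5, 1e6), 0.1)       # 0.5 * 1.2/6
  expect_equal(single_penalty(0.3, 10), 0.3)        # below boundary
  expect_error(single_penalty(0.3, 0.5), "abundance")
})

test_that("verbatim rate-argument penalty floors negative rates at zero", {
  m <- penalty_model("verbatim_eq3")
  expect_equal(single_penalty(0.1, 100, m), 0)      # 1.2/log10(0.1) = -12
  expect_equal(single_penalty(0.99, 100, m), 0)     # negative for any mu < 1
})

test_that("null scenario leaves rates untouched and dead lineages get zero", {
  com <- make_community(c(0.2, 0.3, 0.4, 0.5), alive = c(TRUE, TRUE, TRUE, FALSE),
                        bead_id = c("b1", "b2", "b2", "b3"),
                        environment = "beads")
  eff <- apply_scenario(com, interaction_scenario("null"),
                        penalty_model("off"), seed = 1)
  expect_equal(eff, c(0.2, 0.3, 0.4, 0))
})

test_that("positive-on-slow applies the slow-grower boost formula", {
  scen <- interaction_scenario("positive_on_slow", p_apply = 1)
  f <- pair_factors(scen, mu = c(0.01, 0.1), seed = 1)
  expect_equal(0.01 * f[1], -log(0.01) * 0.01, tolerance = 1e-12)  # ~0.0461
  expect_equal(0.1 * f[2], -log(0.1) * 0.1, tolerance = 1e-12)
})

test_that("biased-positive branch probabilities and support are honored", {
  scen <- interaction_scenario("biased_positive")
  f <- pair_factors(scen, mu = rep(0.3, 100000), seed = 2)
  expect_true(all(f >= 0.4 & f <= 1.4))
  se <- sqrt(0.4 * 0.6 / 100000)
  expect_lt(abs(mean(f < 0.6) - 0.4), 4 * se)
})

test_that("random scenario factors are uniform on their range", {
  scen <- interaction_scenario("random")
  f <- pair_factors(scen, mu = rep(0.3, 100000), seed = 3)
  expect_true(all(f >= 0.01 & f <= 1.25))
  ks <- suppressWarnings(stats::ks.test(f, "punif", 0.01, 1.25))
  expect_gt(ks$p.value, 0.01)
})

test_that("biased-negative penalizes slow growers twice as often as fast", {
  scen <- interaction_scenario("biased_negative")
  mu <- c(rep(0.3, 50000), rep(0.1, 50000))
  f <- pair_factors(scen, mu = mu, seed = 4)
  hit <- f < 1
  expect_true(all(f[hit] >= 0.01 & f[hit] <= 0.1))
  se <- sqrt(0.2 * 0.8 / 50000)
  expect_lt(abs(mean(hit[1:50000]) - 0.2), 4 * se)
  se2 <- sqrt(0.4 * 0.6 / 50000)
  expect_lt(abs(mean(hit[50001:100000]) - 0.4), 4 * se2)
})

test_that("bimodal factors split at the abundance threshold", {
  scen <- interaction_scenario("bimodal")
  la <- c(rep(2.0, 5000), rep(3.5, 5000))
  f <- pair_factors(scen, mu = rep(0.3, 10000), log10_abundance = la, seed = 5)
  expect_true(all(f[1:5000] >= 0.01 & f[1:5000] <= 1.0))
  expect_true(all(f[5001:10000] >= 1.0 & f[5001:10000] <= 2.2))
})

test_that("effective rates are capped at the global maximum", {
  com <- make_community(c(0.5, 0.5), bead_id = c("b1", "b1"),
                        environment = "beads")
  scen <- interaction_scenario("bimodal")  # high mode boosts up to 2.2x
  abund <- tibble::tibble(otu_id = com$otu_id, reads = c(1e4, 1e4))
  eff <- apply_scenario(com, scen, penalty_model("off"), abund, seed = 6)
  expect_true(all(eff <= 0.6))
  expect_true(all(eff > 0))
})

test_that("scenario ordering: biased negative <= null <= boosted scenarios", {
  tab <- generate_master_distribution(small_config(seed = 12))
  abund <- otu_probabilities(tab)
  com <- assemble_community(tab, "beads", n_cells = 4000, seed = 12)
  occ <- stats::ave(rep(1L, nrow(com)), com$bead_id, FUN = sum)
  mean_pair_rate <- function(name) {
    eff <- apply_scenario(com, interaction_scenario(name),
                          penalty_model("off"), abund, seed = 13)
    mean(eff[occ == 2 & com$alive])
  }
  expect_lte(mean_pair_rate("biased_negative"), mean_pair_rate("null"))
  expect_lte(mean_pair_rate("random"), mean_pair_rate("null"))
})

test_that("scenario registry rejects unknown names and bad parameters", {
  expect_error(interaction_scenario("cooperative"), "arg")
  expect_error(interaction_scenario("biased_positive", p_negative = 1.4),
               "probabilities")
  expect_error(interaction_scenario("random", range = c(2, 1)), "ranges")
})
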