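# Growth-rate modifiers: the single-occupancy penalty and the six pairwise
# interspecific-interaction scenarios. All scenarios act as multiplicative
# factors on the assigned maximum specific growth rates, drawn once at t = 0
# and clamped to the global 0.6 h^-1 cap.

SCENARIO_NAMES <- c("null", "bimodal", "biased_positive", "positive_on_slow",
                    "biased_negative", "random")

#' Interspecific-interaction scenario
#'
#' Returns the named scenario with its stochastic rule for drawing a
#' rate-modifying factor, independently for each partner in a paired bead:
#'
#' * `null`: factor 1 (no interactions).
#' * `bimodal`: rare and abundant community members behave differently —
#'   below the abundance threshold (log10 reads < 2.8) the factor is
#'   uniform on the low mode `[0.01, 1.0]`, above it on the high mode
#'   `[1.0, 2.2]`, so abundant members tend to be boosted.
#' * `biased_positive`: 40% chance of a lowering factor `U(0.4, 0.6)`, 60%
#'   chance of a modulating/boosting factor `U(0.6, 1.4)`.
#' * `positive_on_slow`: 40% chance that the rate is replaced by
#'   `-ln(mu) * mu`, which boosts slow growers (equivalently a factor of
#'   `-ln(mu)`); otherwise 1.
#' * `biased_negative`: fast growers (`mu > 0.15`) suffer a strong negative
#'   factor `U(0.01, 0.1)` with 20% probability, slower growers with 40%
#'   probability; otherwise 1.
#' * `random`: factor uniform on `[0.01, 1.25]` for everyone.
#'
#' All probabilities, ranges and thresholds are exposed as parameters.
#'
#' @param name Scenario name (see above).
#' @param ... Overrides for the scenario's default parameters.
#' @return A list of class `interaction_scenario`.
#' @export
#' @examples
#' interaction_scenario("biased_positive")
interaction_scenario <- function(name = SCENARIO_NAMES, ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    null = list(),
    bimodal = list(abund_threshold_log10 = 2.8,
                   low_range = c(0.01, 1.0), high_range = c(1.0, 2.2)),
    biased_positive = list(p_negative = 0.4,
                           negative_range = c(0.4, 0.6),
                           positive_range = c(0.6, 1.4)),
    positive_on_slow = list(p_apply = 0.4),
    biased_negative = list(mu_threshold = 0.15, p_fast = 0.2, p_slow = 0.4,
                           negative_range = c(0.01, 0.1)),
    random = list(range = c(0.01, 1.25))
  )
  pars <- modifyList(defaults, list(...))
  probs <- unlist(pars[grepl("^p_", names(pars))])
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0, 1]")
  for (rg in pars[grepl("range$", names(pars))]) {
    assert_that(length(rg) == 2 && rg[1] > 0 && rg[1] <= rg[2],
                "factor ranges must be positive and ordered")
  }
  structure(c(list(name = name), pars), class = "interaction_scenario")
}

#' Single-occupancy growth penalty model
#'
#' A founder growing alone in a bead is penalized. Two readings of the
#' penalty are available:
#'
#' * `abundance_inverse` (default): the penalty factor is inversely
#'   proportional to the OTU's initial abundance,
#'   `f = min(1, 1.2 / log10(abundance))` (no penalty below
#'   `10^1.2` reads), so initially abundant OTUs are slowed down.
#' * `verbatim_eq3`: the rate itself is replaced by `1.2 / log10(mu)`;
#'   since `mu < 1`, this is negative and floored to zero (no growth) —
#'   the literal reading in which slow growers are the penalized ones.
#' * `off`: no penalty.
#'
#' @param mode One of `"abundance_inverse"`, `"verbatim_eq3"`, `"off"`.
#' @param mu_cap Cap applied to the resulting rate, h^-1.
#' @return A list of class `penalty_model`.
#' @export
penalty_model <- function(mode = c("abundance_inverse", "verbatim_eq3", "off"),
                          mu_cap = MU_MAX) {
  mode <- match.arg(mode)
  structure(list(mode = mode, mu_cap = mu_cap), class = "penalty_model")
}

#' Apply the single-occupancy penalty to growth rates
#'
#' @param mu Assigned maximum specific growth rate(s), h^-1.
#' @param abundance Initial read abundance(s) of the lineage's OTU (>= 1).
#' @param model A [penalty_model()].
#' @return Effective rate(s), clamped to `[0, mu_cap]`.
#' @export
#' @examples
#' single_penalty(0.5, 1e6)  # 0.5 * 1.2/6 = 0.1
single_penalty <- function(mu, abundance, model = penalty_model()) {
  assert_that(all(abundance >= 1), "`abundance` must be >= 1")
  out <- switch(model$mode,
    off = mu,
    abundance_inverse = {
      la <- log10(abundance)
      f <- ifelse(la > 1.2, pmin(1, 1.2 / la), 1)
      mu * f
    },
    verbatim_eq3 = {
      v <- 1.2 / log10(mu)
      pmax(v, 0)
    }
  )
  pmin(pmax(out, 0), model$mu_cap)
}

#' Draw pairwise interaction factors
#'
#' Draws one multiplicative rate factor per paired lineage under a scenario.
#' For `positive_on_slow` the applied branch replaces `mu` by
#' `-ln(mu) * mu`, which is reported here as the equivalent factor
#' `-ln(mu)`.
#'
#' @param scenario An [interaction_scenario()].
#' @param mu Assigned rate(s) of the lineages, h^-1.
#' @param log10_abundance log10 initial read abundance(s) (used by
#'   `bimodal`).
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return Numeric factor(s), one per lineage.
#' @export
pair_factors <- function(scenario, mu, log10_abundance = NULL, seed = NULL) {
  assert_that(inherits(scenario, "interaction_scenario"),
              "`scenario` must be an interaction_scenario()")
  n <- length(mu)
  with_seed(seed, {
    switch(scenario$name,
      null = rep(1, n),
      bimodal = {
        assert_that(!is.null(log10_abundance) && length(log10_abundance) == n,
                    "bimodal scenario needs log10_abundance per lineage")
        low <- log10_abundance < scenario$abund_threshold_log10
        f <- numeric(n)
        f[low] <- runif(sum(low), scenario$low_range[1], scenario$low_range[2])
        f[!low] <- runif(sum(!low), scenario$high_range[1], scenario$high_range[2])
        f
      },
      biased_positive = {
        neg <- runif(n) < scenario$p_negative
        f <- numeric(n)
        f[neg] <- runif(sum(neg), scenario$negative_range[1],
                        scenario$negative_range[2])
        f[!neg] <- runif(sum(!neg), scenario$positive_range[1],
                         scenario$positive_range[2])
        f
      },
      positive_on_slow = {
        apply_b <- runif(n) < scenario$p_apply
        ifelse(apply_b, -log(mu), 1)
      },
      biased_negative = {
        fast <- mu > scenario$mu_threshold
        p <- ifelse(fast, scenario$p_fast, scenario$p_slow)
        hit <- runif(n) < p
        f <- rep(1, n)
        f[hit] <- runif(sum(hit), scenario$negative_range[1],
                        scenario$negative_range[2])
        f
      },
      random = runif(n, scenario$range[1], scenario$range[2])
    )
  })
}

#' Compute effective growth rates for a bead community
#'
#' Combines the single-occupancy penalty (for lineages alone in a bead) and
#' the pairwise interaction scenario (for paired lineages) into per-lineage
#' effective maximum rates. Dead lineages get rate 0; every rate is clamped
#' to `[0, mu_cap]`.
#'
#' @param community A bead `connsim_community`.
#' @param scenario An [interaction_scenario()].
#' @param penalty A [penalty_model()].
#' @param abundances Tibble mapping `otu_id` to initial `reads` (e.g. from
#'   [otu_probabilities()]).
#' @param seed Integer seed for the factor draws.
#' @param mu_cap Global rate cap, h^-1.
#' @return Numeric vector of effective rates aligned with `community` rows.
#' @export
apply_scenario <- function(community,
                           scenario = interaction_scenario("null"),
                           penalty = penalty_model(),
                           abundances = NULL,
                           seed = 1L,
                           mu_cap = MU_MAX) {
  assert_that(community_environment(community) == "beads",
              "`apply_scenario` needs a bead community")
  assert_that("mu" %in% names(community), "community needs assigned rates")
  n <- nrow(community)
  occupancy <- stats::ave(rep(1L, n), community$bead_id, FUN = sum)
  reads <- rep(NA_real_, n)
  if (!is.null(abundances)) {
    assert_that(all(c("otu_id", "reads") %in% names(abundances)),
                "`abundances` must have otu_id and reads columns")
    reads <- abundances$reads[match(community$otu_id, abundances$otu_id)]
  }
  needs_abund <- penalty$mode == "abundance_inverse" ||
    scenario$name == "bimodal"
  assert_that(!needs_abund || !anyNA(reads),
              "this penalty/scenario combination needs `abundances` covering every OTU")

  eff <- community$mu
  single <- occupancy == 1
  if (any(single) && penalty$mode != "off") {
    ab <- reads[single]
    ab[is.na(ab)] <- 1
    eff[single] <- single_penalty(community$mu[single], pmax(ab, 1),
                                  model = penalty)
  }
  if (any(!single)) {
    f <- pair_factors(scenario, community$mu[!single],
                      log10_abundance = log10(pmax(reads[!single], 1)),
                      seed = seed)
    eff[!single] <- community$mu[!single] * f
  }
  alive <- if ("alive" %in% names(community)) community$alive else rep(TRUE, n)
  eff[!alive] <- 0
  pmin(pmax(eff, 0), mu_cap)
}
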