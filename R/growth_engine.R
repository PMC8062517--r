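# Discrete-time Monod growth on a single shared substrate pool.
#
# All lineages (whether suspended in liquid or enclosed in beads) draw on
# one global substrate concentration S. Per step, each live lineage's
# specific rate is evaluated from S at step start (synchronous update) and
# biomass grows exactly exponentially within the step; the carbon consumed
# (biomass formed divided by yield) is subtracted from S. When S falls
# below Smin, growth stops.

#' Growth-kinetics parameters
#'
#' @param Ks Half-saturation constant, g ml^-1.
#' @param yield Biomass yield on carbon, g g^-1 (accounts for CO2 loss).
#' @param cell_mass_fg Cell mass, fg per cell; converts biomass to cells.
#' @param S0 Initial carbon concentration, g ml^-1 (default 0.05 =
#'   50 mg ml^-1).
#' @param Smin Concentration below which growth stops, g ml^-1.
#' @param dt Time step, h.
#' @param n_steps Number of steps (default 120, i.e. 60 h).
#' @param mu_cap Maximum individual growth rate, h^-1.
#' @param volume_ml System volume in ml; concentrations are per ml.
#' @return A list of class `growth_params`.
#' @export
#' @examples
#' growth_params()$S0
growth_params <- function(Ks = 0.3e-6, yield = 0.3, cell_mass_fg = 120,
                          S0 = 0.05, Smin = 3e-6, dt = 0.5, n_steps = 120,
                          mu_cap = 0.6, volume_ml = 1) {
  vals <- c(Ks = Ks, yield = yield, cell_mass_fg = cell_mass_fg, S0 = S0,
            Smin = Smin, dt = dt, mu_cap = mu_cap, volume_ml = volume_ml)
  assert_that(all(vals > 0), "all growth parameters must be strictly positive")
  assert_that(Smin < S0, "`Smin` must be below `S0`")
  n_steps <- check_count(n_steps, "n_steps")
  structure(list(Ks = Ks, yield = yield, cell_mass_fg = cell_mass_fg,
                 cell_mass_g = cell_mass_fg * 1e-15, S0 = S0, Smin = Smin,
                 dt = dt, n_steps = n_steps, mu_cap = mu_cap,
                 volume_ml = volume_ml),
            class = "growth_params")
}

#' Monod specific growth rate
#'
#' `mu = mu_max * S / (Ks + S)`: saturating in substrate, half-maximal at
#' `S = Ks`.
#'
#' @param mu_max Maximum specific growth rate(s), h^-1.
#' @param S Substrate concentration, g ml^-1 (scalar, non-negative).
#' @param params A [growth_params()].
#' @return Specific growth rate(s), h^-1, in `[0, mu_max]`.
#' @export
#' @examples
#' monod_rate(0.6, 0.3e-6, growth_params())  # half-saturation -> 0.3
monod_rate <- function(mu_max, S, params = growth_params()) {
  assert_that(length(S) == 1 && is.finite(S) && S >= 0,
              "`S` must be a single non-negative number")
  mu_max * S / (params$Ks + S)
}

#' Convert biomass to cell numbers
#'
#' @param biomass Biomass in grams.
#' @param params A [growth_params()].
#' @return Real-valued cell counts (`biomass / cell mass`); rounding is left
#'   to reporting.
#' @export
biomass_to_cells <- function(biomass, params = growth_params()) {
  assert_that(all(biomass >= 0), "`biomass` must be non-negative")
  biomass / params$cell_mass_g
}

#' Simulate community growth to stationary phase
#'
#' Advances a founder community through `n_steps` discrete steps (or until
#' the substrate is depleted below `Smin`). Effective growth rates default
#' to each lineage's assigned `mu` (zero for dead lineages); supply
#' `effective_rates` to run with penalty/interaction-modified rates (see
#' [apply_scenario()]). The engine itself is deterministic.
#'
#' If the substrate decrement of a step would drive S below zero, all
#' lineages' biomass increments are scaled proportionally so S lands exactly
#' at zero, preserving relative competition on the depletion step.
#'
#' @param community A `connsim_community` tibble.
#' @param params A [growth_params()].
#' @param effective_rates Optional numeric vector of effective maximum rates
#'   (h^-1), one per lineage, aligned with `community` rows.
#' @return An object of class `connsim_sim`: a list with `lineages` (the
#'   community plus `mu_eff`, `final_biomass` in g, `final_cells`),
#'   `trajectory` (tibble: step, time_h, substrate, total_biomass),
#'   `stop_step`, `params`, and the community environment.
#' @export
#' @examples
#' tab <- generate_master_distribution(community_config(seed = 1))
#' com <- assemble_community(tab, "liquid", n_cells = 500, seed = 2)
#' sim <- simulate_growth(com, growth_params(n_steps = 20))
#' glance(sim)
simulate_growth <- function(community, params = growth_params(),
                            effective_rates = NULL) {
  assert_that("mu" %in% names(community) || !is.null(effective_rates),
              "community needs assigned rates or explicit effective_rates")
  n <- nrow(community)
  alive <- if ("alive" %in% names(community)) community$alive else rep(TRUE, n)
  mu_eff <- if (is.null(effective_rates)) {
    ifelse(alive, community$mu, 0)
  } else {
    assert_that(length(effective_rates) == n,
                "`effective_rates` must have one value per lineage")
    assert_that(!anyNA(effective_rates[alive]),
                "missing effective rate for a live lineage")
    effective_rates
  }
  mu_eff <- pmin(pmax(mu_eff, 0), params$mu_cap)

  X <- rep(params$cell_mass_g, n)
  X0 <- X
  S <- params$S0
  carbon_cap <- params$volume_ml  # grams of carbon per unit concentration
  substrate <- numeric(params$n_steps)
  total_biomass <- numeric(params$n_steps)
  stop_step <- params$n_steps
  for (step in seq_len(params$n_steps)) {
    if (S >= params$Smin) {
      mu <- mu_eff * S / (params$Ks + S)
      dX <- X * expm1(mu * params$dt)
      need <- sum(dX) / (params$yield * carbon_cap)  # substrate decrement
      if (need >= S) {
        scale <- S * params$yield * carbon_cap / sum(dX)
        X <- X + dX * scale
        S <- 0
      } else {
        X <- X + dX
        S <- S - need
      }
      if (S < params$Smin && stop_step == params$n_steps) stop_step <- step
    }
    substrate[step] <- S
    total_biomass[step] <- sum(X)
  }
  lineages <- as_tibble(community)
  lineages$mu_eff <- mu_eff
  lineages$final_biomass <- X
  lineages$final_cells <- X / params$cell_mass_g
  structure(
    list(
      lineages = lineages,
      trajectory = tibble(step = seq_len(params$n_steps),
                          time_h = seq_len(params$n_steps) * params$dt,
                          substrate = substrate,
                          total_biomass = total_biomass),
      initial_biomass = sum(X0),
      stop_step = stop_step,
      params = params,
      environment = community_environment(community)
    ),
    class = "connsim_sim"
  )
}

#' Maximum relative carbon-balance error of a simulation
#'
#' At every step, the carbon drawn from the substrate pool times the yield
#' must equal the biomass formed: `(S0 - S_t) * V * yield = sum(X_t - X_0)`.
#' Returns the largest relative discrepancy over all steps with non-zero
#' growth.
#'
#' @param sim A `connsim_sim`.
#' @return A single non-negative number.
#' @export
conservation_error <- function(sim) {
  p <- sim$params
  dx <- sim$trajectory$total_biomass - sim$initial_biomass
  used <- (p$S0 - sim$trajectory$substrate) * p$volume_ml * p$yield
  grown <- dx > 0
  if (!any(grown)) return(0)
  max(abs(used[grown] - dx[grown]) / dx[grown])
}

#' Per-bead stationary biomass totals
#'
#' @param sim A `connsim_sim` from a bead-environment run.
#' @return Tibble with `bead_id`, `n_founders`, `biomass` (g), `cells`, and
#'   `occupancy` (`"single"`/`"pair"`).
#' @export
per_bead_biomass <- function(sim) {
  assert_that(inherits(sim, "connsim_sim"), "`sim` must be a connsim_sim")
  assert_that(sim$environment == "beads", "per-bead totals need a bead run")
  sim$lineages %>%
    group_by(.data$bead_id) %>%
    summarise(n_founders = dplyr::n(),
              biomass = sum(.data$final_biomass),
              cells = sum(.data$final_cells),
              .groups = "drop") %>%
    mutate(occupancy = ifelse(.data$n_founders == 1, "single", "pair"))
}

#' Stationary-phase OTU cell counts
#'
#' Aggregates final cell numbers per OTU, the simulation analogue of an OTU
#' read-count vector at stationary phase.
#'
#' @param sim A `connsim_sim`.
#' @return Tibble with `otu_id` and `cells`.
#' @export
otu_cell_counts <- function(sim) {
  sim$lineages %>%
    group_by(.data$otu_id) %>%
    summarise(cells = sum(.data$final_cells), .groups = "drop")
}

#' @export
print.connsim_sim <- function(x, ...) {
  cat(sprintf(
    "<connsim_sim> %s environment: %d lineages, stop step %d/%d, final S = %.3g g/ml\n",
    x$environment, nrow(x$lineages), x$stop_step, x$params$n_steps,
    x$trajectory$substrate[nrow(x$trajectory)]))
  invisible(x)
}

#' @export
glance.connsim_sim <- function(x, ...) {
  tr <- x$trajectory
  tibble(
    environment = x$environment,
    n_lineages = nrow(x$lineages),
    n_alive = sum(if ("alive" %in% names(x$lineages)) x$lineages$alive else TRUE),
    stop_step = x$stop_step,
    final_substrate = tr$substrate[nrow(tr)],
    final_biomass = tr$total_biomass[nrow(tr)],
    total_cells = tr$total_biomass[nrow(tr)] / x$params$cell_mass_g
  )
}

#' @export
tidy.connsim_sim <- function(x, ...) {
  x$lineages
}
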