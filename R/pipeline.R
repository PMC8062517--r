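# End-to-end experiment orchestration: generate -> assemble -> simulate ->
# readout -> diversity, per interaction scenario and repeat, from a single
# configuration with deterministic stage seeding.

#' Experiment configuration
#'
#' Bundles the configuration of every pipeline stage. All printed model
#' constants appear here as explicit defaults. Stage seeds derive from
#' `master_seed` via [stage_seed()], so a whole experiment is reproducible
#' from one integer.
#'
#' @param community A [community_config()] (its `seed` is overridden per
#'   repeat).
#' @param n_cells Founder cells per simulation (default 200,000).
#' @param rate_mode Growth-rate attribution mode.
#' @param death A [death_model()]; default fast-biased 85% death above
#'   0.25 h^-1.
#' @param penalty A [penalty_model()] for single-occupancy beads.
#' @param scenarios Character vector of interaction scenario names.
#' @param growth A [growth_params()].
#' @param fraction_single Single-occupancy bead fraction.
#' @param subsample_reads Stationary-phase OTU subsampling depth.
#' @param subsample_beads Stationary-phase paired-bead subsampling count.
#' @param n_repeats Independent repeats (default 5).
#' @param master_seed Integer master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(community = community_config(),
                       n_cells = 200000,
                       rate_mode = "abundance_proportional",
                       death = death_model("fast_biased"),
                       penalty = penalty_model("abundance_inverse"),
                       scenarios = SCENARIO_NAMES,
                       growth = growth_params(),
                       fraction_single = 0.75,
                       subsample_reads = 50000,
                       subsample_beads = 5000,
                       n_repeats = 5,
                       master_seed = 1L) {
  assert_that(all(scenarios %in% SCENARIO_NAMES),
              sprintf("unknown scenario(s): %s",
                      paste(setdiff(scenarios, SCENARIO_NAMES), collapse = ", ")))
  n_repeats <- check_count(n_repeats, "n_repeats")
  structure(list(community = community, n_cells = n_cells,
                 rate_mode = rate_mode, death = death, penalty = penalty,
                 scenarios = scenarios, growth = growth,
                 fraction_single = fraction_single,
                 subsample_reads = subsample_reads,
                 subsample_beads = subsample_beads,
                 n_repeats = n_repeats, master_seed = master_seed),
            class = "run_config")
}

#' Load an experiment configuration from YAML
#'
#' The YAML file may override any [run_config()] field; nested blocks
#' `community`, `death`, `penalty` and `growth` are passed to their
#' constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$community)) args$community <- do.call(community_config, y$community)
  if (!is.null(y$death)) args$death <- do.call(death_model, y$death)
  if (!is.null(y$penalty)) args$penalty <- do.call(penalty_model, y$penalty)
  if (!is.null(y$growth)) args$growth <- do.call(growth_params, y$growth)
  scalar <- intersect(names(y), c("n_cells", "rate_mode", "scenarios",
                                  "fraction_single", "subsample_reads",
                                  "subsample_beads", "n_repeats", "master_seed"))
  do.call(run_config, c(args, y[scalar]))
}

#' Paired size ratios of a bead simulation
#'
#' Extracts per-bead partner sizes (final cells) from a bead-environment
#' simulation, optionally subsampling beads and excluding pairs with a
#' non-growing or dead partner, and returns absolute log10 size ratios.
#'
#' @param sim A `connsim_sim` from a bead run.
#' @param n_beads Paired beads to subsample (without replacement); `NULL`
#'   keeps all.
#' @param exclude_nongrowing Drop pairs with a partner at <= 1 cell.
#' @param seed Integer seed for the subsample.
#' @return Tibble with `bead_id`, `size1`, `size2`, `log10_ratio`.
#' @export
pair_size_ratios <- function(sim, n_beads = 5000, exclude_nongrowing = TRUE,
                             seed = 1L) {
  assert_that(sim$environment == "beads", "needs a bead simulation")
  pairs <- sim$lineages %>%
    group_by(.data$bead_id) %>%
    filter(dplyr::n() == 2) %>%
    summarise(size1 = .data$final_cells[1], size2 = .data$final_cells[2],
              .groups = "drop")
  if (exclude_nongrowing) {
    pairs <- filter(pairs, .data$size1 > 1, .data$size2 > 1)
  }
  if (!is.null(n_beads) && nrow(pairs) > n_beads) {
    pairs <- with_seed(seed, pairs[sample.int(nrow(pairs), n_beads), ])
  }
  mutate(pairs, log10_ratio = abs(log10(.data$size1 / .data$size2)))
}

run_one_repeat <- function(config, r, tab, abund) {
  ms <- config$master_seed
  beads <- assemble_community(tab, "beads", n_cells = config$n_cells,
                              rate_mode = config$rate_mode,
                              death = config$death,
                              fraction_single = config$fraction_single,
                              seed = stage_seed(ms, "assemble_beads", r))
  liquid <- assemble_community(tab, "liquid", n_cells = config$n_cells,
                               rate_mode = config$rate_mode,
                               death = config$death,
                               seed = stage_seed(ms, "assemble_liquid", r))

  sim_liquid <- simulate_growth(liquid, config$growth)
  founder_counts <- beads %>% count(.data$otu_id, name = "count")

  div_rows <- list(
    tibble(condition = "t0", rep = r,
           counts = list(tibble(otu_id = founder_counts$otu_id,
                                count = founder_counts$count))),
    tibble(condition = "high", rep = r,
           counts = list(otu_cell_counts(sim_liquid) %>%
                           rename(count = "cells")))
  )

  summary_rows <- list()
  ratio_profiles <- list()
  for (sc in config$scenarios) {
    scen <- interaction_scenario(sc)
    eff <- apply_scenario(beads, scen, config$penalty, abund,
                          seed = stage_seed(ms, paste0("scenario_", sc), r))
    sim <- simulate_growth(beads, config$growth, effective_rates = eff)
    pb <- per_bead_biomass(sim)
    ratio <- mean(pb$biomass[pb$occupancy == "pair"]) /
      mean(pb$biomass[pb$occupancy == "single"])
    summary_rows[[sc]] <- tibble(
      scenario = sc, rep = r,
      paired_single_ratio = ratio,
      stop_step = sim$stop_step,
      final_substrate = sim$trajectory$substrate[nrow(sim$trajectory)],
      conservation_err = conservation_error(sim)
    )
    ratio_profiles[[sc]] <- pair_size_ratios(
      sim, n_beads = config$subsample_beads,
      seed = stage_seed(ms, paste0("ratios_", sc), r))$log10_ratio
    div_rows[[paste0("low_", sc)]] <- tibble(
      condition = paste0("low_", sc), rep = r,
      counts = list(otu_cell_counts(sim) %>% rename(count = "cells")))
  }
  list(summary = bind_rows(summary_rows),
       diversity_counts = bind_rows(div_rows),
       ratio_profiles = ratio_profiles)
}

#' Run a full simulation experiment
#'
#' Generates one synthetic t = 0 community table, then for each repeat
#' assembles bead (low connectivity) and liquid (high connectivity) founder
#' communities from it, computes effective rates per interaction scenario,
#' simulates growth to stationary phase, and collects per-bead productivity
#' summaries, paired-growth ratio profiles and subsampled alpha-diversity
#' measures. Repeats share the t = 0 distribution and re-randomize every
#' simulation stage, mirroring independent simulation runs against one
#' measured community.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, summary tables and a JSON
#'   manifest are written there as TSV/JSON.
#' @return An object of class `connsim_experiment`: `summary` (tibble:
#'   scenario, rep, paired_single_ratio, stop_step, final_substrate),
#'   `diversity` (tibble: condition, rep, measures), `ratio_profiles`
#'   (named list: scenario -> list of per-repeat ratio vectors), `config`,
#'   `manifest`.
#' @export
#' @examples
#' cfg <- run_config(community = community_config(n_otus_master = 200,
#'                                                per_replicate_depth = 2000),
#'                   n_cells = 2000, scenarios = c("null", "random"),
#'                   n_repeats = 2, subsample_reads = 1000,
#'                   subsample_beads = 200, master_seed = 7)
#' exp <- run_experiment(cfg)
#' exp$summary
run_experiment <- function(config = run_config(), out_dir = NULL) {
  assert_that(inherits(config, "run_config"), "`config` must be a run_config()")
  # one t = 0 community table per experiment: repeats re-randomize the
  # simulation (founder sampling, rates, death, pairing, interactions), not
  # the underlying community distribution
  cfg_com <- config$community
  cfg_com$seed <- stage_seed(config$master_seed, "community")
  tab <- generate_master_distribution(cfg_com)
  abund <- otu_probabilities(tab)
  reps <- lapply(seq_len(config$n_repeats), function(r) {
    tryCatch(run_one_repeat(config, r, tab, abund), error = function(e) {
      abort(sprintf("repeat %d failed: %s", r, conditionMessage(e)),
            class = "connectisim_stage_error")
    })
  })
  summary_tbl <- bind_rows(lapply(reps, `[[`, "summary"))
  div_counts <- bind_rows(lapply(reps, `[[`, "diversity_counts"))
  diversity <- purrr::map_dfr(seq_len(nrow(div_counts)), function(i) {
    cc <- div_counts$counts[[i]]
    sub <- subsample_counts(cc$count, config$subsample_reads,
                            seed = stage_seed(config$master_seed,
                                              paste0("divsub_", div_counts$condition[i]),
                                              div_counts$rep[i]))
    dplyr::bind_cols(tibble(condition = div_counts$condition[i],
                            rep = div_counts$rep[i]),
                     alpha_diversity(as.numeric(sub)))
  })
  ratio_profiles <- lapply(setNames(config$scenarios, config$scenarios),
                           function(sc) lapply(reps, function(x) x$ratio_profiles[[sc]]))
  manifest <- list(
    package = "connectisim",
    version = as.character(utils::packageVersion("connectisim")),
    master_seed = config$master_seed,
    n_repeats = config$n_repeats,
    n_cells = config$n_cells,
    scenarios = config$scenarios,
    death = unclass(config$death),
    penalty = config$penalty$mode,
    growth = unclass(config$growth)
  )
  out <- structure(list(summary = summary_tbl, diversity = diversity,
                        ratio_profiles = ratio_profiles, config = config,
                        manifest = manifest),
                   class = "connsim_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(summary_tbl, file.path(out_dir, "summary.tsv"))
    readr::write_tsv(diversity, file.path(out_dir, "diversity.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.connsim_experiment <- function(x, ...) {
  cat(sprintf("<connsim_experiment> %d scenarios x %d repeats (master seed %s)\n",
              length(x$config$scenarios), x$config$n_repeats,
              x$config$master_seed))
  print(x$summary %>%
          group_by(.data$scenario) %>%
          summarise(mean_paired_single_ratio = mean(.data$paired_single_ratio),
                    .groups = "drop"))
  invisible(x)
}

#' @export
tidy.connsim_experiment <- function(x, ...) x$summary

#' @export
glance.connsim_experiment <- function(x, ...) {
  tibble(n_scenarios = length(x$config$scenarios),
         n_repeats = x$config$n_repeats,
         n_cells = x$config$n_cells,
         master_seed = x$config$master_seed)
}

#' Run the full condition battery of the study
#'
#' Enumerates the four single-occupancy model variants — DP (single-growth
#' penalty plus fast-biased death), noDP (penalty only), noDnoP (neither),
#' DnoP (death only) — and the paired-interaction battery (null,
#' death-model variants, and the five interaction scenarios), and returns
#' a cross-condition summary: paired-to-single productivity ratios and
#' diversity per condition and repeat.
#'
#' @param n_cells Founder cells per run.
#' @param n_repeats Repeats per condition (default 5).
#' @param master_seed Integer master seed.
#' @param community A [community_config()].
#' @param growth A [growth_params()].
#' @param subsample_reads,subsample_beads Readout subsampling sizes.
#' @return A list of class `connsim_suite`: `single_variants` (tibble of
#'   the four single-occupancy variants), `paired_battery` (a
#'   `connsim_experiment` under DP settings with all scenarios), and
#'   `summary` (combined tibble, one row per condition x repeat).
#' @export
reproduce_study_suite <- function(n_cells = 200000, n_repeats = 5,
                                  master_seed = 1L,
                                  community = community_config(),
                                  growth = growth_params(),
                                  subsample_reads = 50000,
                                  subsample_beads = 5000) {
  variants <- list(
    DP = list(death = death_model("fast_biased"),
              penalty = penalty_model("abundance_inverse")),
    noDP = list(death = death_model("none"),
                penalty = penalty_model("abundance_inverse")),
    noDnoP = list(death = death_model("none"), penalty = penalty_model("off")),
    DnoP = list(death = death_model("fast_biased"), penalty = penalty_model("off"))
  )
  single_rows <- purrr::imap_dfr(variants, function(v, nm) {
    cfg <- run_config(community = community, n_cells = n_cells,
                      death = v$death, penalty = v$penalty,
                      scenarios = "null", growth = growth,
                      subsample_reads = subsample_reads,
                      subsample_beads = subsample_beads,
                      n_repeats = n_repeats,
                      master_seed = stage_seed(master_seed, paste0("variant_", nm)))
    run_experiment(cfg)$summary %>% mutate(condition = nm, .before = 1)
  })
  battery_cfg <- run_config(community = community, n_cells = n_cells,
                            death = death_model("fast_biased"),
                            penalty = penalty_model("abundance_inverse"),
                            scenarios = SCENARIO_NAMES, growth = growth,
                            subsample_reads = subsample_reads,
                            subsample_beads = subsample_beads,
                            n_repeats = n_repeats,
                            master_seed = stage_seed(master_seed, "battery"))
  battery <- run_experiment(battery_cfg)
  summary <- bind_rows(
    single_rows %>% select("condition", "rep", "paired_single_ratio"),
    battery$summary %>%
      mutate(condition = paste0("DP_", .data$scenario)) %>%
      select("condition", "rep", "paired_single_ratio")
  )
  structure(list(single_variants = single_rows, paired_battery = battery,
                 summary = summary),
            class = "connsim_suite")
}
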