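# Founder community assembly: occurrence probabilities, founder sampling,
# growth-rate attribution, initial-death models, and bead partitioning.

MU_MIN <- 0.01
MU_MAX <- 0.6

#' OTU occurrence probabilities
#'
#' Converts the read counts of one replicate (or the replicate sum) into the
#' percent probability of occurrence used to seed the in-silico community:
#' `P(OTU_i) = 100 * OTU_i / sum(OTU_i)`.
#'
#' @param table An OTU abundance table.
#' @param replicate Replicate column to use; `NULL` (default) sums reads
#'   over all replicates.
#' @return A tibble with `otu_id`, `reads`, `prob_pct`; `prob_pct` sums to
#'   100 within 1e-9.
#' @export
#' @examples
#' tab <- generate_master_distribution(community_config(seed = 1))
#' p <- otu_probabilities(tab, "rep1")
#' sum(p$prob_pct)
otu_probabilities <- function(table, replicate = NULL) {
  reps <- otu_replicates(table)
  reads <- if (is.null(replicate)) {
    rowSums(as.matrix(table[, reps, drop = FALSE]))
  } else {
    assert_that(replicate %in% reps,
                sprintf("replicate '%s' not found", replicate))
    table[[replicate]]
  }
  assert_that(all(reads >= 0), "read counts must be non-negative")
  tot <- sum(reads)
  assert_that(tot > 0, "total reads are zero")
  tibble(otu_id = table$otu_id, reads = as.numeric(reads),
         prob_pct = 100 * reads / tot)
}

#' Sample founder cells from occurrence probabilities
#'
#' Draws `n_cells` founder cells with replacement from the OTU occurrence
#' probabilities, one row per in-silico cell (lineage).
#'
#' @param probabilities Tibble from [otu_probabilities()] (columns `otu_id`,
#'   `prob_pct` summing to 100, and `reads`).
#' @param n_cells Number of founder cells (default 200,000).
#' @param seed Integer seed.
#' @return A tibble with `lineage_id` and `otu_id`, one row per cell.
#' @export
sample_founders <- function(probabilities, n_cells = 200000, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  assert_that(all(c("otu_id", "prob_pct") %in% names(probabilities)),
              "`probabilities` must have otu_id and prob_pct columns")
  assert_that(abs(sum(probabilities$prob_pct) - 100) < 1e-6,
              "`prob_pct` must sum to 100")
  with_seed(seed, {
    idx <- sample.int(nrow(probabilities), n_cells, replace = TRUE,
                      prob = probabilities$prob_pct)
    tibble(lineage_id = seq_len(n_cells),
           otu_id = probabilities$otu_id[idx])
  })
}

#' Assign maximum specific growth rates to founder lineages
#'
#' Each OTU receives one maximum specific growth rate in `[0.01, 0.6]` h^-1,
#' shared by all its lineages. Two attribution modes:
#'
#' * `random`: each OTU gets an independent uniform draw on the range.
#' * `abundance_proportional`: uniform draws are rank-coupled to abundance —
#'   rates are sorted and handed out along an OTU order sampled without
#'   replacement with weights proportional to `log10(reads + 1)`, so
#'   abundant OTUs tend to receive the faster rates while the marginal rate
#'   distribution stays uniform.
#'
#' @param lineages Tibble with an `otu_id` column (e.g. from
#'   [sample_founders()]).
#' @param table The OTU abundance table the lineages were sampled from.
#' @param mode `"random"` or `"abundance_proportional"`.
#' @param replicate Replicate used for abundances; `NULL` sums replicates.
#' @param seed Integer seed.
#' @return `lineages` with an added `mu` column (h^-1).
#' @export
assign_growth_rates <- function(lineages, table,
                                mode = c("abundance_proportional", "random"),
                                replicate = NULL, seed = 1L) {
  mode <- match.arg(mode)
  assert_that("otu_id" %in% names(lineages), "`lineages` needs an otu_id column")
  abund <- otu_probabilities(table, replicate)
  unknown <- setdiff(unique(lineages$otu_id), abund$otu_id)
  assert_that(length(unknown) == 0,
              sprintf("unknown otu_id(s): %s", paste(head(unknown, 3), collapse = ", ")))
  with_seed(seed, {
    n <- nrow(abund)
    rates <- runif(n, MU_MIN, MU_MAX)
    mu <- if (mode == "random") {
      setNames(rates, abund$otu_id)
    } else {
      w <- log10(abund$reads + 1)
      w[w <= 0] <- 1e-6
      order_ids <- abund$otu_id[sample.int(n, n, replace = FALSE, prob = w)]
      setNames(sort(rates, decreasing = TRUE), order_ids)
    }
    lineages$mu <- unname(mu[lineages$otu_id])
    lineages
  })
}

#' Initial-death model
#'
#' Describes which founder cells are dead (unable to divide) at t = 0:
#' `none` (all alive), `random` (each lineage dead with probability
#' `p_dead`), or `fast_biased` (lineages whose OTU growth rate exceeds
#' `mu_threshold` are dead with probability `p_dead`; slower lineages stay
#' alive). The default `fast_biased` parameters reflect an 85% death
#' probability for fast growers above 0.25 h^-1.
#'
#' @param mode One of `"none"`, `"random"`, `"fast_biased"`.
#' @param p_dead Death probability in `[0, 1]`.
#' @param mu_threshold Growth-rate threshold (h^-1) for `fast_biased`.
#' @return A list of class `death_model`.
#' @export
death_model <- function(mode = c("none", "random", "fast_biased"),
                        p_dead = 0.85, mu_threshold = 0.25) {
  mode <- match.arg(mode)
  p_dead <- check_fraction(p_dead, "p_dead")
  structure(list(mode = mode, p_dead = p_dead, mu_threshold = mu_threshold),
            class = "death_model")
}

#' Apply an initial-death model to founder lineages
#'
#' @param lineages Tibble with `mu` assigned (see [assign_growth_rates()]).
#' @param model A [death_model()].
#' @param seed Integer seed.
#' @return `lineages` with an added logical `alive` column.
#' @export
apply_death <- function(lineages, model = death_model(), seed = 1L) {
  assert_that(inherits(model, "death_model"), "`model` must be a death_model()")
  n <- nrow(lineages)
  with_seed(seed, {
    alive <- switch(model$mode,
      none = rep(TRUE, n),
      random = runif(n) >= model$p_dead,
      fast_biased = {
        assert_that("mu" %in% names(lineages),
                    "fast_biased death needs assigned growth rates")
        fast <- lineages$mu > model$mu_threshold
        a <- rep(TRUE, n)
        a[fast] <- runif(sum(fast)) >= model$p_dead
        a
      }
    )
    lineages$alive <- alive
    lineages
  })
}

#' Partition founder lineages into beads
#'
#' Assigns every lineage to exactly one bead. Each bead independently holds
#' a single founder with probability `fraction_single` (default 75%) or a
#' pair of founders otherwise, matching the observed bead occupancy mix.
#'
#' @param lineages Founder tibble (at least 2 rows).
#' @param fraction_single Probability that a bead is single-occupancy.
#' @param seed Integer seed.
#' @return A founder community tibble (class `connsim_community`,
#'   environment `"beads"`) with `bead_id` and `slot` columns.
#' @export
partition_beads <- function(lineages, fraction_single = 0.75, seed = 1L) {
  fraction_single <- check_fraction(fraction_single, "fraction_single")
  n <- nrow(lineages)
  assert_that(n >= 2, "need at least 2 lineages to partition")
  with_seed(seed, {
    ord <- sample.int(n, n)
    # draw bead occupancies (1 or 2 cells) until the cell budget is consumed
    sizes <- integer(0)
    while (sum(sizes) < n) {
      need <- n - sum(sizes)
      k <- max(16L, ceiling(need / (2 - fraction_single) * 1.3))
      draw <- ifelse(runif(k) < fraction_single, 1L, 2L)
      sizes <- c(sizes, draw)
    }
    keep <- which(cumsum(sizes) >= n)[1]
    sizes <- sizes[seq_len(keep)]
    if (sum(sizes) > n) sizes[keep] <- 1L  # last bead downgraded to a single
    bead <- rep(seq_along(sizes), times = sizes)
    slot <- unlist(lapply(sizes, seq_len), use.names = FALSE)
    out <- lineages[ord, , drop = FALSE]
    out$bead_id <- sprintf("bead_%06d", bead)
    out$slot <- slot
    out <- arrange(out, .data$lineage_id)
    as_community(out, environment = "beads")
  })
}

#' Mark a founder table as a community
#'
#' @param lineages Founder tibble.
#' @param environment `"liquid"` or `"beads"`.
#' @param source Optional identifier of the source OTU table.
#' @return The tibble with class `connsim_community` and attributes
#'   `environment` and `source`.
#' @export
as_community <- function(lineages, environment = c("liquid", "beads"),
                         source = NULL) {
  environment <- match.arg(environment)
  if (environment == "beads") {
    assert_that(all(c("bead_id", "slot") %in% names(lineages)),
                "bead communities need bead_id and slot columns")
  }
  structure(as_tibble(lineages), environment = environment, source = source,
            class = c("connsim_community", class(tibble())))
}

#' Environment of a founder community
#' @param community A `connsim_community`.
#' @return `"liquid"` or `"beads"`.
#' @export
community_environment <- function(community) {
  attr(community, "environment") %||% "liquid"
}

#' Assemble a founder community from an OTU table
#'
#' Convenience wrapper chaining [otu_probabilities()], [sample_founders()],
#' [assign_growth_rates()], [apply_death()] and, for the bead environment,
#' [partition_beads()]. Stage seeds are derived from `seed` with
#' [stage_seed()].
#'
#' @param table OTU abundance table.
#' @param environment `"liquid"` (high connectivity) or `"beads"` (low
#'   connectivity).
#' @param n_cells Number of founder cells (default 200,000).
#' @param rate_mode Growth-rate attribution mode (see
#'   [assign_growth_rates()]).
#' @param death A [death_model()].
#' @param fraction_single Single-occupancy bead fraction (beads only).
#' @param replicate Replicate used for probabilities and abundances.
#' @param seed Integer seed.
#' @return A `connsim_community` tibble.
#' @export
#' @examples
#' tab <- generate_master_distribution(community_config(seed = 1))
#' com <- assemble_community(tab, "beads", n_cells = 1000, seed = 3)
#' dplyr::count(com, bead_id)
assemble_community <- function(table,
                               environment = c("liquid", "beads"),
                               n_cells = 200000,
                               rate_mode = "abundance_proportional",
                               death = death_model("none"),
                               fraction_single = 0.75,
                               replicate = NULL,
                               seed = 1L) {
  environment <- match.arg(environment)
  probs <- otu_probabilities(table, replicate)
  founders <- sample_founders(probs, n_cells, seed = stage_seed(seed, "sample"))
  founders <- assign_growth_rates(founders, table, mode = rate_mode,
                                  replicate = replicate,
                                  seed = stage_seed(seed, "rates"))
  founders <- apply_death(founders, death, seed = stage_seed(seed, "death"))
  if (environment == "beads") {
    partition_beads(founders, fraction_single, seed = stage_seed(seed, "beads"))
  } else {
    as_community(founders, "liquid")
  }
}
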