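# Synthetic sand-community generator.
#
# Emulates the t = 0 washed sand community: a master pool of OTUs with
# heavy-tailed (log-normal) read abundances, observed through several
# sequencing replicates that share the pool but differ by detection thinning
# and finite read depth. Default calibration targets the study community:
# union richness over 7 replicates ~ 1200 OTUs, mean per-replicate richness
# ~ 543.

#' Configuration for the synthetic community generator
#'
#' The master community holds `n_otus_master` OTUs whose log10 read counts
#' are drawn from a normal distribution (counts are therefore log-normal,
#' a standard heavy-tailed species-abundance law). Each sequencing replicate
#' observes the shared pool through two thinning stages: a per-OTU detection
#' step whose probability increases with abundance (logistic in log10 reads,
#' midpoint `detection_midpoint`, scale `detection_scale`), followed by a
#' multinomial draw of `per_replicate_depth` reads from the detected OTUs.
#' The defaults are calibrated so that 7 replicates have mean per-replicate
#' richness near 543 and union richness near 1200.
#'
#' @param n_otus_master Number of OTUs in the master pool.
#' @param lognormal_mu,lognormal_sigma Mean and SD of the log10 read-count
#'   distribution of the master pool; `lognormal_sigma` must be positive.
#' @param n_replicates Number of sequencing replicates to emit.
#' @param per_replicate_depth Reads per replicate (multinomial total).
#' @param detection_midpoint,detection_scale Logistic detection curve
#'   parameters on the log10 read-count axis.
#' @param replicate_detection_prob Optional function of log10 master counts
#'   returning per-OTU detection probabilities; overrides the logistic curve.
#' @param seed Integer seed; the whole table is deterministic given the seed.
#' @return A list of class `community_config`.
#' @export
#' @examples
#' cfg <- community_config(seed = 1)
#' tab <- generate_master_distribution(cfg)
#' summarize_distribution(tab)$union_richness
community_config <- function(n_otus_master = 1900,
                             lognormal_mu = 1.3,
                             lognormal_sigma = 1.2,
                             n_replicates = 7,
                             per_replicate_depth = 50000,
                             detection_midpoint = 2.0,
                             detection_scale = 1.6,
                             replicate_detection_prob = NULL,
                             seed = 1L) {
  assert_that(lognormal_sigma > 0, "`lognormal_sigma` must be > 0")
  cfg <- list(
    n_otus_master = check_count(n_otus_master, "n_otus_master"),
    lognormal_mu = lognormal_mu,
    lognormal_sigma = lognormal_sigma,
    n_replicates = check_count(n_replicates, "n_replicates"),
    per_replicate_depth = check_count(per_replicate_depth, "per_replicate_depth"),
    detection_midpoint = detection_midpoint,
    detection_scale = detection_scale,
    replicate_detection_prob = replicate_detection_prob,
    seed = seed
  )
  structure(cfg, class = "community_config")
}

#' Generate a synthetic t = 0 OTU abundance table
#'
#' Draws the master pool and the per-replicate read counts described in
#' [community_config()]. The result is a wide tibble with one row per OTU:
#' `otu_id`, `taxon`, `master_count`, then one count column per replicate
#' (`rep1`, `rep2`, ...). Taxon labels are opaque placeholders.
#'
#' @param config A [community_config()].
#' @return A tibble of class `connsim_otu_table`; replicate column names are
#'   stored in `attr(, "replicates")`.
#' @export
generate_master_distribution <- function(config = community_config()) {
  assert_that(inherits(config, "community_config"),
              "`config` must be created by community_config()")
  with_seed(config$seed, {
    n <- config$n_otus_master
    x <- rnorm(n, config$lognormal_mu, config$lognormal_sigma)
    master <- pmax(1, round(10^x))
    detect_p <- if (is.null(config$replicate_detection_prob)) {
      stats::plogis((log10(master) - config$detection_midpoint) /
                      config$detection_scale)
    } else {
      p <- config$replicate_detection_prob(log10(master))
      assert_that(all(p >= 0 & p <= 1), "detection probabilities must be in [0, 1]")
      p
    }
    rep_ids <- paste0("rep", seq_len(config$n_replicates))
    reps <- matrix(0L, nrow = n, ncol = config$n_replicates,
                   dimnames = list(NULL, rep_ids))
    for (r in seq_len(config$n_replicates)) {
      det <- runif(n) < detect_p
      w <- master * det
      if (sum(w) > 0) {
        reps[, r] <- rmultinom(1, config$per_replicate_depth, w)[, 1]
      }
    }
    out <- tibble(
      otu_id = sprintf("OTU_%05d", seq_len(n)),
      taxon = sprintf("taxon_%05d", seq_len(n)),
      master_count = as.integer(master)
    )
    out <- dplyr::bind_cols(out, as_tibble(reps))
    new_otu_table(out, rep_ids)
  })
}

new_otu_table <- function(tbl, replicates) {
  structure(tbl, replicates = replicates,
            class = c("connsim_otu_table", class(tibble())))
}

#' Replicate column names of an OTU table
#' @param table A `connsim_otu_table` (or any tibble with `rep*` columns).
#' @return Character vector of replicate column names.
#' @export
otu_replicates <- function(table) {
  reps <- attr(table, "replicates")
  if (is.null(reps)) reps <- grep("^rep", names(table), value = TRUE)
  assert_that(length(reps) >= 1, "table has no replicate columns")
  reps
}

#' Summarize an OTU abundance table
#'
#' Computes per-replicate richness (OTUs with non-zero reads), the union
#' richness over all replicates, and a normalized histogram of log10 summed
#' read abundances.
#'
#' @param table An OTU table as returned by [generate_master_distribution()].
#' @param bin_width Width of the log10-abundance histogram bins.
#' @return A list with elements `per_replicate` (tibble: replicate,
#'   richness), `union_richness` (integer), `mean_richness` (double), and
#'   `histogram` (tibble: log10_mid, prop; props sum to 1).
#' @export
summarize_distribution <- function(table, bin_width = 0.25) {
  assert_that(nrow(table) > 0, "`table` is empty")
  reps <- otu_replicates(table)
  counts <- as.matrix(table[, reps, drop = FALSE])
  assert_that(all(counts >= 0), "counts must be non-negative")
  richness <- colSums(counts > 0)
  union_rich <- sum(rowSums(counts) > 0)
  tot <- rowSums(counts)
  pos <- tot[tot > 0]
  hist_tbl <- if (length(pos) > 0) {
    br <- seq(0, ceiling(max(log10(pos)) / bin_width) * bin_width + bin_width,
              by = bin_width)
    h <- hist(log10(pos), breaks = br, plot = FALSE)
    tibble(log10_mid = h$mids, prop = h$counts / sum(h$counts))
  } else {
    tibble(log10_mid = numeric(), prop = numeric())
  }
  list(
    per_replicate = tibble(replicate = reps, richness = as.integer(richness)),
    union_richness = as.integer(union_rich),
    mean_richness = mean(richness),
    histogram = hist_tbl
  )
}

#' Generate a synthetic bead/microcolony observation table
#'
#' Emits per-bead microcolony records (area in pixels, mean fluorescence
#' intensity) of the kind produced by time-series imaging of cell-laden
#' agarose beads. Single-occupancy beads carry one colony; paired beads two.
#' Paired beads are drawn from the four pair-growth categories used in the
#' per-bead productivity (PBP) analysis, in the proportions `category_mix`:
#'
#' * `both_no_growth`: both partners below the no-growth PBP threshold;
#' * `one_not_growing`: exactly one partner below the threshold;
#' * `balanced`: both growing, PBP ratio within `[0.125, 8]`;
#' * `imbalanced`: both growing, PBP ratio outside that band.
#'
#' @param n_beads Number of beads to emit.
#' @param occupancy_mix Fraction of single-occupancy beads.
#' @param category_mix Numeric vector of 4 target fractions (summing to 1)
#'   for paired beads, in the order listed above.
#' @param pbp_level_params List with `nogrow` and `grow` elements, each
#'   `c(mean, sd)` of the log10 PBP level of non-growing and growing
#'   colonies. The defaults straddle the no-growth threshold `10^3.25`.
#' @param time_h,condition Metadata stamped on every record.
#' @param seed Integer seed.
#' @return A tibble of class `connsim_bead_table` with columns `bead_id`,
#'   `time_h`, `condition`, `colony_idx`, `area_px`, `mean_intensity`,
#'   `channel`.
#' @export
#' @examples
#' beads <- generate_bead_table(200, seed = 7)
#' dplyr::count(beads, bead_id)
generate_bead_table <- function(n_beads,
                                occupancy_mix = 0.75,
                                category_mix = c(both_no_growth = 0.25,
                                                 one_not_growing = 0.30,
                                                 balanced = 0.25,
                                                 imbalanced = 0.20),
                                pbp_level_params = list(nogrow = c(mean = 2.4, sd = 0.35),
                                                        grow = c(mean = 4.6, sd = 0.5)),
                                time_h = 48,
                                condition = "synthetic",
                                seed = 1L) {
  n_beads <- check_count(n_beads, "n_beads")
  occupancy_mix <- check_fraction(occupancy_mix, "occupancy_mix")
  assert_that(length(category_mix) == 4 && all(category_mix >= 0) &&
                abs(sum(category_mix) - 1) < 1e-8,
              "`category_mix` must be 4 non-negative fractions summing to 1")
  cat_names <- c("both_no_growth", "one_not_growing", "balanced", "imbalanced")

  # truncated-normal draws of log10 PBP, rejection-free via clamping margins
  draw_nogrow <- function(k) {
    p <- pbp_level_params$nogrow
    pmin(rnorm(k, p[["mean"]], p[["sd"]]), 3.15)
  }
  draw_grow <- function(k, lo = 3.35) {
    p <- pbp_level_params$grow
    pmax(rnorm(k, p[["mean"]], p[["sd"]]), lo)
  }

  with_seed(seed, {
    is_single <- runif(n_beads) < occupancy_mix
    n_pairs <- sum(!is_single)
    pair_cat <- if (n_pairs > 0) {
      sample(cat_names, n_pairs, replace = TRUE, prob = category_mix)
    } else character()

    rows <- vector("list", n_beads)
    pair_i <- 0L
    for (b in seq_len(n_beads)) {
      bead_id <- sprintf("bead_%05d", b)
      if (is_single[b]) {
        lp <- draw_grow(1)
        rows[[b]] <- tibble(bead_id = bead_id, colony_idx = 1L, log10_pbp = lp)
      } else {
        pair_i <- pair_i + 1L
        lp <- switch(pair_cat[pair_i],
          both_no_growth = draw_nogrow(2),
          one_not_growing = c(draw_nogrow(1), draw_grow(1)),
          balanced = {
            base <- draw_grow(1, lo = 4.25)
            c(base, base + runif(1, -0.85, 0.85))
          },
          imbalanced = {
            base <- draw_grow(1, lo = 3.35)
            c(base, base + runif(1, 1.0, 2.0))
          }
        )
        lp <- sample(lp)
        rows[[b]] <- tibble(bead_id = bead_id, colony_idx = c(1L, 2L),
                            log10_pbp = lp)
      }
    }
    out <- dplyr::bind_rows(rows)
    out$mean_intensity <- runif(nrow(out), 50, 150)
    out$area_px <- 10^out$log10_pbp / out$mean_intensity
    out <- out %>%
      mutate(time_h = time_h, condition = condition, channel = "SC") %>%
      select("bead_id", "time_h", "condition", "colony_idx",
             "area_px", "mean_intensity", "channel")
    structure(out, class = c("connsim_bead_table", class(tibble())))
  })
}
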