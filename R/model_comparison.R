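# Simulation-versus-observation agreement: bootstrap Spearman correlation,
# fold-range prediction accuracy, PCA of binned histograms, confidence
# envelope deviation of paired-growth ratio profiles, and scenario ranking.

#' Bootstrap Spearman correlation between simulated and observed abundances
#'
#' Spearman rank correlation on matched (relative) abundance vectors, with
#' a confidence interval from resampling OTUs with replacement.
#'
#' @param simulated,observed Matched numeric vectors (same OTU universe;
#'   absent OTUs as zero). At least 3 entries.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Tibble with `rho`, `ci_lo`, `ci_hi`, `n_otus`, `n_boot`.
#' @export
spearman_bootstrap <- function(simulated, observed, n_boot = 1000,
                               conf = 0.95, seed = 1L) {
  assert_that(length(simulated) == length(observed),
              "vectors must be matched")
  assert_that(length(simulated) >= 3, "need at least 3 shared OTUs")
  rho <- cor(simulated, observed, method = "spearman")
  n <- length(simulated)
  bs <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(simulated[idx], observed[idx], method = "spearman"))
    })
  })
  a <- (1 - conf) / 2
  tibble(rho = rho,
         ci_lo = unname(quantile(bs, a, na.rm = TRUE)),
         ci_hi = unname(quantile(bs, 1 - a, na.rm = TRUE)),
         n_otus = n, n_boot = n_boot)
}

#' Fold-range prediction accuracy
#'
#' Percentage of OTUs whose simulated relative abundance falls within a
#' k-fold range of the observed one (`ratio in [1/k, k]`). OTUs absent from
#' the observation are excluded (undefined ratio); OTUs absent from the
#' simulation count as failures at every fold. Vectors are normalized to
#' relative abundances internally.
#'
#' @param simulated,observed Matched non-negative abundance vectors.
#' @param folds Fold thresholds (default 2 and 4).
#' @return Tibble with `fold`, `n_otus`, `pct_within`.
#' @export
#' @examples
#' fold_accuracy(c(3, 3, 3), c(1, 1, 1))  # 0% at 2-fold, 100% at 4-fold
fold_accuracy <- function(simulated, observed, folds = c(2, 4)) {
  assert_that(length(simulated) == length(observed),
              "vectors must be matched")
  keep <- observed > 0
  assert_that(any(keep), "no OTUs observed")
  sim <- simulated[keep] / sum(simulated[keep])
  obs <- observed[keep] / sum(observed[keep])
  ratio <- sim / obs
  purrr::map_dfr(folds, function(k) {
    within_k <- sim > 0 & ratio >= 1 / k & ratio <= k
    tibble(fold = k, n_otus = length(ratio),
           pct_within = 100 * mean(within_k))
  })
}

#' PCA of probability-normalized binned histograms
#'
#' Principal component decomposition of a set of datasets described by
#' equal-structure binned histograms (e.g. microcolony-size histograms or
#' flattened 12 x 12 paired-growth grids). Rows are normalized to sum to 1,
#' centered per bin, and not scaled.
#'
#' @param histograms Numeric matrix (or data frame) with one dataset per
#'   row and one bin per column; at least 3 rows. Row names label datasets.
#' @return A list of class `connsim_pca`: `scores` (tibble with `dataset`
#'   and PC columns) and `explained_var` (percent per component).
#' @export
pca_histograms <- function(histograms) {
  m <- as.matrix(histograms)
  assert_that(nrow(m) >= 3, "need at least 3 datasets")
  rs <- rowSums(m)
  assert_that(all(rs > 0), "every histogram needs positive mass")
  m <- m / rs
  assert_that(any(apply(m, 2, sd) > 0), "constant histogram matrix")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  labels <- rownames(m) %||% paste0("dataset", seq_len(nrow(m)))
  scores <- as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble(dataset = labels), scores)
  structure(list(scores = scores, explained_var = ev), class = "connsim_pca")
}

#' @export
tidy.connsim_pca <- function(x, ...) x$scores

#' @export
glance.connsim_pca <- function(x, ...) {
  tibble(n_datasets = nrow(x$scores),
         pc1_var = x$explained_var[1],
         pc2_var = if (length(x$explained_var) >= 2) x$explained_var[2] else NA_real_)
}

default_ratio_ranges <- function() {
  list(smallest = c(0, 0.5), mid = c(0.5, 2), largest = c(2, 6))
}

ratio_profile <- function(ratios, bin_width = 0.5, log10_max = 6) {
  br <- seq(0, log10_max, by = bin_width)
  h <- hist(pmin(pmax(ratios, 0), log10_max - 1e-9), breaks = br, plot = FALSE)
  if (sum(h$counts) > 0) h$counts / sum(h$counts) else h$counts * 0
}

#' Deviation of an observed ratio profile from a simulated envelope
#'
#' Builds a 5th-95th percentile envelope of normalized paired-growth
#' log10 size-ratio profiles by repeatedly subsampling (default 1000
#' ratios, 1000 draws) from the pooled per-repeat simulated ratio
#' distributions, then measures where the observed profile leaves the
#' envelope: observed mass below the 5th percentile is a deficit
#' (negative), above the 95th an excess (positive). Deviations are
#' aggregated over three log10-ratio ranges (`smallest`, `mid`, `largest`).
#'
#' @param observed_ratios Observed absolute log10 size ratios.
#' @param sim_ratios List of numeric vectors, one per simulation repeat
#'   (at least 2).
#' @param n_subsample Ratios per subsampled profile (default 1000).
#' @param n_draws Number of subsampled profiles (default 1000).
#' @param ranges Named list of log10-ratio ranges.
#' @param bin_width,log10_max Profile bin geometry.
#' @param seed Integer seed.
#' @return A list of class `connsim_deviation`: `by_range` (tibble `range`,
#'   `deviation_pct` signed), `by_bin` (tibble with envelope and observed
#'   mass per bin), `total_abs` (sum of absolute range deviations).
#' @export
ci_deviation <- function(observed_ratios, sim_ratios, n_subsample = 1000,
                         n_draws = 1000, ranges = default_ratio_ranges(),
                         bin_width = 0.5, log10_max = 6, seed = 1L) {
  assert_that(is.list(sim_ratios) && length(sim_ratios) >= 2,
              "need >= 2 simulation repeats")
  pooled <- unlist(sim_ratios, use.names = FALSE)
  assert_that(length(pooled) > 0, "simulated ratio pool is empty")
  obs_prof <- ratio_profile(observed_ratios, bin_width, log10_max)
  n_bins <- length(obs_prof)
  draws <- with_seed(seed, {
    vapply(seq_len(n_draws), function(b) {
      ratio_profile(sample(pooled, min(n_subsample, length(pooled)),
                           replace = TRUE),
                    bin_width, log10_max)
    }, numeric(n_bins))
  })
  q05 <- apply(draws, 1, quantile, probs = 0.05)
  q95 <- apply(draws, 1, quantile, probs = 0.95)
  dev_bin <- ifelse(obs_prof > q95, obs_prof - q95,
                    ifelse(obs_prof < q05, obs_prof - q05, 0))
  mids <- seq(bin_width / 2, log10_max - bin_width / 2, by = bin_width)
  by_bin <- tibble(log10_mid = mids, observed = obs_prof,
                   env_lo = q05, env_hi = q95, deviation = dev_bin)
  by_range <- purrr::imap_dfr(ranges, function(rg, nm) {
    in_rg <- mids >= rg[1] & mids < rg[2] |
      (nm == names(ranges)[length(ranges)] & mids == rg[2])
    tibble(range = nm, deviation_pct = 100 * sum(dev_bin[in_rg]))
  })
  structure(list(by_range = by_range, by_bin = by_bin,
                 total_abs = sum(abs(by_range$deviation_pct))),
            class = "connsim_deviation")
}

#' @export
tidy.connsim_deviation <- function(x, ...) x$by_range

#' Rank interaction scenarios against an observed ratio profile
#'
#' Scenarios are ranked by the total absolute deviation of their simulated
#' paired-growth ratio envelope from the observed profile (see
#' [ci_deviation()]), smallest first; ties are broken by Euclidean distance
#' to the observation in the PC space of the mean ratio profiles.
#'
#' @param observed_ratios Observed absolute log10 size ratios.
#' @param scenario_sims Named list; each element a list of per-repeat ratio
#'   vectors for one scenario.
#' @param ... Passed on to [ci_deviation()].
#' @param seed Integer seed.
#' @return Tibble with `scenario`, `total_abs_deviation`, `pca_distance`,
#'   `rank` (1 = best).
#' @export
rank_scenarios <- function(observed_ratios, scenario_sims, ..., seed = 1L) {
  assert_that(is.list(scenario_sims) && !is.null(names(scenario_sims)),
              "`scenario_sims` must be a named list")
  devs <- purrr::imap_dfr(scenario_sims, function(sims, nm) {
    d <- ci_deviation(observed_ratios, sims, ...,
                      seed = stage_seed(seed, paste0("dev_", nm)))
    tibble(scenario = nm, total_abs_deviation = d$total_abs)
  })
  profiles <- rbind(
    observed = ratio_profile(observed_ratios),
    do.call(rbind, lapply(scenario_sims, function(sims) {
      rowMeans(vapply(sims, ratio_profile, numeric(12)))
    }))
  )
  pca_dist <- rep(NA_real_, length(scenario_sims))
  if (nrow(profiles) >= 3 && any(apply(profiles, 2, sd) > 0)) {
    pc <- pca_histograms(profiles)
    sc <- as.matrix(pc$scores[, -1, drop = FALSE])
    d <- sqrt(rowSums((sc[-1, , drop = FALSE] -
                         matrix(sc[1, ], nrow(sc) - 1, ncol(sc), byrow = TRUE))^2))
    pca_dist <- d
  }
  devs$pca_distance <- pca_dist
  devs %>%
    arrange(.data$total_abs_deviation, .data$pca_distance) %>%
    mutate(rank = row_number())
}
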