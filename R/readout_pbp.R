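# Stationary-phase readouts: subsampling, per-bead productivity (PBP),
# pair-growth categories, paired-growth grids/ratios, generation estimates.

#' Subsample a count vector without replacement
#'
#' Draws a fixed total (e.g. 50,000 reads or 5,000 beads) from a vector of
#' counts by a multivariate hypergeometric draw, preserving zeros and never
#' exceeding the input counts. If the input total is already at or below
#' `target`, the counts are returned unchanged with attribute
#' `subsampled = FALSE`. For totals too large for exact hypergeometric
#' arithmetic (or non-integer counts, e.g. real-valued cell numbers), the
#' draw falls back to a multinomial on the input proportions, which is the
#' exact limit of the hypergeometric when the sampling fraction is
#' negligible.
#'
#' @param counts Non-negative numeric vector.
#' @param target Total count to draw.
#' @param seed Integer seed.
#' @return Integer-valued vector of the same length summing to `target`.
#' @export
#' @examples
#' subsample_counts(c(600, 400), 100, seed = 1)
subsample_counts <- function(counts, target, seed = 1L) {
  target <- check_count(target, "target")
  assert_that(all(counts >= 0), "`counts` must be non-negative")
  total <- sum(counts)
  if (total <= target) {
    return(structure(counts, subsampled = FALSE))
  }
  with_seed(seed, {
    exact <- total < 2^31 - 1 && all(counts == floor(counts))
    out <- numeric(length(counts))
    if (exact) {
      remaining_total <- total
      remaining_draw <- target
      for (i in seq_along(counts)) {
        if (remaining_draw == 0) break
        ki <- rhyper(1, counts[i], remaining_total - counts[i], remaining_draw)
        out[i] <- ki
        remaining_total <- remaining_total - counts[i]
        remaining_draw <- remaining_draw - ki
      }
    } else {
      out <- rmultinom(1, target, prob = counts)[, 1]
    }
    structure(out, subsampled = TRUE)
  })
}

#' Pair-category thresholds
#'
#' @param log10_nogrowth log10 PBP below which a colony counts as
#'   non-growing (default 3.25).
#' @param ratio_bounds PBP ratio band regarded as balanced growth
#'   (default `c(0.125, 8)`).
#' @return A list of class `pair_thresholds`.
#' @export
pair_thresholds <- function(log10_nogrowth = 3.25, ratio_bounds = c(0.125, 8)) {
  assert_that(length(ratio_bounds) == 2 && ratio_bounds[1] < ratio_bounds[2],
              "`ratio_bounds` must be an ordered pair")
  structure(list(log10_nogrowth = log10_nogrowth, ratio_bounds = ratio_bounds),
            class = "pair_thresholds")
}

PAIR_CATEGORIES <- c("both_no_growth", "one_not_growing", "balanced", "imbalanced")

#' Per-bead productivity (PBP) records
#'
#' Aggregates a bead observation table into one record per bead: PBP is the
#' sum over the bead's microcolonies of colony area times mean fluorescence
#' intensity; beads with at most one colony are `single` occupancy,
#' otherwise `multiple`.
#'
#' @param beads A bead observation tibble (see [generate_bead_table()]).
#' @return Tibble with `bead_id`, `time_h`, `condition`, `pbp`,
#'   `n_colonies`, `occupancy_class`.
#' @export
compute_pbp <- function(beads) {
  assert_that(all(c("bead_id", "area_px", "mean_intensity") %in% names(beads)),
              "`beads` must have bead_id, area_px and mean_intensity columns")
  assert_that(all(beads$area_px > 0), "colony areas must be positive")
  assert_that(all(beads$mean_intensity >= 0), "intensities must be non-negative")
  grp <- intersect(c("bead_id", "time_h", "condition"), names(beads))
  beads %>%
    group_by(across(all_of(grp))) %>%
    summarise(pbp = sum(.data$area_px * .data$mean_intensity),
              n_colonies = dplyr::n(), .groups = "drop") %>%
    mutate(occupancy_class = ifelse(.data$n_colonies <= 1, "single", "multiple"))
}

#' Per-colony PBPs of two-colony beads
#'
#' @param beads A bead observation tibble.
#' @return Tibble with `bead_id`, `pbp1`, `pbp2` (per-colony
#'   area-times-intensity products), for beads with exactly two colonies.
#' @export
pair_pbp <- function(beads) {
  beads %>%
    mutate(colony_pbp = .data$area_px * .data$mean_intensity) %>%
    group_by(.data$bead_id) %>%
    filter(dplyr::n() == 2) %>%
    summarise(pbp1 = .data$colony_pbp[1], pbp2 = .data$colony_pbp[2],
              .groups = "drop")
}

#' Classify a paired bead into a pair-growth category
#'
#' The four exhaustive, mutually exclusive categories: both partners below
#' the no-growth PBP threshold (`both_no_growth`); exactly one below
#' (`one_not_growing`); both growing with a PBP ratio inside the balanced
#' band (`balanced`); the remainder (`imbalanced`).
#'
#' @param pbp1,pbp2 Non-negative per-colony PBP values (vectorized).
#' @param thresholds A [pair_thresholds()].
#' @return Factor with levels `both_no_growth`, `one_not_growing`,
#'   `balanced`, `imbalanced`.
#' @export
#' @examples
#' classify_pair(10^4, 10^4.5)  # balanced
classify_pair <- function(pbp1, pbp2, thresholds = pair_thresholds()) {
  assert_that(all(pbp1 >= 0) && all(pbp2 >= 0), "PBP values must be >= 0")
  cut_v <- 10^thresholds$log10_nogrowth
  below1 <- pbp1 < cut_v
  below2 <- pbp2 < cut_v
  ratio <- pbp1 / pbp2
  balanced <- ratio >= thresholds$ratio_bounds[1] &
    ratio <= thresholds$ratio_bounds[2]
  out <- ifelse(below1 & below2, "both_no_growth",
         ifelse(xor(below1, below2), "one_not_growing",
         ifelse(balanced, "balanced", "imbalanced")))
  factor(out, levels = PAIR_CATEGORIES)
}

#' Pair-category percentages of a set of paired beads
#'
#' @param pairs Tibble with `pbp1`, `pbp2` (see [pair_pbp()]).
#' @param thresholds A [pair_thresholds()].
#' @return Tibble with `category`, `n`, `pct` (percentages sum to 100).
#' @export
pair_category_table <- function(pairs, thresholds = pair_thresholds()) {
  assert_that(nrow(pairs) > 0, "no paired beads supplied")
  cat_v <- classify_pair(pairs$pbp1, pairs$pbp2, thresholds)
  tb <- table(cat_v)
  tibble(category = names(tb), n = as.integer(tb),
         pct = 100 * as.integer(tb) / sum(tb))
}

#' Monte-Carlo null for pair-category percentages
#'
#' Scatters `n_points` uniform points in the given log10 PBP-by-PBP
#' rectangle, classifies them, and repeats `n_repeats` times to build a
#' null distribution of category percentages. Observed percentages are then
#' compared to the null replicates with a two-sided unequal-variance
#' t-test (one-sample against the observed value when only a single
#' observed percentage is available).
#'
#' @param observed Tibble with `category` and `pct` columns; several rows
#'   per category (e.g. one per time point) are used as a second t-test
#'   sample.
#' @param log10_bounds Length-2 numeric: the log10 PBP range of the square
#'   scatter region.
#' @param n_points Points per null replicate (default 1000).
#' @param n_repeats Null replicates (default 10,000).
#' @param thresholds A [pair_thresholds()].
#' @param seed Integer seed.
#' @return Tibble with `category`, `observed_mean`, `null_mean`, `null_sd`,
#'   `p_value`.
#' @export
random_category_null <- function(observed, log10_bounds = c(1, 6),
                                 n_points = 1000, n_repeats = 10000,
                                 thresholds = pair_thresholds(), seed = 1L) {
  assert_that(diff(log10_bounds) > 0, "degenerate `log10_bounds`")
  assert_that(all(c("category", "pct") %in% names(observed)),
              "`observed` needs category and pct columns")
  with_seed(seed, {
    total <- n_points * n_repeats
    p1 <- 10^runif(total, log10_bounds[1], log10_bounds[2])
    p2 <- 10^runif(total, log10_bounds[1], log10_bounds[2])
    cats <- classify_pair(p1, p2, thresholds)
    rep_id <- rep(seq_len(n_repeats), each = n_points)
    null_pct <- 100 * table(rep_id, cats) / n_points
    purrr::map_dfr(intersect(PAIR_CATEGORIES, observed$category), function(cc) {
      obs <- observed$pct[observed$category == cc]
      null_v <- as.numeric(null_pct[, cc])
      p <- if (length(obs) >= 2) {
        tryCatch(t.test(obs, null_v)$p.value, error = function(e) NA_real_)
      } else {
        tryCatch(t.test(null_v, mu = obs)$p.value, error = function(e) NA_real_)
      }
      tibble(category = cc, observed_mean = mean(obs),
             null_mean = mean(null_v), null_sd = sd(null_v), p_value = p)
    })
  })
}

#' Fraction of beads exceeding a fold-change in productivity
#'
#' Computes the fraction of beads whose PBP exceeds `fold` times a t = 0
#' reference level (the cohort median of `pbp_t0`). With a `replicate`
#' label per bead, the fraction and its 95% confidence interval are taken
#' across replicate-level fractions (normal approximation); otherwise a
#' bootstrap over beads is used.
#'
#' @param pbp_t PBP values at the later time point.
#' @param pbp_t0 PBP values at t = 0 (reference cohort).
#' @param replicate Optional replicate label per element of `pbp_t`.
#' @param fold Fold-change threshold (default 10).
#' @param n_boot Bootstrap draws when no replicates are given.
#' @param seed Integer seed (bootstrap only).
#' @return Tibble with `fraction`, `ci_lo`, `ci_hi`, `n_beads`, `n_replicates`.
#' @export
fraction_over_10x <- function(pbp_t, pbp_t0, replicate = NULL, fold = 10,
                              n_boot = 1000, seed = 1L) {
  assert_that(length(pbp_t) > 0 && length(pbp_t0) > 0,
              "both PBP vectors must be non-empty")
  ref <- median(pbp_t0)
  over <- pbp_t > fold * ref
  if (!is.null(replicate)) {
    assert_that(length(replicate) == length(pbp_t),
                "`replicate` must match `pbp_t`")
    fr <- tapply(over, replicate, mean)
    m <- mean(fr)
    se <- sd(fr) / sqrt(length(fr))
    tibble(fraction = m, ci_lo = max(0, m - 1.96 * se),
           ci_hi = min(1, m + 1.96 * se),
           n_beads = length(over), n_replicates = length(fr))
  } else {
    m <- mean(over)
    bs <- with_seed(seed, {
      replicate(n_boot, mean(sample(over, length(over), replace = TRUE)))
    })
    tibble(fraction = m, ci_lo = unname(quantile(bs, 0.025)),
           ci_hi = unname(quantile(bs, 0.975)),
           n_beads = length(over), n_replicates = NA_integer_)
  }
}

#' Compare single-occupancy and multiple-occupancy productivity
#'
#' Multiple-occupancy PBPs are first corrected by the mean number of
#' colonies per multiple bead, then compared to singles by (i) a Wilcoxon
#' rank-sum test on the full distributions, (ii) a Wilcoxon test on
#' replicate-level 75th percentiles (skipped with a warning when fewer than
#' two replicates per group are available), and (iii) a Monte-Carlo
#' Fisher's exact test (2000 replicates) on binned normalized PBP
#' distributions.
#'
#' @param pbp_single PBP values of single-occupancy beads.
#' @param pbp_multiple PBP values of multiple-occupancy beads.
#' @param mean_colonies Mean number of colonies per multiple bead; the
#'   correction divisor.
#' @param replicate_single,replicate_multiple Optional replicate labels.
#' @param n_bins Number of log10 PBP bins for the Fisher test.
#' @param fisher_reps Monte-Carlo replicates for the Fisher test.
#' @param seed Integer seed.
#' @return A tibble with one row per test: `test`, `statistic`, `p_value`,
#'   plus the `pbp_ratio` of multiple to single medians after correction.
#' @export
compare_single_vs_paired <- function(pbp_single, pbp_multiple, mean_colonies,
                                     replicate_single = NULL,
                                     replicate_multiple = NULL,
                                     n_bins = 12, fisher_reps = 2000,
                                     seed = 1L) {
  assert_that(length(pbp_single) > 0 && length(pbp_multiple) > 0,
              "both groups must be non-empty")
  assert_that(mean_colonies > 0, "`mean_colonies` must be positive")
  corrected <- pbp_multiple / mean_colonies

  w_all <- wilcox.test(pbp_single, corrected, exact = FALSE)
  rows <- tibble(test = "wilcoxon_median", statistic = unname(w_all$statistic),
                 p_value = w_all$p.value)

  if (!is.null(replicate_single) && !is.null(replicate_multiple) &&
      length(unique(replicate_single)) >= 2 &&
      length(unique(replicate_multiple)) >= 2) {
    q_s <- tapply(pbp_single, replicate_single, quantile, probs = 0.75)
    q_m <- tapply(corrected, replicate_multiple, quantile, probs = 0.75)
    w_q <- wilcox.test(as.numeric(q_s), as.numeric(q_m), exact = FALSE)
    rows <- bind_rows(rows, tibble(test = "wilcoxon_p75",
                                   statistic = unname(w_q$statistic),
                                   p_value = w_q$p.value))
  } else {
    warn("fewer than 2 replicates per group: 75th-percentile test skipped")
  }

  lx <- log10(pmax(c(pbp_single, corrected), 1e-12))
  br <- seq(min(lx), max(lx), length.out = n_bins + 1)
  br[1] <- br[1] - 1e-9; br[n_bins + 1] <- br[n_bins + 1] + 1e-9
  b_s <- table(cut(log10(pmax(pbp_single, 1e-12)), br))
  b_m <- table(cut(log10(pmax(corrected, 1e-12)), br))
  ct <- rbind(as.integer(b_s), as.integer(b_m))
  ct <- ct[, colSums(ct) > 0, drop = FALSE]
  f <- with_seed(seed, fisher.test(ct, simulate.p.value = TRUE, B = fisher_reps))
  bind_rows(rows,
            tibble(test = "fisher_mc", statistic = NA_real_, p_value = f$p.value)) %>%
    mutate(pbp_ratio = median(pbp_multiple) / mean_colonies / median(pbp_single))
}

#' Paired-growth grid and size-ratio profile
#'
#' Bins paired microcolony sizes into a 12 x 12 grid of log10 size bins
#' (0.5 wide, covering log10 = 0-6) and computes the distribution of
#' absolute log10 size ratios. Partners are unordered, so ratios are
#' reported as `>= 1` (larger over smaller).
#'
#' @param size1,size2 Paired sizes (e.g. per-partner cell counts or PBPs).
#' @param exclude_nongrowing Drop pairs with a partner at or below
#'   `nogrow_size`.
#' @param nogrow_size Size at or below which a partner counts as
#'   non-growing (default 1, i.e. no division).
#' @param bin_width,log10_max Grid geometry (defaults 0.5 and 6).
#' @return A list with `grid` (tibble `bin_i`, `bin_j`, `count`, including
#'   zero cells; `bin_i` indexes partner 1), `log10_ratios` (numeric), and
#'   `ratio_hist` (tibble `log10_mid`, `prop` over bins of width
#'   `bin_width`, props summing to 1).
#' @export
pair_grid_and_ratios <- function(size1, size2, exclude_nongrowing = FALSE,
                                 nogrow_size = 1, bin_width = 0.5,
                                 log10_max = 6) {
  assert_that(length(size1) == length(size2), "paired sizes must align")
  if (exclude_nongrowing) {
    keep <- size1 > nogrow_size & size2 > nogrow_size
    size1 <- size1[keep]; size2 <- size2[keep]
  }
  # sizes <= 1 (incl. non-positive with exclusion off) land in the first bin
  l1 <- pmin(pmax(log10(pmax(size1, 1)), 0), log10_max - 1e-9)
  l2 <- pmin(pmax(log10(pmax(size2, 1)), 0), log10_max - 1e-9)
  n_bins <- round(log10_max / bin_width)
  i1 <- pmin(floor(l1 / bin_width) + 1L, n_bins)
  i2 <- pmin(floor(l2 / bin_width) + 1L, n_bins)
  grid <- tidyr::expand_grid(bin_i = seq_len(n_bins), bin_j = seq_len(n_bins)) %>%
    left_join(
      tibble(bin_i = i1, bin_j = i2) %>% count(.data$bin_i, .data$bin_j),
      by = c("bin_i", "bin_j")
    ) %>%
    mutate(count = tidyr::replace_na(.data$n, 0L)) %>%
    select("bin_i", "bin_j", "count")
  ratios <- abs(l1 - l2)
  br <- seq(0, log10_max, by = bin_width)
  h <- hist(pmin(ratios, log10_max - 1e-9), breaks = br, plot = FALSE)
  prop <- if (length(ratios) > 0) h$counts / sum(h$counts) else h$counts * 0
  list(grid = grid, log10_ratios = ratios,
       ratio_hist = tibble(log10_mid = h$mids, prop = prop))
}

#' Estimate generations of cell division
#'
#' `log2(final / initial)` divisions per founder. Values below zero (final
#' smaller than initial) are reported as 0 with a warning.
#'
#' @param final_cells Final cell count(s).
#' @param initial_cells Initial cell count(s) (default 1 founder).
#' @return Generations (vectorized).
#' @export
#' @examples
#' estimate_generations(1024)  # 10
estimate_generations <- function(final_cells, initial_cells = 1) {
  assert_that(all(initial_cells >= 1), "`initial_cells` must be >= 1")
  g <- log2(final_cells / initial_cells)
  if (any(g < 0)) {
    warn("final cell count below initial; generations floored at 0")
    g <- pmax(g, 0)
  }
  g
}

#' Estimate generations from colony geometry
#'
#' Assumes a round, packed colony: the cell count is
#' `packing * (d_colony / d_cell)^3`, and generations are its log2.
#'
#' @param d_colony,d_cell Colony and cell diameters (same units).
#' @param packing Sphere packing fraction (default 0.5).
#' @return A tibble with `n_cells` and `generations`.
#' @export
#' @examples
#' estimate_generations_geometry(12.6, 1)  # ~1000 cells, ~10 generations
estimate_generations_geometry <- function(d_colony, d_cell, packing = 0.5) {
  assert_that(all(d_colony > 0) && all(d_cell > 0) && all(packing > 0),
              "geometry inputs must be positive")
  n_cells <- packing * (d_colony / d_cell)^3
  tibble(n_cells = n_cells, generations = log2(pmax(n_cells, 1)))
}
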