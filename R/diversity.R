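# Alpha-diversity measures and between-condition comparisons.

DIVERSITY_MEASURES <- c("richness", "shannon", "simpson", "inv_simpson", "evenness")

#' Alpha-diversity measures of a count vector
#'
#' Computes five alpha-diversity measures on one OTU count vector:
#' richness (OTUs with non-zero counts), Shannon index (natural log),
#' Simpson index (`sum p_i^2`), inverse Simpson, and Pielou evenness
#' (`H / ln(richness)`, `NA` for fewer than two OTUs). Shannon and inverse
#' Simpson are delegated to \pkg{vegan}.
#'
#' @param counts Non-negative numeric vector with positive total.
#' @return A one-row tibble with the five measures.
#' @export
#' @examples
#' alpha_diversity(c(10, 10, 10, 10))  # H = log(4), evenness 1
alpha_diversity <- function(counts) {
  assert_that(all(counts >= 0), "`counts` must be non-negative")
  assert_that(sum(counts) > 0, "all-zero count vector")
  rich <- sum(counts > 0)
  h <- as.numeric(vegan::diversity(counts, index = "shannon"))
  inv <- as.numeric(vegan::diversity(counts, index = "invsimpson"))
  tibble(
    richness = as.integer(rich),
    shannon = h,
    simpson = 1 / inv,
    inv_simpson = inv,
    evenness = if (rich > 1) h / log(rich) else NA_real_
  )
}

#' Compare alpha diversity between two groups of samples
#'
#' Welch's two-sided t-test per measure, reporting `log10(p)` and the
#' direction of the comparison group: `"loss"` when group B's mean is below
#' group A's, `"gain"` otherwise. Identical degenerate groups (zero
#' variance, equal means) give p = 1.
#'
#' @param a,b Tibbles of per-sample measure values (as rows of
#'   [alpha_diversity()] output); each needs at least 2 rows.
#' @param measures Measure columns to compare.
#' @return Tibble with `measure`, `mean_a`, `mean_b`, `p_value`, `log10_p`,
#'   `direction`.
#' @export
diversity_compare <- function(a, b, measures = DIVERSITY_MEASURES) {
  assert_that(nrow(a) >= 2 && nrow(b) >= 2, "each group needs >= 2 samples")
  measures <- intersect(measures, intersect(names(a), names(b)))
  assert_that(length(measures) > 0, "no shared measure columns")
  purrr::map_dfr(measures, function(m) {
    xa <- a[[m]][!is.na(a[[m]])]
    xb <- b[[m]][!is.na(b[[m]])]
    p <- if (length(unique(c(xa, xb))) == 1) {
      1
    } else {
      tryCatch(t.test(xa, xb)$p.value, error = function(e) NA_real_)
    }
    tibble(measure = m, mean_a = mean(xa), mean_b = mean(xb),
           p_value = p, log10_p = log10(p),
           direction = ifelse(mean(xb) < mean(xa), "loss", "gain"))
  })
}

#' Alpha-diversity trajectory across simulated conditions
#'
#' Computes alpha-diversity measures on subsampled stationary-phase OTU
#' counts, per condition and repeat. Input is a long tibble of per-OTU
#' counts (e.g. from [otu_cell_counts()] stacked over conditions/repeats);
#' each condition-repeat vector is subsampled without replacement to
#' `target` counts (default 50,000) before the measures are computed.
#'
#' @param counts_long Tibble with columns `condition`, `rep`, `otu_id`, and
#'   `count`.
#' @param target Subsampling depth per sample.
#' @param seed Integer seed; each sample's subsample seed derives from it.
#' @return Tibble with `condition`, `rep`, and the five measures.
#' @export
diversity_trajectory <- function(counts_long, target = 50000, seed = 1L) {
  assert_that(all(c("condition", "rep", "otu_id", "count") %in% names(counts_long)),
              "`counts_long` needs condition, rep, otu_id, count columns")
  groups <- counts_long %>% dplyr::distinct(.data$condition, .data$rep)
  assert_that(nrow(groups) >= 1, "empty input")
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- counts_long %>%
      filter(.data$condition == groups$condition[i], .data$rep == groups$rep[i])
    sub <- subsample_counts(g$count, target,
                            seed = stage_seed(seed, paste0("div_", groups$condition[i]),
                                              as.integer(as.factor(groups$rep))[i]))
    dplyr::bind_cols(tibble(condition = groups$condition[i], rep = groups$rep[i]),
                     alpha_diversity(as.numeric(sub)))
  })
}
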