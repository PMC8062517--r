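# Small in-code fixtures shared across test files.

# wrap a counts matrix (OTUs x replicates) as an OTU abundance table
make_otu_table <- function(counts, otu_ids = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  reps <- paste0("rep", seq_len(ncol(counts)))
  colnames(counts) <- reps
  tbl <- tibble::tibble(
    otu_id = otu_ids %||% sprintf("OTU_%03d", seq_len(n)),
    taxon = sprintf("taxon_%03d", seq_len(n)),
    master_count = as.integer(rowSums(counts))
  )
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(counts))
  connectisim:::new_otu_table(tbl, reps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal founder community with explicit fields
make_community <- function(mu, alive = TRUE, bead_id = NULL, slot = NULL,
                           otu_id = NULL, environment = "liquid") {
  n <- length(mu)
  tbl <- tibble::tibble(
    lineage_id = seq_len(n),
    otu_id = otu_id %||% sprintf("OTU_%03d", seq_len(n)),
    mu = mu,
    alive = rep_len(alive, n)
  )
  if (!is.null(bead_id)) {
    tbl$bead_id <- bead_id
    tbl$slot <- slot %||% stats::ave(rep(1L, n), bead_id, FUN = seq_along)
  }
  as_community(tbl, environment)
}

# small standard generator config used in several tests (fast to draw)
small_config <- function(seed = 1L, ...) {
  community_config(n_otus_master = 300, per_replicate_depth = 5000,
                   n_replicates = 4, seed = seed, ...)
}
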