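# Plain-text (TSV) serialization of the package's tables.

#' Write / read an OTU abundance table as TSV
#'
#' Columns: `otu_id`, `taxon`, optionally `master_count`, then one column
#' per replicate. Reading restores the replicate attribute and class.
#'
#' @param table A `connsim_otu_table`.
#' @param path File path.
#' @return `write_otu_table` returns `path` invisibly; `read_otu_table`
#'   returns the table.
#' @export
write_otu_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  new_otu_table(tbl, grep("^rep", names(tbl), value = TRUE))
}

#' Write / read a bead observation table as TSV
#'
#' Columns: `bead_id`, `time_h`, `condition`, `colony_idx`, `area_px`,
#' `mean_intensity`, `channel`.
#'
#' @param beads A bead observation tibble.
#' @param path File path.
#' @return `write_bead_table` returns `path` invisibly; `read_bead_table`
#'   returns the tibble.
#' @export
write_bead_table <- function(beads, path) {
  readr::write_tsv(as_tibble(beads), path)
  invisible(path)
}

#' @rdname write_bead_table
#' @export
read_bead_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  structure(tbl, class = c("connsim_bead_table", class(tibble())))
}

#' Write / read a founder community as TSV
#'
#' Columns: `lineage_id`, `otu_id`, `mu`, `alive`, and for bead
#' communities `bead_id`, `slot`. The environment is stored in a header
#' comment line.
#'
#' @param community A `connsim_community`.
#' @param path File path.
#' @return `write_community` returns `path` invisibly; `read_community`
#'   returns the community.
#' @export
write_community <- function(community, path) {
  env <- community_environment(community)
  con <- file(path, "w")
  writeLines(sprintf("# environment: %s", env), con)
  close(con)
  readr::write_tsv(as_tibble(community), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_community
#' @export
read_community <- function(path) {
  first <- readLines(path, n = 1)
  env <- if (grepl("environment: beads", first)) "beads" else "liquid"
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  as_community(tbl, environment = env)
}
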