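#' Read and write distribution / sample tables
#'
#' Distributions travel as TSV (one row per state: species columns, then
#' `prob`); samples and trajectories as CSV (one row per sample/event).
#' Both are trivially diffable and plottable.
#'
#' @param dist A `cme_dist`.
#' @param file Path.
#' @export
write_dist_tsv <- function(dist, file) {
  utils::write.table(as.data.frame(dist), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_dist_tsv
#' @param scale Scale factor of the lattice the table lives on (default 1).
#' @export
read_dist_tsv <- function(file, scale = 1L) {
  df <- utils::read.delim(file, check.names = FALSE)
  if (!"prob" %in% names(df)) stop("distribution TSV needs a `prob` column", call. = FALSE)
  species <- setdiff(names(df), "prob")
  upper <- vapply(species, function(s) max(df[[s]]), numeric(1))
  space <- state_space(stats::setNames(as.integer(upper), species), scale = scale)
  prob <- numeric(n_states(space))
  prob[state_to_index(space, as.matrix(df[species]))] <- df$prob
  new_cme_dist(space, prob)
}

#' @rdname write_dist_tsv
#' @param samples A `cme_samples` tibble.
#' @export
write_samples_csv <- function(samples, file) {
  utils::write.csv(as.data.frame(samples), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dist_tsv
#' @export
read_samples_csv <- function(file) {
  df <- tibble::as_tibble(utils::read.csv(file, check.names = FALSE))
  class(df) <- c("cme_samples", class(df))
  df
}
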