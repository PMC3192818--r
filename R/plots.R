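#' Plot a distribution
#'
#' 1-D distributions draw as probability columns; 2-D joint distributions
#' as a probability heat map.
#'
#' @param object A `cme_dist`.
#' @param trans Optional transform applied to the fill scale for 2-D plots
#'   (e.g. `"sqrt"` to bring up minor modes).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cme_dist <- function(object, trans = "identity", ...) {
  sp <- dist_space(object)
  if (length(sp$species) == 1) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[sp$species[1]]], y = .data$prob)) +
      ggplot2::geom_col(width = 0.9 * sp$scale, fill = "steelblue") +
      ggplot2::labs(x = paste(sp$species[1], "(molecules)"), y = "probability") +
      ggplot2::theme_minimal()
  } else if (length(sp$species) == 2) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[sp$species[1]]],
                                         y = .data[[sp$species[2]]],
                                         fill = .data$prob)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(trans = trans) +
      ggplot2::labs(x = paste(sp$species[1], "(molecules)"),
                    y = paste(sp$species[2], "(molecules)"), fill = "prob") +
      ggplot2::theme_minimal()
  } else {
    stop("autoplot supports 1- and 2-species distributions; marginalize first",
         call. = FALSE)
  }
}

#' Plot a sample set
#'
#' 1-D samples draw as a frequency histogram on the lattice; 2-D samples as
#' a binned count heat map.
#'
#' @param object A `cme_samples` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cme_samples <- function(object, ...) {
  sp <- attr(object, "space")
  cols <- if (!is.null(sp)) sp$species else setdiff(names(object), ".mode")
  if (length(cols) == 1) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[cols[1]]])) +
      ggplot2::geom_histogram(binwidth = 1, fill = "steelblue", colour = NA) +
      ggplot2::labs(x = paste(cols[1], "(molecules)"), y = "count") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[cols[1]]], y = .data[[cols[2]]])) +
      ggplot2::geom_bin2d(binwidth = c(1, 1)) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = paste(cols[1], "(molecules)"),
                    y = paste(cols[2], "(molecules)")) +
      ggplot2::theme_minimal()
  }
}

#' Overlay marginals of several distributions
#'
#' Convenience comparison plot: the 1-D marginal of each named
#' distribution for one species, overlaid as step lines (e.g. direct CME
#' solution vs sampler histogram vs convolved distribution).
#'
#' @param ... Named `cme_dist` objects on compatible spaces.
#' @param species Species to marginalize onto (default: first).
#' @return A ggplot object.
#' @export
plot_marginals <- function(..., species = NULL) {
  dists <- list(...)
  if (is.null(names(dists)) || any(!nzchar(names(dists)))) {
    names(dists) <- paste0("dist", seq_along(dists))
  }
  if (is.null(species)) species <- dist_space(dists[[1]])$species[1]
  df <- dplyr::bind_rows(lapply(names(dists), function(nm) {
    m <- marginal(dists[[nm]], species)
    tibble::tibble(x = m[[species]], prob = m$prob, which = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$prob,
                                   colour = .data$which)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = paste(species, "(molecules)"), y = "probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
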