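#' Probability distributions on the state lattice
#'
#' A `cme_dist` is a tibble with one row per lattice point: the species
#' columns hold molecule numbers and `prob` the probability mass. The
#' underlying [state_space()] is kept as an attribute so distributions can
#' be compared, convolved and marginalized consistently. For scaled lattices
#' (`S > 1`) `prob` is the aggregated mass represented by each coarse point;
#' the per-fine-state density view is `prob / S^d`.
#'
#' @param space A [state_space()].
#' @param prob Numeric vector of masses over `enumerate_states(space)`
#'   (column-major order); normalized to sum to 1.
#' @return A tibble of class `cme_dist`.
#' @export
new_cme_dist <- function(space, prob) {
  if (length(prob) != n_states(space)) {
    stop("`prob` has length ", length(prob), "; space has ", n_states(space),
         " points", call. = FALSE)
  }
  if (any(!is.finite(prob)) || any(prob < -1e-12)) {
    stop("probability mass must be finite and nonnegative", call. = FALSE)
  }
  prob <- pmax(prob, 0)
  total <- sum(prob)
  if (total <= 0) stop("all-zero probability mass", call. = FALSE)
  out <- tibble::as_tibble(as.data.frame(enumerate_states(space)))
  out$prob <- prob / total
  attr(out, "space") <- space
  class(out) <- c("cme_dist", class(out))
  out
}

#' @export
print.cme_dist <- function(x, ...) {
  sp <- dist_space(x)
  cat("<cme_dist> over ", format(nrow(x), big.mark = ","), " states (",
      paste(sp$species, collapse = ", "),
      if (sp$scale > 1L) paste0("; scale S = ", sp$scale), ")\n", sep = "")
  NextMethod()
}

#' @rdname new_cme_dist
#' @param dist A `cme_dist`.
#' @export
dist_space <- function(dist) attr(dist, "space")

#' Histogram samples onto a state lattice
#'
#' Bins a sample set onto the lattice of `space`, producing an empirical
#' `cme_dist`. Values outside the box are clamped into the boundary cell
#' (the clamped mass fraction is reported in attribute `clamped`);
#' non-integer values are rounded to the nearest lattice point.
#'
#' @param samples A `cme_samples` tibble (see [mgs_sample()]) or a matrix /
#'   data frame of states with one column per species.
#' @param space A [state_space()].
#' @return A `cme_dist` with the empirical state frequencies.
#' @export
as_cme_dist <- function(samples, space) {
  m <- as.matrix(as.data.frame(samples)[, space$species, drop = FALSE])
  S <- space$scale
  m <- round(m / S) * S
  clamped <- 0L
  for (i in seq_along(space$species)) {
    out_i <- m[, i] < 0 | m[, i] > space$upper[i]
    clamped <- clamped + sum(out_i)
    m[, i] <- pmin(pmax(m[, i], 0), (space$dims[i] - 1L) * S)
  }
  idx <- state_to_index(space, m)
  mass <- tabulate(idx, nbins = n_states(space))
  out <- new_cme_dist(space, mass / sum(mass))
  attr(out, "clamped") <- clamped / nrow(m)
  out
}

#' Marginal distribution of one species
#'
#' @param dist A `cme_dist`.
#' @param species Species name to marginalize onto.
#' @return A 1-D `cme_dist` over that species.
#' @export
marginal <- function(dist, species) {
  sp <- dist_space(dist)
  if (!species %in% sp$species) stop("unknown species `", species, "`", call. = FALSE)
  v <- dist[[species]]
  grid <- seq(0L, by = sp$scale, length.out = sp$dims[match(species, sp$species)])
  mass <- vapply(grid, function(g) sum(dist$prob[v == g]), numeric(1))
  sp1 <- state_space(stats::setNames(sp$upper[species], species), scale = sp$scale)
  new_cme_dist(sp1, mass)
}

#' Per-species mean and standard deviation
#'
#' Exact moments for distributions (over the full truncated lattice) and
#' sample moments for sample sets.
#'
#' @param x A `cme_dist` or `cme_samples`.
#' @return A tibble with columns `species`, `mean`, `sd`.
#' @examples
#' poisson_constitutive(20, 1, 60) |> summarize_dist()
#' @export
summarize_dist <- function(x) {
  if (inherits(x, "cme_dist")) {
    sp <- dist_space(x)
    res <- lapply(sp$species, function(s) {
      v <- x[[s]]
      mu <- sum(v * x$prob)
      tibble::tibble(species = s, mean = mu,
                     sd = sqrt(max(sum((v - mu)^2 * x$prob), 0)))
    })
    return(dplyr::bind_rows(res))
  }
  df <- as.data.frame(x)
  cols <- setdiff(names(df), c("prob", ".iter"))
  dplyr::bind_rows(lapply(cols, function(s) {
    tibble::tibble(species = s, mean = mean(df[[s]]), sd = stats::sd(df[[s]]))
  }))
}

#' Draw exact samples from a distribution
#'
#' @param dist A `cme_dist`.
#' @param n Number of draws.
#' @return A `cme_samples` tibble (one row per draw).
#' @export
sample_dist <- function(dist, n) {
  sp <- dist_space(dist)
  idx <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$prob)
  out <- tibble::as_tibble(as.data.frame(index_to_state(sp, idx)))
  attr(out, "space") <- sp
  class(out) <- c("cme_samples", class(out))
  out
}
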