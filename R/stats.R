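#' Sum of squared deviations between two distributions
#'
#' `sum((P - Q)^2)` over the shared lattice; the standard comparison metric
#' for steady-state distributions here. Bounded by 2 (attained by disjoint
#' point masses). Sample sets are histogrammed onto the grid first via
#' [as_cme_dist()].
#'
#' @param p,q `cme_dist` objects on the same state space (or `cme_samples`
#'   for `q`, binned onto `p`'s space).
#' @return A number in `[0, 2]`.
#' @export
ssd <- function(p, q) {
  if (!inherits(p, "cme_dist")) stop("`p` must be a cme_dist", call. = FALSE)
  if (!inherits(q, "cme_dist")) q <- as_cme_dist(q, dist_space(p))
  sp <- dist_space(p); sq <- dist_space(q)
  if (!identical(sp$species, sq$species) || !identical(sp$dims, sq$dims) ||
      sp$scale != sq$scale) {
    stop("distributions live on different state spaces", call. = FALSE)
  }
  sum((p$prob - q$prob)^2)
}

#' ON fraction by the dominant-species rule
#'
#' For a two-species distribution, the ON fraction is the probability that
#' the first species has the higher molecule number; mass on the tie
#' diagonal is split 50/50 by default (the partitioning convention for the
#' toggle switch, where ON means U-dominant).
#'
#' @param dist A 2-species `cme_dist`.
#' @param tie One of `"split"` (default), `"on"`, `"off"`: where tie mass
#'   `u = v` goes.
#' @return ON fraction in `[0, 1]`; `1 -` the complementary fraction exactly.
#' @examples
#' make_toggle() |> solve_model() |> on_fraction_dominant()
#' @export
on_fraction_dominant <- function(dist, tie = c("split", "on", "off")) {
  tie <- match.arg(tie)
  sp <- dist_space(dist)
  if (length(sp$species) != 2) stop("dominant-species rule needs exactly 2 species", call. = FALSE)
  u <- dist[[sp$species[1]]]; v <- dist[[sp$species[2]]]
  on <- sum(dist$prob[u > v])
  tw <- sum(dist$prob[u == v])
  on + switch(tie, split = tw / 2, on = tw, off = 0)
}

# Local maxima of a mass vector after merging plateaus; each plateau is
# represented by its leftmost bin. Returns indices.
local_maxima <- function(p) {
  stopifnot(length(p) >= 2)
  keep <- c(TRUE, p[-1] != p[-length(p)])  # plateau left edges
  q <- p[keep]
  pos <- which(keep)
  L <- length(q)
  is_max <- vapply(seq_len(L), function(i) {
    left <- if (i > 1) q[i - 1] else -Inf
    right <- if (i < L) q[i + 1] else -Inf
    q[i] > left && q[i] > right
  }, logical(1))
  # ignore maxima that are vanishingly small relative to the global peak
  # (numerical wiggle in far tails)
  pos[is_max & q > 1e-12 * max(p)]
}

# Topographic prominence of each local maximum: height minus the highest
# saddle on a route to higher terrain (the global maximum gets its full
# height). For a smooth bimodal histogram the two most prominent peaks are
# simply the two modes; on noisy histograms prominence discounts wiggles
# riding on a peak's flank.
peak_prominence <- function(p, peaks) {
  vapply(peaks, function(i) {
    h <- p[i]
    saddles <- c()
    left_higher <- which(p[seq_len(i - 1)] > h)
    if (length(left_higher)) {
      saddles <- c(saddles, min(p[max(left_higher):i]))
    }
    right_higher <- i + which(p[-seq_len(i)] > h)
    if (length(right_higher)) {
      saddles <- c(saddles, min(p[i:min(right_higher)]))
    }
    if (!length(saddles)) h else h - max(saddles)
  }, numeric(1))
}

#' ON fraction by the valley rule
#'
#' Partitions a 1-D histogram into OFF (low molecule numbers) and ON (high)
#' by locating the two most prominent peaks (local maxima ranked by
#' topographic prominence, which for a smooth bimodal histogram is just
#' the two modes; plateaus are merged and represented by their leftmost
#' bin) and
#' taking the lowest bin strictly between them as the border; the border
#' bin itself belongs to OFF. If only one peak exists, the shoulder rule
#' applies: the border is the interior point with the smallest absolute
#' finite difference between consecutive bins.
#'
#' @param hist A 1-D `cme_dist`, or a bare numeric mass vector over bins
#'   `0, 1, 2, ...`.
#' @return A one-row tibble with columns `on` (ON mass, strictly above the
#'   border bin), `border` (0-based border bin) and `rule` (`"valley"` or
#'   `"shoulder"`).
#' @examples
#' on_fraction_valley(c(0.3, 0.1, 0.05, 0.1, 0.45))
#' @export
on_fraction_valley <- function(hist) {
  p <- if (inherits(hist, "cme_dist")) {
    if (length(dist_space(hist)$species) != 1) stop("valley rule needs a 1-D distribution", call. = FALSE)
    hist$prob
  } else as.numeric(hist)
  L <- length(p)
  if (L < 2) stop("histogram needs at least 2 bins", call. = FALSE)
  peaks <- local_maxima(p)
  if (length(peaks) >= 2) {
    prom <- peak_prominence(p, peaks)
    top2 <- sort(peaks[order(prom, decreasing = TRUE)][1:2])
    between <- (top2[1] + 1):(top2[2] - 1)
    border <- between[which.min(p[between])]
    rule <- "valley"
  } else {
    d <- abs(diff(p))
    border <- which.min(d) + 1L  # right endpoint of the flattest step
    rule <- "shoulder"
  }
  tibble::tibble(on = sum(p[seq_len(L) > border]), border = border - 1L, rule = rule)
}
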