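#' Extrinsic noise specification
#'
#' Extrinsic noise (variability from everything outside the modeled
#' reactions) is represented as convolution of the intrinsic-noise-only
#' distribution with a zero-mean Gaussian shift distribution, plus an
#' optional uniform-weight background term:
#' `P = (1 - a) * (P_intrinsic * M0) + a * B`.
#'
#' @param sigma Shift standard deviation(s): a scalar (isotropic), a vector
#'   (diagonal covariance, molecule-number units), or a full covariance
#'   matrix (units squared, symmetric positive semidefinite).
#' @param a Background weight in `[0, 1)`.
#' @param background Background distribution `B` (a `cme_dist`), or `NULL`
#'   for uniform over the truncated box (the distribution of extrinsic
#'   noise far from the intrinsic prediction).
#' @param modes Optional per-mode widths: a list of
#'   `list(center = <state>, sigma = <as above>)`; the input distribution
#'   is partitioned by nearest mode center (Euclidean distance scaled by
#'   each mode's mean sigma) and each part convolved with its own kernel.
#' @param mean Optional kernel mean shift (default zero; used by
#'   [fit_extrinsic_sigma()] when a systematic shift is co-fitted).
#' @return An object of class `cme_noise`.
#' @export
extrinsic_noise <- function(sigma, a = 0, background = NULL, modes = NULL,
                            mean = NULL) {
  if (a < 0 || a >= 1) stop("background weight `a` must be in [0, 1)", call. = FALSE)
  check_cov <- function(s) {
    if (is.matrix(s)) {
      if (!isSymmetric(unname(s)) || any(eigen(s, symmetric = TRUE,
                                               only.values = TRUE)$values < -1e-10)) {
        stop("covariance must be symmetric positive semidefinite", call. = FALSE)
      }
      s
    } else {
      if (any(s < 0)) stop("sigma must be nonnegative", call. = FALSE)
      s
    }
  }
  sigma <- check_cov(sigma)
  if (!is.null(modes)) for (m in modes) check_cov(m$sigma)
  structure(list(sigma = sigma, a = a, background = background, modes = modes,
                 mean = mean),
            class = "cme_noise")
}

# sigma spec (scalar / vector / covariance) -> d x d covariance matrix
as_cov <- function(sigma, d) {
  if (is.matrix(sigma)) {
    stopifnot(nrow(sigma) == d)
    sigma
  } else {
    diag(rep(sigma, length.out = d)^2, d)
  }
}

# Discrete Gaussian kernel weights on lattice offsets within +/- 6 sd
# (unnormalized; per-source renormalization happens in convolve_grid).
# Returns list(offsets = matrix, w = numeric).
gaussian_kernel <- function(sigma, d, mean = NULL) {
  cov <- as_cov(sigma, d)
  if (is.null(mean)) mean <- rep(0, d)
  sds <- sqrt(diag(cov))
  half <- ceiling(6 * sds + abs(mean))
  if (all(half == 0)) {
    return(list(offsets = matrix(0L, 1, d), w = 1))
  }
  grids <- lapply(seq_len(d), function(i) (-half[i]):half[i])
  offsets <- as.matrix(expand.grid(grids))
  colnames(offsets) <- NULL
  # degenerate directions (zero variance) carry a point mass at the mean
  pos <- diag(cov) > 0
  w <- rep(1, nrow(offsets))
  if (any(pos)) {
    ci <- solve(cov[pos, pos, drop = FALSE])
    dev <- sweep(offsets[, pos, drop = FALSE], 2, mean[pos])
    w <- exp(-0.5 * rowSums((dev %*% ci) * dev))
  }
  if (any(!pos)) {
    hit <- rep(TRUE, nrow(offsets))
    for (i in which(!pos)) hit <- hit & offsets[, i] == round(mean[i])
    w <- w * hit
  }
  keep <- w > 0
  list(offsets = offsets[keep, , drop = FALSE], w = w[keep])
}

#' Convolve a distribution with an extrinsic noise kernel
#'
#' Computes `(1 - a) * (P * M0) + a * B` by direct summation on the lattice.
#' The discrete Gaussian kernel is the multivariate normal density evaluated
#' at integer offsets, renormalized over the truncated box per source state
#' (boundary-renormalized: no mass is lost off-grid, so the output sums to
#' 1 exactly). With per-mode widths, the input is partitioned by nearest
#' mode center and each part convolved with its own kernel.
#'
#' @param p A normalized `cme_dist` (1 or 2 species, scale 1).
#' @param spec An [extrinsic_noise()] spec (or a bare sigma, promoted).
#' @return A `cme_dist` on the same space.
#' @examples
#' poisson_constitutive(20, 1, 80) |> convolve_grid(extrinsic_noise(sigma = 3))
#' @export
convolve_grid <- function(p, spec) {
  if (!inherits(spec, "cme_noise")) spec <- extrinsic_noise(spec)
  space <- dist_space(p)
  d <- length(space$species)
  if (d > 2) stop("direct-summation convolution supports 1 or 2 species", call. = FALSE)
  if (is.null(spec$modes)) {
    out <- convolve_mass(p$prob, space, spec$sigma, spec$mean)
  } else {
    states <- enumerate_states(space)
    centers <- do.call(rbind, lapply(spec$modes, function(m) as.numeric(m$center)))
    scal <- vapply(spec$modes, function(m) mean(sqrt(diag(as_cov(m$sigma, d)))),
                   numeric(1))
    scal[scal <= 0] <- 1
    dist2 <- vapply(seq_len(nrow(centers)), function(k) {
      rowSums(sweep(states, 2, centers[k, ])^2) / scal[k]^2
    }, numeric(nrow(states)))
    assign_k <- max.col(-dist2, ties.method = "first")
    out <- numeric(n_states(space))
    for (k in seq_along(spec$modes)) {
      part <- p$prob * (assign_k == k)
      if (sum(part) > 0) {
        out <- out + convolve_mass(part, space, spec$modes[[k]]$sigma, spec$mean)
      }
    }
  }
  if (spec$a > 0) {
    B <- if (is.null(spec$background)) {
      rep(1 / n_states(space), n_states(space))
    } else spec$background$prob
    out <- (1 - spec$a) * out + spec$a * B
  }
  res <- new_cme_dist(space, out)
  res$prob <- out / sum(out)  # keep exact mass bookkeeping
  res
}

# Direct-summation convolution of a (sub-normalized) mass vector with a
# Gaussian kernel, per-source boundary renormalization. Returns a mass
# vector with the same total as the input.
convolve_mass <- function(mass, space, sigma, mean = NULL) {
  d <- length(space$species)
  k <- gaussian_kernel(sigma, d, mean)
  dims <- space$dims
  Pa <- array(mass, dim = c(dims, 1)[seq_len(max(d, 2))])
  if (d == 1) Pa <- matrix(mass, ncol = 1)
  n1 <- dims[1]; n2 <- if (d == 2) dims[2] else 1L
  if (d == 1) k$offsets <- cbind(k$offsets[, 1], 0L)
  keep <- abs(k$offsets[, 1]) < n1 & abs(k$offsets[, 2]) < n2
  k$offsets <- k$offsets[keep, , drop = FALSE]; k$w <- k$w[keep]
  Z <- matrix(0, n1, n2)
  for (r in seq_along(k$w)) {
    o1 <- k$offsets[r, 1]; o2 <- k$offsets[r, 2]
    s1 <- max(1, 1 - o1):min(n1, n1 - o1)
    s2 <- max(1, 1 - o2):min(n2, n2 - o2)
    Z[s1, s2] <- Z[s1, s2] + k$w[r]
  }
  Pn <- matrix(Pa, n1, n2) / Z
  out <- matrix(0, n1, n2)
  for (r in seq_along(k$w)) {
    o1 <- k$offsets[r, 1]; o2 <- k$offsets[r, 2]
    s1 <- max(1, 1 - o1):min(n1, n1 - o1)
    s2 <- max(1, 1 - o2):min(n2, n2 - o2)
    out[s1 + o1, s2 + o2] <- out[s1 + o1, s2 + o2] + k$w[r] * Pn[s1, s2]
  }
  as.numeric(out)
}

#' Add extrinsic noise to a sample set
#'
#' Shifts every sample by an independent zero-mean Gaussian draw
#' (`y_i = x_i + shift_i`); the shifted samples follow the convolved
#' distribution. Values are continuous by default (`round = TRUE` rounds to
#' the nearest lattice point); negative components are clipped to 0, a
#' documented bias near the boundary (the grid convolution instead
#' renormalizes its kernel there, so the two routes differ slightly near
#' 0). With background weight `a > 0`, `n*a/(1-a)` additional points drawn
#' from the background distribution are appended.
#'
#' @param samples A `cme_samples` tibble.
#' @param spec An [extrinsic_noise()] spec (or bare sigma).
#' @param seed Optional RNG seed.
#' @param round Round shifted values to integers (default FALSE).
#' @return A `cme_samples` tibble (numeric columns unless `round`).
#' @export
shift_samples <- function(samples, spec, seed = NULL, round = FALSE) {
  if (!inherits(spec, "cme_noise")) spec <- extrinsic_noise(spec)
  if (!is.null(seed)) set.seed(seed)
  space <- attr(samples, "space")
  sp_names <- if (!is.null(space)) space$species else
    setdiff(names(samples), c(".mode", "prob"))
  x <- as.matrix(as.data.frame(samples)[, sp_names, drop = FALSE])
  n <- nrow(x); d <- ncol(x)
  if (n == 0) stop("empty sample set", call. = FALSE)
  draw_shift <- function(m, cov) {
    if (max(abs(cov)) == 0) return(matrix(0, m, d))
    R <- chol(cov + diag(1e-12 * max(diag(cov)), d))
    matrix(stats::rnorm(m * d), m, d) %*% R
  }
  if (is.null(spec$modes)) {
    y <- x + draw_shift(n, as_cov(spec$sigma, d))
  } else {
    centers <- do.call(rbind, lapply(spec$modes, function(mm) as.numeric(mm$center)))
    scal <- vapply(spec$modes, function(mm) mean(sqrt(diag(as_cov(mm$sigma, d)))),
                   numeric(1))
    scal[scal <= 0] <- 1
    dist2 <- vapply(seq_len(nrow(centers)), function(k) {
      rowSums(sweep(x, 2, centers[k, ])^2) / scal[k]^2
    }, numeric(n))
    assign_k <- max.col(-dist2, ties.method = "first")
    y <- x
    for (k in seq_along(spec$modes)) {
      idx <- which(assign_k == k)
      if (length(idx)) {
        y[idx, ] <- x[idx, , drop = FALSE] +
          draw_shift(length(idx), as_cov(spec$modes[[k]]$sigma, d))
      }
    }
  }
  y <- pmax(y, 0)
  if (spec$a > 0) {
    nb <- round(n * spec$a / (1 - spec$a))
    if (nb > 0) {
      B <- if (is.null(spec$background)) {
        new_cme_dist(space, rep(1, n_states(space)))
      } else spec$background
      yb <- as.matrix(as.data.frame(sample_dist(B, nb)))
      y <- rbind(y, yb)
    }
  }
  if (round) y <- round(y)
  out <- tibble::as_tibble(as.data.frame(y))
  names(out) <- sp_names
  attr(out, "space") <- space
  class(out) <- c("cme_samples", class(out))
  out
}

#' Fit an extrinsic noise width to a target distribution
#'
#' Finds the isotropic Gaussian width `sigma` (and optionally a systematic
#' mean shift) minimizing the unweighted sum of squared probability
#' differences between `convolve_grid(p_intrinsic, sigma)` and `p_target`
#' on their shared grid. With `per_mode = TRUE`, `modes` gives the mode
#' centers and one sigma is fitted per mode.
#'
#' @param p_intrinsic,p_target `cme_dist` objects on the same grid.
#' @param shift Co-fit a mean shift of the kernel (default FALSE).
#' @param per_mode Fit one sigma per mode (default FALSE).
#' @param modes Mode centers for `per_mode` (list of states).
#' @param upper Upper bound of the sigma search interval (default: 3 x the
#'   target standard deviation).
#' @return A one-row tibble `sigma` (or one row per mode), `shift`,
#'   `residual` (objective at the optimum).
#' @examples
#' p <- poisson_constitutive(20, 1, 120)
#' fit_extrinsic_sigma(p, convolve_grid(p, extrinsic_noise(3)))
#' @export
fit_extrinsic_sigma <- function(p_intrinsic, p_target, shift = FALSE,
                                per_mode = FALSE, modes = NULL, upper = NULL) {
  sp <- dist_space(p_intrinsic); st <- dist_space(p_target)
  if (!identical(sp$dims, st$dims)) stop("distributions must share a grid", call. = FALSE)
  if (max(p_target$prob) - min(p_target$prob) < 1e-12) {
    warning("target distribution is flat; fit is ill-determined", call. = FALSE)
  }
  d <- length(sp$species)
  if (is.null(upper)) {
    upper <- 3 * max(summarize_dist(p_target)$sd)
  }
  make_spec <- function(sig, mu) {
    if (per_mode) {
      extrinsic_noise(sigma = sig[1],
                      modes = lapply(seq_along(modes), function(k) {
                        list(center = modes[[k]], sigma = sig[k])
                      }),
                      mean = if (shift) rep(mu, d) else NULL)
    } else {
      extrinsic_noise(sigma = sig, mean = if (shift) rep(mu, d) else NULL)
    }
  }
  nsig <- if (per_mode) length(modes) else 1L
  obj <- function(par) {
    sig <- exp(par[seq_len(nsig)])
    mu <- if (shift) par[nsig + 1] else 0
    sum((convolve_grid(p_intrinsic, make_spec(sig, mu))$prob - p_target$prob)^2)
  }
  if (!shift && nsig == 1L) {
    op <- stats::optimize(function(s) obj(log(s)), interval = c(1e-3, upper))
    sig <- op$minimum; mu <- 0; val <- op$objective
  } else {
    start <- c(rep(log(max(upper / 3, 0.5)), nsig), if (shift) 0)
    op <- stats::optim(start, obj, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    sig <- exp(op$par[seq_len(nsig)])
    mu <- if (shift) op$par[nsig + 1] else 0
    val <- op$value
  }
  tibble::tibble(mode = seq_len(nsig), sigma = sig, shift = mu, residual = val)
}
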