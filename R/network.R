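#' Define a reaction
#'
#' A reaction has a propensity (probability per unit time that it fires,
#' in molecular units) given as an arithmetic expression over species
#' molecule numbers and named parameters, and an effect that is either a
#' fixed integer change vector or a jump kernel assigning a probability
#' mass over destination states (used e.g. for binomial partitioning at
#' cell division). A fixed change is the degenerate kernel that puts all
#' mass on one destination.
#'
#' @param name Reaction name.
#' @param propensity A single string with the rate expression, e.g.
#'   `"r_u / (1 + (v / K_v)^beta)"`. Allowed: `+ - * / ^ ( )`, `exp`,
#'   `log`, `sqrt`, `min`, `max`, `pmin`, `pmax`, numbers, species names
#'   and parameter names.
#' @param change Named integer vector of per-species changes (species not
#'   named are unchanged). Mutually exclusive with `kernel`.
#' @param kernel A function `function(state, parameters)` returning
#'   `list(states = <integer matrix>, prob = <numeric>)` with probabilities
#'   summing to 1 (checked to 1e-12 by [validate_network()]); or the name of
#'   a registered kernel (see [kernel_registry()]).
#' @return An object of class `cme_reaction`.
#' @export
reaction <- function(name, propensity, change = NULL, kernel = NULL) {
  if (is.null(change) == is.null(kernel)) {
    stop("reaction `", name, "`: give exactly one of `change` or `kernel`", call. = FALSE)
  }
  expr <- tryCatch(
    str2lang(propensity),
    error = function(e) stop("reaction `", name, "`: cannot parse propensity: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.null(change)) {
    if (is.null(names(change))) stop("reaction `", name, "`: `change` must be named", call. = FALSE)
    change <- stats::setNames(as.integer(change), names(change))
  }
  structure(
    list(name = name, propensity = propensity, expr = expr,
         change = change, kernel = kernel),
    class = "cme_reaction"
  )
}

#' Assemble a reaction network
#'
#' @param species Character vector of species names (defines state order).
#' @param reactions List of [reaction()] objects.
#' @param parameters Named numeric vector or list of rate parameters.
#' @return An object of class `cme_network`.
#' @examples
#' bd <- reaction_network(
#'   species = "n",
#'   reactions = list(
#'     reaction("synthesis", "k_s", change = c(n = 1)),
#'     reaction("degradation", "k_d * n", change = c(n = -1))
#'   ),
#'   parameters = c(k_s = 20, k_d = 1)
#' )
#' propensity_vector(bd, c(n = 5))
#' @export
reaction_network <- function(species, reactions, parameters = numeric()) {
  parameters <- unlist(parameters)
  if (length(parameters) && is.null(names(parameters))) {
    stop("`parameters` must be named", call. = FALSE)
  }
  net <- structure(
    list(species = species, reactions = reactions,
         parameters = parameters),
    class = "cme_network"
  )
  validate_network(net)
  net
}

#' @export
print.cme_network <- function(x, ...) {
  cat("<cme_network> ", length(x$species), " species (",
      paste(x$species, collapse = ", "), "), ",
      length(x$reactions), " reactions\n", sep = "")
  for (r in x$reactions) {
    eff <- if (is.null(r$change)) {
      "jump kernel"
    } else {
      ch <- r$change[r$change != 0L]
      paste(sprintf("%+d %s", ch, names(ch)), collapse = ", ")
    }
    cat(sprintf("  %-14s %-34s %s\n", r$name, r$propensity, eff))
  }
  if (length(x$parameters)) {
    cat("  parameters: ",
        paste(names(x$parameters), signif(x$parameters, 6), sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

ALLOWED_FUNS <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt",
                  "min", "max", "pmin", "pmax")

# Collect symbols used in an expression; error on disallowed calls.
expr_symbols <- function(e, rxn) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% ALLOWED_FUNS) {
      stop("reaction `", rxn, "`: function `", fn, "` is not allowed in propensities",
           call. = FALSE)
    }
    return(unique(unlist(lapply(as.list(e)[-1], expr_symbols, rxn = rxn))))
  }
  character()
}

#' Validate a reaction network
#'
#' Checks that every propensity expression references only declared species
#' and parameters, that fixed change vectors only name declared species, and
#' that jump kernels return probabilities summing to 1 (tolerance 1e-12) on
#' a probe state.
#'
#' @param network A [reaction_network()].
#' @return The network, invisibly; errors describe the offending reaction.
#' @export
validate_network <- function(network) {
  known <- c(network$species, names(network$parameters))
  for (r in network$reactions) {
    syms <- expr_symbols(r$expr, r$name)
    bad <- setdiff(syms, known)
    if (length(bad)) {
      stop("reaction `", r$name, "`: undeclared symbol(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!is.null(r$change)) {
      bad <- setdiff(names(r$change), network$species)
      if (length(bad)) {
        stop("reaction `", r$name, "`: change names unknown species: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(network)
}

# Full change vector over all species (NULL for kernel reactions).
change_vector <- function(network, r) {
  if (is.null(r$change)) return(NULL)
  ch <- stats::setNames(integer(length(network$species)), network$species)
  ch[names(r$change)] <- r$change
  ch
}

resolve_kernel <- function(network, r) {
  k <- r$kernel
  if (is.character(k)) k <- kernel_registry(k)
  function(state) {
    out <- k(state, network$parameters)
    stopifnot(is.list(out), !is.null(out$states), !is.null(out$prob))
    out
  }
}

#' Evaluate reaction propensities at a state
#'
#' @param network A [reaction_network()].
#' @param state Named integer vector (one entry per species).
#' @return Named numeric vector, one nonnegative rate per reaction
#'   (events per unit time).
#' @export
propensity_vector <- function(network, state) {
  m <- matrix(as.integer(state[network$species]), nrow = 1,
              dimnames = list(NULL, network$species))
  drop(propensity_matrix(network, m))
}

#' Evaluate propensities over many states at once
#'
#' @param network A [reaction_network()].
#' @param states Integer matrix with one column per species.
#' @return Numeric matrix, `nrow(states)` rows by one column per reaction.
#' @export
propensity_matrix <- function(network, states) {
  env <- c(as.list(network$parameters),
           lapply(seq_along(network$species), function(i) states[, i]))
  names(env) <- c(names(network$parameters), network$species)
  env <- list2env(env, parent = baseenv())
  out <- matrix(0, nrow = nrow(states), ncol = length(network$reactions))
  colnames(out) <- vapply(network$reactions, `[[`, "", "name")
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    a <- eval(r$expr, env)
    a <- rep_len(a, nrow(states))
    if (any(!is.finite(a)) || any(a < 0)) {
      stop("reaction `", r$name, "`: propensity is negative or non-finite ",
           "at an in-range state", call. = FALSE)
    }
    out[, j] <- a
  }
  out
}

# Registry of named jump kernels available to model config files. -----------

#' Named jump kernels
#'
#' Kernels usable by name in [reaction()] and in model config files.
#' Currently registered:
#' \describe{
#'   \item{`t7_division`}{Cell-division kernel for the T7 RNAP circuit with
#'     state `(n, m)` (free polymerase, inactive promoters) and promoter count
#'     parameter `M`: the free pool `n` is partitioned binomially with
#'     `p = 1/2` between the daughters and all promoters reset to the
#'     inactive state (`m = M`); promoter-bound molecules are not returned to
#'     the tracked daughter's free pool.}
#' }
#'
#' @param name Kernel name.
#' @return The kernel function.
#' @export
kernel_registry <- function(name) {
  switch(name,
    t7_division = function(state, parameters) {
      M <- as.integer(parameters[["M"]])
      n <- as.integer(state[["n"]])
      list(
        states = cbind(n = 0:n, m = rep(M, n + 1L)),
        prob = stats::dbinom(0:n, n, 0.5)
      )
    },
    stop("unknown kernel `", name, "`", call. = FALSE)
  )
}

# Summed propensity of unit-step reactions changing species i by +1 (synth)
# or -1 (degr), evaluated at each row of `states`. Used by the detailed-
# balance machinery; errors if any fixed-change reaction moving species i is
# not a unit step.
axis_rates <- function(network, states, i, direction) {
  total <- numeric(nrow(states))
  found <- FALSE
  for (r in network$reactions) {
    ch <- change_vector(network, r)
    if (is.null(ch)) next
    if (ch[i] == 0L) next
    if (abs(ch[i]) != 1L || any(ch[-i] != 0L)) {
      stop("detailed-balance conditionals require unit axis steps; reaction `",
           r$name, "` moves species in a non-unit or diagonal step", call. = FALSE)
    }
    if (ch[i] == direction) {
      env <- c(as.list(network$parameters),
               lapply(seq_along(network$species), function(k) states[, k]))
      names(env) <- c(names(network$parameters), network$species)
      total <- total + rep_len(eval(r$expr, list2env(env, parent = baseenv())),
                               nrow(states))
      found <- TRUE
    }
  }
  attr(total, "found") <- found
  total
}
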