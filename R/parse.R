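#' Parse a model configuration document
#'
#' Model configs are YAML documents describing a reaction network and its
#' truncated state space:
#'
#' ```yaml
#' species: [u, v]
#' parameters: {K_u: 1, K_v: 1, r_u: 10, r_v: 9, beta: 2, gamma: 2, d_u: 1, d_v: 1}
#' bounds: {u: 60, v: 60}
#' scale: 1
#' reactions:
#'   - name: synth_u
#'     propensity: r_u / (1 + (v / K_v)^beta)
#'     change: {u: 1}
#'   - name: divide
#'     propensity: mu / (1 + n / theta)
#'     kernel: t7_division
#' ```
#'
#' `change` entries are per-species integers (unnamed species unchanged);
#' `kernel` names a registered jump kernel ([kernel_registry()]). Unknown
#' symbols in propensity expressions are rejected with the offending symbol
#' named; malformed YAML is reported with the line. The format round-trips
#' through [write_model_config()].
#'
#' @param text The document: a file path or a single YAML string.
#' @return `list(network, space)` as used by [solve_model()] and friends.
#' @examples
#' cfg <- system.file("extdata", "models", "birth_death.model", package = "cmenoise")
#' model <- parse_model_config(cfg)
#' model$network
#' @export
parse_model_config <- function(text) {
  # keep YAML-1.1 boolean-like scalars (y/n/yes/no/...) as plain strings:
  # species are routinely named `n`
  handlers <- list(
    "bool#yes" = function(x) x,
    "bool#no" = function(x) x
  )
  doc <- tryCatch(
    if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
      yaml::read_yaml(text, handlers = handlers)
    } else {
      yaml::yaml.load(paste(text, collapse = "\n"), handlers = handlers)
    },
    error = function(e) stop("model config parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  for (field in c("species", "reactions", "bounds")) {
    if (is.null(doc[[field]])) {
      stop("model config is missing the `", field, "` section", call. = FALSE)
    }
  }
  species <- as.character(doc$species)
  bounds <- unlist(doc$bounds)
  if (!all(species %in% names(bounds))) {
    stop("`bounds` must give an upper bound for every species", call. = FALSE)
  }
  if (any(bounds < 0)) stop("negative truncation bound", call. = FALSE)
  scale <- if (is.null(doc$scale)) 1L else doc$scale
  if (scale < 1) stop("scale factor S must be >= 1", call. = FALSE)
  reactions <- lapply(doc$reactions, function(r) {
    if (is.null(r$name) || is.null(r$propensity)) {
      stop("every reaction needs `name` and `propensity`", call. = FALSE)
    }
    reaction(r$name, as.character(r$propensity),
             change = if (!is.null(r$change)) unlist(r$change),
             kernel = r$kernel)
  })
  network <- reaction_network(species, reactions,
                              parameters = unlist(doc$parameters))
  list(network = network,
       space = state_space(bounds[species], scale = scale))
}

#' Serialize a model back to config text
#'
#' Inverse of [parse_model_config()]: the emitted YAML re-parses to an
#' equivalent network (identical propensities on every state).
#'
#' @param model `list(network, space)`.
#' @param file Optional path to write to.
#' @return The YAML text, invisibly when writing to a file.
#' @export
write_model_config <- function(model, file = NULL) {
  net <- model$network; sp <- model$space
  doc <- list(
    species = net$species,
    parameters = as.list(net$parameters),
    bounds = as.list(stats::setNames(as.integer(sp$upper), sp$species)),
    scale = sp$scale,
    reactions = lapply(net$reactions, function(r) {
      out <- list(name = r$name, propensity = r$propensity)
      if (!is.null(r$change)) out$change <- as.list(r$change)
      if (!is.null(r$kernel)) {
        if (!is.character(r$kernel)) {
          stop("only registry-named kernels can be serialized", call. = FALSE)
        }
        out$kernel <- r$kernel
      }
      out
    })
  )
  txt <- yaml::as.yaml(doc)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
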