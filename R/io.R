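#' Network and state file I/O
#'
#' Networks are exchanged as edge-list TSV (two 0-based integer columns,
#' `from` and `to`) or GraphML; agent states as CSV with columns
#' `agent_id` (0-based), `opinion`, `attitude`, `frozen`, `group`.
#'
#' @param net a [social_network()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  el <- edge_list(net) - 1L
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("from", "to"))
  invisible(path)
}

#' @rdname write_network_tsv
#' @param n_agents population size; defaults to `max(index) + 1` so isolated
#'   trailing agents survive a round trip when given explicitly.
#' @export
read_network_tsv <- function(path, n_agents = NULL) {
  el <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(n_agents)) {
    n_agents <- if (nrow(el) > 0L) max(el) + 1L else 0L
  }
  social_network(n_agents, as.matrix(el) + 1L)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_tsv
#' @param states an [agent_states()] object.
#' @export
write_states_csv <- function(states, path) {
  df <- as.data.frame(states)
  df$group <- as.character(classify(states)$group)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration
#'
#' Flat JSON file whose keys mirror [model_params()] argument names exactly;
#' unknown keys are an error naming the offending key. Keys omitted from the
#' file keep their defaults; entries in `override` (e.g. from command-line
#' flags) win over the file.
#'
#' @param path JSON file path, or `NULL` for pure-default parameters.
#' @param override named list of parameter overrides.
#' @return a validated [model_params()].
#' @export
read_config <- function(path = NULL, override = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  cfg[names(override)] <- override
  known <- names(formals(model_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key: ", unknown[1L], call. = FALSE)
  }
  do.call(model_params, cfg)
}

#' @rdname read_config
#' @param params a [model_params()] to serialise.
#' @export
write_config <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# run manifest: config snapshot, seed, package version, outputs, timestamps
write_manifest <- function(params, outputs, path) {
  man <- list(
    package = "opinionfield",
    version = as.character(utils::packageVersion("opinionfield")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = params$seed,
    config = unclass(params),
    outputs = outputs
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a run manifest
#'
#' @param path manifest JSON path.
#' @return list with the manifest fields; `$config` re-parses into a
#'   [model_params()] equivalent to the one that produced the run.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  man$config <- do.call(model_params, man$config)
  man
}
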