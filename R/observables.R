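#' Opinion/attitude group of each agent
#'
#' Agents fall into eight groups: the opinion class -- `expert` (frozen at
#' `+1`), `fundamentalist` (frozen at `-1`), `ignorant_positive` /
#' `ignorant_negative` (undecided, by opinion sign) -- crossed with the sign
#' of the quenched attitude. Boundary convention: `x = 0` counts as positive
#' opinion and `alpha = 0` as positive attitude (measure-zero events, fixed
#' for determinism).
#'
#' @param states an [agent_states()] object.
#' @return data.frame with factors `opinion_class` (4 levels),
#'   `attitude_sign` (2 levels) and their interaction `group` (8 levels).
#' @export
classify <- function(states) {
  oc <- ifelse(states$frozen,
               ifelse(states$opinion > 0, "expert", "fundamentalist"),
               ifelse(states$opinion >= 0, "ignorant_positive",
                      "ignorant_negative"))
  as_sign <- ifelse(states$attitude >= 0, "positive", "negative")
  oc <- factor(oc, levels = opinion_class_levels())
  as_sign <- factor(as_sign, levels = c("positive", "negative"))
  data.frame(opinion_class = oc,
             attitude_sign = as_sign,
             group = factor(paste(oc, as_sign, sep = "."),
                            levels = group_levels()))
}

opinion_class_levels <- function() {
  c("expert", "ignorant_positive", "ignorant_negative", "fundamentalist")
}

group_levels <- function() {
  as.vector(t(outer(opinion_class_levels(), c("positive", "negative"),
                    paste, sep = ".")))
}

#' Model-side agreement fraction n+
#'
#' The analogue of a survey agreement fraction: positive-opinion agents over
#' all opinionated agents. With `mode = "all"` every agent counts by opinion
#' sign (`x = 0` counting as positive, the package-wide convention); with
#' `mode = "frozen"` only decided agents count, mirroring the exclusion of
#' "do not know" answers in the survey normalisation (returns `NA` when no
#' agent is frozen).
#'
#' @param states an [agent_states()] object.
#' @param mode `"all"` or `"frozen"`.
#' @return scalar in `[0, 1]`, or `NA`.
#' @export
n_plus <- function(states, mode = c("all", "frozen")) {
  mode <- match.arg(mode)
  if (mode == "all") {
    mean(states$opinion >= 0)
  } else {
    if (!any(states$frozen)) return(NA_real_)
    mean(states$opinion[states$frozen] > 0)
  }
}

#' Mean within-group degree towards the same group
#'
#' Average number of links a member of the given opinion class has to other
#' members of the same class -- the cohesion measure behind the observation
#' that fundamentalist communities under positive field are more tightly
#' interconnected than expert groups under the mirrored negative field.
#'
#' @param net a [social_network()].
#' @param states an [agent_states()] object.
#' @param opinion_class one of `"expert"`, `"ignorant_positive"`,
#'   `"ignorant_negative"`, `"fundamentalist"`.
#' @return mean internal degree, or `NA` if the group is empty.
#' @export
group_internal_degree <- function(net, states, opinion_class) {
  cls <- classify(states)$opinion_class
  members <- which(cls == opinion_class)
  if (length(members) == 0L) return(NA_real_)
  sub <- net$adj[members, members, drop = FALSE]
  mean(rowSums(sub))
}

#' Fraction of expert-fundamentalist geodesics passing through undecided agents
#'
#' For every (fundamentalist, expert) pair in the same component, one
#' shortest path is taken and marked if any interior vertex is undecided.
#' Under strong positive field the undecided "ignorants" sit between the
#' tight fundamentalist community and the experts, so this fraction exceeds
#' the undecided population share.
#'
#' @param net a [social_network()].
#' @param states an [agent_states()] object.
#' @param max_pairs subsample cap on the number of pairs inspected.
#' @return list with `bridge_fraction` (`NA` if no connected pair exists),
#'   `undecided_share`, and `n_pairs` inspected.
#' @export
bridging_fraction <- function(net, states, max_pairs = 400L) {
  cls <- classify(states)$opinion_class
  fund <- which(cls == "fundamentalist")
  expe <- which(cls == "expert")
  und <- which(!states$frozen)
  share <- length(und) / net$n_agents
  if (length(fund) == 0L || length(expe) == 0L) {
    return(list(bridge_fraction = NA_real_, undecided_share = share,
                n_pairs = 0L))
  }
  g <- as_igraph(net)
  pairs <- expand.grid(f = fund, e = expe)
  if (nrow(pairs) > max_pairs) {
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }
  hit <- 0L
  n_conn <- 0L
  for (r in seq_len(nrow(pairs))) {
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = pairs$f[r], to = pairs$e[r])$vpath[[1]]
    )
    if (length(sp) == 0L) next
    n_conn <- n_conn + 1L
    interior <- as.integer(sp)[-c(1L, length(sp))]
    if (any(interior %in% und)) hit <- hit + 1L
  }
  list(bridge_fraction = if (n_conn > 0L) hit / n_conn else NA_real_,
       undecided_share = share, n_pairs = n_conn)
}

#' Summary observables of a system state
#'
#' Computes, for the current `(net, states)` pair: the eight group fractions
#' `n_g` (summing to 1), the relative group contributions to the average
#' degree `k_g n_g / <k>` (summing to 1 whenever `<k> > 0`), the
#' degree-weighted nearest-neighbours' average opinion per group (isolated
#' agents are excluded from the aggregate; `NA` when a group has no connected
#' member), the mean degree, the average local clustering coefficient
#' (agents of degree < 2 contribute 0), the undecided fraction, the model
#' agreement fraction `n+`, and the number of connected components.
#'
#' @param net a [social_network()].
#' @param states an [agent_states()] object.
#' @param params optional [model_params()] supplying `n_plus_mode` and
#'   `nn_weighting`.
#' @return a one-row data.frame (class `observable_record`); group-valued
#'   quantities appear as columns `frac.<group>`, `degc.<group>`,
#'   `nn.<group>`.
#' @export
summarize_system <- function(net, states, params = NULL) {
  n <- net$n_agents
  n_plus_mode <- if (is.null(params)) "all" else params$n_plus_mode
  nn_weighting <- if (is.null(params)) "degree" else params$nn_weighting

  cl <- classify(states)
  deg <- rowSums(net$adj)
  mean_deg <- mean(deg)

  counts <- table(cl$group)
  fracs <- as.numeric(counts) / n
  names(fracs) <- names(counts)

  degc <- vapply(group_levels(), function(gl) {
    members <- which(cl$group == gl)
    if (length(members) == 0L || mean_deg == 0) return(0)
    # k_g * n_g / <k> computed as sum(deg)/N / mean(deg): exact normalisation
    sum(deg[members]) / n / mean_deg
  }, numeric(1))

  x <- states$opinion
  nb_sum <- as.numeric(net$adj %*% x)
  nn_i <- ifelse(deg > 0, nb_sum / pmax(deg, 1), NA_real_)
  nn <- vapply(group_levels(), function(gl) {
    members <- which(cl$group == gl & deg > 0)
    if (length(members) == 0L) return(NA_real_)
    w <- if (nn_weighting == "degree") deg[members] else rep(1, length(members))
    sum(w * nn_i[members]) / sum(w)
  }, numeric(1))

  g <- as_igraph(net)
  local_c <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_c[!is.finite(local_c)] <- 0

  out <- data.frame(
    time = NA_integer_,
    mean_degree = mean_deg,
    clustering = mean(local_c),
    undecided_fraction = mean(!states$frozen),
    agreement_fraction = n_plus(states, n_plus_mode),
    n_components = igraph::components(g)$no
  )
  for (gl in group_levels()) {
    out[[paste0("frac.", gl)]] <- fracs[[gl]]
    out[[paste0("degc.", gl)]] <- degc[[gl]]
    out[[paste0("nn.", gl)]] <- nn[[gl]]
  }
  class(out) <- c("observable_record", "data.frame")
  out
}

#' Tidy per-group view of recorded observables
#'
#' Reshapes the wide `records` table of a [run_simulation()] result into one
#' row per (time, group), plus the per-time scalars.
#'
#' @param records the `records` data.frame of a `sim_result`.
#' @return long-format data.frame with columns `time`, `group`, `fraction`,
#'   `degree_contribution`, `nn_avg_opinion` and the per-time scalars.
#' @export
tidy_records <- function(records) {
  scalars <- c("time", "mean_degree", "clustering", "undecided_fraction",
               "agreement_fraction", "n_components")
  out <- do.call(rbind, lapply(group_levels(), function(gl) {
    data.frame(records[scalars],
               group = gl,
               fraction = records[[paste0("frac.", gl)]],
               degree_contribution = records[[paste0("degc.", gl)]],
               nn_avg_opinion = records[[paste0("nn.", gl)]])
  }))
  out[order(out$time, out$group), ]
}
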