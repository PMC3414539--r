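#' Neighbours an agent would cut, in order
#'
#' When an undecided agent rewires it breaks links preferentially where the
#' disagreement `|x_i - x_j|` is largest: neighbours are returned sorted by
#' opinion difference, descending, ties broken by the current RNG stream.
#' With `links_per_event = "all"` (the default model behaviour) every
#' neighbour is returned.
#'
#' @param i rewiring agent (must be undecided).
#' @param states an [agent_states()] object.
#' @param net a [social_network()].
#' @param links_per_event `"all"` or a positive integer cap.
#' @return integer vector of neighbour indices, possibly empty.
#' @export
select_cut_links <- function(i, states, net, links_per_event = "all") {
  nb <- neighbours_of(net, i)
  if (length(nb) == 0L) return(integer(0))
  diffs <- abs(states$opinion[i] - states$opinion[nb])
  ord <- order(-diffs, stats::runif(length(nb)))
  nb <- nb[ord]
  if (!identical(links_per_event, "all")) {
    nb <- nb[seq_len(min(length(nb), as.integer(links_per_event)))]
  }
  nb
}

#' Ranked link-creation candidates
#'
#' Triadic closure proposes "friends of friends": agents at geodesic distance
#' exactly 2, ranked by how much the new link would help agent `i` towards
#' total conviction, i.e. by `|x_i + x_j|` descending. Focal closure proposes
#' strangers -- agents at distance 3 or more, or in other components -- ranked
#' by opinion similarity `|x_i - x_j|` ascending. Both exclude `i`, its
#' current neighbours and duplicates; ties are broken by the RNG stream.
#'
#' @inheritParams select_cut_links
#' @param mechanism `"triadic"` or `"focal"`.
#' @return integer vector of candidate indices (possibly empty), best first.
#' @export
closure_candidates <- function(i, states, net, mechanism = c("triadic", "focal")) {
  mechanism <- match.arg(mechanism)
  nb <- neighbours_of(net, i)
  second <- if (length(nb) > 0L) {
    hits <- which(colSums(net$adj[nb, , drop = FALSE]) > 0)
    setdiff(hits, c(i, nb))
  } else integer(0)
  if (mechanism == "triadic") {
    cand <- second
    if (length(cand) == 0L) return(integer(0))
    score <- abs(states$opinion[i] + states$opinion[cand])
    cand[order(-score, stats::runif(length(cand)))]
  } else {
    cand <- setdiff(seq_len(net$n_agents), c(i, nb, second))
    if (length(cand) == 0L) return(integer(0))
    dis <- abs(states$opinion[i] - states$opinion[cand])
    cand[order(dis, stats::runif(length(cand)))]
  }
}

#' Build one agent's rewiring plan
#'
#' Collects the cuts and the same number of creations (fewer when the
#' candidate pool is exhausted) for one undecided agent, from the current
#' (pre-phase) network snapshot.
#'
#' @inheritParams closure_candidates
#' @param links_per_event `"all"` or a positive integer.
#' @return list of class `rewiring_plan` with `agent`, `mechanism`, `cuts`,
#'   `creations`, and `shortfall` (requested minus realised creations).
#' @export
build_rewiring_plan <- function(i, states, net,
                                mechanism = c("triadic", "focal"),
                                links_per_event = "all") {
  mechanism <- match.arg(mechanism)
  cuts <- select_cut_links(i, states, net, links_per_event)
  creations <- integer(0)
  if (length(cuts) > 0L) {
    cand <- closure_candidates(i, states, net, mechanism)
    creations <- cand[seq_len(min(length(cuts), length(cand)))]
  }
  structure(list(agent = i, mechanism = mechanism, cuts = cuts,
                 creations = creations,
                 shortfall = length(cuts) - length(creations)),
            class = "rewiring_plan")
}

#' Apply a set of rewiring plans simultaneously
#'
#' Conceptually simultaneous two-phase update: all cuts are applied as a set
#' union first, then all creations, duplicate proposals collapsing to a
#' single edge. The result does not depend on the order of the plans, and the
#' total edge count may change (both endpoints of a cut edge may each create
#' a replacement).
#'
#' @param net a [social_network()] (the snapshot the plans were built from).
#' @param plans list of [build_rewiring_plan()] results.
#' @return the updated [social_network()].
#' @export
apply_rewiring_plans <- function(net, plans) {
  adj <- net$adj
  for (pl in plans) {
    adj[pl$agent, pl$cuts] <- FALSE
    adj[pl$cuts, pl$agent] <- FALSE
  }
  for (pl in plans) {
    adj[pl$agent, pl$creations] <- TRUE
    adj[pl$creations, pl$agent] <- TRUE
  }
  diag(adj) <- FALSE
  sn_from_adj(adj)
}

#' One network rewiring phase
#'
#' Every undecided agent draws a uniform variate `u` on `(0, 1)` and uses
#' focal closure when `u < q` (`q = params$closure_mix`), triadic closure
#' otherwise; its plan is
#' built from the pre-phase snapshot. Decided (frozen) agents initiate
#' nothing but can be cut from or linked to. Plans are then applied
#' simultaneously via [apply_rewiring_plans()]. Agents are visited in index
#' order so the RNG draw sequence is reproducible.
#'
#' @param states an [agent_states()] object.
#' @param net a [social_network()].
#' @param params a [model_params()] (`closure_mix`, `links_per_event`).
#' @param return_plans also attach the plan list as attribute `"plans"`.
#' @return the rewired [social_network()].
#' @export
rewire_phase <- function(states, net, params, return_plans = FALSE) {
  undecided <- which(!states$frozen)
  plans <- vector("list", length(undecided))
  for (k in seq_along(undecided)) {
    i <- undecided[k]
    mech <- if (stats::runif(1) < params$closure_mix) "focal" else "triadic"
    plans[[k]] <- build_rewiring_plan(i, states, net, mech,
                                      params$links_per_event)
  }
  out <- apply_rewiring_plans(net, plans)
  if (return_plans) attr(out, "plans") <- plans
  out
}
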