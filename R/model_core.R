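#' Agent states
#'
#' Column-wise container for the per-agent state: continuous opinion
#' `x in [-1, 1]`, quenched attitude `alpha in [-1, 1]`, and the frozen flag
#' set once an agent reaches total conviction (`|x| = 1`), after which its
#' opinion never changes although it remains visible to its neighbours.
#'
#' @param opinion numeric vector in `[-1, 1]`.
#' @param attitude numeric vector in `[-1, 1]`, same length.
#' @param frozen logical vector, same length; frozen agents must sit exactly
#'   at `-1` or `+1`.
#' @return object of class `agent_states`.
#' @export
agent_states <- function(opinion, attitude, frozen = rep(FALSE, length(opinion))) {
  stopifnot(length(opinion) == length(attitude),
            length(opinion) == length(frozen))
  if (any(abs(opinion) > 1 + 1e-12)) {
    stop("opinion out of [-1, 1]", call. = FALSE)
  }
  if (any(abs(attitude) > 1 + 1e-12)) {
    stop("attitude out of [-1, 1]", call. = FALSE)
  }
  if (any(frozen & abs(abs(opinion) - 1) > 1e-12)) {
    stop("frozen agents must have |opinion| = 1", call. = FALSE)
  }
  structure(list(opinion = as.numeric(opinion),
                 attitude = as.numeric(attitude),
                 frozen = as.logical(frozen)),
            class = "agent_states")
}

#' @export
print.agent_states <- function(x, ...) {
  cat(sprintf("agent_states: %d agents, %d frozen (%d at +1, %d at -1)\n",
              length(x$opinion), sum(x$frozen),
              sum(x$frozen & x$opinion > 0), sum(x$frozen & x$opinion < 0)))
  invisible(x)
}

#' @export
as.data.frame.agent_states <- function(x, ...) {
  data.frame(agent_id = seq_along(x$opinion) - 1L,
             opinion = x$opinion, attitude = x$attitude, frozen = x$frozen)
}

# inverse-CDF draw from the standard normal truncated to (-1, 1);
# fixed draw count keeps the RNG stream aligned across runs
rtruncnorm01 <- function(n) {
  lo <- stats::pnorm(-1)
  hi <- stats::pnorm(1)
  stats::qnorm(lo + stats::runif(n) * (hi - lo))
}

#' Initialise network and agent states
#'
#' Draws an Erdos-Renyi random graph with edge probability
#' `mean_degree / (n_agents - 1)`, i.i.d. uniform attitudes on `[-1, 1]` and
#' i.i.d. truncated standard normal initial opinions on `(-1, 1)`. No agent
#' starts frozen. The draw order (attitudes, opinions, then edges) is fixed,
#' so identical parameters and seed give bit-identical output.
#'
#' @param params a [model_params()] object.
#' @param set_seed if `TRUE` (default) seed R's RNG from `params$seed` first;
#'   set to `FALSE` when calling from inside an already-seeded run.
#' @return list with elements `net` ([social_network()]) and `states`
#'   ([agent_states()]).
#' @export
init_system <- function(params, set_seed = TRUE) {
  validate_params(params)
  if (set_seed) set.seed(params$seed)
  n <- params$n_agents
  attitude <- stats::runif(n, -1, 1)
  opinion <- rtruncnorm01(n)
  p_edge <- params$mean_degree / (n - 1)
  g <- igraph::sample_gnp(n, p_edge)
  adj <- matrix(FALSE, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0L) {
    adj[el] <- TRUE
    adj[el[, 2:1, drop = FALSE]] <- TRUE
  }
  list(net = sn_from_adj(adj),
       states = agent_states(opinion, attitude))
}

#' Long-range public opinion seen by one agent
#'
#' The opinion of all agents at geodesic distance `n >= 2` from agent `i`,
#' weighted by strictly decreasing positive shell weights `w_n`. Direct
#' neighbours (distance 1) and `i` itself are excluded; they enter the
#' dynamics through the pair term instead. By default the weighted sum is
#' divided by the total weight, so `m_i` is an opinion-scale average in
#' `[-1, 1]`; `normalize = FALSE` returns the raw weighted sum
#' `sum_n w_n sum_{j in S_n(i)} x_j`.
#'
#' @param net a [social_network()].
#' @param states an [agent_states()] object.
#' @param i agent index.
#' @param shell_decay weight decay base (see [shell_weight()]).
#' @param normalize divide by the total shell weight (default `TRUE`).
#' @param dist optional precomputed distance matrix.
#' @return scalar `m_i`; 0 when no agent lies beyond distance 1.
#' @export
long_range_opinion <- function(net, states, i, shell_decay = 2,
                               normalize = TRUE, dist = NULL) {
  if (is.null(dist)) {
    d <- igraph::distances(as_igraph(net), v = i)[1L, ]
  } else {
    d <- dist[i, ]
  }
  sel <- is.finite(d) & d >= 2
  if (!any(sel)) return(0)
  w <- shell_weight(d[sel], shell_decay)
  s <- sum(w * states$opinion[sel])
  if (normalize) s / sum(w) else s
}

#' Opinion velocity of one agent
#'
#' Sum of the three kernel terms for an unfrozen agent `i`:
#' long-range reaction to the public opinion, pairwise discussions with every
#' direct neighbour, and the external field.
#'
#' @inheritParams long_range_opinion
#' @param kernels an [interaction_kernels()] record.
#' @param h external field strength.
#' @param params optional [model_params()] for shell weighting options
#'   (defaults used when omitted).
#' @return scalar time derivative `dx_i/dt`.
#' @export
opinion_derivative <- function(i, states, net, kernels = default_kernels(),
                               h = 0, params = NULL, dist = NULL) {
  if (states$frozen[i]) {
    stop("logic error: opinion_derivative called on a frozen agent",
         call. = FALSE)
  }
  shell_decay <- if (is.null(params)) 2 else params$shell_decay
  normalize <- if (is.null(params)) TRUE else params$normalize_long_range
  m <- long_range_opinion(net, states, i, shell_decay, normalize, dist)
  x <- states$opinion
  nb <- neighbours_of(net, i)
  pair_sum <- if (length(nb) > 0L) {
    sum(vapply(nb, function(j) kernels$pair_term(x[i], x[j]), numeric(1)))
  } else 0
  kernels$long_range_term(states$attitude[i], x[i], m) +
    pair_sum +
    kernels$field_term(x[i], h)
}

#' One synchronous opinion transaction (reference implementation)
#'
#' Applies a single explicit-Euler step of size `dt` to every unfrozen agent,
#' all derivatives evaluated at the pre-step state. Any agent whose updated
#' opinion reaches or exceeds `1` in magnitude is clamped to the attained
#' extreme and frozen; frozen agents are untouched but keep contributing to
#' their neighbours' terms. This pure-R path is the reference against which
#' the compiled block integrator is tested; [run_simulation()] uses the
#' compiled path for the default kernels.
#'
#' @inheritParams opinion_derivative
#' @param states an [agent_states()] object.
#' @param net a [social_network()].
#' @param params a [model_params()]; `params$field` and `params$step_size`
#'   are used.
#' @param weight_matrix optional precomputed long-range weight matrix (rows
#'   already normalised when `params$normalize_long_range`).
#' @return updated [agent_states()].
#' @export
step_opinions <- function(states, net, kernels = default_kernels(), params,
                          weight_matrix = NULL) {
  x <- states$opinion
  n <- length(x)
  if (is.null(weight_matrix)) {
    weight_matrix <- long_range_weight_matrix(net, params$shell_decay,
                                              params$normalize_long_range,
                                              params$long_range_coupling)
  }
  m <- as.numeric(weight_matrix %*% x)
  new_x <- x
  new_frozen <- states$frozen
  for (i in seq_len(n)) {
    if (states$frozen[i]) next
    nb <- which(net$adj[i, ])
    pair_sum <- if (length(nb) > 0L) {
      sum(vapply(nb, function(j) kernels$pair_term(x[i], x[j]), numeric(1)))
    } else 0
    dx <- kernels$long_range_term(states$attitude[i], x[i], m[i]) +
      pair_sum + kernels$field_term(x[i], params$field)
    xi <- x[i] + params$step_size * dx
    if (abs(xi) >= 1) {
      new_x[i] <- sgn(xi)
      new_frozen[i] <- TRUE
    } else {
      new_x[i] <- xi
    }
  }
  agent_states(new_x, states$attitude, new_frozen)
}

# run a block of up to nsteps transactions; compiled fast path for default
# kernels, R loop otherwise. Returns list(states, steps).
run_block <- function(states, net, kernels, params, nsteps, weight_matrix) {
  if (nsteps <= 0L || all(states$frozen)) {
    return(list(states = states, steps = 0L))
  }
  if (isTRUE(kernels$is_default)) {
    el <- edge_list(net)
    res <- cpp_run_block(states$opinion, states$frozen, states$attitude,
                         el - 1L, weight_matrix, params$field,
                         params$step_size, as.integer(nsteps))
    return(list(states = agent_states(res$opinion, states$attitude,
                                      res$frozen),
                steps = res$steps))
  }
  steps <- 0L
  for (k in seq_len(nsteps)) {
    states <- step_opinions(states, net, kernels, params, weight_matrix)
    steps <- steps + 1L
    if (all(states$frozen)) break
  }
  list(states = states, steps = steps)
}

#' Run a full co-evolution simulation
#'
#' Alternates `g = transactions_per_rewiring` opinion transactions with one
#' network rewiring phase until either every agent is frozen or `max_steps`
#' transactions have been executed. Observables are recorded at the start and
#' after every rewiring phase (and at the final state). The whole run is
#' reproducible from `params$seed`.
#'
#' @param params a [model_params()].
#' @param kernels an [interaction_kernels()] record.
#' @param init optional list `(net, states)` overriding the random
#'   initialisation (the seed is still set, keeping the rewiring draw stream
#'   aligned across runs that share a seed).
#' @return object of class `sim_result`: list with `params`, final `net` and
#'   `states`, `records` (a data.frame of [summarize_system()] rows, one per
#'   recording time), `rewire_log` (one row per rewiring event: step, 0-based
#'   agent, mechanism, links cut and created; `NULL` if no rewiring
#'   happened), `n_rewirings`, `steps` executed, and `converged` (`TRUE`
#'   when every agent froze before the horizon).
#' @export
run_simulation <- function(params, kernels = default_kernels(), init = NULL) {
  validate_params(params)
  set.seed(params$seed)
  if (is.null(init)) {
    init <- init_system(params, set_seed = FALSE)
  }
  net <- init$net
  states <- init$states
  g <- params$transactions_per_rewiring

  weight_matrix <- long_range_weight_matrix(net, params$shell_decay,
                                            params$normalize_long_range,
                                            params$long_range_coupling)
  records <- list()
  rec <- function(t) {
    r <- summarize_system(net, states, params)
    r$time <- t
    records[[length(records) + 1L]] <<- r
  }
  rec(0L)

  steps <- 0L
  n_rewirings <- 0L
  rewire_log <- list()
  while (steps < params$max_steps && !all(states$frozen)) {
    block <- run_block(states, net, kernels, params,
                       min(g, params$max_steps - steps), weight_matrix)
    states <- block$states
    steps <- steps + block$steps
    if (all(states$frozen)) {
      rec(steps)
      break
    }
    net <- rewire_phase(states, net, params, return_plans = TRUE)
    plans <- attr(net, "plans")
    attr(net, "plans") <- NULL
    if (length(plans) > 0L) {
      rewire_log[[length(rewire_log) + 1L]] <- data.frame(
        step = steps,
        agent = vapply(plans, `[[`, 0L, "agent") - 1L,
        mechanism = vapply(plans, `[[`, "", "mechanism"),
        n_cut = vapply(plans, function(p) length(p$cuts), 0L),
        n_created = vapply(plans, function(p) length(p$creations), 0L))
    }
    n_rewirings <- n_rewirings + 1L
    weight_matrix <- long_range_weight_matrix(net, params$shell_decay,
                                              params$normalize_long_range,
                                              params$long_range_coupling)
    rec(steps)
  }

  structure(list(params = params,
                 net = net,
                 states = states,
                 records = do.call(rbind, records),
                 rewire_log = if (length(rewire_log) > 0L) {
                   do.call(rbind, rewire_log)
                 } else NULL,
                 n_rewirings = n_rewirings,
                 steps = steps,
                 converged = all(states$frozen)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("sim_result: N = %d, h = %.3g, q = %.2f | %d steps, ",
                     "%d rewirings, %s\n"),
              x$params$n_agents, x$params$field, x$params$closure_mix,
              x$steps, x$n_rewirings,
              if (x$converged) "all agents frozen" else "horizon reached"))
  invisible(x)
}
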