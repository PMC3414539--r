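#' Simulation parameters
#'
#' Builds and validates the full set of constants for one model run: the
#' population size, the initial Erdos-Renyi mean degree, the external field
#' strength `h` (mass-media drive; `h > 0` pushes towards the scientific
#' position at `+1`, `h < 0` towards the opposite extreme), the closure mix
#' `q` (probability that a rewiring agent uses focal instead of triadic
#' closure), the time-scale ratio `g` (opinion transactions per rewiring
#' phase), the Euler step size `dt`, and the run horizon in transactions.
#'
#' Attitudes are quenched draws from the uniform distribution on `[-1, 1]`
#' (centre 0, unit half-width); initial opinions are drawn from the standard
#' normal truncated to `(-1, 1)`. Both distributions are fixed properties of
#' the model, not tunables.
#'
#' @param n_agents population size `N`.
#' @param mean_degree target initial average degree `<k>`; the initial graph
#'   is Erdos-Renyi with edge probability `mean_degree / (n_agents - 1)`.
#' @param field external field strength `h`.
#' @param closure_mix focal-closure probability `q` in `[0, 1]`.
#' @param transactions_per_rewiring `g >= 1`, transactions between rewirings.
#' @param step_size Euler step `dt > 0`.
#' @param max_steps horizon in transactions; non-convergence by `max_steps`
#'   is reported in the trajectory, not an error.
#' @param links_per_event `"all"` (an agent cuts every link when it rewires,
#'   the default) or a positive integer cap.
#' @param shell_decay base `b > 1` of the geodesic shell weights
#'   `w_n = b^-(n-1)`, positive and strictly decreasing in `n`.
#' @param normalize_long_range if `TRUE` (default) the long-range public
#'   opinion `m_i` is the weight-normalised mean over shells `n >= 2` scaled
#'   by `long_range_coupling`; if `FALSE` it is the raw weighted sum (whose
#'   magnitude then grows with the population size).
#' @param long_range_coupling strength `C` of the normalised public-opinion
#'   signal, `m_i = C x weighted shell mean`. The attitude spring
#'   `alpha_i x_i |m_i|` competes with the pairwise drive of about
#'   `mean_degree` decided neighbours, so `C` of the order of the degree
#'   separates the regimes: agents whose attitude opposes a positive field
#'   are trapped at small opinions (persistent "ignorants"), while under a
#'   negative field the non-vanishing field term plus the fundamentalist
#'   neighbourhood still force everyone to decide. Default 8.
#' @param n_plus_mode population used for the model-side agreement fraction
#'   `n+`: `"all"` counts every agent by opinion sign, `"frozen"` counts
#'   decided agents only (the analogue of excluding "do not know" answers).
#' @param nn_weighting `"degree"` (default) or `"uniform"` aggregation of the
#'   per-agent nearest-neighbour opinion averages within a group.
#' @param seed integer seed; all randomness in a run flows from it.
#'
#' @return an object of class `model_params` (a validated named list).
#' @export
model_params <- function(n_agents = 200L,
                         mean_degree = 6,
                         field = 0,
                         closure_mix = 0,
                         transactions_per_rewiring = 100L,
                         step_size = 0.01,
                         max_steps = 50000L,
                         links_per_event = "all",
                         shell_decay = 2,
                         normalize_long_range = TRUE,
                         long_range_coupling = 8,
                         n_plus_mode = c("all", "frozen"),
                         nn_weighting = c("degree", "uniform"),
                         seed = 1L) {
  n_plus_mode <- match.arg(n_plus_mode)
  nn_weighting <- match.arg(nn_weighting)
  p <- list(
    n_agents = as.integer(n_agents),
    mean_degree = as.numeric(mean_degree),
    field = as.numeric(field),
    closure_mix = as.numeric(closure_mix),
    transactions_per_rewiring = as.integer(transactions_per_rewiring),
    step_size = as.numeric(step_size),
    max_steps = as.integer(max_steps),
    links_per_event = links_per_event,
    shell_decay = as.numeric(shell_decay),
    normalize_long_range = isTRUE(normalize_long_range),
    long_range_coupling = as.numeric(long_range_coupling),
    n_plus_mode = n_plus_mode,
    nn_weighting = nn_weighting,
    seed = as.integer(seed)
  )
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (is.na(p$n_agents) || p$n_agents < 2L) {
    stop("configuration error: n_agents must be an integer >= 2", call. = FALSE)
  }
  if (!is.finite(p$mean_degree) || p$mean_degree <= 0 ||
      p$mean_degree >= p$n_agents - 1 + 1e-12) {
    stop("configuration error: mean_degree must lie in (0, n_agents - 1]",
         call. = FALSE)
  }
  if (p$closure_mix < 0 || p$closure_mix > 1) {
    stop("configuration error: closure_mix (q) must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.finite(p$step_size) || p$step_size < 0) {
    stop("configuration error: step_size (dt) must be >= 0", call. = FALSE)
  }
  if (p$transactions_per_rewiring < 1L) {
    stop("configuration error: transactions_per_rewiring (g) must be >= 1",
         call. = FALSE)
  }
  if (p$max_steps < 0L) {
    stop("configuration error: max_steps must be >= 0", call. = FALSE)
  }
  lpe <- p$links_per_event
  ok <- identical(lpe, "all") ||
    (is.numeric(lpe) && length(lpe) == 1L && is.finite(lpe) && lpe >= 1)
  if (!ok) {
    stop("configuration error: links_per_event must be \"all\" or an integer >= 1",
         call. = FALSE)
  }
  if (!is.finite(p$shell_decay) || p$shell_decay <= 1) {
    stop("configuration error: shell_decay must be > 1", call. = FALSE)
  }
  if (!is.finite(p$long_range_coupling) || p$long_range_coupling < 0) {
    stop("configuration error: long_range_coupling must be >= 0",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Geodesic shell weights
#'
#' Weight `w_n = shell_decay^-(n-1)` attached to agents `n` steps away in the
#' long-range (public opinion) term; positive and strictly decreasing in `n`.
#'
#' @param n shell index (vector allowed), `n >= 1`.
#' @param shell_decay decay base, default 2.
#' @return numeric vector of weights.
#' @export
shell_weight <- function(n, shell_decay = 2) {
  shell_decay^(-(n - 1))
}

#' Interaction kernels of the opinion dynamics
#'
#' The opinion velocity of an unfrozen agent is the sum of three terms: a
#' long-range reaction `long_range_term(alpha_i, x_i, m_i)` to the public
#' opinion `m_i` of agents at geodesic distance two or more, modulated by the
#' quenched attitude `alpha_i`; a pairwise discussion term
#' `pair_term(x_i, x_j)` summed over direct neighbours, which reinforces
#' same-sign opinions and weakens opposite-sign ones; and a field term
#' `field_term(x_i, h)` coupling every agent to the mass-media drive `h`,
#' vanishing at `x_i = 1` so that agents already holding the scientific
#' position are unaffected by further propaganda.
#'
#' The defaults are
#' `long_range = alpha * (m + x * |m|) = alpha * m * (1 + x * sgn(m))`,
#' `pair = sgn(x_i) * (|x_i + x_j| - |x_i - x_j|) / 2` and
#' `field = (h / 2) * (1 - x_i)`, with `sgn(0)` taken as `+1`.
#' The `(1 + x sgn(m))` receptivity factor makes agents at the extreme
#' opposing the prevailing public mood deaf to it (stubborn defence of a
#' fully formed conviction), while agents aligned with the mood remain fully
#' receptive; it is odd under the joint mirror `x -> -x`, so at `h = 0` the
#' dynamics stay perfectly symmetric and the field term is the only symmetry
#' breaker.
#' Any component can be replaced; the integrator only uses this record, but
#' the compiled fast path is bypassed for non-default kernels.
#'
#' @param long_range_term function `(attitude, opinion, m) -> numeric`.
#' @param pair_term function `(x_i, x_j) -> numeric`.
#' @param field_term function `(x_i, h) -> numeric`.
#' @return an object of class `interaction_kernels`.
#' @export
interaction_kernels <- function(long_range_term = NULL,
                                pair_term = NULL,
                                field_term = NULL) {
  defaults <- list(
    long_range_term = function(attitude, opinion, m) {
      attitude * (m + opinion * abs(m))
    },
    pair_term = function(x_i, x_j) {
      sgn(x_i) * (abs(x_i + x_j) - abs(x_i - x_j)) / 2
    },
    field_term = function(x_i, h) (h / 2) * (1 - x_i)
  )
  is_default <- is.null(long_range_term) && is.null(pair_term) &&
    is.null(field_term)
  k <- list(
    long_range_term = if (is.null(long_range_term)) defaults$long_range_term else long_range_term,
    pair_term = if (is.null(pair_term)) defaults$pair_term else pair_term,
    field_term = if (is.null(field_term)) defaults$field_term else field_term,
    is_default = is_default
  )
  class(k) <- "interaction_kernels"
  k
}

#' Default kernel set
#'
#' @return the default [interaction_kernels()] record.
#' @export
default_kernels <- function() interaction_kernels()

# sign with sgn(0) = +1, the package-wide tie-break convention
sgn <- function(x) ifelse(x >= 0, 1, -1)
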