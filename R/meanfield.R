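#' @name meanfield
#' @title Mean-field reduction of the co-evolution model
#'
#' @description
#' In the asymptotically stationary state the site-dependent pair and
#' long-range terms are replaced by slowly varying averages `Phi` and `M`,
#' turning the opinion equation into the linear form
#' `dx/dt = abar |M| x + Phi + (h/2)(1 - x)` with solution
#' `x(t) = x* + (x0 - x*) exp(lambda t)`, mean fixed point `x*` and
#' eigenvalue `lambda = abar |M| - h/2` (`abar = E|alpha| = 1/2`, the mean
#' attitude magnitude: the raw mean attitude is zero by symmetry and would
#' kill the long-range term altogether).
#'
#' Writing `z = x* / x_b` with scale `x_b = sqrt(2)`, the truncated-normal
#' density of initial opinions becomes `p(x) = p0 exp(-z^2) ~ p0 (1 - z^2)`,
#' and the decided-agent imbalance `u = n_E - n_F = 1 - 2 F(x*)` has the
#' cubic Taylor form `u(z) = -a (z - z^3/3)` with `a = 2 p0 x_b`. Closing the
#' averages as `Phi = kbar u(z)` (each decided neighbour pushes with its full
#' conviction) and `M = -a z` (linear response of the distant-opinion mean)
#' gives a cubic equation for the scaled fixed point,
#' `(kbar a / 3) z^3 + (abar a x_b) z^2 - (kbar a + h x_b / 2) z + h/2 = 0`,
#' whose branch continuous from the `h -> -inf` asymptote (where `x* -> 1`)
#' is the physically meaningful one; it coincides with the largest real root
#' for every `h`.
#'
#' The eigenvalue `lambda(h) = abar a z(h) - h/2` is then trivially positive
#' for `h <= 0` (repulsive fixed point, negative consensus) and changes sign
#' at a critical field `h_c > 0`, beyond which the attractive fixed point
#' traps agents at interior opinions and undecided agents persist.
NULL

# fixed numerical constants of the reduction
mf_constants <- function() {
  z_mass <- stats::pnorm(1) - stats::pnorm(-1)
  p0 <- stats::dnorm(0) / z_mass
  x_b <- sqrt(2)
  list(x_b = x_b, p0 = p0, a = 2 * p0 * x_b, alpha_bar = 0.5,
       trunc_mass = z_mass)
}

#' Truncated-normal CDF and density of initial opinions
#'
#' Standard normal truncated to `(-1, 1)`; the CDF is clamped to `[0, 1]`
#' outside the support so threshold arithmetic can be done without case
#' analysis.
#'
#' @param x evaluation points.
#' @return probabilities (resp. densities).
#' @export
ptrunc01 <- function(x) {
  lo <- stats::pnorm(-1)
  hi <- stats::pnorm(1)
  pmin(pmax((stats::pnorm(x) - lo) / (hi - lo), 0), 1)
}

#' @rdname ptrunc01
#' @export
dtrunc01 <- function(x) {
  ifelse(abs(x) < 1, stats::dnorm(x) / (stats::pnorm(1) - stats::pnorm(-1)), 0)
}

#' Acyclic-network layer count
#'
#' Treats the network as a Cayley tree with coordination number `k`: layer
#' `n` holds `k (k-1)^(n-1)` nodes. `n_max` is the largest layer index such
#' that the cumulative node count stays below `N - 1`; the remaining `R`
#' nodes sit in layer `n_max + 1`.
#'
#' @param k coordination number (mean degree), must exceed 1.
#' @param n_agents population size `N`.
#' @return list with `n_max`, `layer_sizes` (layers `1..n_max`), and
#'   `remainder`.
#' @export
layer_count <- function(k, n_agents) {
  if (k <= 1) stop("domain error: tree layer count needs mean degree > 1",
                   call. = FALSE)
  avail <- n_agents - 1
  sizes <- numeric(0)
  total <- 0
  n <- 0L
  repeat {
    nxt <- k * (k - 1)^n
    if (total + nxt >= avail) break
    n <- n + 1L
    sizes[n] <- nxt
    total <- total + nxt
  }
  list(n_max = n, layer_sizes = sizes, remainder = avail - total)
}

# mu = sum_{n>=2} w_n N_n + w_{n_max+1} R: average number of further
# neighbours weighted by geodesic distance (layers 2 and beyond)
mu_factor <- function(k, n_agents, shell_decay = 2) {
  lc <- layer_count(k, n_agents)
  mu <- 0
  if (lc$n_max >= 2L) {
    ns <- 2:lc$n_max
    mu <- sum(shell_weight(ns, shell_decay) * lc$layer_sizes[ns])
  }
  rem_layer <- max(lc$n_max + 1L, 2L)
  mu + shell_weight(rem_layer, shell_decay) * lc$remainder
}

#' Conversion fractions from the initial-opinion distribution
#'
#' Fractions `rho(s, s')` of agents starting with opinion sign `s` that end
#' frozen at the extreme of sign `s'`, obtained by integrating the truncated
#' standard normal. Around a repulsive fixed point every agent below `x*`
#' flows to `-1` and every agent above to `+1`; when `lambda` is supplied the
#' finite-horizon thresholds
#' `x_pm = x* + (pm 1 - x*) exp(-lambda g dt)` (the initial opinions that
#' reach the extremes in exactly `g` steps of size `dt`) are used instead,
#' leaving an undecided band of mass `s` together with its first-order
#' estimate `s_linear = 2 p(x*) exp(-lambda g dt)`.
#'
#' @param x_star mean fixed point.
#' @param params a [model_params()] (supplies `g` and `dt`).
#' @param lambda optional eigenvalue enabling the finite-horizon thresholds.
#' @return list with the conditional fractions `pp`, `pm`, `mp`, `mm`
#'   (start sign then end sign), threshold positions `x_plus`, `x_minus`,
#'   undecided fraction `s`, and `s_linear`.
#' @export
rho_fractions <- function(x_star, params, lambda = NULL) {
  if (is.null(lambda)) {
    x_plus <- x_minus <- x_star
  } else {
    damp <- exp(-lambda * params$transactions_per_rewiring * params$step_size)
    x_plus <- x_star + (1 - x_star) * damp
    x_minus <- x_star + (-1 - x_star) * damp
  }
  f_plus <- ptrunc01(x_plus)   # mass that fails to reach +1
  f_minus <- ptrunc01(x_minus) # mass that reaches -1
  half <- 0.5                  # truncated normal is symmetric about 0
  pp <- (1 - max(f_plus, half)) / half
  pm <- max(f_minus - half, 0) / half
  mm <- min(f_minus, half) / half
  mp <- max(half - f_plus, 0) / half
  s <- max(f_plus - f_minus, 0)
  s_linear <- if (is.null(lambda)) 0 else {
    2 * dtrunc01(x_star) *
      exp(-lambda * params$transactions_per_rewiring * params$step_size)
  }
  list(pp = pp, pm = pm, mp = mp, mm = mm,
       x_plus = x_plus, x_minus = x_minus, s = s, s_linear = s_linear)
}

#' Mean interaction terms at a scaled fixed point
#'
#' `Phi` is the mean short-range (discussion) drive: the expert and
#' fundamentalist neighbour populations push with their full convictions,
#' `Phi = kbar (n_E - n_F)`, so each sign's decided fraction contributes
#' additively and `|Phi| <= kbar`. `M` is the mean long-range public opinion;
#' its distance-weighted layer structure (factor `mu` from the acyclic
#' approximation) cancels in the normalised average, leaving the linear
#' response `M = -a z` of the decided imbalance, `|M|` bounded well below
#' the population size. Exact (CDF-based) counterparts of the cubic-order
#' forms are returned alongside.
#'
#' @param z scaled fixed point `x*/x_b`.
#' @param params a [model_params()].
#' @param kbar mean degree entering `Phi` (default [degree_decay()] at
#'   `h = params$field`); must exceed 1.
#' @param lambda optional eigenvalue for finite-horizon decided fractions.
#' @return list with `phi`, `m_bar`, their exact-CDF versions `phi_exact`,
#'   `m_exact`, the per-sign contributions `phi_pos`, `phi_neg`, and the
#'   layer diagnostics `mu`, `n_max`.
#' @export
mean_terms <- function(z, params, kbar = NULL, lambda = NULL) {
  cst <- mf_constants()
  if (is.null(kbar)) kbar <- degree_decay(params$field, params)
  if (kbar <= 1) {
    stop("domain error: mean degree <= 1, tree approximation degenerate",
         call. = FALSE)
  }
  x_star <- cst$x_b * z
  rho <- rho_fractions(x_star, params, lambda)
  n_e <- (rho$pp + rho$mp) / 2
  n_f <- (rho$pm + rho$mm) / 2
  u_poly <- -cst$a * (z - z^3 / 3)
  lc <- layer_count(kbar, params$n_agents)
  list(phi = kbar * u_poly,
       phi_exact = kbar * (n_e - n_f),
       phi_pos = kbar * n_e,
       phi_neg = -kbar * n_f,
       m_bar = -cst$a * z,
       m_exact = n_e - n_f,
       mu = mu_factor(kbar, params$n_agents, params$shell_decay),
       n_max = lc$n_max)
}

#' Predicted mean degree after the first rewiring
#'
#' The simultaneous rewiring of neighbouring undecided agents creates and
#' deletes links in pairs: a doubly-cut bond is replaced twice (degree gain
#' `~ s^2`) while a doubly-created bond collapses to one (loss
#' `~ s^2/(k0-1)`), with `s` the fraction of agents still undecided at the
#' first rewiring. The package closes this as
#' `kbar(h) = k0 (1 + s^2 (1 - 1/(k0 - 1)))`, with `s` evaluated on the
#' repulsive branch at field `-|h|` (the regime in which the estimate is
#' derived), so the correction vanishes when `s = 0` and decays
#' exponentially as `|h|` grows -- under a strong field agents decide before
#' they ever rewire and the network stays as random as it started.
#'
#' @param h external field strength.
#' @param params a [model_params()].
#' @param iterations self-consistency iterations (the undecided fraction
#'   depends on the fixed point, which depends on the degree).
#' @return predicted mean degree, with the undecided fraction attached as
#'   attribute `"s"`.
#' @export
degree_decay <- function(h, params, iterations = 12L) {
  cst <- mf_constants()
  k0 <- params$mean_degree
  hm <- -abs(h)
  kbar <- k0
  s <- 0
  for (it in seq_len(iterations)) {
    z <- cubic_branch_root(hm, kbar, params)
    lambda <- cst$alpha_bar * cst$a * z - hm / 2
    s <- rho_fractions(cst$x_b * z, params, lambda)$s
    kbar <- k0 * (1 + s^2 * (1 - 1 / (k0 - 1)))
  }
  structure(kbar, s = s)
}

#' Coefficients of the cubic fixed-point equation
#'
#' `G(z) = c3 z^3 + c2 z^2 + c1 z + c0` with
#' `c3 = kbar a / 3`, `c2 = abar a x_b`, `c1 = -(kbar a + h x_b / 2)`,
#' `c0 = h / 2`.
#'
#' @param h external field.
#' @param kbar mean degree entering the short-range term.
#' @param params a [model_params()] (unused fields ignored; kept for
#'   signature symmetry).
#' @return numeric vector `c(c0, c1, c2, c3)` in ascending powers.
#' @export
cubic_coefficients <- function(h, kbar, params = NULL) {
  cst <- mf_constants()
  c(h / 2,
    -(kbar * cst$a + h * cst$x_b / 2),
    cst$alpha_bar * cst$a * cst$x_b,
    kbar * cst$a / 3)
}

# largest real root of the cubic = the branch continuous from h -> -inf
cubic_branch_root <- function(h, kbar, params) {
  co <- cubic_coefficients(h, kbar, params)
  r <- polyroot(co)
  real <- Re(r[abs(Im(r)) < 1e-8 * pmax(1, abs(Re(r)))])
  if (length(real) == 0L) {
    stop("solver error: cubic has no real root (numerically degenerate); ",
         "coefficients: ", paste(signif(co, 6), collapse = ", "),
         call. = FALSE)
  }
  z <- max(real)
  # Newton polish so the residual meets the 1e-10 contract
  for (it in 1:3) {
    g <- co[1] + co[2] * z + co[3] * z^2 + co[4] * z^3
    dg <- co[2] + 2 * co[3] * z + 3 * co[4] * z^2
    if (abs(dg) < 1e-14) break
    z <- z - g / dg
  }
  z
}

#' Solve the mean-field fixed point at a given field
#'
#' Solves the cubic for the scaled fixed point `z` on the branch continuous
#' in `h` from the `h -> -inf` asymptote (the largest real root), then
#' assembles the full solution: `x* = x_b z`, eigenvalue
#' `lambda = abar a z - h/2`, mean terms, predicted degree, conversion
#' fractions and undecided fraction.
#'
#' @param h external field strength.
#' @param params a [model_params()].
#' @return object of class `meanfield_solution`: list with `field`,
#'   `fixed_point`, `scaled_fixed_point`, `eigenvalue`,
#'   `predicted_mean_degree`, `phi`, `m_bar`, `mu`, `rho` (from
#'   [rho_fractions()] with the finite-horizon thresholds),
#'   `undecided_fraction`, and `residual` of the cubic at the root.
#' @export
solve_fixed_point <- function(h, params) {
  cst <- mf_constants()
  kbar <- degree_decay(h, params)
  z <- cubic_branch_root(h, kbar, params)
  co <- cubic_coefficients(h, kbar, params)
  residual <- abs(co[1] + co[2] * z + co[3] * z^2 + co[4] * z^3)
  lambda <- cst$alpha_bar * cst$a * z - h / 2
  terms <- mean_terms(z, params, kbar = as.numeric(kbar), lambda = lambda)
  rho <- rho_fractions(cst$x_b * z, params, lambda)
  structure(list(field = h,
                 fixed_point = cst$x_b * z,
                 scaled_fixed_point = z,
                 eigenvalue = lambda,
                 predicted_mean_degree = as.numeric(kbar),
                 phi = terms$phi,
                 m_bar = terms$m_bar,
                 mu = terms$mu,
                 rho = rho,
                 undecided_fraction = rho$s,
                 residual = residual),
            class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf(paste0("meanfield_solution: h = %.4g | x* = %.4f (z = %.4f), ",
                     "lambda = %.4f, <k> = %.3f, s = %.4f\n"),
              x$field, x$fixed_point, x$scaled_fixed_point, x$eigenvalue,
              x$predicted_mean_degree, x$undecided_fraction))
  invisible(x)
}

#' Critical field
#'
#' `lambda(h)` is continuous and positive for `h <= 0`; the smallest
#' `h_c > 0` with `lambda(h_c) = 0` is located by scanning a field grid for
#' a sign change and bisecting the bracket. Failure to find a sign change on
#' the grid is an explicit error, never an extrapolation.
#'
#' @param params a [model_params()].
#' @param h_max upper end of the scanned range.
#' @param n_grid number of scan points on `(0, h_max]`.
#' @param tol bisection tolerance on `h`.
#' @return `h_c` with `|lambda(h_c)| < 1e-8`.
#' @export
critical_field <- function(params, h_max = 6, n_grid = 61L, tol = 1e-12) {
  lam <- function(h) solve_fixed_point(h, params)$eigenvalue
  hs <- seq(0, h_max, length.out = n_grid)
  vals <- vapply(hs, lam, numeric(1))
  flip <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (length(flip) == 0L) {
    stop("solver error: no sign change of lambda(h) on (0, ", h_max,
         "]; lambda range [", signif(min(vals), 4), ", ",
         signif(max(vals), 4), "]", call. = FALSE)
  }
  i <- flip[1L]
  stats::uniroot(lam, lower = hs[i], upper = hs[i + 1L], tol = tol)$root
}

#' Mean-field curve over a field grid
#'
#' @param params a [model_params()].
#' @param h_grid ordered field values.
#' @return data.frame with one row per field value: `h`, `z`, `x_star`,
#'   `lambda`, `mean_degree`, `phi`, `m_bar`, `undecided_fraction`,
#'   `residual`.
#' @export
meanfield_curve <- function(params, h_grid = seq(-3, 6, by = 0.1)) {
  rows <- lapply(h_grid, function(h) {
    s <- solve_fixed_point(h, params)
    data.frame(h = h, z = s$scaled_fixed_point, x_star = s$fixed_point,
               lambda = s$eigenvalue, mean_degree = s$predicted_mean_degree,
               phi = s$phi, m_bar = s$m_bar,
               undecided_fraction = s$undecided_fraction,
               residual = s$residual)
  })
  do.call(rbind, rows)
}
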