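test_that("truncated-normal machinery matches a quadrature oracle", {
  # generic thresholds: CDF differences vs numerical integration of the density
  pairs <- list(c(-0.83, 0.21), c(-0.4, 0.97), c(0.05, 0.4), c(-1, 1))
  for (ab in pairs) {
    q <- stats::integrate(dtrunc01, ab[1], ab[2], rel.tol = 1e-10)$value
    expect_equal(ptrunc01(ab[2]) - ptrunc01(ab[1]), q, tolerance = 1e-8)
  }
  # clamped outside the support
  expect_identical(ptrunc01(c(-2, 2)), c(0, 1))
})

test_that("rho_fractions: boundary, symmetry and horizon behaviour", {
  p <- model_params()
  # threshold at the upper cutoff: nothing reaches +1
  expect_equal(rho_fractions(1, p)$pp, 0)
  # symmetric fixed point at 0: each side holds half the mass
  r0 <- rho_fractions(0, p)
  expect_equal(r0$pp, 1) # all initially-positive agents sit above x* = 0
  expect_equal(r0$mm, 1)
  expect_equal(ptrunc01(0), 0.5)
  # finite-horizon thresholds leave an undecided band matching its
  # first-order estimate when the band is narrow
  rl <- rho_fractions(0.2, p, lambda = 3)
  expect_gt(rl$s, 0)
  expect_equal(rl$s, rl$s_linear, tolerance = 0.05 * rl$s_linear)
  # conditional fractions never exceed 1 per starting sign
  for (xs in c(-0.5, 0, 0.4, 1.5)) {
    r <- rho_fractions(xs, p, lambda = 1.2)
    expect_lte(r$pp + r$pm, 1 + 1e-12)
    expect_lte(r$mp + r$mm, 1 + 1e-12)
  }
})

test_that("layer_count enumerates Cayley-tree shells", {
  # k = 3, N = 22: layers 3, 6 fit below 21; adding 12 would exceed
  lc <- layer_count(3, 22)
  expect_identical(lc$n_max, 2L)
  expect_equal(lc$layer_sizes, c(3, 6))
  expect_equal(lc$remainder, 12)
  expect_error(layer_count(1, 10), "domain error")
})

test_that("mean_terms: per-sign additivity and bounds", {
  p <- model_params()
  # fixed point beyond the cutoff: no experts, so the positive contribution
  # to Phi vanishes
  mt <- mean_terms(1, p, kbar = 6)
  expect_equal(mt$phi_pos, 0)
  expect_equal(mt$phi_exact, mt$phi_pos + mt$phi_neg)
  # Phi bounded by the degree, M far below the population size
  for (z in seq(-0.6, 1.6, by = 0.2)) {
    m <- mean_terms(z, p, kbar = 6)
    expect_lte(abs(m$phi_exact), 6 + 1e-12)
    expect_lte(abs(m$m_exact), 1)
    expect_lt(abs(m$m_exact), p$n_agents - 1)
  }
  expect_error(mean_terms(0.2, p, kbar = 0.9), "domain error")
})

test_that("cubic-order decided imbalance is the Taylor form of the exact CDF", {
  cst <- opinionfield:::mf_constants()
  u_exact <- function(z) 1 - 2 * ptrunc01(cst$x_b * z)
  u_cubic <- function(z) -cst$a * (z - z^3 / 3)
  for (z in c(0.05, 0.1, 0.2)) {
    expect_equal(u_cubic(z), u_exact(z), tolerance = 1e-3)
    # error shrinks like z^5: order-of-magnitude check at z/2
    err_z <- abs(u_cubic(z) - u_exact(z))
    err_h <- abs(u_cubic(z / 2) - u_exact(z / 2))
    expect_lt(err_h, err_z / 8)
  }
})

test_that("degree_decay: zero correction, |h| monotonicity, dual path", {
  p <- model_params()
  # at default generation time the undecided band at the first rewiring is
  # empty, so the degree stays at its initial value
  kd <- degree_decay(-2, p)
  expect_equal(as.numeric(kd), p$mean_degree)
  expect_equal(attr(kd, "s"), 0)

  # short generations leave undecided agents; correction is positive and
  # decays with |h|
  ps <- model_params(transactions_per_rewiring = 10L)
  ks <- vapply(c(0, 0.5, 1, 2, 4), function(h) as.numeric(degree_decay(h, ps)),
               numeric(1))
  expect_gt(ks[1], ps$mean_degree)
  expect_true(all(diff(ks) <= 1e-10))
  expect_equal(degree_decay(-1.5, ps), degree_decay(1.5, ps)) # |h| only

  # dual-implementation oracle: rebuild the closed form from the solution's
  # own undecided fraction
  for (h in c(0, 1, 3)) {
    kd <- degree_decay(h, ps)
    s <- attr(kd, "s")
    k0 <- ps$mean_degree
    expect_equal(as.numeric(kd), k0 * (1 + s^2 * (1 - 1 / (k0 - 1))),
                 tolerance = 1e-12)
  }
})

test_that("solve_fixed_point: residuals, branch continuity, lambda signs", {
  p <- model_params()
  hs <- seq(-3, 6, by = 0.05)
  curve <- meanfield_curve(p, hs)
  expect_true(all(curve$residual < 1e-10))
  # single continuous branch: no jumps between adjacent grid points
  expect_lt(max(abs(diff(curve$z))), 0.01)
  expect_lt(max(abs(diff(curve$lambda))), 0.05)
  # eigenvalue trivially positive for h <= 0, negative for large h
  expect_true(all(curve$lambda[curve$h <= 0] > 0))
  expect_true(all(curve$lambda[curve$h >= 5] < 0))
})

test_that("cubic solver agrees with dense-grid bisection", {
  # independent oracle: bracket the largest sign change of the polynomial on
  # a dense grid and bisect, without polyroot
  p <- model_params()
  bisect_root <- function(co, lo = 0, hi = 8, n = 4000) {
    f <- function(z) co[1] + co[2] * z + co[3] * z^2 + co[4] * z^3
    zs <- seq(lo, hi, length.out = n)
    v <- f(zs)
    flip <- which(v[-1] * v[-n] <= 0)
    i <- flip[length(flip)]
    a <- zs[i]; b <- zs[i + 1]
    for (it in 1:200) {
      m <- (a + b) / 2
      if (f(a) * f(m) <= 0) b <- m else a <- m
    }
    (a + b) / 2
  }
  for (h in seq(-2.5, 5.5, by = 0.4)) {
    sol <- solve_fixed_point(h, p)
    co <- cubic_coefficients(h, sol$predicted_mean_degree, p)
    expect_equal(sol$scaled_fixed_point, bisect_root(co), tolerance = 1e-8)
  }
})

test_that("critical_field brackets and bisects the lambda sign change", {
  p <- model_params()
  hc <- critical_field(p)
  expect_gt(hc, 0)
  expect_lt(abs(solve_fixed_point(hc, p)$eigenvalue), 1e-8)
  eps <- 0.05
  expect_gt(solve_fixed_point(hc - eps, p)$eigenvalue, 0)
  expect_lt(solve_fixed_point(hc + eps, p)$eigenvalue, 0)
  # grid-scan oracle: argmin |lambda| on a fine grid sits next to hc
  hs <- seq(0.5, 5, by = 0.01)
  lam <- vapply(hs, function(h) solve_fixed_point(h, p)$eigenvalue, numeric(1))
  expect_lt(abs(hs[which.min(abs(lam))] - hc), 0.011)
})

test_that("mean-field ODE diverges from a repulsive and settles on an attractive fixed point", {
  p <- model_params()
  evolve <- function(sol, x0, t_end = 6, dt = 1e-3) {
    drive <- sol$phi + sol$field / 2 # constant part with Phi, M frozen
    x <- x0
    for (i in seq_len(t_end / dt)) x <- x + dt * (sol$eigenvalue * x + drive)
    x
  }
  rep_sol <- solve_fixed_point(-1, p) # lambda > 0
  xs <- rep_sol$fixed_point
  expect_gt(abs(evolve(rep_sol, xs + 1e-3) - xs), 0.1)
  att_sol <- solve_fixed_point(5, p) # lambda < 0
  xa <- att_sol$fixed_point
  expect_lt(abs(evolve(att_sol, xa + 0.5) - xa), 1e-3)
})
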