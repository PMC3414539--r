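test_that("model_params validates its ranges", {
  expect_s3_class(model_params(), "model_params")
  expect_error(model_params(n_agents = 1), "n_agents")
  expect_error(model_params(mean_degree = 0), "mean_degree")
  expect_error(model_params(n_agents = 10, mean_degree = 10), "mean_degree")
  expect_error(model_params(closure_mix = 1.2), "closure_mix")
  expect_error(model_params(step_size = -0.1), "step_size")
  expect_error(model_params(transactions_per_rewiring = 0), "transactions")
  expect_error(model_params(links_per_event = 0), "links_per_event")
})

test_that("init_system is deterministic and respects its distributions", {
  p <- small_params()
  a <- init_system(p)
  b <- init_system(p)
  expect_identical(a$net$adj, b$net$adj)
  expect_identical(a$states$opinion, b$states$opinion)
  expect_identical(a$states$attitude, b$states$attitude)
  expect_false(any(a$states$frozen))
  expect_true(all(abs(a$states$opinion) < 1))
  expect_true(all(abs(a$states$attitude) <= 1))
  # different seed, different draw
  p2 <- small_params(seed = 43L)
  expect_false(identical(init_system(p2)$states$opinion, a$states$opinion))
})

test_that("init_system N=2 with mean_degree 1 gives the single edge surely", {
  p <- model_params(n_agents = 2L, mean_degree = 1, seed = 7L)
  sys <- init_system(p)
  expect_equal(n_edges(sys$net), 1L)
})

test_that("empirical ER mean degree matches the binomial sampling oracle", {
  # oracle: mean degree of G(N, p) has mean (N-1)p = 6 and per-graph variance
  # Var(2E/N) = 4 Var(E)/N^2, E ~ Binom(N(N-1)/2, p)
  n <- 200L; k <- 6
  p_edge <- k / (n - 1)
  n_seeds <- 100L
  means <- vapply(seq_len(n_seeds), function(s) {
    sys <- init_system(model_params(n_agents = n, mean_degree = k, seed = s))
    mean(degrees(sys$net))
  }, numeric(1))
  var_e <- n * (n - 1) / 2 * p_edge * (1 - p_edge)
  se <- sqrt(4 * var_e / n^2 / n_seeds)
  expect_lt(abs(mean(means) - k), 3 * se)
})

test_that("long_range_opinion handles shells, exclusions and normalisation", {
  # star centre: no agent at distance >= 2
  st <- states_of(c(0.5, 1, -1, 0.3))
  expect_identical(long_range_opinion(star_net(4), st, 1), 0)
  # path a-b-c: m_a = w_2 * x_c in raw-sum mode (spec form), x_c normalised
  st3 <- states_of(c(0, 0, 0.8))
  expect_equal(long_range_opinion(path_net(3), st3, 1, normalize = FALSE),
               shell_weight(2) * 0.8)
  expect_equal(long_range_opinion(path_net(3), st3, 1, normalize = TRUE), 0.8)
  # all opinions zero -> 0 by linearity
  stz <- states_of(rep(0, 5))
  expect_identical(long_range_opinion(path_net(5), stz, 2), 0)
  # direct neighbours and self excluded: opinions there do not matter
  st4 <- states_of(c(0.9, 0.9, 0.4, 0.2))
  m <- long_range_opinion(path_net(4), st4, 1, normalize = FALSE)
  expect_equal(m, shell_weight(2) * 0.4 + shell_weight(3) * 0.2)
})

test_that("default kernels satisfy their sign contracts", {
  k <- default_kernels()
  # reinforcement / weakening of the pair term over a grid
  for (xi in c(-0.9, -0.3, 0.2, 0.7)) {
    for (xj in c(-0.8, -0.1, 0.4, 0.95)) {
      v <- k$pair_term(xi, xj)
      if (sign(xi) == sign(xj)) {
        expect_identical(sign(v), sign(xi))
      } else {
        expect_true(v == 0 || sign(v) == -sign(xi))
      }
    }
  }
  # field term: zero at h = 0, linear in x, magnitude non-increasing in x
  xs <- seq(-1, 1, by = 0.25)
  expect_identical(k$field_term(xs, 0), rep(0, length(xs)))
  fv <- k$field_term(xs, 1.5)
  expect_true(all(diff(abs(fv)) <= 1e-12))
  expect_equal(k$field_term(1, 3), 0)
  # long-range term proportional to attitude, vanishing with m
  expect_identical(k$long_range_term(0.7, 0.5, 0), 0)
  expect_equal(k$long_range_term(0.8, 0.5, -2), 2 * k$long_range_term(0.4, 0.5, -2))
})

test_that("opinion_derivative matches its contracts", {
  # isolated agent, h = 0: all terms vanish
  net <- social_network(3, rbind(c(2L, 3L)))
  st <- states_of(c(0.4, 0.1, 0.1), attitude = c(0.5, 0, 0))
  expect_identical(opinion_derivative(1, st, net, h = 0), 0)
  # same-sign neighbour reinforces, opposite-sign weakens
  net2 <- social_network(2, rbind(c(1L, 2L)))
  up <- opinion_derivative(1, states_of(c(0.5, 0.5)), net2, h = 0)
  expect_gt(up, 0)
  dn <- opinion_derivative(1, states_of(c(0.5, -0.9)), net2, h = 0)
  expect_lte(dn, 0)
  # frozen agent is a logic error
  stf <- states_of(c(1, 0.5), frozen = c(TRUE, FALSE))
  expect_error(opinion_derivative(1, stf, net2), "frozen")
})

test_that("step_opinions clamps, freezes and respects dt = 0", {
  p <- model_params(n_agents = 2L, mean_degree = 1, step_size = 0.05)
  net <- social_network(2, rbind(c(1L, 2L)))
  # frozen agent untouched across steps
  st <- states_of(c(1, 0.5), frozen = c(TRUE, FALSE))
  out <- step_opinions(st, net, default_kernels(), p)
  expect_identical(out$opinion[1], 1)
  expect_true(out$frozen[1])
  # overshoot clamps to the attained extreme and freezes
  p2 <- model_params(n_agents = 2L, mean_degree = 1, step_size = 1,
                     field = 2)
  st2 <- states_of(c(0.9, 0.95))
  out2 <- step_opinions(st2, net, default_kernels(), p2)
  expect_identical(out2$opinion, c(1, 1))
  expect_true(all(out2$frozen))
  # dt = 0 is the identity
  p3 <- model_params(n_agents = 2L, mean_degree = 1, step_size = 0)
  out3 <- step_opinions(st2, net, default_kernels(), p3)
  expect_identical(out3$opinion, st2$opinion)
})

test_that("compiled block integrator agrees with the R reference step", {
  p <- small_params(field = 0.7)
  sys <- init_system(p)
  w <- opinionfield:::long_range_weight_matrix(sys$net, p$shell_decay,
                                               p$normalize_long_range,
                                               p$long_range_coupling)
  # 25 reference steps in R
  ref <- sys$states
  for (i in 1:25) ref <- step_opinions(ref, sys$net, default_kernels(), p, w)
  # same 25 steps through the compiled path
  blk <- opinionfield:::run_block(sys$states, sys$net, default_kernels(), p,
                                  25L, w)
  expect_equal(blk$states$opinion, ref$opinion, tolerance = 1e-12)
  expect_identical(blk$states$frozen, ref$frozen)
})

test_that("run_simulation scheduling, determinism and state invariants", {
  g <- 50L
  p <- small_params(max_steps = 2L * g)
  res <- run_simulation(p)
  if (!res$converged) {
    expect_identical(res$n_rewirings, 2L) # exactly 2 rewiring phases
  }
  res2 <- run_simulation(p)
  expect_identical(res$states$opinion, res2$states$opinion)
  expect_identical(res$net$adj, res2$net$adj)
  expect_identical(res$records, res2$records)

  # boundedness and freeze permanence along a longer run
  p3 <- small_params(field = 0.5, max_steps = 1200L)
  res3 <- run_simulation(p3)
  expect_true(all(abs(res3$states$opinion) <= 1))
  expect_true(all(diff(res3$records$undecided_fraction) <= 1e-12))
})

test_that("zero-field trajectories mirror under opinion negation", {
  p <- small_params(field = 0, max_steps = 300L)
  sys <- init_system(p)
  mirrored <- list(net = sys$net,
                   states = agent_states(-sys$states$opinion,
                                         sys$states$attitude))
  a <- run_simulation(p, init = sys)
  b <- run_simulation(p, init = mirrored)
  expect_equal(b$states$opinion, -a$states$opinion, tolerance = 1e-12)
  expect_identical(b$states$frozen, a$states$frozen)
  expect_identical(b$net$adj, a$net$adj)
})
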