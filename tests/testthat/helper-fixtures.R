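# shared fixtures: small, fast parameter sets and hand-built graphs

small_params <- function(...) {
  args <- utils::modifyList(
    list(n_agents = 60L, mean_degree = 5, transactions_per_rewiring = 50L,
         step_size = 0.01, max_steps = 1500L, seed = 42L),
    list(...))
  do.call(model_params, args)
}

# path graph 1-2-3-...-n
path_net <- function(n) {
  social_network(n, cbind(seq_len(n - 1), seq_len(n - 1) + 1L))
}

# star with centre 1
star_net <- function(n) {
  social_network(n, cbind(1L, 2:n))
}

complete_net <- function(n) {
  social_network(n, t(utils::combn(n, 2)))
}

states_of <- function(opinion, attitude = rep(0, length(opinion)),
                      frozen = rep(FALSE, length(opinion))) {
  agent_states(opinion, attitude, frozen)
}

# final summary row of a run
final_record <- function(res) res$records[nrow(res$records), ]
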