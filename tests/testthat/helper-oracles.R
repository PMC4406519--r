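# Independent oracles used across the suite. Both enumerate probability
# tables directly and share no code with the package's inference paths.

# --- naive-Bayes toy problems -------------------------------------------

# A randomized two-class problem over `n_factors` discrete factors whose
# joint distribution satisfies class-conditional independence by
# construction: P(C, f1..fn) = P(C) * prod_k P(fk | C).
random_nb_toy <- function(seed, n_factors = 3, n_levels = 3) {
  set.seed(seed)
  p_yes <- runif(1, 0.1, 0.9)
  conditionals <- lapply(seq_len(n_factors), function(k) {
    yes <- runif(n_levels, 0.05, 1)
    no <- runif(n_levels, 0.05, 1)
    list(yes = yes / sum(yes), no = no / sum(no))
  })
  observed <- sapply(seq_len(n_factors), function(k) sample.int(n_levels, 1))
  list(
    p_yes = p_yes, conditionals = conditionals, observed = observed,
    n_factors = n_factors, n_levels = n_levels
  )
}

# Exact posterior P(C = yes | observed levels) by brute-force summation
# over every cell of the fully enumerated joint table.
nb_brute_posterior <- function(toy) {
  grid <- expand.grid(c(
    lapply(seq_len(toy$n_factors), function(k) seq_len(toy$n_levels)),
    list(class = c("yes", "no"))
  ), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  w <- ifelse(grid$class == "yes", toy$p_yes, 1 - toy$p_yes)
  for (k in seq_len(toy$n_factors)) {
    pk <- toy$conditionals[[k]]
    w <- w * ifelse(grid$class == "yes",
      pk$yes[grid[[k]]], pk$no[grid[[k]]]
    )
  }
  match_obs <- Reduce(`&`, lapply(
    seq_len(toy$n_factors),
    function(k) grid[[k]] == toy$observed[k]
  ))
  sum(w[match_obs & grid$class == "yes"]) / sum(w[match_obs])
}

# Per-factor marginal conditionals q_k = P(C = yes | f_k = observed level),
# the quantities the package's 1-1 curves stand for.
nb_toy_q <- function(toy) {
  sapply(seq_len(toy$n_factors), function(k) {
    pk <- toy$conditionals[[k]]
    v <- toy$observed[k]
    pk$yes[v] * toy$p_yes / (pk$yes[v] * toy$p_yes + pk$no[v] * (1 - toy$p_yes))
  })
}

# Constant curves delivering exactly those q_k as risk percentages.
nb_toy_models <- function(toy) {
  q <- nb_toy_q(toy)
  stats::setNames(
    lapply(q, function(qk) make_curve("linear", c(100 * qk, 0))),
    paste0("f", seq_along(q))
  )
}

# --- Bayesian-network brute force ---------------------------------------

# Full-joint enumeration over ALL nodes of a compiled network, conditioned
# on the observed factors; independent of infer()'s ancestor-set algorithm.
bn_brute_posterior <- function(network, observations = numeric()) {
  spec <- network$spec
  kinds <- vapply(spec$nodes, `[[`, character(1), "kind")
  all_nodes <- names(spec$nodes)
  state_sets <- lapply(stats::setNames(all_nodes, all_nodes), function(v) {
    if (kinds[[v]] == "factor") spec$schemes[[v]]$bins else c("yes", "no")
  })
  joint <- expand.grid(state_sets, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  w <- rep(1, nrow(joint))
  for (v in all_nodes) {
    if (kinds[[v]] == "factor") {
      w <- w * network$root_priors[[v]][joint[[v]]]
    } else {
      cpt <- as.data.frame(network$cpts[[v]])
      key_cols <- setdiff(names(cpt), "p_yes")
      lookup <- stats::setNames(
        cpt$p_yes, do.call(paste, c(cpt[key_cols], sep = "|"))
      )
      p <- unname(lookup[do.call(paste, c(joint[key_cols], sep = "|"))])
      w <- w * ifelse(joint[[v]] == "yes", p, 1 - p)
    }
  }
  if (length(observations)) {
    for (f in names(observations)) {
      state <- names(discretize_value(observations[[f]], spec$schemes[[f]]))
      keep <- joint[[f]] == state
      joint <- joint[keep, , drop = FALSE]
      w <- w[keep]
    }
  }
  comps <- all_nodes[kinds == "complication"]
  vapply(stats::setNames(comps, comps), function(cn) {
    sum(w[joint[[cn]] == "yes"]) / sum(w)
  }, numeric(1))
}

# random root-state marginals for a list of schemes
random_marginals <- function(schemes) {
  purrr::map_dfr(schemes, function(sch) {
    p <- runif(length(sch$bins), 0.2, 1)
    tibble::tibble(factor = sch$factor_name, bin = sch$bins, p = p / sum(p))
  })
}

# Small test networks (compiled with seed-dependent marginals):
# two factors feeding one complication
toy_net_fork <- function(seed) {
  set.seed(seed)
  schemes <- list(
    A = disc_scheme("A", c(0, 1, 2, 3)),
    B = disc_scheme("B", c(0, 10, 20))
  )
  spec <- network_spec(
    list(
      node_spec("A", "factor"), node_spec("B", "factor"),
      node_spec("C", "complication", parents = c("A", "B"))
    ),
    schemes
  )
  compile_network(
    spec,
    models = list(C = list(
      A = make_curve("linear", c(10, 8)),
      B = make_curve("linear", c(5, 1.5))
    )),
    priors = c(C = runif(1, 0.1, 0.6)),
    marginals = random_marginals(schemes)
  )
}

# factor -> complication -> complication chain (C2 sees F and C1)
toy_net_chain <- function(seed) {
  set.seed(seed)
  schemes <- list(F1 = disc_scheme("F1", c(0, 2, 4, 6)))
  spec <- network_spec(
    list(
      node_spec("F1", "factor"),
      node_spec("C1", "complication", parents = "F1"),
      node_spec("C2", "complication",
        parents = c("F1", "C1"),
        parent_value_map = list(C1 = c(yes = 5, no = 1))
      )
    ),
    schemes
  )
  compile_network(
    spec,
    models = list(
      C1 = list(F1 = make_curve("linear", c(8, 6))),
      C2 = list(
        F1 = make_curve("linear", c(12, 4)),
        C1 = make_curve("linear", c(10, 7))
      )
    ),
    priors = c(C1 = runif(1, 0.1, 0.5), C2 = runif(1, 0.1, 0.5)),
    marginals = random_marginals(schemes)
  )
}

# diamond: two complications sharing both factor parents, the second also
# depending on the first (the case where marginal mixing would be wrong)
toy_net_diamond <- function(seed) {
  set.seed(seed)
  schemes <- list(
    F1 = disc_scheme("F1", c(0, 1, 2)),
    F2 = disc_scheme("F2", c(0, 5, 10, 15))
  )
  spec <- network_spec(
    list(
      node_spec("F1", "factor"), node_spec("F2", "factor"),
      node_spec("C1", "complication", parents = c("F1", "F2")),
      node_spec("C2", "complication",
        parents = c("F1", "F2", "C1"),
        parent_value_map = list(C1 = c(yes = 12, no = 2))
      )
    ),
    schemes
  )
  compile_network(
    spec,
    models = list(
      C1 = list(
        F1 = make_curve("linear", c(15, 10)),
        F2 = make_curve("linear", c(8, 2))
      ),
      C2 = list(
        F1 = make_curve("linear", c(20, 12)),
        F2 = make_curve("linear", c(10, 3)),
        C1 = make_curve("linear", c(6, 3))
      )
    ),
    priors = c(C1 = runif(1, 0.15, 0.5), C2 = runif(1, 0.15, 0.5)),
    marginals = random_marginals(schemes)
  )
}
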