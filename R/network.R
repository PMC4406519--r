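#' Discretization scheme for a continuous risk factor
#'
#' Continuous factors enter the network as discrete states defined by
#' half-open, left-open right-closed bins `]lo, hi]` (so a value equal to an
#' edge belongs to the bin below it). Each bin carries a representative
#' value — the point at which the 1-1 dose-response curves are evaluated
#' when the bin stands for its whole range — defaulting to the midpoint.
#' Open-ended top bins have no midpoint and require an explicit
#' representative.
#'
#' @param factor_name Factor the scheme discretizes.
#' @param edges Strictly increasing numeric bin edges (length = bins + 1);
#'   the last edge may be `Inf`.
#' @param representatives Optional numeric vector, one value per bin, each
#'   inside its bin.
#' @return A `disc_scheme` with `bins` (labels like `"]7,8]"`), `edges` and
#'   `representatives`.
#' @examples
#' disc_scheme("HbA1c", c(5, 6, 7, 8, 9, 10, 12, 14))
#' @export
disc_scheme <- function(factor_name, edges, representatives = NULL) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    rlang::abort("`edges` must be strictly increasing with at least 2 values.")
  }
  n_bins <- length(edges) - 1L
  if (is.null(representatives)) {
    if (!all(is.finite(edges))) {
      rlang::abort("Open-ended bins need explicit `representatives`.")
    }
    representatives <- (edges[-length(edges)] + edges[-1]) / 2
  }
  if (length(representatives) != n_bins) {
    rlang::abort("Need one representative value per bin.")
  }
  inside <- representatives > edges[-length(edges)] & representatives <= edges[-1]
  if (!all(inside)) {
    rlang::abort("Each representative value must lie inside its bin.")
  }
  structure(
    list(
      factor_name = factor_name,
      edges = edges,
      bins = sprintf("]%g,%g]", edges[-length(edges)], edges[-1]),
      representatives = as.numeric(representatives)
    ),
    class = "disc_scheme"
  )
}

#' Assign a value to its half-open bin
#'
#' Returns the unique bin with `lo < value <= hi`; values at a shared edge
#' fall in the lower bin (right-closed), values at or below the bottom edge
#' or above the top edge are rejected naming the covered range.
#'
#' @param value Numeric values to discretize (vectorized).
#' @param scheme A [disc_scheme()].
#' @return Integer bin indices with the bin labels as names.
#' @examples
#' s <- disc_scheme("HbA1c", c(7, 8, 9))
#' discretize_value(c(7.8, 8, 8.0001), s) # bins ]7,8], ]7,8], ]8,9]
#' @export
discretize_value <- function(value, scheme) {
  idx <- vapply(value, function(v) sum(v > scheme$edges), integer(1))
  bad <- idx < 1L | idx > length(scheme$bins) | !is.finite(value)
  if (any(bad)) {
    rlang::abort(sprintf(
      "Value(s) %s outside the covered range ]%g, %g] for factor '%s'.",
      toString(value[bad]), scheme$edges[1],
      scheme$edges[length(scheme$edges)], scheme$factor_name
    ))
  }
  stats::setNames(idx, scheme$bins[idx])
}

#' Declare a network node
#'
#' Factor nodes are roots (no parents, no CPT) observed in the patient;
#' complication nodes have parents and a conditional probability table with
#' states `yes`/`no`. A complication may itself be the parent of another
#' complication (e.g. albuminuria stages feeding retinopathy); such an edge
#' is quantified through `parent_value_map`, which maps the parent's
#' `yes`/`no` states onto representative values of an underlying measured
#' factor so an ordinary dose-response curve can supply the conditional.
#'
#' @param name Node name.
#' @param kind `"factor"` or `"complication"`.
#' @param parents Character vector of parent node names (complications only).
#' @param parent_value_map For complication-valued parents of this node: a
#'   named list, `parent name -> c(yes = value, no = value)`.
#' @return A `node_spec`.
#' @export
node_spec <- function(name, kind = c("factor", "complication"),
                      parents = character(), parent_value_map = list()) {
  kind <- match.arg(kind)
  if (kind == "factor" && length(parents) > 0L) {
    rlang::abort("Factor nodes are roots and cannot have parents.")
  }
  structure(
    list(
      name = name, kind = kind, parents = parents,
      parent_value_map = parent_value_map
    ),
    class = "node_spec"
  )
}

#' Assemble nodes and schemes into a network specification
#'
#' Validates that parent references resolve, that every factor node has a
#' discretization scheme, that complication-valued parents carry a value
#' map, and that the directed graph is acyclic.
#'
#' @param nodes List of [node_spec()] objects.
#' @param schemes Named list of [disc_scheme()] objects, keyed by factor
#'   node name.
#' @return A `network_spec` with nodes in topological order.
#' @export
network_spec <- function(nodes, schemes) {
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  kinds <- vapply(nodes, `[[`, character(1), "kind")
  for (nd in nodes) {
    unknown <- setdiff(nd$parents, names(nodes))
    if (length(unknown)) {
      rlang::abort(sprintf(
        "Node '%s' references unknown parent(s): %s.", nd$name, toString(unknown)
      ))
    }
    comp_parents <- nd$parents[kinds[nd$parents] == "complication"]
    unmapped <- setdiff(comp_parents, names(nd$parent_value_map))
    if (length(unmapped)) {
      rlang::abort(sprintf(
        "Complication parent(s) %s of node '%s' need a `parent_value_map`.",
        toString(unmapped), nd$name
      ))
    }
  }
  missing_schemes <- setdiff(names(nodes)[kinds == "factor"], names(schemes))
  if (length(missing_schemes)) {
    rlang::abort(paste0(
      "Missing discretization scheme(s) for factor(s): ", toString(missing_schemes)
    ))
  }
  # Kahn's algorithm: detects cycles and yields a topological order
  remaining <- names(nodes)
  ordered <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(
      remaining,
      function(nm) all(nodes[[nm]]$parents %in% ordered), logical(1)
    )]
    if (!length(ready)) {
      rlang::abort(paste0("Cyclic network specification involving: ", toString(remaining)))
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(
    list(nodes = nodes[ordered], schemes = schemes),
    class = "network_spec"
  )
}

# state labels and the factor value each state stands for, per parent
parent_states <- function(node, spec) {
  lapply(stats::setNames(node$parents, node$parents), function(p) {
    if (spec$nodes[[p]]$kind == "factor") {
      sch <- spec$schemes[[p]]
      list(states = sch$bins, values = sch$representatives)
    } else {
      map <- node$parent_value_map[[p]]
      list(states = c("yes", "no"), values = unname(map[c("yes", "no")]))
    }
  })
}

#' Build the conditional probability table of a complication node
#'
#' Enumerates the Cartesian product of the parents' state sets; for each
#' combination the per-factor curves are evaluated at the states'
#' representative values and combined by [combine_posterior()]. The row
#' count is the product of the parents' state counts.
#'
#' @param node A complication [node_spec()].
#' @param spec The [network_spec()] the node belongs to.
#' @param models Named list of `fitted_curve` objects, keyed by parent name,
#'   giving P(this complication | parent) on the parent's measured scale.
#' @param p_yes Prior probability of the complication.
#' @return A `cpt` tibble: one column per parent holding state labels, plus
#'   `p_yes`.
#' @export
build_cpt <- function(node, spec, models, p_yes) {
  if (node$kind != "complication") {
    rlang::abort("Only complication nodes carry a CPT.")
  }
  missing_models <- setdiff(node$parents, names(models))
  if (length(missing_models)) {
    rlang::abort(sprintf(
      "Missing 1-1 model(s) for parent(s) %s of node '%s'.",
      toString(missing_models), node$name
    ))
  }
  ps <- parent_states(node, spec)
  grid <- expand.grid(
    lapply(ps, function(s) seq_along(s$states)),
    KEEP.OUT.ATTRS = FALSE
  )
  rows <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    obs <- vapply(
      node$parents,
      function(p) ps[[p]]$values[grid[i, p]], numeric(1)
    )
    suppressWarnings(
      combine_posterior(node$name, obs, models, p_yes)
    )
  })
  out <- tibble::as_tibble(purrr::imap(ps, function(s, p) s$states[grid[[p]]]))
  out$p_yes <- rows
  structure(out,
    class = c("cpt", class(tibble::tibble())),
    node_name = node$name
  )
}

#' Compile a full network
#'
#' Builds every complication node's CPT (in topological order) and attaches
#' the root-state distributions of the factors, producing an object ready
#' for exact inference with [infer()].
#'
#' @param spec A [network_spec()].
#' @param models Nested named list: `models[[complication]][[parent]]` is the
#'   `fitted_curve` for that edge.
#' @param priors Named numeric vector of per-complication prior
#'   probabilities `p_yes`, or a tibble with columns `complication`, `p_yes`.
#' @param marginals Root-state distributions: a tibble with columns
#'   `factor`, `bin`, `p` (per-factor probabilities summing to 1), as
#'   produced by [estimate_priors()].
#' @return A `compiled_network`.
#' @export
compile_network <- function(spec, models, priors, marginals) {
  if (is.data.frame(priors)) {
    priors <- stats::setNames(priors$p_yes, priors$complication)
  }
  kinds <- vapply(spec$nodes, `[[`, character(1), "kind")
  comps <- names(spec$nodes)[kinds == "complication"]
  factors <- names(spec$nodes)[kinds == "factor"]
  missing_priors <- setdiff(comps, names(priors))
  if (length(missing_priors)) {
    rlang::abort(paste0("Missing prior p_yes for: ", toString(missing_priors)))
  }
  root_priors <- lapply(stats::setNames(factors, factors), function(f) {
    sch <- spec$schemes[[f]]
    m <- marginals[marginals$factor == f, ]
    p <- m$p[match(sch$bins, m$bin)]
    if (any(is.na(p))) {
      rlang::abort(sprintf("Marginals for factor '%s' do not cover all bins.", f))
    }
    if (abs(sum(p) - 1) > 1e-9) {
      rlang::abort(sprintf("Marginal probabilities for '%s' must sum to 1.", f))
    }
    stats::setNames(p, sch$bins)
  })
  cpts <- lapply(stats::setNames(comps, comps), function(cn) {
    build_cpt(spec$nodes[[cn]], spec, models[[cn]], priors[[cn]])
  })
  structure(
    list(
      spec = spec, cpts = cpts, root_priors = root_priors,
      priors = priors[comps]
    ),
    class = "compiled_network"
  )
}

#' @export
print.compiled_network <- function(x, ...) {
  kinds <- vapply(x$spec$nodes, `[[`, character(1), "kind")
  cat(sprintf(
    "<compiled_network> %d factor node(s), %d complication node(s)\n",
    sum(kinds == "factor"), sum(kinds == "complication")
  ))
  for (cn in names(x$cpts)) {
    cat(sprintf(
      "  %s | %s (%d CPT rows)\n", cn,
      paste(x$spec$nodes[[cn]]$parents, collapse = ", "), nrow(x$cpts[[cn]])
    ))
  }
  invisible(x)
}

# all ancestors of a node (excluding the node itself)
node_ancestors <- function(spec, name) {
  out <- character()
  frontier <- spec$nodes[[name]]$parents
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(frontier, function(p) spec$nodes[[p]]$parents))),
      out
    )
  }
  out
}

# CPT probability of `state` for each row of an assignment data frame
cpt_prob <- function(cpt, node, assign_df, state_col) {
  key_cols <- setdiff(names(cpt), "p_yes")
  key <- do.call(paste, c(cpt[key_cols], sep = "\r"))
  lookup <- stats::setNames(cpt$p_yes, key)
  q <- do.call(paste, c(assign_df[key_cols], sep = "\r"))
  p <- unname(lookup[q])
  ifelse(assign_df[[state_col]] == "yes", p, 1 - p)
}

#' Query a compiled network by exact enumeration
#'
#' Computes, for every complication node, the probability of the `yes`
#' state given the observed factors. Observed factors are fixed to their
#' discretized states; unobserved factor ancestors are summed over their
#' root-state distributions and complication-valued ancestors over their
#' CPTs — a brute-force sum over the joint distribution of the query node's
#' ancestor set, which is exact on a discrete DAG.
#'
#' @param network A [compile_network()] result.
#' @param observations Observed factor values: named numeric vector or a
#'   data frame with columns `factor` and `value`. Unobserved factors are
#'   permitted; `NA` values count as unobserved.
#' @return A tibble with columns `complication` and `probability`.
#' @examples
#' # see vignette("risk-advisor") for a complete compiled example
#' @export
infer <- function(network, observations = numeric()) {
  spec <- network$spec
  if (is.data.frame(observations)) {
    observations <- stats::setNames(observations$value, observations$factor)
  }
  observations <- observations[!is.na(observations)]
  kinds <- vapply(spec$nodes, `[[`, character(1), "kind")
  unknown <- setdiff(names(observations), names(spec$nodes)[kinds == "factor"])
  if (length(unknown)) {
    rlang::abort(paste0(
      "Unknown factor(s): ", toString(unknown),
      ". Known factors: ", toString(names(spec$nodes)[kinds == "factor"])
    ))
  }
  obs_state <- purrr::imap_chr(
    as.list(observations),
    function(v, f) names(discretize_value(v, spec$schemes[[f]]))
  )
  comps <- names(spec$nodes)[kinds == "complication"]
  out <- purrr::map_dbl(stats::setNames(comps, comps), function(target) {
    vars <- c(node_ancestors(spec, target), target)
    state_sets <- lapply(stats::setNames(vars, vars), function(v) {
      if (kinds[[v]] == "factor") {
        if (v %in% names(obs_state)) obs_state[[v]] else spec$schemes[[v]]$bins
      } else {
        c("yes", "no")
      }
    })
    joint <- expand.grid(state_sets,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    w <- rep(1, nrow(joint))
    for (v in vars) {
      if (kinds[[v]] == "factor") {
        if (!v %in% names(obs_state)) {
          w <- w * network$root_priors[[v]][joint[[v]]]
        }
      } else {
        w <- w * cpt_prob(network$cpts[[v]], v, joint, v)
      }
    }
    sum(w[joint[[target]] == "yes"]) / sum(w)
  })
  tibble::tibble(complication = comps, probability = unname(out))
}

#' Export a CPT in the published table layout
#'
#' One column per parent holding the state ranges, plus a final
#' `risk_percent` column (the `yes` probability as a percentage).
#'
#' @param cpt A [build_cpt()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
cpt_to_csv <- function(cpt, path) {
  out <- tibble::as_tibble(cpt)
  out$risk_percent <- 100 * out$p_yes
  out$p_yes <- NULL
  readr::write_csv(out, path)
  invisible(path)
}

#' Serialize a compiled network to JSON and back
#'
#' Stores nodes, discretization schemes, CPTs, priors and root marginals;
#' the restored object answers [infer()] queries identically.
#'
#' @param network A `compiled_network`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `network_to_json()`: the path (or JSON string) invisibly;
#'   `network_from_json()`: a `compiled_network`.
#' @export
network_to_json <- function(network, path = NULL) {
  payload <- list(
    nodes = lapply(network$spec$nodes, function(nd) {
      list(
        name = nd$name, kind = nd$kind, parents = I(nd$parents),
        parent_value_map = lapply(nd$parent_value_map, as.list)
      )
    }),
    schemes = lapply(network$spec$schemes, function(s) {
      list(
        factor_name = s$factor_name, edges = s$edges,
        representatives = s$representatives
      )
    }),
    cpts = lapply(network$cpts, function(cpt) as.data.frame(cpt)),
    priors = as.list(network$priors),
    root_priors = lapply(network$root_priors, as.list)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) {
    return(invisible(as.character(json)))
  }
  writeLines(json, path)
  invisible(path)
}

#' @rdname network_to_json
#' @param json A path to a JSON file or a JSON string.
#' @export
network_from_json <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  nodes <- lapply(p$nodes, function(nd) {
    node_spec(
      nd$name, nd$kind,
      parents = as.character(unlist(nd$parents)),
      parent_value_map = lapply(nd$parent_value_map, unlist)
    )
  })
  schemes <- lapply(p$schemes, function(s) {
    disc_scheme(s$factor_name, s$edges, s$representatives)
  })
  spec <- network_spec(unname(nodes), schemes)
  cpts <- lapply(stats::setNames(names(p$cpts), names(p$cpts)), function(nm) {
    structure(tibble::as_tibble(p$cpts[[nm]]),
      class = c("cpt", class(tibble::tibble())), node_name = nm
    )
  })
  structure(
    list(
      spec = spec, cpts = cpts,
      root_priors = lapply(p$root_priors, unlist),
      priors = unlist(p$priors)
    ),
    class = "compiled_network"
  )
}
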