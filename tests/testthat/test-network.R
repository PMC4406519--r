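test_that("values fall in half-open, right-closed bins", {
  s <- disc_scheme("HbA1c", c(7, 8, 9))
  expect_identical(names(discretize_value(7.8, s)), "]7,8]")
  expect_identical(names(discretize_value(8, s)), "]7,8]")
  expect_identical(names(discretize_value(8.0001, s)), "]8,9]")
  expect_identical(names(discretize_value(9, s)), "]8,9]")
  expect_error(discretize_value(7, s), "\\]7, 9\\]") # bottom edge is excluded
  expect_error(discretize_value(9.5, s), "covered range")
})

test_that("schemes validate representatives and open-ended bins", {
  s <- disc_scheme("x", c(0, 2, 4))
  expect_equal(s$representatives, c(1, 3))
  expect_error(disc_scheme("x", c(0, 2, 4), c(1, 5)), "inside its bin")
  expect_error(disc_scheme("x", c(0, 2, Inf)), "explicit")
  open_top <- disc_scheme("x", c(0, 2, Inf), c(1, 10))
  expect_identical(open_top$bins[2], "]2,Inf]")
  expect_error(disc_scheme("x", c(3, 2)), "strictly increasing")
})

test_that("CPT rows enumerate the Cartesian product of parent states", {
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
  cpt <- build_cpt(spec$nodes$C, spec,
    models = list(
      A = make_curve("linear", c(10, 8)),
      B = make_curve("linear", c(5, 1.5))
    ),
    p_yes = 0.3
  )
  expect_equal(nrow(cpt), 6L)
  expect_equal(nrow(unique(cpt[c("A", "B")])), 6L)
  expect_true(all(cpt$p_yes >= 0 & cpt$p_yes <= 1))
})

test_that("a single-parent CPT is the clipped 1-1 prediction at each representative", {
  schemes <- list(A = disc_scheme("A", c(0, 1, 2, 3)))
  spec <- network_spec(
    list(node_spec("A", "factor"), node_spec("C", "complication", parents = "A")),
    schemes
  )
  curve <- make_curve("linear", c(10, 8))
  cpt <- build_cpt(spec$nodes$C, spec, models = list(A = curve), p_yes = 0.3)
  expect_equal(
    cpt$p_yes,
    predict(curve, schemes$A$representatives) / 100,
    tolerance = 1e-12
  )
})

test_that("constant conditionals equal to the prior give a flat CPT", {
  schemes <- list(
    A = disc_scheme("A", c(0, 1, 2)),
    B = disc_scheme("B", c(0, 1, 2, 3))
  )
  spec <- network_spec(
    list(
      node_spec("A", "factor"), node_spec("B", "factor"),
      node_spec("C", "complication", parents = c("A", "B"))
    ),
    schemes
  )
  cpt <- build_cpt(spec$nodes$C, spec,
    models = list(
      A = make_curve("linear", c(30, 0)),
      B = make_curve("linear", c(30, 0))
    ),
    p_yes = 0.3
  )
  expect_equal(cpt$p_yes, rep(0.3, 6), tolerance = 1e-12)
})

test_that("missing edge models and cyclic specs are rejected", {
  schemes <- list(A = disc_scheme("A", c(0, 1, 2)))
  spec <- network_spec(
    list(node_spec("A", "factor"), node_spec("C", "complication", parents = "A")),
    schemes
  )
  expect_error(build_cpt(spec$nodes$C, spec, models = list(), p_yes = 0.3), "Missing 1-1")
  expect_error(
    network_spec(
      list(
        node_spec("C1", "complication",
          parents = "C2",
          parent_value_map = list(C2 = c(yes = 1, no = 0.1))
        ),
        node_spec("C2", "complication",
          parents = "C1",
          parent_value_map = list(C1 = c(yes = 1, no = 0.1))
        )
      ),
      schemes = list()
    ),
    "Cyclic"
  )
})

test_that("inference equals the matching CPT row when every parent is observed", {
  net <- toy_net_fork(1)
  obs <- c(A = 1.4, B = 13) # bins ]1,2] and ]10,20]
  res <- infer(net, obs)
  cpt <- net$cpts$C
  row <- cpt[cpt$A == "]1,2]" & cpt$B == "]10,20]", ]
  expect_equal(res$probability, row$p_yes, tolerance = 1e-14)
})

test_that("inference with no observations is the prior-weighted CPT mixture", {
  for (seed in 1:10) {
    net <- toy_net_fork(seed)
    res <- infer(net)
    oracle <- bn_brute_posterior(net)
    expect_equal(res$probability, unname(oracle["C"]), tolerance = 1e-13)
  }
})

test_that("exact enumeration matches full-joint brute force on chain and diamond nets", {
  for (seed in 1:10) {
    for (builder in list(toy_net_chain, toy_net_diamond)) {
      net <- builder(seed)
      # unobserved
      res <- infer(net)
      oracle <- bn_brute_posterior(net)
      expect_equal(
        stats::setNames(res$probability, res$complication),
        oracle,
        tolerance = 1e-13
      )
      # partially observed
      f <- names(net$spec$schemes)[1]
      sch <- net$spec$schemes[[f]]
      obs <- stats::setNames(sch$representatives[1], f)
      res_o <- infer(net, obs)
      oracle_o <- bn_brute_posterior(net, obs)
      expect_equal(
        stats::setNames(res_o$probability, res_o$complication),
        oracle_o,
        tolerance = 1e-13
      )
    }
  }
})

test_that("conditioning consistency: observing F equals the brute-force conditional", {
  net <- toy_net_diamond(3)
  sch <- net$spec$schemes$F2
  for (b in seq_along(sch$bins)) {
    obs <- c(F2 = sch$representatives[b])
    res <- infer(net, obs)
    oracle <- bn_brute_posterior(net, obs)
    expect_equal(
      stats::setNames(res$probability, res$complication),
      oracle,
      tolerance = 1e-13
    )
  }
})

test_that("unknown factors are rejected listing the known ones", {
  net <- toy_net_fork(2)
  expect_error(infer(net, c(Q = 1)), "Known factors")
})

test_that("the default clinical network compiles and scores the worked patient", {
  net <- default_compiled_network(n_patients = 2000, seed = 5)
  expect_equal(nrow(net$cpts$micro), 7 * 5 * 5)
  expect_equal(nrow(net$cpts$DR), 7 * 5 * 4 * 2 * 2)
  patient <- c(HbA1c = 7.8, AER = 21, Duration = 8)
  res1 <- infer(net, patient)
  res2 <- infer(net, patient)
  expect_identical(res1, res2)
  expect_equal(sort(res1$complication), sort(c("micro", "macro", "DR", "NPDR", "PDR")))
  expect_true(all(res1$probability > 0 & res1$probability < 1))
})

test_that("compiled networks survive a JSON round trip", {
  net <- toy_net_diamond(4)
  path <- withr::local_tempfile(fileext = ".json")
  network_to_json(net, path)
  back <- network_from_json(path)
  obs <- c(F1 = 0.5)
  expect_equal(
    infer(back, obs)$probability,
    infer(net, obs)$probability,
    tolerance = 1e-14
  )
})

test_that("CPT export uses the published layout", {
  net <- toy_net_fork(5)
  path <- withr::local_tempfile(fileext = ".csv")
  cpt_to_csv(net$cpts$C, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(names(out), c("A", "B", "risk_percent"))
  expect_equal(out$risk_percent, 100 * net$cpts$C$p_yes)
})
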