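test_that("built-in presets carry the published clamp sets exactly", {
  ps <- builtin_presets()
  expect_length(ps, 10)

  expect_equal(ps$lit_control_dynamic$clamps,
               c(a5b1 = 1, avb3 = 1, TRPV4 = 1))
  expect_equal(ps$lit_TNF_unloaded$clamps,
               c(a5b1 = 0.5, avb3 = 0.5, TRPV4 = 0.5, TNF = 1))
  expect_equal(ps$exp_TNF_unloaded$clamps,
               c(a5b1 = 0.5, TRPV4 = 0.25, Actin = 0, IL4 = 0.2585, TNF = 1))
  expect_equal(ps$exp_control_unloaded$clamps,
               c(a5b1 = 0.5, TRPV4 = 0.5, Actin = 0, IL4 = 0.2585))

  # experiment-derived dynamic rows clamp identically to unloaded
  expect_equal(ps$exp_control_dynamic$clamps, ps$exp_control_unloaded$clamps)
  expect_equal(ps$exp_TNF_dynamic$clamps, ps$exp_TNF_unloaded$clamps)

  # exact decimal preservation through config serialization
  json <- jsonlite::toJSON(lapply(ps, function(p) {
    p <- unclass(p)
    p$clamps <- as.list(p$clamps)
    p
  }), auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_identical(back$exp_TNF_unloaded$clamps[["IL4"]], 0.2585)
  expect_identical(back$exp_TNF_unloaded$clamps[["TRPV4"]], 0.25)
  expect_identical(back$lit_control_unloaded$clamps[["a5b1"]], 0.5)
})

test_that("steady states classify by the inclusive readout threshold", {
  rule <- classification_rule()
  expect_equal(classify_state(c(ACAN = 0.5), rule), "pro-anabolic")
  expect_equal(classify_state(c(ACAN = 0.49), rule), "pro-catabolic")
  expect_equal(classify_state(c(ACAN = 1.0), rule), "pro-anabolic")
  expect_error(classify_state(c(MMP13 = 1), rule), "readout")
  expect_error(classification_rule(threshold = 0))
})

test_that("ensembles are seed-deterministic with conserved label fractions", {
  bm <- make_benchmark_network()
  e1 <- run_ensemble(bm$network, builtin_presets()$lit_control_unloaded,
                     n = 100, seed = 5)
  e2 <- run_ensemble(bm$network, builtin_presets()$lit_control_unloaded,
                     n = 100, seed = 5)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$labels, e2$labels)
  expect_equal(e1$frac_anabolic + e1$frac_catabolic, 100)
  expect_true(all(e1$mean_activation >= 0 & e1$mean_activation <= 1))
})

test_that("clamping the inflammatory driver forces a catabolic state", {
  bm <- make_benchmark_network()
  ens <- run_ensemble(bm$network, bm$truth$forced_catabolic_clamp,
                      n = 50, seed = 9)
  expect_equal(ens$n_converged, 50)
  expect_equal(ens$frac_catabolic, 100)
})

test_that("a preset clamping a node the network lacks is a clear error", {
  net <- make_toy_network("toggle")$network
  expect_error(run_ensemble(net, builtin_presets()$exp_TNF_unloaded,
                            n = 5, seed = 1),
               "Actin")
})

test_that("bistable ensembles split between basins as a large MC predicts", {
  net <- make_toy_network("toggle")$network
  ens <- run_ensemble(net, NULL, n = 2000, seed = 11)
  expect_gt(ens$frac_anabolic, 0)
  expect_lt(ens$frac_anabolic, 100)
  mc <- run_ensemble(net, NULL, n = 10000, seed = 12)
  expect_lt(abs(ens$frac_anabolic - mc$frac_anabolic), 3)
})

test_that("condition deltas report signed changes with a division guard", {
  bm <- make_benchmark_network()
  e0 <- run_ensemble(bm$network, c(TNF = 0), n = 60, seed = 21)
  expect_equal(predict_condition_deltas(e0, e0)$delta,
               rep(0, nrow(bm$network$nodes)))

  e1 <- run_ensemble(bm$network, c(TNF = 1), n = 60, seed = 21)
  d <- predict_condition_deltas(e0, e1, nodes = c("ACAN", "NFKB"))
  expect_lt(d$delta[d$node == "ACAN"], 0)   # readout falls under TNF
  expect_gt(d$delta[d$node == "NFKB"], 0)   # inflammatory hub rises

  # meanA exactly 0 (clamped) -> relative change undefined, delta reported
  e0z <- run_ensemble(bm$network, c(TNF = 0, NFKB = 0), n = 20, seed = 22)
  dz <- predict_condition_deltas(e0z, e1, nodes = "NFKB")
  expect_gt(dz$delta, 0)
  expect_true(is.na(dz$rel_change_pct))
  expect_warning(predict_condition_deltas(e0, e1, nodes = c("ACAN", "ZZZ")),
                 "ZZZ")
})

test_that("bisection recovers a planted critical clamp and flags no crossing", {
  toy <- make_toy_network("switch", flip = 0.3)
  cc <- find_critical_clamp(toy$network, toy$truth$scan_node,
                            base_clamps = toy$truth$scan_clamps,
                            tol = 1e-4, seed = 31)
  expect_equal(as.numeric(cc), 0.3, tolerance = 1e-3)
  cc2 <- find_critical_clamp(toy$network, toy$truth$scan_node,
                             base_clamps = toy$truth$scan_clamps,
                             tol = 1e-4, seed = 31)
  expect_equal(as.numeric(cc), as.numeric(cc2), tolerance = 1e-4)

  # monotone network with no flip on the interval
  casc <- make_toy_network("cascade")$network
  expect_error(find_critical_clamp(casc, "X", base_clamps = NULL,
                                   interval = c(0, 0.4), seed = 1),
               "no crossing")
})

test_that("ensemble-mean readout is monotone in a clamp on an activating path", {
  net <- make_toy_network("cascade")$network
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(v) {
    run_ensemble(net, c(X = v), n = 20, seed = 41)$mean_activation[["ACAN"]]
  }, 0)
  expect_true(all(diff(means) >= -1e-9))
})
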