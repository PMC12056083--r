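make_tiny_panel <- function(mfi, blank = 120) {
  secretome_panel(
    measurements = data.frame(analyte = "IL-6", donor = 1,
                              condition = "control_unloaded", day = 7,
                              mfi = mfi),
    standards = data.frame(analyte = "IL-6",
                           concentration = c(1, 10, 100, 1000, 10000),
                           mfi = c(50, 200, 2000, 15000, 22000)),
    blanks = data.frame(analyte = "IL-6", mfi = blank),
    loq = data.frame(analyte = "IL-6", lloq = 1, uloq = 1000))
}

true_5pl <- list(A = 40, D = 22000, C = 55, B = 1.2, G = 0.95)
pl5_eval <- function(conc, p = true_5pl) {
  p$D + (p$A - p$D) / (1 + (conc / p$C)^p$B)^p$G
}

test_that("blank subtraction nets out background and floors at zero", {
  p <- subtract_blank(make_tiny_panel(500))
  expect_equal(p$measurements$mfi, 380)
  expect_false(p$measurements$floored)

  p2 <- subtract_blank(make_tiny_panel(100, blank = 150))
  expect_equal(p2$measurements$mfi, 0)
  expect_true(p2$measurements$floored)

  p3 <- subtract_blank(make_tiny_panel(120))   # all-blank panel
  expect_equal(p3$measurements$mfi, 0)

  p4 <- make_tiny_panel(500)
  p4$blanks <- data.frame(analyte = "OTHER", mfi = 1)
  expect_error(subtract_blank(p4), "IL-6")
})

test_that("5PL fitting recovers known parameters from clean standards", {
  conc <- exp(seq(log(0.5), log(3000), length.out = 8))
  cv <- fit_5pl(data.frame(concentration = conc, mfi = pl5_eval(conc)))
  expect_true(cv$converged)
  expect_false(cv$fallback_4pl)
  rel <- abs(coef(cv) - unlist(true_5pl)) / abs(unlist(true_5pl))
  expect_lt(max(rel), 0.01)

  # 3-point standards cannot support the full parameter count
  cv3 <- fit_5pl(data.frame(concentration = conc[c(1, 4, 8)],
                            mfi = pl5_eval(conc[c(1, 4, 8)])))
  expect_true(cv3$fallback_4pl)
})

test_that("noisy standards still localize the inflection (replicated study)", {
  conc <- rep(exp(seq(log(0.5), log(3000), length.out = 8)), 2)
  y <- pl5_eval(conc)
  set.seed(77)
  Cs <- replicate(20, {
    yn <- y * exp(stats::rnorm(length(y), 0, 0.02))
    fit_5pl(data.frame(concentration = conc, mfi = yn))$par$C
  })
  expect_lt(abs(stats::median(Cs) - true_5pl$C) / true_5pl$C, 0.05)
})

test_that("curve inversion round-trips and censors at the asymptotes", {
  conc <- exp(seq(log(0.5), log(3000), length.out = 8))
  cv <- fit_5pl(data.frame(concentration = conc, mfi = pl5_eval(conc)))

  y <- predict(cv, 42.7)
  iv <- invert_5pl(cv, y, lloq = 1, uloq = 1000)
  expect_equal(iv$conc, 42.7, tolerance = 1e-9)
  expect_equal(iv$censor, "none")

  low <- invert_5pl(cv, cv$par$A - 1, lloq = 1, uloq = 1000)
  expect_equal(low$conc, 1)
  expect_equal(low$censor, "lower")
  high <- invert_5pl(cv, cv$par$D + 1, lloq = 1, uloq = 1000)
  expect_equal(high$conc, 1000)
  expect_equal(high$censor, "upper")

  # monotonicity: increasing MFI never decreases reported concentration
  ys <- sort(c(cv$par$A - 5, seq(cv$par$A + 1, cv$par$D - 1,
                                 length.out = 50), cv$par$D + 5))
  cc <- invert_5pl(cv, ys, lloq = 0.01, uloq = 1e5)$conc
  expect_true(all(diff(cc) >= 0))
})

test_that("LOQ normalization pins the quantification window to [0,1]", {
  expect_equal(normalize_loq(10, 10, 1000), 0)
  expect_equal(normalize_loq(1000, 10, 1000), 1)
  expect_equal(normalize_loq(505, 10, 1000), 0.5)
  expect_equal(normalize_loq(5, 10, 1000), 0)      # clipped
  expect_equal(normalize_loq(2000, 10, 1000), 1)   # clipped
  expect_error(normalize_loq(5, 10, 10), "lloq")
  # log-scale option: geometric midpoint maps to 0.5
  expect_equal(normalize_loq(100, 10, 1000, log_scale = TRUE), 0.5)
})

test_that("reference subtraction is exact and bounded", {
  cal <- expand.grid(analyte = c("IL-6", "VEGF"), donor = 1:2,
                     condition = c("control_unloaded", "TNF_unloaded"),
                     day = c(7, 14), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  tnf <- cal$condition == "TNF_unloaded"
  # IL-6 rises 0.2 -> 0.9 under TNF; VEGF falls from 1 to 0
  cal$x <- ifelse(cal$analyte == "IL-6", ifelse(tnf, 0.9, 0.2),
                  ifelse(tnf, 0, 1))
  out <- aggregate_and_reference(cal)
  expect_s3_class(out, "calibrated_secretome")
  ref_rows <- out[out$condition == "control_unloaded", ]
  expect_true(all(ref_rows$x_ref == 0))
  expect_equal(out$x_ref[out$analyte == "IL-6" &
                           out$condition == "TNF_unloaded"], 0.7)
  expect_equal(out$x_ref[out$analyte == "VEGF" &
                           out$condition == "TNF_unloaded"], -1)
  expect_true(all(out$x_ref >= -1 & out$x_ref <= 1))

  # analyte with no reference condition is excluded with a warning
  cal2 <- rbind(cal, data.frame(analyte = "NGF", donor = 1,
                                condition = "TNF_unloaded", day = 7, x = 0.5))
  expect_warning(out2 <- aggregate_and_reference(cal2), "NGF")
  expect_false("NGF" %in% out2$analyte)
})

test_that("noiseless synthetic data round-trips the full calibration", {
  sec <- make_synthetic_secretome(seed = 5, n_analytes = 12,
                                  sigma_donor = 0, sigma_resid = 0)
  cal <- aggregate_and_reference(calibrate_panel(sec$panel))
  m <- merge(as.data.frame(cal), sec$truth$referenced,
             by = c("analyte", "condition"), suffixes = c("", ".true"))
  expect_equal(nrow(m), 12 * 4)
  expect_lt(max(abs(m$x - m$x.true)), 1e-6)
  expect_lt(max(abs(m$x_ref - m$x_ref.true)), 1e-6)
})

test_that("a planted TNF effect is recovered from noisy donors", {
  eff <- vapply(1:20, function(s) {
    sec <- make_synthetic_secretome(seed = 1000 + s, n_analytes = 12,
                                    sigma_donor = 0.05, sigma_resid = 0)
    cal <- aggregate_and_reference(calibrate_panel(sec$panel))
    cal$x_ref[cal$analyte == "IL-8" & cal$condition == "TNF_unloaded"]
  }, 0)
  expect_lt(abs(stats::median(eff) - 0.3), 0.05)
})
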