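test_that("equilibration reaches the repressor pool's closed form", {
  p <- reference_parameters()
  s <- equilibrate(p, sugar_condition(0, 0))
  expect_true(attr(s, "converged"))
  expect_equal(s[["Rtot"]], p[["aR"]] / p[["d"]], tolerance = 1e-5)
})

test_that("a fixed point is returned unchanged", {
  p <- reference_parameters()
  s <- equilibrate(p, sugar_condition(0, 0))
  s2 <- equilibrate(p, sugar_condition(0, 0), init = s)
  expect_equal(as.numeric(s2), as.numeric(s), tolerance = 1e-5)
})

test_that("equilibrate agrees with a fine fixed-step integrator", {
  p <- reference_parameters()
  conds <- list(c(0, 2), c(0, 0.25), c(0.0625, 0.5))
  for (cn in conds) {
    cond <- sugar_condition(cn[1], cn[2])
    got <- equilibrate(p, cond)
    want <- oracle_rk4(zero_state(), p, cn[1], cn[2])
    expect_equal(got[["G1"]], want[["G1"]], tolerance = 1e-4)
  }
})

test_that("ON/OFF initial conditions reflect the pre-equilibration protocol", {
  p <- reference_parameters()
  ii <- on_off_inits(p)
  expect_gt(ii$on[["G1"]], ii$off[["G1"]])
  ## without galactose pre-equilibration the two protocols coincide
  same <- on_off_inits(p, solver_config(on_init_gal = 0))
  expect_equal(unname(same$on[]), unname(same$off[]))
  ## gal80 deletion leaves no Gal80p in either state
  g80 <- on_off_inits(apply_knockout(p, "GAL80"))
  expect_equal(g80$on[["G80"]], 0, tolerance = 1e-8)
  expect_equal(g80$off[["G80"]], 0, tolerance = 1e-8)
})

test_that("modality classification applies the inclusive 5-fold rule", {
  expect_identical(classify_modality(5, 1, profile_half_max = 10), "bimodal")
  expect_identical(classify_modality(4.9, 1, profile_half_max = 2),
                   "unimodal_ON")
  expect_identical(classify_modality(0.4, 0.1, profile_half_max = 2),
                   "unimodal_OFF")
  ## a true-zero OFF state with any induced ON state is bimodal
  expect_identical(classify_modality(1e-3, 0, profile_half_max = 1),
                   "bimodal")
  expect_error(classify_modality(1, 2, 1), "g1_high >= g1_low")
})

test_that("the default grid is the 96-condition twofold design", {
  g <- sugar_grid()
  expect_length(g$glucose, 8)
  expect_length(g$galactose, 12)
  expect_equal(nrow(grid_conditions(g)), 96)
  expect_identical(g$glucose[1], 1)
  expect_identical(g$glucose[7], 0.015625)
  expect_identical(g$galactose[1], 4)
  expect_identical(g$galactose[11], 0.00390625)
  expect_identical(g$glucose[8], 0)
  expect_identical(g$galactose[12], 0)
  expect_equal(sum(default_growth_mask(g)), 4)
})

test_that("the simulated reference grid shows hysteresis and monotone repression", {
  prof <- simulate_grid(reference_parameters())
  expect_true(all(prof$g1_high >= prof$g1_low))
  expect_true(all(c("unimodal_OFF", "bimodal", "unimodal_ON") %in%
                    prof$modality[!prof$masked]))
  for (ga in unique(prof$galactose)) {
    sub <- prof[prof$galactose == ga & !prof$masked, ]
    sub <- sub[order(sub$glucose), ]
    expect_true(all(diff(sub$normalized_high) <= 0.02))
  }
  expect_equal(max(prof$normalized_high[!prof$masked]), 1)
})

test_that("a GAL1 deletion yields an all-zero profile with a warning", {
  p <- apply_knockout(reference_parameters(), "GAL1")
  expect_warning(prof <- simulate_grid(p, tiny_grid()), "All-zero")
  expect_true(all(prof$normalized_high == 0))
})

test_that("titration and dual-init modes find the same bimodal set", {
  p <- reference_parameters()
  g <- sugar_grid(glucose_levels = c(0.25, 0.0625, 0),
                  galactose_levels = c(2, 0.5, 0.125, 0.03125, 0.0078125, 0))
  dual <- simulate_grid(p, g, solver_config(mode = "dual"))
  titr <- simulate_grid(p, g, solver_config(mode = "titrate"))
  expect_identical(dual$modality == "bimodal", titr$modality == "bimodal")
})

test_that("decision front interpolation is log-linear", {
  prof <- tibble::tibble(
    glucose = rep(0.125, 4),
    galactose = c(0.03125, 0.0625, 0.125, 0.25),
    normalized_high = c(0.1, 0.25, 0.75, 0.9),
    masked = FALSE)
  fr <- decision_front(prof)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$galactose_crossing, sqrt(0.0625 * 0.125), tolerance = 1e-9)
  ## all values below half maximum: no crossing
  prof$normalized_high <- prof$normalized_high / 10
  expect_equal(nrow(decision_front(prof)), 0)
})

test_that("the reference decision front is straight in log-log space", {
  prof <- simulate_grid(reference_parameters())
  fr <- decision_front(prof)
  fr <- fr[fr$glucose > 0, ]
  expect_gte(nrow(fr), 5)
  fit <- stats::lm(log(galactose_crossing) ~ log(glucose), data = fr)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("induction ratio snaps the median front ratio to a power of two", {
  fr <- tibble::tibble(glucose = c(0.03125, 0.0625),
                       galactose_crossing = c(0.00390625, 0.0078125))
  class(fr) <- c("decision_front", class(fr))
  r <- induction_ratio(fr)
  expect_identical(r$ratio, 8)
  expect_equal(r$raw, 8)
  fr1 <- tibble::tibble(glucose = c(0.1, 0.2),
                        galactose_crossing = c(0.1, 0.2))
  expect_identical(induction_ratio(fr1)$ratio, 1)
  expect_error(induction_ratio(fr[1, ]), "fewer than two")
})
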