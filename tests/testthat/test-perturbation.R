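test_that("delta metrics reproduce the worked twofold-ladder examples", {
  ref <- fake_boundaries(0.0625, 0.25)
  expect_identical(as.numeric(delta_on(ref, fake_boundaries(0.25, 1))), 2)
  ref2 <- fake_boundaries(0.125, 0.5)
  expect_identical(as.numeric(delta_on(ref2, fake_boundaries(0.0625, 0.25))), -1)
  expect_identical(as.numeric(delta_full(ref, fake_boundaries(0.125, 0.25))), 0)
  expect_identical(as.numeric(delta_full(ref, fake_boundaries(0.25, 1))), 2)
  ## identity perturbation
  expect_identical(as.numeric(delta_on(ref, ref)), 0)
  expect_identical(as.numeric(delta_full(ref, ref)), 0)
})

test_that("degeneration to unimodal OFF maps to the positive sentinel cap", {
  ref <- fake_boundaries(0.0625, 0.25)
  off <- fake_boundaries(NA, NA, always_off = TRUE)
  d1 <- delta_on(ref, off)
  expect_true(attr(d1, "degenerate"))
  expect_equal(as.numeric(d1), log2(8 / 0.0625))  # cap = 2 x ladder max
  d2 <- delta_full(ref, off)
  expect_true(attr(d2, "degenerate"))
  expect_gt(as.numeric(d2), 0)
  expect_error(delta_on(fake_boundaries(NA, NA), off), "undefined")
})

test_that("delta metrics are antisymmetric when both boundaries exist", {
  a <- fake_boundaries(0.03125, 0.125)
  b <- fake_boundaries(0.5, 2)
  expect_equal(as.numeric(delta_on(a, b)), -as.numeric(delta_on(b, a)))
  expect_equal(as.numeric(delta_full(a, b)), -as.numeric(delta_full(b, a)))
})

test_that("delta_level is the relative change with its -1 floor", {
  expect_identical(delta_level(2, 2), 0)
  expect_identical(delta_level(1.5, 3), 1)
  expect_identical(delta_level(0.8, 0), -1)
  expect_error(delta_level(0, 1), "zero reference")
})

test_that("titration boundaries match the dual-init grid classification", {
  p <- reference_parameters()
  gl <- 0.0625
  ladder <- sort(sugar_grid()$galactose[sugar_grid()$galactose > 0])
  b <- bimodal_boundaries(p, gl, ladder)
  prof <- simulate_grid(p, sugar_grid(glucose_levels = gl,
                                      galactose_levels = ladder),
                        mask = rep(FALSE, length(ladder)))
  prof <- prof[order(prof$galactose), ]
  grid_on <- prof$galactose[which(prof$modality == "bimodal")[1]]
  expect_equal(b$gal_on, grid_on)
})

test_that("boundaries agree with a brute-force finer titration", {
  p <- reference_parameters()
  coarse <- sort(sugar_grid()$galactose[sugar_grid()$galactose > 0])
  fine <- sort(unique(c(coarse, 4 / 2^(seq(0.5, 10, by = 0.5)))))
  b_coarse <- bimodal_boundaries(p, 0.0625, coarse)
  b_fine <- bimodal_boundaries(p, 0.0625, fine)
  ## the fine boundary lies within one coarse ladder step
  expect_lte(abs(log2(b_coarse$gal_on / b_fine$gal_on)), 1)
})

test_that("degenerate and saturated systems classify correctly", {
  p <- reference_parameters()
  half <- bimodal_boundaries(p, 0.0625)$peak_level / 2
  off <- bimodal_boundaries(make_variant(p, c(ag80 = 100)), 0.0625,
                            half_max = half)
  expect_true(off$always_off)
  expect_true(is.na(off$gal_on))
  on <- bimodal_boundaries(apply_knockout(p, "GAL80"), 0.0625,
                           half_max = half)
  expect_false(on$always_off)
  expect_true(is.na(on$gal_on))         # bimodality never appears
  expect_equal(on$gal_full, min(on$ladder))
})

test_that("identity factors give exactly zero rows of the right shape", {
  p <- reference_parameters()
  ladder <- 4 / 2^(seq(10, 0, by = -2))
  mat <- build_perturbation_matrix(p, free_names = c("kf83", "rHXT", "a1"),
                                   factors = 1,
                                   glucose_levels = c(0.25, 0.0625),
                                   gal_ladder = sort(ladder))
  expect_equal(nrow(mat), 3)
  dcols <- grep("^delta_", names(mat))
  expect_length(dcols, 6)  # 3 metrics x 2 glucose levels
  vals <- unlist(mat[, grep("^delta_(on|full)_", names(mat))])
  expect_true(all(vals[!is.na(vals)] == 0))
  lvl <- unlist(mat[, grep("^delta_level_", names(mat))])
  expect_true(all(abs(lvl[!is.na(lvl)]) < 1e-4))
  expect_false(any(mat$degenerate))
})

test_that("non-sentinel boundary shifts are integers on the twofold ladder", {
  p <- reference_parameters()
  mat <- build_perturbation_matrix(p, free_names = c("kf83", "ag80"),
                                   factors = c(0.1, 10),
                                   glucose_levels = c(0.25, 0.03125))
  shifts <- unlist(mat[!mat$degenerate, grep("^delta_on_", names(mat))])
  shifts <- shifts[!is.na(shifts)]
  expect_true(all(abs(shifts - round(shifts)) < 1e-9))
})

test_that("raising Gal80p synthesis represses the pathway", {
  p <- reference_parameters()
  mat <- build_perturbation_matrix(p, free_names = "ag80", factors = 100,
                                   glucose_levels = c(0.25, 0.0625, 0.015625))
  don <- unlist(mat[, grep("^delta_on_", names(mat))])
  expect_true(all(don[!is.na(don)] > 0 | mat$degenerate))
  lab <- classify_perturbations(mat)
  expect_identical(lab$label, "more_repressed")
})

test_that("row classification follows the fold-change rules", {
  template <- build_perturbation_matrix(
    reference_parameters(), free_names = "a1", factors = 1,
    glucose_levels = c(0.25, 0.0625), gal_ladder = c(0.03125, 0.5, 2))
  make_row <- function(don, dfull, dlev, degen = FALSE) {
    m <- template
    m[, grep("^delta_on_", names(m))] <- as.list(don)
    m[, grep("^delta_full_", names(m))] <- as.list(dfull)
    m[, grep("^delta_level_", names(m))] <- as.list(dlev)
    m$degenerate <- degen
    classify_perturbations(m)$label
  }
  expect_identical(make_row(c(0, 0), c(0, 0), c(0, 0)),
                   "bimodality_insensitive")
  expect_identical(make_row(c(-3, -3), c(-1, 0), c(0.5, 0.2)),
                   "more_inducible")
  expect_identical(make_row(c(3, 4), c(2, 2), c(-0.5, -0.2)),
                   "more_repressed")
  expect_identical(make_row(c(0, 0), c(0, 0), c(0, 0), degen = TRUE),
                   "more_repressed")
  expect_identical(make_row(c(-2, 2), c(0, 0), c(0, 0)), "other")
})

test_that("sensor-branch perturbations act in both directions, Gal2p only inducibly", {
  p <- reference_parameters()
  gl <- c(0.25, 0.0625)
  mat <- build_perturbation_matrix(
    p, free_names = c("kf83", "kf3", "dsugar", "a2"),
    factors = c(0.01, 100), glucose_levels = gl)
  don <- function(nm, f) {
    unlist(mat[mat$parameter == nm & mat$factor == f,
               grep("^delta_on_", names(mat))])
  }
  ## stronger sensing or slower sugar turnover: bimodality at >= 8-fold
  ## lower galactose; the opposite direction represses
  expect_true(all(don("kf83", 100) <= -3))
  expect_true(all(don("kf83", 0.01) >= 3 |
                    mat$degenerate[mat$parameter == "kf83" & mat$factor == 0.01]))
  expect_true(all(don("kf3", 100) <= -3))
  expect_true(all(don("kf3", 0.01) >= 3))
  expect_true(all(don("dsugar", 0.01) <= -3))
  expect_true(all(don("dsugar", 100) >= 3))
  ## Gal2p abundance: inducible direction only
  expect_true(all(don("a2", 100) < 0))
  expect_true(all(abs(don("a2", 0.01)) <= 1))
})

test_that("the embedding is deterministic and separates distinct blocks", {
  m <- build_perturbation_matrix(
    reference_parameters(), free_names = "a1", factors = 1,
    glucose_levels = c(0.25, 0.0625), gal_ladder = c(0.03125, 0.5, 2))
  blockA <- blockB <- m[rep(1, 6), ]
  dcols <- grep("^delta_", names(m))
  set.seed(2)
  blockA[, dcols] <- lapply(blockA[, dcols], function(x) rnorm(6, 0, 0.1))
  blockB[, dcols] <- lapply(blockB[, dcols], function(x) rnorm(6, 8, 0.1))
  both <- dplyr::bind_rows(blockA, blockB)
  class(both) <- class(m)
  e1 <- embed_perturbations(both, seed = 1)
  e2 <- embed_perturbations(both, seed = 1)
  expect_identical(e1, e2)
  sil <- silhouette_mean(cbind(e1$x, e1$y), rep(c("A", "B"), each = 6))
  expect_gt(sil, 0.5)
  ## identical rows land on coincident points
  twin <- dplyr::bind_rows(blockA[1, ], blockA[1, ], blockB)
  class(twin) <- class(m)
  et <- embed_perturbations(twin)
  expect_lt((et$x[1] - et$x[2])^2 + (et$y[1] - et$y[2])^2, 1e-12)
  expect_error(embed_perturbations(m[c(1, 1), ]), "constant")
})
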