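test_that("a noise-free table generated from the same parameters scores zero", {
  p <- reference_parameters()
  tab <- generate_strain_table(strain_spec("self", NULL, character(), 0, 1),
                               p, tiny_grid())
  expect_lt(objective(p, tab, tiny_grid()), 1e-8)
})

test_that("the objective is the sum of squared high and low residuals", {
  prof <- tibble::tibble(glucose = c(0.0625, 0.0625),
                         galactose = c(0.5, 0.03125),
                         normalized_high = c(0.8, 0.3),
                         normalized_low = c(0.1, 0.05),
                         masked = c(FALSE, FALSE))
  tab <- tibble::tibble(strain_id = "t", glucose = c(0.0625, 0.0625),
                        galactose = c(0.5, 0.03125),
                        on_peak = c(0.9, 0.9), off_peak = c(0.3, 0.3),
                        valid = c(TRUE, FALSE))
  ## one valid condition, residuals 0.1 (high) and 0.2 (low)
  expect_equal(objective(NULL, tab, profile = prof), 0.01 + 0.04)
  ## a masked simulated cell is excluded even when the table row is valid
  tab$valid <- c(TRUE, TRUE)
  prof$masked <- c(FALSE, TRUE)
  expect_equal(objective(NULL, tab, profile = prof), 0.05)
  tab$valid <- c(FALSE, FALSE)
  expect_error(objective(NULL, tab, profile = prof), "No valid conditions")
})

test_that("the multi-strain objective reduces to per-strain objectives", {
  p <- reference_parameters()
  tab <- generate_strain_table(strain_spec("wt", NULL, character(), 0, 1),
                               p, tiny_grid())
  single <- objective(p, tab, tiny_grid())
  multi <- multi_strain_objective(p, list(list(table = tab)), tiny_grid())
  expect_equal(multi$total, single)
  expect_error(multi_strain_objective(p, list()), "At least one strain")
})

test_that("a knockout panel generated from one shared vector fits at zero", {
  p <- reference_parameters()
  specs <- list(
    list(table = generate_strain_table(
      strain_spec("wt", NULL, character(), 0, 1), p, tiny_grid())),
    list(table = generate_strain_table(
      strain_spec("mig1d", NULL, "MIG1", 0, 2), p, tiny_grid()),
      knockouts = "MIG1"),
    list(table = generate_strain_table(
      strain_spec("gal80d", NULL, "GAL80", 0, 3), p, tiny_grid()),
      knockouts = "GAL80"))
  res <- multi_strain_objective(p, specs, tiny_grid())
  expect_lt(res$total, 1e-8)
  expect_length(res$per_strain, 3)
})

test_that("the log posterior combines likelihood and log-normal priors", {
  p <- reference_parameters()
  ## flat priors: log-posterior differences equal -delta(Obj) / sigma^2
  tab <- generate_strain_table(strain_spec("wt", NULL, character(), 0, 1),
                               p, tiny_grid())
  spec <- list(list(table = tab))
  lp0 <- log_posterior(p, spec, priors = NULL, sigma = 0.2, grid = tiny_grid())
  p2 <- make_variant(p, c(kf83 = 3))
  lp2 <- log_posterior(p2, spec, priors = NULL, sigma = 0.2, grid = tiny_grid())
  obj2 <- objective(p2, tab, tiny_grid())
  expect_equal(as.numeric(lp0) - as.numeric(lp2),
               (obj2 - 0) / 0.2^2, tolerance = 1e-6)
  ## empty tables: prior-only score
  pr <- default_priors(p, names = "kf83")
  lp_prior <- log_posterior(p, list(), priors = pr, sigma = 0.1)
  expect_equal(as.numeric(lp_prior),
               stats::dnorm(log10(p[["kf83"]]), log10(p[["kf83"]]), 1,
                            log = TRUE))
  ## prior centers maximize the prior-only score along a 1-d scan
  scan <- sapply(10^seq(-1, 1, length.out = 11) * p[["kf83"]], function(v) {
    x <- stats::setNames(as.numeric(p), names(p)); x["kf83"] <- v
    as.numeric(log_posterior(gal_params(x), list(), priors = pr, sigma = 0.1))
  })
  expect_equal(which.max(scan), 6)
})

test_that("sampling behaves correctly on an analytic Gaussian target", {
  mu <- 0.3; sd_t <- 0.25
  target <- function(v) -(log10(v[["x"]]) - mu)^2 / (2 * sd_t^2)
  cfg <- fit_config(free = "kf83", step = 0.25, n_steps = 50000, seed = 99)
  cfg$free <- "x"
  chain <- mh_sample(target, c(x = 1), cfg)
  keep <- chain$draws$step > cfg$burn_in
  th <- chain$draws$x[keep]
  n_eff <- length(th) / (2 * sum(stats::acf(th, plot = FALSE,
                                            lag.max = 200)$acf) - 1)
  se_mean <- sd_t / sqrt(n_eff)
  expect_lt(abs(mean(th) - mu), 3 * se_mean)
  se_sd <- sd_t / sqrt(2 * (n_eff - 1))
  expect_lt(abs(stats::sd(th) - sd_t), 3 * se_sd)
  ## determinism under the seed
  chain2 <- mh_sample(target, c(x = 1), cfg)
  expect_identical(chain$draws, chain2$draws)
})

test_that("uphill proposals are always accepted and best-so-far is monotone", {
  target <- function(v) -(log10(v[["x"]]) - 1)^2
  cfg <- fit_config(free = "kf83", step = 0.3, n_steps = 2000, seed = 3)
  cfg$free <- "x"
  chain <- suppressWarnings(mh_sample(target, c(x = 1), cfg))
  d <- chain$draws
  uphill <- which(diff(d$log_posterior) > 0)
  expect_true(all(d$accepted[uphill + 1]))
  best_trace <- cummin(d$objective)
  expect_true(all(diff(best_trace) <= 0))
  expect_error(mh_sample(target, c(x = 1),
                         {cfg$n_steps <- 0L; cfg}), "at least 1")
})

test_that("an empty free list returns the initial parameters unchanged", {
  p <- reference_parameters()
  tab <- generate_strain_table(strain_spec("wt", NULL, character(), 0, 1),
                               p, tiny_grid())
  cfg <- fit_config(free = character(), n_steps = 10, seed = 1)
  fit <- fit_strains(list(list(table = tab)), p, cfg, grid = tiny_grid())
  expect_identical(as.numeric(fit$best_params), as.numeric(p))
  expect_lt(fit$objective, 1e-8)
})

test_that("chain tidiers summarize draws and fit quality", {
  target <- function(v) -(log10(v[["x"]]))^2
  cfg <- fit_config(free = "kf83", step = 0.3, n_steps = 500, seed = 5)
  cfg$free <- "x"
  chain <- suppressWarnings(mh_sample(target, c(x = 2), cfg))
  td <- tidy(chain)
  expect_identical(td$parameter, "x")
  expect_true(td$conf.low <= td$estimate && td$estimate <= td$conf.high)
  gl <- glance(chain)
  expect_identical(gl$n_steps, 500L)
  expect_true(gl$acceptance_rate > 0 && gl$acceptance_rate <= 1)
})
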