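test_that("the objective vanishes at the generating parameters", {
  fit <- fx_fit()
  obs <- make_observation(fit$truth, fit$mesh, fit$plan, fit$region, seed = 5)
  expect_lt(objective(fit$truth, obs, fit$mesh, fit$plan, fit$region), 1e-16)
})

test_that("the objective is sensitive to a Poisson-ratio perturbation", {
  fit <- fx_fit()
  obs <- make_observation(fit$truth, fit$mesh, fit$plan, fit$region, seed = 5)
  off <- fit$truth; off[["nu"]] <- off[["nu"]] - 0.05
  expect_gt(objective(off, fit$mesh, plan = fit$plan, observed = obs,
                      orbit_region = fit$region), 1e-4)
})

test_that("jointly rescaling stiffness and pressure leaves the outcome unchanged", {
  fit <- fx_fit()
  # the forward model at (E, p) and (s E, s p) gives identical fields, so
  # the identifiable coordinates (p/E, ratio, nu) fix the outcome
  base <- orbdecomp:::materials_from_params(c(E_muscle_ratio = 4, nu = 0.45))
  plan <- fit$plan; plan$pressure_kPa <- 0.4
  u0 <- simulate_scenario(fit$mesh, plan, base, n_steps = 1)$u
  for (s in c(2, 5, 10)) {
    scaled <- material_params(E = s * base$E, nu = base$nu)
    plan_s <- plan; plan_s$pressure_kPa <- 0.4 * s
    us <- simulate_scenario(fit$mesh, plan_s, scaled, n_steps = 1)$u
    expect_equal(us, u0, tolerance = 1e-9)
  }
})

test_that("fitting absolute stiffness and pressure jointly is refused", {
  fit <- fx_fit()
  obs <- make_observation(fit$truth, fit$mesh, fit$plan, fit$region, seed = 5)
  expect_error(fit_parameters(obs, fit$mesh, fit$plan, fit$region,
                              fit_params = c("E_fat", "pressure")),
               "non-identifiable")
  expect_error(fit_parameters(obs, fit$mesh, fit$plan, fit$region,
                              fit_params = c("E_fat", "nu")),
               "non-identifiable|unknown")
})

test_that("the recorded trajectory is non-increasing and truth is a fixed point", {
  fit <- fx_fit()
  obs <- make_observation(fit$truth, fit$mesh, fit$plan, fit$region, seed = 5)
  quick <- fit_parameters(obs, fit$mesh, fit$plan, fit$region,
                          init = fit$truth, restarts = 0L, maxit = 40L)
  expect_true(all(diff(quick$trajectory) <= 0))
  # started at the generating parameters the very first evaluation is optimal
  expect_lt(quick$trajectory[1], 1e-16)
  expect_lt(quick$objective, 1e-12)
})

test_that("a two-parameter fit recovers the generating values", {
  fit <- fx_fit()
  obs <- make_observation(fit$truth, fit$mesh, fit$plan, fit$region, seed = 5)
  est <- fit_parameters(obs, fit$mesh, fit$plan, fit$region,
                        fit_params = c("p_over_E_fat", "nu"),
                        fixed = c(E_muscle_ratio = fit$truth[["E_muscle_ratio"]]),
                        restarts = 1L, maxit = 120L)
  expect_lt(abs(coef(est)[["p_over_E_fat"]] / fit$truth[["p_over_E_fat"]] - 1),
            0.05)
  expect_lt(abs(coef(est)[["nu"]] - fit$truth[["nu"]]), 0.02)
})

test_that("recovery degrades gracefully with observation noise", {
  fit <- fx_fit()
  err_at <- function(noise, seeds) {
    median(vapply(seeds, function(s) {
      obs <- make_observation(fit$truth, fit$mesh, fit$plan, fit$region,
                              noise = noise, seed = s)
      est <- fit_parameters(obs, fit$mesh, fit$plan, fit$region,
                            restarts = 0L, maxit = 100L)
      abs(coef(est)[["p_over_E_fat"]] / fit$truth[["p_over_E_fat"]] - 1)
    }, numeric(1)))
  }
  e0 <- err_at(0, 11)
  e1 <- err_at(0.05, 11:13)
  e2 <- err_at(0.25, 11:13)
  expect_lt(e0, e1)
  expect_lt(e1, e2)
})
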