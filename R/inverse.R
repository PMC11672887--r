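# Inverse estimation of tissue parameters from observed surgical outcome.
#
# Linear elastostatics with traction loading is invariant under joint
# rescaling of all moduli and the pressure, so absolute E and p are not
# jointly identifiable from outcome observations.  The fit therefore works
# in identifiable coordinates: the pressure-to-fat-stiffness ratio
# p/E_fat, the muscle-to-fat stiffness ratio E_muscle/E_fat, and the
# Poisson ratio.  The bulbus-to-fat stiffness ratio is held at its default
# (the globe is far stiffer than fat and the outcome is insensitive to
# it).  Optimisation is a derivative-free Nelder-Mead simplex in
# transformed (log / scaled-logit) coordinates with random restarts.

#' Observed post-surgery outcome
#'
#' @param released_cm3 observed released tissue volume (cm^3), or NULL.
#' @param sample_nodes node indices where surface displacements were
#'   observed, or NULL.
#' @param sample_u matching matrix of observed displacement vectors (mm).
#' @param noise annotation of the observation noise level (fraction).
#' @return Object of class `observed_outcome`.
#' @export
observed_outcome <- function(released_cm3 = NULL, sample_nodes = NULL,
                             sample_u = NULL, noise = 0) {
  if (is.null(released_cm3) && is.null(sample_nodes))
    stopf("observed_outcome needs at least one observation")
  if (!is.null(sample_nodes) && (is.null(sample_u) ||
                                 nrow(rbind(sample_u)) != length(sample_nodes)))
    stopf("sample_u must have one row per sample node")
  structure(list(released_cm3 = released_cm3,
                 sample_nodes = sample_nodes,
                 sample_u = if (!is.null(sample_u)) rbind(sample_u),
                 noise = noise),
            class = "observed_outcome")
}

# default identifiable parameter bounds
default_fit_bounds <- function() {
  list(p_over_E_fat = c(0.02, 2), E_muscle_ratio = c(1, 40),
       nu = c(0.2, 0.49))
}

# materials + plan realised from identifiable parameters (E_fat is the
# reference scale and is fixed at 1 kPa)
materials_from_params <- function(params, bulbus_ratio = 30) {
  material_params(E = c(fat = 1, muscle = unname(params[["E_muscle_ratio"]]),
                        bulbus = bulbus_ratio),
                  nu = c(fat = unname(params[["nu"]]),
                         muscle = unname(params[["nu"]]),
                         bulbus = unname(params[["nu"]])))
}

#' Synthesise an observation by running the forward model
#'
#' Convenience generator for recovery experiments: simulates the scenario
#' at known parameters and returns the (optionally noisy) observation.
#'
#' @param params named vector with `p_over_E_fat`, `E_muscle_ratio`, `nu`.
#' @param mesh,plan,orbit_region forward-model inputs.
#' @param n_samples number of boundary nodes sampled for surface
#'   displacements.
#' @param noise multiplicative Gaussian noise fraction applied to every
#'   observation component.
#' @param seed RNG seed (sampling + noise).
#' @param n_steps,pitch forward-model resolution.
#' @param volume_mode released-volume estimator (see [released_volume()]).
#' @return An `observed_outcome`.
#' @export
make_observation <- function(params, mesh, plan, orbit_region,
                             n_samples = 25L, noise = 0, seed = 1L,
                             n_steps = 1L, pitch = 1.0,
                             volume_mode = "sample") {
  set.seed(seed)
  plan$pressure_kPa <- unname(params[["p_over_E_fat"]])   # E_fat = 1
  mats <- materials_from_params(params)
  fld <- simulate_scenario(mesh, plan, mats, n_steps = n_steps)
  rv <- released_volume(mesh, fld, orbit_region, pitch = pitch,
                        mode = volume_mode)
  nodes <- sort(sample(unique(as.vector(mesh$boundary$facets)),
                       min(n_samples, nrow(mesh$nodes))))
  u <- fld$u[nodes, , drop = FALSE]
  if (noise > 0) {
    rv <- rv * (1 + noise * stats::rnorm(1))
    u <- u * (1 + noise * matrix(stats::rnorm(length(u)), nrow(u)))
  }
  observed_outcome(released_cm3 = rv, sample_nodes = nodes, sample_u = u,
                   noise = noise)
}

#' Inverse-problem objective
#'
#' Weighted sum of squared discrepancies between the simulated and
#' observed outcome: `w_vol (dV)^2 + w_u sum |du|^2`.  Zero exactly when
#' the simulation reproduces every observation.
#'
#' @param params named vector (`p_over_E_fat`, `E_muscle_ratio`, `nu`).
#' @param observed an `observed_outcome`.
#' @param mesh,plan,orbit_region forward-model inputs.
#' @param weights list with `volume` and `displacement` weights.
#' @param n_steps,pitch forward-model resolution (must match the
#'   observation protocol).
#' @param volume_mode released-volume estimator (see [released_volume()]).
#' @return Non-negative scalar.
#' @export
objective <- function(params, observed, mesh, plan, orbit_region,
                      weights = list(volume = 1, displacement = 1),
                      n_steps = 1L, pitch = 1.0, volume_mode = "sample") {
  bounds <- default_fit_bounds()
  for (nm in names(bounds)) {
    v <- params[[nm]]
    if (v < bounds[[nm]][1] - 1e-12 || v > bounds[[nm]][2] + 1e-12)
      stopf("parameter %s = %g outside bounds [%g, %g]", nm, v,
            bounds[[nm]][1], bounds[[nm]][2])
  }
  plan$pressure_kPa <- unname(params[["p_over_E_fat"]])
  mats <- materials_from_params(params)
  fld <- tryCatch(simulate_scenario(mesh, plan, mats, n_steps = n_steps),
                  error = function(e)
                    stopf("forward simulation failed at (p/E=%.3g, ratio=%.3g, nu=%.3g): %s",
                          params[["p_over_E_fat"]], params[["E_muscle_ratio"]],
                          params[["nu"]], conditionMessage(e)))
  val <- 0
  if (!is.null(observed$released_cm3)) {
    rv <- released_volume(mesh, fld, orbit_region, pitch = pitch,
                          mode = volume_mode)
    val <- val + weights$volume * (rv - observed$released_cm3)^2
  }
  if (!is.null(observed$sample_nodes)) {
    du <- fld$u[observed$sample_nodes, , drop = FALSE] - observed$sample_u
    val <- val + weights$displacement * sum(du^2)
  }
  val
}

#' Fit tissue parameters to an observed outcome
#'
#' Derivative-free Nelder-Mead simplex search in transformed coordinates
#' (log for the two ratios, scaled logit for the Poisson ratio, so bound
#' constraints hold by construction) with random restarts.  Deterministic
#' given `init` and `seed`.
#'
#' Requesting the absolute parameters `E_fat` and `pressure` jointly is
#' refused: with traction loading they only enter through p/E_fat, and a
#' joint fit would return an arbitrary point on that ridge.
#'
#' @param observed an `observed_outcome`.
#' @param mesh,plan,orbit_region forward-model inputs.
#' @param init named starting values (defaults to bound midpoints on the
#'   transformed scale).
#' @param bounds list of `c(lo, hi)` per parameter.
#' @param fit_params names of the parameters to fit.
#' @param fixed named values for parameters held fixed during the fit
#'   (non-fitted parameters default to their bound midpoints).
#' @param restarts number of additional random starts.
#' @param seed RNG seed for the restarts.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param weights,n_steps,pitch,volume_mode passed to [objective()].
#' @return Object of class `orbfit`: estimates, objective trajectory
#'   (best-so-far, non-increasing), convergence flag, iteration count.
#' @export
fit_parameters <- function(observed, mesh, plan, orbit_region,
                           init = NULL, bounds = default_fit_bounds(),
                           fit_params = c("p_over_E_fat", "E_muscle_ratio", "nu"),
                           fixed = NULL,
                           restarts = 3L, seed = 17L, maxit = 150L,
                           weights = list(volume = 1, displacement = 1),
                           n_steps = 1L, pitch = 1.0, volume_mode = "sample") {
  if (all(c("E_fat", "pressure") %in% fit_params))
    stopf(paste("non-identifiable parameterization: E_fat and pressure",
                "only enter the traction-driven model through p/E_fat;",
                "fit p_over_E_fat instead"))
  bad <- setdiff(fit_params, names(default_fit_bounds()))
  if (length(bad))
    stopf("unknown or non-identifiable fit parameter(s): %s",
          paste(bad, collapse = ", "))

  # transforms: log for ratios, scaled logit for nu
  to_t <- function(p) {
    vapply(fit_params, function(nm) {
      b <- bounds[[nm]]
      if (nm == "nu") stats::qlogis((p[[nm]] - b[1]) / (b[2] - b[1]))
      else log(p[[nm]])
    }, numeric(1))
  }
  from_t <- function(tv) {
    out <- vapply(seq_along(fit_params), function(i) {
      nm <- fit_params[i]; b <- bounds[[nm]]
      if (nm == "nu") b[1] + (b[2] - b[1]) * stats::plogis(tv[i])
      else min(max(exp(tv[i]), b[1]), b[2])
    }, numeric(1))
    names(out) <- fit_params
    out
  }

  mid_all <- vapply(names(default_fit_bounds()), function(nm) {
    b <- bounds[[nm]] %||% default_fit_bounds()[[nm]]
    if (nm == "nu") mean(b) else exp(mean(log(b)))
  }, numeric(1))
  names(mid_all) <- names(default_fit_bounds())
  complete <- function(p) {
    full <- mid_all
    if (length(fixed)) full[names(fixed)] <- unlist(fixed)
    full[names(p)] <- p
    full
  }

  trajectory <- numeric(0)
  n_eval <- 0L
  best <- Inf
  n_failed <- 0L
  fn <- function(tv) {
    p <- complete(from_t(tv))
    # a failed forward solve (e.g. element inversion at an extreme
    # parameter combination) is scored with a large penalty so the
    # simplex retreats instead of aborting the whole fit
    val <- tryCatch(objective(p, observed, mesh, plan, orbit_region,
                              weights = weights, n_steps = n_steps,
                              pitch = pitch, volume_mode = volume_mode),
                    error = function(e) { n_failed <<- n_failed + 1L; 1e8 })
    n_eval <<- n_eval + 1L
    if (val < best) best <<- val
    trajectory <<- c(trajectory, best)
    val
  }

  mid <- vapply(fit_params, function(nm) {
    b <- bounds[[nm]]
    if (nm == "nu") mean(b) else exp(mean(log(b)))
  }, numeric(1))
  names(mid) <- fit_params
  starts <- list(to_t(as.list(init %||% mid)))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    rp <- vapply(fit_params, function(nm) {
      b <- bounds[[nm]]
      if (nm == "nu") stats::runif(1, b[1] + 0.02, b[2] - 0.02)
      else exp(stats::runif(1, log(b[1] * 1.2), log(b[2] / 1.2)))
    }, numeric(1))
    names(rp) <- fit_params
    starts[[r + 1L]] <- to_t(as.list(rp))
  }

  best_fit <- NULL
  for (s in starts) {
    opt <- stats::optim(s, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best_fit) || opt$value < best_fit$value) best_fit <- opt
  }
  est <- complete(from_t(best_fit$par))[unique(c(fit_params, names(fixed)))]

  k <- length(trajectory)
  converged <- FALSE
  if (k > 20L) {
    prev <- trajectory[k - 20L]
    converged <- (prev - trajectory[k]) <= 1e-6 * max(prev, 1e-300)
  }
  structure(list(coefficients = est,
                 objective = best_fit$value,
                 trajectory = trajectory,
                 converged = converged,
                 iterations = n_eval,
                 n_failed_evals = n_failed,
                 fit_params = fit_params,
                 bounds = bounds,
                 observed = observed),
            class = "orbfit")
}

#' @export
print.orbfit <- function(x, ...) {
  cat("Tissue-parameter fit (Nelder-Mead simplex)\n")
  for (nm in names(x$coefficients))
    cat(sprintf("  %-15s %.4g\n", nm, x$coefficients[[nm]]))
  cat(sprintf("  objective %.4g after %d evaluations (converged: %s)\n",
              x$objective, x$iterations, x$converged))
  invisible(x)
}

#' @export
coef.orbfit <- function(object, ...) object$coefficients

#' @export
summary.orbfit <- function(object, ...) {
  cat("Tissue-parameter fit\n")
  cat(sprintf("  %d objective evaluations, final objective %.4g\n",
              object$iterations, object$objective))
  cat(sprintf("  converged: %s\n", object$converged))
  tab <- data.frame(estimate = unlist(object$coefficients),
                    lower = vapply(object$fit_params,
                                   function(nm) object$bounds[[nm]][1], 0),
                    upper = vapply(object$fit_params,
                                   function(nm) object$bounds[[nm]][2], 0))
  print(tab)
  invisible(object)
}

#' @export
plot.orbfit <- function(x, ...) {
  graphics::plot(seq_along(x$trajectory), x$trajectory, type = "s", log = "y",
                 xlab = "objective evaluation", ylab = "best objective",
                 main = "fit convergence", ...)
  invisible(x)
}
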