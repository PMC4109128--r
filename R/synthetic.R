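#' Generate synthetic observations from the data model
#'
#' Draws \eqn{y_i = \theta + \epsilon_i} with \eqn{\epsilon_i \sim
#' N(0, \tau^2)} i.i.d., reproducibly under a fixed seed.
#'
#' @param n Number of observations.
#' @param theta True mean.
#' @param tau2 True noise variance (positive).
#' @param seed Optional integer seed.
#' @return Numeric vector of length \code{n}.
#' @export
simulate_normal_data <- function(n, theta, tau2, seed = NULL) {
  stopifnot(n >= 1, tau2 > 0)
  with_seed(seed, theta + sqrt(tau2) * rnorm(n))
}

#' Calibration study of the Gibbs estimator
#'
#' Repeatedly simulates data at a known truth, fits the model by
#' [hsgm_gibbs()] and records, per replicate, the posterior mean, SD and
#' equal-tailed credible interval for \eqn{\theta} and \eqn{\tau^2},
#' whether the interval covers the truth, and the constraining effect at
#' the posterior mean of \eqn{\tau^2}.  Replicate \code{r} uses seed
#' \code{seed + r} so runs are reproducible and replicates independent.
#'
#' @param model An [hsgm_model()].
#' @param theta_true,tau2_true True parameter values for the simulation.
#' @param n Observations per replicate.
#' @param replicates Number of replicates (at least 1).
#' @param seed Integer base seed.
#' @param n_iter,burn_in Gibbs settings per replicate.
#' @param level Credible level (default 0.95).
#' @param output_dir If non-\code{NULL}, writes \code{calibration.csv}
#'   (per-replicate table) and \code{calibration.json} (rollup) there.
#'
#' @return A list with \code{results} (one data-frame row per replicate)
#'   and \code{rollup} (coverage rates, mean bias, RMSE, mean posterior
#'   SD, failure count and the configuration).
#' @export
run_calibration <- function(model, theta_true, tau2_true, n,
                            replicates = 200, seed = 1,
                            n_iter = 11000, burn_in = 1000,
                            level = 0.95, output_dir = NULL) {
  stopifnot(inherits(model, "hsgm_model"), replicates >= 1, n >= 1)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- vector("list", replicates)
  failures <- 0L
  for (r in seq_len(replicates)) {
    rows[[r]] <- tryCatch({
      y <- simulate_normal_data(n, theta_true, tau2_true, seed = seed + r)
      fit <- hsgm_gibbs(y, model, n_iter = n_iter, burn_in = burn_in,
                        seed = seed + r)
      qt <- quantile(fit$theta, pr)
      q2 <- quantile(fit$tau2, pr)
      eff <- constraining_effect(
        theta_full_conditional(y, mean(fit$tau2), model))
      data.frame(
        replicate = r,
        theta_mean = mean(fit$theta), theta_sd = sd(fit$theta),
        theta_lo = qt[1], theta_hi = qt[2],
        theta_covered = theta_true >= qt[1] && theta_true <= qt[2],
        tau2_mean = mean(fit$tau2), tau2_sd = sd(fit$tau2),
        tau2_lo = q2[1], tau2_hi = q2[2],
        tau2_covered = tau2_true >= q2[1] && tau2_true <= q2[2],
        mean_shift = eff$mean_shift,
        variance_reduction = eff$variance_reduction,
        row.names = NULL
      )
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      failures <<- failures + 1L
      NULL
    })
  }
  results <- do.call(rbind, rows)
  if (failures > 0.05 * replicates) {
    stop("more than 5% of calibration replicates failed (", failures, ")")
  }
  rollup <- list(
    replicates = replicates, failures = failures, n = n, level = level,
    theta_true = theta_true, tau2_true = tau2_true,
    theta_coverage = mean(results$theta_covered),
    tau2_coverage = mean(results$tau2_covered),
    theta_bias = mean(results$theta_mean) - theta_true,
    theta_rmse = sqrt(mean((results$theta_mean - theta_true)^2)),
    mean_posterior_sd = mean(results$theta_sd),
    seed = seed,
    model = unclass(model)
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(output_dir, "calibration.csv"),
              row.names = FALSE)
    jsonlite::write_json(rollup, file.path(output_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, rollup = rollup)
}

#' Entropy-gap and uncertainty-degree curve tables
#'
#' Produces the four canonical curve tables: the entropy gap
#' \code{diff_ent} and the uncertainty degree \eqn{(1-\alpha)\times
#' 100\%} as functions of \eqn{\delta}, for the two reference constraint
#' intervals \eqn{[-1, 0]} and \eqn{[-1, 1.5]} with \eqn{\mu = 0} and a
#' small grid of prior variances.
#'
#' @param out_dir If non-\code{NULL}, writes the four tables there as
#'   \code{diff_ent_a.csv}, \code{diff_ent_b.csv},
#'   \code{uncertainty_a.csv}, \code{uncertainty_b.csv}.
#' @param mu Prior mean.
#' @param sigma2 Vector of prior variances.
#' @param delta_grid Grid of screening proportions in \eqn{(0, 1)}.
#' @param n_draws Monte-Carlo draws per entropy grid point (entropy-gap
#'   curves only; the uncertainty curves are analytic).
#' @param seed Integer seed for the Monte-Carlo entropy terms.
#'
#' @return A named list of four data frames: \code{diff_ent_a},
#'   \code{diff_ent_b} (columns as in [diff_ent_curve()]) and
#'   \code{uncertainty_a}, \code{uncertainty_b} (columns as in
#'   [uncertainty_curve()]); panels a and b correspond to the intervals
#'   \eqn{[-1, 0]} and \eqn{[-1, 1.5]}.
#' @export
figure_curves <- function(out_dir = NULL, mu = 0, sigma2 = c(0.5, 1, 2),
                          delta_grid = seq(0.01, 0.99, length.out = 50),
                          n_draws = 2e4, seed = 1) {
  panels <- list(a = c(-1, 0), b = c(-1, 1.5))
  out <- list()
  for (nm in names(panels)) {
    iv <- panels[[nm]]
    out[[paste0("diff_ent_", nm)]] <- diff_ent_curve(
      mu, sigma2, iv[1], iv[2], delta_grid,
      n_draws = n_draws, seed = seed + 1000 * match(nm, names(panels)))
    out[[paste0("uncertainty_", nm)]] <- uncertainty_curve(
      mu, sigma2, iv[1], iv[2], delta_grid)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  out
}

#' Read and write experiment configurations
#'
#' An experiment configuration bundles the model hyperparameters, the
#' simulation truth and the run settings into a versioned YAML document,
#' so that a calibration run is fully described by one file.  Reading
#' then writing then reading a configuration is the identity.
#'
#' @param path Path to a YAML file.
#' @return For \code{read_experiment_config}, an object of class
#'   \code{"hsgm_config"} (a named list with components \code{model},
#'   \code{truth}, \code{n}, \code{replicates}, \code{seed} and optional
#'   \code{n_iter}, \code{burn_in}, \code{output_dir}).
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("model", "truth", "n", "replicates", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing fields: ", paste(missing, collapse = ", "))
  }
  mf <- c("mu", "sigma2", "delta", "a", "b", "c", "d")
  if (!all(mf %in% names(cfg$model))) {
    stop("config$model needs fields: ", paste(mf, collapse = ", "))
  }
  stopifnot(cfg$n >= 1, cfg$replicates >= 1,
            cfg$truth$tau2_true > 0)
  class(cfg) <- "hsgm_config"
  cfg
}

#' @rdname read_experiment_config
#' @param config An \code{"hsgm_config"} object (or compatible list).
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a calibration study from a configuration
#'
#' @param config An \code{"hsgm_config"} from [read_experiment_config()].
#' @return As [run_calibration()].
#' @export
run_calibration_config <- function(config) {
  m <- config$model
  model <- hsgm_model(m$mu, m$sigma2, m$delta, m$a, m$b, m$c, m$d)
  run_calibration(
    model,
    theta_true = config$truth$theta_true,
    tau2_true = config$truth$tau2_true,
    n = config$n, replicates = config$replicates, seed = config$seed,
    n_iter = if (is.null(config$n_iter)) 11000 else config$n_iter,
    burn_in = if (is.null(config$burn_in)) 1000 else config$burn_in,
    output_dir = config$output_dir
  )
}
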