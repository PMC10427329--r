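recipe_fields <- c("name", "game", "n", "b", "epsilon", "epsilon_grid",
                   "authority_G", "dist_mean", "dist_sd", "row_sum",
                   "steps", "revision_prob", "noise_sd", "record_every",
                   "init_max", "n_runs", "D0", "D1", "D2")

#' Experiment recipe
#'
#' Bundles everything needed to reproduce an ensemble experiment: the
#' population sampling configuration, the simulation configuration and the
#' sweep grid over the normative-weight scale epsilon. Built-in recipes
#' named after the standard study figures are available through
#' [figure_recipe()].
#'
#' @param game one of `"coordination"`, `"pgg_quadratic"`, `"cpr"`,
#'   `"generic"`.
#' @param n group size.
#' @param epsilon normative-weight scale in `[0, 1]` (used when no grid is
#'   swept).
#' @param epsilon_grid optional vector of epsilon values for sweeps
#'   (e.g. `c(0, 0.25, 0.5, 0.75, 1)`).
#' @param authority_G promoted standard of the external authority, or `NULL`
#'   for no external influence.
#' @param b fixed benefit parameter (game-specific default when `NULL`).
#' @param dist_mean,dist_sd log-normal parameter distribution moments.
#' @param row_sum total per-row belief-update weight.
#' @param steps,revision_prob,noise_sd,record_every simulation controls.
#' @param init_max upper bound of the uniform initial-state distribution.
#' @param n_runs ensemble size.
#' @param name optional label.
#' @param D0,D1,D2 marginal-payoff coefficients for `game = "generic"`.
#' @return an object of class `"norm_recipe"`.
#' @export
norm_recipe <- function(game = "coordination", n = 100, epsilon = 1,
                        epsilon_grid = NULL, authority_G = NULL, b = NULL,
                        dist_mean = 1, dist_sd = 0.1, row_sum = 0.5,
                        steps = 1000, revision_prob = 0.5, noise_sd = 0.01,
                        record_every = 1, init_max = 0.1, n_runs = 40,
                        name = NULL, D0 = 0, D1 = 0, D2 = 0) {
  r <- list(name = name, game = game, n = n, b = b, epsilon = epsilon,
            epsilon_grid = epsilon_grid, authority_G = authority_G,
            dist_mean = dist_mean, dist_sd = dist_sd, row_sum = row_sum,
            steps = steps, revision_prob = revision_prob, noise_sd = noise_sd,
            record_every = record_every, init_max = init_max, n_runs = n_runs,
            D0 = D0, D1 = D1, D2 = D2)
  validate_recipe(r)
}

validate_recipe <- function(r) {
  fail <- function(field, msg) stop(sprintf("recipe field '%s': %s", field, msg))
  if (!r$game %in% c("coordination", "pgg_quadratic", "cpr", "generic"))
    fail("game", "must be coordination, pgg_quadratic, cpr or generic")
  if (!is.numeric(r$n) || r$n < 2) fail("n", "group size must be >= 2")
  if (r$epsilon < 0 || r$epsilon > 1) fail("epsilon", "must be in [0, 1]")
  if (!is.null(r$epsilon_grid) &&
      (any(r$epsilon_grid < 0) || any(r$epsilon_grid > 1)))
    fail("epsilon_grid", "values must be in [0, 1]")
  if (!is.null(r$authority_G) && r$authority_G < 0)
    fail("authority_G", "must be non-negative")
  if (r$revision_prob < 0 || r$revision_prob > 1)
    fail("revision_prob", "must be in [0, 1]")
  if (r$noise_sd < 0) fail("noise_sd", "must be non-negative")
  if (r$steps < 0) fail("steps", "must be non-negative")
  if (r$n_runs < 1) fail("n_runs", "must be at least 1")
  if (r$dist_mean <= 0) fail("dist_mean", "must be positive")
  if (r$dist_sd < 0) fail("dist_sd", "must be non-negative")
  if (r$row_sum <= 0 || r$row_sum > 1) fail("row_sum", "must be in (0, 1]")
  structure(r, class = "norm_recipe")
}

#' Built-in figure recipes
#'
#' Named experiment recipes pinning the standard study protocols:
#' `"fig2"`/`"fig3a"` heterogeneous coordination (n = 100, no authority),
#' `"fig3b"` coordination with an authority promoting G = 2,
#' `"fig4a"`/`"fig4b"` public goods with quadratic costs (n = 40, b = 40;
#' `b` variant with G = 2), `"fig5a"`/`"fig5b"` common pool resource
#' (n = 20, b = 10; `b` variant with the authority promoting the socially
#' optimal effort G = 0.5). All use log-normal(mean 1, sd 0.1) parameter
#' heterogeneity, initial states uniform on `[0, 0.1]`, revision
#' probability 0.5, noise sd 0.01, 1000 steps and 40 runs.
#'
#' @param name recipe name.
#' @return a [norm_recipe()].
#' @export
figure_recipe <- function(name = c("fig2", "fig3a", "fig3b", "fig4a",
                                   "fig4b", "fig5a", "fig5b")) {
  name <- match.arg(name)
  base <- list(name = name, epsilon_grid = c(0, 0.25, 0.5, 0.75, 1))
  args <- switch(name,
    fig2 = list(game = "coordination", n = 100),
    fig3a = list(game = "coordination", n = 100),
    fig3b = list(game = "coordination", n = 100, authority_G = 2),
    fig4a = list(game = "pgg_quadratic", n = 40, b = 40),
    fig4b = list(game = "pgg_quadratic", n = 40, b = 40, authority_G = 2),
    fig5a = list(game = "cpr", n = 20, b = 10),
    fig5b = list(game = "cpr", n = 20, b = 10, authority_G = 0.5))
  do.call(norm_recipe, c(args, base))
}

#' @export
print.norm_recipe <- function(x, ...) {
  cat(sprintf("<norm_recipe%s: %s, n = %d, %d runs x %d steps>\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              x$game, x$n, x$n_runs, x$steps))
  if (!is.null(x$authority_G)) cat("  authority G =", x$authority_G, "\n")
  if (!is.null(x$epsilon_grid))
    cat("  epsilon grid:", paste(x$epsilon_grid, collapse = ", "), "\n")
  invisible(x)
}

recipe_authority <- function(recipe) {
  if (is.null(recipe$authority_G)) NULL else authority(recipe$authority_G)
}

recipe_group <- function(recipe, epsilon = recipe$epsilon, seed = NULL) {
  auth <- recipe_authority(recipe)
  if (recipe$game == "generic") {
    if (!is.null(seed)) set.seed(seed)
    spec <- generic_game(rep_len(recipe$D0, recipe$n),
                         rep_len(recipe$D1, recipe$n),
                         rep_len(recipe$D2, recipe$n))
    sample_group(spec, n = recipe$n, epsilon = epsilon, auth = auth,
                 dist_mean = recipe$dist_mean, dist_sd = recipe$dist_sd,
                 row_sum = recipe$row_sum)
  } else {
    sample_group(recipe$game, n = recipe$n, epsilon = epsilon, auth = auth,
                 b = recipe$b, dist_mean = recipe$dist_mean,
                 dist_sd = recipe$dist_sd, row_sum = recipe$row_sum,
                 seed = seed)
  }
}

#' Load and save experiment recipes
#'
#' Recipes round-trip through strict JSON: unknown keys are rejected, all
#' values are validated, and defaults are filled for omitted fields. An
#' empty file (or `{}`) plus a built-in `name` yields that figure recipe.
#'
#' @param path file path.
#' @param name optional built-in recipe name used as the base configuration.
#' @return `load_recipe()` returns a [norm_recipe()]; `save_recipe()`
#'   returns `path` invisibly.
#' @export
load_recipe <- function(path, name = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  if (!is.null(vals$name) && is.null(name)) name <- vals$name
  unknown <- setdiff(names(vals), recipe_fields)
  if (length(unknown))
    stop("unknown recipe field(s): ", paste(unknown, collapse = ", "))
  base <- if (!is.null(name) && name %in% c("fig2", "fig3a", "fig3b", "fig4a",
                                            "fig4b", "fig5a", "fig5b"))
    unclass(figure_recipe(name)) else unclass(norm_recipe())
  for (f in setdiff(names(vals), "name")) base[[f]] <- vals[[f]]
  if (!is.null(name)) base$name <- name
  validate_recipe(base)
}

#' @rdname load_recipe
#' @param recipe a [norm_recipe()].
#' @export
save_recipe <- function(recipe, path) {
  stopifnot(inherits(recipe, "norm_recipe"))
  jsonlite::write_json(Filter(Negate(is.null), unclass(recipe)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

recipe_hash <- function(recipe) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_recipe(recipe, tf)
  unname(tools::md5sum(tf))
}

#' Run an experiment recipe and write its outputs
#'
#' Runs the recipe's ensemble for every epsilon value in its grid (or its
#' single epsilon), computes the ensemble equilibrium statistics and writes
#' `summary.csv` (one row per variable per epsilon), `summary.json`, and a
#' provenance log `provenance.json` carrying the full configuration, its
#' hash, the master seed and all per-run seeds. Outputs with equal
#' configuration hashes and seeds are identical.
#'
#' @param recipe a [norm_recipe()].
#' @param outdir output directory (created if missing).
#' @param master_seed integer seed.
#' @param last_k statistics window (final recorded steps; default 100).
#' @param trajectories if `TRUE`, also write tidy per-agent trajectories
#'   (`trajectories.csv`; large).
#' @return invisibly, the summary data frame across epsilon values.
#' @export
run_recipe <- function(recipe, outdir, master_seed = 1, last_k = 100,
                       trajectories = FALSE) {
  stopifnot(inherits(recipe, "norm_recipe"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  eps_grid <- if (!is.null(recipe$epsilon_grid)) recipe$epsilon_grid else recipe$epsilon
  all_rows <- list()
  all_seeds <- list()
  all_traj <- list()
  for (eps in eps_grid) {
    ens <- run_ensemble(recipe, master_seed = master_seed, epsilon = eps)
    st <- equilibrium_stats(ens, last_k = last_k)
    st$epsilon <- eps
    all_rows[[length(all_rows) + 1]] <- as.data.frame(st)
    all_seeds[[as.character(eps)]] <- ens$seeds
    if (trajectories)
      all_traj[[length(all_traj) + 1]] <- cbind(epsilon = eps,
                                                as.data.frame(ens))
  }
  if (trajectories)
    utils::write.csv(do.call(rbind, all_traj),
                     file.path(outdir, "trajectories.csv"), row.names = FALSE)
  out <- do.call(rbind, all_rows)
  hash <- recipe_hash(recipe)
  utils::write.csv(cbind(out, config_hash = hash, master_seed = master_seed),
                   file.path(outdir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(config_hash = hash, master_seed = master_seed,
                            summary = out),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(list(config = Filter(Negate(is.null), unclass(recipe)),
                            config_hash = hash, master_seed = master_seed,
                            run_seeds = all_seeds,
                            package_version = as.character(utils::packageVersion("normdyn")),
                            r_version = R.version.string),
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Analytic predictions for a recipe without simulating
#'
#' Samples one group from the recipe, solves the exact fixed point, and
#' reports the regime classification, the mean-theta prediction and the
#' evolutionary game theory baselines (Nash efforts; for the common pool
#' resource game also the per-capita social optimum).
#'
#' @param recipe a [norm_recipe()].
#' @param seed integer seed for the sampled group.
#' @return a list with `regime`, `theta_bar`, `equilibrium`
#'   (a `"norm_equilibrium"` or an error message when the dynamics are not
#'   contractive), `nash` and, for the common pool resource game,
#'   `social_optimum`.
#' @export
predict_recipe <- function(recipe, seed = 1) {
  stopifnot(inherits(recipe, "norm_recipe"))
  g <- recipe_group(recipe, seed = seed)
  eq <- tryCatch(predict(g), error = function(e) conditionMessage(e))
  nash <- tryCatch(nash_baseline(g$game, g$n), error = function(e) NULL)
  out <- list(regime = regime_classify(g),
              theta_bar = mean(g$theta),
              equilibrium = eq,
              nash = nash)
  if (recipe$game == "cpr")
    out$social_optimum <- social_optimum_cpr(
      b = mean(g$game$params$b), d = mean(g$game$params$d),
      c = mean(g$game$params$c), n = g$n)
  out
}
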