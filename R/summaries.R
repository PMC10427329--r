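#' Kendall rank correlation with significance
#'
#' Tie-corrected Kendall tau (the tau-b variant, appropriate after clipping
#' at zero can create ties) with a two-sided significance test, through
#' [stats::cor.test()]. All-tied input in either vector is flagged as `NA`.
#'
#' @param a,b numeric vectors of equal length (at least 2).
#' @return list with `tau`, `p` and logical `degenerate`.
#' @export
kendall_tau <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(tau = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(a, b, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Convergence half-time
#'
#' The time at which the distance between the group-mean trajectory and its
#' equilibrium value first halves relative to the initial distance, with
#' linear interpolation between recorded steps. Trajectories that never
#' halve the distance are censored at the trajectory length.
#'
#' @param traj a `"norm_traj"` object, or a numeric vector of group means
#'   (taken to be recorded at times `0, 1, 2, ...`).
#' @param equilibrium_value the equilibrium level, typically the group-mean
#'   component of [predict.norm_group()].
#' @param variable which group-mean variable to track (default the action).
#' @return numeric half-time, with attribute `censored` (logical).
#' @export
half_time <- function(traj, equilibrium_value, variable = "x") {
  if (inherits(traj, "norm_traj")) {
    v <- traj$mean[, variable]
    tt <- traj$time
  } else {
    v <- as.numeric(traj)
    tt <- seq_along(v) - 1
  }
  d <- abs(v - equilibrium_value)
  if (d[1] <= 0) return(structure(0, censored = FALSE))
  target <- 0.5 * d[1]
  hit <- which(d <= target)
  if (length(hit) == 0)
    return(structure(tt[length(tt)], censored = TRUE))
  j <- hit[1]
  if (j == 1) return(structure(0, censored = FALSE))
  # linear interpolation of the distance between recorded steps
  frac <- (d[j - 1] - target) / (d[j - 1] - d[j])
  structure(tt[j - 1] + frac * (tt[j] - tt[j - 1]), censored = FALSE)
}

#' Ensemble equilibrium statistics
#'
#' The standard protocol behind the reported equilibrium summaries: each
#' agent's variables are time-averaged over the last `last_k` recorded
#' steps of each run; per run, the across-agent mean, standard deviation
#' and Kendall rank correlation with theta are computed; runs are then
#' averaged with equal weight. Significance of the mean Kendall correlation
#' is assessed by a two-sided one-sample t-test of the per-run correlations
#' against zero (each run has its own independently sampled population, so
#' correlations cannot be pooled across runs).
#'
#' When an exact fixed point is available per run (contractive dynamics),
#' the convergence half-time of each group-mean variable towards it is also
#' reported (run-averaged, censored runs dropped).
#'
#' @param ensemble a `"norm_ensemble"` (from [run_ensemble()] or
#'   [simulate.norm_group()] with `nsim > 1`).
#' @param last_k number of final recorded steps to average over
#'   (default 100).
#' @param half_times if `TRUE` (default), compute convergence half-times
#'   against each run's exact fixed point.
#' @return a `"norm_summary"` data frame with one row per variable
#'   (`x`, `y`, `y_exp`, `x_exp`) and columns `mean`, `sd`, `cv`, `tau`,
#'   `p_tau`, `signif`, `tau_half`, plus attributes `n_runs` and `last_k`.
#' @export
equilibrium_stats <- function(ensemble, last_k = 100, half_times = TRUE) {
  stopifnot(inherits(ensemble, "norm_ensemble"))
  runs <- ensemble$runs
  groups <- if (!is.null(ensemble$groups)) ensemble$groups else
    lapply(runs, `[[`, "group")
  vars <- c("x", "y", "y_exp", "x_exp")
  nr <- length(runs)
  means <- sds <- taus <- ps <- ths <- matrix(NA_real_, nr, 4,
                                              dimnames = list(NULL, vars))
  for (i in seq_len(nr)) {
    tr <- runs[[i]]
    nrec <- dim(tr$states)[1]
    if (nrec < last_k) stop("trajectory has fewer recorded steps than last_k")
    sel <- (nrec - last_k + 1):nrec
    tbar <- apply(tr$states[sel, , , drop = FALSE], c(2, 3), mean)
    th <- groups[[i]]$theta
    eqm <- if (half_times)
      tryCatch(stats::predict(groups[[i]])$mean, error = function(e) NULL)
    else NULL
    for (v in vars) {
      means[i, v] <- mean(tbar[, v])
      sds[i, v] <- stats::sd(tbar[, v])
      kt <- if (all(is.finite(th))) kendall_tau(tbar[, v], th) else
        list(tau = NA_real_, p = NA_real_)
      taus[i, v] <- kt$tau
      ps[i, v] <- kt$p
      if (!is.null(eqm) && is.finite(eqm[v])) {
        h <- half_time(tr, eqm[v], variable = v)
        ths[i, v] <- if (attr(h, "censored")) NA_real_ else as.numeric(h)
      }
    }
  }
  p_tau <- rep(NA_real_, 4)
  for (j in 1:4) {
    tv <- taus[, j][is.finite(taus[, j])]
    if (length(tv) == 1) {
      p_tau[j] <- ps[, j][is.finite(taus[, j])]
    } else if (length(tv) >= 2) {
      p_tau[j] <- if (stats::sd(tv) > 0)
        stats::t.test(tv, mu = 0)$p.value
      else if (tv[1] != 0) 0 else 1
    }
  }
  mu <- colMeans(means); s <- colMeans(sds)
  out <- data.frame(
    variable = vars,
    mean = mu,
    sd = s,
    cv = ifelse(mu > 0, s / mu, NA_real_),
    tau = colMeans(taus),
    p_tau = p_tau,
    signif = !is.na(p_tau) & p_tau < 0.05,
    tau_half = colMeans(ths, na.rm = TRUE),
    row.names = NULL)
  structure(out, class = c("norm_summary", "data.frame"),
            n_runs = nr, last_k = last_k)
}

#' @export
summary.norm_ensemble <- function(object, last_k = 100, ...) {
  equilibrium_stats(object, last_k = last_k, ...)
}

#' @export
print.norm_summary <- function(x, ...) {
  cat(sprintf("Ensemble equilibrium statistics (%d runs, last %d recorded steps)\n",
              attr(x, "n_runs"), attr(x, "last_k")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Norm tightness metrics
#'
#' Coefficients of variation (sd/mean) of the equilibrium distributions of
#' actions, attitudes and beliefs: the operational measure of how tight
#' (uniform) or loose (dispersed) the group's norms are. Lower values mean
#' tighter norms. Variables with non-positive mean are flagged as `NA`.
#'
#' @param table a `"norm_summary"` from [equilibrium_stats()].
#' @return named numeric vector of per-variable coefficients of variation.
#' @export
tightness_metrics <- function(table) {
  stopifnot(inherits(table, "norm_summary") || is.data.frame(table))
  cv <- ifelse(table$mean > 0, table$sd / table$mean, NA_real_)
  names(cv) <- table$variable
  cv
}
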