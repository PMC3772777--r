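# Experiment harness: each run_* function regenerates a random-graph
# population with the scheme the corresponding comparison was designed
# around, computes the per-graph measures, and fits the stated model.
# Every run is a pure function of its arguments: the same (config, seed)
# yields an identical table.

sub_seed <- function(seed, offset) {
  (seed %% 1000000L) * 1013L + offset
}

# r and r-squared of a simple linear fit y ~ x, with a zero-variance guard
linear_fit <- function(x, y, model = "linear") {
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(data.frame(model = model, intercept = NA_real_, slope = NA_real_,
                      r = NA_real_, r_squared = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  data.frame(model = model, intercept = stats::coef(fit)[[1]],
             slope = stats::coef(fit)[[2]], r = r, r_squared = r^2)
}

#' Average Connectedness versus SD on Bernoulli populations
#'
#' For each network size, generates a Bernoulli-scheme population
#' (each connection present with probability `p`), computes AC and SD
#' per graph, and fits AC as an exponential function of SD
#' (`AC = a * exp(b * SD)`, fitted by least squares on `log(AC)`, the
#' spreadsheet-style exponential trendline whose r-squared is reported).
#' AC is strictly positive on weakly connected graphs, so the log is
#' always defined.
#'
#' @param n_values network sizes to run (default 4:13).
#' @param samples graphs per size; recycled along `n_values` so small
#'   sizes can use smaller counts (4-node digraphs have only 199 weakly
#'   connected isomorphism classes, which bounds what isomorph
#'   rejection can yield there).
#' @param seed integer seed; the whole experiment is reproducible from
#'   it.
#' @param p Bernoulli connection probability.
#' @return list with `records` (one row per graph: `n`, `graph_id`,
#'   `density`, `sd`, `ac`) and `fits` (per size: coefficients `a`,
#'   `b`, `r`, `r_squared` of the exponential fit).
#' @export
run_dev_experiment <- function(n_values = 4:13, samples = 150, seed = 1,
                               p = 0.5) {
  samples <- rep_len(samples, length(n_values))
  records <- list()
  fits <- list()
  for (i in seq_along(n_values)) {
    n <- n_values[i]
    pop <- sample_population(n, samples[i], scheme = "bernoulli",
                             seed = sub_seed(seed, n), p = p)
    rec <- data.frame(
      n = n, graph_id = seq_along(pop),
      density = vapply(pop, connection_density, numeric(1)),
      sd = vapply(pop, sd_degree_form, numeric(1)),
      ac = vapply(pop, average_connectedness, numeric(1)))
    f <- linear_fit(rec$sd, log(rec$ac), model = "exponential")
    fits[[length(fits) + 1L]] <- data.frame(
      n = n, model = "exponential", a = exp(f$intercept), b = f$slope,
      r = f$r, r_squared = f$r_squared)
    records[[length(records) + 1L]] <- rec
  }
  list(records = do.call(rbind, records), fits = do.call(rbind, fits))
}

#' SD against graph-theory metrics on fixed-column populations
#'
#' Generates a fixed-column normalized population and tabulates SD
#' together with the selected comparison metrics, then fits SD as a
#' second-degree polynomial of each metric.
#'
#' @param n network size.
#' @param samples number of graphs.
#' @param seed integer seed.
#' @param select metrics to compare against SD.
#' @param k column-normalization constant.
#' @return list with `records` and `fits` (per metric: quadratic
#'   coefficients `c0 + c1 x + c2 x^2` and `r_squared`).
#' @export
run_metric_sweep <- function(n = 11, samples = 1000, seed = 1,
                             select = c("density", "max_degree", "omega",
                                        "avg_path_length", "motif_number3",
                                        "motif_number4"),
                             k = 0.5) {
  if (length(select) == 0) stop("empty metric selection", call. = FALSE)
  pop <- sample_population(n, samples, scheme = "fixed_column",
                           seed = sub_seed(seed, 17L), k = k)
  rows <- lapply(seq_along(pop), function(i) {
    cbind(data.frame(n = n, graph_id = i),
          graph_metric_row(pop[[i]], select = c("sd", select)))
  })
  records <- do.call(rbind, rows)
  fits <- do.call(rbind, lapply(select, function(m) {
    quadratic_fit(records[[m]], records$sd, metric = m)
  }))
  list(records = records, fits = fits)
}

# SD ~ c0 + c1 x + c2 x^2 least squares
quadratic_fit <- function(x, y, metric) {
  if (stats::var(x) == 0) {
    return(data.frame(metric = metric, c0 = NA_real_, c1 = NA_real_,
                      c2 = NA_real_, r_squared = NA_real_))
  }
  fit <- stats::lm(y ~ x + I(x^2))
  co <- stats::coef(fit)
  data.frame(metric = metric, c0 = co[[1]], c1 = co[[2]], c2 = co[[3]],
             r_squared = summary(fit)$r.squared)
}

#' Linear correlation of 2003 Phi with SD
#'
#' For each network size, generates a fixed-column normalized
#' population (columns sum to `k`), computes SD and 2003 Phi
#' (reference covariance, full subset search) per graph, and linearly
#' regresses Phi on SD.
#'
#' @inheritParams run_metric_sweep
#' @param n_values network sizes.
#' @param cp,ci perturbation and intrinsic noise magnitudes.
#' @param mode covariance mode passed to [phi_2003()].
#' @return list with `records` (per graph: `sd`, `phi`) and `fits`
#'   (per size: `r`, `r_squared`, slope, intercept).
#' @export
run_phi_correlation <- function(n_values = 8:11, samples = 1000, seed = 1,
                                k = 0.5, cp = 1, ci = 1e-5,
                                mode = "reference") {
  records <- list()
  fits <- list()
  for (n in n_values) {
    pop <- sample_population(n, samples, scheme = "fixed_column",
                             seed = sub_seed(seed, 100L + n), k = k)
    rec <- data.frame(
      n = n, graph_id = seq_along(pop),
      density = vapply(pop, connection_density, numeric(1)),
      sd = vapply(pop, sd_degree_form, numeric(1)),
      phi = vapply(pop, function(g) phi_2003(g, cp, ci, mode)$phi,
                   numeric(1)))
    f <- linear_fit(rec$sd, rec$phi)
    fits[[length(fits) + 1L]] <- cbind(data.frame(n = n), f)
    records[[length(records) + 1L]] <- rec
  }
  list(records = do.call(rbind, records), fits = do.call(rbind, fits))
}

#' SD against substructure on uniform-density populations
#'
#' Generates networks sampled uniformly over density, computes SD and
#' the substructure metrics, fits the quadratic trends of SD over
#' density and omega, and localizes the peak of SD over average path
#' length by binned means (bin width 0.1; the center of the bin with
#' maximal mean SD is reported, since the skewed trend has no global
#' quadratic representation).
#'
#' @inheritParams run_metric_sweep
#' @param select metrics to include alongside `sd`.
#' @param bin_width bin width for the path-length peak.
#' @return list with `records`, `fits` (quadratics for any of
#'   `density`/`omega` present) and `peak_path_length` (bin center, or
#'   `NA` if path length was not selected).
#' @export
run_substructure <- function(n = 50, samples = 1000, seed = 1,
                             select = c("density", "omega",
                                        "n_maximal_cliques",
                                        "avg_maximal_clique",
                                        "avg_path_length"),
                             bin_width = 0.1) {
  pop <- sample_population(n, samples, scheme = "uniform_density",
                           seed = sub_seed(seed, 50L))
  rows <- lapply(seq_along(pop), function(i) {
    cbind(data.frame(n = n, graph_id = i),
          graph_metric_row(pop[[i]], select = c("sd", select)))
  })
  records <- do.call(rbind, rows)
  fits <- do.call(rbind, lapply(intersect(select, c("density", "omega")),
                                function(m) {
    quadratic_fit(records[[m]], records$sd, metric = m)
  }))
  peak <- NA_real_
  if ("avg_path_length" %in% select) {
    apl <- records$avg_path_length
    ok <- is.finite(apl)
    bins <- floor(apl[ok] / bin_width)
    means <- tapply(records$sd[ok], bins, mean)
    peak <- (as.numeric(names(means)[which.max(means)]) + 0.5) * bin_width
  }
  list(records = records, fits = fits, peak_path_length = peak)
}

#' Empirical Phi versus SD on fixed-column populations
#'
#' Generates fixed-column normalized networks, computes SD, density and
#' lag-tau empirical Phi per graph for each requested lag (plus their
#' sum), and correlates each Phi column with SD.  Optionally computes
#' 2003 Phi on the same graphs so the two measures can be compared at
#' matched scale.
#'
#' @inheritParams run_phi_correlation
#' @param n network size.
#' @param taus lags for the empirical Phi.
#' @param include_phi2003 also compute 2003 Phi per graph.
#' @return list with `records` and `correlations` (per Phi column:
#'   Pearson `r` with SD and `r_squared`).
#' @export
run_phi_empirical_comparison <- function(n = 9, samples = 1000, seed = 1,
                                         taus = 1:4, k = 0.5,
                                         include_phi2003 = FALSE,
                                         cp = 1, ci = 1e-5) {
  pop <- sample_population(n, samples, scheme = "fixed_column",
                           seed = sub_seed(seed, 200L + n), k = k)
  rec <- data.frame(
    n = n, graph_id = seq_along(pop),
    density = vapply(pop, connection_density, numeric(1)),
    sd = vapply(pop, sd_degree_form, numeric(1)))
  pe <- lapply(pop, phi_empirical, taus = taus)
  for (i in seq_along(taus)) {
    rec[[paste0("phi_emp_tau", taus[i])]] <-
      vapply(pe, function(x) x$per_tau[[i]], numeric(1))
  }
  rec$phi_emp_sum <- vapply(pe, function(x) x$phi_sum, numeric(1))
  if (include_phi2003) {
    rec$phi2003 <- vapply(pop, function(g) phi_2003(g, cp, ci)$phi,
                          numeric(1))
  }
  phi_cols <- setdiff(names(rec), c("n", "graph_id", "density", "sd"))
  correlations <- do.call(rbind, lapply(phi_cols, function(cn) {
    cbind(data.frame(measure = cn), linear_fit(rec$sd, rec[[cn]])[-1])
  }))
  list(records = rec, correlations = correlations)
}
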