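# Benchmark harness: runs the six model families over the behavior catalog,
# collects per-(behavior, model) evaluation records, aggregates by firing
# class and ranks the pruned models.

#' Names of the benchmark model roster
#'
#' `"izhikevich"` is the ground-truth identity row; `"srm"`/`"ssrm"` are the
#' unpruned lagged and Fourier-feature models (ridge only); `"rsrm"`/
#' `"rssrm"` add L1 pruning to a target coefficient count; `"pcr"` and
#' `"rcr"` reach the same count through principal components and
#' raised-cosine bumps.
#'
#' @return character vector.
#' @export
model_roster <- function() {
  c("izhikevich", "srm", "ssrm", "rsrm", "rssrm", "pcr", "rcr")
}

#' Benchmark configuration
#'
#' @param scale duration scale factor for [behavior_catalog()].
#' @param dt integration step (ms).
#' @param models subset of [model_roster()].
#' @param lag_frac lag counts for the lagged design as a fraction of the
#'   sample count: `J = Q = floor(n * lag_frac)`.
#' @param l2 ridge strength shared by all models.
#' @param zero_tol zero threshold for pruned-coefficient counting.
#' @param slack relative tolerance of the L1 count search.
#' @param tolerance_cap maximum-tolerance cap (ms) applied to the PCR and
#'   RCR models.
#' @param vrd_tau van Rossum kernel time constant (ms).
#' @param seed integer seed, recorded with the outputs (the pipeline itself
#'   is deterministic).
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(scale = 1, dt = 0.25, models = model_roster(),
                             lag_frac = 0.25, l2 = 0.01, zero_tol = 1e-8,
                             slack = 0.02, tolerance_cap = 30, vrd_tau = 1,
                             seed = 1L) {
  stopifnot(length(models) >= 1, all(models %in% model_roster()))
  structure(list(scale = scale, dt = dt, models = models,
                 lag_frac = lag_frac, l2 = l2, zero_tol = zero_tol,
                 slack = slack, tolerance_cap = tolerance_cap,
                 vrd_tau = vrd_tau, seed = as.integer(seed)),
            class = "benchmark_config")
}

# restrict the ground-truth train to the design's target window
.window_truth <- function(trace, rows) {
  n <- length(rows)
  idx <- round(trace$spike_times / trace$dt) + 1L
  keep <- idx >= rows[1] & idx <= rows[n]
  spike_train(trace$spike_times[keep], n_steps = n, dt = trace$dt,
              t0 = trace$t[rows[1]])
}

#' Fit, convert and score one model on one behavior
#'
#' Builds the model's design matrix, fits the penalized regression,
#' converts predicted potentials to spikes (quantile/local-maximum
#' detection, inflation-coefficient search, maximum-tolerance matching and
#' substitution) and scores RMSE, van Rossum distance and
#' precision/recall/F1.  Fully deterministic.
#'
#' @param model one of [model_roster()].
#' @param trace a `neuron_trace`.
#' @param target_params pruned-coefficient target for rsrm/rssrm/pcr/rcr
#'   (defaults to the behavior's catalog value carried on the trace call).
#' @param config a [benchmark_config()].
#' @return one-row data.frame (`evaluation record`), or `NULL` for a
#'   degenerate zero-spike trace (with a warning).
#' @export
run_model_on_behavior <- function(model, trace, target_params,
                                  config = benchmark_config()) {
  stopifnot(model %in% model_roster(), inherits(trace, "neuron_trace"))
  truth_full <- extract_spike_train(trace)
  if (truth_full$r == 0) {
    warning(sprintf("behavior '%s' fired no spikes; skipped", trace$name))
    return(NULL)
  }
  n <- length(trace$v)
  S <- truth_full$indicator
  S_prev <- lag_indicator(S)
  t_start <- Sys.time()
  achieved_target <- NA_integer_

  if (model == "izhikevich") {
    rows <- seq_len(n)
    u_hat <- trace$v
    n_params <- NA_integer_
  } else if (model == "srm" || model == "rsrm" || model == "pcr") {
    J <- Q <- max(1L, floor(n * config$lag_frac))
    des <- lagged_design(trace$I, S, J, Q)
    rows <- des$target_rows
    y <- trace$v[rows]
    if (model == "srm") {
      fit <- fit_penalized(des, y, penalty_spec(l2 = config$l2))
      n_params <- ncol(des$X)
    } else if (model == "rsrm") {
      tuned <- tune_l1_for_count(des, y, target_params, l2 = config$l2,
                                 zero_tol = config$zero_tol,
                                 slack = config$slack)
      fit <- tuned$fit
      n_params <- tuned$achieved
      achieved_target <- tuned$achieved
    } else {
      des <- pca_design(des, k = target_params)
      fit <- fit_penalized(des, y, penalty_spec(l2 = config$l2))
      n_params <- ncol(des$X)
    }
    u_hat <- predict(fit, des)
  } else {  # ssrm, rssrm, rcr: single spike-history lag, full-length rows
    if (model == "rcr") {
      des <- raised_cosine_design(trace$I, S_prev, k_bumps = target_params)
    } else {
      des <- fourier_feature_design(trace$I, S_prev)
    }
    rows <- des$target_rows
    y <- trace$v[rows]
    if (model == "rssrm") {
      tuned <- tune_l1_for_count(des, y, target_params, l2 = config$l2,
                                 zero_tol = config$zero_tol,
                                 slack = config$slack)
      fit <- tuned$fit
      n_params <- tuned$achieved
      achieved_target <- tuned$achieved
    } else {
      fit <- fit_penalized(des, y, penalty_spec(l2 = config$l2))
      n_params <- ncol(des$X)
    }
    u_hat <- predict(fit, des)
  }

  truth <- .window_truth(trace, rows)
  if (truth$r == 0) {
    warning(sprintf("behavior '%s': no spikes inside the '%s' window; skipped",
                    trace$name, model))
    return(NULL)
  }
  grid <- if (model %in% c("izhikevich", "srm", "ssrm")) beta_grid("full")
          else beta_grid("reduced")
  cap <- if (model %in% c("pcr", "rcr")) config$tolerance_cap else Inf
  sel <- select_beta(u_hat, truth, grid = grid, cap = cap)
  elapsed <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  data.frame(
    behavior = trace$name,
    model = model,
    n_params = n_params,
    rmse = rmse(trace$v[rows], u_hat),
    vrd = van_rossum(truth$times, sel$train$times, tau = config$vrd_tau),
    precision = sel$report$precision,
    recall = sel$report$recall,
    f1 = sel$f1,
    beta = sel$beta,
    tau_max = sel$tau_max,
    n_true_spikes = length(truth$times),
    n_pred_spikes = length(sel$train$times),
    wall_time_s = elapsed,
    stringsAsFactors = FALSE)
}

#' Run the full benchmark
#'
#' Simulates every behavior in the catalog, runs every model of the roster
#' on it, and collects evaluation records, per-class averages and pruned-
#' model rankings.
#'
#' @param config a [benchmark_config()].
#' @param behaviors optional subset of behavior names.
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV plus a JSON run summary via [write_benchmark()].
#' @param verbose print progress.
#' @return list of class `benchmark_result`: `records` (data.frame),
#'   `classes` (named behavior classes), `summary` (per-class averages),
#'   `rankings` (per-metric competition ranks of the pruned models),
#'   `config`.
#' @export
run_benchmark <- function(config = benchmark_config(), behaviors = NULL,
                          out_dir = NULL, verbose = interactive()) {
  set.seed(config$seed)
  catalog <- behavior_catalog(dt = config$dt, scale = config$scale,
                              names = behaviors)
  records <- list()
  classes <- character(0)
  for (spec in catalog) {
    trace <- simulate_behavior(spec)
    cls <- classify_behavior(trace)
    classes[spec$name] <- cls
    if (is.na(cls)) next
    for (model in config$models) {
      if (verbose)
        message(sprintf("behavior %s / model %s", spec$name, model))
      rec <- run_model_on_behavior(model, trace,
                                   target_params = spec$target_params,
                                   config = config)
      records[[length(records) + 1]] <- rec
    }
  }
  records <- do.call(rbind, records)
  records$class <- classes[records$behavior]
  summary <- list(
    all = aggregate_records(records, "all"),
    `one-spike` = aggregate_records(records, "one-spike"),
    `multiple-spike` = aggregate_records(records, "multiple-spike"))
  pruned <- intersect(config$models, c("rsrm", "rssrm", "pcr", "rcr"))
  rankings <- if (length(pruned) >= 2) {
    sub <- records[records$model %in% pruned, ]
    list(rmse = rank_models(sub, "rmse"),
         vrd = rank_models(sub, "vrd"),
         f1 = rank_models(sub, "f1"))
  }
  out <- structure(list(records = records, classes = classes,
                        summary = summary, rankings = rankings,
                        config = config),
                   class = "benchmark_result")
  if (!is.null(out_dir)) write_benchmark(out, out_dir)
  out
}

#' Average evaluation records over a firing class
#'
#' Arithmetic means per model of the coefficient counts and metrics over
#' the behaviors of a class.
#'
#' @param records data.frame of evaluation records with a `class` column.
#' @param class `"all"`, `"one-spike"` or `"multiple-spike"`.
#' @return data.frame, one row per model.
#' @export
aggregate_records <- function(records, class = c("all", "one-spike",
                                                 "multiple-spike")) {
  class <- match.arg(class)
  sub <- if (class == "all") records else records[records$class == class, ]
  if (!nrow(sub)) return(NULL)
  models <- unique(sub$model)
  behaviors <- unique(sub$behavior)
  missing <- vapply(models, function(m)
    length(setdiff(behaviors, sub$behavior[sub$model == m])), integer(1))
  if (any(missing > 0))
    stop("incomplete records for model(s): ",
         paste(models[missing > 0], collapse = ", "))
  num_cols <- c("n_params", "rmse", "vrd", "precision", "recall", "f1",
                "tau_max", "wall_time_s")
  out <- do.call(rbind, lapply(models, function(m) {
    rows <- sub[sub$model == m, ]
    cbind(data.frame(model = m, n_behaviors = nrow(rows)),
          as.data.frame(as.list(colMeans(rows[num_cols]))))
  }))
  rownames(out) <- NULL
  out
}

#' Competition-rank models per behavior on one metric
#'
#' Ties share the minimal rank and the next rank is skipped (`1, 1, 3`).
#' Lower is better for `rmse` and `vrd`; higher is better for `f1`,
#' `precision` and `recall`.
#'
#' @param records data.frame of evaluation records (>= 2 models).
#' @param metric metric column name.
#' @return data.frame of ranks, behaviors in rows, models in columns, with
#'   a final `"mean"` row.
#' @export
rank_models <- function(records, metric = c("rmse", "vrd", "f1",
                                            "precision", "recall")) {
  metric <- match.arg(metric)
  lower_better <- metric %in% c("rmse", "vrd")
  models <- unique(records$model)
  if (length(models) < 2) stop("ranking needs at least 2 models")
  behaviors <- unique(records$behavior)
  ranks <- t(vapply(behaviors, function(b) {
    rows <- records[records$behavior == b, ]
    x <- rows[[metric]][match(models, rows$model)]
    if (lower_better) rank(x, ties.method = "min")
    else rank(-x, ties.method = "min")
  }, numeric(length(models))))
  colnames(ranks) <- models
  out <- as.data.frame(ranks)
  out <- rbind(out, mean = colMeans(out))
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d records (%d behaviors x %d models), scale=%g\n",
              nrow(x$records), length(unique(x$records$behavior)),
              length(unique(x$records$model)), x$config$scale))
  print(x$summary$all, digits = 4)
  invisible(x)
}
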