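# Plain-text serialization: traces as columnar text with a structured
# header, catalogs as editable YAML, benchmark results as CSV + JSON.

#' Write a simulation trace as columnar text
#'
#' One row per sample (`t`, `I`, `v`, `u`, `spike` indicator), preceded by
#' `#`-prefixed header lines carrying the behavior name and grid.
#'
#' @param trace a `neuron_trace`.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "neuron_trace"))
  spike <- extract_spike_train(trace)$indicator
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# behavior: %s", trace$name),
               sprintf("# dt_ms: %.17g", trace$dt),
               sprintf("# n_steps: %d", length(trace$v)),
               "t\tI\tv\tu\tspike"), con)
  utils::write.table(
    data.frame(t = trace$t, I = trace$I, v = trace$v, u = trace$u,
               spike = spike),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path file path.
#' @return a `neuron_trace`.
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 3)
  name <- sub("^# behavior: ", "", header[1])
  dt <- as.numeric(sub("^# dt_ms: ", "", header[2]))
  df <- utils::read.table(path, skip = 3, header = TRUE, sep = "\t")
  structure(list(t = df$t, I = df$I, v = df$v, u = df$u,
                 spike_times = df$t[df$spike == 1], dt = dt, name = name),
            class = "neuron_trace")
}

#' Export a behavior catalog to YAML
#'
#' Writes every hyperparameter, initial state, grid and stimulus segment so
#' the catalog can be edited and read back with [read_catalog()].
#'
#' @param catalog named list of [behavior_spec()] objects.
#' @param path output file.
#' @export
write_catalog <- function(catalog, path) {
  as_list <- lapply(catalog, function(sp) {
    list(name = sp$name, label = sp$label,
         a = sp$a, b = sp$b, c = sp$c, d = sp$d,
         v0 = sp$v0, u0 = sp$u0, dt = sp$dt, n_steps = sp$n_steps,
         quad = as.numeric(sp$quad), u_rule = sp$u_rule,
         target_params = sp$target_params,
         baseline = sp$stimulus$baseline,
         segments = lapply(seq_len(nrow(sp$stimulus$segments)), function(i)
           as.list(sp$stimulus$segments[i, ])))
  })
  yaml::write_yaml(as_list, path)
  invisible(path)
}

#' Read a behavior catalog from YAML
#'
#' @param path file written by [write_catalog()].
#' @return named list of [behavior_spec()] objects.
#' @export
read_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(x) {
    seg <- if (length(x$segments))
      do.call(rbind, lapply(x$segments, as.data.frame)) else NULL
    behavior_spec(name = x$name, label = x$label, a = x$a, b = x$b,
                  c = x$c, d = x$d, v0 = x$v0, u0 = x$u0, dt = x$dt,
                  n_steps = x$n_steps,
                  stimulus = stimulus_protocol(seg, baseline = x$baseline),
                  quad = x$quad, u_rule = x$u_rule,
                  target_params = x$target_params)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Write benchmark outputs to a directory
#'
#' Writes the per-(behavior, model) record table, the per-class averages,
#' the pruned-model rankings (CSV) and a JSON run summary with the
#' configuration.
#'
#' @param result a `benchmark_result` from [run_benchmark()].
#' @param out_dir directory (created if needed).
#' @export
write_benchmark <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  for (cls in names(result$summary)) {
    s <- result$summary[[cls]]
    if (!is.null(s))
      utils::write.csv(s, file.path(out_dir, paste0("summary_", gsub("-", "_", cls), ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(result$rankings)) {
    for (m in names(result$rankings))
      utils::write.csv(cbind(behavior = rownames(result$rankings[[m]]),
                             result$rankings[[m]]),
                       file.path(out_dir, paste0("ranks_", m, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(
    list(config = unclass(result$config), classes = as.list(result$classes)),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(out_dir)
}

#' Plot a behavior: potentials and spike raster
#'
#' Base-graphics figure of the ground-truth membrane potential with an
#' optional predicted overlay and spike raster.
#'
#' @param trace a `neuron_trace`.
#' @param u_hat optional predicted potentials aligned to `rows`.
#' @param rows sample indices `u_hat` corresponds to (default all).
#' @param pred_times optional predicted spike times for the raster.
#' @param ... passed to [plot()].
#' @export
plot_behavior <- function(trace, u_hat = NULL, rows = NULL,
                          pred_times = NULL, ...) {
  plot(trace$t, trace$v, type = "l", col = "darkgreen",
       xlab = "time (ms)", ylab = "membrane potential (mV)",
       main = trace$name, ...)
  if (!is.null(u_hat)) {
    if (is.null(rows)) rows <- seq_along(trace$v)
    graphics::lines(trace$t[rows], u_hat, col = "steelblue")
  }
  if (length(trace$spike_times))
    graphics::points(trace$spike_times, rep(max(trace$v) + 2,
                                            length(trace$spike_times)),
                     pch = "|", col = "black")
  if (!is.null(pred_times) && length(pred_times))
    graphics::points(pred_times, rep(max(trace$v) + 5, length(pred_times)),
                     pch = "|", col = "steelblue")
  invisible(NULL)
}
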