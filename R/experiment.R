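# Grid orchestration and aggregation: replicate runs over the census-size x
# maximum-lifespan grid, and the summaries behind trajectory and
# detection-frequency curves.

#' Enumerate the parameter sets of a grid
#'
#' @param base a [sim_params] object providing every non-grid parameter.
#' @param n_isolated_list,max_age_list grid values.
#' @return data.frame with columns `set_id`, `n_isolated`, `max_age` (one
#'   row per parameter set; the full published design, 5 census sizes x 6
#'   lifespans, yields 30).
#' @export
grid_param_sets <- function(base,
                            n_isolated_list = c(50L, 100L, 200L, 350L, 500L),
                            max_age_list = c(2L, 22L, 42L, 62L, 82L, 102L)) {
  validate_sim_params(base)
  if (length(n_isolated_list) == 0L || length(max_age_list) == 0L)
    stop("grid lists must be non-empty")
  g <- expand.grid(n_isolated = as.integer(n_isolated_list),
                   max_age = as.integer(max_age_list))
  data.frame(set_id = seq_len(nrow(g)), g)
}

#' Run a replicated parameter grid
#'
#' Runs `n_replicates` seeded replicates of [run_replicate()] for every
#' (census size, maximum lifespan) pair.  Per-replicate seeds are all drawn
#' up front from `master_seed`, so results are identical whatever the worker
#' count.  A replicate that errors is logged and excluded, with its count
#' reported, never silently averaged.
#'
#' @inheritParams grid_param_sets
#' @param n_replicates replicates per parameter set.
#' @param freqs founder frequencies.
#' @param analysis an [analysis_config].
#' @param master_seed seed from which all replicate seeds derive.
#' @param workers parallel workers (forked; >1 unavailable on Windows).
#' @return an object of class `grid_result`: `sets` (the grid), `traces`
#'   (list of `replicate_trace` lists per set), `summary` and `detection`
#'   (see [summarize_traces()]), and `n_failed`.
#' @export
run_grid <- function(base,
                     n_isolated_list = c(50L, 100L, 200L, 350L, 500L),
                     max_age_list = c(2L, 22L, 42L, 62L, 82L, 102L),
                     n_replicates = base$n_replicates,
                     freqs = founder_profile(),
                     analysis = analysis_config(),
                     master_seed = 1L, workers = 1L) {
  sets <- grid_param_sets(base, n_isolated_list, max_age_list)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  set.seed(as.integer(master_seed))
  seeds <- matrix(sample.int(.Machine$integer.max, nrow(sets) * n_replicates),
                  nrow(sets), n_replicates)
  jobs <- expand.grid(rep = seq_len(n_replicates), set = seq_len(nrow(sets)))
  one <- function(j) {
    si <- jobs$set[j]; ri <- jobs$rep[j]
    p <- base
    p$n_isolated <- sets$n_isolated[si]
    p$max_age <- sets$max_age[si]
    p$subsample_size <- min(p$subsample_size, p$n_isolated)
    tryCatch(run_replicate(p, freqs, seed = seeds[si, ri], analysis),
             error = function(e) {
               warning(sprintf("replicate failed (set %d, seed %d): %s",
                               si, seeds[si, ri], conditionMessage(e)),
                       call. = FALSE)
               NULL
             })
  }
  workers <- if (.Platform$OS.type == "windows") 1L else as.integer(workers)
  res <- if (workers > 1L)
    parallel::mclapply(seq_len(nrow(jobs)), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  else lapply(seq_len(nrow(jobs)), one)
  traces <- lapply(seq_len(nrow(sets)), function(si)
    Filter(Negate(is.null), res[jobs$set == si]))
  n_failed <- nrow(jobs) - sum(lengths(traces))
  agg <- summarize_traces_by_set(sets, traces)
  structure(list(sets = sets, traces = traces, summary = agg$summary,
                 detection = agg$detection, n_failed = n_failed,
                 master_seed = as.integer(master_seed)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("Grid result: %d parameter sets, %d traces (%d failed)\n",
              nrow(x$sets), sum(lengths(x$traces)), x$n_failed))
  invisible(x)
}

#' Summarise replicate traces into trajectory and detection tables
#'
#' A pure function of its input traces: re-summarising stored traces
#' reproduces the tables exactly.
#'
#' @param traces list of `replicate_trace` objects sharing a parameter set.
#' @return list with `summary` (year x statistic mean, sd, and replicate
#'   count, long format) and `detection` (per clustering year: fraction of
#'   replicates whose chosen K is 2, with count).
#' @export
summarize_traces <- function(traces) {
  if (length(traces) == 0L) stop("no traces to summarise")
  stats_long <- do.call(rbind, lapply(traces, function(tr) {
    y <- tr$yearly
    do.call(rbind, lapply(
      c("he_source", "he_isolated", "theta", "dapc_misassignment"),
      function(s) data.frame(year = y$year, statistic = s, value = y[[s]])))
  }))
  stats_long <- stats_long[!is.na(stats_long$value), ]
  summary <- do.call(rbind, lapply(
    split(stats_long, stats_long[c("statistic", "year")], drop = TRUE),
    function(d) data.frame(year = d$year[1], statistic = d$statistic[1],
                           mean = mean(d$value), sd = stats::sd(d$value),
                           n = nrow(d))))
  summary <- summary[order(summary$statistic, summary$year), ]
  rownames(summary) <- NULL

  clust <- do.call(rbind, lapply(traces, function(tr) tr$clustering))
  detection <- if (!is.null(clust) && nrow(clust) > 0) {
    clust <- clust[!is.na(clust$best_k), ]
    out <- do.call(rbind, lapply(split(clust, clust$year), function(d)
      data.frame(year = d$year[1],
                 detection_frequency = mean(d$best_k == 2L),
                 n = nrow(d))))
    rownames(out) <- NULL
    out
  } else data.frame(year = integer(0), detection_frequency = numeric(0),
                    n = integer(0))
  list(summary = summary, detection = detection)
}

summarize_traces_by_set <- function(sets, traces_by_set) {
  parts <- lapply(seq_len(nrow(sets)), function(si) {
    if (length(traces_by_set[[si]]) == 0L) return(NULL)
    agg <- summarize_traces(traces_by_set[[si]])
    key <- sets[si, c("set_id", "n_isolated", "max_age")]
    list(summary = cbind(key, agg$summary, row.names = NULL),
         detection = if (nrow(agg$detection))
           cbind(key, agg$detection, row.names = NULL) else NULL)
  })
  parts <- Filter(Negate(is.null), parts)
  detection <- do.call(rbind, Filter(Negate(is.null),
                                     lapply(parts, `[[`, "detection")))
  if (is.null(detection))
    detection <- data.frame(set_id = integer(0), n_isolated = integer(0),
                            max_age = integer(0), year = integer(0),
                            detection_frequency = numeric(0), n = integer(0))
  list(summary = do.call(rbind, lapply(parts, `[[`, "summary")),
       detection = detection)
}

#' Detection frequency at a scheduled clustering year
#'
#' @param traces list of `replicate_trace` objects sharing a parameter set.
#' @param year a year on the traces' clustering schedule.
#' @return fraction of replicates whose admixture model choice was K = 2.
#' @export
detection_frequency <- function(traces, year) {
  if (length(traces) == 0L) stop("no traces")
  ks <- vapply(traces, function(tr) {
    i <- match(year, tr$clustering$year)
    if (is.na(i))
      stop("year ", year, " is not on the clustering schedule")
    tr$clustering$best_k[i]
  }, integer(1))
  mean(ks == 2L, na.rm = TRUE)
}

#' Per-year mean and spread of a recorded statistic
#'
#' @param traces list of `replicate_trace` objects sharing a parameter set.
#' @param statistic one of `"he_source"`, `"he_isolated"`, `"theta"`,
#'   `"dapc_misassignment"`.
#' @return data.frame with year, mean, sd and replicate count (scheduled
#'   years only).
#' @export
trajectory_summary <- function(traces, statistic) {
  choices <- c("he_source", "he_isolated", "theta", "dapc_misassignment")
  if (!statistic %in% choices)
    stop("unknown statistic '", statistic, "'; expected one of: ",
         paste(choices, collapse = ", "))
  s <- summarize_traces(traces)$summary
  out <- s[s$statistic == statistic, c("year", "mean", "sd", "n")]
  rownames(out) <- NULL
  out
}
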