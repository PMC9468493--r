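# Batch driver and the frequentist layer: per-ROI posterior means are
# treated as individual measurements, summarised per experimental group
# (mean, standard error) and compared between groups with the two-sample
# Kolmogorov-Smirnov test.

#' Read per-ROI traces from a CSV file
#'
#' Expects the long-format trace dialect with header
#' \code{roi_id,time_s,fluorescence} (UTF-8, '.' decimal). One trace per
#' distinct ROI id; each ROI's time grid must be uniform and free of
#' duplicates.
#'
#' @param path Path to the CSV file.
#' @return A list of \code{ca_trace} objects (empty, with a warning, for a
#'   header-only file).
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "time_s", "fluorescence")
  if (!all(need %in% names(df)))
    stop("malformed trace file (expected columns roi_id,time_s,fluorescence): ",
         path)
  if (nrow(df) == 0L) {
    warning("trace file contains no rows: ", path)
    return(list())
  }
  if (any(!is.finite(df$time_s)) || any(!is.finite(df$fluorescence)))
    stop("malformed rows: non-numeric time or fluorescence in ", path)
  out <- list()
  for (roi in unique(df$roi_id)) {
    sub <- df[df$roi_id == roi, ]
    sub <- sub[order(sub$time_s), ]
    if (anyDuplicated(sub$time_s))
      stop("duplicate (roi, time) pairs for ROI ", roi)
    dt <- diff(sub$time_s)
    if (length(dt) >= 2L && max(dt) - min(dt) > 1e-6 * mean(dt))
      stop("non-uniform time grid for ROI ", roi)
    out[[roi]] <- make_trace(sub$time_s, sub$fluorescence, roi)
  }
  out
}

#' Write traces to the CSV trace dialect
#'
#' @param traces A list of \code{ca_trace} objects or a \code{ca_cohort}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "ca_cohort")) traces <- traces$traces
  if (inherits(traces, "ca_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr)
    data.frame(roi_id = tr$roi_id, time_s = tr$times,
               fluorescence = tr$fluorescence, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Invert a batch of traces
#'
#' Runs one independent inversion per trace. Divergent runs are kept in
#' the output flagged as rejected; nothing is fatal per-trace. Results do
#' not depend on the order of the input traces.
#'
#' @param traces List of \code{ca_trace} objects (or a \code{ca_cohort}).
#' @param priors Prior specification, see [default_priors()].
#' @param config An [inversion_config()].
#' @return List of class \code{"batch_results"} of
#'   \code{posterior_summary} objects, named by ROI id.
#' @export
run_batch <- function(traces, priors = default_priors(),
                      config = inversion_config()) {
  if (inherits(traces, "ca_cohort")) traces <- traces$traces
  if (inherits(traces, "ca_trace")) traces <- list(traces)
  if (length(traces) == 0L) stop("no traces to invert")
  out <- lapply(traces, function(tr) {
    res <- try(invert_trace(tr, priors, config), silent = TRUE)
    if (inherits(res, "try-error")) {
      res <- structure(list(roi_id = tr$roi_id, accepted = FALSE,
                            diverged = TRUE, free_energy = numeric(0),
                            n_iterations = 0L,
                            alpha = list(shape = NA_real_, rate = NA_real_,
                                         mean = NA_real_),
                            sigma = list(shape = NA_real_, rate = NA_real_,
                                         mean = NA_real_),
                            r_squared = NA_real_),
                       class = "posterior_summary")
    }
    res
  })
  names(out) <- vapply(out, function(s) s$roi_id, character(1))
  class(out) <- "batch_results"
  out
}

#' Tabulate batch results
#'
#' One row per ROI: physical-scale posterior means and variances of the
#' free parameters, observation parameters, final free energy, precision
#' estimates, R-squared, and the acceptance flag.
#'
#' @param results A \code{batch_results} list from [run_batch()].
#' @return A data frame.
#' @export
results_table <- function(results) {
  free_names <- default_priors()$name[default_priors()$block == "kinetic"]
  rows <- lapply(results, function(s) {
    row <- data.frame(roi_id = s$roi_id, accepted = isTRUE(s$accepted),
                      diverged = isTRUE(s$diverged),
                      stringsAsFactors = FALSE)
    for (nm in free_names) {
      row[[nm]] <- if (isTRUE(s$diverged)) NA_real_ else s$physical_mean[[nm]]
      row[[paste0(nm, "_var")]] <-
        if (isTRUE(s$diverged)) NA_real_ else s$physical_var[[nm]]
    }
    row$kappa_f <- if (isTRUE(s$diverged)) NA_real_ else s$obs_mean[["kappa_f"]]
    row$d_f <- if (isTRUE(s$diverged)) NA_real_ else s$obs_mean[["d_f"]]
    row$free_energy <- if (length(s$free_energy))
      s$free_energy[length(s$free_energy)] else NA_real_
    row$alpha_hat <- s$alpha$mean
    row$sigma_hat <- s$sigma$mean
    row$r_squared <- s$r_squared
    row$n_iterations <- s$n_iterations
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise accepted inversions for one experimental group
#'
#' Across-ROI mean and standard error (sd / sqrt(n)) of the posterior
#' means of each free kinetic parameter, computed over accepted runs only.
#'
#' @param results A \code{batch_results} list, or a data frame from
#'   [results_table()].
#' @return A list of class \code{"group_summary"}: \code{stats} (data
#'   frame with parameter, mean, se, n), \code{n_accepted},
#'   \code{n_total}, \code{rejection_rate}.
#' @export
summarize_group <- function(results) {
  tab <- if (is.data.frame(results)) results else results_table(results)
  free_names <- default_priors()$name[default_priors()$block == "kinetic"]
  acc <- tab[tab$accepted, , drop = FALSE]
  if (nrow(acc) < 2L)
    stop("need at least 2 accepted inversions to summarise a group")
  stats_df <- do.call(rbind, lapply(free_names, function(nm) {
    v <- acc[[nm]]
    data.frame(parameter = nm, mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), n = length(v),
               stringsAsFactors = FALSE)
  }))
  structure(list(stats = stats_df, n_accepted = nrow(acc),
                 n_total = nrow(tab),
                 rejection_rate = 1 - nrow(acc) / nrow(tab)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group summary: %d/%d runs accepted (rejection rate %.1f%%)\n",
              x$n_accepted, x$n_total, 100 * x$rejection_rate))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided KS test of the distributions of a per-ROI parameter between
#' two groups. Uses the asymptotic p-value by default, matching the
#' group-comparison layer; set \code{exact = TRUE} for the exact
#' small-sample computation.
#'
#' @param values_a,values_b Numeric samples (each of size >= 2).
#' @param exact Logical; exact p-value computation (default asymptotic).
#' @return List of class \code{"ks_result"} with \code{statistic}
#'   (supremum ECDF distance) and \code{p_value}.
#' @export
ks_compare <- function(values_a, values_b, exact = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("both samples must have at least 2 values")
  kt <- suppressWarnings(stats::ks.test(values_a, values_b,
                                        alternative = "two.sided",
                                        exact = exact))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS: D = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Compare free-parameter distributions between two groups
#'
#' Runs [ks_compare()] per free kinetic parameter on the accepted per-ROI
#' posterior means of two batches. No multiple-testing correction is
#' applied by default (per-parameter reporting); \code{bonferroni = TRUE}
#' multiplies p-values by the number of parameters.
#'
#' @param results_a,results_b \code{batch_results} or [results_table()]
#'   data frames for the two groups.
#' @param bonferroni Logical; apply Bonferroni correction across the six
#'   parameters.
#' @return Data frame with columns \code{parameter}, \code{statistic},
#'   \code{p_value}.
#' @export
compare_groups <- function(results_a, results_b, bonferroni = FALSE) {
  ta <- if (is.data.frame(results_a)) results_a else results_table(results_a)
  tb <- if (is.data.frame(results_b)) results_b else results_table(results_b)
  ta <- ta[ta$accepted, , drop = FALSE]
  tb <- tb[tb$accepted, , drop = FALSE]
  free_names <- default_priors()$name[default_priors()$block == "kinetic"]
  out <- do.call(rbind, lapply(free_names, function(nm) {
    ks <- ks_compare(ta[[nm]], tb[[nm]])
    data.frame(parameter = nm, statistic = ks$statistic,
               p_value = ks$p_value, stringsAsFactors = FALSE)
  }))
  if (bonferroni)
    out$p_value <- pmin(1, out$p_value * length(free_names))
  out
}

#' Write or read a flat parameter/config file
#'
#' Kinetic and observation parameters serialise to a flat key-value YAML
#' mapping keyed by the model symbols.
#'
#' @param params A [kinetic_params()] or [observation_params()] object.
#' @param path File path.
#' @return For write: the path, invisibly. For read: a named list.
#' @export
write_config <- function(params, path) {
  yaml::write_yaml(as.list(unclass(params)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
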