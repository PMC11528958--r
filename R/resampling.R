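# Size-matched resampling null for comparing a diagnosis-group network
# against the all-patients cohort.
#
# The all-patients cohort is repeatedly downsampled to the diagnosis group's
# patient count; each draw is rebuilt into a sharing network (same threshold
# and isolate policy as the observed network) and summarized.  Professional
# attributes are frozen from the full cohort: subsampling changes which
# professionals clear the sharing threshold — that is the intended source of
# null variability — not who they are.

#' Uniform patient subsample of a cohort
#'
#' @param all_visits visit table for the full cohort.
#' @param n_patients number of patients to draw (without replacement).
#' @param seed integer seed.
#' @return visit table containing all visits of the sampled patients.
#' @export
sample_matched_cohort <- function(all_visits, n_patients, seed = 1L) {
  all_visits <- data.table::as.data.table(all_visits)
  patients <- sort(unique(all_visits$patient_id))
  if (n_patients > length(patients)) {
    stop("argument error: n_patients (", n_patients, ") exceeds cohort size (",
         length(patients), ")", call. = FALSE)
  }
  chosen <- with_seed(seed, sample(patients, n_patients))
  all_visits[all_visits$patient_id %in% chosen, ][]
}

#' Null distributions of network statistics under size-matched resampling
#'
#' @param all_visits visit table for the full (all-patients) cohort.
#' @param n_patients target patient count (the diagnosis group's size).
#' @param M number of resampling iterations (default 100).
#' @param seed master seed; draw m uses `derive_seed(seed, paste0("null:", m))`.
#' @param professionals frozen attribute table from [resolve_attributes()]
#'   on the full cohort.
#' @param min_shared sharing threshold tau.
#' @param keep_isolates isolate policy, must match the observed network.
#' @param statistics optional character subset of statistic names to keep
#'   (default: all computed by [network_summary()]).
#' @return object of class `null_distribution`: list with `values` (an
#'   M-row matrix, one column per statistic), `n_patients`, `M`, `seeds`.
#' @export
null_distribution <- function(all_visits, n_patients, M = 100L, seed = 1L,
                              professionals = NULL, min_shared = 5L,
                              keep_isolates = TRUE, statistics = NULL) {
  all_visits <- data.table::as.data.table(all_visits)
  seeds <- vapply(seq_len(M), function(m) derive_seed(seed, paste0("null:", m)), 0L)
  rows <- vector("list", M)
  for (m in seq_len(M)) {
    sub <- sample_matched_cohort(all_visits, n_patients, seeds[m])
    net <- project_sharing(build_bipartite(sub), min_shared = min_shared,
                           professionals = professionals,
                           keep_isolates = keep_isolates)
    v <- stats_vector(network_summary(net))
    if (!is.null(statistics)) v <- v[intersect(statistics, names(v))]
    rows[[m]] <- v
  }
  nm <- unique(unlist(lapply(rows, names)))
  values <- do.call(rbind, lapply(rows, function(v) v[nm]))
  colnames(values) <- nm
  structure(list(values = values, n_patients = n_patients, M = M, seeds = seeds),
            class = "null_distribution")
}

#' Compare an observed statistic against its resampling null
#'
#' `wilcoxon_p` is the two-sided one-sample Wilcoxon signed-rank test of the
#' differences (null values minus observed) against location zero, with
#' zero differences dropped.  `median_test_p` is the two-sided exact sign
#' test (binomial on the counts above/below the observed value) — the
#' one-sample analogue of a nonparametric median test.
#'
#' @param observed observed (diagnosis-group) statistic, finite.
#' @param null either a `null_distribution` plus `statistic` name, or a
#'   bare numeric vector of null values.
#' @param statistic column name when `null` is a `null_distribution`.
#' @return object of class `comparison_result`: list with `observed`,
#'   `null_mean`, `null_median`, `wilcoxon_p`, `median_test_p`,
#'   `degenerate` (TRUE when all differences were zero).
#' @export
compare_stat <- function(observed, null, statistic = NULL) {
  values <- if (inherits(null, "null_distribution")) {
    if (is.null(statistic)) stop("'statistic' required with a null_distribution", call. = FALSE)
    null$values[, statistic]
  } else as.numeric(null)
  values <- values[is.finite(values)]
  if (!is.finite(observed)) stop("argument error: 'observed' must be finite", call. = FALSE)
  d <- values - observed
  dnz <- d[d != 0]
  degenerate <- length(dnz) == 0L
  if (degenerate) {
    wilcoxon_p <- 1
    median_test_p <- 1
  } else {
    wilcoxon_p <- suppressWarnings(
      stats::wilcox.test(dnz, mu = 0, alternative = "two.sided")$p.value)
    median_test_p <- stats::binom.test(sum(dnz > 0), length(dnz), 0.5,
                                       alternative = "two.sided")$p.value
  }
  structure(list(observed = observed,
                 null_mean = mean(values), null_median = stats::median(values),
                 n_null = length(values),
                 wilcoxon_p = wilcoxon_p, median_test_p = median_test_p,
                 degenerate = degenerate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("observed %.4g vs null mean %.4g (median %.4g, n = %d)\n",
              x$observed, x$null_mean, x$null_median, x$n_null))
  cat(sprintf("  Wilcoxon signed-rank p = %.3g; exact sign test p = %.3g%s\n",
              x$wilcoxon_p, x$median_test_p,
              if (x$degenerate) " [degenerate: all differences zero]" else ""))
  invisible(x)
}

#' Comparison table for one diagnosis-group network
#'
#' Runs [null_distribution()] at the group's patient count and compares
#' every statistic of the observed group network to it.
#'
#' @param group_stats `network_stats` for the observed group network.
#' @param all_visits full-cohort visit table.
#' @param n_patients patient count of the group.
#' @inheritParams null_distribution
#' @return data.frame: statistic, sampled_mean, observed, wilcoxon_p,
#'   median_test_p; attribute `"null"` holds the `null_distribution`.
#' @export
comparison_table <- function(group_stats, all_visits, n_patients, M = 100L,
                             seed = 1L, professionals = NULL, min_shared = 5L,
                             keep_isolates = TRUE) {
  null <- null_distribution(all_visits, n_patients, M = M, seed = seed,
                            professionals = professionals,
                            min_shared = min_shared,
                            keep_isolates = keep_isolates)
  obs <- stats_vector(group_stats)
  stats_common <- intersect(colnames(null$values), names(obs))
  rows <- lapply(stats_common, function(s) {
    if (!is.finite(obs[[s]])) {
      return(data.frame(statistic = s, sampled_mean = mean(null$values[, s]),
                        observed = obs[[s]], wilcoxon_p = NA_real_,
                        median_test_p = NA_real_, stringsAsFactors = FALSE))
    }
    cr <- compare_stat(obs[[s]], null, s)
    data.frame(statistic = s, sampled_mean = cr$null_mean, observed = cr$observed,
               wilcoxon_p = cr$wilcoxon_p, median_test_p = cr$median_test_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "null") <- null
  out
}
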