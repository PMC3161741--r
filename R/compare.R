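#' Compute ENA indices for every sample of an ensemble
#'
#' @param spec the `fw_model` the ensemble was drawn from.
#' @param e a `fw_ensemble`.
#' @param apl_variant passed to [average_path_length()].
#' @return data.frame with one row per sample and one column per index
#'   (the elements of [ena_indices()]).
#' @export
index_ensemble <- function(spec, e, apl_variant = "net") {
  stopifnot(identical(sort(e$flow_order), sort(spec$flows$id)))
  rows <- apply(e$samples, 1L, function(xi)
    unlist(ena_indices(spec, stats::setNames(xi, e$flow_order),
                       apl_variant = apl_variant)))
  as.data.frame(t(rows))
}

# effective sample size from the initial positive sequence of the
# autocorrelation function (Geyer-style truncation)
effective_n <- function(v) {
  n <- length(v)
  if (stats::sd(v) == 0 || n < 10L) return(n)
  ac <- stats::acf(v, lag.max = min(n - 1L, 10L * ceiling(sqrt(n))),
                   plot = FALSE)$acf[-1L]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1L] - 1L)]
  max(1, n / (1 + 2 * sum(ac)))
}

#' Compare two per-sample index tables
#'
#' Reproduces the published model-comparison protocol: per index, means,
#' standard deviations, the 0.5% and 99.5% quantiles of the two
#' distributions, whether those quantile intervals overlap, a two-tailed
#' t-test on the raw draws, and the direction of the difference. The
#' t-test is applied to the Markov chain draws as-is; with
#' `ess_correct = TRUE` the degrees of freedom and standard errors use an
#' autocorrelation-based effective sample size instead (off by default, for
#' fidelity to the original protocol).
#'
#' @param tableA,tableB data.frames from [index_ensemble()] with identical
#'   columns.
#' @param probs lower/upper quantile probabilities.
#' @param ess_correct use effective sample sizes in the t-test.
#' @return data.frame of class `fw_comparison`, one row per index:
#'   `index`, `mean_A`, `mean_B`, `sd_A`, `sd_B`, `q005_A`, `q995_A`,
#'   `q005_B`, `q995_B`, `quantile_overlap`, `t_statistic`, `p_value`,
#'   `direction` (+1 when A > B).
#' @export
compare_models <- function(tableA, tableB, probs = c(0.005, 0.995),
                           ess_correct = FALSE) {
  stopifnot(nrow(tableA) > 0, nrow(tableB) > 0,
            identical(names(tableA), names(tableB)))
  rows <- lapply(names(tableA), function(ix) {
    a <- tableA[[ix]]; b <- tableB[[ix]]
    if (anyNA(a) || anyNA(b))   # index undefined on degenerate samples
      return(data.frame(index = ix, mean_A = NA_real_, mean_B = NA_real_,
                        sd_A = NA_real_, sd_B = NA_real_, q005_A = NA_real_,
                        q995_A = NA_real_, q005_B = NA_real_,
                        q995_B = NA_real_, quantile_overlap = NA,
                        t_statistic = NA_real_, p_value = NA_real_,
                        direction = NA_real_))
    qa <- stats::quantile(a, probs, names = FALSE)
    qb <- stats::quantile(b, probs, names = FALSE)
    overlap <- qa[1] <= qb[2] && qb[1] <= qa[2]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else if (ess_correct) {
      na <- effective_n(a); nb <- effective_n(b)
      se <- sqrt(stats::var(a) / na + stats::var(b) / nb)
      tstat <- (mean(a) - mean(b)) / se
      df <- se^4 / ((stats::var(a) / na)^2 / (na - 1) +
                    (stats::var(b) / nb)^2 / (nb - 1))
      tt <- list(statistic = tstat,
                 p.value = 2 * stats::pt(-abs(tstat), df))
    } else {
      # numerically constant columns (equality-pinned indices) have no
      # defined t statistic
      ht <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      tt <- if (is.null(ht)) list(statistic = NA_real_, p.value = NA_real_)
            else list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(index = ix, mean_A = mean(a), mean_B = mean(b),
               sd_A = stats::sd(a), sd_B = stats::sd(b),
               q005_A = qa[1], q995_A = qa[2],
               q005_B = qb[1], q995_B = qb[2],
               quantile_overlap = overlap,
               t_statistic = tt$statistic, p_value = tt$p.value,
               direction = sign(mean(a) - mean(b)))
  })
  structure(do.call(rbind, rows), class = c("fw_comparison", "data.frame"))
}

#' Box-plot summary numbers per index
#'
#' Median, quartiles and whiskers at 1.5 IQR (Tukey's rule, as computed by
#' [grDevices::boxplot.stats()]), emitted as numbers so plotting is
#' optional.
#'
#' @param table data.frame from [index_ensemble()].
#' @return data.frame: `index`, `whisker_low`, `q1`, `median`, `q3`,
#'   `whisker_high`, `n_outliers`.
#' @export
boxplot_summary <- function(table) {
  rows <- lapply(names(table), function(ix) {
    bs <- grDevices::boxplot.stats(table[[ix]])
    data.frame(index = ix, whisker_low = bs$stats[1], q1 = bs$stats[2],
               median = bs$stats[3], q3 = bs$stats[4],
               whisker_high = bs$stats[5], n_outliers = length(bs$out))
  })
  do.call(rbind, rows)
}

#' Write a comparison report as JSON and CSV
#'
#' @param report a `fw_comparison`.
#' @param path output path without extension; `<path>.json` and
#'   `<path>.csv` are written.
#' @return the two paths, invisibly.
#' @export
write_comparison <- function(report, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(report), js, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(js, csv))
}
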