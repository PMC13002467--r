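# Region-level biomarker decisions: a region is flagged when the central
# credible interval of its connectivity-behavior cross-covariance
# excludes zero. Intervals are per-region; no multiplicity correction is
# applied (decisions are reported with their full posterior uncertainty).

#' Summarize cross-covariance posteriors into a biomarker report
#'
#' Per region: posterior mean and central credible interval of the
#' cross-covariance draws (empirical quantiles, linear interpolation,
#' `stats::quantile` type 7), and a significance flag for intervals that
#' exclude zero.
#'
#' @param samples A `posterior_samples` object (>= 100 retained draws).
#' @param level Credible level (default 0.95).
#' @return An object of class `biomarker_report`: a data.frame with
#'   columns `region`, `posterior_mean`, `ci_low`, `ci_high`,
#'   `significant`, plus attributes `level` and `n_draws`.
#' @export
summarize_covariances <- function(samples, level = 0.95) {
  stopifnot(inherits(samples, "posterior_samples"))
  draws <- samples$cross_cov
  n <- nrow(draws)
  if (n < 100L) {
    stop("need at least 100 retained draws to summarize; have ", n)
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  rep_ <- data.frame(
    region = samples$region_labels,
    posterior_mean = colMeans(draws),
    ci_low = qs[1L, ],
    ci_high = qs[2L, ],
    stringsAsFactors = FALSE
  )
  rep_$significant <- rep_$ci_low > 0 | rep_$ci_high < 0
  structure(rep_, class = c("biomarker_report", "data.frame"),
            level = level, n_draws = n)
}

#' Power and specificity of a biomarker report against simulation truth
#'
#' Power is the fraction of true signal regions flagged significant;
#' specificity the fraction of true null regions not flagged. A component
#' with an empty denominator (no signal regions, or no null regions) is
#' returned as `NA`, never as 0/0.
#'
#' @param report A `biomarker_report`.
#' @param truth A `simulation_truth` (from [simulate_dataset()]).
#' @return Named numeric vector `c(power = , specificity = )`.
#' @export
power_specificity <- function(report, truth) {
  stopifnot(inherits(report, "biomarker_report"),
            inherits(truth, "simulation_truth"))
  V <- nrow(report)
  if (nrow(truth$true_Sigma) != V + 1L) {
    stop("report covers ", V, " regions but truth has ",
         nrow(truth$true_Sigma) - 1L)
  }
  is_signal <- seq_len(V) %in% truth$signal_regions
  flagged <- report$significant
  power <- if (any(is_signal)) mean(flagged[is_signal]) else NA_real_
  specificity <- if (any(!is_signal)) mean(!flagged[!is_signal]) else NA_real_
  c(power = power, specificity = specificity)
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("biomarker_report:", nrow(x), "regions,", sum(x$significant),
      "significant at level", attr(x, "level"),
      "(", attr(x, "n_draws"), "draws )\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a biomarker report as delimited text
#'
#' @param report A `biomarker_report`.
#' @param path Output CSV path.
#' @export
write_biomarker_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
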