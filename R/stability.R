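#' Synthetic temporal-stability fixture
#'
#' Generates weekly ROI-mean measurements of T1, T2 and ADC for each
#' tissue gel over a storage period, with stationary ground truth (zero
#' true drift) plus multiplicative Gaussian measurement noise. This is a
#' synthetic stand-in for wet-lab storage studies: it emulates
#' measurement-to-measurement scatter only, not chemistry (dehydration,
#' gel ageing), so it supports a type-I-error check of the drift test but
#' says nothing about real gel shelf life.
#'
#' @param targets Tissue target table as in [tissue_targets()].
#' @param weeks Number of weekly time points (default 12).
#' @param cv Coefficient of variation of one measurement (default 0.01,
#'   i.e. 1 %, matching the batch scatter scale of repeat preparations).
#' @param seed Integer seed.
#' @return A `stability_fixture` data.frame with columns `week`, `name`,
#'   `parameter`, `truth`, `value`.
#' @export
stability_fixture <- function(targets = tissue_targets(), weeks = 12,
                              cv = 0.01, seed = NULL) {
  stopifnot(is.data.frame(targets), weeks >= 3, cv >= 0)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    for (par in c("t1", "t2", "adc")) {
      truth <- targets[[par]][i]
      vals <- truth * (1 + stats::rnorm(weeks, 0, cv))
      rows[[length(rows) + 1L]] <- data.frame(
        week = seq_len(weeks), name = targets$name[i], parameter = par,
        truth = truth, value = vals)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stability_fixture", "data.frame")
  out
}

#' Temporal drift report
#'
#' Per gel and parameter, regresses the measured value on the week and
#' reports the linear trend with its confidence interval; drift is flagged
#' when the interval excludes zero. On a stationary fixture the flag rate
#' is the test's type-I error (5 % at the default 95 % interval).
#'
#' @param fixture A [stability_fixture()] (or any data.frame with columns
#'   `week`, `name`, `parameter`, `value`), with at least 3 time points
#'   per series.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return A `stability_report` data.frame with columns `name`,
#'   `parameter`, `slope` (units/week), `ci_lower`, `ci_upper`,
#'   `drift_flagged`.
#' @export
stability_report <- function(fixture, conf_level = 0.95) {
  stopifnot(is.data.frame(fixture),
            all(c("week", "name", "parameter", "value") %in% names(fixture)))
  rows <- list()
  for (nm in unique(fixture$name)) {
    for (par in unique(fixture$parameter)) {
      sub <- fixture[fixture$name == nm & fixture$parameter == par, ]
      if (nrow(sub) == 0) next
      if (length(unique(sub$week)) < 3) {
        stop("at least 3 time points are required per series", call. = FALSE)
      }
      fit <- stats::lm(value ~ week, data = sub)
      slope <- unname(stats::coef(fit)[2])
      if (stats::sd(sub$value) == 0) {
        # constant series: slope exactly 0, no sampling variability
        ci <- c(0, 0); slope <- 0
      } else {
        ci <- stats::confint(fit, "week", level = conf_level)[1, ]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, parameter = par, slope = slope,
        ci_lower = ci[1], ci_upper = ci[2],
        drift_flagged = ci[1] > 0 || ci[2] < 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stability_report", "data.frame")
  out
}
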