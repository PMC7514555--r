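# Monte Carlo harness: repeated simulate -> fit -> estimate/interval,
# aggregated into expected value (EV), mean squared error (MSE), average
# interval length (AL) and coverage probability (CP), each with a Monte
# Carlo standard error so scaled-down runs stay interpretable.

#' Configuration of a Monte Carlo study
#'
#' @param params true [iwd_params].
#' @param schemes list of [censoring_scheme]s.
#' @param reps replications per scheme (default 1000).
#' @param estimators character subset of `"mle"`, `"lindley"`, `"is"`.
#' @param intervals character subset of `"normal"`, `"log_normal"`,
#'   `"hpd"`.
#' @param level interval confidence/credible level.
#' @param prior a [prior_spec] for the Bayes estimators.
#' @param losses list of [loss_spec]s applied to each Bayes engine.
#' @param targets character subset of `"alpha"`, `"lambda"`, `"entropy"`.
#' @param M importance-sampling draw count per replication.
#' @param base_seed integer; replication `r` of scheme `s` runs on seed
#'   `base_seed + (s - 1) * reps + r`, so studies are reproducible and
#'   parallel-safe.
#' @param max_retries redraws allowed per replication when the MLE fails
#'   to converge before the replication is dropped.
#' @return A list of class `"pff_study_config"`.
#' @export
study_config <- function(params, schemes, reps = 1000,
                         estimators = "mle",
                         intervals = character(),
                         level = 0.95,
                         prior = prior_spec(1, 1),
                         losses = list(loss_spec("self")),
                         targets = c("alpha", "lambda", "entropy"),
                         M = 5000,
                         base_seed = 1,
                         max_retries = 5L) {
  stopifnot(inherits(params, "iwd_params"), length(schemes) >= 1,
            all(vapply(schemes, inherits, TRUE, "pff_scheme")),
            reps >= 1)
  estimators <- match.arg(estimators, c("mle", "lindley", "is"),
                          several.ok = TRUE)
  if (length(intervals)) {
    intervals <- match.arg(intervals, c("normal", "log_normal", "hpd"),
                           several.ok = TRUE)
  }
  targets <- match.arg(targets, c("alpha", "lambda", "entropy"),
                       several.ok = TRUE)
  structure(list(params = params, schemes = schemes, reps = reps,
                 estimators = estimators, intervals = intervals,
                 level = level, prior = prior, losses = losses,
                 targets = targets, M = M, base_seed = base_seed,
                 max_retries = max_retries),
            class = "pff_study_config")
}

.loss_label <- function(loss) {
  switch(loss$kind,
         self = "self",
         linex = sprintf("linex(p=%g)", loss$p),
         gelf = sprintf("gelf(q=%g)", loss$q))
}

#' Run a Monte Carlo study
#'
#' For each replication: simulate a censored sample at the true
#' parameters, fit the MLE, then evaluate every requested estimator and
#' interval.  Point estimators are aggregated into EV and MSE against the
#' truth; intervals into AL (mean width) and CP (fraction covering the
#' truth).  Non-convergent replications are redrawn up to
#' `max_retries` times, then dropped (the drop rate is reported).
#'
#' @param cfg a [study_config].
#' @return A list of class `"pff_study"` with data frames `estimates`
#'   (scheme, estimator, target, EV, MSE, their MC standard errors, reps
#'   used) and `intervals` (scheme, method, target, AL, CP, MC standard
#'   errors), plus the truth used.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "pff_study_config"))
  truth <- c(alpha = cfg$params$alpha, lambda = cfg$params$lambda,
             entropy = iwd_entropy(cfg$params))
  est_rows <- list()
  int_rows <- list()
  drop_rate <- numeric(length(cfg$schemes))
  for (si in seq_along(cfg$schemes)) {
    sc <- cfg$schemes[[si]]
    label <- sprintf("k=%d n=%d m=%d %s", sc$k, sc$n, sc$m,
                     format_scheme(sc$R))
    est_acc <- list()   # estimator -> target -> vector of estimates
    int_acc <- list()   # method -> target -> list(len, cover vectors)
    used <- 0L
    dropped <- 0L
    for (r in seq_len(cfg$reps)) {
      seed0 <- cfg$base_seed + (si - 1L) * cfg$reps + r
      fit <- NULL
      for (attempt in 0:cfg$max_retries) {
        s <- simulate_pff(sc, cfg$params,
                          seed = seed0 + attempt * 1000003L)
        f <- tryCatch(fit_iwd(s), error = function(e) NULL)
        if (!is.null(f) && f$converged) {
          fit <- f
          break
        }
      }
      if (is.null(fit)) {
        dropped <- dropped + 1L
        next
      }
      used <- used + 1L
      draws <- NULL
      if ("is" %in% cfg$estimators || "hpd" %in% cfg$intervals) {
        draws <- draw_posterior(fit$sample, cfg$prior, M = cfg$M,
                                seed = seed0 + 500009L)
      }
      for (est in cfg$estimators) {
        if (est == "mle") {
          vals <- coef(fit)[cfg$targets]
          est_acc <- .acc_est(est_acc, "mle", vals)
        } else if (est == "lindley") {
          for (loss in cfg$losses) {
            vals <- tryCatch(
              lindley_estimate(fit, cfg$prior, loss, cfg$targets),
              error = function(e) setNames(rep(NA_real_,
                                               length(cfg$targets)),
                                           cfg$targets))
            est_acc <- .acc_est(est_acc,
                                paste0("lindley:", .loss_label(loss)), vals)
          }
        } else {
          for (loss in cfg$losses) {
            vals <- tryCatch(
              is_estimate(draws, loss, cfg$targets),
              error = function(e) setNames(rep(NA_real_,
                                               length(cfg$targets)),
                                           cfg$targets))
            est_acc <- .acc_est(est_acc, paste0("is:", .loss_label(loss)),
                                vals)
          }
        }
      }
      for (mth in cfg$intervals) {
        for (tg in cfg$targets) {
          ci <- tryCatch(switch(mth,
            normal = ci_normal(fit, tg, cfg$level),
            log_normal = ci_lognormal(fit, tg, cfg$level),
            hpd = hpd_interval(draws, tg, cfg$level)),
            error = function(e) NULL)
          if (is.null(ci)) next
          key <- paste0(mth, "|", tg)
          int_acc[[key]]$len <- c(int_acc[[key]]$len, ci$upper - ci$lower)
          int_acc[[key]]$cov <- c(int_acc[[key]]$cov,
                                  ci$lower <= truth[tg] &&
                                    truth[tg] <= ci$upper)
        }
      }
    }
    for (ename in names(est_acc)) {
      for (tg in names(est_acc[[ename]])) {
        v <- est_acc[[ename]][[tg]]
        v <- v[is.finite(v)]
        sqd <- (v - truth[tg])^2
        est_rows[[length(est_rows) + 1L]] <- data.frame(
          scheme = label, estimator = ename, target = tg,
          EV = mean(v), EV_se = stats::sd(v) / sqrt(length(v)),
          MSE = mean(sqd), MSE_se = stats::sd(sqd) / sqrt(length(v)),
          reps = length(v))
      }
    }
    for (key in names(int_acc)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      len <- int_acc[[key]]$len
      cov <- as.numeric(int_acc[[key]]$cov)
      int_rows[[length(int_rows) + 1L]] <- data.frame(
        scheme = label, method = parts[1], target = parts[2],
        AL = mean(len), AL_se = stats::sd(len) / sqrt(length(len)),
        CP = mean(cov), CP_se = sqrt(mean(cov) * (1 - mean(cov)) /
                                       length(cov)),
        reps = length(cov))
    }
    if (used == 0L) {
      stop(sprintf("all replications failed for scheme %s", label))
    }
    drop_rate[si] <- dropped / cfg$reps
  }
  structure(list(
    estimates = if (length(est_rows)) do.call(rbind, est_rows) else NULL,
    intervals = if (length(int_rows)) do.call(rbind, int_rows) else NULL,
    drop_rate = drop_rate,
    truth = truth, config = cfg), class = "pff_study")
}

.acc_est <- function(acc, name, vals) {
  for (tg in names(vals)) {
    acc[[name]][[tg]] <- c(acc[[name]][[tg]], vals[[tg]])
  }
  acc
}

#' @export
print.pff_study <- function(x, ...) {
  cat("Monte Carlo study,", x$config$reps, "replications per scheme\n")
  cat(sprintf("truth: alpha = %g, lambda = %g, entropy = %.6f\n",
              x$truth["alpha"], x$truth["lambda"], x$truth["entropy"]))
  if (!is.null(x$estimates)) {
    cat("\nPoint estimators (EV / MSE):\n")
    print(x$estimates, digits = 4, row.names = FALSE)
  }
  if (!is.null(x$intervals)) {
    cat("\nIntervals (AL / CP):\n")
    print(x$intervals, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Render study results as aligned text or CSV
#'
#' @param study a [run_study] result.
#' @param file optional path; when given, the estimator and interval
#'   tables are written as CSV files `<file>_estimates.csv` and
#'   `<file>_intervals.csv`.
#' @return The character representation, invisibly when writing files.
#' @export
render_tables <- function(study, file = NULL) {
  stopifnot(inherits(study, "pff_study"))
  out <- utils::capture.output(print(study))
  if (!is.null(file)) {
    if (!is.null(study$estimates)) {
      write.table(study$estimates, paste0(file, "_estimates.csv"),
                  sep = ",", row.names = FALSE, quote = TRUE)
    }
    if (!is.null(study$intervals)) {
      write.table(study$intervals, paste0(file, "_intervals.csv"),
                  sep = ",", row.names = FALSE, quote = TRUE)
    }
    return(invisible(out))
  }
  out
}
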