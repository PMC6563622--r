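#' Draw true item parameters from the generating distributions
#'
#' Discriminations are lognormal, \eqn{a \sim \log N(0, 0.25)} (0.25 being
#' the standard deviation of \eqn{\log a}), and easiness intercepts follow
#' a normal distribution \eqn{d \sim N(0, 1.5)} truncated to
#' \eqn{(-2.5, 2.5)} by rejection sampling (no boundary atoms). Whether the
#' second parameters denote standard deviations or variances is
#' configurable; standard deviations are the default.
#'
#' @param n number of items.
#' @param sdlog standard deviation of \eqn{\log a}.
#' @param d_sd standard deviation of the untruncated easiness distribution.
#' @param d_range truncation interval for \code{d}.
#' @param scale_is_sd set \code{FALSE} to interpret \code{sdlog} and
#'   \code{d_sd} as variances instead.
#' @param seed optional seed.
#' @return data frame with columns \code{a}, \code{d}.
#' @export
draw_item_parameters <- function(n, sdlog = 0.25, d_sd = 1.5,
                                 d_range = c(-2.5, 2.5),
                                 scale_is_sd = TRUE, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (!scale_is_sd) { sdlog <- sqrt(sdlog); d_sd <- sqrt(d_sd) }
  a <- stats::rlnorm(n, 0, sdlog)
  d <- numeric(0)
  while (length(d) < n) {
    cand <- stats::rnorm(n, 0, d_sd)
    d <- c(d, cand[cand > d_range[1] & cand < d_range[2]])
  }
  data.frame(a = a, d = d[seq_len(n)])
}

#' Ability drift across test cycles
#'
#' In the first test cycle abilities are standard normal. In every later
#' cycle the population mean is drawn from \code{means} and the standard
#' deviation from \code{sds} (independently, uniformly over the listed
#' values, fresh each cycle), emulating examinee cohorts that differ
#' between test cycles.
#'
#' @param means,sds candidate values of the cycle mean and SD.
#' @return a list of class \code{ability_drift_model}.
#' @export
ability_drift_model <- function(means = c(-0.5, 0, 0.5),
                                sds = c(0.7, 1.0, 1.3)) {
  structure(list(means = means, sds = sds), class = "ability_drift_model")
}

#' Draw true abilities for one test cycle
#'
#' @param n number of examinees.
#' @param cycle cycle index (1 = initial phase, standard normal).
#' @param drift an \code{\link{ability_drift_model}}.
#' @param seed optional seed.
#' @return numeric vector of abilities.
#' @export
draw_abilities <- function(n, cycle, drift = ability_drift_model(),
                           seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (cycle <= 1L) return(stats::rnorm(n))
  mu <- resample(drift$means, 1L)
  sg <- resample(drift$sds, 1L)
  stats::rnorm(n, mu, sg)
}

#' True transformation constants from generated abilities
#'
#' The reference values the estimated constants are judged against:
#' \eqn{A_t = \sigma(\theta_t) / \sigma(\theta_p)} and
#' \eqn{B_t = \mu(\theta_t) - A_t \mu(\theta_p)}, computed on the true
#' generated abilities of the current cycle (\eqn{\theta_t}) and of all
#' previous cycles pooled (\eqn{\theta_p}).
#'
#' @param theta_previous pooled true abilities of all prior cycles.
#' @param theta_current true abilities of the current cycle.
#' @return \code{\link{link_constants}} with method \code{"true"}.
#' @export
true_constants <- function(theta_previous, theta_current) {
  if (length(theta_previous) < 2L || length(theta_current) < 2L)
    stop("need at least two abilities on each side")
  sp <- stats::sd(theta_previous)
  if (sp == 0) stop("degenerate ability distribution: zero SD")
  A <- stats::sd(theta_current) / sp
  link_constants(A, mean(theta_current) - A * mean(theta_previous), "true")
}

#' Signed errors of estimated transformation constants
#'
#' \eqn{Error(A) = \hat A - A}, \eqn{Error(B) = \hat B - B}; their averages
#' over replications are the bias of the constants. Only defined for
#' feasible equatings.
#'
#' @param estimated,true \code{\link{link_constants}}.
#' @return named numeric vector \code{c(error_A, error_B)}.
#' @export
error_constants <- function(estimated, true) {
  c(error_A = estimated$A - true$A, error_B = estimated$B - true$B)
}

#' The seven easiness intervals for conditional precision
#'
#' Breaks partitioning the easiness line into
#' \eqn{(-\infty,-2], (-2,-1], (-1,-0.25], (-0.25,0.25], (0.25,1], (1,2],
#' (2,\infty)}.
#'
#' @return numeric vector of interval breaks.
#' @export
easiness_breaks <- function() c(-Inf, -2, -1, -0.25, 0.25, 1, 2, Inf)

#' Conditional mean squared error of item parameter estimates
#'
#' MSE of the discrimination and easiness estimates within bins of the
#' TRUE easiness, averaged over replications and member items. Bins with
#' no member items are absent from the result, not reported as zero.
#'
#' @param records data frame with columns \code{a_true}, \code{d_true},
#'   \code{a_est}, \code{d_est} (one row per item and replication).
#' @param breaks interval breaks (default \code{\link{easiness_breaks}}).
#' @return data frame with columns \code{bin} (label), \code{n},
#'   \code{mse_a}, \code{mse_d}; the attribute \code{"overall"} holds the
#'   membership-weighted overall MSEs.
#' @export
conditional_mse <- function(records, breaks = easiness_breaks()) {
  bin <- cut(records$d_true, breaks = breaks)
  se_a <- (records$a_est - records$a_true)^2
  se_d <- (records$d_est - records$d_true)^2
  keep <- !is.na(bin)
  agg <- data.frame(bin = levels(bin),
                    n = as.vector(table(bin[keep])),
                    mse_a = as.vector(tapply(se_a[keep], bin[keep], mean)),
                    mse_d = as.vector(tapply(se_d[keep], bin[keep], mean)))
  agg <- agg[agg$n > 0, , drop = FALSE]
  attr(agg, "overall") <- c(mse_a = mean(se_a), mse_d = mean(se_d))
  agg
}

#' Factorial design of the equating-setup evaluation
#'
#' Fully crossed grid of common-item difficulty distribution (3), scale
#' transformation method (4) and sample size per test cycle (3) - 36
#' conditions at the default levels - each run for a number of independent
#' CCS replications of 10 test cycles.
#'
#' @param distributions common-item difficulty distributions.
#' @param methods scale transformation methods.
#' @param sample_sizes examinees per test cycle.
#' @param replications replications per condition (200 at full scale).
#' @param cycles test cycles per replication.
#' @return object of class \code{ccs_design}: the condition grid plus
#'   design metadata.
#' @export
ccs_design <- function(distributions = c("bimodal", "normal", "uniform"),
                       methods = c("mean_mean", "mean_sigma", "haebara",
                                   "stocking_lord"),
                       sample_sizes = c(50, 100, 300),
                       replications = 200, cycles = 10) {
  grid <- expand.grid(distribution = distributions, method = methods,
                      sample_size = sample_sizes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$condition <- seq_len(nrow(grid))
  structure(list(conditions = grid[, c("condition", "distribution",
                                       "method", "sample_size")],
                 replications = replications, cycles = cycles),
            class = "ccs_design")
}

#' @export
print.ccs_design <- function(x, ...) {
  cat(sprintf("CCS evaluation design: %d conditions x %d replications, %d cycles\n",
              nrow(x$conditions), x$replications, x$cycles))
  invisible(x)
}

#' Run the Monte Carlo evaluation of equating setups
#'
#' For every condition and replication, runs a complete no-drift CCS
#' (\code{\link{run_ccs}}) and collects the evaluation criteria: per-cycle
#' equating feasibility, retained and drifted common-item counts, errors of
#' the transformation constants against their true values, and the
#' conditional MSE of the item parameter estimates after each cycle.
#' Child seeds are derived from the master seed per (condition,
#' replication) upfront, so results are reproducible and independent of
#' execution order.
#'
#' @param design a \code{\link{ccs_design}}.
#' @param seed master seed.
#' @param mse_cycles cycles at which item-parameter records are kept for
#'   the conditional MSE (default: all continuous-phase cycles).
#' @param verbose print progress.
#' @return object of class \code{ccs_study}: \code{design},
#'   \code{cycle_metrics} (long data frame over condition, replication and
#'   cycle), \code{bin_stats} (squared-error sums per condition, cycle and
#'   easiness bin), \code{failures}, and \code{run_meta}.
#' @export
run_study <- function(design = ccs_design(), seed = 1,
                      mse_cycles = NULL, verbose = FALSE) {
  conds <- design$conditions
  R <- design$replications
  set.seed(seed)
  child <- matrix(sample.int(.Machine$integer.max - 1L, nrow(conds) * R),
                  nrow(conds), R)
  metrics <- list()
  bins <- list()
  failures <- list()
  t0 <- Sys.time()
  breaks <- easiness_breaks()
  labs <- levels(cut(0, breaks))
  for (ci in seq_len(nrow(conds))) {
    for (r in seq_len(R)) {
      res <- tryCatch({
        run <- run_ccs(n_cycles = design$cycles,
                       n_examinees = conds$sample_size[ci],
                       method = conds$method[ci],
                       scheme = conds$distribution[ci],
                       seed = child[ci, r])
        ev <- evaluate_run(run)
        ev$condition <- conds$condition[ci]
        ev$replication <- r
        keep <- if (is.null(mse_cycles)) ev$cycle else mse_cycles
        bs <- do.call(rbind, lapply(run$state$cycles, function(cc) {
          if (!(cc$cycle %in% keep)) return(NULL)
          b <- cc$bank_snapshot
          bin <- cut(b$d_true, breaks = breaks)
          data.frame(condition = conds$condition[ci], cycle = cc$cycle,
                     bin = levels(bin),
                     sse_a = as.vector(tapply((b$a_est - b$a_true)^2, bin,
                                              sum, default = 0)),
                     sse_d = as.vector(tapply((b$d_est - b$d_true)^2, bin,
                                              sum, default = 0)),
                     n = as.vector(table(bin)))
        }))
        list(ev = ev, bs = bs)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(condition = conds$condition[ci], replication = r,
                     message = conditionMessage(res))
        next
      }
      metrics[[length(metrics) + 1L]] <- res$ev
      bins[[length(bins) + 1L]] <- res$bs
    }
    if (verbose)
      message(sprintf("condition %d/%d done (%.1f s elapsed)", ci,
                      nrow(conds),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  cycle_metrics <- do.call(rbind, metrics)
  bin_stats <- do.call(rbind, bins)
  if (!is.null(bin_stats)) {
    agg <- stats::aggregate(cbind(sse_a, sse_d, n) ~ condition + cycle + bin,
                            data = bin_stats, FUN = sum)
    agg$bin <- factor(agg$bin, levels = labs)
    agg <- agg[agg$n > 0, , drop = FALSE]   # empty bins are absent, not zero
    bin_stats <- agg[order(agg$condition, agg$cycle, agg$bin), ]
    bin_stats$mse_a <- bin_stats$sse_a / bin_stats$n
    bin_stats$mse_d <- bin_stats$sse_d / bin_stats$n
  }
  structure(list(design = design, cycle_metrics = cycle_metrics,
                 bin_stats = bin_stats,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 run_meta = list(seed = seed,
                                 elapsed_s = as.numeric(
                                   difftime(Sys.time(), t0, units = "secs")))),
            class = "ccs_study")
}

#' @export
print.ccs_study <- function(x, ...) {
  print(x$design)
  cat(sprintf("  %d cycle records collected in %.1f s; %d failed replication(s)\n",
              if (is.null(x$cycle_metrics)) 0L else nrow(x$cycle_metrics),
              x$run_meta$elapsed_s,
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  invisible(x)
}

#' Per-condition summary of the evaluation criteria
#'
#' @param object a \code{ccs_study}.
#' @param feasible_min retained-item count above which a cycle's equating
#'   counts as feasible for the reported percentage (2 = the breakdown
#'   rule; 10 = the stricter screen discussed for operational use).
#' @param ... unused.
#' @return data frame with one row per condition: proportion of feasible
#'   equatings, median retained common items, proportion of drifted items,
#'   and bias (mean error) of the constants A and B.
#' @export
summary.ccs_study <- function(object, feasible_min = 2, ...) {
  cm <- object$cycle_metrics
  conds <- object$design$conditions
  out <- do.call(rbind, lapply(conds$condition, function(ci) {
    m <- cm[cm$condition == ci, , drop = FALSE]
    data.frame(condition = ci,
               prop_feasible = mean(m$n_retained >= feasible_min),
               median_retained = stats::median(m$n_retained),
               prop_drifted = sum(m$n_drifted) / sum(m$n_common),
               bias_A = mean(m$error_A, na.rm = TRUE),
               bias_B = mean(m$error_B, na.rm = TRUE),
               sd_error_A = stats::sd(m$error_A, na.rm = TRUE),
               sd_error_B = stats::sd(m$error_B, na.rm = TRUE))
  }))
  merge(conds, out, by = "condition")
}
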