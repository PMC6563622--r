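# sample() that never interprets a length-1 vector as 1:n
resample <- function(x, size) x[sample.int(length(x), size)]

#' Select the linking-cluster common items
#'
#' Draws \code{n} common items from the eligible pool (items calibrated in
#' previous cycles that were not common in the immediately preceding cycle)
#' so that their easiness distribution follows the requested shape.
#' Categories are computed from the current base-scale easiness estimates:
#' \describe{
#'   \item{normal}{five ordinal categories (cut at the 2/15, 5/15, 10/15
#'     and 13/15 quantiles) with 2, 3, 5, 3, 2 items drawn from them.}
#'   \item{uniform}{15 equal-probability quantile bins, one item from each.}
#'   \item{bimodal}{the 11 easiest and the 11 hardest eligible items form
#'     two subsamples; 7 are drawn from one and 8 from the other, the
#'     direction decided by a fair coin.}
#' }
#'
#' @param eligible data frame with columns \code{id} and \code{d_est}.
#' @param scheme \code{"normal"}, \code{"uniform"} or \code{"bimodal"}.
#' @param n number of common items (default 15; fixed for the quantile
#'   patterns above).
#' @return vector of \code{n} selected item ids.
#' @export
select_common_items <- function(eligible, scheme = c("normal", "uniform",
                                                     "bimodal"), n = 15) {
  scheme <- match.arg(scheme)
  need <- if (scheme == "bimodal") 22L else n
  if (nrow(eligible) < need)
    stop("not enough eligible items for the ", scheme, " scheme")
  d <- eligible$d_est
  if (scheme == "normal") {
    qs <- stats::quantile(d, c(2, 5, 10, 13) / 15, names = FALSE)
    cat5 <- cut(d, breaks = c(-Inf, qs, Inf), labels = FALSE)
    counts <- c(2L, 3L, 5L, 3L, 2L)
    picked <- unlist(lapply(1:5, function(k) {
      ids <- eligible$id[cat5 == k]
      if (length(ids) < counts[k])
        stop("category ", k, " has too few eligible items")
      resample(ids, counts[k])
    }))
  } else if (scheme == "uniform") {
    qs <- stats::quantile(d, seq(0, 1, length.out = n + 1), names = FALSE)
    bin <- cut(d, breaks = qs, labels = FALSE, include.lowest = TRUE)
    picked <- vapply(seq_len(n), function(k) {
      ids <- eligible$id[bin == k]
      if (length(ids) == 0L) stop("empty quantile bin in uniform scheme")
      resample(ids, 1L)
    }, eligible$id[1])
  } else {
    ord <- order(d)
    hardest <- eligible$id[ord[1:11]]          # lowest easiness
    easiest <- eligible$id[ord[(length(d) - 10):length(d)]]
    n_easy <- if (stats::runif(1) < 0.5) 7L else 8L
    picked <- c(resample(easiest, n_easy), resample(hardest, n - n_easy))
  }
  picked
}

#' Run the initial (non-adaptive) phase of the CCS
#'
#' The first test cycle: 60 freshly written items are administered to all
#' examinees, calibrated by MML, and the resulting estimates define the
#' base scale (lineage 0) that the continuous phase maintains.
#'
#' @param n_examinees sample size of the first cycle.
#' @param blueprint a \code{\link{test_blueprint}}.
#' @param items optional data frame \code{id}, \code{a}, \code{d} of true
#'   generating parameters (drawn from the generating distributions when
#'   omitted).
#' @param theta optional true abilities (standard normal draws when
#'   omitted).
#' @param seed optional seed.
#' @return a \code{ccs_state} list: \code{bank} (item records), \code{vcov}
#'   (per-item estimate covariances), \code{lineage}, per-cycle response
#'   matrices, true abilities and person estimates.
#' @export
run_initial_phase <- function(n_examinees, blueprint = test_blueprint(),
                              items = NULL, theta = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(items)) {
    items <- draw_item_parameters(blueprint$test_length)
    items$id <- seq_len(blueprint$test_length)
  }
  if (is.null(theta)) theta <- stats::rnorm(n_examinees)
  u <- administer_initial_phase(theta, items, blueprint$test_length)
  fit <- calibrate_2pl(u)
  bank <- data.frame(id = items$id, a_true = items$a, d_true = items$d,
                     a_est = fit$est$a, d_est = fit$est$d,
                     cycle_introduced = 1L, common_last = FALSE,
                     stringsAsFactors = FALSE)
  persons <- map_ability(u, data.frame(a = fit$est$a, d = fit$est$d))
  structure(list(bank = bank, vcov = fit$vcov,
                 joint_info = fit$joint_info, joint_ids = fit$joint_ids,
                 lineage = 0L,
                 responses = list(u), thetas = list(theta),
                 person_est = list(persons), blueprint = blueprint,
                 next_id = max(items$id) + 1L, cycles = list()),
            class = "ccs_state")
}

#' Run one continuous-phase test cycle
#'
#' Executes the seven steps of a CCS cycle: (1) common-item selection,
#' (2) test assembly and administration, (3) temporary item parameter
#' estimation on the cycle's responses, (4) scale transformation of the
#' common items onto the base scale, (5) drift detection with iterative
#' purification, (6) FCIP calibration on the cumulative responses with the
#' retained common items anchored at their base-scale values (or, on a
#' breakdown, a concurrent recalibration that starts a new scale lineage),
#' and (7) person parameter estimation. Twenty brand-new items enter the
#' bank, so the pool grows to \eqn{60 + (t - 1) \cdot 20} items after
#' cycle \eqn{t}.
#'
#' @param state a \code{ccs_state} from \code{\link{run_initial_phase}} or a
#'   previous \code{run_cycle}.
#' @param cycle cycle index (2, 3, ...).
#' @param n_examinees sample size of this cycle.
#' @param method scale-transformation method (see
#'   \code{\link{estimate_link}}).
#' @param scheme common-item difficulty distribution (see
#'   \code{\link{select_common_items}}).
#' @param alpha drift-test significance level.
#' @param drift ability drift model (see \code{\link{ability_drift_model}}).
#' @param new_items,theta optional true parameters of the 20 new items and
#'   true abilities (drawn when omitted).
#' @return the updated \code{ccs_state}; the cycle's record is appended to
#'   \code{state$cycles}.
#' @export
run_cycle <- function(state, cycle, n_examinees, method, scheme,
                      alpha = 0.05, drift = ability_drift_model(),
                      new_items = NULL, theta = NULL) {
  bp <- state$blueprint
  bank <- state$bank

  # (1) common item selection
  eligible <- bank[!bank$common_last, c("id", "d_est")]
  common_ids <- select_common_items(eligible, scheme, bp$n_linking)
  linking <- bank[match(common_ids, bank$id),
                  c("id", "a_true", "d_true", "a_est", "d_est")]

  # (2) test assembly and administration
  if (is.null(new_items)) {
    new_items <- draw_item_parameters(bp$n_calibration)
    new_items$id <- state$next_id + seq_len(bp$n_calibration) - 1L
  }
  if (is.null(theta)) theta <- draw_abilities(n_examinees, cycle, drift)
  calibration <- data.frame(id = new_items$id, a_true = new_items$a,
                            d_true = new_items$d)
  pool <- bank[!(bank$id %in% common_ids),
               c("id", "a_true", "d_true", "a_est", "d_est")]
  adm <- administer_cycle(theta, linking, calibration, pool, bp)

  # (3) temporary item parameter estimation (all items of this cycle)
  known <- match(colnames(adm$responses), as.character(bank$id))
  start <- data.frame(id = colnames(adm$responses)[!is.na(known)],
                      a = bank$a_est[known[!is.na(known)]],
                      d = bank$d_est[known[!is.na(known)]])
  temp <- calibrate_2pl(adm$responses, start = start)

  # (4)+(5) scale transformation and drift purification
  ti <- match(as.character(common_ids), temp$est$id)
  bi <- match(common_ids, bank$id)
  pairs <- common_item_pairs(common_ids,
                             a_l = bank$a_est[bi], d_l = bank$d_est[bi],
                             a_k = temp$est$a[ti], d_k = temp$est$d[ti],
                             cov_l = state$vcov[as.character(bank$id[bi])],
                             cov_k = temp$vcov[ti])
  outcome <- purify(pairs, method, alpha)

  # (6) FCIP calibration (or concurrent recalibration on breakdown)
  all_resp <- c(state$responses, list(adm$responses))
  newbank <- rbind(bank,
                   data.frame(id = calibration$id, a_true = calibration$a_true,
                              d_true = calibration$d_true,
                              a_est = NA_real_, d_est = NA_real_,
                              cycle_introduced = cycle, common_last = FALSE))
  warm <- data.frame(id = bank$id, a = bank$a_est, d = bank$d_est)
  if (outcome$feasible) {
    # warm-start new items from their transformed temporary estimates
    ni <- match(as.character(calibration$id), temp$est$id)
    tr <- transform_items(data.frame(a = temp$est$a[ni], d = temp$est$d[ni]),
                          outcome$constants)
    warm <- rbind(warm, data.frame(id = calibration$id,
                                   a = pmin(pmax(tr$a, -1), 5),
                                   d = pmin(pmax(tr$d, -5), 5)))
    anchors <- data.frame(id = outcome$retained,
                          a = bank$a_est[match(outcome$retained, bank$id)],
                          d = bank$d_est[match(outcome$retained, bank$id)])
    fit <- calibrate_2pl(stack_responses(all_resp), fixed = anchors,
                         start = warm)
  } else {
    fit <- concurrent_calibrate(all_resp, start = warm)
    state$lineage <- state$lineage + 1L
  }
  fi <- match(as.character(newbank$id), fit$est$id)
  newbank$a_est <- fit$est$a[fi]
  newbank$d_est <- fit$est$d[fi]
  newbank$common_last <- newbank$id %in% common_ids
  state$vcov <- fit$vcov[fi]
  names(state$vcov) <- as.character(newbank$id)
  state$joint_info <- fit$joint_info
  state$joint_ids <- fit$joint_ids

  # (7) person parameter estimation on the final base-scale estimates
  persons <- estimate_persons(adm$responses, newbank)

  state$bank <- newbank
  state$responses <- all_resp
  state$thetas <- c(state$thetas, list(theta))
  state$person_est <- c(state$person_est, list(persons))
  state$next_id <- max(newbank$id) + 1L
  state$cycles[[length(state$cycles) + 1L]] <-
    list(cycle = cycle, common_ids = common_ids, new_ids = calibration$id,
         equating = outcome, theta_true = theta, person_est = persons,
         pool_size = nrow(newbank),
         bank_snapshot = newbank[, c("id", "a_true", "d_true",
                                     "a_est", "d_est")],
         lineage = state$lineage)
  state
}

#' MAP person estimates from the calibrated bank
#'
#' @param responses persons x items response matrix (columns named by item
#'   id); examinees with no observed responses are dropped with a warning.
#' @param bank item bank data frame with \code{id}, \code{a_est},
#'   \code{d_est}.
#' @return numeric vector of MAP ability estimates (NA for dropped rows).
#' @export
estimate_persons <- function(responses, bank) {
  j <- match(colnames(responses), as.character(bank$id))
  if (anyNA(j)) stop("responses contain items missing from the bank")
  items <- data.frame(a = bank$a_est[j], d = bank$d_est[j])
  none <- rowSums(!is.na(responses)) == 0L
  out <- rep(NA_real_, nrow(responses))
  if (any(none))
    warning(sum(none), " examinee(s) with no observed responses excluded")
  if (any(!none))
    out[!none] <- map_ability(responses[!none, , drop = FALSE], items)
  out
}

#' Run a complete continuous calibration strategy
#'
#' One replication of the CCS: the initial phase followed by
#' \code{n_cycles - 1} continuous-phase cycles under a fixed equating setup
#' (common-item difficulty scheme, scale-transformation method, sample size
#' per cycle).
#'
#' @param n_cycles total number of test cycles including the initial phase.
#' @param n_examinees examinees per test cycle.
#' @param method scale-transformation method.
#' @param scheme common-item difficulty distribution.
#' @param alpha drift-test significance level.
#' @param drift ability drift model for cycles 2+.
#' @param blueprint a \code{\link{test_blueprint}}.
#' @param seed optional seed (one seed reproduces the whole replication).
#' @return object of class \code{ccs_run}: the final \code{ccs_state} plus
#'   the run configuration.
#' @examples
#' \donttest{
#' run <- run_ccs(n_cycles = 3, n_examinees = 50,
#'                method = "stocking_lord", scheme = "normal", seed = 1)
#' summary(run)
#' }
#' @export
run_ccs <- function(n_cycles = 10, n_examinees = 100,
                    method = c("mean_mean", "mean_sigma", "haebara",
                               "stocking_lord"),
                    scheme = c("normal", "uniform", "bimodal"),
                    alpha = 0.05, drift = ability_drift_model(),
                    blueprint = test_blueprint(), seed = NULL) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  state <- run_initial_phase(n_examinees, blueprint)
  for (t in seq_len(n_cycles - 1L) + 1L)
    state <- run_cycle(state, t, n_examinees, method, scheme, alpha, drift)
  structure(list(state = state, n_cycles = n_cycles,
                 n_examinees = n_examinees, method = method,
                 scheme = scheme, alpha = alpha, seed = seed),
            class = "ccs_run")
}

#' @export
print.ccs_run <- function(x, ...) {
  cat(sprintf("CCS run: %d cycles, N = %d per cycle, %s / %s scheme\n",
              x$n_cycles, x$n_examinees, x$method, x$scheme))
  cat(sprintf("  final pool: %d items, scale lineage %d\n",
              nrow(x$state$bank), x$state$lineage))
  feas <- vapply(x$state$cycles, function(cc) cc$equating$feasible, FALSE)
  cat(sprintf("  feasible equatings: %d/%d\n", sum(feas), length(feas)))
  invisible(x)
}

#' Per-cycle evaluation of one CCS run
#'
#' Tabulates, for every continuous-phase cycle: equating feasibility, the
#' numbers of retained and drifted common items, the estimated
#' transformation constants, the true constants computed from the true
#' generated abilities (pooled previous cycles vs. current cycle), and
#' their signed errors (only defined when the equating was feasible).
#'
#' @param run a \code{ccs_run}.
#' @return data frame with one row per continuous-phase cycle.
#' @export
evaluate_run <- function(run) {
  st <- run$state
  rows <- lapply(st$cycles, function(cc) {
    t <- cc$cycle
    theta_p <- unlist(st$thetas[seq_len(t - 1L)])
    tc <- true_constants(theta_p, st$thetas[[t]])
    eq <- cc$equating
    A_hat <- if (eq$feasible) eq$constants$A else NA_real_
    B_hat <- if (eq$feasible) eq$constants$B else NA_real_
    data.frame(cycle = t, feasible = eq$feasible,
               n_common = eq$n_items, n_retained = length(eq$retained),
               n_drifted = nrow(eq$drifted),
               A_hat = A_hat, B_hat = B_hat, A_true = tc$A, B_true = tc$B,
               error_A = A_hat - tc$A, error_B = B_hat - tc$B,
               pool_size = cc$pool_size, lineage = cc$lineage)
  })
  do.call(rbind, rows)
}

#' @export
summary.ccs_run <- function(object, ...) {
  ev <- evaluate_run(object)
  bank <- object$state$bank
  structure(list(cycles = ev,
                 mse_a = mean((bank$a_est - bank$a_true)^2),
                 mse_d = mean((bank$d_est - bank$d_true)^2),
                 run = object),
            class = "summary.ccs_run")
}

#' @export
print.summary.ccs_run <- function(x, digits = 3, ...) {
  print(x$run)
  cat(sprintf("  final-cycle MSE: a %.4f, d %.4f\n", x$mse_a, x$mse_d))
  print(format(x$cycles[, c("cycle", "feasible", "n_retained", "n_drifted",
                            "A_hat", "B_hat", "A_true", "B_true")],
               digits = digits), row.names = FALSE)
  invisible(x)
}

#' Trajectory of item-parameter precision across cycles
#'
#' Plots the overall mean squared error of the easiness and discrimination
#' estimates after each continuous-phase cycle.
#'
#' @param x a \code{ccs_run}.
#' @param ... passed to \code{\link[graphics]{matplot}}.
#' @export
plot.ccs_run <- function(x, ...) {
  cyc <- vapply(x$state$cycles, `[[`, 0, "cycle")
  mse <- t(vapply(x$state$cycles, function(cc) {
    b <- cc$bank_snapshot
    c(mean((b$a_est - b$a_true)^2), mean((b$d_est - b$d_true)^2))
  }, numeric(2)))
  graphics::matplot(cyc, mse, type = "b", pch = c(1, 2), lty = 1,
                    xlab = "test cycle", ylab = "MSE", ...)
  graphics::legend("topright", c("a", "d"), pch = c(1, 2), lty = 1,
                   col = 1:2)
  invisible(x)
}
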