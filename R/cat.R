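#' Default test blueprint of the continuous phase
#'
#' One continuous-phase test has a fixed length of 60 items split into a
#' calibration cluster of 20 brand-new items, a linking cluster of 15 common
#' items, and an adaptive cluster of 25 items selected by maximum
#' information. The initial phase administers one identical 60-item set to
#' all examinees.
#'
#' @param test_length,n_calibration,n_linking,n_adaptive cluster sizes; they
#'   must add up to \code{test_length}.
#' @return a list of class \code{ccs_blueprint}.
#' @export
test_blueprint <- function(test_length = 60, n_calibration = 20,
                           n_linking = 15, n_adaptive = 25) {
  if (n_calibration + n_linking + n_adaptive != test_length)
    stop("cluster sizes must sum to the test length")
  structure(list(test_length = test_length, n_calibration = n_calibration,
                 n_linking = n_linking, n_adaptive = n_adaptive,
                 cluster_order = c("linking", "calibration", "adaptive")),
            class = "ccs_blueprint")
}

#' Maximum-information item selection
#'
#' Returns the id of the available item with the largest Fisher information
#' at the current ability estimate; ties are broken deterministically in
#' favour of the smallest item id.
#'
#' @param theta_hat current ability estimate (scalar).
#' @param pool data frame with columns \code{id}, \code{a}, \code{d} of
#'   available calibrated items.
#' @return the selected item id.
#' @export
select_next_item <- function(theta_hat, pool) {
  if (nrow(pool) == 0L) stop("item pool exhausted")
  pool <- pool[order(pool$id), , drop = FALSE]
  info <- item_information(theta_hat, pool$a, pool$d)
  pool$id[which.max(info)]
}

#' Administer the non-adaptive initial phase
#'
#' All examinees answer the identical full-length item set; the resulting
#' response matrix is complete (no structural missingness).
#'
#' @param theta true abilities of the examinees.
#' @param items data frame with columns \code{id}, \code{a}, \code{d} (true
#'   generating parameters); must contain exactly \code{test_length} rows.
#' @param test_length required number of items.
#' @param seed optional seed.
#' @return persons x items 0/1 matrix.
#' @export
administer_initial_phase <- function(theta, items, test_length = 60,
                                     seed = NULL) {
  if (nrow(items) != test_length)
    stop("initial phase requires exactly ", test_length, " items")
  generate_responses(theta, items, seed = seed)
}

#' Administer one continuous-phase test cycle
#'
#' Every examinee answers the fixed linking cluster (common items) and
#' calibration cluster (new items) plus \code{n_adaptive} adaptively chosen
#' items. Responses are generated from the items' true parameters; item
#' selection and interim ability estimation use the current base-scale
#' estimates. The interim MAP is initialized from the linking-cluster
#' responses (the only fixed items with parameter estimates at
#' administration time) and updated after every adaptive response.
#'
#' @param theta true abilities (length N).
#' @param linking data frame of the 15 common items with columns \code{id},
#'   \code{a_true}, \code{d_true}, \code{a_est}, \code{d_est}.
#' @param calibration data frame of the 20 new items with columns \code{id},
#'   \code{a_true}, \code{d_true}.
#' @param adaptive_pool data frame of previously calibrated items (columns
#'   as \code{linking}), disjoint from the fixed clusters.
#' @param blueprint a \code{\link{test_blueprint}}.
#' @param seed optional seed.
#' @return list with \code{responses} (persons x administered-items matrix,
#'   \code{NA} = not administered) and \code{log} (long data frame:
#'   examinee, position, item_id, response, theta_interim).
#' @export
administer_cycle <- function(theta, linking, calibration, adaptive_pool,
                             blueprint = test_blueprint(), seed = NULL) {
  n <- length(theta)
  if (nrow(linking) != blueprint$n_linking ||
      nrow(calibration) != blueprint$n_calibration)
    stop("fixed cluster sizes do not match the blueprint")
  if (any(adaptive_pool$id %in% c(linking$id, calibration$id)))
    stop("adaptive pool must be disjoint from the fixed clusters")
  if (nrow(adaptive_pool) < blueprint$n_adaptive)
    stop("adaptive pool smaller than the adaptive cluster")
  if (!is.null(seed)) set.seed(seed)

  u_link <- generate_responses(theta,
                               data.frame(id = linking$id, a = linking$a_true,
                                          d = linking$d_true))
  u_cal <- generate_responses(theta,
                              data.frame(id = calibration$id,
                                         a = calibration$a_true,
                                         d = calibration$d_true))
  pool <- adaptive_pool[order(adaptive_pool$id), , drop = FALSE]
  np <- nrow(pool)

  # interim MAP from the linking cluster
  th <- map_ability(u_link, data.frame(a = linking$a_est, d = linking$d_est))

  aL <- matrix(linking$a_est, n, nrow(linking), byrow = TRUE)
  dL <- matrix(linking$d_est, n, nrow(linking), byrow = TRUE)
  admin <- matrix(FALSE, n, np)
  idx <- matrix(0L, n, blueprint$n_adaptive)   # pool row chosen at each step
  uA <- matrix(NA_real_, n, blueprint$n_adaptive)
  thA <- matrix(NA_real_, n, blueprint$n_adaptive)
  for (s in seq_len(blueprint$n_adaptive)) {
    p <- logistic(outer(th, pool$a_est) +
                    matrix(pool$d_est, n, np, byrow = TRUE))
    info <- sweep(p * (1 - p), 2, pool$a_est^2, "*")
    info[admin] <- -Inf
    choice <- max.col(info, ties.method = "first")
    admin[cbind(seq_len(n), choice)] <- TRUE
    idx[, s] <- choice
    pt <- stats::plogis(pool$a_true[choice] * theta + pool$d_true[choice])
    uA[, s] <- as.integer(stats::runif(n) < pt)
    aA <- matrix(pool$a_est[idx[, seq_len(s), drop = FALSE]], n, s)
    dA <- matrix(pool$d_est[idx[, seq_len(s), drop = FALSE]], n, s)
    th <- map_newton(cbind(aL, aA), cbind(dL, dA),
                     cbind(u_link, uA[, seq_len(s), drop = FALSE]),
                     theta0 = th)
    thA[, s] <- th
  }

  used <- sort(unique(as.vector(idx)))
  u_adap <- matrix(NA_real_, n, length(used),
                   dimnames = list(NULL, as.character(pool$id[used])))
  col_of <- match(as.vector(idx), used)
  u_adap[cbind(rep(seq_len(n), blueprint$n_adaptive), col_of)] <- as.vector(uA)
  responses <- cbind(u_link, u_cal, u_adap)

  log <- data.frame(
    examinee = rep(seq_len(n), blueprint$test_length),
    position = rep(seq_len(blueprint$test_length), each = n),
    item_id = c(rep(linking$id, each = n), rep(calibration$id, each = n),
                as.vector(matrix(pool$id[idx], n))),
    response = c(as.vector(u_link), as.vector(u_cal), as.vector(uA)),
    theta_interim = c(rep(NA_real_, n * (blueprint$n_linking +
                                           blueprint$n_calibration)),
                      as.vector(thA)))
  list(responses = responses, log = log, theta_final = th)
}
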