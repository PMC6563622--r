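# fast stable logistic helpers (hot path: EM, MAP, adaptive selection)
logistic <- function(x) 1 / (1 + exp(-x))
# log(1 - plogis(x)) = min(-x, 0) - log1p(exp(-|x|)); min via arithmetic
log1m_logistic <- function(x) {
  ax <- abs(x)
  -0.5 * (x + ax) - log1p(exp(-ax))
}

#' Marginal maximum likelihood calibration of 2PL items
#'
#' Fits the two-parameter logistic model in slope/intercept form to a binary
#' persons-by-items response matrix by marginal maximum likelihood (MML),
#' integrating the latent ability out against a normal prior over a fixed
#' quadrature. Estimation uses an EM algorithm whose M-step performs a few
#' projected Newton steps per item on the expected complete-data
#' log-likelihood, with backtracking so the marginal log-likelihood never
#' decreases. Item parameters are constrained to closed boxes, and selected
#' items can be held fixed at given values (anchor items), which is how
#' fixed common-item parameter (FCIP) calibration carries an established
#' scale forward.
#'
#' Structural missingness (\code{NA} cells, items not administered to a
#' person) is ignored in the likelihood; it is never treated as incorrect.
#'
#' @param responses persons x items matrix with cells in \{0, 1, NA\};
#'   column names identify items.
#' @param fixed optional data frame with columns \code{id}, \code{a},
#'   \code{d}: anchor items held exactly at these values.
#' @param bounds_a,bounds_d closed intervals constraining the estimates;
#'   defaults \eqn{a \in [-1, 5]}, \eqn{d \in [-5, 5]}.
#' @param start optional data frame with columns \code{id}, \code{a},
#'   \code{d} giving starting values for free items (defaults a = 1, d = 0).
#' @param prior_mean,prior_sd latent normal prior; the standard normal
#'   default identifies the scale.
#' @param n_quad,quad_range quadrature: \code{n_quad} equally spaced nodes
#'   over \code{quad_range} with renormalized normal-density weights.
#' @param tol EM convergence tolerance on the maximum absolute parameter
#'   change.
#' @param maxit maximum number of EM cycles; non-convergence is flagged in
#'   the result, not an error.
#' @return an object of class \code{cal2pl}: a list with components
#'   \code{est} (data frame \code{id}, \code{a}, \code{d}, \code{b},
#'   \code{fixed}, \code{n_obs}), \code{vcov} (named list of 2x2
#'   covariance matrices of \eqn{(\hat a, \hat d)}; the zero matrix for
#'   anchors, \code{NA} when the information matrix is singular),
#'   \code{loglik}, \code{loglik_trace}, \code{converged},
#'   \code{n_iterations}, and the quadrature used.
#' @seealso \code{\link{map_ability}}, \code{\link{concurrent_calibrate}}
#' @examples
#' items <- data.frame(id = paste0("i", 1:5), a = c(0.8, 1, 1.2, 1, 0.9),
#'                     d = c(-1, -0.5, 0, 0.5, 1))
#' u <- generate_responses(rnorm(400), items, seed = 1)
#' fit <- calibrate_2pl(u)
#' coef(fit)
#' @export
calibrate_2pl <- function(responses, fixed = NULL,
                          bounds_a = c(-1, 5), bounds_d = c(-5, 5),
                          start = NULL, prior_mean = 0, prior_sd = 1,
                          n_quad = 61, quad_range = c(-6, 6),
                          tol = 1e-4, maxit = 500L) {
  check_response_matrix(responses)
  ids <- colnames(responses)
  if (is.null(ids)) ids <- paste0("item", seq_len(ncol(responses)))
  nI <- ncol(responses)
  obs <- !is.na(responses); storage.mode(obs) <- "double"
  u0 <- responses; u0[is.na(u0)] <- 0; storage.mode(u0) <- "double"

  nodes <- seq(quad_range[1], quad_range[2], length.out = n_quad)
  w <- stats::dnorm(nodes, prior_mean, prior_sd)
  w <- w / sum(w)
  logw <- log(w)

  a <- rep(1, nI); d <- rep(0, nI)
  if (!is.null(start)) {
    j <- match(as.character(start$id), ids)
    ok <- !is.na(j)
    a[j[ok]] <- start$a[ok]; d[j[ok]] <- start$d[ok]
  }
  free <- rep(TRUE, nI)
  if (!is.null(fixed) && nrow(fixed)) {
    j <- match(as.character(fixed$id), ids)
    if (anyNA(j)) stop("fixed item ids not present in the response matrix")
    if (any(fixed$a < bounds_a[1] | fixed$a > bounds_a[2] |
            fixed$d < bounds_d[1] | fixed$d > bounds_d[2]))
      stop("fixed item values must lie inside the bounds")
    a[j] <- fixed$a; d[j] <- fixed$d
    free[j] <- FALSE
  }
  a[free] <- pmin(pmax(a[free], bounds_a[1]), bounds_a[2])
  d[free] <- pmin(pmax(d[free], bounds_d[1]), bounds_d[2])

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  nik <- rik <- NULL
  freerows <- which(free)
  rows <- freerows          # active set: items still moving; a subset
  full <- TRUE              # M-step over a subset is still a monotone GEM
  repeat {
    iter <- iter + 1L
    lin <- outer(a, nodes) + d                        # items x nodes
    # u*logP + (1-u)*logQ = u*lin + logQ on observed cells
    ll_pn <- u0 %*% lin + obs %*% log1m_logistic(lin) # persons x nodes
    ll_pn <- ll_pn + rep(logw, each = nrow(ll_pn))
    mx <- ll_pn[, 1L]
    for (k in 2:ncol(ll_pn)) mx <- pmax(mx, ll_pn[, k])
    post <- exp(ll_pn - mx)
    s <- rowSums(post)
    trace <- c(trace, sum(mx + log(s)))
    post <- post / s
    nik <- crossprod(obs, post)                       # items x nodes
    rik <- crossprod(u0, post)

    if (length(rows)) {
      ms <- .mstep_cpp(a[rows], d[rows], nik[rows, , drop = FALSE],
                       rik[rows, , drop = FALSE], nodes,
                       bounds_a[1], bounds_a[2], bounds_d[1], bounds_d[2],
                       8L)
      ch <- pmax(abs(ms$a - a[rows]), abs(ms$d - d[rows]))
      a[rows] <- ms$a; d[rows] <- ms$d
      delta <- max(ch)
    } else { delta <- 0; ch <- numeric(0) }
    if (full && delta < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
    act <- rows[ch > 0.1 * tol]
    full <- length(act) == 0L || iter %% 5L == 0L
    rows <- if (full) freerows else act
  }

  # per-item information at the solution in cross-product form: outer
  # products of the per-person marginal score vectors, accumulated over the
  # quadrature-weighted posterior ability distribution. This estimates the
  # marginal (not complete-data) information, so the missing-data loss from
  # the latent ability is reflected in the standard errors.
  lin <- outer(a, nodes) + d
  p <- logistic(lin)
  pe <- tcrossprod(post, p)                      # persons x items, E[P]
  pt <- tcrossprod(post, p * rep(nodes, each = nI))
  s_d <- u0 - obs * pe
  s_a <- u0 * drop(post %*% nodes) - obs * pt
  Iaa <- colSums(s_a * s_a); Iad <- colSums(s_a * s_d)
  Idd <- colSums(s_d * s_d)
  vcov <- vector("list", nI); names(vcov) <- ids
  for (i in seq_len(nI)) {
    if (!free[i]) { vcov[[i]] <- matrix(0, 2, 2); next }
    info <- matrix(c(Iaa[i], Iad[i], Iad[i], Idd[i]), 2, 2)
    v <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(v) || any(!is.finite(v)) || any(diag(v) < 0)) {
      v <- matrix(NA_real_, 2, 2)
    }
    dimnames(v) <- list(c("a", "d"), c("a", "d"))
    vcov[[i]] <- v
  }

  # Joint information over all free items' (a, d), carrying cross-item
  # covariance (items are correlated through the shared latent posterior).
  # Preferred form: the observed information by Louis' identity,
  # I_obs = I_complete - I_missing, whose rank is not limited by the
  # number of persons; its missing-information term costs
  # n_quad * N * (2I)^2 operations, so very large calibrations fall back
  # to the cross-product (outer-score) approximation.
  F2 <- 2L * length(freerows)
  louis <- n_quad * nrow(responses) * (2 * nI)^2 <= 2e9
  if (louis && length(freerows)) {
    AA <- AD <- DD <- matrix(0, nI, nI)
    N <- nrow(responses)
    for (k in seq_len(n_quad)) {
      Ek <- u0 - obs * rep(p[, k], each = N)      # m_ij (u_ij - P_ik)
      Ck <- crossprod(Ek * post[, k], Ek)
      AA <- AA + nodes[k]^2 * Ck
      AD <- AD + nodes[k] * Ck
      DD <- DD + Ck
    }
    Wc <- nik * p * (1 - p)                        # complete-data blocks
    OAA <- crossprod(s_a) - AA
    OAD <- crossprod(s_a, s_d) - AD
    ODD <- crossprod(s_d) - DD
    diag(OAA) <- diag(OAA) + drop(Wc %*% nodes^2)
    diag(OAD) <- diag(OAD) + drop(Wc %*% nodes)
    diag(ODD) <- diag(ODD) + rowSums(Wc)
    ia <- seq(1, F2, by = 2); id_ <- ia + 1L
    joint_info <- matrix(0, F2, F2)
    joint_info[ia, ia] <- OAA[freerows, freerows]
    joint_info[ia, id_] <- OAD[freerows, freerows]
    joint_info[id_, ia] <- t(OAD)[freerows, freerows]
    joint_info[id_, id_] <- ODD[freerows, freerows]
    joint_info <- (joint_info + t(joint_info)) / 2
  } else {
    S <- matrix(0, nrow(responses), F2)
    if (length(freerows)) {
      S[, seq(1, F2, by = 2)] <- s_a[, freerows, drop = FALSE]
      S[, seq(2, F2, by = 2)] <- s_d[, freerows, drop = FALSE]
    }
    joint_info <- crossprod(S)
  }
  joint_ids <- ids[freerows]

  est <- data.frame(id = ids, a = a, d = d,
                    b = ifelse(a != 0, -d / a, NA_real_),
                    fixed = !free, n_obs = colSums(obs),
                    stringsAsFactors = FALSE)
  structure(list(est = est, vcov = vcov,
                 joint_info = joint_info, joint_ids = joint_ids,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 converged = converged, n_iterations = iter,
                 n_persons = nrow(responses),
                 bounds_a = bounds_a, bounds_d = bounds_d,
                 nodes = nodes, weights = w,
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 call = match.call()),
            class = "cal2pl")
}

#' Concurrent calibration across test cycles
#'
#' A single MML run over the stacked (sparse, structurally missing) response
#' matrix of several test cycles with no anchor items. The latent standard
#' normal prior identifies the metric, so the result lives on a new scale:
#' callers must treat the scale lineage as reset. Used as the fallback when
#' an equating breaks down (fewer than two common items survive drift
#' purification).
#'
#' @param responses_list list of persons x items response matrices (columns
#'   named by item id); persons are assumed distinct across elements.
#' @param ... passed on to \code{\link{calibrate_2pl}}.
#' @return a \code{cal2pl} fit on the stacked matrix.
#' @export
concurrent_calibrate <- function(responses_list, ...) {
  calibrate_2pl(stack_responses(responses_list), ...)
}

#' Stack response matrices from several cycles by item id
#'
#' Rows are concatenated; columns are the union of item ids, with \code{NA}
#' (not administered) where a cycle did not contain an item.
#'
#' @param responses_list list of response matrices with item-id column names.
#' @return a single response matrix.
#' @export
stack_responses <- function(responses_list) {
  if (length(responses_list) == 1L) return(responses_list[[1L]])
  ids <- unique(unlist(lapply(responses_list, colnames)))
  n <- sum(vapply(responses_list, nrow, 0L))
  out <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  at <- 0L
  for (u in responses_list) {
    out[at + seq_len(nrow(u)), colnames(u)] <- u
    at <- at + nrow(u)
  }
  out
}

# Newton ascent for the MAP of theta, vectorized over persons with
# per-person item sets given as matrices (NA response = not administered).
map_newton <- function(aM, dM, uM, prior_mean = 0, prior_sd = 1,
                       theta0 = NULL) {
  n <- nrow(uM)
  seen <- !is.na(uM)
  u0 <- ifelse(seen, uM, 0)
  a0 <- ifelse(seen, aM, 0)
  d0 <- ifelse(seen, dM, 0)
  theta <- if (is.null(theta0)) rep(prior_mean, n) else theta0
  for (it in 1:100) {
    p <- logistic(a0 * theta + d0)
    g <- -(theta - prior_mean) / prior_sd^2 + rowSums(a0 * (u0 - p) * seen)
    h <- -1 / prior_sd^2 - rowSums(a0^2 * p * (1 - p) * seen)
    stp <- g / h
    theta <- theta - stp
    if (max(abs(stp)) < 1e-8) break
  }
  theta
}

#' Joint covariance block of selected items' estimates
#'
#' Marginal covariance of the \eqn{(\hat a, \hat d)} estimates of a subset
#' of free items, taken from the inverse of the joint cross-product
#' information over all free items, so cross-item covariance (induced by
#' the shared latent posterior) is carried. The block of the inverse is
#' computed by the Schur complement; information of the remaining items is
#' pseudo-inverted so that items with degenerate information (e.g.
#' administered to a handful of examinees) contribute nothing rather than
#' breaking the computation.
#'
#' @param fit a \code{cal2pl} fit (or any list with \code{joint_info} and
#'   \code{joint_ids}).
#' @param ids item ids of the requested block, in the requested order.
#' @return a \code{2k x 2k} covariance matrix with parameters ordered
#'   \code{(a, d)} per item, or \code{NULL} when the block is not
#'   invertible (callers fall back to per-item covariances).
#' @export
joint_vcov_block <- function(fit, ids) {
  j <- match(as.character(ids), fit$joint_ids)
  if (anyNA(j)) return(NULL)
  sel <- as.vector(rbind(2L * j - 1L, 2L * j))
  info <- fit$joint_info
  icc <- info[sel, sel, drop = FALSE]
  irr <- info[-sel, -sel, drop = FALSE]
  icr <- info[sel, -sel, drop = FALSE]
  out <- tryCatch({
    corr <- if (ncol(irr)) icr %*% MASS::ginv(irr) %*% t(icr) else 0
    m <- icc - corr
    if (rcond(m) < 1e-10) return(NULL)  # degenerate (e.g. rank-deficient)
    v <- solve(m)
    (v + t(v)) / 2
  }, error = function(e) NULL)
  if (!is.null(out) && (any(!is.finite(out)) || any(diag(out) < 0)))
    return(NULL)
  out
}

#' Maximum a posteriori ability estimation
#'
#' Posterior mode of \eqn{\theta} under the 2PL likelihood of the observed
#' (non-missing) responses and a normal prior. The log-posterior is strictly
#' concave, so Newton iteration converges to the unique mode; with no
#' observed responses the prior mode is returned.
#'
#' @param responses a 0/1/NA vector (one person) or persons x items matrix.
#' @param items data frame with columns \code{a}, \code{d} aligned to the
#'   columns of \code{responses}.
#' @param prior_mean,prior_sd normal prior (standard normal by default).
#' @return numeric vector of MAP estimates, one per person.
#' @export
map_ability <- function(responses, items, prior_mean = 0, prior_sd = 1) {
  if (!is.matrix(responses)) responses <- matrix(responses, nrow = 1L)
  n <- nrow(responses)
  aM <- matrix(items$a, n, nrow(items), byrow = TRUE)
  dM <- matrix(items$d, n, nrow(items), byrow = TRUE)
  map_newton(aM, dM, responses, prior_mean, prior_sd)
}
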