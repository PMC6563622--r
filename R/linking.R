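#' Transformation constants linking two latent scales
#'
#' If the 2PL holds in two examinee groups, their latent scales differ by a
#' linear map \eqn{\theta_L = A \theta_K + B}. Item parameters move between
#' the scales as \eqn{a_L = a_K / A} and \eqn{b_L = A b_K + B}.
#'
#' @param A slope (must be nonzero; positive for any feasible link).
#' @param B shift.
#' @param method label of the estimator that produced the constants.
#' @param loss criterion value at the solution (curve methods).
#' @param fallback TRUE when an optimizer failure forced a moment-method
#'   fallback.
#' @return object of class \code{ccs_link}.
#' @export
link_constants <- function(A, B, method = "manual", loss = NA_real_,
                           fallback = FALSE) {
  if (!is.finite(A) || !is.finite(B) || A == 0)
    stop("invalid transformation constants")
  structure(list(A = A, B = B, method = method, loss = loss,
                 fallback = fallback), class = "ccs_link")
}

#' @export
print.ccs_link <- function(x, ...) {
  cat(sprintf("scale link (%s): A = %.4f, B = %.4f%s\n", x$method, x$A, x$B,
              if (isTRUE(x$fallback)) " [fallback]" else ""))
  invisible(x)
}

#' Transform item parameters onto the base scale
#'
#' Applies \eqn{a_L = a_K / A}, \eqn{b_L = A b_K + B}; the easiness
#' intercept is recomputed as \eqn{d_L = -a_L b_L}.
#'
#' @param items data frame with columns \code{a} and one of \code{b} or
#'   \code{d} on scale K.
#' @param constants a \code{\link{link_constants}} object.
#' @return data frame with columns \code{a}, \code{b}, \code{d} on scale L
#'   (other columns carried through).
#' @export
transform_items <- function(items, constants) {
  if (constants$A == 0) stop("invalid transformation constants: A = 0")
  b_k <- if (!is.null(items$b)) items$b else easiness_to_difficulty(items$a, items$d)
  out <- items
  out$a <- items$a / constants$A
  out$b <- constants$A * b_k + constants$B
  out$d <- -out$a * out$b
  out
}

#' Bundle common-item parameter estimates from two scales
#'
#' Builds the pairing consumed by the scale-transformation estimators and
#' the drift test: per common item, the base-scale (L, established metric)
#' and current-cycle (K, temporary calibration) estimates in \eqn{(a, b)}
#' parametrization with delta-method covariance matrices.
#'
#' @param id item ids.
#' @param a_l,d_l base-scale estimates.
#' @param a_k,d_k current-cycle estimates.
#' @param cov_l,cov_k lists of 2x2 covariance matrices of \eqn{(\hat a,
#'   \hat d)} (optional; required only for drift testing).
#' @param jcov_l,jcov_k optional joint \eqn{2n \times 2n} covariance
#'   matrices of the \eqn{(\hat a, \hat d)} estimates (parameters ordered
#'   \code{(a, d)} per item, items ordered as \code{id}), e.g. from
#'   \code{\link{joint_vcov_block}}. When supplied they carry cross-item
#'   covariance into the drift test and override \code{cov_l}/\code{cov_k}.
#' @return data frame with columns \code{id}, \code{a_k}, \code{b_k},
#'   \code{a_l}, \code{b_l} and list columns \code{cov_k}, \code{cov_l}
#'   holding \eqn{(a, b)} covariances; joint \eqn{(a, b)} covariances, when
#'   available, ride along as attributes \code{jcov_k}, \code{jcov_l}.
#' @export
common_item_pairs <- function(id, a_l, d_l, a_k, d_k,
                              cov_l = NULL, cov_k = NULL,
                              jcov_l = NULL, jcov_k = NULL) {
  n <- length(id)
  pairs <- data.frame(id = id, a_k = a_k, b_k = easiness_to_difficulty(a_k, d_k),
                      a_l = a_l, b_l = easiness_to_difficulty(a_l, d_l),
                      stringsAsFactors = FALSE)
  joint_ab <- function(jcov, a, d) {
    # blockdiagonal delta-method Jacobian for b_i = -d_i/a_i
    J <- matrix(0, 2 * n, 2 * n)
    for (i in seq_len(n)) {
      r <- 2 * i - 1:0
      J[r, r] <- matrix(c(1, d[i] / a[i]^2, 0, -1 / a[i]), 2, 2)
    }
    v <- J %*% jcov %*% t(J)
    (v + t(v)) / 2
  }
  diag_blocks <- function(v) lapply(seq_len(n), function(i) {
    b <- v[2 * i - 1:0, 2 * i - 1:0]
    dimnames(b) <- list(c("a", "b"), c("a", "b"))
    b
  })
  to_ab <- function(covs, a, d) {
    if (is.null(covs)) return(replicate(n, matrix(NA_real_, 2, 2),
                                        simplify = FALSE))
    lapply(seq_len(n), function(i) {
      v <- covs[[i]]
      if (is.null(v) || any(is.na(v))) matrix(NA_real_, 2, 2)
      else cov_ad_to_ab(v, a[i], d[i])
    })
  }
  if (!is.null(jcov_k)) {
    jk <- joint_ab(jcov_k, a_k, -a_k * pairs$b_k)
    attr(pairs, "jcov_k") <- jk
    pairs$cov_k <- diag_blocks(jk)
  } else pairs$cov_k <- to_ab(cov_k, a_k, d_k)
  if (!is.null(jcov_l)) {
    jl <- joint_ab(jcov_l, a_l, -a_l * pairs$b_l)
    attr(pairs, "jcov_l") <- jl
    pairs$cov_l <- diag_blocks(jl)
  } else pairs$cov_l <- to_ab(cov_l, a_l, d_l)
  pairs
}

#' Moment-method scale transformation: mean/mean
#'
#' \eqn{A = \bar a_K / \bar a_L}, \eqn{B = \bar b_L - A \bar b_K}.
#'
#' @param pairs a \code{\link{common_item_pairs}} data frame (>= 2 rows).
#' @return \code{\link{link_constants}}.
#' @export
mean_mean <- function(pairs) {
  if (nrow(pairs) < 2L) stop("at least two common items are required")
  A <- mean(pairs$a_k) / mean(pairs$a_l)
  link_constants(A, mean(pairs$b_l) - A * mean(pairs$b_k), "mean_mean")
}

#' Moment-method scale transformation: mean/sigma
#'
#' \eqn{A = s(b_L) / s(b_K)}, \eqn{B = \bar b_L - A \bar b_K}.
#'
#' @inheritParams mean_mean
#' @export
mean_sigma <- function(pairs) {
  if (nrow(pairs) < 2L) stop("at least two common items are required")
  s_k <- stats::sd(pairs$b_k)
  if (s_k == 0) stop("degenerate link: zero difficulty spread on scale K")
  A <- stats::sd(pairs$b_l) / s_k
  link_constants(A, mean(pairs$b_l) - A * mean(pairs$b_k), "mean_sigma")
}

#' Characteristic-curve scale transformation (Haebara, Stocking-Lord)
#'
#' Finds \eqn{(A, B)} minimizing the squared discrepancy between the
#' base-scale curves and the transformed current-cycle curves over an
#' ability grid: per item characteristic curve (Haebara) or the test
#' characteristic curve (Stocking-Lord). Only the K-to-L direction enters
#' the criterion (the classic non-symmetric definitions). The optimizer is
#' started at the identity link \eqn{(1, 0)}, so the returned loss never
#' exceeds the identity loss; on optimizer failure the mean/mean constants
#' are returned with a warning and \code{fallback = TRUE}.
#'
#' @inheritParams mean_mean
#' @param criterion \code{"haebara"} or \code{"stocking_lord"}.
#' @param grid ability quadrature nodes (uniform weights).
#' @return \code{\link{link_constants}} with the criterion value in
#'   \code{loss}.
#' @export
characteristic_curve_link <- function(pairs,
                                      criterion = c("haebara",
                                                    "stocking_lord"),
                                      grid = seq(-4, 4, length.out = 61)) {
  criterion <- match.arg(criterion)
  if (nrow(pairs) < 2L) stop("at least two common items are required")
  if (length(grid) == 0L) stop("empty ability grid")
  p_of <- function(a, b) stats::plogis(outer(grid, a, function(t, a) a * t) -
                                         matrix(a * b, length(grid),
                                                length(a), byrow = TRUE))
  pl <- p_of(pairs$a_l, pairs$b_l)
  loss <- function(par) {
    pk <- p_of(pairs$a_k / par[1], par[1] * pairs$b_k + par[2])
    if (criterion == "haebara") sum((pk - pl)^2)
    else sum((rowSums(pk) - rowSums(pl))^2)
  }
  # Nelder-Mead on (log A, B) keeps A positive without box constraints;
  # started at the identity link so the returned loss never exceeds it
  opt <- tryCatch(
    stats::optim(c(0, 0), function(p) loss(c(exp(p[1]), p[2])),
                 method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || !is.finite(opt$value)) {
    warning("characteristic-curve optimizer failed; ",
            "falling back to mean/mean constants")
    mm <- mean_mean(pairs)
    return(link_constants(mm$A, mm$B, criterion, fallback = TRUE))
  }
  link_constants(exp(opt$par[1]), opt$par[2], criterion, loss = opt$value)
}

#' Estimate transformation constants by a named method
#'
#' @inheritParams mean_mean
#' @param method one of \code{"mean_mean"}, \code{"mean_sigma"},
#'   \code{"haebara"}, \code{"stocking_lord"}.
#' @param grid ability grid for the characteristic-curve methods.
#' @export
estimate_link <- function(pairs, method = c("mean_mean", "mean_sigma",
                                            "haebara", "stocking_lord"),
                          grid = seq(-4, 4, length.out = 61)) {
  method <- match.arg(method)
  switch(method,
         mean_mean = mean_mean(pairs),
         mean_sigma = mean_sigma(pairs),
         haebara = characteristic_curve_link(pairs, "haebara", grid),
         stocking_lord = characteristic_curve_link(pairs, "stocking_lord",
                                                   grid))
}

#' Lord-type chi-squared test for item parameter drift
#'
#' Tests whether a common item's current-cycle estimates, transformed onto
#' the base scale, differ from its base-scale estimates. With
#' \eqn{\delta = (\hat a_L, \hat b_L) - (\hat a_K / A, A \hat b_K + B)} and
#' \eqn{\Sigma} the sum of the base-scale covariance and the transformed
#' current-cycle covariance (delta method through the linear scale map),
#' the statistic \eqn{\delta' \Sigma^{-1} \delta} is referred to a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param pair one row of a \code{\link{common_item_pairs}} data frame.
#' @param constants estimated \code{\link{link_constants}}.
#' @param alpha significance level (default 0.05).
#' @return list with \code{statistic}, \code{p_value}, \code{drifted}, and
#'   \code{testable} (FALSE when the pooled covariance is singular or
#'   unavailable, in which case the item is retained untested).
#' @export
lord_chi2_test <- function(pair, constants, alpha = 0.05) {
  A <- constants$A; B <- constants$B
  delta <- c(pair$a_l - pair$a_k / A,
             pair$b_l - (A * pair$b_k + B))
  J <- diag(c(1 / A, A))
  ck <- pair$cov_k[[1]]; cl <- pair$cov_l[[1]]
  if (any(is.na(ck)) || any(is.na(cl)))
    return(list(statistic = NA_real_, p_value = NA_real_, drifted = FALSE,
                testable = FALSE))
  sigma <- cl + J %*% ck %*% t(J)
  inv <- tryCatch(solve(sigma), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(inv)))
    return(list(statistic = NA_real_, p_value = NA_real_, drifted = FALSE,
                testable = FALSE))
  stat <- drop(t(delta) %*% inv %*% delta)
  p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  list(statistic = stat, p_value = p, drifted = p < alpha, testable = TRUE)
}

# Analytic gradient of the characteristic-curve criterion with respect to
# (A, B). Parametrize the transformed curves by at = aK/A, bt = A*bK + B;
# dz/dA = aK*(B - theta)/A^2, dz/dB = -aK/A for z = at*(theta - bt).
cc_criterion_grad <- function(c, pairs, criterion, grid) {
  A <- c[1]; B <- c[2]
  at <- pairs$a_k / A
  bt <- A * pairs$b_k + B
  z <- outer(grid, at) - matrix(at * bt, length(grid), nrow(pairs),
                                byrow = TRUE)
  p <- logistic(z)
  pl <- logistic(outer(grid, pairs$a_l) -
                   matrix(pairs$a_l * pairs$b_l, length(grid), nrow(pairs),
                          byrow = TRUE))
  w <- p * (1 - p)
  dzdA <- (matrix(pairs$a_k, length(grid), nrow(pairs), byrow = TRUE) *
             (B - grid)) / A^2
  dzdB <- -matrix(pairs$a_k, length(grid), nrow(pairs), byrow = TRUE) / A
  if (criterion == "haebara") {
    r <- p - pl
    c(sum(2 * r * w * dzdA), sum(2 * r * w * dzdB))
  } else {
    r <- rowSums(p) - rowSums(pl)
    c(sum(2 * r * rowSums(w * dzdA)), sum(2 * r * rowSums(w * dzdB)))
  }
}

# Jacobian d(A, B) / d(item parameters) with parameter order
# (a_l, b_l, a_k, b_k) per item. Moment methods: central finite differences
# of the closed-form estimators. Characteristic-curve methods: implicit
# function theorem at the criterion minimum, with the cross-derivatives of
# the analytic gradient taken by central differences.
link_jacobian <- function(pairs, constants, method,
                          grid = seq(-4, 4, length.out = 61)) {
  n <- nrow(pairs)
  pvec <- as.vector(rbind(pairs$a_l, pairs$b_l, pairs$a_k, pairs$b_k))
  unpack <- function(p) {
    m <- matrix(p, 4, n)
    data.frame(id = pairs$id, a_l = m[1, ], b_l = m[2, ],
               a_k = m[3, ], b_k = m[4, ])
  }
  if (method %in% c("mean_mean", "mean_sigma")) {
    est <- function(p) {
      q <- unpack(p)
      cc <- if (method == "mean_mean") mean_mean(q) else mean_sigma(q)
      c(cc$A, cc$B)
    }
    T <- matrix(0, 2, 4 * n)
    for (l in seq_along(pvec)) {
      h <- 1e-6 * max(1, abs(pvec[l]))
      up <- dn <- pvec; up[l] <- up[l] + h; dn[l] <- dn[l] - h
      T[, l] <- (est(up) - est(dn)) / (2 * h)
    }
    return(T)
  }
  criterion <- method
  cvec <- c(constants$A, constants$B)
  gfun <- function(c, p) cc_criterion_grad(c, unpack(p), criterion, grid)
  hc <- 1e-6
  H <- matrix(0, 2, 2)
  for (l in 1:2) {
    up <- dn <- cvec; up[l] <- up[l] + hc; dn[l] <- dn[l] - hc
    H[, l] <- (gfun(up, pvec) - gfun(dn, pvec)) / (2 * hc)
  }
  Fcp <- matrix(0, 2, 4 * n)
  for (l in seq_along(pvec)) {
    h <- 1e-6 * max(1, abs(pvec[l]))
    up <- dn <- pvec; up[l] <- up[l] + h; dn[l] <- dn[l] - h
    Fcp[, l] <- (gfun(cvec, up) - gfun(cvec, dn)) / (2 * h)
  }
  -solve(H, Fcp)
}

# Row subset of a pairs data frame that keeps the joint covariance
# attributes aligned.
subset_pairs <- function(pairs, rows) {
  out <- pairs[rows, , drop = FALSE]
  for (at in c("jcov_l", "jcov_k")) {
    v <- attr(pairs, at)
    if (!is.null(v)) {
      sel <- as.vector(rbind(2L * rows - 1L, 2L * rows))
      attr(out, at) <- v[sel, sel, drop = FALSE]
    }
  }
  out
}

# Assemble the (a, b) covariance of one side as a dense 2n x 2n matrix:
# the joint matrix when the pairs carry one, otherwise block-diagonal from
# the per-item covariances (untestable items contribute zero).
side_cov <- function(pairs, side) {
  v <- attr(pairs, paste0("jcov_", side))
  n <- nrow(pairs)
  if (!is.null(v)) return(v)
  out <- matrix(0, 2 * n, 2 * n)
  covs <- pairs[[paste0("cov_", side)]]
  for (i in seq_len(n)) {
    b <- covs[[i]]
    if (!any(is.na(b))) out[2 * i - 1:0, 2 * i - 1:0] <- b
  }
  out
}

# Drift statistics for all active common items at once. When
# account_constants is TRUE the covariance of each difference vector
# carries the full delta method: the direct item-parameter part, the
# propagated sampling variance of the estimated constants (A, B), their
# covariance with the item estimates (all items contribute to the
# constants), and - when the pairs carry joint covariance matrices -
# cross-item covariance of the calibrations. Items with unavailable
# covariance are untestable; their (unknown) contribution to the
# constants' variance is omitted.
drift_tests <- function(pairs, constants, method, grid, alpha,
                        account_constants = TRUE) {
  n <- nrow(pairs)
  A <- constants$A; B <- constants$B
  ok_cov <- vapply(seq_len(n), function(i)
    !any(is.na(pairs$cov_k[[i]])) && !any(is.na(pairs$cov_l[[i]])), FALSE)
  T <- if (account_constants)
    tryCatch(link_jacobian(pairs, constants, method, grid),
             error = function(e) NULL)
  else NULL
  Vl <- side_cov(pairs, "l")
  Vk <- side_cov(pairs, "k")
  if (!is.null(T)) {
    # estimator Jacobian split by side, parameter order (a, b) per item
    li <- as.vector(vapply(seq_len(n), function(j) 4L * (j - 1L) + 1:2,
                           integer(2)))
    ki <- li + 2L
    Tl <- T[, li, drop = FALSE]
    Tk <- T[, ki, drop = FALSE]
  }
  stat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!ok_cov[i]) next
    delta <- c(pairs$a_l[i] - pairs$a_k[i] / A,
               pairs$b_l[i] - (A * pairs$b_k[i] + B))
    if (is.null(T)) {
      J <- diag(c(1 / A, A))
      sigma <- pairs$cov_l[[i]] + J %*% pairs$cov_k[[i]] %*% t(J)
    } else {
      Di <- matrix(c(pairs$a_k[i] / A^2, -pairs$b_k[i], 0, -1), 2, 2)
      Gl <- Di %*% Tl
      Gk <- Di %*% Tk
      sel <- 2L * i - 1:0
      Gl[, sel] <- Gl[, sel] + diag(2)
      Gk[, sel] <- Gk[, sel] + matrix(c(-1 / A, 0, 0, -A), 2, 2)
      sigma <- Gl %*% Vl %*% t(Gl) + Gk %*% Vk %*% t(Gk)
    }
    inv <- tryCatch(solve(sigma), error = function(e) NULL)
    if (is.null(inv) || any(!is.finite(inv))) next
    stat[i] <- drop(t(delta) %*% inv %*% delta)
  }
  p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  data.frame(id = pairs$id, statistic = stat, p_value = p,
             drifted = !is.na(p) & p < alpha, testable = !is.na(stat))
}

#' Iterative purification of the common-item set
#'
#' Alternates scale-transformation estimation and per-item drift testing:
#' while any remaining common item shows significant drift, the item with
#' the largest test statistic is removed (one item per iteration) and the
#' constants are re-estimated on the reduced set. The loop stops when no
#' item drifts or fewer than two common items remain; in the latter case
#' the equating is infeasible (a breakdown) because at least two link items
#' are needed to keep the scale comparable.
#'
#' @inheritParams estimate_link
#' @param alpha significance level of the drift test.
#' @param account_constants when TRUE (default), the drift-test covariance
#'   carries the sampling variance of the estimated constants and its
#'   covariance with the item estimates (the modified Lord test); when
#'   FALSE only the two item-level covariances are summed
#'   (\code{\link{lord_chi2_test}}).
#' @return object of class \code{equating_outcome}: \code{constants}
#'   (final-set estimate, \code{NULL} on breakdown), \code{retained},
#'   \code{drifted} (data frame id, statistic, p_value, iteration),
#'   \code{feasible}, \code{n_iterations}, \code{n_items} (initial set
#'   size), \code{untestable} (ids skipped for singular covariance).
#' @export
purify <- function(pairs, method = c("mean_mean", "mean_sigma", "haebara",
                                     "stocking_lord"),
                   alpha = 0.05, grid = seq(-4, 4, length.out = 61),
                   account_constants = TRUE) {
  method <- match.arg(method)
  if (nrow(pairs) < 2L) stop("at least two initial common items are required")
  active <- pairs
  drifted <- data.frame(id = pairs$id[0], statistic = numeric(0),
                        p_value = numeric(0), iteration = integer(0))
  untestable <- character(0)
  iter <- 0L
  constants <- NULL
  feasible <- FALSE
  repeat {
    if (nrow(active) < 2L) { feasible <- FALSE; constants <- NULL; break }
    iter <- iter + 1L
    constants <- estimate_link(active, method, grid)
    tests <- drift_tests(active, constants, method, grid, alpha,
                         account_constants)
    untestable <- union(untestable, as.character(tests$id[!tests$testable]))
    if (!any(tests$drifted)) { feasible <- TRUE; break }
    worst <- which(tests$drifted)[which.max(tests$statistic[tests$drifted])]
    drifted <- rbind(drifted,
                     data.frame(id = tests$id[worst],
                                statistic = tests$statistic[worst],
                                p_value = tests$p_value[worst],
                                iteration = iter))
    active <- subset_pairs(active, setdiff(seq_len(nrow(active)), worst))
  }
  structure(list(constants = constants, retained = active$id,
                 drifted = drifted, feasible = feasible,
                 n_iterations = iter, n_items = nrow(pairs),
                 method = method, alpha = alpha,
                 untestable = untestable),
            class = "equating_outcome")
}

#' @export
print.equating_outcome <- function(x, ...) {
  cat(sprintf("equating (%s): %s, %d/%d common items retained, %d iteration(s)\n",
              x$method, if (x$feasible) "feasible" else "BREAKDOWN",
              length(x$retained), x$n_items, x$n_iterations))
  if (!is.null(x$constants))
    cat(sprintf("  A = %.4f, B = %.4f\n", x$constants$A, x$constants$B))
  if (nrow(x$drifted))
    cat("  drifted:", paste(x$drifted$id, collapse = ", "), "\n")
  invisible(x)
}
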