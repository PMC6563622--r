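#' @export
print.cal2pl <- function(x, ...) {
  cat("2PL marginal maximum likelihood calibration\n")
  cat(sprintf("  %d items (%d anchored), %d persons\n",
              nrow(x$est), sum(x$est$fixed), x$n_persons))
  cat(sprintf("  log-likelihood %.2f after %d EM cycles (%s)\n",
              x$loglik, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.cal2pl <- function(object, ...) {
  m <- as.matrix(object$est[, c("a", "d", "b")])
  rownames(m) <- object$est$id
  m
}

#' Covariance matrices of the item parameter estimates
#'
#' @param object a \code{cal2pl} fit.
#' @param parametrization \code{"ad"} for \eqn{(\hat a, \hat d)} or
#'   \code{"ab"} for \eqn{(\hat a, \hat b)} via the delta method through
#'   \eqn{b = -d/a}.
#' @param ... unused.
#' @return named list of 2x2 matrices (zero for anchors, \code{NA} when the
#'   information matrix was singular).
#' @export
vcov.cal2pl <- function(object, parametrization = c("ad", "ab"), ...) {
  parametrization <- match.arg(parametrization)
  if (parametrization == "ad") return(object$vcov)
  out <- object$vcov
  for (i in seq_along(out)) {
    if (any(is.na(out[[i]]))) next
    out[[i]] <- cov_ad_to_ab(out[[i]], object$est$a[i], object$est$d[i])
  }
  out
}

# delta method for b = -d/a: J = [[1, 0], [d/a^2, -1/a]]
cov_ad_to_ab <- function(v, a, d) {
  J <- matrix(c(1, d / a^2, 0, -1 / a), 2, 2)
  out <- J %*% v %*% t(J)
  out <- (out + t(out)) / 2      # keep exactly symmetric
  dimnames(out) <- list(c("a", "b"), c("a", "b"))
  out
}

#' @export
logLik.cal2pl <- function(object, ...) {
  structure(object$loglik, df = 2L * sum(!object$est$fixed),
            nobs = object$n_persons, class = "logLik")
}

#' @export
summary.cal2pl <- function(object, ...) {
  se <- t(vapply(object$vcov, function(v) sqrt(pmax(diag(v), 0)),
                 numeric(2)))
  tab <- data.frame(object$est[, c("id", "a", "d", "b")],
                    se_a = se[, 1], se_d = se[, 2],
                    fixed = object$est$fixed, n_obs = object$est$n_obs)
  structure(list(table = tab, loglik = object$loglik,
                 converged = object$converged,
                 n_iterations = object$n_iterations,
                 n_persons = object$n_persons),
            class = "summary.cal2pl")
}

#' @export
print.summary.cal2pl <- function(x, digits = 3, ...) {
  cat(sprintf("2PL calibration: %d items, %d persons, logLik %.2f (%s)\n",
              nrow(x$table), x$n_persons, x$loglik,
              if (x$converged) "converged" else "not converged"))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Predicted response probabilities from a calibration
#'
#' @param object a \code{cal2pl} fit.
#' @param theta numeric vector of ability values.
#' @param items optional character vector of item ids (default: all).
#' @param ... unused.
#' @return matrix of \eqn{P(u = 1 \mid \theta)}, persons x items.
#' @export
predict.cal2pl <- function(object, theta = seq(-4, 4, by = 0.1),
                           items = NULL, ...) {
  est <- object$est
  if (!is.null(items)) est <- est[match(items, est$id), , drop = FALSE]
  p <- stats::plogis(outer(theta, est$a) +
                       matrix(est$d, length(theta), nrow(est), byrow = TRUE))
  dimnames(p) <- list(NULL, est$id)
  p
}

#' Item characteristic curves of a calibration
#'
#' @param x a \code{cal2pl} fit.
#' @param items item ids to draw (default: all).
#' @param ... passed to \code{\link[graphics]{matplot}}.
#' @export
plot.cal2pl <- function(x, items = NULL, ...) {
  theta <- seq(-4, 4, by = 0.05)
  p <- predict(x, theta = theta, items = items)
  graphics::matplot(theta, p, type = "l", lty = 1,
                    xlab = expression(theta), ylab = "P(u = 1)",
                    main = "Item characteristic curves", ...)
  invisible(x)
}

#' Simulate responses from fitted item parameters
#'
#' @param object a \code{cal2pl} fit.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param theta abilities to simulate for (default: standard normal draws,
#'   one per calibration respondent).
#' @param ... unused.
#' @return a list of \code{nsim} response matrices.
#' @export
simulate.cal2pl <- function(object, nsim = 1, seed = NULL, theta = NULL,
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- stats::rnorm(object$n_persons)
  items <- data.frame(id = object$est$id, a = object$est$a, d = object$est$d)
  replicate(nsim, generate_responses(theta, items), simplify = FALSE)
}
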