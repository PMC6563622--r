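#' Two-parameter logistic response probability
#'
#' Probability of a correct response under the 2PL model in slope/intercept
#' form, \eqn{P(u=1 \mid \theta) = \exp(a\theta + d) / (1 + \exp(a\theta + d))},
#' where \code{a} is the item discrimination and \code{d} the item easiness
#' (intercept). Computed via \code{\link[stats]{plogis}}, which is stable for
#' arbitrarily large \eqn{|a\theta + d|}.
#'
#' @param theta numeric vector of latent ability values.
#' @param a,d numeric vectors (recycled) of discrimination and easiness.
#' @return numeric vector of probabilities in \[0, 1\].
#' @examples
#' prob_2pl(0, a = 1.2, d = 0)     # 0.5
#' prob_2pl(1, a = 1, d = 0)       # plogis(1)
#' @export
prob_2pl <- function(theta, a, d) {
  if (!all(is.finite(theta), is.finite(a), is.finite(d)))
    stop("prob_2pl: all inputs must be finite")
  stats::plogis(a * theta + d)
}

#' Convert item easiness to difficulty
#'
#' The 2PL can be written \eqn{a(\theta - b)} with difficulty
#' \eqn{b = -d/a}; the discrimination is identical in both parametrizations.
#'
#' @param a discrimination (must be nonzero).
#' @param d easiness intercept.
#' @return difficulty \code{b} on the latent-trait scale.
#' @export
easiness_to_difficulty <- function(a, d) {
  if (any(a == 0)) stop("difficulty b = -d/a is undefined for a = 0")
  -d / a
}

#' Fisher information of a 2PL item
#'
#' \eqn{I(\theta) = a^2 P(\theta)(1 - P(\theta))}; maximal near
#' \eqn{\theta = b = -d/a}. This is the criterion used by
#' maximum-information adaptive item selection.
#'
#' @inheritParams prob_2pl
#' @return nonnegative information values.
#' @export
item_information <- function(theta, a, d) {
  p <- prob_2pl(theta, a, d)
  a^2 * p * (1 - p)
}

#' Generate binary responses under the 2PL model
#'
#' Each cell of the returned persons-by-items matrix is an independent
#' Bernoulli draw with success probability \code{prob_2pl(theta_j, a_i, d_i)}.
#' \code{NA} never appears here: structural missingness (items that were not
#' administered) is introduced only by the adaptive test assembly.
#'
#' @param theta numeric vector of person abilities.
#' @param items data frame with columns \code{a} and \code{d} (one row per
#'   item); row order defines column order of the result.
#' @param seed optional integer seed for reproducibility.
#' @return integer matrix (persons x items) of 0/1 responses, with
#'   \code{colnames} taken from \code{items$id} when present.
#' @export
generate_responses <- function(theta, items, seed = NULL) {
  if (length(theta) == 0L || nrow(items) == 0L)
    stop("generate_responses: need at least one person and one item")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::plogis(outer(theta, items$a) +
                       matrix(items$d, length(theta), nrow(items), byrow = TRUE))
  u <- matrix(as.integer(stats::runif(length(p)) < p), nrow(p), ncol(p))
  if (!is.null(items$id)) colnames(u) <- as.character(items$id)
  u
}

# Validate a persons x items response matrix: cells in {0, 1, NA}, every
# person row has at least one observed response.
check_response_matrix <- function(u) {
  if (!is.matrix(u)) stop("responses must be a matrix")
  vals <- u[!is.na(u)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("response cells must be 0, 1 or NA")
  if (any(rowSums(!is.na(u)) == 0L))
    stop("every person must have at least one observed response")
  invisible(u)
}
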