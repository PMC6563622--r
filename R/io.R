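#' Write and read a response matrix as CSV
#'
#' Dialect: header row of item ids, first column \code{person}, cells in
#' \{0, 1, NA\} with \code{NA} meaning "not administered". Structural
#' missingness survives the round trip; it is never recoded.
#'
#' @param u persons x items response matrix.
#' @param file path.
#' @export
write_response_matrix <- function(u, file) {
  df <- data.frame(person = seq_len(nrow(u)), u, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, na = "NA")
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  u <- as.matrix(df[, -1, drop = FALSE])
  rownames(u) <- df$person
  check_response_matrix(u)
  u
}

#' Write and read item bank records as CSV
#'
#' Columns: \code{item_id}, \code{a_true}, \code{d_true}, \code{a_est},
#' \code{d_est}, \code{cycle_introduced}.
#'
#' @param bank item bank data frame (as in a \code{ccs_state}).
#' @param file path.
#' @export
write_item_parameters <- function(bank, file) {
  out <- data.frame(item_id = bank$id, a_true = bank$a_true,
                    d_true = bank$d_true, a_est = bank$a_est,
                    d_est = bank$d_est,
                    cycle_introduced = bank$cycle_introduced)
  utils::write.csv(out, file, row.names = FALSE)
}

#' @rdname write_item_parameters
#' @export
read_item_parameters <- function(file) {
  df <- utils::read.csv(file)
  data.frame(id = df$item_id, a_true = df$a_true, d_true = df$d_true,
             a_est = df$a_est, d_est = df$d_est,
             cycle_introduced = df$cycle_introduced, common_last = FALSE)
}

#' Serialize a calibration result
#'
#' Writes the per-item estimates and standard errors as CSV
#' (\code{item_id}, \code{a_est}, \code{d_est}, \code{se_a}, \code{se_d},
#' \code{cov_ad}) and, when the jsonlite package is available, a JSON
#' sidecar with the run metadata (log-likelihood, iterations, convergence).
#'
#' @param fit a \code{cal2pl} fit.
#' @param file CSV path; metadata goes to \code{<file>.meta.json}.
#' @export
write_calibration <- function(fit, file) {
  v <- t(vapply(fit$vcov, function(m) c(sqrt(pmax(diag(m), 0)), m[1, 2]),
                numeric(3)))
  out <- data.frame(item_id = fit$est$id, a_est = fit$est$a,
                    d_est = fit$est$d, se_a = v[, 1], se_d = v[, 2],
                    cov_ad = v[, 3])
  utils::write.csv(out, file, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(loglik = fit$loglik, n_iterations = fit$n_iterations,
                 converged = fit$converged, n_persons = fit$n_persons)
    jsonlite::write_json(meta, paste0(file, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Serialize per-cycle equating outcomes
#'
#' One CSV row per continuous-phase cycle: method, estimated constants,
#' retained count, drifted item ids and the feasibility flag.
#'
#' @param run a \code{ccs_run}.
#' @param file path.
#' @export
write_equating_outcomes <- function(run, file) {
  rows <- lapply(run$state$cycles, function(cc) {
    eq <- cc$equating
    data.frame(cycle = cc$cycle, method = eq$method,
               A_hat = if (eq$feasible) eq$constants$A else NA_real_,
               B_hat = if (eq$feasible) eq$constants$B else NA_real_,
               n_retained = length(eq$retained),
               drifted = paste(eq$drifted$id, collapse = ";"),
               feasible = eq$feasible)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
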