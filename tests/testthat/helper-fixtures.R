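# Small deterministic fixtures built in code.

make_items <- function(n, seed = 1) {
  it <- draw_item_parameters(n, seed = seed)
  it$id <- seq_len(n)
  it
}

# Common-item pairs generated by applying an exact linear scale map
# (optionally with parameter noise) so the truth is known by construction.
make_pairs <- function(n = 15, A = 1, B = 0, noise = 0, seed = 1,
                       cov_scale = 1e-4) {
  set.seed(seed)
  it <- draw_item_parameters(n)
  b_k <- -it$d / it$a
  tr <- transform_items(data.frame(a = it$a, b = b_k), link_constants(A, B))
  a_l <- tr$a + stats::rnorm(n, 0, noise)
  b_l <- tr$b + stats::rnorm(n, 0, noise)
  covs <- replicate(n, cov_scale * diag(2), simplify = FALSE)
  common_item_pairs(seq_len(n),
                    a_l = a_l, d_l = -a_l * b_l,
                    a_k = it$a, d_k = it$d,
                    cov_l = covs, cov_k = covs)
}

# The shared no-drift simulation batch behind the stochastic acceptance
# checks: 20 replications of the Stocking-Lord / normal / N = 100 condition
# plus 20 replications for each remaining transformation method at N = 50.
# Computed once per test session.
.batch_env <- new.env()

acceptance_batch <- function() {
  if (!is.null(.batch_env$batch)) return(.batch_env$batch)
  conds <- list(
    stocking_lord = list(method = "stocking_lord", n = 100, seed0 = 100),
    mean_mean     = list(method = "mean_mean",     n = 50,  seed0 = 200),
    mean_sigma    = list(method = "mean_sigma",    n = 50,  seed0 = 300),
    haebara       = list(method = "haebara",       n = 50,  seed0 = 400))
  out <- lapply(conds, function(cn) {
    do.call(rbind, lapply(1:20, function(r) {
      run <- run_ccs(n_cycles = 10, n_examinees = cn$n, method = cn$method,
                     scheme = "normal", seed = cn$seed0 + r)
      ev <- evaluate_run(run)
      ev$replication <- r
      ev
    }))
  })
  .batch_env$batch <- out
  out
}
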