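# Internal numeric helpers shared across modules.

# log(sum(exp(x))) without overflow; returns -Inf for empty/all -Inf input.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise logsumexp of a matrix.
col_logsumexp <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx, "-"))))
}

# Stable log inverse-logit: log plogis(eta) valid for |eta| up to ~700.
log_inv_logit <- function(eta) plogis(eta, log.p = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards so package functions never perturb user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
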