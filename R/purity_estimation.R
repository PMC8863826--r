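# Simplified tumor-content estimation from tumor-only VAFs.
#
# A transparent grid-likelihood estimator over purity p in {0.01, ..., 1}:
# each presumed-somatic variant is explained by one of three genotype
# states (mutant copies m, local total copy number cn) with expected VAF
# f(p, state) = m p / (2 (1 - p) + cn p), clonality fixed at 1, and
# contributes the binomial log-likelihood of its read counts under the best
# state.  Because a clonal-het cohort at purity p is fit equally well by
# the amplified state at purity p/2 (f is identical), the default adds a
# sparsity log-prior over states favoring the diploid heterozygous
# interpretation; this is the standard way purity callers resolve the
# halving degeneracy.  Set `state_prior = NULL` for the pure grid MLE.

.default_states <- list(c(m = 1, cn = 2), c(m = 2, cn = 2), c(m = 1, cn = 1))

#' Default sparsity prior over genotype states
#'
#' Weight 0.9 on the first (het-diploid) state and the remaining 0.1 split
#' over the aberrant states; a single state gets weight 1.
#'
#' @param states List of genotype states as in [estimate_purity()].
#' @return Numeric vector of prior weights.
#' @export
default_state_prior <- function(states) {
  k <- length(states)
  if (k == 1) 1 else c(0.9, rep(0.1 / (k - 1), k - 1))
}

#' Estimate tumor purity from presumed-somatic calls
#'
#' Grid maximum-(penalized-)likelihood estimate of tumor purity from
#' tumor-only read counts.  Per grid purity and variant, the best of the
#' allowed genotype states is taken; `p_hat` maximizes the summed best-state
#' binomial log-likelihood (plus the state log-prior), with ties broken
#' toward smaller purity.
#'
#' @param calls Variant-call table; at least 5 calls with positive depth,
#'   not all with VAF 0.
#' @param states List of genotype states, each `c(m = , cn = )`; default
#'   het-diploid (1,2), amplified mutant (2,2), and mutant on a
#'   single-copy locus (1,1).
#' @param state_prior Prior weights over `states` (normalized internally),
#'   or `NULL` for an unpenalized MLE.  Default `c(0.9, 0.05, 0.05)`
#'   favors the het-diploid state.
#' @param grid_step Purity grid resolution (default 0.01).
#' @return An object of class `purity_estimate`: `p_hat`,
#'   `log_likelihood` (at `p_hat`, including any prior term),
#'   `state_assignment` (per-variant chosen state at `p_hat`),
#'   `grid_step`, and the full `grid` / `grid_loglik` profile.
#' @examples
#' calls <- variant_call("chr1", 1:50 * 100, "A", "T",
#'                       depth_total = 1000, depth_alt = 250)
#' estimate_purity(calls, states = list(c(m = 1, cn = 2)))$p_hat  # 0.5
#' @export
estimate_purity <- function(calls, states = .default_states,
                            state_prior = default_state_prior(states),
                            grid_step = 0.01) {
  validate_calls(calls)
  calls <- calls[calls$depth_total > 0L, , drop = FALSE]
  if (nrow(calls) < 5) {
    stop("purity estimation needs at least 5 calls with positive depth")
  }
  if (all(calls$depth_alt == 0L)) stop("all VAFs are zero")
  if (!is.null(state_prior)) {
    if (length(state_prior) != length(states) || any(state_prior <= 0)) {
      stop("state_prior must hold one positive weight per state")
    }
    log_prior <- log(state_prior / sum(state_prior))
  } else {
    log_prior <- rep(0, length(states))
  }
  n_steps <- round(1 / grid_step)
  grid <- seq_len(n_steps) / n_steps
  alt <- calls$depth_alt; dp <- calls$depth_total
  n <- nrow(calls)
  grid_ll <- numeric(length(grid))
  best_state <- integer(n)
  for (k in seq_along(grid)) {
    p <- grid[k]
    ll <- matrix(-Inf, n, length(states))
    for (j in seq_along(states)) {
      s <- states[[j]]
      f <- s[["m"]] * p / (2 * (1 - p) + s[["cn"]] * p)
      ll[, j] <- stats::dbinom(alt, dp, f, log = TRUE) + log_prior[j]
    }
    best_j <- max.col(ll, ties.method = "first")
    grid_ll[k] <- sum(ll[cbind(seq_len(n), best_j)])
    if (k == 1 || grid_ll[k] > max(grid_ll[seq_len(k - 1)])) {
      best_state <- best_j
    }
  }
  k_hat <- which.max(grid_ll)           # first max = smallest p on ties
  state_lab <- vapply(states, function(s)
    sprintf("m%d_cn%d", s[["m"]], s[["cn"]]), "")
  assign_df <- data.frame(calls[c("chrom", "pos", "ref", "alt")],
                          state = state_lab[best_state],
                          stringsAsFactors = FALSE)
  structure(list(p_hat = grid[k_hat], log_likelihood = grid_ll[k_hat],
                 state_assignment = assign_df, grid_step = grid_step,
                 grid = grid, grid_loglik = grid_ll, n_calls = n),
            class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("<purity_estimate> p_hat = %.2f (log-lik %.2f, %d calls)\n",
              x$p_hat, x$log_likelihood, x$n_calls))
  invisible(x)
}

#' Estimate purity for each fraction of a trio
#'
#' Runs [estimate_purity()] independently on each fraction's detected call
#' set.  Presumed-somatic input is the calls absent from the trio's blood
#' key set when one is available, otherwise all detected calls.  Fractions
#' with fewer than 5 usable calls yield `NA` with a note instead of an
#' estimate.
#'
#' @param trio A [fraction_trio()] whose fractions already passed
#'   [detect()].
#' @param ... Passed on to [estimate_purity()].
#' @return A list with `estimates` (named list over fractions; each a
#'   `purity_estimate` or `NULL`), `p_hat` (named numeric vector, `NA`
#'   where unavailable) and `tumor_exceeds_unseparated` (logical).
#' @export
purity_by_fraction <- function(trio, ...) {
  stopifnot(inherits(trio, "fraction_trio"))
  bk <- if (!is.null(trio$blood_keys)) variant_key(trio$blood_keys) else NULL
  estimates <- list()
  p_hat <- stats::setNames(rep(NA_real_, 3), fraction_names())
  for (nm in fraction_names()) {
    calls <- trio[[nm]]
    if (!is.null(bk)) calls <- calls[!(variant_key(calls) %in% bk), , drop = FALSE]
    est <- tryCatch(estimate_purity(calls, ...), error = function(e) NULL)
    estimates[[nm]] <- est
    if (!is.null(est)) p_hat[nm] <- est$p_hat
  }
  tumor_gt <- if (anyNA(p_hat[c("tumor", "unseparated")])) NA else
    unname(p_hat["tumor"] > p_hat["unseparated"])
  list(estimates = estimates, p_hat = p_hat,
       tumor_exceeds_unseparated = tumor_gt)
}
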