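# Independent oracles, deliberately naive: they re-derive quantities from
# first principles and never call the code paths they are used to check.

# Breslow partial log-likelihood for a single covariate, written out
# directly from the definition (no ties assumed in the data used with it).
breslow_partial_loglik <- function(gamma, time, event, b) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + gamma * b[i] - log(sum(exp(gamma * b[risk])))
  }
  ll
}

# Grid argmax of the Breslow partial likelihood.
breslow_grid_mle <- function(time, event, b, grid) {
  ll <- vapply(grid, breslow_partial_loglik, numeric(1),
               time = time, event = event, b = b)
  list(gamma = grid[which.max(ll)], loglik = max(ll))
}

# Uncensored two-parameter Weibull log-likelihood (shape k, scale lam),
# maximized by direct optimization over both parameters.
weibull_mle_oracle <- function(time) {
  nll <- function(par) {
    k <- exp(par[1]); lam <- exp(par[2])
    -sum(stats::dweibull(time, shape = k, scale = lam, log = TRUE))
  }
  o <- stats::optim(c(0, log(mean(time))), nll, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 5000))
  list(shape = exp(o$par[1]), scale = exp(o$par[2]), loglik = -o$value)
}

# Enumerate every unordered balance with k+ <= kmax and k- <= kmax and
# return the one with the largest fitted model log-likelihood.
all_balances <- function(K, kmax = 2) {
  out <- list()
  idx <- seq_len(K)
  sets <- unlist(lapply(seq_len(kmax), function(k)
    utils::combn(idx, k, simplify = FALSE)), recursive = FALSE)
  for (a in seq_along(sets)) {
    for (b in seq_along(sets)) {
      if (b <= a) next  # unordered: orientation swap has equal loglik
      if (length(intersect(sets[[a]], sets[[b]])) > 0) next
      out[[length(out) + 1]] <- list(plus = sets[[a]], minus = sets[[b]])
    }
  }
  out
}

exhaustive_best <- function(X, outcome, model = "cox", kmax = 2) {
  cands <- all_balances(ncol(X$X), kmax)
  best <- NULL
  for (cand in cands) {
    spec <- balance_spec(cand$plus, cand$minus)
    b <- compute_balance(X, spec)
    fit <- tryCatch(
      if (model == "cox") fit_cox(b, outcome)
      else fit_weibull_aft(b, outcome),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik)
      best <- list(spec = spec, loglik = fit$loglik)
  }
  best
}

# Core greedy search without the community-test wrapper (used where only
# the selection path is under scrutiny).
greedy_final <- function(X, outcome, model = "cox", max_taxa = 15, tol = 2) {
  init <- initialize_pair(X, outcome, model)
  tr <- suppressMessages(greedy_grow(X, outcome, model, init,
                                     max_taxa = max_taxa, tol = tol))
  tr[[length(tr)]]
}

# Set-level agreement of two balances, ignoring orientation.
same_balance <- function(s1, s2) {
  (setequal(s1$plus, s2$plus) && setequal(s1$minus, s2$minus)) ||
    (setequal(s1$plus, s2$minus) && setequal(s1$minus, s2$plus))
}
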