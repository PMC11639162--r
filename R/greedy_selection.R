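## Greedy forward search for the balance most associated with a censored
## outcome. The criterion is the maximized model log-likelihood (partial
## for Cox, full for the AFT family); ties break toward the lowest taxon
## index, with the plus side tried before the minus side.

.fit_balance <- function(model, b, outcome, ties = "efron",
                         dist = "weibull") {
  fit <- tryCatch(
    if (model == "cox") fit_cox(b, outcome, ties = ties)
    else fit_weibull_aft(b, outcome, dist = dist),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged))
    return(list(ok = FALSE, fit = fit))
  gamma <- if (model == "cox") fit$gamma else fit$gamma_prime
  list(ok = TRUE, loglik = fit$loglik, gamma = gamma,
       p_gamma = fit$p_gamma, fit = fit)
}

.subset_outcome <- function(outcome, idx) {
  survival_outcome(outcome$time[idx], outcome$event[idx],
                   Z = if (is.null(outcome$Z)) NULL
                       else outcome$Z[idx, , drop = FALSE],
                   sample_ids = outcome$sample_ids[idx])
}

.subset_composition <- function(X, idx) {
  composition(X$X[idx, , drop = FALSE])
}

.step <- function(spec, eval, added_taxon = NA_integer_,
                  added_side = "init") {
  list(spec = spec, criterion = eval$loglik, gamma = eval$gamma,
       p_gamma = eval$p_gamma, added_taxon = added_taxon,
       added_side = added_side)
}

#' Initialize the search with the best 1-vs-1 balance
#'
#' Evaluates every pair of distinct taxa as a one-taxon-vs-one-taxon
#' balance (swapping numerator and denominator only flips the sign of the
#' balance and of \eqn{\hat\gamma}, leaving the log-likelihood unchanged,
#' so each unordered pair is fitted once and the orientation with
#' \eqn{\hat\gamma \ge 0} is reported). Returns the pair maximizing the
#' fitted model log-likelihood.
#'
#' @param X a [composition].
#' @param outcome a [survival_outcome].
#' @param model `"cox"` or `"weibull"`.
#' @param ties tie handling for the Cox model.
#' @param dist AFT error family.
#' @return a selection step: list with `spec`, `criterion` (log-likelihood),
#'   `gamma`, `p_gamma`, `added_taxon`, `added_side`.
#' @export
initialize_pair <- function(X, outcome, model = c("cox", "weibull"),
                            ties = "efron", dist = "weibull") {
  model <- match.arg(model)
  stopifnot(inherits(X, "composition"))
  K <- ncol(X$X)
  if (K < 2) stop("need at least 2 taxa")
  best <- NULL
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      spec <- balance_spec(i, j)
      ev <- .fit_balance(model, compute_balance(X, spec), outcome,
                         ties = ties, dist = dist)
      if (!ev$ok) next
      if (is.null(best) || ev$loglik > best$criterion) {
        if (ev$gamma < 0) {          # canonical orientation: gamma >= 0
          spec <- swap_sign(spec)
          ev$gamma <- -ev$gamma
        }
        best <- .step(spec, ev)
      }
    }
  }
  if (is.null(best))
    stop("no initial pair could be fitted; all model fits failed")
  best
}

#' Grow a balance by greedy forward addition
#'
#' Starting from an initial step, every unused taxon is tried on each side
#' of the balance; the single (taxon, side) addition with the largest
#' model log-likelihood is accepted if it improves the criterion by more
#' than `tol`. The search stops when no addition clears `tol`, when
#' `max_taxa` taxa are in the balance, or when all taxa are used. Candidate
#' fits that fail to converge are skipped with a message.
#'
#' @param X a [composition].
#' @param outcome a [survival_outcome].
#' @param model `"cox"` or `"weibull"`.
#' @param init the starting step from [initialize_pair()].
#' @param max_taxa maximum total number of taxa in the balance (default 15).
#' @param tol minimum log-likelihood improvement to accept an addition
#'   (default 2, about an AIC penalty for one extra parameter-equivalent).
#' @param ties,dist passed to the model fitters.
#' @return list of accepted selection steps, starting with `init`; the
#'   criterion is strictly increasing by more than `tol` along the trace.
#' @export
greedy_grow <- function(X, outcome, model = c("cox", "weibull"), init,
                        max_taxa = 15, tol = 2, ties = "efron",
                        dist = "weibull") {
  model <- match.arg(model)
  stopifnot(inherits(X, "composition"))
  if (max_taxa < 2) stop("max_taxa must be at least 2")
  if (tol < 0) stop("tol must be nonnegative")
  K <- ncol(X$X)
  trace <- list(init)
  current <- init
  repeat {
    spec <- current$spec
    used <- c(spec$plus, spec$minus)
    if (length(used) >= max_taxa || length(used) >= K) break
    free <- setdiff(seq_len(K), used)
    best <- NULL
    n_failed <- 0
    for (side in c("plus", "minus")) {   # plus side tried first on ties
      for (j in free) {
        cand <- if (side == "plus")
          balance_spec(c(spec$plus, j), spec$minus)
        else
          balance_spec(spec$plus, c(spec$minus, j))
        ev <- .fit_balance(model, compute_balance(X, cand), outcome,
                           ties = ties, dist = dist)
        if (!ev$ok) { n_failed <- n_failed + 1; next }
        if (is.null(best) || ev$loglik > best$criterion)
          best <- .step(cand, ev, added_taxon = j, added_side = side)
      }
    }
    if (n_failed > 0)
      message(n_failed, " candidate fit(s) failed to converge and were skipped")
    if (is.null(best) || best$criterion - current$criterion <= tol) break
    trace[[length(trace) + 1]] <- best
    current <- best
  }
  trace
}

.run_search <- function(X, outcome, model, max_taxa, tol, ties, dist) {
  init <- initialize_pair(X, outcome, model, ties = ties, dist = dist)
  greedy_grow(X, outcome, model, init, max_taxa = max_taxa, tol = tol,
              ties = ties, dist = dist)
}

.cv_choose_size <- function(X, outcome, model, max_taxa, tol, ties, dist,
                            cv_folds) {
  n <- nrow(X$X)
  if (cv_folds < 2 || cv_folds > n) stop("invalid number of CV folds")
  folds <- sample(rep_len(seq_len(cv_folds), n))
  # test-fold log-likelihood (refit on the held-out fold at the trained
  # spec) per balance size, averaged across folds
  sizes <- 2:max_taxa
  ll <- matrix(NA_real_, nrow = cv_folds, ncol = length(sizes))
  for (f in seq_len(cv_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (sum(outcome$event[te]) < 2) next
    trace <- tryCatch(
      .run_search(.subset_composition(X, tr), .subset_outcome(outcome, tr),
                  model, max_taxa, tol, ties, dist),
      error = function(e) NULL)
    if (is.null(trace)) next
    Xte <- .subset_composition(X, te)
    oute <- .subset_outcome(outcome, te)
    for (s in seq_along(trace)) {
      sz <- length(trace[[s]]$spec$plus) + length(trace[[s]]$spec$minus)
      ev <- .fit_balance(model, compute_balance(Xte, trace[[s]]$spec), oute,
                         ties = ties, dist = dist)
      if (ev$ok) ll[f, match(sz, sizes)] <- ev$loglik
    }
  }
  ok <- colSums(!is.na(ll)) > 0
  if (!any(ok)) return(NULL)
  mu <- colMeans(ll, na.rm = TRUE)
  se <- apply(ll, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(0)
    stats::sd(v) / sqrt(length(v))
  })
  best <- which.max(replace(mu, !ok, -Inf))
  # smallest size within one SE of the best mean criterion
  within <- which(ok & mu >= mu[best] - se[best])
  sizes[min(within)]
}

#' Select the balance most associated with a survival outcome
#'
#' Runs the community-level kernel pre-test, then the greedy balance
#' search ([initialize_pair()] followed by [greedy_grow()]), and reports
#' the final balance with its fitted model, the step trace, the community
#' test result and a caution flag. The reported orientation always has
#' \eqn{\hat\gamma \ge 0}: under the Cox model the plus set is
#' hazard-increasing; under the AFT model it is survival-time-increasing.
#'
#' @param X a [composition] used for balance computation.
#' @param outcome a [survival_outcome].
#' @param model `"cox"` or `"weibull"`.
#' @param counts optional [count_table] of raw counts for the community
#'   test (Jaccard presence/absence and pseudocount-free Bray-Curtis).
#'   If omitted, the Bray-Curtis kernel is built from `X` and the Jaccard
#'   kernel is skipped.
#' @param max_taxa,tol greedy stopping controls; see [greedy_grow()].
#' @param cv_folds optional number of cross-validation folds used to pick
#'   the balance size (smallest size within one SE of the best mean
#'   held-out log-likelihood); `NULL` (default) returns the final trace
#'   element.
#' @param n_permutations permutations for the community test.
#' @param alpha significance level of the caution gate (default 0.05).
#' @param seed optional integer seed controlling CV fold assignment and
#'   the community-test permutations.
#' @param ties,dist passed to the model fitters.
#' @return object of class `selection_result`: `best_spec`, `fit`,
#'   `trace`, `community_test`, `caution`, `taxon_ids`, `settings`.
#' @export
select_balance <- function(X, outcome, model = c("cox", "weibull"),
                           counts = NULL, max_taxa = 15, tol = 2,
                           cv_folds = NULL, n_permutations = 999,
                           alpha = 0.05, seed = NULL, ties = "efron",
                           dist = "weibull") {
  model <- match.arg(model)
  stopifnot(inherits(X, "composition"), inherits(outcome, "survival_outcome"))
  if (!is.null(seed)) set.seed(seed)

  ct <- if (!is.null(counts)) {
    community_test(counts, outcome, n_permutations = n_permutations)
  } else {
    message("no raw counts supplied: community test uses Bray-Curtis only")
    mirkat_s(list(bray_curtis = kernel_from_distance(bray_curtis(X))),
             outcome, n_permutations = n_permutations)
  }
  caution <- gate_warning(ct, alpha = alpha)
  if (caution)
    warning("no significant community-level association (omnibus p = ",
            signif(ct$omnibus_p, 3),
            "): advising caution when interpreting the selected balance",
            call. = FALSE)

  trace <- .run_search(X, outcome, model, max_taxa, tol, ties, dist)

  if (!is.null(cv_folds)) {
    size <- .cv_choose_size(X, outcome, model, max_taxa, tol, ties, dist,
                            cv_folds)
    if (!is.null(size)) {
      sizes <- vapply(trace, function(s)
        length(s$spec$plus) + length(s$spec$minus), integer(1))
      keep <- which(sizes <= size)
      trace <- trace[seq_len(max(keep))]
    }
  }

  final <- trace[[length(trace)]]
  spec <- final$spec
  fit <- .fit_balance(model, compute_balance(X, spec), outcome,
                      ties = ties, dist = dist)
  if (fit$ok && fit$gamma < 0) {
    spec <- swap_sign(spec)
    fit <- .fit_balance(model, compute_balance(X, spec), outcome,
                        ties = ties, dist = dist)
  }
  if (!fit$ok) stop("final model refit failed")

  structure(list(
    best_spec = spec,
    fit = fit$fit,
    gamma = fit$gamma,
    trace = trace,
    community_test = ct,
    caution = caution,
    taxon_ids = X$taxon_ids,
    settings = list(model = model, max_taxa = max_taxa, tol = tol,
                    cv_folds = cv_folds, n_permutations = n_permutations,
                    alpha = alpha, seed = seed, ties = ties, dist = dist)),
    class = "selection_result")
}

#' Tabulate a selection trace
#'
#' @param result a `selection_result` (or a raw trace list).
#' @return data frame with one row per accepted step: balance size,
#'   criterion, effect estimate, p-value, added taxon and side.
#' @export
trace_table <- function(result) {
  trace <- if (inherits(result, "selection_result")) result$trace else result
  do.call(rbind, lapply(seq_along(trace), function(i) {
    s <- trace[[i]]
    data.frame(step = i,
               n_taxa = length(s$spec$plus) + length(s$spec$minus),
               plus = paste(s$spec$plus, collapse = ","),
               minus = paste(s$spec$minus, collapse = ","),
               criterion = s$criterion,
               gamma = s$gamma,
               p_gamma = s$p_gamma,
               added_taxon = s$added_taxon,
               added_side = s$added_side)
  }))
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selected balance (", x$settings$model, " model)\n", sep = "")
  cat("  plus  (k+ = ", x$best_spec$k_plus, "): ",
      paste(x$taxon_ids[x$best_spec$plus], collapse = ", "), "\n", sep = "")
  cat("  minus (k- = ", x$best_spec$k_minus, "): ",
      paste(x$taxon_ids[x$best_spec$minus], collapse = ", "), "\n", sep = "")
  cat(sprintf("  gamma = %.4f, LRT p = %.3g\n", x$gamma, x$fit$p_gamma))
  cat(sprintf("  community omnibus p = %.4g; caution = %s\n",
              x$community_test$omnibus_p, x$caution))
  invisible(x)
}
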