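#' Bray-Curtis distance matrix
#'
#' \eqn{D_{ij} = \sum_k |X_{ik} - X_{jk}| / \sum_k (X_{ik} + X_{jk})};
#' with rows closed to 1 the denominator is 2. Computed on the composition
#' closed WITHOUT pseudocount so true zeros are preserved (pseudocount
#' inflation would distort ecological distances).
#'
#' @param X a [composition] or a nonnegative matrix with positive row sums.
#' @return object of class `distance_matrix` with fields `D` (symmetric,
#'   zero diagonal, entries in `[0,1]`) and `metric_name = "bray_curtis"`.
#' @export
bray_curtis <- function(X) {
  m <- if (inherits(X, "composition")) X$X else as.matrix(X)
  D <- as.matrix(vegan::vegdist(m, method = "bray"))
  dimnames(D) <- list(rownames(m), rownames(m))
  structure(list(D = D, metric_name = "bray_curtis"),
            class = "distance_matrix")
}

#' Jaccard distance matrix on presence/absence
#'
#' Presence is defined as raw count > 0 (before any pseudocount).
#' \eqn{D_{ij} = 1 - |A_i \cap A_j| / |A_i \cup A_j|} where \eqn{A_i} is
#' the set of taxa present in sample i. A pair of samples with an empty
#' union is assigned distance 0 with a message.
#'
#' @param tab a [count_table] (raw counts).
#' @return object of class `distance_matrix` with `metric_name = "jaccard"`.
#' @export
jaccard <- function(tab) {
  m <- if (inherits(tab, "count_table")) tab$counts else as.matrix(tab)
  P <- (m > 0) * 1
  inter <- tcrossprod(P)
  rs <- rowSums(P)
  uni <- outer(rs, rs, "+") - inter
  D <- 1 - inter / uni
  if (any(uni == 0)) {
    message("sample pair(s) with empty presence union: distance set to 0")
    D[uni == 0] <- 0
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  structure(list(D = D, metric_name = "jaccard"), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix (", x$metric_name, "): ", nrow(x$D), " samples\n",
      sep = "")
  invisible(x)
}

#' Gower-center a distance matrix into a PSD kernel
#'
#' Computes \eqn{K = -\tfrac12 J D^{\circ 2} J} with
#' \eqn{J = I - \mathbf{1}\mathbf{1}^\top/n} (elementwise square of D),
#' then clips negative eigenvalues to zero so the result is positive
#' semidefinite.
#'
#' @param D a `distance_matrix` or a symmetric numeric matrix.
#' @return symmetric PSD kernel matrix.
#' @export
kernel_from_distance <- function(D) {
  d <- if (inherits(D, "distance_matrix")) D$D else as.matrix(D)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  K <- -0.5 * J %*% (d^2) %*% J
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < 0) {
    K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    K <- (K + t(K)) / 2
  }
  dimnames(K) <- dimnames(d)
  K
}

#' Cauchy-combination (ACAT) of p-values
#'
#' Transforms each p to a standard Cauchy quantile, averages, and back
#' transforms. Identical inputs are a fixed point: `acat(c(p, p)) == p`.
#'
#' @param p vector of p-values in (0, 1].
#' @param weights optional nonnegative weights, default equal.
#' @return combined p-value.
#' @export
acat <- function(p, weights = NULL) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  weights <- weights / sum(weights)
  stat <- sum(weights * tan((0.5 - p) * pi))
  min(1, max(0, 0.5 - atan(stat) / pi))
}

#' Community-level kernel association test for survival outcomes
#'
#' A kernel-machine score test in the MiRKAT-S style. Martingale residuals
#' r from a null Cox model containing only the covariates (with no
#' covariates this reduces to the Nelson-Aalen cumulative hazard) play the
#' role of the outcome; the per-kernel statistic is \eqn{Q = r^\top K r}.
#' P-values come from permuting the residuals (the same permutations are
#' reused across kernels, preserving their correlation) with the
#' \eqn{(b+1)/(B+1)} estimator, and the omnibus p-value is the Cauchy
#' combination (ACAT) across kernels.
#'
#' @param kernels named list of kernel matrices aligned to the samples.
#' @param outcome a [survival_outcome]; must contain at least one event.
#' @param n_permutations number of residual permutations B (default 999;
#'   values below 99 trigger a warning).
#' @param seed optional integer seed for the permutations.
#' @return object of class `kernel_test_result`: `per_kernel_p`,
#'   `omnibus_p`, `statistic`, `n_permutations`.
#' @export
mirkat_s <- function(kernels, outcome, n_permutations = 999, seed = NULL) {
  stopifnot(inherits(outcome, "survival_outcome"), is.list(kernels))
  if (sum(outcome$event) < 1) stop("at least one event is required")
  if (n_permutations < 99)
    warning("fewer than 99 permutations: p-values will be coarse")
  n <- length(outcome$time)
  for (K in kernels) if (!all(dim(K) == n)) stop("kernel dimension mismatch")
  if (is.null(names(kernels)))
    names(kernels) <- paste0("kernel", seq_along(kernels))

  df <- data.frame(time = outcome$time, event = outcome$event)
  if (is.null(outcome$Z)) {
    fit0 <- survival::coxph(survival::Surv(time, event) ~ 1, data = df)
  } else {
    df <- cbind(df, as.data.frame(outcome$Z))
    fit0 <- survival::coxph(stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(colnames(outcome$Z), collapse = " + "))), data = df)
  }
  r <- stats::residuals(fit0, type = "martingale")

  if (!is.null(seed)) set.seed(seed)
  B <- n_permutations
  perm <- replicate(B, sample.int(n))
  R <- matrix(r[perm], nrow = n, ncol = B)

  stat <- numeric(length(kernels))
  pk <- numeric(length(kernels))
  names(stat) <- names(pk) <- names(kernels)
  for (k in seq_along(kernels)) {
    K <- kernels[[k]]
    q_obs <- drop(crossprod(r, K %*% r))
    q_perm <- colSums((K %*% R) * R)
    stat[k] <- q_obs
    pk[k] <- (1 + sum(q_perm >= q_obs)) / (B + 1)
  }
  structure(list(per_kernel_p = pk,
                 omnibus_p = acat(pk),
                 statistic = stat,
                 n_permutations = B),
            class = "kernel_test_result")
}

#' @export
print.kernel_test_result <- function(x, ...) {
  cat("community-level kernel association test\n")
  for (k in names(x$per_kernel_p))
    cat(sprintf("  %-12s Q = %.4g, p = %.4g\n", k, x$statistic[k],
                x$per_kernel_p[k]))
  cat(sprintf("  omnibus p = %.4g (%d permutations)\n", x$omnibus_p,
              x$n_permutations))
  invisible(x)
}

#' Community-association caution gate
#'
#' Returns `TRUE` (advise caution) when the omnibus p-value is at or above
#' `alpha`: the selected balance is then not backed by a detectable global
#' community-outcome association. The gate never blocks selection; an
#' insignificant community-level association does not invalidate the
#' balance, it only prompts caution in interpreting it.
#'
#' @param result a `kernel_test_result`.
#' @param alpha significance level (default 0.05).
#' @return logical caution flag.
#' @export
gate_warning <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "kernel_test_result"))
  result$omnibus_p >= alpha
}

#' Run the default two-kernel community test
#'
#' Convenience wrapper building the Bray-Curtis kernel from the
#' pseudocount-free closed composition and the Jaccard kernel from raw
#' presence/absence, then calling [mirkat_s()].
#'
#' @param tab a [count_table] of raw counts.
#' @param outcome a [survival_outcome].
#' @param n_permutations,seed passed to [mirkat_s()].
#' @return a `kernel_test_result`.
#' @export
community_test <- function(tab, outcome, n_permutations = 999, seed = NULL) {
  stopifnot(inherits(tab, "count_table"))
  Xraw <- tab$counts / rowSums(tab$counts)  # true zeros preserved
  kern <- list(
    bray_curtis = kernel_from_distance(bray_curtis(Xraw)),
    jaccard = kernel_from_distance(jaccard(tab)))
  mirkat_s(kern, outcome, n_permutations = n_permutations, seed = seed)
}
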