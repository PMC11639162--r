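#' Specify a balance of two disjoint taxon sets
#'
#' A balance is defined by an ordered set of "plus" taxon indices (the set
#' whose geometric mean enters the numerator) and a disjoint "minus" set
#' (denominator). Under the Cox model the plus set is interpreted as
#' hazard-increasing; under the AFT model as survival-time-increasing.
#'
#' @param plus,minus integer vectors of taxon (column) indices; disjoint,
#'   each nonempty.
#' @return object of class `balance_spec` with fields `plus`, `minus` and
#'   derived sizes `k_plus`, `k_minus`.
#' @export
balance_spec <- function(plus, minus) {
  plus <- as.integer(plus)
  minus <- as.integer(minus)
  if (length(plus) < 1 || length(minus) < 1)
    stop("both taxon sets must be nonempty")
  if (anyDuplicated(plus) || anyDuplicated(minus))
    stop("duplicate indices within a set")
  if (length(intersect(plus, minus)) > 0)
    stop("plus and minus sets must be disjoint")
  if (any(c(plus, minus) < 1)) stop("indices must be >= 1")
  structure(list(plus = plus, minus = minus,
                 k_plus = length(plus), k_minus = length(minus)),
            class = "balance_spec")
}

#' @export
print.balance_spec <- function(x, ...) {
  cat("balance_spec: plus {", paste(x$plus, collapse = ","),
      "} vs minus {", paste(x$minus, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Compute per-sample balance values
#'
#' The balance of sample i is the normalized log-ratio of geometric means
#'
#' \deqn{B_i = \sqrt{k_+ k_- / (k_+ + k_-)}\,
#'   \log\frac{(\prod_{j \in I_+} X_{ij})^{1/k_+}}
#'            {(\prod_{j \in I_-} X_{ij})^{1/k_-}},}
#'
#' computed in log space (natural log) as the difference of mean log
#' abundances, never by multiplying abundances. As a log-contrast with
#' coefficients summing to zero it is invariant to rescaling a sample's
#' abundances, which is what makes it a legitimate feature for
#' compositional data.
#'
#' @param X a [composition], or any strictly positive numeric matrix
#'   (samples x taxa) — closure is not required because the balance is a
#'   log-contrast and therefore invariant to per-sample rescaling.
#' @param spec a [balance_spec] with indices valid for `X`.
#' @return numeric vector of balance values, named by sample id.
#' @export
compute_balance <- function(X, spec) {
  stopifnot(inherits(spec, "balance_spec"))
  m <- if (inherits(X, "composition")) X$X else as.matrix(X)
  if (!is.numeric(m)) stop("abundances must be numeric")
  K <- ncol(m)
  if (any(c(spec$plus, spec$minus) > K))
    stop("balance indices exceed number of taxa")
  if (any(m <= 0)) stop("abundances must be strictly positive")
  lX <- log(m)
  norm <- sqrt(spec$k_plus * spec$k_minus / (spec$k_plus + spec$k_minus))
  b <- norm * (rowMeans(lX[, spec$plus, drop = FALSE]) -
                 rowMeans(lX[, spec$minus, drop = FALSE]))
  names(b) <- if (inherits(X, "composition")) X$sample_ids else rownames(m)
  b
}

#' Exchange the plus and minus sets of a balance
#'
#' Negates the balance exactly: `compute_balance(X, swap_sign(s))`
#' equals `-compute_balance(X, s)`.
#'
#' @param spec a [balance_spec].
#' @return the swapped [balance_spec].
#' @export
swap_sign <- function(spec) {
  stopifnot(inherits(spec, "balance_spec"))
  balance_spec(plus = spec$minus, minus = spec$plus)
}

#' Write per-sample balance values as TSV
#'
#' @param b named numeric vector from [compute_balance()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_balance_tsv <- function(b, path) {
  df <- data.frame(sample_id = names(b), balance = as.numeric(b))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
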