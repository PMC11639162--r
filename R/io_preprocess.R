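#' Construct a count table
#'
#' A count table holds raw nonnegative integer abundances with samples in
#' rows and taxa in columns, together with unique sample and taxon
#' identifiers. It is the entry point of the pipeline; all downstream
#' objects (compositions, balances) are derived from it.
#'
#' @param counts numeric matrix of nonnegative counts, samples x taxa.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `rownames(counts)`.
#' @param taxon_ids character vector of unique taxon identifiers;
#'   defaults to `colnames(counts)`.
#' @return An object of class `count_table` with fields `counts`,
#'   `sample_ids`, `taxon_ids`.
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon identifiers")
  if (length(sample_ids) != nrow(counts) || length(taxon_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions")
  if (ncol(counts) < 2) stop("need at least 2 taxa")
  if (nrow(counts) < 3) stop("need at least 3 samples")
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 taxon_ids = taxon_ids),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(x$sample_ids), "samples x",
      length(x$taxon_ids), "taxa\n")
  invisible(x)
}

#' Construct a survival outcome
#'
#' Per-sample follow-up time and event indicator, with an optional numeric
#' covariate matrix, row-aligned to a count table.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (1 = event observed, 0 = right-censored).
#' @param Z optional numeric covariate matrix (samples x p) with column names.
#' @param sample_ids optional sample identifiers.
#' @return An object of class `survival_outcome`.
#' @export
survival_outcome <- function(time, event, Z = NULL, sample_ids = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("time must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be coded 0/1")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (!is.numeric(Z)) stop("covariates must be numeric")
    if (nrow(Z) != length(time)) stop("covariate rows must match samples")
    if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  }
  if (!is.null(sample_ids)) {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != length(time)) stop("sample_ids length mismatch")
  }
  structure(list(time = time, event = event, Z = Z, sample_ids = sample_ids),
            class = "survival_outcome")
}

#' @export
print.survival_outcome <- function(x, ...) {
  cat("survival_outcome:", length(x$time), "samples,",
      sum(x$event), "events")
  if (!is.null(x$Z)) cat(",", ncol(x$Z), "covariate(s)")
  cat("\n")
  invisible(x)
}

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read count and metadata tables
#'
#' Reads a samples x taxa count table (first column = sample id) and a
#' metadata table keyed by the same identifier, aligns them by the shared
#' samples, and returns the count table together with the survival outcome.
#' Samples present in only one of the two files are dropped with a message.
#'
#' @param counts_path path to a TSV/CSV count table, samples in rows,
#'   first column the sample identifier.
#' @param metadata_path path to a TSV/CSV metadata table keyed by the same
#'   identifier in its first column.
#' @param time_col,event_col names of the survival time and 0/1 event
#'   columns in the metadata.
#' @param covariate_cols optional character vector of numeric covariate
#'   column names to carry along.
#' @return list with elements `counts` (a [count_table]) and `outcome`
#'   (a [survival_outcome]), rows aligned.
#' @export
read_tables <- function(counts_path, metadata_path, time_col, event_col,
                        covariate_cols = NULL) {
  if (!file.exists(counts_path)) stop("count table not found: ", counts_path)
  if (!file.exists(metadata_path)) stop("metadata not found: ", metadata_path)
  ct <- .read_table_auto(counts_path)
  md <- .read_table_auto(metadata_path)
  for (cl in c(time_col, event_col, covariate_cols)) {
    if (!cl %in% colnames(md)) stop("metadata column missing: ", cl)
  }
  ids_ct <- as.character(ct[[1]])
  ids_md <- as.character(md[[1]])
  shared <- intersect(ids_ct, ids_md)
  if (length(shared) == 0) stop("no overlapping samples between tables")
  n_drop <- length(union(ids_ct, ids_md)) - length(shared)
  if (n_drop > 0)
    message(n_drop, " sample(s) absent from one table dropped")
  ct <- ct[match(shared, ids_ct), , drop = FALSE]
  md <- md[match(shared, ids_md), , drop = FALSE]
  cmat <- as.matrix(ct[, -1, drop = FALSE])
  storage.mode(cmat) <- "numeric"
  if (any(is.na(cmat))) stop("non-numeric values in count table")
  time <- md[[time_col]]
  event <- md[[event_col]]
  if (!is.numeric(time)) stop("time column is not numeric")
  if (!is.numeric(event)) stop("event column is not numeric")
  Z <- NULL
  if (length(covariate_cols)) {
    Z <- as.matrix(md[, covariate_cols, drop = FALSE])
    storage.mode(Z) <- "numeric"
    if (any(is.na(Z))) stop("non-numeric covariate values")
  }
  tab <- count_table(cmat, sample_ids = shared)
  out <- survival_outcome(time, event, Z = Z, sample_ids = shared)
  list(counts = tab, outcome = out)
}

#' Mean relative abundance per taxon
#'
#' Mean over samples of count / sample total, the filtering statistic.
#' Computed on raw counts, before any zero replacement.
#'
#' @param tab a [count_table].
#' @return named numeric vector, one value per taxon.
#' @export
mean_relative_abundance <- function(tab) {
  stopifnot(inherits(tab, "count_table"))
  tot <- rowSums(tab$counts)
  if (any(tot == 0)) stop("sample(s) with all-zero counts")
  colMeans(tab$counts / tot)
}

#' Filter taxa by mean relative abundance
#'
#' `remove_rare` drops taxa whose mean relative abundance is strictly below
#' `threshold`; `keep_common` keeps only taxa strictly above it. Surviving
#' taxa keep their input order.
#'
#' @param tab a [count_table].
#' @param mode `"remove_rare"` or `"keep_common"`.
#' @param threshold relative-abundance fraction in `[0, 1)`, e.g. `1e-4`
#'   for 0.01%.
#' @return filtered [count_table]; at least 2 taxa must survive.
#' @export
filter_taxa <- function(tab, mode = c("remove_rare", "keep_common"),
                        threshold) {
  mode <- match.arg(mode)
  stopifnot(inherits(tab, "count_table"))
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  mra <- mean_relative_abundance(tab)
  keep <- if (mode == "remove_rare") mra >= threshold else mra > threshold
  if (sum(keep) < 2)
    stop("fewer than 2 taxa survive ", mode, " filtering at threshold ",
         format(threshold))
  count_table(tab$counts[, keep, drop = FALSE],
              sample_ids = tab$sample_ids,
              taxon_ids = tab$taxon_ids[keep])
}

#' Close counts to a strictly positive composition
#'
#' Adds a pseudocount to every entry and divides each row by its total, so
#' every relative abundance is strictly positive and each row sums to 1.
#' With strictly positive input `pseudocount = 0` is allowed, in which case
#' closure is exactly scale-invariant.
#'
#' @param tab a [count_table] or a nonnegative numeric matrix.
#' @param pseudocount nonnegative additive pseudocount (default 0.5);
#'   must be > 0 whenever the input contains zeros.
#' @return object of class `composition`: list with `X` (rows sum to 1,
#'   all entries > 0), `sample_ids`, `taxon_ids`.
#' @export
close_composition <- function(tab, pseudocount = 0.5) {
  if (inherits(tab, "count_table")) {
    m <- tab$counts
    sids <- tab$sample_ids
    tids <- tab$taxon_ids
  } else {
    m <- as.matrix(tab)
    sids <- rownames(m)
    tids <- colnames(m)
    if (is.null(sids)) sids <- paste0("S", seq_len(nrow(m)))
    if (is.null(tids)) tids <- paste0("T", seq_len(ncol(m)))
  }
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop("pseudocount must be nonnegative")
  if (pseudocount == 0 && any(m <= 0))
    stop("pseudocount must be > 0 when counts contain zeros")
  m <- m + pseudocount
  X <- m / rowSums(m)
  dimnames(X) <- list(sids, tids)
  composition(X)
}

#' Construct a composition
#'
#' @param X strictly positive matrix whose rows sum to 1 (within 1e-8 on
#'   input; rows are renormalized to machine accuracy).
#' @return object of class `composition`.
#' @export
composition <- function(X) {
  X <- as.matrix(X)
  if (any(X <= 0)) stop("composition entries must be strictly positive")
  rs <- rowSums(X)
  if (any(abs(rs - 1) > 1e-8)) stop("composition rows must sum to 1")
  X <- X / rs
  sids <- rownames(X)
  tids <- colnames(X)
  if (is.null(sids)) sids <- paste0("S", seq_len(nrow(X)))
  if (is.null(tids)) tids <- paste0("T", seq_len(ncol(X)))
  dimnames(X) <- list(sids, tids)
  structure(list(X = X, sample_ids = sids, taxon_ids = tids),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("composition:", nrow(x$X), "samples x", ncol(x$X), "taxa\n")
  invisible(x)
}
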