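#' Configure a synthetic dataset
#'
#' Describes a Dirichlet-multinomial compositional count generator with
#' balance-driven censored survival times. Defaults describe a typical
#' 16S profiling study: 100 samples, 20 taxa at sequencing depth 10000,
#' a sparse community (symmetric Dirichlet concentration 0.5), a planted
#' 1-vs-1 balance with a strong effect (gamma 1.5), and 20% uniform
#' right-censoring.
#'
#' @param n_samples number of samples.
#' @param n_taxa number of taxa K.
#' @param planted_plus,planted_minus disjoint taxon index sets driving the
#'   outcome (the planted balance).
#' @param gamma_true balance effect size (log-hazard scale in `"cox"` mode,
#'   log-time scale in `"weibull"` mode).
#' @param model generative survival model, `"cox"` or `"weibull"`.
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   for `"cox"` mode.
#' @param aft_intercept,aft_scale intercept and error scale of the
#'   log-linear model in `"weibull"` mode.
#' @param censoring_rate target fraction of right-censored samples in
#'   `[0, 1)`; censoring times are uniform on (0, c) with c solved so the
#'   expected censored fraction matches.
#' @param sequencing_depth multinomial total count per sample.
#' @param dirichlet_alpha Dirichlet concentration, scalar or length-K.
#' @param seed integer seed for full reproducibility.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 100, n_taxa = 20,
                              planted_plus = 1, planted_minus = 2,
                              gamma_true = 1.5,
                              model = c("cox", "weibull"),
                              baseline_shape = 1.5, baseline_scale = 1,
                              aft_intercept = 2, aft_scale = 0.5,
                              censoring_rate = 0.2,
                              sequencing_depth = 10000,
                              dirichlet_alpha = 0.5,
                              seed = 1L) {
  model <- match.arg(model)
  planted_plus <- as.integer(planted_plus)
  planted_minus <- as.integer(planted_minus)
  if (length(intersect(planted_plus, planted_minus)) > 0)
    stop("planted sets must be disjoint")
  if (any(c(planted_plus, planted_minus) > n_taxa))
    stop("planted indices exceed n_taxa")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  if (!length(dirichlet_alpha) %in% c(1, n_taxa))
    stop("dirichlet_alpha must be scalar or length n_taxa")
  structure(list(n_samples = n_samples, n_taxa = n_taxa,
                 planted_plus = planted_plus, planted_minus = planted_minus,
                 gamma_true = gamma_true, model = model,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 aft_intercept = aft_intercept, aft_scale = aft_scale,
                 censoring_rate = censoring_rate,
                 sequencing_depth = sequencing_depth,
                 dirichlet_alpha = dirichlet_alpha,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  W <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  W / rowSums(W)
}

#' Draw a latent composition and multinomial counts
#'
#' Per sample, a latent strictly positive composition is drawn from a
#' Dirichlet distribution and counts from a multinomial at the configured
#' sequencing depth. The latent composition is zero-free, so the planted
#' balance is exact; the observed counts carry sampling zeros and exercise
#' the full preprocessing path.
#'
#' @param cfg a [simulation_config].
#' @param use_seed set the RNG from `cfg$seed` (default TRUE; internal
#'   callers that manage the RNG themselves pass FALSE).
#' @return list with `composition` (latent, zero-free) and `counts`
#'   (a [count_table]).
#' @export
simulate_composition <- function(cfg, use_seed = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (use_seed) set.seed(cfg$seed)
  alpha <- rep_len(cfg$dirichlet_alpha, cfg$n_taxa)
  P <- .rdirichlet(cfg$n_samples, alpha)
  counts <- t(apply(P, 1, function(p)
    stats::rmultinom(1, size = cfg$sequencing_depth, prob = p)))
  rownames(P) <- rownames(counts) <- paste0("S", seq_len(cfg$n_samples))
  colnames(P) <- colnames(counts) <- paste0("T", seq_len(cfg$n_taxa))
  list(composition = composition(P),
       counts = count_table(counts))
}

#' Simulate balance-driven censored survival times
#'
#' In `"cox"` mode, event times follow a Weibull baseline hazard scaled by
#' \eqn{\exp(\gamma B)} via inverse-transform sampling:
#' \eqn{T = \lambda (E e^{-\gamma B})^{1/k}} with \eqn{E \sim Exp(1)}.
#' In `"weibull"` (AFT) mode, \eqn{\log T = \mu + \gamma B + \sigma\epsilon}
#' with standard minimum extreme-value noise. Censoring times are uniform
#' on (0, c), with c solved numerically so the expected censored fraction
#' matches `censoring_rate`.
#'
#' @param comp latent [composition] from [simulate_composition()].
#' @param cfg a [simulation_config].
#' @param use_seed set the RNG from `cfg$seed + 1` (default TRUE).
#' @return list with `outcome` (a [survival_outcome]), `true_balance`
#'   (numeric vector), `latent_time` (uncensored event times).
#' @export
simulate_survival <- function(comp, cfg, use_seed = TRUE) {
  stopifnot(inherits(comp, "composition"), inherits(cfg, "simulation_config"))
  if (use_seed) set.seed(cfg$seed + 1L)
  truth <- balance_spec(cfg$planted_plus, cfg$planted_minus)
  B <- compute_balance(comp, truth)
  n <- length(B)
  if (cfg$model == "cox") {
    E <- stats::rexp(n)
    Tlat <- cfg$baseline_scale *
      (E * exp(-cfg$gamma_true * B))^(1 / cfg$baseline_shape)
  } else {
    eps <- log(stats::rexp(n))   # standard minimum extreme value
    Tlat <- exp(cfg$aft_intercept + cfg$gamma_true * B + cfg$aft_scale * eps)
  }
  if (cfg$censoring_rate == 0) {
    time <- Tlat
    event <- rep(1, n)
  } else {
    cmax <- .censor_bound(Tlat, cfg$censoring_rate)
    C <- stats::runif(n, 0, cmax)
    time <- pmin(Tlat, C)
    event <- as.numeric(Tlat <= C)
  }
  list(outcome = survival_outcome(time, event,
                                  sample_ids = comp$sample_ids),
       true_balance = B, latent_time = Tlat)
}

# solve E[censored fraction] = 1 - E[min(T,c)]/c ... for C ~ U(0,c):
# P(censored | T = t) = P(C < t) = min(t, c)/c, so the expected censored
# fraction is mean(pmin(T, c))/c; monotone decreasing in c.
.censor_bound <- function(Tlat, rate) {
  f <- function(cc) mean(pmin(Tlat, cc)) / cc - rate
  up <- max(Tlat) / rate   # f(up) <= max(T)/up - rate = 0 at equality
  lo <- min(Tlat) * 1e-6
  if (f(up) > 0) up <- up * 100
  stats::uniroot(f, c(lo, up), tol = 1e-10)$root
}

#' Simulate a complete dataset with known truth
#'
#' @param cfg a [simulation_config].
#' @return object of class `simulated_dataset`: `counts` ([count_table]),
#'   `composition` (latent), `outcome` ([survival_outcome]), `truth`
#'   (planted [balance_spec]), `true_balance`, `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  cmp <- simulate_composition(cfg, use_seed = FALSE)
  srv <- simulate_survival(cmp$composition, cfg, use_seed = FALSE)
  structure(list(counts = cmp$counts, composition = cmp$composition,
                 outcome = srv$outcome,
                 truth = balance_spec(cfg$planted_plus, cfg$planted_minus),
                 true_balance = srv$true_balance,
                 config = cfg),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", x$config$n_samples, "samples x",
      x$config$n_taxa, "taxa;", sum(x$outcome$event), "events\n")
  invisible(x)
}

#' Precision and recall of a selected balance against the planted truth
#'
#' Computed over the union of the plus and minus sets on each side,
#' orientation-agnostic: precision is the fraction of selected taxa that
#' were planted, recall the fraction of planted taxa recovered.
#'
#' @param result a `selection_result` or a [balance_spec].
#' @param truth the planted [balance_spec].
#' @return named numeric vector `c(precision, recall)`; an empty selection
#'   yields precision 0 with attribute `empty_selection = TRUE`.
#' @export
evaluate_selection <- function(result, truth) {
  spec <- if (inherits(result, "selection_result")) result$best_spec
          else result
  stopifnot(inherits(truth, "balance_spec"))
  sel <- union(spec$plus, spec$minus)
  pla <- union(truth$plus, truth$minus)
  if (length(sel) == 0) {
    out <- c(precision = 0, recall = 0)
    attr(out, "empty_selection") <- TRUE
    return(out)
  }
  hit <- length(intersect(sel, pla))
  c(precision = hit / length(sel), recall = hit / length(pla))
}

#' Write a simulated dataset as the TSV pair the pipeline reads
#'
#' @param sim a `simulated_dataset`.
#' @param dir output directory (created if missing).
#' @return named character vector of the three written paths (counts,
#'   metadata, truth JSON), invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cpath <- file.path(dir, "counts.tsv")
  mpath <- file.path(dir, "metadata.tsv")
  tpath <- file.path(dir, "truth.json")
  cdf <- data.frame(sample_id = sim$counts$sample_ids,
                    sim$counts$counts, check.names = FALSE)
  utils::write.table(cdf, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mdf <- data.frame(sample_id = sim$outcome$sample_ids,
                    time = sim$outcome$time, event = sim$outcome$event)
  utils::write.table(mdf, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(plus = sim$counts$taxon_ids[sim$truth$plus],
                minus = sim$counts$taxon_ids[sim$truth$minus],
                gamma_true = sim$config$gamma_true,
                model = sim$config$model,
                seed = sim$config$seed)
  writeLines(as.character(jsonlite::toJSON(truth, auto_unbox = TRUE)),
             tpath)
  invisible(c(counts = cpath, metadata = mpath, truth = tpath))
}
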