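#' Assemble and validate a pipeline run configuration
#'
#' Every user-settable option of the end-to-end pipeline. All fields are
#' validated here, before any computation, and the effective configuration
#' (including defaults) is echoed verbatim into the output report.
#'
#' @param counts_path,metadata_path input TSV/CSV paths (see
#'   [read_tables()]).
#' @param time_col,event_col,covariate_cols metadata column names.
#' @param model `"cox"` or `"weibull"`.
#' @param ties Cox tie handling.
#' @param dist AFT error family.
#' @param filter_mode `"remove_rare"`, `"keep_common"`, or `"none"`.
#' @param filter_threshold relative-abundance threshold for the filter
#'   (default 1e-4, i.e. mean relative abundance 0.01%).
#' @param pseudocount additive pseudocount before closure (default 0.5).
#' @param max_taxa,tol,cv_folds greedy selection controls.
#' @param n_permutations,alpha community-test controls.
#' @param seed integer seed (CV folds and permutations).
#' @param out_dir output directory for report artifacts.
#' @param plot write quartile-stratified survival-curve figure (PNG).
#' @param by_covariate optional name of a fitted binary covariate; curves
#'   are then rendered per level of that covariate instead of at the mean
#'   profile.
#' @return object of class `run_config`.
#' @export
run_config <- function(counts_path, metadata_path, time_col, event_col,
                       covariate_cols = NULL,
                       model = c("cox", "weibull"),
                       ties = c("efron", "breslow"),
                       dist = c("weibull", "lognormal", "loglogistic"),
                       filter_mode = c("remove_rare", "keep_common", "none"),
                       filter_threshold = 1e-4, pseudocount = 0.5,
                       max_taxa = 15, tol = 2, cv_folds = NULL,
                       n_permutations = 999, alpha = 0.05, seed = 1L,
                       out_dir = "survbalance_out", plot = FALSE,
                       by_covariate = NULL) {
  model <- match.arg(model)
  ties <- match.arg(ties)
  dist <- match.arg(dist)
  filter_mode <- match.arg(filter_mode)
  stopifnot(is.numeric(filter_threshold), filter_threshold >= 0,
            filter_threshold < 1, pseudocount > 0, max_taxa >= 2, tol >= 0,
            n_permutations >= 1, alpha > 0, alpha < 1)
  if (!is.null(by_covariate) && !by_covariate %in% covariate_cols)
    stop("by_covariate must name one of covariate_cols")
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 time_col = time_col, event_col = event_col,
                 covariate_cols = covariate_cols, model = model,
                 ties = ties, dist = dist, filter_mode = filter_mode,
                 filter_threshold = filter_threshold,
                 pseudocount = pseudocount, max_taxa = max_taxa, tol = tol,
                 cv_folds = cv_folds, n_permutations = n_permutations,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir,
                 plot = plot, by_covariate = by_covariate),
            class = "run_config")
}

#' Write a square distance matrix as TSV
#'
#' @param D a `distance_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  m <- D$D
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quartile-stratified predicted survival curves
#'
#' Evaluates [predict_survival_curves()] at the empirical first and third
#' quartiles (linear-interpolation convention, `stats::quantile` type 7)
#' of the per-sample balance values. The covariate profile defaults to the
#' covariate means; for a binary covariate of interest, one curve set per
#' observed level can be rendered instead.
#'
#' @param fit a `cox_fit` or `aft_fit`.
#' @param balances numeric vector of per-sample balance values (>= 4
#'   samples, otherwise quartiles are ill-defined).
#' @param Z optional covariate matrix used for the mean profile.
#' @param by_covariate optional covariate name; curves are produced at
#'   each observed level of that covariate (others held at their means).
#' @param file optional PNG path for the figure.
#' @return data frame `(group, level, time, survival)` where `level` is
#'   the balance quartile value; written to `file` as a figure when given.
#' @export
render_curves <- function(fit, balances, Z = NULL, by_covariate = NULL,
                          file = NULL) {
  if (length(balances) < 4)
    stop("at least 4 samples are required to form balance quartiles")
  qs <- stats::quantile(balances, c(0.25, 0.75), names = FALSE, type = 7)
  profiles <- list(all = if (is.null(Z)) NULL else colMeans(Z))
  if (!is.null(by_covariate)) {
    if (is.null(Z) || !by_covariate %in% colnames(Z))
      stop("by_covariate not found among fitted covariates")
    profiles <- lapply(sort(unique(Z[, by_covariate])), function(v) {
      pr <- colMeans(Z)
      pr[by_covariate] <- v
      pr
    })
    names(profiles) <- paste0(by_covariate, "=",
                              sort(unique(Z[, by_covariate])))
  }
  out <- do.call(rbind, lapply(names(profiles), function(g) {
    cv <- profiles[[g]]
    df <- predict_survival_curves(fit, qs, covariate_profile = cv)
    cbind(group = g, df)
  }))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 650, res = 110)
    on.exit(grDevices::dev.off())
    groups <- unique(out$group)
    graphics::par(mfrow = c(1, length(groups)))
    for (g in groups) {
      sub <- out[out$group == g, ]
      graphics::plot(NA, xlim = range(sub$time), ylim = c(0, 1),
                     xlab = "time", ylab = "survival probability",
                     main = paste0("balance quartiles (", g, ")"))
      cols <- c("#2166AC", "#B2182B")
      for (i in seq_along(qs)) {
        s <- sub[sub$level == qs[i], ]
        graphics::lines(s$time, s$survival, type = "s", col = cols[i],
                        lwd = 2)
      }
      graphics::legend("bottomleft",
                       legend = sprintf("%s quartile (B = %.2f)",
                                        c("first", "third"), qs),
                       col = cols, lwd = 2, bty = "n")
    }
  }
  out
}

#' Run the full balance-selection pipeline
#'
#' Executes read, filter, closure, community test, greedy selection, final
#' model fit, and writes all artifacts to the configured output directory:
#' `report.json` (selection, fit, community test, caution flag and the
#' echoed configuration), `balance.tsv` (per-sample balance values of the
#' selected balance), `distance_bray_curtis.tsv` and
#' `distance_jaccard.tsv`, `trace.tsv` (accepted greedy steps),
#' `curves.tsv` and optionally `curves.png` (quartile-stratified predicted
#' survival). Reruns with an identical configuration and seed produce a
#' byte-identical report.
#'
#' @param cfg a [run_config].
#' @return the `selection_result`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  inp <- read_tables(cfg$counts_path, cfg$metadata_path, cfg$time_col,
                     cfg$event_col, cfg$covariate_cols)
  tab <- inp$counts
  if (cfg$filter_mode != "none")
    tab <- filter_taxa(tab, cfg$filter_mode, cfg$filter_threshold)
  X <- close_composition(tab, pseudocount = cfg$pseudocount)

  res <- withCallingHandlers(
    select_balance(X, inp$outcome, model = cfg$model, counts = tab,
                   max_taxa = cfg$max_taxa, tol = cfg$tol,
                   cv_folds = cfg$cv_folds,
                   n_permutations = cfg$n_permutations, alpha = cfg$alpha,
                   seed = cfg$seed, ties = cfg$ties, dist = cfg$dist),
    warning = function(w) {
      message("WARNING: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  b <- compute_balance(X, res$best_spec)
  write_balance_tsv(b, file.path(cfg$out_dir, "balance.tsv"))
  Xraw <- tab$counts / rowSums(tab$counts)
  write_distance_tsv(bray_curtis(Xraw),
                     file.path(cfg$out_dir, "distance_bray_curtis.tsv"))
  write_distance_tsv(jaccard(tab),
                     file.path(cfg$out_dir, "distance_jaccard.tsv"))
  utils::write.table(trace_table(res), file.path(cfg$out_dir, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  curves <- render_curves(res$fit, b, Z = inp$outcome$Z,
                          by_covariate = cfg$by_covariate,
                          file = if (cfg$plot)
                            file.path(cfg$out_dir, "curves.png") else NULL)
  utils::write.table(curves, file.path(cfg$out_dir, "curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    config = unclass(cfg),
    n_samples = length(inp$outcome$time),
    n_events = sum(inp$outcome$event),
    n_taxa_after_filter = length(tab$taxon_ids),
    plus_taxa = tab$taxon_ids[res$best_spec$plus],
    minus_taxa = tab$taxon_ids[res$best_spec$minus],
    gamma = res$gamma,
    se_gamma = res$fit$se_gamma,
    gamma_ci95 = c(res$gamma - 1.96 * res$fit$se_gamma,
                   res$gamma + 1.96 * res$fit$se_gamma),
    p_gamma = res$fit$p_gamma,
    loglik = res$fit$loglik,
    per_kernel_p = as.list(res$community_test$per_kernel_p),
    omnibus_p = res$community_test$omnibus_p,
    caution = res$caution,
    balance_quartiles = as.list(stats::quantile(
      b, c(0.25, 0.75), names = FALSE, type = 7)),
    trace = trace_table(res))
  writeLines(as.character(jsonlite::toJSON(
    report, auto_unbox = TRUE, digits = 10, dataframe = "rows",
    null = "null")),
    file.path(cfg$out_dir, "report.json"))

  if (res$caution)
    message("CAUTION: community-level association not significant ",
            "(omnibus p = ", signif(res$community_test$omnibus_p, 3),
            "); interpret the selected balance with care")
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches the `run`, `simulate` and `test-community` subcommands used
#' by the `exec/survbalance` script. Exit status: 0 on success, 2 on a
#' validation error, 3 on a numerical failure.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
survbalance_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: survbalance <run|simulate|test-community> [options]",
    "",
    "run            --counts F --metadata F --time-col C --event-col C",
    "               [--covariates a,b] [--model cox|weibull]",
    "               [--ties efron|breslow] [--dist weibull|lognormal|loglogistic]",
    "               [--filter remove_rare|keep_common|none] [--filter-threshold 1e-4]",
    "               [--pseudocount 0.5] [--max-taxa 15] [--tol 2] [--cv-folds K]",
    "               [--permutations 999] [--alpha 0.05] [--seed 1]",
    "               [--out DIR] [--plot] [--by-covariate C]",
    "simulate       --out DIR [--n 100] [--taxa 20] [--gamma 1.5]",
    "               [--model cox|weibull] [--censoring 0.2] [--seed 1]",
    "test-community --counts F --metadata F --time-col C --event-col C",
    "               [--covariates a,b] [--permutations 999] [--seed 1]",
    sep = "\n")
  opt <- function(name, default = NULL) {
    i <- which(args == name)
    if (length(i) == 0) return(default)
    if (i == length(args)) stop("missing value for ", name)
    args[i + 1]
  }
  flag <- function(name) name %in% args
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0))
  }
  cmd <- args[1]
  status <- tryCatch({
    if (cmd == "run") {
      cov <- opt("--covariates")
      cfg <- run_config(
        counts_path = opt("--counts"), metadata_path = opt("--metadata"),
        time_col = opt("--time-col"), event_col = opt("--event-col"),
        covariate_cols = if (is.null(cov)) NULL
                         else strsplit(cov, ",")[[1]],
        model = opt("--model", "cox"), ties = opt("--ties", "efron"),
        dist = opt("--dist", "weibull"),
        filter_mode = opt("--filter", "remove_rare"),
        filter_threshold = as.numeric(opt("--filter-threshold", "1e-4")),
        pseudocount = as.numeric(opt("--pseudocount", "0.5")),
        max_taxa = as.integer(opt("--max-taxa", "15")),
        tol = as.numeric(opt("--tol", "2")),
        cv_folds = if (is.null(opt("--cv-folds"))) NULL
                   else as.integer(opt("--cv-folds")),
        n_permutations = as.integer(opt("--permutations", "999")),
        alpha = as.numeric(opt("--alpha", "0.05")),
        seed = as.integer(opt("--seed", "1")),
        out_dir = opt("--out", "survbalance_out"),
        plot = flag("--plot"), by_covariate = opt("--by-covariate"))
      res <- run_pipeline(cfg)
      print(res)
      0
    } else if (cmd == "simulate") {
      cfg <- simulation_config(
        n_samples = as.integer(opt("--n", "100")),
        n_taxa = as.integer(opt("--taxa", "20")),
        gamma_true = as.numeric(opt("--gamma", "1.5")),
        model = opt("--model", "cox"),
        censoring_rate = as.numeric(opt("--censoring", "0.2")),
        seed = as.integer(opt("--seed", "1")))
      sim <- simulate_dataset(cfg)
      paths <- write_simulated_dataset(sim, opt("--out", "survbalance_sim"))
      cat("wrote:", paste(paths, collapse = " "), "\n")
      0
    } else if (cmd == "test-community") {
      cov <- opt("--covariates")
      inp <- read_tables(opt("--counts"), opt("--metadata"),
                         opt("--time-col"), opt("--event-col"),
                         if (is.null(cov)) NULL else strsplit(cov, ",")[[1]])
      seed <- opt("--seed")
      res <- community_test(inp$counts, inp$outcome,
                            n_permutations =
                              as.integer(opt("--permutations", "999")),
                            seed = if (is.null(seed)) NULL
                                   else as.integer(seed))
      print(res)
      0
    } else {
      message("unknown subcommand: ", cmd, "\n", usage)
      2
    }
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("converge|singular|numerical", conditionMessage(e))) 3 else 2
  })
  invisible(status)
}
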