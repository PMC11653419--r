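#' Default run configuration
#'
#' Assembles the configuration consumed by [run_simulation()] and
#' [run_analysis()]: which (decision, driver) pairs to analyze, the
#' criterion-sweep grid bounds per driver (0-120 dB HL for hearing loss,
#' 0-100 points for THI), prior/sampler settings, imputation chain, and
#' an optional utility context for the expected-value-optimal criterion.
#'
#' @param seed Integer seed recorded in every output.
#' @param output Output directory for report bundles.
#' @return A nested list; any element can be overridden, e.g. from a YAML
#'   file via [read_run_config()].
#' @export
default_run_config <- function(seed = 1L, output = "sdtreat-out") {
  list(
    seed = as.integer(seed),
    output = output,
    simulate = list(n = 300L, p_s2 = 0.4),
    pairs = list(
      list(decision = "SEDEP", driver = "hearing_loss"),
      list(decision = "PCU", driver = "thi_baseline")
    ),
    grid = list(hearing_loss = c(0, 120), thi_baseline = c(0, 100)),
    prior = default_prior(),
    sampler = default_sampler(),
    mcid = 7,
    alpha = 0.01,
    exploratory = FALSE,
    utility = NULL,
    io = list(delimiter = ",", na_token = "NA")
  )
}

#' Read a run configuration from a YAML file
#'
#' Values present in the file override the defaults; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding both default and file value.
#' @return A run-config list.
#' @export
read_run_config <- function(path, seed = NULL) {
  cfg <- default_run_config()
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, override) {
    for (nm in names(override)) {
      if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
          !is.null(names(base[[nm]]))) {
        base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
      } else {
        base[[nm]] <- override[[nm]]
      }
    }
    base
  }
  cfg <- merge_lists(cfg, user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(cfg$utility)) {
    cfg$utility <- do.call(utility_context, cfg$utility)
  }
  cfg
}

#' Analyze one (decision, driver) pair of a cohort
#'
#' Runs the per-pair analysis chain: extract the marginal yes/no dataset,
#' orient the driver, fit both population regressions, test the slopes,
#' and — if the data are consistent with the driver assumption (or
#' `exploratory` is set) — derive the fitted CDF/PDF curves, ROC and AUC,
#' logit-ROC accuracy, likelihood-ratio curve, unbiased criterion, LR
#' extremum, and optionally the expected-value-optimal criterion.
#'
#' @param table An imputed, complete `cohort_table`.
#' @param decision_id,driver_id Pair to analyze.
#' @param config Run configuration (see [default_run_config()]).
#' @return A `pair_analysis` list: `dataset`, `fits`, `verdicts`, `model`
#'   (possibly `NULL`), and when modelled: `curves` (data.frame of x,
#'   cdf/pdf per population, LR), `roc`, `auc_partial`, `auc_closed`,
#'   `logit_roc`, `unbiased`, `lr_extremum`, `utility` results.
#' @export
analyze_pair <- function(table, decision_id, driver_id,
                         config = default_run_config()) {
  bounds <- config$grid[[driver_id]]
  dataset <- extract_decision_dataset(
    table, decision_id, driver_id,
    x_min = bounds[1], x_max = bounds[2], mcid = config$mcid)
  fit <- fit_decision_model(
    dataset, prior = config$prior, sampler = config$sampler,
    seed = config$seed, alpha = config$alpha,
    exploratory = isTRUE(config$exploratory))
  out <- list(decision = decision_id, driver = driver_id,
              dataset = fit$dataset, fit_s1 = fit$fit_s1,
              fit_s2 = fit$fit_s2, verdicts = fit$verdicts,
              model = fit$model, seed = config$seed)
  if (is.null(fit$model)) {
    out$note <- "driver not consistent with SDT assumptions"
    class(out) <- "pair_analysis"
    return(out)
  }
  model <- fit$model
  xs <- seq(model$x_min, model$x_max, length.out = 512L)
  out$curves <- data.frame(
    x = xs,
    cdf_s1 = sdt_cdf(model$s1, xs), cdf_s2 = sdt_cdf(model$s2, xs),
    pdf_s1 = sdt_pdf(model$s1, xs), pdf_s2 = sdt_pdf(model$s2, xs),
    lr = likelihood_ratio(model, xs))
  out$roc <- roc_curve(model)
  out$auc_partial <- roc_auc(out$roc, "partial")
  out$auc_closed <- roc_auc(out$roc, "closed")
  out$logit_roc <- logit_roc(model)
  unb <- unbiased_criterion(model)
  out$unbiased <- list(criteria = as.numeric(unb),
                       criteria_original = criterion_to_original(
                         model, as.numeric(unb)),
                       regime = attr(unb, "regime"))
  out$lr_extremum <- lr_extremum(model)
  if (!is.null(config$utility)) {
    beta <- optimal_beta(config$utility)
    out$utility <- list(beta = beta,
                        criteria = criterion_for_beta(model, beta))
  }
  class(out) <- "pair_analysis"
  out
}

#' @export
print.pair_analysis <- function(x, ...) {
  cat(sprintf("pair analysis: %s ~ %s\n", x$decision, x$driver))
  cat(sprintf("  slope verdicts: S1 %s, S2 %s\n",
              x$verdicts[["S1"]], x$verdicts[["S2"]]))
  if (is.null(x$model)) {
    cat("  ", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("  accuracy index (logit-ROC intercept): %.3f, slope: %.3f\n",
              x$logit_roc$intercept, x$logit_roc$slope))
  cat(sprintf("  AUC (partial): %.3f, AUC (closed): %.3f\n",
              x$auc_partial, x$auc_closed))
  if (length(x$unbiased$criteria)) {
    cat(sprintf("  unbiased criterion at %s (driver units)\n",
                paste(sprintf("%.2f", x$unbiased$criteria_original),
                      collapse = ", ")))
  } else {
    cat(sprintf("  no unbiased criterion in range: %s\n",
                x$unbiased$regime))
  }
  invisible(x)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Order follows the methods chain: impute missing scores, label
#' outcomes, extract each pair's marginal dataset, orient, fit, test the
#' slopes, and derive the accuracy/criterion outputs. Each pair yields a
#' set of delimited tables plus a key-value summary; a pair failing the
#' slope test yields only its verdict file unless `config$exploratory`.
#'
#' @param table A `cohort_table` (may contain missing scores).
#' @param config Run configuration.
#' @return Named list of `pair_analysis` objects (invisibly also written
#'   to `config$output` when `write = TRUE`).
#' @param write Write the bundle files to `config$output`.
#' @export
run_analysis <- function(table, config = default_run_config(),
                         write = FALSE) {
  chain_targets <- vapply(default_chain_config(), `[[`, "", "target")
  if (any(vapply(chain_targets, function(t) anyNA(table[[t]]), logical(1)))) {
    table <- impute_chain(table)
  }
  results <- list()
  for (pair in config$pairs) {
    key <- paste(pair$decision, pair$driver, sep = "_")
    results[[key]] <- analyze_pair(table, pair$decision, pair$driver,
                                   config)
  }
  if (write) write_bundle(results, table, config)
  invisible(results)
}

write_kv <- function(path, kv) {
  writeLines(sprintf("%s = %s", names(kv),
                     vapply(kv, function(v) paste(format(v), collapse = " "),
                            character(1))),
             path)
}

write_bundle <- function(results, table, config) {
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(config)
  prov <- sprintf("# sdtreat %s | seed=%d | config=%s",
                  as.character(utils::packageVersion("sdtreat")),
                  config$seed, cfg_hash)
  write_csv_prov <- function(df, path) {
    con <- file(path, "wt"); on.exit(close(con))
    writeLines(prov, con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                       na = "NA")
  }
  rep_tab <- imputation_report_table(table)
  if (nrow(rep_tab)) {
    write_csv_prov(rep_tab, file.path(config$output, "imputation_report.csv"))
  }
  for (key in names(results)) {
    res <- results[[key]]
    stem <- file.path(config$output, key)
    post <- posterior_summary_table(list(res$fit_s1, res$fit_s2))
    write_csv_prov(post, paste0(stem, "_posterior.csv"))
    kv <- list(decision = res$decision, driver = res$driver,
               verdict_s1 = res$verdicts[["S1"]],
               verdict_s2 = res$verdicts[["S2"]],
               seed = config$seed, config_hash = cfg_hash)
    if (!is.null(res$model)) {
      write_csv_prov(res$curves, paste0(stem, "_curves.csv"))
      write_csv_prov(as.data.frame(res$roc), paste0(stem, "_roc.csv"))
      kv <- c(kv, list(
        mu_s1 = res$model$s1$mu, s_s1 = res$model$s1$s,
        mu_s2 = res$model$s2$mu, s_s2 = res$model$s2$s,
        orientation = res$model$orientation,
        auc_partial = res$auc_partial, auc_closed = res$auc_closed,
        logit_roc_slope = res$logit_roc$slope,
        logit_roc_intercept = res$logit_roc$intercept,
        accuracy = res$logit_roc$accuracy,
        unbiased_criterion = if (length(res$unbiased$criteria_original))
          res$unbiased$criteria_original else NA,
        criterion_regime = res$unbiased$regime))
      if (!is.null(res$lr_extremum)) {
        kv <- c(kv, list(lr_extremum_x = res$lr_extremum$x,
                         lr_extremum_value = res$lr_extremum$lr,
                         lr_extremum_type = res$lr_extremum$type))
      }
      if (!is.null(res$utility)) {
        kv <- c(kv, list(optimal_beta = res$utility$beta,
                         beta_criteria = if (nrow(res$utility$criteria))
                           res$utility$criteria$criterion else NA))
      }
    } else {
      kv <- c(kv, list(note = res$note))
    }
    write_kv(paste0(stem, "_summary.txt"), kv)
  }
  invisible(config$output)
}

#' Collate a report bundle into a single summary table
#'
#' Reads the per-pair key-value summaries written by [run_analysis()]
#' and assembles one row per (decision, driver) pair; pairs whose
#' driver-consistency test failed are flagged rather than omitted.
#'
#' @param bundle_dir Directory holding `*_summary.txt` files.
#' @return Data.frame with one row per pair.
#' @export
collate_report <- function(bundle_dir) {
  files <- list.files(bundle_dir, pattern = "_summary\\.txt$",
                      full.names = TRUE)
  if (length(files) == 0L) {
    warning("no pair summaries found in ", bundle_dir)
    return(data.frame(decision = character(0), driver = character(0)))
  }
  rows <- lapply(files, function(f) {
    lines <- readLines(f)
    kv <- strsplit(lines, " = ", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, "", 2L),
                            vapply(kv, `[`, "", 1L))
    num_or_chr <- function(v) {
      n <- suppressWarnings(as.numeric(v))
      if (is.na(n)) v else n
    }
    get <- function(key) if (key %in% names(vals))
      num_or_chr(vals[[key]]) else NA
    data.frame(
      decision = vals[["decision"]], driver = vals[["driver"]],
      modelled = "accuracy" %in% names(vals),
      accuracy = get("accuracy"),
      logit_roc_slope = get("logit_roc_slope"),
      auc_partial = get("auc_partial"),
      unbiased_criterion = get("unbiased_criterion"),
      criterion_regime = if ("criterion_regime" %in% names(vals))
        vals[["criterion_regime"]] else "not modelled",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `impute`, `analyze` and `report`
#' subcommands used by the `sdtreat-cli.R` script installed under
#' `inst/cli/`. Exit codes: 0 success, 2 validation/configuration error,
#' 3 model-gate failure (no pair passed the driver-consistency test).
#'
#' @param args Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` in the script).
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sdtreat-cli.R <simulate|impute|analyze|report> [options]",
    "  --config FILE   YAML run configuration",
    "  --seed N        integer seed (overrides config)",
    "  --input FILE    cohort CSV (impute/analyze; overrides config)",
    "  --output DIR    output directory",
    "  --exploratory   keep modelling even if a slope test fails",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]
  opts <- parse_cli_options(args[-1L])
  code <- tryCatch({
    cfg <- if (!is.null(opts$config)) {
      read_run_config(opts$config, seed = opts$seed)
    } else {
      default_run_config(seed = opts$seed %||% 1L)
    }
    if (!is.null(opts$output)) cfg$output <- opts$output
    if (isTRUE(opts$exploratory)) cfg$exploratory <- TRUE
    dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
    switch(cmd,
      simulate = {
        sim <- simulate_cohort(
          ground_truth(n = cfg$simulate$n %||% 300L,
                       p_s2 = cfg$simulate$p_s2 %||% 0.4),
          seed = cfg$seed)
        cohort <- inject_mcar(sim$cohort, seed = cfg$seed + 1L)
        write_cohort(cohort, file.path(cfg$output, "cohort.csv"),
                     seed = cfg$seed, config = cfg)
        utils::write.csv(sim$truth_table,
                         file.path(cfg$output, "truth.csv"),
                         row.names = FALSE)
        message("wrote cohort.csv and truth.csv to ", cfg$output)
        0L
      },
      impute = {
        input <- opts$input %||% cfg$input
        if (is.null(input)) stop("impute needs --input")
        table <- read_cohort(input, cfg$io)
        table <- impute_chain(table)
        write_cohort(table, file.path(cfg$output, "cohort_imputed.csv"),
                     seed = cfg$seed, config = cfg)
        utils::write.csv(imputation_report_table(table),
                         file.path(cfg$output, "imputation_report.csv"),
                         row.names = FALSE)
        0L
      },
      analyze = {
        input <- opts$input %||% cfg$input
        if (is.null(input)) stop("analyze needs --input")
        table <- read_cohort(input, cfg$io)
        results <- run_analysis(table, cfg, write = TRUE)
        if (all(vapply(results, function(r) is.null(r$model), logical(1)))) {
          message("no pair passed the driver-consistency gate")
          3L
        } else 0L
      },
      report = {
        input_dir <- opts$input %||% cfg$output
        tab <- collate_report(input_dir)
        utils::write.csv(tab, file.path(cfg$output, "report.csv"),
                         row.names = FALSE)
        0L
      },
      { message("unknown subcommand '", cmd, "'\n", usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--exploratory") {
      opts$exploratory <- TRUE
      i <- i + 1L
    } else if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(args)) stop("option ", a, " needs a value")
      val <- args[i + 1L]
      opts[[key]] <- if (key == "seed") as.integer(val) else val
      i <- i + 2L
    } else {
      stop("unrecognized argument '", a, "'")
    }
  }
  opts
}
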