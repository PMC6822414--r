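#' Write / read long-format choice data as CSV
#'
#' Comma-separated, dot decimal, UTF-8; one row per respondent x task x
#' alternative with the documented header (`respondent_id`, `task_id`,
#' `alt_id`, `is_optout`, `chosen`, `rank`, then the utility columns). The
#' first line is a `#` comment recording the seed and attribute-config hash
#' that produced the file; [read_choice_csv()] ignores comment lines and
#' re-validates the dataset invariants, failing with the offending task when
#' a task has zero or several chosen rows or duplicate keys.
#'
#' @param data a `choice_data` object.
#' @param path file path.
#' @param seed seed recorded in the header comment.
#' @param config_sha attribute-config hash recorded in the header comment.
#' @export
write_choice_csv <- function(data, path, seed = NA, config_sha = NA) {
  stopifnot(inherits(data, "choice_data"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# capdce choices; seed=", seed,
                    "; config_sha=", config_sha,
                    "; params=", paste(attr(data, "params"), collapse = "|")), con)
  utils::write.csv(as.data.frame(data), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choice_csv
#' @param params utility column names; when NULL they are recovered from the
#'   file's header comment.
#' @export
read_choice_csv <- function(path, params = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    stop("empty choice CSV: ", path, call. = FALSE)
  if (is.null(params) && grepl("params=", first, fixed = TRUE))
    params <- strsplit(sub(".*params=", "", first), "|", fixed = TRUE)[[1L]]
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (!nrow(df)) stop("choice CSV has a header but no rows: ", path, call. = FALSE)
  if (is.null(params))
    params <- setdiff(names(df), c("respondent_id", "task_id", "alt_id",
                                   "is_optout", "chosen", "rank"))
  as_choice_data(df, params)
}

#' Run the full pilot pipeline: design, simulate, fit, report
#'
#' Mirrors the pilot workflow: generate a D-efficient design under the
#' config's priors, simulate random-utility responses, fit the MNL (and
#' optionally the panel mixed logit), and compute WTA / relative-importance
#' reports. Writes `design.csv`, `choices.csv`, `fit.json`, `report.txt` and
#' `manifest.json` into `out_dir`; the manifest records seeds, package
#' version and md5 hashes of every output, so identical configs yield
#' identical manifests. A stage failure aborts with the stage name and
#' leaves a `FAILED` marker in `out_dir`.
#'
#' @param config either a list or a path to a JSON file with fields:
#'   `attribute_config` (path), `n_tasks`, `n_alts`, `design_seed`,
#'   `n_starts`, `beta_true` (length K), `n_respondents`, `sim_seed`,
#'   `include_optout`, `cluster`, `mmnl` (logical), `n_draws`,
#'   `baseline_ll` (optional), `out_dir`.
#' @param out_dir output directory (overrides the config's).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
         else config
  defaults <- list(n_tasks = 8L, n_alts = 2L, design_seed = 1L, n_starts = 5L,
                   n_respondents = 31L, sim_seed = 1L, include_optout = TRUE,
                   cluster = TRUE, mmnl = FALSE, n_draws = 200L,
                   baseline_ll = NULL, out_dir = ".")
  for (f in names(defaults)) if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$attribute_config))
    stop("pipeline config needs 'attribute_config'", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage=", name, "\n", conditionMessage(e)), failed)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  attrs <- stage("config", read_attribute_config(cfg$attribute_config))
  sha <- config_hash(attrs)

  opt <- stage("design", optimize_design(
    attrs, n_tasks = cfg$n_tasks, n_alts = cfg$n_alts,
    seed = cfg$design_seed, n_starts = cfg$n_starts))
  design_path <- file.path(cfg$out_dir, "design.csv")
  write_design_csv(opt$design, design_path, seed = cfg$design_seed)
  message("stage=design tasks=", cfg$n_tasks, " d_error=",
          signif(opt$score$d_error, 6))

  beta_true <- if (is.null(cfg$beta_true)) prior_vector(attrs)
               else as.numeric(cfg$beta_true)
  sim <- stage("simulate", simulate_choices(
    opt$design, beta_true, n_respondents = cfg$n_respondents,
    seed = cfg$sim_seed))
  choices_path <- file.path(cfg$out_dir, "choices.csv")
  write_choice_csv(sim, choices_path, seed = cfg$sim_seed, config_sha = sha)
  message("stage=simulate rows=", nrow(sim))

  fit <- stage("fit", fit_mnl(sim, include_optout = cfg$include_optout,
                              cluster = cfg$cluster))
  fs <- fit_stats(fit, baseline = cfg$baseline_ll)
  mmnl_out <- NULL
  if (isTRUE(cfg$mmnl))
    mmnl_out <- stage("fit", fit_mmnl(sim, n_draws = cfg$n_draws,
                                      seed = cfg$sim_seed))
  fit_path <- file.path(cfg$out_dir, "fit.json")
  fit_json <- list(
    seed = cfg$sim_seed, config_sha = sha,
    beta_hat = as.list(fit$beta_hat),
    robust_se = as.list(stats::setNames(sqrt(diag(fit$cov_robust)),
                                        names(fit$beta_hat))),
    ll_final = fit$ll_final, ll_null = fit$ll_null,
    aic = fs$aic, bic = fs$bic, adj_rho2 = fs$adj_rho2,
    n_obs = fit$n_obs, n_respondents = fit$n_respondents,
    converged = fit$converged,
    dropped_optout_tasks = fit$dropped_optout_tasks)
  if (!is.null(mmnl_out))
    fit_json$mmnl <- list(means = as.list(mmnl_out$means),
                          sds = as.list(mmnl_out$sds),
                          sim_ll = mmnl_out$sim_ll,
                          n_draws = mmnl_out$n_draws)
  jsonlite::write_json(fit_json, fit_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message("stage=fit n_obs=", fit$n_obs, " ll=", signif(fit$ll_final, 6),
          " dropped=", fit$dropped_optout_tasks)

  report_path <- file.path(cfg$out_dir, "report.txt")
  rep <- stage("report", post_estimates(fit, attrs))
  con <- file(report_path, "w")
  writeLines(paste0("# capdce report; seed=", cfg$sim_seed,
                    "; config_sha=", sha), con)
  utils::capture.output(print(rep), file = con)
  close(con)
  message("stage=report path=", report_path)

  outs <- c(design = design_path, choices = choices_path,
            fit = fit_path, report = report_path)
  manifest <- list(
    package = "capdce",
    version = as.character(utils::packageVersion("capdce")),
    config_sha = sha,
    seeds = list(design = cfg$design_seed, simulate = cfg$sim_seed),
    n_tasks = cfg$n_tasks, n_respondents = cfg$n_respondents,
    outputs = lapply(stats::setNames(outs, names(outs)), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
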