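#' Convert administered-activity units
#'
#' Exact conversion between GBq, MBq and mCi at the defining constant
#' 1 mCi = 37 MBq. No display rounding is applied.
#'
#' @param value numeric activity value(s).
#' @param from,to units, one of `"GBq"`, `"MBq"`, `"mCi"`.
#' @return Converted value(s).
#' @examples
#' convert_activity(195.4, "mCi", "GBq")  # 7.2298
#' @export
convert_activity <- function(value, from, to) {
  mbq_per <- c(GBq = 1000, MBq = 1, mCi = 37)
  if (!from %in% names(mbq_per)) stop("unknown unit: ", from, call. = FALSE)
  if (!to %in% names(mbq_per)) stop("unknown unit: ", to, call. = FALSE)
  value * mbq_per[[from]] / mbq_per[[to]]
}

run_config_fields <- c("generator", "policy", "counting", "grid",
                       "output_dir", "verbose")

#' Read a run configuration (JSON or YAML)
#'
#' A run configuration bundles a [generator_config()] (`generator`), a
#' [risk_policy()] (`policy`), [counting_rules()] (`counting`), a contour
#' grid spec (`grid`: `d1_min`, `d1_max`, `d2_min`, `d2_max`, `step` in
#' Gy), an `output_dir` and a `verbose` flag. Unknown top-level keys are
#' rejected. Omitted sections take the package defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return List with elements `generator`, `policy`, `counting`, `grid`,
#'   `output_dir`, `verbose`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else stop("config must be .json, .yaml or .yml", call. = FALSE)
  unknown <- setdiff(names(raw), run_config_fields)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  build_run_config(raw)
}

build_run_config <- function(raw = list()) {
  gen_args <- raw$generator %||% list()
  for (nm in c("dropout", "stop_reason_mix"))
    if (!is.null(gen_args[[nm]])) gen_args[[nm]] <- unlist(gen_args[[nm]])
  gen <- do.call(generator_config, gen_args)
  pol <- do.call(risk_policy, raw$policy %||% list())
  cnt <- do.call(counting_rules, raw$counting %||% list())
  grid <- modifyList(list(d1_min = 0, d1_max = 12, d2_min = 0, d2_max = 12,
                          step = 0.1), raw$grid %||% list())
  if (grid$step <= 0) stop("grid step must be > 0", call. = FALSE)
  if (grid$d1_max < grid$d1_min || grid$d2_max < grid$d2_min)
    stop("grid ranges must be non-empty", call. = FALSE)
  list(generator = gen, policy = pol, counting = cnt, grid = grid,
       output_dir = raw$output_dir %||% ".",
       verbose = isTRUE(raw$verbose))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable polynomial hash of a config, for run logging only
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_run <- function(cmd, cfg, seed) {
  message(sprintf("[prrtplan %s] config hash %s, seed %s",
                  cmd, config_hash(cfg), format(seed)))
}

#' Run the full pipeline and write a summary report
#'
#' Generates a cohort, fits the four dose-prediction models, plans
#' per-patient follow-up, counts the workload under both protocols, and
#' writes `cohort.csv`, `fits.txt`, `plan.csv`, `workload.txt` and the
#' two contour grids to the output directory. The run is fully
#' reproducible: the same configuration yields byte-identical outputs.
#'
#' @param config run configuration, e.g. from [read_run_config()]; NULL
#'   uses all defaults.
#' @param output_dir overrides the configured output directory.
#' @return Invisibly, a list with the cohort, fits, plans and the
#'   [reduction_report()] summary.
#' @export
run_report <- function(config = NULL, output_dir = NULL) {
  cfg <- if (is.null(config)) build_run_config() else config
  dir <- output_dir %||% cfg$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_run("report", cfg, cfg$generator$seed)

  cohort <- generate_cohort(cfg$generator)
  write_cohort(cohort, file.path(dir, "cohort.csv"))
  fits <- fit_dose_models(cohort)
  write_fit_summary(fits, file.path(dir, "fits.txt"))
  plans <- plan_cohort(cohort, fits, cfg$policy)
  write_plan(plans, file.path(dir, "plan.csv"))
  emp <- count_empiric(cohort, cfg$counting)
  pred <- count_predictive(cohort, plans, cfg$counting)
  summ <- reduction_report(emp, pred, cfg$counting)
  write_grids(fits, cfg, dir)
  con <- file(file.path(dir, "workload.txt"), "w")
  sink(con); print(summ); sink(); close(con)
  invisible(list(cohort = cohort, fits = fits, plans = plans,
                 workload = summ))
}

write_fit_summary <- function(fits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(fits)) {
    f <- fits[[nm]]
    s <- summary(f)
    writeLines(sprintf("[%s] response on %s", nm,
                       paste(f$predictor_labels, collapse = " + ")), con)
    writeLines(sprintf("  coef %s = %.6f", names(f$coefficients),
                       f$coefficients), con)
    writeLines(sprintf("  s = %.6f Gy, df = %d, n = %d",
                       f$residual_scale, f$df, f$n), con)
    if (!is.na(s$pearson_r))
      writeLines(sprintf("  pearson_r = %.4f", s$pearson_r), con)
    writeLines(sprintf("  lilliefors_p = %.4g, runs_p = %.4g",
                       s$lilliefors_p, s$runs_p), con)
  }
}

write_plan <- function(plans, path) {
  rows <- lapply(plans, function(p) {
    data.frame(patient_id = p$patient_id,
               cycles = length(p$scanned),
               scanned_cycles = paste(which(p$scanned), collapse = ";"),
               final_action = p$final_action,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
}

write_grids <- function(fits, cfg, dir) {
  d1 <- seq(cfg$grid$d1_min, cfg$grid$d1_max, by = cfg$grid$step)
  d2 <- seq(cfg$grid$d2_min, cfg$grid$d2_max, by = cfg$grid$step)
  for (nm in c("eq1", "eq2")) {
    g <- exceedance_grid(fits[[nm]], d1, d2,
                         threshold = cfg$policy$dose_threshold)
    write.csv(g, file.path(dir, paste0("contour_", nm, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
}

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]; i <- i + 2L
    }
  }
  out
}

cli_load_fits <- function(opts) {
  cohort <- read_cohort(opts$cohort %||%
                          stop("--cohort <file> required", call. = FALSE))
  fit_dose_models(cohort)
}

cli_policy <- function(opts) {
  risk_policy(
    dose_threshold = as.numeric(opts$threshold %||% 25),
    continue_risk = as.numeric(opts[["continue-risk"]] %||% 0.10),
    preclusion_risk = as.numeric(opts[["preclusion-risk"]] %||% 0.05))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `synth`, `fit`, `classify`, `plan`,
#' `workload`, `contour` and `report` (see `inst/scripts/prrtplan` for
#' the launcher). Each command logs its configuration hash and seed to
#' stderr and writes results to files; failures produce a one-line
#' diagnostic and a non-zero status.
#'
#' @param args character vector of command-line arguments (first element
#'   the subcommand).
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1L)
      stop("usage: prrtplan <synth|fit|classify|plan|workload|contour|report> [--options]",
           call. = FALSE)
    cmd <- args[[1L]]
    opts <- cli_args_to_list(args[-1L])
    switch(cmd,
      synth = {
        cfg <- generator_config(
          n_patients = as.integer(opts$n %||% 200),
          seed = as.integer(opts$seed %||% 1))
        log_run("synth", cfg, cfg$seed)
        write_cohort(generate_cohort(cfg), opts$out %||% "cohort.csv")
      },
      fit = {
        fits <- cli_load_fits(opts)
        log_run("fit", opts, NA)
        write_fit_summary(fits, opts$out %||% "fits.txt")
      },
      classify = {
        fits <- cli_load_fits(opts)
        pol <- cli_policy(opts)
        log_run("classify", opts, NA)
        z <- classify_zones(fits$eq1, fits$eq2,
                            as.numeric(opts$d1), as.numeric(opts$d2), pol)
        cat(sprintf("zones %s/%s p4=%.4f p3=%.4f\n", z$four_cycle_zone,
                    z$three_cycle_zone, z$p4, z$p3))
      },
      plan = {
        cohort <- read_cohort(opts$cohort %||%
                                stop("--cohort <file> required", call. = FALSE))
        fits <- fit_dose_models(cohort)
        log_run("plan", opts, NA)
        write_plan(plan_cohort(cohort, fits, cli_policy(opts)),
                   opts$out %||% "plan.csv")
      },
      workload = {
        cohort <- read_cohort(opts$cohort %||%
                                stop("--cohort <file> required", call. = FALSE))
        fits <- fit_dose_models(cohort)
        log_run("workload", opts, NA)
        plans <- plan_cohort(cohort, fits, cli_policy(opts))
        summ <- reduction_report(count_empiric(cohort),
                                 count_predictive(cohort, plans))
        out <- opts$out %||% "workload.txt"
        con <- file(out, "w"); sink(con); print(summ); sink(); close(con)
      },
      contour = {
        fits <- cli_load_fits(opts)
        log_run("contour", opts, NA)
        g <- exceedance_grid(fits[[opts$model %||% "eq1"]],
                             threshold = as.numeric(opts$threshold %||% 25))
        write.csv(g, opts$out %||% "contour.csv", row.names = FALSE,
                  quote = FALSE)
      },
      report = {
        cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
               else build_run_config()
        run_report(cfg, output_dir = opts$out)
      },
      stop("unknown command: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("prrtplan error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
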