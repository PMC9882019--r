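# Pipeline orchestration: calibrate -> generate -> simulate -> fit ->
# report, driven by a single structured config. Every run writes a
# resolved-config snapshot and a manifest next to its outputs so a result
# directory is self-describing and exactly reproducible.

#' Read a pipeline configuration
#'
#' Loads the YAML configuration controlling geometry, noise, cohort,
#' policy, calibration and sampler settings. With no argument, the
#' packaged default configuration is loaded (which carries the calibrated
#' per-variant noise levels).
#'
#' @param path path to a YAML config; default the shipped
#'   `default_config.yaml`.
#' @return A config list (class `"pipeline_config"`).
#' @export
read_pipeline_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml",
                        package = "occamfia", mustWork = TRUE)
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$policy <- cfg$policy %||% list(type = "observer",
                                     strategy = "posterior_sample")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Validate a pipeline configuration
#'
#' Schema and invariant checks: seed presence, parseable and disjoint
#' variant geometry, positive noise, cohort sizes, known policy type and
#' sampler settings. Returns an itemized report rather than failing on
#' the first issue.
#'
#' @param config a config list or a path to a YAML file.
#' @return An object of class `"config_validation"` with fields `ok` and
#'   `issues` (data.frame field/message).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  issues <- list()
  add <- function(field, msg)
    issues[[length(issues) + 1L]] <<- data.frame(field = field,
                                                 message = msg)
  if (is.null(config$seed)) add("seed", "master seed is missing")
  else if (!is.numeric(config$seed)) add("seed", "seed must be numeric")
  nobs <- config$noise$n_obs
  if (is.null(nobs) || !is.numeric(nobs) || nobs < 1)
    add("noise.n_obs", "observations per trial must be >= 1")
  if (is.null(config$variants) || !length(config$variants)) {
    add("variants", "no task variants defined")
  } else {
    for (vn in names(config$variants)) {
      gv <- config$variants[[vn]]
      sg <- gv$sigma
      if (is.null(sg) || !is.numeric(sg) || sg <= 0)
        add(paste0("variants.", vn, ".sigma"),
            "sigma must be a positive number")
      shapes <- tryCatch(
        list(a = manifold_from_list(gv$shape_a),
             b = manifold_from_list(gv$shape_b)),
        error = function(e) e)
      if (inherits(shapes, "error")) {
        add(paste0("variants.", vn), conditionMessage(shapes))
      } else if (manifolds_overlap(shapes$a, shapes$b)) {
        add(paste0("variants.", vn),
            "shape_a and shape_b overlap in the data plane")
      }
    }
  }
  ch <- config$cohort
  if (is.null(ch$n_participants) || ch$n_participants < 2)
    add("cohort.n_participants", "need at least 2 participants")
  if (is.null(ch$n_trials) || ch$n_trials < 1)
    add("cohort.n_trials", "need at least 1 trial per participant")
  if (!is.null(config$policy) &&
      !config$policy$type %in% c("observer", "logistic"))
    add("policy.type", "policy type must be 'observer' or 'logistic'")
  sm <- config$sampler
  for (f in c("chains", "warmup", "iter")) {
    if (is.null(sm[[f]]) || sm[[f]] < 1)
      add(paste0("sampler.", f), "must be a positive integer")
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(field = character(), message = character())
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "config_validation")
}

#' @export
print.config_validation <- function(x, ...) {
  if (x$ok) {
    cat("config OK\n")
  } else {
    cat(sprintf("config INVALID (%d issue%s):\n", nrow(x$issues),
                if (nrow(x$issues) == 1L) "" else "s"))
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  - %s: %s\n", x$issues$field[i], x$issues$message[i]))
  }
  invisible(x)
}

#' Run the analysis pipeline
#'
#' Executes the requested stage(s) in dependency order and writes
#' delimited-text artifacts plus a manifest under `out_dir`:
#' \describe{
#'   \item{calibrate}{per-variant noise calibration
#'     (`calibration.tsv`);}
#'   \item{generate}{cohort trials (`trials.tsv`, `points.tsv`);}
#'   \item{simulate}{choices and planted ground truth (`choices.tsv`,
#'     `ground_truth.tsv`);}
#'   \item{fit}{hierarchical sensitivity fits, full and likelihood-only
#'     (`population_sensitivity.tsv`, `participant_sensitivity.tsv`,
#'     `waic.tsv`, `diagnostics.tsv`, `population_draws.tsv`);}
#'   \item{report}{summary tables (`accuracy_summary.tsv`,
#'     `report.tsv`).}
#' }
#' `stage = "all"` runs everything. Later stages require the artifacts of
#' earlier ones and raise a dependency error when they are missing.
#'
#' @param config a config list from [read_pipeline_config()] (or a path).
#' @param stage one of `"calibrate"`, `"generate"`, `"simulate"`,
#'   `"fit"`, `"report"`, `"all"`.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config = read_pipeline_config(),
                         stage = c("all", "calibrate", "generate",
                                   "simulate", "fit", "report"),
                         out_dir = "pipeline_out", quiet = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  val <- validate_config(config)
  if (!val$ok) {
    msg <- paste0("invalid pipeline config:\n",
                  paste(sprintf("  - %s: %s", val$issues$field,
                                val$issues$message), collapse = "\n"))
    stop(errorCondition(msg,
                        class = c("occamfia_config_error", "error")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list()
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  need <- function(name, for_stage) {
    p <- file.path(out_dir, name)
    if (!file.exists(p))
      stop(errorCondition(
        sprintf("stage '%s' needs missing artifact '%s'; run earlier stages first",
                for_stage, name),
        class = c("occamfia_dependency_error", "error")))
    utils::read.delim(p)
  }
  stages <- if (stage == "all")
    c("calibrate", "generate", "simulate", "fit", "report") else stage
  seed <- as.integer(config$seed)

  variants_from_config <- function() {
    # prefer calibrated sigmas if a calibration artifact exists
    calp <- file.path(out_dir, "calibration.tsv")
    sig <- NULL
    if (file.exists(calp)) {
      cal <- utils::read.delim(calp)
      sig <- stats::setNames(cal$sigma, cal$variant)
    }
    default_variants(config, sigma = sig)
  }

  if ("calibrate" %in% stages) {
    say("calibrating task difficulty ...")
    t0 <- Sys.time()
    vs <- default_variants(config)
    calcfg <- config$calibration %||% list()
    rows <- lapply(names(vs), function(vn) {
      v <- calibrate_difficulty(
        vs[[vn]], target_gap = calcfg$target_gap %||% 0.01,
        budget = calcfg$budget %||% 40000L,
        sigma_range = unlist(calcfg$sigma_range %||% c(0.15, 3)),
        tol = calcfg$tol %||% 0.0015,
        seed = derive_seed(seed, paste0("calibrate-", vn)))
      cal <- attr(v, "calibration")
      data.frame(variant = vn, sigma = cal$sigma,
                 achieved_gap = cal$achieved, target_gap = cal$target)
    })
    tsv(do.call(rbind, rows), "calibration.tsv")
    say("  done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  }

  cohort <- NULL
  build_cohort <- function() {
    if (!is.null(cohort)) return(cohort)
    vs <- variants_from_config()
    spec <- cohort_spec(
      variants = names(vs),
      n_participants = config$cohort$n_participants,
      n_trials = config$cohort$n_trials,
      policy = config$policy,
      master_seed = derive_seed(seed, "cohort"))
    cohort <<- generate_cohort(spec, vs)
    cohort
  }

  if ("generate" %in% stages) {
    say("generating trials ...")
    coh <- build_cohort()
    tsv(coh$trials, "trials.tsv")
    tsv(coh$points, "points.tsv")
  }

  if ("simulate" %in% stages) {
    say("simulating choices ...")
    need("trials.tsv", "simulate")
    coh <- build_cohort()
    tsv(coh$choices, "choices.tsv")
    tsv(coh$participants, "ground_truth.tsv")
  }

  if ("fit" %in% stages) {
    say("fitting the hierarchical sensitivity model ...")
    trials <- need("trials.tsv", "fit")
    choices <- need("choices.tsv", "fit")
    vs <- variants_from_config()
    des <- build_design(trials, vs, choices = choices)
    sm <- config$sampler
    thr <- sm$rhat_threshold %||% 1.01
    fit <- fit_hierarchical(des, chains = sm$chains, warmup = sm$warmup,
                            iter = sm$iter, rhat_threshold = thr,
                            seed = derive_seed(seed, "fit"))
    fit_l <- fit_hierarchical(des, terms = "L", chains = sm$chains,
                              warmup = sm$warmup, iter = sm$iter,
                              rhat_threshold = thr,
                              seed = derive_seed(seed, "fit-lik"))
    if (!fit$converged || !fit_l$converged)
      stop(errorCondition(
        "hierarchical fit did not converge; see diagnostics",
        class = c("occamfia_convergence_error", "error")))
    rs <- relative_sensitivity(fit)
    tsv(rs$population, "population_sensitivity.tsv")
    tsv(rs$participant, "participant_sensitivity.tsv")
    wt <- compare_waic(fit, fit_l)
    wt$diff <- attr(wt, "diff"); wt$se_diff <- attr(wt, "se_diff")
    tsv(wt, "waic.tsv")
    tsv(data.frame(parameter = names(fit$diagnostics$rhat),
                   rhat = fit$diagnostics$rhat,
                   ess = fit$diagnostics$ess[
                     names(fit$diagnostics$rhat)]),
        "diagnostics.tsv")
    tsv(as.data.frame(fit$draws$mu), "population_draws.tsv")
  }

  if ("report" %in% stages) {
    say("writing report tables ...")
    choices <- need("choices.tsv", "report")
    pop <- need("population_sensitivity.tsv", "report")
    acc <- stats::aggregate(
      cbind(accuracy_generative = correct_generative,
            accuracy_ml = correct_ml) ~ participant_id + variant,
      data = choices, FUN = mean)
    tsv(acc, "accuracy_summary.tsv")
    rep_df <- data.frame(
      quantity = c(paste0("relative_sensitivity_", pop$term),
                   "mean_accuracy_generative", "mean_accuracy_ml"),
      value = c(pop$mean, mean(choices$correct_generative),
                mean(choices$correct_ml)),
      sd = c(pop$sd, NA, NA))
    tsv(rep_df, "report.tsv")
  }

  # resolved config + manifest make the directory self-describing
  resolved <- unclass(config)
  calp <- file.path(out_dir, "calibration.tsv")
  if (file.exists(calp)) {
    cal <- utils::read.delim(calp)
    for (i in seq_len(nrow(cal)))
      resolved$variants[[cal$variant[i]]]$sigma <- cal$sigma[i]
  }
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  paths[["resolved_config.yaml"]] <- file.path(out_dir,
                                               "resolved_config.yaml")
  vs <- tryCatch(default_variants(
    structure(resolved, class = c("pipeline_config", "list"))),
    error = function(e) NULL)
  manifest <- list(
    stages = stages, seed = seed,
    geometry_hash = if (!is.null(vs)) geometry_hash(vs) else NA,
    package_version = as.character(utils::packageVersion("occamfia")),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = names(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths[["run_manifest.json"]] <- file.path(out_dir, "run_manifest.json")
  invisible(paths)
}
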