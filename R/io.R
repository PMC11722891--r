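#' Read and write NONMEM-style concentration datasets
#'
#' The canonical on-disk layout is a plain CSV with columns `ID`, `TIME`,
#' `DV`, `AMT`, `EVID` (1 = dose, 0 = observation), `ROUTE` and `CENS`
#' (1 = below LLOQ, with `DV` set to the LLOQ). Missing `DV` on dose rows
#' is written as `.`. `read_pkdataset` validates rather than coerces:
#' missing mandatory columns, non-numeric `TIME`/`DV`, duplicate
#' `(ID, TIME, EVID)` rows, subjects without a dose record and observations
#' before the first dose are all hard errors naming the offending subject.
#'
#' @param path file path.
#' @return `read_pkdataset`: a `pk_dataset` data.frame;
#'   `write_pkdataset`: the path, invisibly. Writing then re-reading then
#'   re-writing a canonical file is byte-stable.
#' @export
read_pkdataset <- function(path) {
  raw <- utils::read.csv(path, na.strings = ".", stringsAsFactors = FALSE)
  needed <- c("ID", "TIME", "DV", "AMT", "EVID", "ROUTE", "CENS")
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("TIME", "DV", "AMT", "EVID", "CENS")) {
    if (!is.numeric(raw[[col]]) && !all(is.na(raw[[col]])))
      stop("column ", col, " must be numeric", call. = FALSE)
  }
  key <- paste(raw$ID, raw$TIME, raw$EVID)
  if (anyDuplicated(key))
    stop("duplicate (ID, TIME, EVID) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  for (id in unique(raw$ID)) {
    sub <- raw[raw$ID == id, ]
    doses <- sub[sub$EVID == 1L, ]
    if (nrow(doses) == 0L)
      stop("subject ", id, " has no dose record", call. = FALSE)
    obs <- sub[sub$EVID == 0L, ]
    if (nrow(obs) && any(obs$TIME < min(doses$TIME)))
      stop("subject ", id, " has observation(s) before any dose", call. = FALSE)
  }
  class(raw) <- c("pk_dataset", "data.frame")
  raw
}

#' @rdname read_pkdataset
#' @param data a `pk_dataset` (or compatible data.frame).
#' @export
write_pkdataset <- function(data, path) {
  needed <- c("ID", "TIME", "DV", "AMT", "EVID", "ROUTE", "CENS")
  stopifnot(all(needed %in% names(data)))
  utils::write.csv(as.data.frame(data)[, needed], path, quote = FALSE,
                   row.names = FALSE, na = ".")
  invisible(path)
}

#' Read / write a pipeline run configuration
#'
#' Configurations are YAML with blocks: `seed` (mandatory; there is no
#' silent default randomness), `output_dir`, `arms` (named blocks each with
#' a `design` and a generating/initial `model`), optional `fit`
#' (passed to [fit_settings()]) and `diagnostics` (`n_sim`). The parse ->
#' serialize -> parse round trip is lossless.
#'
#' @param path YAML file path.
#' @return `read_run_config`: the validated config list;
#'   `write_run_config`: the path, invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  if (is.null(config$seed))
    stop("config must declare an explicit seed", call. = FALSE)
  if (is.null(config$arms) || !length(config$arms) || is.null(names(config$arms)))
    stop("config must declare at least one named arm", call. = FALSE)
  for (nm in names(config$arms)) {
    arm <- config$arms[[nm]]
    if (is.null(arm$design) || is.null(arm$model))
      stop("arm '", nm, "' needs both a design and a model block", call. = FALSE)
  }
  config
}

.arm_design <- function(d) {
  study_design(route = d$route, dose = d$dose,
               sampling_times = unlist(d$sampling_times),
               n_subjects = d$n_subjects,
               lloq = if (is.null(d$lloq)) NA else d$lloq)
}

.arm_model <- function(m) {
  population_model(structure = m$structure, typical = unlist(m$typical),
                   omega = unlist(m$omega), b = m$b)
}

#' Run the full analysis pipeline
#'
#' Executes the study workflow on synthetic data: per arm, simulate a
#' population dataset, run per-subject NCA, fit the population model by
#' SAEM, and compute VPC and NPDE diagnostics; when both an i.v. and an
#' oral arm are present, absolute bioavailability is computed from the
#' mean dose-normalized AUC(0-Inf) of the two arms. Every stage output is
#' written under `output_dir` together with a JSON manifest recording the
#' seeds, settings and package version; the run is a pure function of the
#' configuration.
#'
#' @param config a config list (see [read_run_config()]) or a YAML path.
#' @param output_dir overrides `config$output_dir`.
#' @return (invisibly) a list with per-arm results (`data`, `nca`, `fit`,
#'   `vpc`, `npde`), `bioavailability` (or NULL) and `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- output_dir %||% config$output_dir %||% stop(
    "config must declare an output_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  fit_cfg <- config$fit %||% list()
  fit_cfg$seed <- NULL  # fit seeds are derived from the master seed
  n_sim <- (config$diagnostics %||% list())$n_sim %||% 1000
  arms <- list()
  files <- character()
  for (a in seq_along(config$arms)) {
    nm <- names(config$arms)[a]
    arm <- config$arms[[a]]
    design <- .arm_design(arm$design)
    model <- .arm_model(arm$model)
    sim_seed <- seed + 1000L * a
    data <- simulate_population(design, model, seed = sim_seed)
    f_data <- file.path(out_dir, paste0(nm, "_dataset.csv"))
    write_pkdataset(data, f_data)
    nca_tab <- nca_dataset(data)
    f_nca <- file.path(out_dir, paste0(nm, "_nca.csv"))
    utils::write.csv(nca_tab, f_nca, row.names = FALSE)
    settings <- do.call(fit_settings,
                        c(fit_cfg, list(seed = sim_seed + 1L)))
    fit <- saem_fit(data, model$structure, settings)
    f_fit <- file.path(out_dir, paste0(nm, "_fit.json"))
    jsonlite::write_json(list(structure = fit$structure$name,
                              theta = as.list(fit$theta_hat),
                              omega = as.list(fit$omega_hat),
                              b = fit$b_hat,
                              rse_pct = as.list(fit$rse_pct),
                              log_likelihood = fit$log_likelihood,
                              aic = fit$aic, bic = fit$bic,
                              converged = fit$converged),
                         f_fit, auto_unbox = TRUE, digits = NA)
    f_trace <- file.path(out_dir, paste0(nm, "_trace.csv"))
    utils::write.csv(fit$trace, f_trace, row.names = FALSE)
    v <- vpc(fit, n_sim = n_sim, seed = sim_seed + 2L)
    f_vpc <- file.path(out_dir, paste0(nm, "_vpc.csv"))
    utils::write.csv(as.data.frame(v), f_vpc, row.names = FALSE)
    np <- npde(fit, n_sim = n_sim, seed = sim_seed + 3L)
    f_npde <- file.path(out_dir, paste0(nm, "_npde.csv"))
    utils::write.csv(data.frame(npde = np$npde), f_npde, row.names = FALSE)
    arms[[nm]] <- list(data = data, nca = nca_tab, fit = fit, vpc = v,
                       npde = np, seed = sim_seed)
    files <- c(files, f_data, f_nca, f_fit, f_trace, f_vpc, f_npde)
  }
  fabs <- NULL
  routes <- vapply(arms, function(x) attr(x$data, "design")$route, "")
  if (any(routes == "iv_bolus") && any(routes == "oral")) {
    iv <- arms[[which(routes == "iv_bolus")[1]]]
    po <- arms[[which(routes == "oral")[1]]]
    fabs <- bioavailability(mean(po$nca$auc_0_inf),
                            attr(po$data, "design")$dose,
                            mean(iv$nca$auc_0_inf),
                            attr(iv$data, "design")$dose)
  }
  manifest <- list(package = "saempk",
                   version = as.character(utils::packageVersion("saempk")),
                   seed = seed,
                   arm_seeds = lapply(arms, `[[`, "seed"),
                   config = config,
                   bioavailability = fabs,
                   files = basename(files))
  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(arms = arms, bioavailability = fabs, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
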