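# Workflow commands tying the stages together: baseline, sweep, fit,
# recover, report.  Structured configs (lists or YAML paths), seeded
# randomness, machine-parsable CSV/JSON outputs with provenance headers.

#' Run a workflow command
#'
#' Commands:
#' \describe{
#'   \item{baseline}{initialize the homeostatic vessel, report the targets
#'     and the diastolic baseline metrics (stored energy, stiffness).}
#'   \item{sweep}{metric CSV across a porosity grid for one scenario.}
#'   \item{fit}{surrogate-management fits of the insult parameters to an
#'     observation CSV, over one or more seeded trials, with a summary table
#'     (per-trial optima, mean and s.e.m.).}
#'   \item{recover}{generate a synthetic observation set at known true
#'     parameters, fit it, and report recovery errors.}
#'   \item{report}{merge the artifacts present in \code{out_dir} into one
#'     summary JSON.}
#' }
#'
#' @param command one of \code{"baseline"}, \code{"sweep"}, \code{"fit"},
#'   \code{"recover"}, \code{"report"}.
#' @param config a named list (or path to a YAML file) with optional entries:
#'   \code{params_file} (baseline parameter YAML), \code{out_dir} (output
#'   directory; no files written if NULL), \code{scenario}, \code{porosities},
#'   \code{seed}, \code{trials}, \code{budget}, \code{noise_cv},
#'   \code{n_per_group}, \code{observations} (CSV path),
#'   \code{A_true} (list: theta_delta_max, theta_Gc_max, g),
#'   \code{n_increments}.
#' @param quiet suppress console summaries.
#' @return invisibly, a list with the command's results (also written to
#'   \code{out_dir} when given).
#' @export
gr_run <- function(command = c("baseline", "sweep", "fit", "recover",
                               "report"),
                   config = list(), quiet = FALSE) {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(params_file = NULL, out_dir = NULL, scenario = "combined",
         porosities = seq(0.115, 0.699, length.out = 13),
         seed = 1, trials = 1, budget = 300, noise_cv = 0.08,
         n_per_group = 8, observations = NULL,
         A_true = list(theta_delta_max = 0.0594, theta_Gc_max = 0.0080,
                       g = 6.21),
         n_increments = 10),
    config)
  par <- if (is.null(cfg$params_file)) vessel_params()
         else read_vessel_params(cfg$params_file)
  baseline <- init_homeostatic(par)
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  prov <- list(seed = cfg$seed, version = "aortagnr 0.1.0",
               config_hash = .config_hash(cfg))

  res <- switch(command,
    baseline = .cmd_baseline(baseline, cfg, prov, quiet),
    sweep = .cmd_sweep(baseline, cfg, prov, quiet),
    fit = .cmd_fit(baseline, cfg, prov, quiet),
    recover = .cmd_recover(baseline, cfg, prov, quiet),
    report = .cmd_report(cfg, prov, quiet))
  invisible(res)
}

.config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small order-stable checksum; no digest dependency
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.cmd_baseline <- function(baseline, cfg, prov, quiet) {
  met <- wild_type_metrics(baseline)
  out <- list(provenance = prov,
              targets = baseline$targets,
              baseline_diastolic_metrics = as.list(met))
  if (!quiet)
    message(sprintf(
      "baseline: W0 = %.1f kPa, c_tttt0 = %.2f MPa, sigma_o = %.1f kPa (support %.4f)",
      met$W_kPa, met$c_tttt_MPa, baseline$targets$sigma_o,
      baseline$targets$support))
  if (!is.null(cfg$out_dir))
    .write_json(out, file.path(cfg$out_dir, "baseline.json"))
  out
}

.cmd_sweep <- function(baseline, cfg, prov, quiet) {
  A <- do.call(insult_params, cfg$A_true)
  sw <- porosity_sweep(cfg$porosities, A, cfg$scenario, baseline,
                       n_increments = cfg$n_increments)
  if (!quiet)
    message(sprintf("sweep (%s): %d porosities, %d converged; last W = %.1f kPa",
                    cfg$scenario, nrow(sw), sum(sw$converged),
                    utils::tail(sw$W_kPa[sw$converged], 1)))
  if (!is.null(cfg$out_dir)) {
    path <- file.path(cfg$out_dir, paste0("sweep_", cfg$scenario, ".csv"))
    utils::write.csv(sw, path, row.names = FALSE)
    # evolved-state dump: one JSON record per porosity plus provenance
    states <- lapply(seq_len(nrow(sw)), function(i) list(
      porosity = sw$porosity[i],
      insults = list(tce = sw$tce[i], tdelta = sw$tdelta[i],
                     tGc = sw$tGc[i]),
      lambda_theta = sw$lambda_theta[i], m_c = sw$m_c[i], m_m = sw$m_m[i],
      a_mm = sw$inner_diameter_mm[i] / 2, h_mm = sw$thickness_mm[i],
      alpha0_deg = sw$alpha0_deg[i], converged = sw$converged[i]))
    .write_json(list(provenance = prov, states = states),
                file.path(cfg$out_dir,
                          paste0("sweep_", cfg$scenario, ".json")))
  }
  sw
}

.fit_trials <- function(obs, baseline, cfg) {
  obj <- phi_objective(obs, baseline, n_increments = cfg$n_increments)
  lapply(seq_len(cfg$trials), function(k) {
    smf_optimize(obj, insult_bounds(), seed = cfg$seed + (k - 1) * 101,
                 budget = cfg$budget)
  })
}

.fit_summary <- function(fits) {
  tab <- do.call(rbind, lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    data.frame(trial = k, theta_delta_max = f$A_star[1],
               theta_Gc_max = f$A_star[2], g = f$A_star[3],
               phi = f$phi_star, n_eval = f$n_eval, seed = f$seed,
               convergence = f$convergence)
  }))
  rownames(tab) <- NULL
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  list(trials = tab,
       mean = colMeans(tab[, c("theta_delta_max", "theta_Gc_max", "g")]),
       sem = if (nrow(tab) > 1)
         vapply(tab[, c("theta_delta_max", "theta_Gc_max", "g")], sem,
                numeric(1)) else c(theta_delta_max = NA_real_,
                                   theta_Gc_max = NA_real_, g = NA_real_))
}

.cmd_fit <- function(baseline, cfg, prov, quiet) {
  if (is.null(cfg$observations)) stop("fit requires config$observations (CSV)")
  obs <- read_observations(cfg$observations, baseline)
  fits <- .fit_trials(obs, baseline, cfg)
  summ <- .fit_summary(fits)
  if (!quiet)
    message(sprintf(
      "fit: %d trial(s); mean theta_delta_max = %.4f, theta_Gc_max = %.4f, g = %.2f",
      cfg$trials, summ$mean[1], summ$mean[2], summ$mean[3]))
  if (!is.null(cfg$out_dir)) {
    utils::write.csv(summ$trials, file.path(cfg$out_dir, "fit_trials.csv"),
                     row.names = FALSE)
    .write_json(list(provenance = prov, mean = as.list(summ$mean),
                     sem = as.list(summ$sem)),
                file.path(cfg$out_dir, "fit_summary.json"))
  }
  c(summ, list(fits = fits))
}

.cmd_recover <- function(baseline, cfg, prov, quiet) {
  A_true <- do.call(insult_params, cfg$A_true)
  obs <- generate_observations(A_true, noise_cv = cfg$noise_cv,
                               n_per_group = cfg$n_per_group,
                               seed = cfg$seed, baseline = baseline)
  fits <- .fit_trials(obs, baseline, cfg)
  summ <- .fit_summary(fits)
  truth <- c(theta_delta_max = A_true$theta_delta_max,
             theta_Gc_max = A_true$theta_Gc_max, g = A_true$g)
  err <- summ$mean - truth
  if (!quiet)
    message(sprintf("recover: phi* = %.3g; g error = %.1f%%",
                    min(vapply(fits, `[[`, numeric(1), "phi_star")),
                    100 * err[3] / truth[3]))
  out <- c(summ, list(A_true = truth, error = err,
                      phi_star = min(vapply(fits, `[[`, numeric(1),
                                            "phi_star")),
                      observations = obs, fits = fits))
  if (!is.null(cfg$out_dir)) {
    write_observations(obs, file.path(cfg$out_dir, "synthetic_observations.csv"))
    .write_json(list(provenance = prov, A_true = as.list(truth),
                     mean = as.list(summ$mean), error = as.list(err),
                     phi_star = out$phi_star),
                file.path(cfg$out_dir, "recovery.json"))
  }
  out
}

.cmd_report <- function(cfg, prov, quiet) {
  if (is.null(cfg$out_dir)) stop("report requires config$out_dir")
  files <- list.files(cfg$out_dir, pattern = "\\.(json|csv)$",
                      full.names = TRUE)
  files <- files[!grepl("report\\.json$", files)]
  merged <- list(provenance = prov, artifacts = basename(files))
  for (f in files[grepl("\\.json$", files)])
    merged[[basename(f)]] <- jsonlite::read_json(f, simplifyVector = TRUE)
  .write_json(merged, file.path(cfg$out_dir, "report.json"))
  if (!quiet) message("report: merged ", length(files), " artifact(s)")
  merged
}
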