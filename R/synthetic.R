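# Synthetic porosity-metric observation sets emulating the two Marfan mouse
# genotype groups, generated from the combined-insult forward model at a
# known insult-parameter triple plus multiplicative lognormal noise.

#' Sample group-labelled elastin porosities
#'
#' The milder heterozygous-like group draws uniformly on [0.115, 0.40], the
#' severe hypomorph-like group on [0.30, 0.699]; the ranges overlap and
#' reproduce the pooled experimental bounds with the observed group ordering.
#'
#' @param n_per_group specimens per group (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns \code{specimen_id}, \code{group}
#'   (\code{"C1041G-like"} / \code{"mgR-like"}), \code{porosity}.
#' @export
generate_porosities <- function(n_per_group, seed) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  u <- .with_seed(seed, stats::runif(2 * n_per_group))
  mild <- 0.115 + u[seq_len(n_per_group)] * (0.40 - 0.115)
  severe <- 0.30 + u[n_per_group + seq_len(n_per_group)] * (0.699 - 0.30)
  data.frame(
    specimen_id = sprintf("S%03d", seq_len(2 * n_per_group)),
    group = rep(c("C1041G-like", "mgR-like"), each = n_per_group),
    porosity = c(mild, severe))
}

#' Generate a synthetic observation set from the forward model
#'
#' Runs the combined-insult equilibrated forward model at every sampled
#' porosity with the stated true insult parameters, then perturbs each metric
#' by multiplicative lognormal noise with coefficient of variation
#' \code{noise_cv} (mean-one noise).  Wild-type normalizers Y_WT are the
#' zero-insult model metrics.  Porosities where the forward model fails are
#' dropped with a warning.
#'
#' @param A_true a \code{gr_insult_params}: the generating insult parameters.
#' @param noise_cv coefficient of variation of the metric noise (>= 0);
#'   default 0.08, a biological-replicate scale.
#' @param n_per_group specimens per group.
#' @param seed integer seed (porosities and noise).
#' @param baseline a \code{gr_baseline}; default built from packaged
#'   parameters.
#' @return an object of class \code{gr_observations}: list with \code{data}
#'   (per-specimen porosity-metric records), \code{Y_WT} (one-row data.frame
#'   of zero-insult metrics) and \code{provenance} (A_true, noise level,
#'   seed).
#' @export
generate_observations <- function(A_true, noise_cv = 0.08, n_per_group = 8,
                                  seed = 1,
                                  baseline = init_homeostatic(vessel_params())) {
  stopifnot(inherits(A_true, "gr_insult_params"))
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  por <- generate_porosities(n_per_group, seed)
  sw <- porosity_sweep(por$porosity, A_true, "combined", baseline)
  keep <- sw$converged
  if (any(!keep))
    warning(sprintf("%d record(s) dropped: forward model failed", sum(!keep)))
  por <- por[keep, , drop = FALSE]
  sw <- sw[keep, , drop = FALSE]

  mcols <- c("W_kPa", "c_tttt_MPa", "c_zzzz_MPa", "distensibility_per_mmHg",
             "inner_diameter_mm", "thickness_mm")
  vals <- as.matrix(sw[, mcols])
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- .with_seed(seed + 1000L,
                      matrix(stats::rlnorm(length(vals),
                                           meanlog = -sdlog^2 / 2,
                                           sdlog = sdlog),
                             nrow = nrow(vals)))
    vals <- vals * fac
  }
  data <- cbind(por, as.data.frame(vals))
  rownames(data) <- NULL
  Y_WT <- wild_type_metrics(baseline)
  structure(list(data = data,
                 Y_WT = Y_WT,
                 provenance = list(A_true = unclass(A_true),
                                   noise_cv = noise_cv,
                                   n_per_group = n_per_group,
                                   seed = seed)),
            class = "gr_observations")
}

#' Write an observation set to CSV with a sidecar JSON
#'
#' @param observations a \code{gr_observations}.
#' @param path CSV output path; the sidecar (normalizers and provenance)
#'   goes to \code{<path>.json}.
#' @return invisibly, the CSV path.
#' @export
write_observations <- function(observations, path) {
  stopifnot(inherits(observations, "gr_observations"))
  utils::write.csv(observations$data, path, row.names = FALSE)
  side <- list(Y_WT = as.list(observations$Y_WT),
               provenance = observations$provenance)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an observation set from CSV (with optional sidecar JSON)
#'
#' Accepts the same schema real per-specimen data would use:
#' \code{specimen_id, group, porosity, W_kPa, c_tttt_MPa, c_zzzz_MPa,
#' distensibility_per_mmHg, inner_diameter_mm, thickness_mm}.  If no sidecar
#' is present, Y_WT is computed from the zero-insult model.
#'
#' @param path CSV path.
#' @param baseline a \code{gr_baseline} used to compute Y_WT when no sidecar
#'   exists.
#' @return a \code{gr_observations} object.
#' @export
read_observations <- function(path,
                              baseline = init_homeostatic(vessel_params())) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("porosity", "W_kPa", "c_tttt_MPa")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("observation CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    Y_WT <- as.data.frame(side$Y_WT)
    prov <- side$provenance
  } else {
    Y_WT <- wild_type_metrics(baseline)
    prov <- list(source = path)
  }
  structure(list(data = data, Y_WT = Y_WT, provenance = prov),
            class = "gr_observations")
}
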