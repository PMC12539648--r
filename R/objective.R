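# Objective function and surrogate management framework optimizer.

#' Normalized mean squared error
#'
#' J_Y = (1/n) * sum_i ((Y_i - Yh_i) / Y_WT)^2, the per-metric misfit between
#' model predictions and target observations normalized by the wild-type
#' value of the metric.
#'
#' @param model_values model predictions Y(A) at the observation porosities.
#' @param target_values observed values Yh.
#' @param Y_WT positive wild-type normalizer for this metric.
#' @param n number of points (default: length of the lists).
#' @return nonnegative misfit; zero iff the fit is perfect.
#' @export
normalized_mse <- function(model_values, target_values, Y_WT,
                           n = length(model_values)) {
  if (length(model_values) == 0 || length(target_values) == 0)
    stop("empty value lists")
  if (length(model_values) != length(target_values))
    stop("model and target lists must have equal length")
  if (Y_WT <= 0) stop("Y_WT must be > 0")
  sum(((model_values - target_values) / Y_WT)^2) / n
}

#' Combined two-metric objective
#'
#' Phi = (J_ctttt + J_W) / 2: the arithmetic mean of the circumferential
#' stiffness and stored-energy misfits.
#'
#' @param J_stiffness,J_energy nonnegative per-metric misfits.
#' @return the combined objective.
#' @export
combined_objective <- function(J_stiffness, J_energy) {
  if (J_stiffness < 0 || J_energy < 0) stop("misfits must be >= 0")
  (J_stiffness + J_energy) / 2
}

#' Latin hypercube sample in a box
#'
#' One point per equal-probability stratum in every dimension; deterministic
#' for a fixed seed.
#'
#' @param bounds 2 x d matrix: row 1 lower, row 2 upper bounds.
#' @param n_points number of points (>= 1).
#' @param seed integer seed.
#' @return n_points x d matrix of parameter points.
#' @export
lhs_sample <- function(bounds, n_points, seed) {
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2) stop("bounds must be a 2 x d matrix")
  if (any(bounds[2, ] <= bounds[1, ])) stop("degenerate bounds")
  if (n_points < 1) stop("n_points must be >= 1")
  d <- ncol(bounds)
  u <- .with_seed(seed, lhs::randomLHS(n_points, d))
  sweep(sweep(u, 2, bounds[2, ] - bounds[1, ], "*"), 2, bounds[1, ], "+")
}

# Evaluate expr with a temporary RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Kriging (Gaussian-process) surrogate
#'
#' Interpolating Gaussian-process regressor with an isotropic
#' squared-exponential correlation on the unit-scaled box, constant
#' (generalized-least-squares) mean, lengthscale fit by profile maximum
#' likelihood, and a tiny nugget (1e-10) for conditioning, so predictions at
#' training points reproduce the training values.
#'
#' @param points n x d matrix of training locations.
#' @param values length-n vector of training values.
#' @param bounds optional 2 x d matrix used to scale inputs to the unit box
#'   (default: the ranges of \code{points}).
#' @param nugget diagonal jitter (default 1e-10).
#' @return an object of class \code{gr_kriging}; use [predict.gr_kriging()].
#' @export
kriging_surrogate <- function(points, values, bounds = NULL, nugget = 1e-10) {
  X <- as.matrix(points)
  y <- as.numeric(values)
  if (nrow(X) < 2) stop("need at least 2 training points")
  if (nrow(X) != length(y)) stop("points/values length mismatch")
  dup <- duplicated(X) | duplicated(X, fromLast = TRUE)
  if (any(dup)) {
    key <- apply(X, 1, paste, collapse = "\r")
    for (k in unique(key[dup]))
      if (length(unique(y[key == k])) > 1)
        stop("duplicated points with conflicting values")
    keep <- !duplicated(key)
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  if (is.null(bounds))
    bounds <- rbind(apply(X, 2, min), apply(X, 2, max))
  span <- pmax(bounds[2, ] - bounds[1, ], .Machine$double.eps)
  U <- sweep(sweep(X, 2, bounds[1, ], "-"), 2, span, "/")
  D2 <- as.matrix(stats::dist(U))^2
  n <- nrow(U)

  nll <- function(log_ell) {
    K <- exp(-D2 / (2 * exp(2 * log_ell))) + diag(nugget, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ones <- rep(1, n)
    Ki_y <- backsolve(ch, forwardsolve(t(ch), y))
    Ki_1 <- backsolve(ch, forwardsolve(t(ch), ones))
    mu <- sum(Ki_y) / sum(Ki_1)
    r <- y - mu
    Ki_r <- backsolve(ch, forwardsolve(t(ch), r))
    s2 <- max(sum(r * Ki_r) / n, 1e-300)
    n / 2 * log(s2) + sum(log(diag(ch)))
  }
  opt <- stats::optimize(nll, interval = log(c(0.03, 10)))
  ell <- exp(opt$minimum)
  K <- exp(-D2 / (2 * ell^2)) + diag(nugget, n)
  ch <- chol(K)
  ones <- rep(1, n)
  Ki_1 <- backsolve(ch, forwardsolve(t(ch), ones))
  Ki_y <- backsolve(ch, forwardsolve(t(ch), y))
  mu <- sum(Ki_y) / sum(Ki_1)
  alpha <- backsolve(ch, forwardsolve(t(ch), y - mu))
  structure(list(U = U, bounds = bounds, span = span, ell = ell,
                 mu = mu, alpha = alpha),
            class = "gr_kriging")
}

#' Predict from a kriging surrogate
#'
#' @param object a \code{gr_kriging} from [kriging_surrogate()].
#' @param newdata m x d matrix (or vector for one point) of locations.
#' @param ... unused.
#' @return length-m vector of predictions; finite everywhere in the box.
#' @export
predict.gr_kriging <- function(object, newdata, ...) {
  Xn <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
        else as.matrix(newdata)
  Un <- sweep(sweep(Xn, 2, object$bounds[1, ], "-"), 2, object$span, "/")
  # cross-correlation
  d2 <- outer(rowSums(Un^2), rowSums(object$U^2), "+") -
    2 * Un %*% t(object$U)
  kx <- exp(-pmax(d2, 0) / (2 * object$ell^2))
  as.numeric(object$mu + kx %*% object$alpha)
}

#' Surrogate management framework optimizer
#'
#' Derivative-free minimization over a box: a Latin-hypercube initial design,
#' kriging SEARCH steps (evaluate the true objective at the surrogate
#' minimizer, repeating while improved points are found) and mesh-adaptive
#' POLL steps (a coordinate positive-spanning stencil around the incumbent,
#' with mesh halving on failure), terminating when the mesh falls below
#' \code{delta_min} of the box width or the evaluation budget is exhausted.
#' Objective failures (errors or non-finite values) count as +Inf and the
#' point is retained in the log.
#'
#' @param objective function of a length-d parameter vector returning a
#'   scalar.
#' @param bounds 2 x d matrix: row 1 lower, row 2 upper bounds.
#' @param seed integer seed controlling the initial design and the surrogate
#'   multistarts.
#' @param budget maximum number of objective evaluations (default 300).
#' @param n_init initial design size (default 10 * d).
#' @param delta_min mesh threshold as a fraction of box width (default 1e-3).
#' @param delta_init initial mesh size as a fraction of box width.
#' @return a list of class \code{gr_optim}: \code{A_star} (named if bounds
#'   have column names), \code{phi_star}, \code{n_eval}, \code{seed},
#'   \code{convergence} ("mesh" or "budget"), and \code{evaluations}
#'   (data.frame log of all evaluated points).
#' @export
smf_optimize <- function(objective, bounds, seed, budget = 300,
                         n_init = NULL, delta_min = 1e-3, delta_init = 0.25) {
  bounds <- as.matrix(bounds)
  d <- ncol(bounds)
  width <- bounds[2, ] - bounds[1, ]
  if (is.null(n_init)) n_init <- 10 * d
  n_init <- min(n_init, budget)

  safe_f <- function(x) {
    v <- tryCatch(suppressWarnings(objective(x)), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  X <- lhs_sample(bounds, n_init, seed)
  y <- apply(X, 1, safe_f)
  n_eval <- n_init
  best <- which.min(y)
  xb <- X[best, ]; fb <- y[best]
  delta <- delta_init
  convergence <- "budget"
  rng_stream <- seed + 1

  clip <- function(x) pmin(pmax(x, bounds[1, ]), bounds[2, ])

  search_step <- function() {
    fin <- is.finite(y)
    if (sum(fin) < 2) return(NULL)
    sur <- tryCatch(kriging_surrogate(X[fin, , drop = FALSE], y[fin],
                                      bounds = bounds),
                    error = function(e) NULL)
    if (is.null(sur)) return(NULL)
    starts <- rbind(xb, lhs_sample(bounds, 4, rng_stream + 7))
    cand <- NULL; cv <- Inf
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(stats::optim(starts[i, ],
                                 function(z) predict(sur, clip(z)),
                                 method = "L-BFGS-B",
                                 lower = bounds[1, ], upper = bounds[2, ]),
                    error = function(e) NULL)
      if (!is.null(o) && o$value < cv) { cand <- o$par; cv <- o$value }
    }
    cand
  }

  while (n_eval < budget) {
    improved <- FALSE
    # SEARCH
    xs <- search_step()
    rng_stream <- rng_stream + 13
    if (!is.null(xs) && n_eval < budget) {
      xs <- clip(xs)
      if (min(sqrt(colSums((t(X) - xs)^2) / sum(width^2))) > 1e-12) {
        fs <- safe_f(xs); n_eval <- n_eval + 1
        X <- rbind(X, xs); y <- c(y, fs)
        if (fs < fb) { xb <- xs; fb <- fs; improved <- TRUE }
      }
    }
    if (improved) next
    # POLL: coordinate positive basis
    for (j in seq_len(d)) {
      for (s in c(1, -1)) {
        if (n_eval >= budget) break
        xp <- clip(xb + s * delta * width * (seq_len(d) == j))
        if (min(sqrt(colSums((t(X) - xp)^2) / sum(width^2))) <= 1e-12) next
        fp <- safe_f(xp); n_eval <- n_eval + 1
        X <- rbind(X, xp); y <- c(y, fp)
        if (fp < fb) { xb <- xp; fb <- fp; improved <- TRUE; break }
      }
      if (improved) break
    }
    if (!improved) {
      delta <- delta / 2
      if (delta < delta_min) { convergence <- "mesh"; break }
    }
  }

  nm <- colnames(bounds)
  A <- as.numeric(xb)
  if (!is.null(nm)) names(A) <- nm
  ev <- as.data.frame(X)
  if (!is.null(nm)) names(ev) <- nm
  ev$phi <- y
  structure(list(A_star = A, phi_star = fb, n_eval = n_eval, seed = seed,
                 convergence = convergence, evaluations = ev),
            class = "gr_optim")
}

#' Build the combined-insult objective for an observation set
#'
#' Returns Phi(A): for the candidate insult parameters
#' A = (theta_delta_max, theta_Gc_max, g), the combined-insult forward model
#' is evaluated at every observation porosity and the circumferential
#' stiffness and stored-energy misfits (normalized by the wild-type values)
#' are averaged.  Forward-model failures yield +Inf.
#'
#' @param observations a \code{gr_observations} object (see
#'   [generate_observations()] / [read_observations()]).
#' @param baseline a \code{gr_baseline} from [init_homeostatic()].
#' @param n_increments continuation increments per forward solve.
#' @return a function A -> Phi.
#' @export
phi_objective <- function(observations, baseline, n_increments = 10) {
  obs <- observations$data
  Y_WT <- observations$Y_WT
  force(baseline)
  function(A_vec) {
    A <- tryCatch(insult_params(theta_delta_max = A_vec[1],
                                theta_Gc_max = A_vec[2], g = A_vec[3]),
                  error = function(e) NULL)
    if (is.null(A)) return(Inf)
    sw <- suppressWarnings(
      porosity_sweep(obs$porosity, A, "combined", baseline,
                     n_increments = n_increments))
    if (any(!sw$converged)) return(Inf)
    Jc <- normalized_mse(sw$c_tttt_MPa, obs$c_tttt_MPa, Y_WT$c_tttt_MPa)
    Jw <- normalized_mse(sw$W_kPa, obs$W_kPa, Y_WT$W_kPa)
    combined_objective(Jc, Jw)
  }
}

#' Default optimization bounds for the insult parameters
#'
#' @return 2 x 3 matrix with columns \code{theta_delta_max},
#'   \code{theta_Gc_max}, \code{g}.
#' @export
insult_bounds <- function() {
  b <- rbind(c(0, 0, 0.01), c(0.1, 0.015, 10))
  colnames(b) <- c("theta_delta_max", "theta_Gc_max", "g")
  b
}
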