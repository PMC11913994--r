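# Monte-Carlo design-space mapping: probability that any analyte misses its
# minimum acceptable response under setpoint jitter and residual noise, and
# selection of a robust weighted optimum within the low-risk region.

#' Acceptance specification for one analyte
#'
#' @param analyte Analyte name (must match a fitted model).
#' @param min_acceptable Minimum acceptable response (same units as the
#'   model's response; > 0).
#' @param weight Positive importance weight used by [select_optimum()].
#' @export
response_spec <- function(analyte, min_acceptable, weight = 1) {
  stopifnot(min_acceptable > 0, weight > 0)
  structure(list(analyte = analyte, min_acceptable = min_acceptable,
                 weight = weight), class = "response_spec")
}

#' Default weighted acceptance specs from fitted models
#'
#' Each analyte's target is a fraction (default 70 %) of its own maximum
#' predicted response over the supplied grid; weights default to the
#' prostaglandin/lipoxin-prioritized scheme used throughout this package
#' (PGE2-d4 and LXA4-d5 = 2, LTB4-d4 = 1.5, HODE/HETE = 1), reflecting the
#' low abundance of prostaglandins and lipoxins in biological samples.
#'
#' @param models Named list of `rsm` models (one per analyte).
#' @param grid Named list of natural-unit axis vectors (see
#'   [design_space_map()]).
#' @param fraction Fraction of the per-analyte predicted maximum (default 0.7).
#' @param weights Named numeric vector of weights; analytes missing from it
#'   get weight 1.
#' @return List of [response_spec()] objects.
#' @export
default_response_specs <- function(models, grid = default_space_grid(),
                                   fraction = 0.7, weights = default_weights()) {
  stopifnot(fraction > 0, fraction < 1)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  lapply(names(models), function(a) {
    m <- models[[a]]
    eta <- rsm_eta(m, natural_to_coded(m$factors, pts))
    mx <- if (m$transform == "log") exp(max(eta)) else max(eta)
    w <- if (a %in% names(weights)) weights[[a]] else 1
    response_spec(a, fraction * mx, w)
  })
}

#' @rdname default_response_specs
#' @export
default_weights <- function() {
  c("PGE2-d4" = 2, "LXA4-d5" = 2, "LTB4-d4" = 1.5,
    "9-HODE-d4" = 1, "5-HETE-d8" = 1)
}

#' @rdname default_response_specs
#' @export
default_space_grid <- function() {
  list(CID = seq(120, 270, by = 2), IntT = seq(282, 400, by = 2),
       IntV = c(1.8, 2.0, 2.2, 2.5, 3.0, 3.2))
}

#' Disturbance model for the Monte-Carlo simulation
#'
#' Setpoint jitter emulates the instrument not holding a factor exactly at
#' its nominal value; by default the jitter SD is 2 % of each factor's
#' nominal range.  Residual resampling adds the model's residual SD to each
#' draw, propagating model uncertainty about the surface.
#'
#' @param factors Named list of [doe_factor()]s.
#' @param jitter_sd Named numeric vector of jitter SDs in natural units;
#'   default 2 % of `high - low` per factor.
#' @param resample_residual Draw additive residual noise (default TRUE).
#' @export
disturbance_spec <- function(factors, jitter_sd = NULL,
                             resample_residual = TRUE) {
  factors <- stopifnot_factor_list(factors)
  if (is.null(jitter_sd))
    jitter_sd <- vapply(factors, function(f) 0.02 * (f$high - f$low), 0)
  if (any(jitter_sd < 0)) stop("jitter SDs must be >= 0")
  if (is.null(names(jitter_sd))) names(jitter_sd) <- names(factors)
  structure(list(jitter_sd = jitter_sd,
                 resample_residual = isTRUE(resample_residual)),
            class = "disturbance_spec")
}

# Core Monte-Carlo engine.  Setpoint jitter draws are shared across grid
# points (common random numbers: the same jittered offsets are applied to
# every candidate setpoint), which leaves every per-point failure estimate
# unbiased while making the map smooth and cheap to compute: for a quadratic
# surface eta(x + d) = eta(x) + grad(x).d + d'Bd, so the grid x sample matrix
# is one matrix product per analyte.
pfail_grid <- function(models, setpoints, specs, disturbance, n_samples, seed) {
  stopifnot(is.list(models), length(models) >= 1)
  spec_an <- vapply(specs, `[[`, "", "analyte")
  missing <- setdiff(spec_an, names(models))
  if (length(missing))
    stop("no model for spec analyte(s): ", paste(missing, collapse = ", "))
  f0 <- models[[spec_an[1]]]$factors
  nm <- names(f0)
  m <- nrow(setpoints)
  coded <- natural_to_coded(f0, setpoints)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  # jitter in coded units, one column per Monte-Carlo draw, shared by all
  # setpoints and all analytes (the whole panel sees the same instrument)
  D <- matrix(0, length(nm), n_samples, dimnames = list(nm, NULL))
  for (f in nm) {
    sd_nat <- disturbance$jitter_sd[[f]]
    if (is.na(sd_nat)) sd_nat <- 0
    if (sd_nat > 0)
      D[f, ] <- stats::rnorm(n_samples, 0, sd_nat / factor_half_range(f0[[f]]))
  }
  fail_any <- matrix(FALSE, m, n_samples)
  for (s in specs) {
    mod <- models[[s$analyte]]
    if (!identical(names(mod$factors), nm))
      stop("models must share one factor space")
    eta0 <- rsm_eta(mod, coded)                    # m
    G <- rsm_gradient(mod, coded)                  # m x k
    # pure-jitter curvature term d'Bd, identical for every setpoint
    qd <- rep(0, n_samples)
    for (lbl in mod$terms) {
      tm <- parse_term(lbl)
      b <- mod$coefficients[[lbl]]
      if (tm$kind == "quadratic") qd <- qd + b * D[tm$factors, ]^2
      if (tm$kind == "interaction")
        qd <- qd + b * D[tm$factors[1], ] * D[tm$factors[2], ]
    }
    eps <- if (disturbance$resample_residual && mod$sigma > 0)
      stats::rnorm(n_samples, 0, mod$sigma) else rep(0, n_samples)
    eta <- (G %*% D) + outer(eta0, qd + eps, `+`)   # m x n
    # threshold on the modelling scale
    thr <- if (mod$transform == "log") log(s$min_acceptable) else s$min_acceptable
    fail_any <- fail_any | (eta < thr)
  }
  rowMeans(fail_any)
}

#' Probability of failure at one setpoint
#'
#' Fraction of seeded Monte-Carlo draws (setpoint jitter, then model
#' prediction, then an additive residual draw on the modelling scale) in
#' which any analyte's predicted response falls below its
#' `min_acceptable`.
#'
#' @param models Named list of `rsm` models sharing one factor space.
#' @param setpoint Named list / one-row data frame of natural-unit settings.
#' @param specs List of [response_spec()]s.
#' @param disturbance A [disturbance_spec()]; default 2 %-of-range jitter
#'   with residual resampling.
#' @param n_samples Number of Monte-Carlo draws (>= 1000).
#' @param seed Integer seed; fixed seed gives a reproducible estimate.
#' @return Failure probability in `[0, 1]`.
#' @export
pfail_at <- function(models, setpoint, specs,
                     disturbance = disturbance_spec(models[[1]]$factors),
                     n_samples = 20000, seed = 1) {
  if (n_samples < 1000) stop("n_samples must be >= 1000")
  sp <- as.data.frame(setpoint)
  pfail_grid(models, sp, specs, disturbance, n_samples, seed)[1]
}

#' Map the design space over a factor grid
#'
#' Evaluates the failure probability at every point of a (full-crossing)
#' natural-unit grid and identifies the region where it stays below the
#' risk threshold (1 % by default).
#'
#' @param models Named list of `rsm` models.
#' @param grid Named list of natural-unit axis vectors, e.g.
#'   `list(CID = seq(120, 270, 2), IntT = seq(282, 400, 2), IntV = c(1.8, 2))`.
#' @param specs List of [response_spec()]s.
#' @param disturbance A [disturbance_spec()].
#' @param threshold Acceptable failure probability (default 0.01).
#' @param n_samples Monte-Carlo draws per grid point.
#' @param seed Integer seed.
#' @return An object of class `design_space_map`: data frame `map` (grid
#'   columns plus `pfail`), `threshold`, `optimum` (from [select_optimum()]),
#'   `no_design_space` flag, `n_samples`, `seed`.
#' @export
design_space_map <- function(models, grid = default_space_grid(), specs,
                             disturbance = disturbance_spec(models[[1]]$factors),
                             threshold = 0.01, n_samples = 2000, seed = 1) {
  stopifnot(threshold > 0, threshold <= 1)
  f0 <- models[[1]]$factors
  for (f in names(grid)) {
    fac <- f0[[f]]
    if (is.null(fac)) stop("grid axis '", f, "' is not a model factor")
    if (any(grid[[f]] < fac$hard_min - 1e-9 | grid[[f]] > fac$hard_max + 1e-9))
      stop("grid for '", f, "' exceeds its hard bounds")
  }
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)[names(f0)]
  pf <- numeric(nrow(pts))
  chunk <- max(1L, floor(2e6 / n_samples))
  starts <- seq(1L, nrow(pts), by = chunk)
  for (i in starts) {
    j <- min(i + chunk - 1L, nrow(pts))
    pf[i:j] <- pfail_grid(models, pts[i:j, , drop = FALSE], specs,
                          disturbance, n_samples, seed)
  }
  map <- cbind(pts, pfail = pf)
  out <- structure(list(map = map, threshold = threshold,
                        n_samples = n_samples, seed = seed,
                        models = models, specs = specs,
                        no_design_space = !any(pf <= threshold)),
                   class = "design_space_map")
  out$optimum <- select_optimum(out)
  out
}

#' Select the robust optimum from a design-space map
#'
#' Among grid points whose failure probability does not exceed the
#' threshold, maximizes the weighted log-margin score
#' \eqn{\sum_a w_a \log(\hat y_a / min_a)} (deterministic predictions, no
#' jitter).  If no grid point meets the threshold the map's
#' `no_design_space` flag is set and the score argmax over the whole grid is
#' returned.  Ties are broken toward the lowest IntV, then the lowest IntT
#' (gentler source settings), then the first grid point.
#'
#' @param map A `design_space_map`.
#' @param models,specs Override the models/specs stored in the map.
#' @return One-row data frame: factor settings, `pfail`, `score`.
#' @export
select_optimum <- function(map, models = map$models, specs = map$specs) {
  stopifnot(inherits(map, "design_space_map"))
  mp <- map$map
  ok <- mp$pfail <= map$threshold
  if (!any(ok)) ok <- rep(TRUE, nrow(mp))
  nm <- setdiff(names(mp), "pfail")
  score <- rep(0, nrow(mp))
  coded <- natural_to_coded(models[[1]]$factors, mp[nm])
  for (s in specs) {
    mod <- models[[s$analyte]]
    eta <- rsm_eta(mod, coded)
    pred_log <- if (mod$transform == "log") eta else log(pmax(eta, 1e-300))
    score <- score + s$weight * (pred_log - log(s$min_acceptable))
  }
  cand <- which(ok)
  keys <- list(-score[cand])
  if ("IntV" %in% nm) keys <- c(keys, list(mp$IntV[cand]))
  if ("IntT" %in% nm) keys <- c(keys, list(mp$IntT[cand]))
  ord <- cand[do.call(order, keys)]
  best <- ord[1]
  out <- mp[best, , drop = FALSE]
  out$score <- score[best]
  rownames(out) <- NULL
  out
}

#' @export
print.design_space_map <- function(x, ...) {
  nm <- setdiff(names(x$map), "pfail")
  inreg <- sum(x$map$pfail <= x$threshold)
  cat(sprintf("<design space> %d grid points, %d (%.1f%%) below pfail %.2g\n",
              nrow(x$map), inreg, 100 * inreg / nrow(x$map), x$threshold))
  if (x$no_design_space)
    cat("  ** no grid point meets the risk threshold **\n")
  cat("  optimum:", paste(sprintf("%s = %g", nm, unlist(x$optimum[nm])),
                          collapse = ", "),
      sprintf(" (pfail %.4f)\n", x$optimum$pfail))
  invisible(x)
}

#' Export a design-space map as a long-format table
#'
#' @param map A `design_space_map`.
#' @param file Optional CSV path; when omitted the data frame is returned.
#' @export
write_design_space <- function(map, file = NULL) {
  stopifnot(inherits(map, "design_space_map"))
  if (is.null(file)) return(map$map)
  utils::write.csv(map$map, file, row.names = FALSE)
  invisible(file)
}
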