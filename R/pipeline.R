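# End-to-end workflow: screening -> response-surface optimization ->
# Monte-Carlo design space -> collision-energy check -> sensitivity
# evaluation, with all randomness funnelled through one root seed.

#' Select factors from screening fits
#'
#' A factor is carried forward when its main effect is significant (95 % CI
#' excluding zero) for at least `min_analytes` of the panel analytes.
#' Requiring agreement across a majority of the panel keeps isolated
#' single-analyte false positives from dragging an inert source factor into
#' the optimization stage.
#'
#' @param fits Named list of screening `rsm` fits (main-effects models).
#' @param min_analytes Minimum number of analytes for which the effect must
#'   be significant (default 3, a majority of the 5-analyte panel).
#' @return Character vector of selected factor names; attribute
#'   `significance` holds the analyte x factor logical matrix.
#' @export
screen_factors <- function(fits, min_analytes = 3) {
  stopifnot(length(fits) >= 1)
  fnames <- names(fits[[1]]$factors)
  sig <- vapply(fits, function(f) {
    s <- abs(f$coefficients) > f$ci95
    vapply(fnames, function(fn) {
      i <- match(fn, f$terms)
      !is.na(i) && s[i]
    }, TRUE)
  }, logical(length(fnames)))
  sig <- matrix(sig, nrow = length(fnames),
                dimnames = list(fnames, names(fits)))
  selected <- fnames[rowSums(sig) >= min_analytes]
  attr(selected, "significance") <- sig
  selected
}

#' Run the full synthetic optimization pipeline
#'
#' Executes, in order: (1) resolution-IV fractional factorial screening of
#' the seven source/collision factors with majority-vote factor selection;
#' (2) central composite optimization of CID, IntT and IntV with refined
#' log-quadratic models per analyte; (3) Monte-Carlo design-space mapping
#' and weighted optimum selection; (4) the D-optimal CE x CID stage with the
#' one-factor-at-a-time CE scan comparison; (5) calibration-based
#' sensitivity evaluation (pre vs post LOQ and S/N, peak-height/AUC
#' improvements).  Every stage draws its inputs from the seeded synthetic
#' instrument, so the whole report is a pure function of `seed` and the
#' configuration.
#'
#' @param seed Root integer seed; per-stage seeds are derived from it.
#' @param stages Subset of
#'   `c("screening", "optimization", "design_space", "ce", "sensitivity")`.
#'   Later stages that depend on an omitted stage re-derive what they need.
#' @param noise_cv Replicate CV of the synthetic instrument (default 0.04).
#' @param grid Design-space grid (default [default_space_grid()]).
#' @param n_samples Monte-Carlo draws per grid point (default 2000).
#' @param threshold Design-space risk threshold (default 0.01).
#' @param spec_fraction Acceptance fraction of each analyte's predicted
#'   maximum (default 0.7).
#' @param weights Analyte weights (default [default_weights()]).
#' @return Object of class `doe_pipeline` with per-stage results and the
#'   recommended instrument settings.
#' @export
run_doe_pipeline <- function(seed = 1,
                             stages = c("screening", "optimization",
                                        "design_space", "ce", "sensitivity"),
                             noise_cv = 0.04,
                             grid = default_space_grid(),
                             n_samples = 2000, threshold = 0.01,
                             spec_fraction = 0.7,
                             weights = default_weights()) {
  stages <- match.arg(stages, several.ok = TRUE)
  surfaces <- oxylipin_surfaces()
  out <- list(seed = seed, stages = stages)

  if ("screening" %in% stages) {
    sdes <- ffd_design(screening_factors())
    sresp <- simulate_responses(sdes, surfaces, seed = derive_seed(seed, 1),
                                noise_cv = noise_cv)
    sfits <- rsm_fit_all(sdes, sresp,
                         terms = c(linear_terms(names(sdes$factors)),
                                   "curvature"),
                         transform = "log", refine = FALSE)
    selected <- screen_factors(sfits)
    out$screening <- list(design = sdes, fits = sfits, selected = selected)
  }

  need_models <- any(c("optimization", "design_space", "ce") %in% stages)
  if (need_models) {
    odes <- ccd_design(optimization_factors())
    oresp <- simulate_responses(odes, surfaces, seed = derive_seed(seed, 2),
                                noise_cv = noise_cv)
    models <- rsm_fit_all(odes, oresp, transform = "log", refine = TRUE)
    diagnostics <- data.frame(
      analyte = names(models),
      r2 = vapply(models, `[[`, 0, "r2"),
      q2 = vapply(models, `[[`, 0, "q2"),
      reproducibility = vapply(models, `[[`, 0, "reproducibility"),
      lof_p = vapply(models, function(m)
        if (is.null(m$lof)) NA_real_ else m$lof$p, 0),
      row.names = NULL)
    out$optimization <- list(design = odes, responses = oresp,
                             models = models, diagnostics = diagnostics)
  }

  if ("design_space" %in% stages) {
    specs <- default_response_specs(models, grid = grid,
                                    fraction = spec_fraction,
                                    weights = weights)
    map <- design_space_map(models, grid = grid, specs = specs,
                            threshold = threshold, n_samples = n_samples,
                            seed = derive_seed(seed, 3))
    out$design_space <- map
    out$optimum <- map$optimum
  }

  if ("ce" %in% stages) {
    cdes <- d_optimal_design(ce_factors(),
                             terms = quadratic_terms(c("CE", "CID")),
                             n_runs = 14, seed = derive_seed(seed, 4))
    cresp <- simulate_responses(cdes, ce_surfaces(),
                                seed = derive_seed(seed, 5),
                                noise_cv = noise_cv)
    cmodels <- fit_ce_cid_models(cdes, cresp)
    scan_cid <- if (!is.null(out$optimum)) out$optimum$CID else 222
    scans <- ofat_ce_scan(simulate_ofat_scan(seed = derive_seed(seed, 6),
                                             cid = scan_cid,
                                             noise_cv = noise_cv))
    out$ce <- list(design = cdes, models = cmodels,
                   cid_retained = attr(cmodels, "cid_retained"),
                   scans = scans,
                   comparison = compare_ce_optima(cmodels, scans))
  }

  if ("sensitivity" %in% stages) {
    pre <- simulate_calibration("pre", seed = derive_seed(seed, 7))
    post <- simulate_calibration("post", seed = derive_seed(seed, 7))
    cal_pre <- lapply(split(pre, pre$analyte), calibrate_series)
    cal_post <- lapply(split(post, post$analyte), calibrate_series)
    mc <- simulate_method_comparison(seed = derive_seed(seed, 8))
    out$sensitivity <- list(
      calibration_pre = cal_pre, calibration_post = cal_post,
      comparison = compare_methods(cal_pre, cal_post),
      improvements = improvement_metrics(mc$pre, mc$post))
  }

  structure(out, class = "doe_pipeline")
}

#' @export
print.doe_pipeline <- function(x, ...) {
  cat("<doe pipeline> seed", x$seed, "\n")
  if (!is.null(x$screening))
    cat("  screening: selected", paste(x$screening$selected, collapse = ", "), "\n")
  if (!is.null(x$optimization)) {
    d <- x$optimization$diagnostics
    cat(sprintf("  models: min R2 %.3f, min Q2 %.3f, min repro %.3f\n",
                min(d$r2), min(d$q2), min(d$reproducibility)))
  }
  if (!is.null(x$optimum))
    cat(sprintf("  recommended settings: CID %g kPa, IntT %g degC, IntV %g kV (pfail %.4f)\n",
                x$optimum$CID, x$optimum$IntT, x$optimum$IntV,
                x$optimum$pfail))
  if (!is.null(x$ce))
    cat(sprintf("  CE check: %d/%d scan optima inside predicted region\n",
                sum(x$ce$comparison$inside_region), nrow(x$ce$comparison)))
  if (!is.null(x$sensitivity)) {
    mc <- x$sensitivity$comparison
    cat(sprintf("  sensitivity: %d/%d analytes improved LOQ, %d/%d improved S/N\n",
                mc$n_loq_improved, mc$n_analytes,
                mc$n_sn_improved, mc$n_analytes))
  }
  invisible(x)
}
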