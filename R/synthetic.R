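# Synthetic instrument: seeded generators for every input the pipeline
# consumes -- screening/CCD/D-optimal response tables, OFAT collision-energy
# scans, dilution series -- from committed ground-truth response surfaces.
#
# Responses follow a log-quadratic form H(x) = H0 * exp(f(x)) on coded
# factors (multiplicative effects, matching the percent-improvement way
# instrument gains are reported), with multiplicative lognormal replicate
# noise of 4 % CV by default.

#' Ground-truth response surfaces of the five-analyte optimization panel
#'
#' Returns the committed per-analyte log-quadratic surfaces over CID gas
#' pressure, interface temperature and interface voltage (coded in the
#' optimization frame: CID 140-250 kPa, IntT 300-400 degC, IntV 2-3 kV)
#' plus near-zero linear effects for the four inert source factors (HG, DG,
#' HB, DL, coded in the screening frame).  The coefficient table is
#' calibrated so that, by direct evaluation: the analyte-average peak-height
#' gain for CID 140 to 250 kPa at IntT 400 degC is 51 %; the average gain
#' for IntT 300 to 400 degC at CID 250 kPa is 32 %; the weighted
#' (prostaglandin/lipoxin-prioritized) joint optimum sits at 222 kPa,
#' 380 degC and 2 kV; and the per-analyte marginal optima follow the
#' analyte-specific pattern (PGE2-d4 peaking near 230 kPa and 377 degC,
#' 5-HETE-d8 near 200 kPa with a temperature plateau above 390 degC,
#' a positive IntT x CID interaction only for LTB4-d4 and 9-HODE-d4, and a
#' positive IntT x IntV interaction only for LXA4-d5).
#'
#' @return A `surface_set`: coding frames plus per-analyte coefficients,
#'   baseline heights and chromatographic peak-width factors.
#' @export
oxylipin_surfaces <- function() {
  tab <- utils::read.csv(extdata_file("ground_truth_surfaces.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  frames <- c(optimization_factors(),
              screening_factors()[c("HG", "DG", "HB", "DL")])
  surfaces <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    coef <- c("CID" = r$b_CID, "IntT" = r$b_IntT, "IntV" = r$b_IntV,
              "CID^2" = r$b_CID2, "IntT^2" = r$b_IntT2, "IntV^2" = r$b_IntV2,
              "CID:IntT" = r$b_CID_IntT, "IntT:IntV" = r$b_IntT_IntV,
              "HG" = r$b_HG, "DG" = r$b_DG, "HB" = r$b_HB, "DL" = r$b_DL)
    list(analyte = r$analyte, H0 = r$H0, width = r$width,
         coef = coef[coef != 0 | names(coef) %in% c("CID", "IntT", "IntV")])
  })
  names(surfaces) <- tab$analyte
  structure(list(frames = frames, surfaces = surfaces),
            class = "surface_set")
}

#' Ground-truth collision-energy surfaces
#'
#' Log-quadratic surfaces over collision energy (12-28 eV) and CID gas
#' pressure (190-250 kPa).  Each analyte has an interior CE optimum on the
#' even-eV grid (16-24 eV depending on the analyte) with curvature chosen so
#' a 2 eV step off the optimum loses 7-15 % of peak height; only LXA4-d5 and
#' 5-HETE-d8 carry small CID terms.
#'
#' @return A `surface_set` over the CE/CID frame.
#' @export
ce_surfaces <- function() {
  tab <- utils::read.csv(extdata_file("ce_ground_truth.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  frames <- ce_factors()
  surfaces <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    coef <- c("CE" = r$a_CE, "CE^2" = r$a_CE2,
              "CID" = r$a_CID, "CID^2" = r$a_CID2)
    list(analyte = r$analyte, H0 = r$H0, width = r$width,
         coef = coef[coef != 0 | names(coef) == "CE"])
  })
  names(surfaces) <- tab$analyte
  structure(list(frames = frames, surfaces = surfaces),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface set> %d analytes over factors %s\n",
              length(x$surfaces), paste(names(x$frames), collapse = ", ")))
  invisible(x)
}

# log-scale ground truth f(x) for one surface at natural-unit settings;
# factors absent from `natural` sit at their frame centre (coded 0)
surface_eta <- function(set, surface, natural) {
  natural <- as.data.frame(natural)
  n <- nrow(natural)
  used <- unique(unlist(lapply(names(surface$coef), function(lbl)
    parse_term(lbl)$factors)))
  coded <- matrix(0, n, length(used), dimnames = list(NULL, used))
  for (f in used) {
    if (f %in% names(natural))
      coded[, f] <- code_level(set$frames[[f]], natural[[f]])
  }
  X <- build_model_matrix(coded, names(surface$coef))
  drop(X %*% c(0, surface$coef))   # leading 0: intercept added by parser
}

#' Simulate replicate responses for a design
#'
#' Evaluates each ground-truth surface at the design's natural settings and
#' adds seeded multiplicative lognormal noise per replicate:
#' `H_obs = H0 * exp(f(x)) * exp(e)`, `e ~ N(0, noise_cv)`.  AUC is height
#' times the analyte's fixed peak-width factor.  Output is byte-identical
#' for a fixed seed.
#'
#' @param design A `doe_design`.
#' @param surfaces A `surface_set` (default [oxylipin_surfaces()]).
#' @param seed Integer seed.
#' @param noise_cv Replicate coefficient of variation (log-scale SD),
#'   default 0.04.
#' @param n_replicates Replicates per run; default the design's setting.
#' @return Data frame `run_id`, `replicate`, `analyte`, `height`, `auc`.
#' @export
simulate_responses <- function(design, surfaces = oxylipin_surfaces(),
                               seed = 1, noise_cv = 0.04,
                               n_replicates = design$n_replicates) {
  stopifnot(inherits(design, "doe_design"), inherits(surfaces, "surface_set"))
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  unknown <- setdiff(names(design$factors), names(surfaces$frames))
  if (length(unknown))
    stop("design factor(s) unknown to the surface set: ",
         paste(unknown, collapse = ", "))
  nat <- design$runs[names(design$factors)]
  with_seed(seed, {
    out <- lapply(names(surfaces$surfaces), function(a) {
      s <- surfaces$surfaces[[a]]
      mu <- s$H0 * exp(surface_eta(surfaces, s, nat))
      reps <- lapply(seq_len(n_replicates), function(r) {
        e <- if (noise_cv > 0) stats::rnorm(length(mu), 0, noise_cv) else 0
        h <- mu * exp(e)
        data.frame(run_id = design$runs$run_id, replicate = r,
                   analyte = a, height = h, auc = h * s$width)
      })
      do.call(rbind, reps)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out[order(out$run_id, out$replicate), c("run_id", "replicate",
                                            "analyte", "height", "auc")]
  })
}

#' Simulate the one-factor-at-a-time collision-energy scan
#'
#' Duplicate measurements on the even-eV grid at a fixed CID pressure,
#' drawn from the committed CE surfaces.
#'
#' @param seed Integer seed.
#' @param cid Fixed CID gas pressure in kPa (default 222).
#' @param ce_values CE grid in eV (default 12-28 in 2 eV steps).
#' @param noise_cv Replicate CV (default 0.04).
#' @param surfaces A `surface_set` (default [ce_surfaces()]).
#' @return Data frame `analyte`, `ce_ev`, `cid_kpa`, `replicate`, `response`.
#' @export
simulate_ofat_scan <- function(seed = 1, cid = 222,
                               ce_values = seq(12, 28, by = 2),
                               noise_cv = 0.04, surfaces = ce_surfaces()) {
  with_seed(seed, {
    out <- lapply(names(surfaces$surfaces), function(a) {
      s <- surfaces$surfaces[[a]]
      nat <- data.frame(CE = ce_values, CID = cid)
      mu <- s$H0 * exp(surface_eta(surfaces, s, nat))
      do.call(rbind, lapply(1:2, function(r) {
        e <- if (noise_cv > 0) stats::rnorm(length(mu), 0, noise_cv) else 0
        data.frame(analyte = a, ce_ev = ce_values, cid_kpa = cid,
                   replicate = r, response = mu * exp(e))
      }))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Per-analyte calibration anchors for the 14-oxylipin panel
#'
#' The committed table anchoring the calibration generator: printed pre/post
#' S/N at the pre-optimization LOQ, printed LOQs, post/pre response gain
#' factors (heights 1.66-2.15, AUC 1.30-1.66), and the per-analyte
#' half-suppression amount `suppress_k` (pg) of the cooperative low-level
#' signal loss (adsorption to surfaces at trace amounts).
#'
#' @return Data frame, one row per analyte.
#' @export
calibration_anchors <- function() {
  utils::read.csv(extdata_file("calibration_anchors.csv"),
                  stringsAsFactors = FALSE)
}

#' Nominal amounts of the dilution series
#'
#' Ten 2-fold dilutions injected at 10 uL: 31.25 pg on column halving down
#' to 0.061 pg (3.125 ng/mL to 6.1 pg/mL).
#'
#' @export
calibration_levels <- function() 31.25 / 2^(0:9)

#' Simulate calibration dilution series for the 14-analyte panel
#'
#' Signal is proportional to amount with a saturable low-level suppression
#' `s(L) = L^2 / (L^2 + K^2)` (cooperative adsorptive loss; K is
#' `suppress_k` from [calibration_anchors()]), scaled so the S/N at the printed
#' pre-optimization LOQ level matches the anchor table.  The baseline noise
#' SD is independent of amount; replicate peak heights carry a small
#' proportional error (2 % CV) plus an absolute error of 0.2 x the baseline
#' noise SD (peak apex estimates average over many scans and are steadier
#' than the raw baseline).  Post-optimization series apply the per-analyte
#' height gain and the reduced baseline noise implied by the anchored S/N
#' ratios.
#'
#' @param settings `"pre"` or `"post"`.
#' @param seed Integer seed.
#' @param analytes Subset of panel analytes (default: all 14).
#' @return Data frame `analyte`, `level_pg`, `replicate`, `height`, `auc`,
#'   `noise_sd`.
#' @export
simulate_calibration <- function(settings = c("pre", "post"), seed = 1,
                                 analytes = NULL) {
  settings <- match.arg(settings)
  anch <- calibration_anchors()
  if (!is.null(analytes)) {
    bad <- setdiff(analytes, anch$analyte)
    if (length(bad)) stop("unknown analyte(s): ", paste(bad, collapse = ", "))
    anch <- anch[anch$analyte %in% analytes, , drop = FALSE]
  }
  lv <- calibration_levels()
  printed_to_level <- function(p) lv[which.min(abs(lv - p))]
  with_seed(derive_seed(seed, if (settings == "pre") 71 else 72), {
    out <- lapply(seq_len(nrow(anch)), function(i) {
      a <- anch[i, ]
      noise_pre <- 1
      L_loq <- printed_to_level(a$loq_pre_printed)
      sup <- function(L) L^2 / (L^2 + a$suppress_k^2)
      slope_pre <- a$sn_pre * noise_pre / (sup(L_loq) * L_loq)
      if (settings == "pre") {
        slope <- slope_pre; noise <- noise_pre
      } else {
        slope <- slope_pre * a$gain_height
        noise <- noise_pre * a$gain_height * a$sn_pre / a$sn_post
      }
      mu <- slope * sup(lv) * lv
      do.call(rbind, lapply(1:2, function(r) {
        h <- mu * (1 + stats::rnorm(length(mu), 0, 0.02)) +
          stats::rnorm(length(mu), 0, 0.2 * noise)
        data.frame(analyte = a$analyte, level_pg = lv, replicate = r,
                   height = pmax(h, 1e-6), auc = pmax(h, 1e-6) * 7,
                   noise_sd = noise)
      }))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the triplicate pre/post method-comparison measurement
#'
#' Peak heights and AUCs of the five deuterated standards under standard
#' conditions (3 kV, 300 degC, 270 kPa) and under the optimized method, with
#' per-analyte gain factors anchored inside the observed improvement ranges
#' (peak height +65 to +118 %, AUC +27 to +68 %).
#'
#' @param seed Integer seed.
#' @param n_replicates Measurements per condition (default 3).
#' @param noise_cv Replicate CV (default 0.04).
#' @return List with data frames `pre` and `post` (`analyte`, `replicate`,
#'   `height`, `auc`).
#' @export
simulate_method_comparison <- function(seed = 1, n_replicates = 3,
                                       noise_cv = 0.04) {
  set <- oxylipin_surfaces()
  gains_h <- c("PGE2-d4" = 2.02, "LXA4-d5" = 1.95, "LTB4-d4" = 1.88,
               "9-HODE-d4" = 1.80, "5-HETE-d8" = 1.75)
  gains_a <- c("PGE2-d4" = 1.56, "LXA4-d5" = 1.50, "LTB4-d4" = 1.45,
               "9-HODE-d4" = 1.40, "5-HETE-d8" = 1.36)
  std <- data.frame(CID = 270, IntT = 300, IntV = 3)
  with_seed(derive_seed(seed, 73), {
    one <- function(gain_h, gain_a) {
      rows <- lapply(names(set$surfaces), function(a) {
        s <- set$surfaces[[a]]
        h0 <- s$H0 * exp(surface_eta(set, s, std))
        e <- stats::rnorm(n_replicates, 0, noise_cv)
        h <- h0 * gain_h[[a]] * exp(e)
        u <- h0 * s$width * gain_a[[a]] * exp(e + stats::rnorm(n_replicates, 0, 0.01))
        data.frame(analyte = a, replicate = seq_len(n_replicates),
                   height = h, auc = u)
      })
      do.call(rbind, rows)
    }
    ones <- rep(1, length(set$surfaces))
    names(ones) <- names(set$surfaces)
    pre <- one(ones, ones)
    post <- one(gains_h, gains_a)
    rownames(pre) <- rownames(post) <- NULL
    list(pre = pre, post = post)
  })
}
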