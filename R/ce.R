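# Collision-energy refinement: CE x CID response-surface models on the
# multilevel D-optimal design, and the one-factor-at-a-time CE scan used to
# validate the predicted optima.

#' Fit per-analyte CE x CID response-surface models
#'
#' Full quadratic models in collision energy and CID gas pressure, fitted on
#' the D-optimal design and backward-refined; reports per analyte whether
#' any CID term survives refinement.
#'
#' @param design A `doe_design` over the CE/CID factors (see [ce_factors()]).
#' @param responses Replicate-level response table (`run_id`, `replicate`,
#'   `analyte`, `height`).
#' @param transform Response transform passed to [rsm_fit()] (default log).
#' @param alpha Significance level for refinement.
#' @return Named list of refined `rsm` models with attribute
#'   `cid_retained` (named logical).
#' @export
fit_ce_cid_models <- function(design, responses, transform = "log",
                              alpha = 0.05) {
  fits <- rsm_fit_all(design, responses,
                      terms = quadratic_terms(names(design$factors)),
                      transform = transform, refine = TRUE, alpha = alpha)
  cid_ret <- vapply(fits, function(f)
    any(vapply(f$terms, function(lbl) "CID" %in% parse_term(lbl)$factors, TRUE)),
    TRUE)
  attr(fits, "cid_retained") <- cid_ret
  fits
}

#' One-factor-at-a-time collision-energy scan
#'
#' Averages duplicate responses at each CE step (CID held fixed) and
#' normalizes to the maximum = 100 %.
#'
#' @param responses Data frame with columns `analyte`, `ce_ev`, `cid_kpa`,
#'   `replicate`, `response`.
#' @return Named list of `ce_scan` objects, one per analyte, each with
#'   `ce_values`, `cid`, `normalized_response` (max = 100) and `mean_response`.
#' @export
ofat_ce_scan <- function(responses) {
  need <- c("analyte", "ce_ev", "cid_kpa", "replicate", "response")
  if (!all(need %in% names(responses)))
    stop("scan table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(responses, responses$analyte), function(d) {
    mn <- tapply(d$response, d$ce_ev, mean)
    ce <- as.numeric(names(mn))
    o <- order(ce); ce <- ce[o]; mn <- as.numeric(mn)[o]
    if (all(mn == 0)) stop("degenerate scan: all responses zero for ",
                           d$analyte[1])
    structure(list(analyte = d$analyte[1], ce_values = ce,
                   cid = unique(d$cid_kpa)[1],
                   mean_response = mn,
                   normalized_response = 100 * mn / max(mn)),
              class = "ce_scan")
  })
  out
}

#' @export
print.ce_scan <- function(x, ...) {
  i <- which.max(x$normalized_response)
  cat(sprintf("<CE scan> %s at CID %g kPa: optimum %g eV (100%%)\n",
              x$analyte, x$cid, x$ce_values[i]))
  invisible(x)
}

#' Compare RSM-predicted and scan-measured collision-energy optima
#'
#' For each analyte: the model-predicted optimal CE region (CE values whose
#' predicted response at the scan's CID reaches at least `region_fraction`
#' of the model maximum), the scan argmax (ties resolved toward the lower
#' CE and flagged), the deviation between the two optima in eV, and an
#' inside/outside verdict.
#'
#' @param models Named list of CE x CID `rsm` models.
#' @param scans Named list of `ce_scan`s (see [ofat_ce_scan()]).
#' @param tolerance_ev Allowed |deviation| for the `within_tolerance` column.
#' @param region_fraction Fraction of the model maximum that defines the
#'   optimal region (default 0.95).
#' @return Data frame, one row per analyte.
#' @export
compare_ce_optima <- function(models, scans, tolerance_ev = 2,
                              region_fraction = 0.95) {
  analytes <- intersect(names(models), names(scans))
  if (!length(analytes)) stop("no common analytes between models and scans")
  rows <- lapply(analytes, function(a) {
    m <- models[[a]]; s <- scans[[a]]
    grid <- data.frame(CE = s$ce_values, CID = s$cid)
    pred <- rsm_eta(m, natural_to_coded(m$factors, grid))
    if (m$transform == "log") pred <- exp(pred)
    region <- s$ce_values[pred >= region_fraction * max(pred)]
    model_opt <- s$ce_values[which.max(pred)]
    mx <- max(s$normalized_response)
    hits <- which(s$normalized_response == mx)
    scan_opt <- s$ce_values[min(hits)]
    data.frame(analyte = a, model_ce_opt = model_opt,
               region_lo = min(region), region_hi = max(region),
               scan_ce_opt = scan_opt, tie = length(hits) > 1,
               deviation_ev = scan_opt - model_opt,
               inside_region = scan_opt >= min(region) & scan_opt <= max(region),
               within_tolerance = abs(scan_opt - model_opt) <= tolerance_ev)
  })
  do.call(rbind, rows)
}
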