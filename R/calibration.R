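# Calibration, signal-to-noise and limit-of-quantification evaluation, and
# the pre/post-optimization method comparison.

#' 1/x-weighted linear calibration fit
#'
#' Weighted least squares \eqn{\sum w_i (y_i - a - b x_i)^2} with
#' \eqn{w_i = 1/x_i} (the weighting conventional for bioanalytical
#' calibration, equalizing relative influence across a wide dynamic range).
#'
#' @param x Nominal amounts (pg on column), strictly positive.
#' @param y Responses (peak heights).
#' @param weighting `"1/x"` (default) or `"none"`.
#' @return List with `slope`, `intercept`, `weights`, `residuals`.
#' @export
weighted_linear_fit <- function(x, y, weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  if (length(unique(x)) < 3)
    stop("insufficient data: need at least 3 distinct calibration levels")
  if (weighting == "1/x" && any(x <= 0)) stop("1/x weighting requires x > 0")
  w <- if (weighting == "1/x") 1 / x else rep(1, length(x))
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), weights = w,
       residuals = unname(stats::residuals(fit)), lm = fit)
}

#' Signal-to-noise ratio
#'
#' Peak height divided by the baseline noise SD.  Vendor software often uses
#' a peak-to-peak noise estimate instead, which differs by a roughly
#' constant factor; `multiplier` rescales to such a convention if needed.
#'
#' @param height Peak height(s).
#' @param noise_sd Baseline noise SD (> 0), same detector units.
#' @param multiplier Convention factor (default 1).
#' @export
snr <- function(height, noise_sd, multiplier = 1) {
  if (any(noise_sd <= 0) || any(!is.finite(noise_sd)))
    stop("noise_sd must be > 0")
  multiplier * height / noise_sd
}

#' Evaluate a calibration dilution series
#'
#' Fits the 1/x-weighted line to replicate-level data, computes per-level
#' back-calculated accuracy (from the mean response at each level) and
#' signal-to-noise, and determines the limit of quantification.
#'
#' @param series Data frame with columns `analyte`, `level_pg`, `replicate`,
#'   `height`, `noise_sd` (and optionally `auc`).
#' @param sn_threshold Minimum S/N at the LOQ level (default 5; the boundary
#'   counts as passing).
#' @param accuracy_limits Acceptable back-calculated accuracy window in
#'   percent (default `c(80, 120)`).
#' @return Object of class `calibration_result`: the fit, a per-level table
#'   (`level_pg`, `mean_height`, `accuracy`, `sn`, `pass_accuracy`,
#'   `pass_sn`), and `loq` (NA if no level qualifies).
#' @export
calibrate_series <- function(series, sn_threshold = 5,
                             accuracy_limits = c(80, 120)) {
  need <- c("analyte", "level_pg", "replicate", "height", "noise_sd")
  if (!all(need %in% names(series)))
    stop("series needs columns: ", paste(need, collapse = ", "))
  if (any(series$level_pg <= 0)) stop("amounts must be > 0")
  fit <- weighted_linear_fit(series$level_pg, series$height)
  lv <- sort(unique(series$level_pg), decreasing = TRUE)
  mh <- vapply(lv, function(L) mean(series$height[series$level_pg == L]), 0)
  ns <- vapply(lv, function(L) mean(series$noise_sd[series$level_pg == L]), 0)
  back <- (mh - fit$intercept) / fit$slope
  accuracy <- 100 * back / lv
  sn_val <- snr(mh, ns)
  tab <- data.frame(level_pg = lv, mean_height = mh, accuracy = accuracy,
                    sn = sn_val,
                    pass_accuracy = accuracy >= accuracy_limits[1] &
                      accuracy <= accuracy_limits[2],
                    pass_sn = sn_val >= sn_threshold)
  structure(list(analyte = series$analyte[1], fit = fit, levels = tab,
                 loq = determine_loq(tab),
                 sn_threshold = sn_threshold,
                 accuracy_limits = accuracy_limits),
            class = "calibration_result")
}

#' Determine the limit of quantification from a per-level table
#'
#' The LOQ is the lowest level L such that every level from L upward passes
#' the back-calculated accuracy window and level L itself passes the S/N
#' threshold.  Requiring accuracy at all higher levels too keeps the
#' quantifiable range contiguous.
#'
#' @param levels Data frame with columns `level_pg` (descending),
#'   `pass_accuracy`, `pass_sn` (as built by [calibrate_series()]).
#' @return LOQ in pg on column, or `NA` if no level qualifies.
#' @export
determine_loq <- function(levels) {
  stopifnot(all(c("level_pg", "pass_accuracy", "pass_sn") %in% names(levels)))
  lv <- levels[order(-levels$level_pg), ]
  acc_ok_down <- cumprod(lv$pass_accuracy) > 0   # all levels >= L pass accuracy
  ok <- acc_ok_down & lv$pass_sn
  if (!any(ok)) return(NA_real_)
  min(lv$level_pg[ok])
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration> %s: slope %.4g, intercept %.4g, LOQ %s pg\n",
              x$analyte, x$fit$slope, x$fit$intercept,
              ifelse(is.na(x$loq), "not reached", format(x$loq, digits = 3))))
  invisible(x)
}

#' Compare pre- and post-optimization methods
#'
#' Either pass two named lists of [calibrate_series()] results (per-analyte
#' LOQs are compared and S/N is read at each analyte's pre-optimization LOQ
#' level under both methods), or a single summary data frame with columns
#' `analyte`, `loq_pre`, `loq_post`, `sn_pre`, `sn_post` (e.g. a transcribed
#' published comparison table).  An analyte improves its LOQ when the
#' post value is strictly lower, and its S/N when the post value is strictly
#' higher.
#'
#' @param pre Named list of `calibration_result`s, or the summary data frame.
#' @param post Named list of `calibration_result`s (omit for the data-frame
#'   form).
#' @return Object of class `method_comparison`: per-analyte `table`,
#'   `n_loq_improved`, `n_sn_improved`, `n_analytes`.
#' @export
compare_methods <- function(pre, post = NULL) {
  if (is.data.frame(pre)) {
    need <- c("analyte", "loq_pre", "loq_post", "sn_pre", "sn_post")
    if (!all(need %in% names(pre)))
      stop("comparison table needs columns: ", paste(need, collapse = ", "))
    tab <- pre[need]
  } else {
    if (is.null(post)) stop("pass 'post' results")
    analytes <- names(pre)
    if (!setequal(analytes, names(post)))
      stop("analyte sets of pre and post differ")
    rows <- lapply(analytes, function(a) {
      p <- pre[[a]]; q <- post[[a]]
      sn_at <- function(res, level) {
        i <- which(abs(res$levels$level_pg - level) < 1e-9)
        if (!length(i)) NA_real_ else res$levels$sn[i]
      }
      data.frame(analyte = a, loq_pre = p$loq, loq_post = q$loq,
                 sn_pre = sn_at(p, p$loq), sn_post = sn_at(q, p$loq))
    })
    tab <- do.call(rbind, rows)
  }
  loq_improved <- !is.na(tab$loq_post) &
    (is.na(tab$loq_pre) | tab$loq_post < tab$loq_pre)
  sn_improved <- !is.na(tab$sn_post) & !is.na(tab$sn_pre) &
    tab$sn_post > tab$sn_pre
  tab$loq_improved <- loq_improved
  tab$sn_improved <- sn_improved
  structure(list(table = tab,
                 n_loq_improved = sum(loq_improved),
                 n_sn_improved = sum(sn_improved),
                 n_analytes = nrow(tab)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method comparison> %d analytes: %d improved LOQ, %d improved S/N\n",
              x$n_analytes, x$n_loq_improved, x$n_sn_improved))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Published LOQ / S/N comparison table for the 14-oxylipin panel
#'
#' Transcription of the printed pre/post-optimization comparison (LOQ in pg
#' on column; S/N at the pre-optimization LOQ level) shipped with the
#' package as a plain-text fixture.
#'
#' @return Data frame with columns `analyte`, `loq_pre`, `loq_post`,
#'   `sn_pre`, `sn_post`.
#' @export
read_loq_comparison <- function() {
  f <- system.file("extdata", "loq_sn_comparison.csv", package = "ionopt",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Percent change in mean peak height and AUC between two methods
#'
#' `100 * (post/pre - 1)` per analyte, with the standard error of the ratio
#' propagated from the replicate SDs (delta method), giving an approximate
#' 95 % confidence interval for the percent change.
#'
#' @param pre,post Data frames with columns `analyte`, `replicate`,
#'   `height`, `auc` (>= 3 replicates per analyte recommended).
#' @return Data frame per analyte: `height_change_pct`, `height_ci_lo/hi`,
#'   `auc_change_pct`, `auc_ci_lo/hi`.
#' @export
improvement_metrics <- function(pre, post) {
  analytes <- intersect(unique(pre$analyte), unique(post$analyte))
  if (!length(analytes)) stop("no common analytes")
  one <- function(a, col) {
    x <- pre[[col]][pre$analyte == a]; y <- post[[col]][post$analyte == a]
    mx <- mean(x); my <- mean(y)
    if (mx <= 0 || my <= 0) stop("nonpositive mean response for ", a)
    r <- my / mx
    se_r <- r * sqrt(stats::var(y) / length(y) / my^2 +
                     stats::var(x) / length(x) / mx^2)
    c(change = 100 * (r - 1), lo = 100 * (r - 1.96 * se_r - 1),
      hi = 100 * (r + 1.96 * se_r - 1))
  }
  rows <- lapply(analytes, function(a) {
    h <- one(a, "height"); u <- one(a, "auc")
    data.frame(analyte = a,
               height_change_pct = h["change"], height_ci_lo = h["lo"],
               height_ci_hi = h["hi"],
               auc_change_pct = u["change"], auc_ci_lo = u["lo"],
               auc_ci_hi = u["hi"], row.names = NULL)
  })
  do.call(rbind, rows)
}
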