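# Quadratic response-surface models in coded units, with the diagnostics
# conventionally reported for instrument-optimization designs: R2, PRESS-
# based Q2, replicate reproducibility and the pure-error lack-of-fit test.

#' Fit a quadratic response-surface model to a designed experiment
#'
#' Ordinary least squares on the coded model matrix, fitted to
#' replicate-level data (not replicate means) so that pure error remains
#' estimable.  Significance of a term is judged by its 95 % confidence
#' interval excluding zero, mirroring the coefficient-plot reading used in
#' instrument optimization software.
#'
#' @param design A `doe_design`.
#' @param responses Data frame with columns `run_id`, `replicate`, `analyte`
#'   and the response column (default `height`).
#' @param analyte Which analyte to fit (default: the only one present).
#' @param terms Character vector of model term labels; default the full
#'   quadratic model in the design factors (see [quadratic_terms()]).
#' @param transform `"identity"` or `"log"`; with `"log"` the model is fitted
#'   to `log(response)` and predictions are back-transformed.
#' @param response Name of the response column.
#' @return An object of class `rsm`: coefficients, 95 % CI half-widths,
#'   residual SD, `r2`, `q2`, `reproducibility`, lack-of-fit test, and the
#'   data needed to refit (used by [refine_rsm()]).
#' @seealso [refine_rsm()], [q2_press()], [lack_of_fit()], [reproducibility()]
#' @export
rsm_fit <- function(design, responses, analyte = NULL,
                    terms = quadratic_terms(names(design$factors)),
                    transform = c("identity", "log"), response = "height") {
  stopifnot(inherits(design, "doe_design"), is.data.frame(responses))
  transform <- match.arg(transform)
  if (is.null(analyte)) {
    analyte <- unique(responses$analyte)
    if (length(analyte) != 1L)
      stop("several analytes present; pass 'analyte' explicitly")
  }
  dat <- responses[responses$analyte == analyte, , drop = FALSE]
  if (!nrow(dat)) stop("no responses for analyte '", analyte, "'")
  idx <- match(dat$run_id, design$runs$run_id)
  if (anyNA(idx)) stop("responses reference run_ids absent from the design")
  y <- dat[[response]]
  if (any(!is.finite(y))) stop("non-finite responses")
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires strictly positive responses")
    y <- log(y)
  }
  Xfull <- build_model_matrix(design, terms)
  X <- Xfull[idx, , drop = FALSE]
  fit_rsm_matrix(X, y, run_id = dat$run_id, analyte = analyte,
                 factors = design$factors, transform = transform,
                 design = design, response = response)
}

fit_rsm_matrix <- function(X, y, run_id, analyte, factors, transform,
                           design = NULL, response = "height") {
  n <- nrow(X); p <- ncol(X)
  if (n < p) stop("fewer observations (", n, ") than model terms (", p, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    groups <- aliased_groups(dropped, colnames(X), design)
    stop(structure(class = c("ionopt_aliased_error", "error", "condition"),
                   list(message = paste0(
                     "model matrix is rank deficient; confounded terms: ",
                     paste(vapply(groups, paste, "", collapse = " = "),
                           collapse = "; ")),
                     call = sys.call(-1), aliased = groups)))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df_res <- n - p
  ss_res <- sum(res^2)
  sigma <- if (df_res > 0) sqrt(ss_res / df_res) else 0
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  se <- sigma * sqrt(diag(XtXinv))
  tcrit <- if (df_res > 0) stats::qt(0.975, df_res) else Inf
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  obj <- structure(list(
    analyte = analyte, terms = colnames(X), coefficients = beta,
    se = se, ci95 = tcrit * se, sigma = sigma, df_residual = df_res,
    r2 = r2, transform = transform, factors = factors,
    X = X, y = y, run_id = run_id, fitted = fitted, residuals = res,
    vcov_unscaled = XtXinv, design = design, response = response,
    refined = FALSE), class = "rsm")
  obj$q2 <- tryCatch(q2_press(obj), error = function(e) NA_real_)
  obj$reproducibility <- tryCatch(reproducibility(obj), error = function(e) NA_real_)
  obj$lof <- tryCatch(lack_of_fit(obj), error = function(e) NULL)
  obj
}

# group the dropped (rank-deficient) columns with the requested terms they
# are confounded with, using the design's alias structure when available
aliased_groups <- function(dropped, requested, design) {
  if (is.null(design) || is.null(design$alias) ||
      !length(design$alias$defining_words))
    return(as.list(dropped))
  fnames <- names(design$factors)
  to_letters <- function(lbl) {
    tm <- parse_term(lbl)
    if (tm$kind %in% c("intercept")) return(NULL)
    paste(sort(LETTERS[match(tm$factors, fnames)]), collapse = "")
  }
  lapply(dropped, function(d) {
    dl <- to_letters(d)
    if (is.null(dl)) return(d)
    al <- aliases_of(design$alias, dl, max_order = 2L)
    al_names <- vapply(al, effect_to_names, "", fnames)
    sort(unique(c(d, intersect(requested, c(al_names,
      # interactions may be listed with factors in either order
      vapply(strsplit(al_names, ":"), function(x)
        paste(rev(x), collapse = ":"), ""))))))
  })
}

#' @export
coef.rsm <- function(object, ...) object$coefficients

#' @export
residuals.rsm <- function(object, ...) object$residuals

#' @export
print.rsm <- function(x, ...) {
  cat(sprintf("<rsm> %s (%s response, %s scale)%s\n", x$analyte, x$response,
              x$transform, if (isTRUE(x$refined)) ", refined" else ""))
  cat(sprintf("  %d terms, %d observations | R2 %.3f  Q2 %.3f  repro %.3f",
              length(x$terms), length(x$y), x$r2,
              ifelse(is.na(x$q2), NaN, x$q2),
              ifelse(is.na(x$reproducibility), NaN, x$reproducibility)))
  if (!is.null(x$lof)) cat(sprintf("  lack-of-fit p %.3f", x$lof$p))
  cat("\n")
  invisible(x)
}

#' @export
summary.rsm <- function(object, ...) {
  tab <- data.frame(term = object$terms, estimate = object$coefficients,
                    se = object$se, ci95 = object$ci95,
                    significant = abs(object$coefficients) > object$ci95,
                    row.names = NULL)
  out <- list(analyte = object$analyte, table = tab, r2 = object$r2,
              q2 = object$q2, reproducibility = object$reproducibility,
              lof = object$lof, sigma = object$sigma,
              transform = object$transform)
  class(out) <- "summary.rsm"
  out
}

#' @export
print.summary.rsm <- function(x, ...) {
  cat("Response-surface model for", x$analyte, "\n")
  print(x$table, digits = 4)
  cat(sprintf("R2 %.4f | Q2 %.4f | reproducibility %.4f | residual SD %.4g\n",
              x$r2, x$q2, x$reproducibility, x$sigma))
  if (!is.null(x$lof))
    cat(sprintf("lack of fit: F = %.3f on (%d, %d) df, p = %.4f\n",
                x$lof$F, x$lof$df_lof, x$lof$df_pe, x$lof$p))
  invisible(x)
}

#' PRESS-based predictability Q2
#'
#' Leave-one-out prediction residuals obtained from the hat matrix:
#' \eqn{PRESS = \sum (e_i / (1 - h_{ii}))^2}, \eqn{Q^2 = 1 - PRESS/SS_{tot}}.
#' Always \eqn{Q^2 \le R^2}.
#'
#' @param model An `rsm` object.
#' @export
q2_press <- function(model) {
  stopifnot(inherits(model, "rsm"))
  h <- rowSums((model$X %*% model$vcov_unscaled) * model$X)
  if (any(h >= 1 - 1e-10))
    stop("saturated fit: hat value of 1, Q2 not computable")
  press <- sum((model$residuals / (1 - h))^2)
  ss_tot <- sum((model$y - mean(model$y))^2)
  1 - press / ss_tot
}

#' Replicate reproducibility
#'
#' `1 - MS_pure_error / MS_total` with the total mean square taken about the
#' grand mean (corrected); 1 means replicates are identical, values near 0
#' mean replicate scatter is as large as the total scatter.
#'
#' @param model An `rsm` object, or a data frame with columns `run_id` and a
#'   response column.
#' @param response Response column name when `model` is a data frame.
#' @export
reproducibility <- function(model, response = "height") {
  if (inherits(model, "rsm")) {
    y <- model$y; run <- model$run_id
  } else {
    y <- model[[response]]; run <- model$run_id
  }
  pe <- pure_error(y, run)
  if (pe$df < 1) stop("no replicated runs: reproducibility not computable")
  ms_tot <- sum((y - mean(y))^2) / (length(y) - 1)
  1 - (pe$ss / pe$df) / ms_tot
}

pure_error <- function(y, run) {
  means <- tapply(y, run, mean)
  counts <- tapply(y, run, length)
  ss <- sum((y - means[as.character(run)])^2)
  list(ss = ss, df = length(y) - length(means),
       n_runs = length(means), counts = counts)
}

#' Pure-error lack-of-fit test
#'
#' Splits the residual sum of squares into pure error (within-run replicate
#' scatter) and lack of fit; `F = (SS_lof/df_lof) / (SS_pe/df_pe)` with the
#' p-value from the F distribution.  A non-significant result (p > 0.05)
#' indicates the quadratic surface is adequate relative to replicate noise.
#'
#' @param model An `rsm` object.
#' @return List with `F`, `p`, `ss_pe`, `ss_lof`, `df_pe`, `df_lof`.
#' @export
lack_of_fit <- function(model) {
  stopifnot(inherits(model, "rsm"))
  pe <- pure_error(model$y, model$run_id)
  if (pe$df < 1) stop("no pure-error degrees of freedom: lack of fit not computable")
  df_lof <- model$df_residual - pe$df
  if (df_lof < 1) stop("no lack-of-fit degrees of freedom")
  ss_lof <- max(sum(model$residuals^2) - pe$ss, 0)
  Fstat <- (ss_lof / df_lof) / (pe$ss / pe$df)
  list(F = Fstat, p = stats::pf(Fstat, df_lof, pe$df, lower.tail = FALSE),
       ss_pe = pe$ss, ss_lof = ss_lof, df_pe = pe$df, df_lof = df_lof)
}

#' Backward refinement of a response-surface model
#'
#' Iteratively removes the least significant removable term (largest
#' p-value among terms whose 95 % CI contains zero), refitting after each
#' removal, until every unprotected term is significant.  The intercept is
#' never removed and, under weak heredity, a main effect is protected while
#' any retained quadratic or interaction term contains its factor.
#' Refinement is idempotent.
#'
#' @param model An `rsm` object (must retain its fitting data).
#' @param alpha Significance level for the CI rule (default 0.05).
#' @param heredity `"weak"` (default) or `"none"`.
#' @return The refined `rsm`.
#' @export
refine_rsm <- function(model, alpha = 0.05, heredity = c("weak", "none")) {
  stopifnot(inherits(model, "rsm"))
  heredity <- match.arg(heredity)
  if (is.null(model$X)) stop("model carries no data; cannot refine")
  X <- model$X; y <- model$y
  repeat {
    p <- ncol(X)
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    res <- y - drop(X %*% beta)
    df_res <- length(y) - p
    sigma2 <- sum(res^2) / max(df_res, 1)
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * diag(XtXinv))
    tval <- abs(beta) / se
    pval <- 2 * stats::pt(tval, df_res, lower.tail = FALSE)
    tcrit <- stats::qt(1 - alpha / 2, df_res)
    labels <- colnames(X)
    nonsig <- tval < tcrit
    protected <- labels == "(Intercept)"
    if (heredity == "weak") {
      parsed <- lapply(labels, parse_term)
      higher <- unique(unlist(lapply(parsed, function(tm)
        if (tm$kind %in% c("quadratic", "interaction")) tm$factors)))
      protected <- protected |
        vapply(parsed, function(tm) tm$kind == "linear" &&
                 tm$factors %in% higher, TRUE)
    }
    removable <- which(nonsig & !protected)
    if (!length(removable) || p <= 1L) break
    drop_i <- removable[which.max(pval[removable])]
    X <- X[, -drop_i, drop = FALSE]
  }
  out <- fit_rsm_matrix(X, y, run_id = model$run_id, analyte = model$analyte,
                        factors = model$factors, transform = model$transform,
                        design = model$design, response = model$response)
  out$refined <- TRUE
  out
}

#' Construct a response-surface model from known coefficients
#'
#' Builds an `rsm` object directly from a coefficient vector, without data.
#' Useful for specifying ground-truth or externally reported surfaces that
#' can then be passed to [predict.rsm()] or [design_space_map()].
#'
#' @param coefficients Named numeric vector; names are term labels
#'   (`"(Intercept)"`, `"CID"`, `"CID^2"`, `"CID:IntT"`, ...).
#' @param factors Named list of [doe_factor()] objects covering all factors
#'   referenced by the terms.
#' @param residual_sd Residual standard deviation on the modelling scale.
#' @param transform `"identity"` or `"log"`.
#' @param analyte Analyte label.
#' @export
rsm_model <- function(coefficients, factors, residual_sd = 0,
                      transform = c("identity", "log"), analyte = "analyte") {
  transform <- match.arg(transform)
  factors <- stopifnot_factor_list(factors)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(analyte = analyte, terms = names(coefficients),
                 coefficients = coefficients, se = rep(NA_real_, length(coefficients)),
                 ci95 = rep(NA_real_, length(coefficients)),
                 sigma = residual_sd, df_residual = Inf, r2 = NA_real_,
                 q2 = NA_real_, reproducibility = NA_real_, lof = NULL,
                 transform = transform, factors = factors,
                 X = NULL, y = NULL, run_id = NULL,
                 vcov_unscaled = NULL, design = NULL, response = "height",
                 refined = FALSE), class = "rsm")
}

# eta (linear predictor on the modelling scale) at coded points
rsm_eta <- function(model, coded) {
  X <- build_model_matrix(coded, model$terms)
  drop(X %*% model$coefficients[colnames(X)])
}

# gradient of eta with respect to each coded factor, at coded points
rsm_gradient <- function(model, coded) {
  coded <- coded_matrix(coded)
  k <- ncol(coded)
  G <- matrix(0, nrow(coded), k, dimnames = list(NULL, colnames(coded)))
  for (lbl in model$terms) {
    tm <- parse_term(lbl)
    b <- model$coefficients[[lbl]]
    if (tm$kind == "linear") {
      G[, tm$factors] <- G[, tm$factors] + b
    } else if (tm$kind == "quadratic") {
      G[, tm$factors] <- G[, tm$factors] + 2 * b * coded[, tm$factors]
    } else if (tm$kind == "interaction") {
      G[, tm$factors[1]] <- G[, tm$factors[1]] + b * coded[, tm$factors[2]]
      G[, tm$factors[2]] <- G[, tm$factors[2]] + b * coded[, tm$factors[1]]
    }
  }
  G
}

# coded matrix from a natural-unit data frame
natural_to_coded <- function(factors, newdata) {
  nm <- names(factors)
  missing <- setdiff(nm, names(newdata))
  if (length(missing))
    stop("newdata lacks factor column(s): ", paste(missing, collapse = ", "))
  m <- vapply(nm, function(f) code_level(factors[[f]], newdata[[f]]),
              numeric(nrow(as.data.frame(newdata))))
  m <- matrix(m, ncol = length(nm), dimnames = list(NULL, nm))
  m
}

#' Predict from a response-surface model
#'
#' @param object An `rsm`.
#' @param newdata Data frame of factor settings in natural units (one column
#'   per model factor).
#' @param type `"response"` back-transforms log-scale models; `"link"`
#'   returns the linear predictor on the modelling scale.
#' @param se.fit Also return the standard error of the mean prediction
#'   (delta-method on the response scale for log models).
#' @param extrapolation_box Half-width of the coded box beyond which an
#'   extrapolation warning is issued (default 1.5).
#' @param ... Unused.
#' @return Numeric vector, or list with `fit` and `se.fit`.
#' @export
predict.rsm <- function(object, newdata, type = c("response", "link"),
                        se.fit = FALSE, extrapolation_box = 1.5, ...) {
  type <- match.arg(type)
  coded <- natural_to_coded(object$factors, newdata)
  if (any(abs(coded) > extrapolation_box + 1e-9))
    warning("prediction outside the coded extrapolation box (|x| > ",
            extrapolation_box, ")")
  eta <- rsm_eta(object, coded)
  fit <- if (type == "response" && object$transform == "log") exp(eta) else eta
  if (!se.fit) return(fit)
  se <- if (is.null(object$vcov_unscaled)) rep(NA_real_, length(eta)) else {
    X <- build_model_matrix(coded, object$terms)
    sqrt(pmax(rowSums((X %*% object$vcov_unscaled) * X), 0)) * object$sigma
  }
  if (type == "response" && object$transform == "log") se <- fit * se
  list(fit = fit, se.fit = se)
}

#' Fit one response-surface model per analyte
#'
#' @inheritParams rsm_fit
#' @param refine Apply [refine_rsm()] to each fit (default TRUE).
#' @param alpha Significance level used during refinement.
#' @return Named list of `rsm` objects.
#' @export
rsm_fit_all <- function(design, responses, terms = quadratic_terms(names(design$factors)),
                        transform = c("identity", "log"), response = "height",
                        refine = TRUE, alpha = 0.05) {
  transform <- match.arg(transform)
  analytes <- unique(responses$analyte)
  fits <- lapply(analytes, function(a) {
    f <- rsm_fit(design, responses, analyte = a, terms = terms,
                 transform = transform, response = response)
    if (refine) f <- refine_rsm(f, alpha = alpha) else f
  })
  names(fits) <- analytes
  fits
}
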