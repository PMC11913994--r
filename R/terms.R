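# Model-term grammar shared by the design and modelling code.
#
# Terms are written as strings: "(Intercept)" or "1" for the intercept,
# "CID" for a linear term, "CID^2" for a quadratic term, and "CID:IntT" for
# a two-factor interaction.

parse_term <- function(term) {
  if (term %in% c("1", "(Intercept)"))
    return(list(kind = "intercept", factors = character(0), label = "(Intercept)"))
  if (term == "curvature")
    return(list(kind = "curvature", factors = character(0), label = "curvature"))
  if (grepl("\\^2$", term)) {
    f <- sub("\\^2$", "", term)
    return(list(kind = "quadratic", factors = f, label = paste0(f, "^2")))
  }
  if (grepl(":", term, fixed = TRUE)) {
    f <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(f) != 2L || f[1] == f[2])
      stop("interaction term '", term, "' must name two distinct factors")
    return(list(kind = "interaction", factors = f,
                label = paste(f, collapse = ":")))
  }
  list(kind = "linear", factors = term, label = term)
}

parse_terms <- function(terms) {
  out <- lapply(terms, parse_term)
  labels <- vapply(out, `[[`, "", "label")
  if (!"(Intercept)" %in% labels) {
    out <- c(list(parse_term("1")), out)
    labels <- c("(Intercept)", labels)
  }
  if (anyDuplicated(labels)) stop("duplicate model terms")
  names(out) <- labels
  out
}

#' Term sets for response-surface models
#'
#' `quadratic_terms()` builds the full second-order model (linear, quadratic
#' and all two-factor interaction terms) for a set of factor names;
#' `linear_terms()` builds the main-effects model used in screening.
#'
#' @param factor_names Character vector of factor names.
#' @return Character vector of term labels (intercept implicit).
#' @export
quadratic_terms <- function(factor_names) {
  stopifnot(length(factor_names) >= 1)
  inter <- if (length(factor_names) >= 2)
    combn(factor_names, 2, paste, collapse = ":") else character(0)
  c(factor_names, paste0(factor_names, "^2"), inter)
}

#' @rdname quadratic_terms
#' @export
linear_terms <- function(factor_names) factor_names

#' Build the coded model matrix for a list of terms
#'
#' One column per term; the intercept is a column of ones, an interaction
#' column is the elementwise product of its parent coded columns, and a
#' quadratic column is the square of its parent.  The special label
#' `"curvature"` (usable only when `design` is a `doe_design`) is an
#' indicator for centre points: with two-level factorial points plus
#' centres, per-factor quadratics are not separately estimable and this
#' single lumped contrast absorbs (and tests) the joint curvature instead.
#'
#' @param design A [doe_design] object or a data frame / matrix of coded
#'   factor levels with factor names as column names.
#' @param terms Character vector of term labels (see [quadratic_terms()]).
#' @return Numeric matrix with term labels as column names.
#' @export
build_model_matrix <- function(design, terms) {
  coded <- coded_matrix(design)
  pt <- parse_terms(terms)
  is_center <- if (inherits(design, "doe_design"))
    as.numeric(design$runs$point_type == "center") else NULL
  cols <- lapply(pt, function(tm) {
    if (tm$kind == "curvature") {
      if (is.null(is_center))
        stop("the 'curvature' term requires a doe_design with point types")
      return(is_center)
    }
    missing <- setdiff(tm$factors, colnames(coded))
    if (length(missing))
      stop("unknown factor(s) in model terms: ", paste(missing, collapse = ", "))
    switch(tm$kind,
           intercept = rep(1, nrow(coded)),
           linear = coded[, tm$factors],
           quadratic = coded[, tm$factors]^2,
           interaction = coded[, tm$factors[1]] * coded[, tm$factors[2]])
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(pt)
  rownames(X) <- rownames(coded)
  X
}

# Extract the coded level matrix from whatever representation we are given.
coded_matrix <- function(design) {
  if (inherits(design, "doe_design")) {
    nm <- names(design$factors)
    m <- as.matrix(design$runs[paste0(nm, "_coded")])
    colnames(m) <- nm
    return(m)
  }
  m <- as.matrix(design)
  if (is.null(colnames(m))) stop("coded level matrix must have column names")
  storage.mode(m) <- "double"
  m
}
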