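# Alias algebra for two-level fractional factorial designs.
#
# Effects are written as sets of factor letters (A, B, C, ...).  The product
# of two effects is the symmetric difference of their letter sets (letters
# appearing twice square to the identity I).  The defining relation of a
# 2^(k-p) design is the group generated by the p generator words; its 2^p - 1
# non-identity words determine the design resolution (shortest word) and the
# alias set of every effect.

word_multiply <- function(a, b) {
  # symmetric difference of two letter vectors
  sort(c(setdiff(a, b), setdiff(b, a)))
}

word_string <- function(w) if (!length(w)) "I" else paste(w, collapse = "")

#' Alias structure of a regular two-level fractional factorial design
#'
#' Expands the defining relation generated by the design generators by brute
#' force multiplication of all generator subsets, computes the resolution
#' (length of the shortest defining word) and the alias map of all main
#' effects and two-factor interactions.
#'
#' @param generators Named character vector mapping each generated factor
#'   letter to its generating word, e.g. `c(E = "ABC", F = "BCD", G = "ACD")`.
#' @param k Total number of factors (base factors are the first `k - p`
#'   letters).
#' @return An object of class `alias_structure` with elements
#'   `defining_words` (character), `resolution` (integer, `Inf` for a full
#'   factorial), and `alias_map` (named list: effect string -> character
#'   vector of confounded effects up to order 2).
#' @examples
#' a <- alias_structure(c(E = "ABC", F = "BCD", G = "ACD"), k = 7)
#' a$resolution          # 4
#' a$alias_map[["AB"]]   # "CE" "FG"
#' @export
alias_structure <- function(generators, k) {
  stopifnot(k >= 1)
  letters_k <- LETTERS[seq_len(k)]
  p <- length(generators)
  if (p == 0L) {
    out <- structure(list(defining_words = character(0), resolution = Inf,
                          alias_map = list(), letters = letters_k),
                     class = "alias_structure")
    return(out)
  }
  if (is.null(names(generators)) || any(!nzchar(names(generators))))
    stop("generators must be a named character vector")
  gen_words <- lapply(seq_along(generators), function(i) {
    sort(c(names(generators)[i], strsplit(generators[[i]], "")[[1]]))
  })
  # all non-empty subsets of the p generator words
  words <- list()
  for (s in seq_len(2^p - 1L)) {
    idx <- which(bitwAnd(s, 2^(seq_len(p) - 1L)) > 0L)
    w <- character(0)
    for (i in idx) w <- word_multiply(w, gen_words[[i]])
    if (!length(w))
      stop("degenerate defining relation: generator product collapses to I")
    words[[s]] <- w
  }
  resolution <- min(lengths(words))
  # alias map for all effects of order 1 and 2
  effects <- c(as.list(letters_k),
               combn(letters_k, 2L, simplify = FALSE))
  amap <- list()
  for (e in effects) {
    al <- vapply(words, function(w) word_string(word_multiply(e, w)), "")
    amap[[word_string(e)]] <- sort(unique(al))
  }
  structure(list(defining_words = vapply(words, word_string, ""),
                 resolution = resolution,
                 alias_map = amap,
                 letters = letters_k),
            class = "alias_structure")
}

#' Aliases of an effect, restricted to a maximum interaction order
#'
#' @param x An [alias_structure()].
#' @param effect Effect string such as `"A"` or `"AB"`.
#' @param max_order Keep only aliases involving at most this many factors.
#' @export
aliases_of <- function(x, effect, max_order = 2L) {
  stopifnot(inherits(x, "alias_structure"))
  effect <- word_string(sort(strsplit(effect, "")[[1]]))
  al <- x$alias_map[[effect]]
  if (is.null(al)) stop("effect '", effect, "' not in alias map")
  al[nchar(al) <= max_order]
}

#' @export
print.alias_structure <- function(x, ...) {
  if (!length(x$defining_words)) {
    cat("<alias structure> full factorial (resolution reported as 'full')\n")
    return(invisible(x))
  }
  cat(sprintf("<alias structure> resolution %s, %d defining words\n",
              as.roman(x$resolution), length(x$defining_words)))
  cat("  I =", paste(x$defining_words, collapse = " = "), "\n")
  invisible(x)
}

# translate a letter-effect ("AB") to factor-name notation ("IntV:IntT")
effect_to_names <- function(effect, factor_names) {
  idx <- match(strsplit(effect, "")[[1]], LETTERS)
  paste(factor_names[idx], collapse = ":")
}
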