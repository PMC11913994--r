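# shared helpers for building small designs and response tables in code

unit_factor <- function(name) {
  doe_factor(name, -1, 1, rounding_step = 1e-6, hard_min = -10, hard_max = 10)
}

# one-factor design at arbitrary coded/natural positions (natural == coded)
line_design <- function(x, n_replicates = 1L, name = "X") {
  manual_design(list(unit_factor(name)),
                stats::setNames(data.frame(x), name),
                n_replicates = n_replicates)
}

# replicate-level response table for a design from a vector of run means
# (recycled per replicate) or an explicit run x replicate matrix
make_responses <- function(design, y, n_replicates = 1L, analyte = "a") {
  if (is.matrix(y)) {
    df <- do.call(rbind, lapply(seq_len(ncol(y)), function(r)
      data.frame(run_id = design$runs$run_id, replicate = r,
                 analyte = analyte, height = y[, r])))
  } else {
    df <- do.call(rbind, lapply(seq_len(n_replicates), function(r)
      data.frame(run_id = design$runs$run_id, replicate = r,
                 analyte = analyte, height = y)))
  }
  df$auc <- df$height
  df
}

# independent alias-algebra oracle: expand the defining relation of a
# regular 2^(k-p) design by brute force and return the order<=2 aliases of
# an effect, both as letter strings
oracle_aliases <- function(generators, effect) {
  mult <- function(a, b) sort(c(setdiff(a, b), setdiff(b, a)))
  gens <- lapply(seq_along(generators), function(i)
    sort(c(names(generators)[i], strsplit(generators[[i]], "")[[1]])))
  p <- length(gens)
  words <- list()
  for (s in seq_len(2^p - 1)) {
    w <- character(0)
    for (i in which(bitwAnd(s, 2^(seq_len(p) - 1)) > 0)) w <- mult(w, gens[[i]])
    words[[s]] <- w
  }
  e <- sort(strsplit(effect, "")[[1]])
  al <- vapply(words, function(w) paste(mult(e, w), collapse = ""), "")
  sort(unique(al[nchar(al) <= 2]))
}
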