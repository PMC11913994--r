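# Experimental design generators: regular two-level fractional factorials,
# central composite designs with rounded/clipped star points, and exact
# D-optimal designs by Fedorov coordinate exchange.

new_doe_design <- function(factors, runs, kind, alpha = NULL,
                           generators = NULL, alias = NULL,
                           n_replicates = 2L, run_order_seed = NULL) {
  stopifnot(is.data.frame(runs))
  if (anyDuplicated(runs$run_id)) stop("run_ids must be unique")
  structure(list(factors = factors, runs = runs, kind = kind, alpha = alpha,
                 generators = generators, alias = alias,
                 n_replicates = as.integer(n_replicates),
                 run_order_seed = run_order_seed),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("<%s design> %d runs x %d factors (%s), %d replicate(s) per run\n",
              x$kind, nrow(x$runs), length(x$factors),
              paste(names(x$factors), collapse = ", "), x$n_replicates))
  if (!is.null(x$alpha)) cat("  star distance alpha =", x$alpha, "\n")
  if (!is.null(x$alias)) {
    res <- x$alias$resolution
    cat("  resolution:", if (is.infinite(res)) "full" else as.character(as.roman(res)), "\n")
  }
  print(utils::head(x$runs, 8))
  if (nrow(x$runs) > 8) cat("  ... and", nrow(x$runs) - 8, "more runs\n")
  invisible(x)
}

# assemble the runs data frame from a coded matrix, decoding naturals and
# recomputing achieved coded levels after rounding/clipping
runs_from_coded <- function(coded, factors, point_type) {
  nm <- names(factors)
  natural <- coded
  achieved <- coded
  clipped <- rep(FALSE, nrow(coded))
  for (j in seq_along(factors)) {
    f <- factors[[j]]
    raw <- factor_center(f) + coded[, j] * factor_half_range(f)
    nat <- decode_level(f, coded[, j])
    clipped <- clipped | (raw < f$hard_min - 1e-9) | (raw > f$hard_max + 1e-9)
    natural[, j] <- nat
    achieved[, j] <- code_level(f, nat)
  }
  df <- data.frame(run_id = seq_len(nrow(coded)), point_type = point_type,
                   clipped = clipped)
  nat_df <- as.data.frame(natural); names(nat_df) <- nm
  cod_df <- as.data.frame(achieved); names(cod_df) <- paste0(nm, "_coded")
  cbind(df, nat_df, cod_df)
}

# standard minimum-aberration generators for the regular designs we support
standard_generators <- function(k, p) {
  key <- paste(k, p, sep = "-")
  gens <- list(
    "7-3" = c(E = "ABC", F = "BCD", G = "ACD"),
    "7-2" = c(F = "ABCD", G = "ABDE"),
    "6-2" = c(E = "ABC", F = "BCD"),
    "5-1" = c(E = "ABCD"),
    "4-1" = c(D = "ABC"))
  if (p == 0L) return(character(0))
  if (is.null(gens[[key]]))
    stop("no generator table for a 2^(", k, "-", p, ") design")
  gens[[key]]
}

#' Two-level (fractional) factorial screening design
#'
#' Builds a regular \eqn{2^{k-p}} design with centre points.  For the
#' seven-factor screening panel with `fraction = 3` this is the 16-run
#' resolution-IV design (generators E = ABC, F = BCD, G = ACD) plus three
#' centre points: 19 runs, each run executed in duplicate by default.
#'
#' @param factors Named list of [doe_factor()] objects (k factors).
#' @param fraction Number of generated factors p (0 for a full factorial).
#' @param n_center Number of centre points (all factors at coded 0).
#' @param resolution_target Minimum acceptable resolution (default 4);
#'   an error is raised if the generator table cannot attain it.
#' @param n_replicates Replicate measurements per run (default 2).
#' @param generators Optional named character vector overriding the built-in
#'   generator table.
#' @return A `doe_design` with an `alias` component ([alias_structure()]).
#' @examples
#' d <- ffd_design(screening_factors())  # 19 runs
#' nrow(d$runs)
#' @export
ffd_design <- function(factors, fraction = length(factors) - 4L, n_center = 3,
                       resolution_target = 4, n_replicates = 2L,
                       generators = NULL) {
  factors <- stopifnot_factor_list(factors)
  k <- length(factors)
  p <- as.integer(fraction)
  if (p < 0L || p >= k) stop("fraction must be in [0, k-1]")
  if (is.null(generators)) generators <- standard_generators(k, p)
  base_k <- k - p
  base <- as.matrix(expand.grid(rep(list(c(-1, 1)), base_k)))
  colnames(base) <- LETTERS[seq_len(base_k)]
  coded <- base
  if (p > 0L) {
    for (i in seq_along(generators)) {
      parents <- strsplit(generators[[i]], "")[[1]]
      coded <- cbind(coded, apply(base[, parents, drop = FALSE], 1, prod))
      colnames(coded)[ncol(coded)] <- names(generators)[i]
    }
  }
  alias <- alias_structure(generators, k)
  if (is.finite(alias$resolution) && alias$resolution < resolution_target)
    stop("design infeasible: attainable resolution ",
         alias$resolution, " < target ", resolution_target)
  if (n_center > 0)
    coded <- rbind(coded, matrix(0, n_center, k,
                                 dimnames = list(NULL, colnames(coded))))
  colnames(coded) <- names(factors)   # letters map to factors in order
  point_type <- c(rep("factorial", 2^base_k), rep("center", n_center))
  runs <- runs_from_coded(coded, factors, point_type)
  new_doe_design(factors, runs, kind = "ffd", generators = generators,
                 alias = alias, n_replicates = n_replicates)
}

#' Central composite design with rounded, hard-bound-clipped star points
#'
#' The cube (2^k factorial) points sit at coded +/-1, the 2k axial points at
#' coded +/-alpha along one factor each, plus `n_center` centre points.
#' Axial natural levels are decoded with clipping to the factor hard bounds
#' and rounding to the settable step; a row whose raw natural level violated
#' a hard bound keeps its run (the achieved coded level is recomputed from
#' the clipped natural value) and is flagged in the `clipped` column.
#'
#' @param factors Named list of [doe_factor()] objects.
#' @param alpha Star distance in coded units (> 0); default 1.35.
#' @param n_center Number of centre points; default 3.
#' @param n_replicates Replicate measurements per run (default 2).
#' @return A `doe_design` of kind `"ccd"`.
#' @examples
#' d <- ccd_design(optimization_factors())  # 8 + 6 + 3 = 17 runs
#' subset(d$runs, clipped)                  # IntT +alpha clipped to 400 degC
#' @export
ccd_design <- function(factors, alpha = 1.35, n_center = 3, n_replicates = 2L) {
  factors <- stopifnot_factor_list(factors)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  k <- length(factors)
  cube <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2L * k, k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -alpha
    axial[2L * j, j] <- alpha
  }
  centers <- matrix(0, n_center, k)
  coded <- rbind(cube, axial, centers)
  colnames(coded) <- names(factors)
  point_type <- c(rep("factorial", nrow(cube)), rep("axial", nrow(axial)),
                  rep("center", n_center))
  runs <- runs_from_coded(coded, factors, point_type)
  new_doe_design(factors, runs, kind = "ccd", alpha = alpha,
                 n_replicates = n_replicates)
}

#' Candidate grid over the settable levels of a factor set
#'
#' @param factors Named list of [doe_factor()] objects.
#' @param steps Optional named numeric vector of grid steps per factor in
#'   natural units; defaults to each factor's `rounding_step`.
#' @return Data frame of natural candidate points (full crossing).
#' @export
candidate_grid <- function(factors, steps = NULL) {
  factors <- stopifnot_factor_list(factors)
  axes <- lapply(factors, function(f) {
    st <- if (!is.null(steps) && f$name %in% names(steps)) steps[[f$name]]
          else f$rounding_step
    seq(f$low, f$high, by = st)
  })
  expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
}

#' Exact D-optimal design by Fedorov coordinate exchange
#'
#' Selects `n_runs` distinct rows from a finite candidate set so as to
#' maximize \eqn{\det(X'X)} of the model matrix (repeats are used only when
#' `n_runs` exceeds the candidate count).  Classic exchange: from a random
#' seeded start, repeatedly replace the design point whose swap with a
#' candidate gives the largest determinant increase, until no swap improves;
#' the whole search is restarted `n_restarts` times and the best design kept.
#' The objective is non-decreasing over exchange iterations within a restart.
#'
#' @param factors Named list of [doe_factor()] objects.
#' @param candidates Data frame of candidate points in natural units (one
#'   column per factor); default [candidate_grid()] over the factors.
#' @param terms Model term labels (see [quadratic_terms()]); the design is
#'   optimal for this model.
#' @param n_runs Number of design runs; must be at least the number of terms.
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer seed controlling the restarts (reproducible).
#' @param n_replicates Replicate measurements per run (default 2).
#' @return A `doe_design` of kind `"d_optimal"`; attributes
#'   `log_det` (achieved log-determinant) and `objective_trace` (per-restart
#'   list of the non-decreasing objective values).
#' @export
d_optimal_design <- function(factors, terms, n_runs,
                             candidates = candidate_grid(factors),
                             n_restarts = 20, seed = 1, n_replicates = 2L) {
  factors <- stopifnot_factor_list(factors)
  nm <- names(factors)
  if (!all(nm %in% names(candidates)))
    stop("candidates must contain a column per factor")
  cand_nat <- as.matrix(candidates[nm])
  cand_coded <- cand_nat
  for (j in seq_along(factors))
    cand_coded[, j] <- code_level(factors[[j]], cand_nat[, j])
  colnames(cand_coded) <- nm
  Fc <- build_model_matrix(cand_coded, terms)
  p <- ncol(Fc)
  n_runs <- as.integer(n_runs)
  if (n_runs < p)
    stop("rank deficiency: n_runs (", n_runs, ") < number of model terms (", p, ")")
  nc <- nrow(Fc)

  log_det <- function(rows) {
    M <- crossprod(Fc[rows, , drop = FALSE])
    d <- determinant(M, logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  allow_repeats <- n_runs > nc
  best <- NULL; best_obj <- -Inf; traces <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    rows <- sample.int(nc, n_runs, replace = allow_repeats)
    obj <- log_det(rows)
    trace <- obj
    repeat {
      improved <- FALSE
      for (i in seq_len(n_runs)) {
        cur <- rows
        objs <- vapply(seq_len(nc), function(j) {
          if (!allow_repeats && j != rows[i] && j %in% rows) return(-Inf)
          cur[i] <- j; log_det(cur)
        }, 0)
        jbest <- which.max(objs)
        if (objs[jbest] > obj + 1e-10) {
          rows[i] <- jbest
          obj <- objs[jbest]
          trace <- c(trace, obj)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    traces[[r]] <- trace
    if (obj > best_obj) { best_obj <- obj; best <- rows }
  }
  coded <- cand_coded[best, , drop = FALSE]
  point_type <- ifelse(rowSums(abs(coded)) == 0, "center", "factorial")
  runs <- runs_from_coded(coded, factors, point_type)
  d <- new_doe_design(factors, runs, kind = "d_optimal",
                      n_replicates = n_replicates)
  attr(d, "log_det") <- best_obj
  attr(d, "objective_trace") <- traces
  attr(d, "terms") <- terms
  d
}

#' Assemble a design from explicit natural-unit settings
#'
#' For ad-hoc experiments (e.g. a one-factor-at-a-time scan) or externally
#' supplied run tables.  Coded levels are computed from the factors; the
#' natural values are used as given (no rounding).
#'
#' @param factors Named list of [doe_factor()] objects.
#' @param natural Data frame of natural settings, one column per factor.
#' @param point_type Optional character vector (default: `"center"` where
#'   all coded levels are 0, `"factorial"` otherwise).
#' @param n_replicates Replicates per run (default 2).
#' @return A `doe_design` of kind `"manual"`.
#' @export
manual_design <- function(factors, natural, point_type = NULL,
                          n_replicates = 2L) {
  factors <- stopifnot_factor_list(factors)
  nm <- names(factors)
  if (!all(nm %in% names(natural)))
    stop("'natural' must contain a column per factor")
  natural <- as.data.frame(natural)[nm]
  coded <- vapply(nm, function(f) code_level(factors[[f]], natural[[f]]),
                  numeric(nrow(natural)))
  coded <- matrix(coded, ncol = length(nm), dimnames = list(NULL, nm))
  if (is.null(point_type))
    point_type <- ifelse(rowSums(abs(coded)) == 0, "center", "factorial")
  df <- data.frame(run_id = seq_len(nrow(natural)), point_type = point_type,
                   clipped = FALSE)
  cod_df <- as.data.frame(coded); names(cod_df) <- paste0(nm, "_coded")
  runs <- cbind(df, natural, cod_df)
  new_doe_design(factors, runs, kind = "manual", n_replicates = n_replicates)
}

#' Write / read a design matrix as CSV
#'
#' Columns: `run_id`, `point_type`, `clipped`, one natural-unit column per
#' factor and one coded column per factor (suffix `_coded`).
#'
#' @param design A `doe_design`.
#' @param file Path to a CSV file.
#' @export
write_design <- function(design, file) {
  stopifnot(inherits(design, "doe_design"))
  utils::write.csv(design$runs, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_design
#' @param factors Factor list matching the design columns.
#' @export
read_design <- function(file, factors, kind = "ffd") {
  runs <- utils::read.csv(file, stringsAsFactors = FALSE)
  new_doe_design(stopifnot_factor_list(factors), runs, kind = kind)
}
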