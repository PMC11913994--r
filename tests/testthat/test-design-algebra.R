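# Design generation, coded/natural conversion and alias algebra.

test_that("coded/natural conversion reproduces the printed factor levels", {
  f <- optimization_factors()
  # star points of the optimization design, rounded to the settable step
  expect_equal(decode_level(f$IntV, -1.35), 1.8)
  expect_equal(decode_level(f$IntV, 1.35), 3.2)
  expect_equal(decode_level(f$CID, -1.35), 120)   # raw 120.75
  expect_equal(decode_level(f$CID, 1.35), 270)
  expect_equal(decode_level(f$IntT, -1.35), 282)  # raw 282.5, half-to-even
  expect_equal(decode_level(f$IntT, 1.35), 400)   # clipped at the hard bound
  # midpoint codes to 0
  expect_equal(code_level(f$IntT, 350), 0)
  expect_error(code_level(f$IntT, NaN), "non-finite")
  expect_error(decode_level(f$IntT, Inf), "non-finite")
})

test_that("decode(code(x)) round-trips every settable natural value", {
  for (f in c(screening_factors(), optimization_factors(), ce_factors())) {
    v <- seq(f$low, f$high, by = f$rounding_step)
    expect_equal(decode_level(f, code_level(f, v)), v, info = f$name)
  }
})

test_that("the 7-factor screening FFD has 19 balanced resolution-IV runs", {
  d <- ffd_design(screening_factors())
  expect_equal(nrow(d$runs), 19L)
  expect_equal(sum(d$runs$point_type == "factorial"), 16L)
  expect_equal(sum(d$runs$point_type == "center"), 3L)
  expect_equal(d$alias$resolution, 4)
  expect_length(d$alias$defining_words, 2^3 - 1)
  expect_true(all(nchar(d$alias$defining_words) >= 4))
  # balance and orthogonality of the factorial block
  cols <- paste0(names(d$factors), "_coded")
  X <- as.matrix(d$runs[d$runs$point_type == "factorial", cols])
  expect_true(all(colSums(X == 1) == 8), info = "eight +1 per column")
  expect_true(all(colSums(X == -1) == 8))
  XtX <- crossprod(X)
  expect_equal(XtX, diag(16, 7), ignore_attr = TRUE)
  # every main effect clear of mains and two-factor interactions
  for (l in LETTERS[1:7])
    expect_true(all(nchar(aliases_of(d$alias, l, max_order = 2)) > 2 |
                      lengths(strsplit(aliases_of(d$alias, l), "")) > 2),
                info = l)
})

test_that("alias map matches a brute-force defining-relation expansion", {
  gens <- c(E = "ABC", F = "BCD", G = "ACD")
  a <- alias_structure(gens, k = 7)
  effects <- c("A", "D", "AB", "AC", "BD", "CE", "FG", "EG")
  for (e in effects)
    expect_equal(aliases_of(a, e, max_order = 2), oracle_aliases(gens, e),
                 info = e)
  expect_equal(aliases_of(a, "AB"), c("CE", "FG"))
  # alias symmetry: B in alias(A) <=> A in alias(B)
  for (e in c("AB", "CE", "FG"))
    for (al in aliases_of(a, e))
      expect_true(e %in% aliases_of(a, al), info = paste(e, al))
})

test_that("a full factorial reports no aliasing and 4 runs for 2 factors", {
  d <- ffd_design(optimization_factors()[c("CID", "IntT")], fraction = 0,
                  n_center = 0)
  expect_equal(nrow(d$runs), 4L)
  expect_true(is.infinite(d$alias$resolution))
  expect_length(d$alias$defining_words, 0)
})

test_that("unattainable resolution raises a design-infeasible error", {
  # 2^(7-3) generators give resolution IV; demanding V must fail
  expect_error(ffd_design(screening_factors(), resolution_target = 5),
               "infeasible")
})

test_that("the CCD has 17 runs with rounded, clipped axial levels", {
  d <- ccd_design(optimization_factors())
  expect_equal(nrow(d$runs), 17L)
  expect_equal(as.vector(table(d$runs$point_type)[c("factorial", "axial", "center")]),
               c(8L, 6L, 3L))
  ax <- d$runs[d$runs$point_type == "axial", ]
  expect_setequal(ax$CID[ax$IntT == 350 & ax$IntV == 2.5], c(120, 270))
  expect_setequal(ax$IntT[ax$CID == 195 & ax$IntV == 2.5], c(282, 400))
  expect_setequal(ax$IntV[ax$CID == 195 & ax$IntT == 350], c(1.8, 3.2))
  # only the IntT +alpha run needed clipping, and it is annotated
  expect_equal(sum(d$runs$clipped), 1L)
  expect_equal(d$runs$IntT[d$runs$clipped], 400)
  # unclipped axial pairs are symmetric about the centre in coded units
  for (f in c("CID", "IntV")) {
    cc <- sort(ax[[paste0(f, "_coded")]][abs(ax[[paste0(f, "_coded")]]) > 1e-9])
    expect_equal(cc[1], -cc[2], info = f)
  }
  expect_error(ccd_design(optimization_factors(), alpha = -1), "alpha")
})

test_that("alpha = 1 gives a face-centred design inside the nominal ranges", {
  d <- ccd_design(optimization_factors(), alpha = 1)
  for (f in d$factors) {
    v <- d$runs[[f$name]]
    expect_true(all(v >= f$low - 1e-9 & v <= f$high + 1e-9), info = f$name)
  }
  expect_false(any(d$runs$clipped))
})

test_that("D-optimal exchange matches exhaustive search on a 3x3 grid", {
  facs <- list(unit_factor("X1"), unit_factor("X2"))
  cand <- expand.grid(X1 = c(-1, 0, 1), X2 = c(-1, 0, 1))
  d <- d_optimal_design(facs, terms = c("X1", "X2"), n_runs = 4,
                        candidates = cand, n_restarts = 5, seed = 3)
  # exhaustive oracle over all C(9,4) = 126 distinct subsets
  F <- cbind(1, as.matrix(cand))
  best <- max(apply(combn(9, 4), 2, function(rows)
    det(crossprod(F[rows, ]))))
  expect_equal(exp(attr(d, "log_det")), best, tolerance = 1e-8)
  # the optimum is the four corners
  pts <- d$runs[order(d$runs$X1, d$runs$X2), c("X1", "X2")]
  expect_equal(as.matrix(pts),
               matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), 4, 2,
                      dimnames = list(NULL, c("X1", "X2"))),
               ignore_attr = TRUE)
})

test_that("D-optimal objective is monotone and handles edge cases", {
  d <- d_optimal_design(ce_factors(), terms = quadratic_terms(c("CE", "CID")),
                        n_runs = 14, seed = 1, n_restarts = 5)
  for (tr in attr(d, "objective_trace"))
    expect_true(all(diff(tr) >= -1e-9))
  # n_runs = |candidates| returns the full candidate set
  facs <- list(unit_factor("X1"))
  cand <- data.frame(X1 = c(-1, 0, 1))
  d2 <- d_optimal_design(facs, terms = "X1", n_runs = 3, candidates = cand,
                         n_restarts = 2, seed = 1)
  expect_setequal(d2$runs$X1, c(-1, 0, 1))
  expect_error(d_optimal_design(facs, terms = c("X1", "X1^2"), n_runs = 2,
                                candidates = cand),
               "rank", ignore.case = TRUE)
  # reproducible for a fixed seed
  d3 <- d_optimal_design(ce_factors(), terms = quadratic_terms(c("CE", "CID")),
                         n_runs = 14, seed = 1, n_restarts = 5)
  expect_identical(d$runs, d3$runs)
})

test_that("seeded D-optimal beats 100 random 14-run subsets on the CE grid", {
  d <- d_optimal_design(ce_factors(), terms = quadratic_terms(c("CE", "CID")),
                        n_runs = 14, seed = 1, n_restarts = 5)
  cand <- candidate_grid(ce_factors())
  cf <- cand
  for (f in names(ce_factors())) cf[[f]] <- code_level(ce_factors()[[f]], cand[[f]])
  F <- build_model_matrix(as.matrix(cf), quadratic_terms(c("CE", "CID")))
  set.seed(99)
  for (i in 1:100) {
    rows <- sample.int(nrow(F), 14)
    ld <- determinant(crossprod(F[rows, ]), logarithm = TRUE)
    rnd <- if (ld$sign <= 0) -Inf else as.numeric(ld$modulus)
    expect_true(attr(d, "log_det") >= rnd - 1e-9)
  }
})
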