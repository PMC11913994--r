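# Response-surface fitting, diagnostics and backward refinement.

test_that("model matrix columns follow the coded-unit conventions", {
  d <- ccd_design(optimization_factors())
  X <- build_model_matrix(d, quadratic_terms(names(d$factors)))
  ctr <- d$runs$point_type == "center"
  expect_true(all(X[ctr, colnames(X) != "(Intercept)"] == 0))
  expect_true(all(X[, "(Intercept)"] == 1))
  # sign rule for interactions
  Xi <- build_model_matrix(matrix(c(1, -1), 1, 2,
                                  dimnames = list(NULL, c("IntT", "CID"))),
                           c("IntT", "CID", "IntT:CID"))
  expect_equal(unname(Xi[1, "IntT:CID"]), -1)
  # orthogonality of linear terms on the 16-run factorial block
  f <- ffd_design(screening_factors())
  Xf <- build_model_matrix(f, linear_terms(names(f$factors)))
  Xf <- Xf[f$runs$point_type == "factorial", ]
  expect_equal(crossprod(Xf), diag(16, 8), ignore_attr = TRUE)
  expect_error(build_model_matrix(d, c("CID", "Nope")), "unknown factor")
})

test_that("noise-free log-quadratic responses are recovered exactly", {
  d <- ccd_design(optimization_factors())
  surf <- oxylipin_surfaces()
  resp <- simulate_responses(d, surf, seed = 1, noise_cv = 0)
  fit <- rsm_fit(d, resp, analyte = "PGE2-d4", transform = "log")
  truth <- surf$surfaces[["PGE2-d4"]]$coef
  truth <- truth[!names(truth) %in% c("HG", "DG", "HB", "DL")]
  expect_equal(fit$coefficients[names(truth)], truth, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               log(surf$surfaces[["PGE2-d4"]]$H0), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$q2, 1, tolerance = 1e-10)
})

test_that("a single perturbed replicate shifts the intercept by d/(2n)", {
  d <- ffd_design(screening_factors())
  resp <- make_responses(d, rep(10, 19), n_replicates = 2)
  delta <- 3
  resp$height[resp$run_id == 5 & resp$replicate == 2] <-
    resp$height[resp$run_id == 5 & resp$replicate == 2] + delta
  fit <- rsm_fit(d, resp, terms = linear_terms(names(d$factors)))
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               10 + (delta / 2) / 19, tolerance = 1e-10)
})

test_that("fitting mutually confounded interactions names the alias group", {
  d <- ffd_design(screening_factors())
  resp <- make_responses(d, seq_len(19) + 10, n_replicates = 2)
  # A = IntV, B = IntT, C = HG, E = HB: AB is confounded with CE (= HG:HB)
  err <- tryCatch(
    rsm_fit(d, resp, terms = c(linear_terms(names(d$factors)),
                               "IntV:IntT", "HG:HB")),
    error = function(e) e)
  expect_s3_class(err, "ionopt_aliased_error")
  expect_true(any(vapply(err$aliased, function(g)
    all(c("IntV:IntT", "HG:HB") %in% g), TRUE)))
})

test_that("lack of fit matches the pencil-and-paper 8-point decomposition", {
  # runs at x = -1, 0, 1, 2 with duplicate responses; straight-line model
  d <- line_design(c(-1, 0, 1, 2))
  y <- matrix(c(0, 1, 4, 9,
                2, 3, 6, 11), ncol = 2)
  resp <- make_responses(d, y)
  fit <- rsm_fit(d, resp, terms = "X")
  # hand arithmetic: slope 3, intercept 3, SS_res 16, SS_pe 8 (df 4),
  # SS_lof 8 (df 2), F = (8/2)/(8/4) = 2
  expect_equal(unname(fit$coefficients), c(3, 3), tolerance = 1e-12)
  lof <- lack_of_fit(fit)
  expect_equal(lof$ss_pe, 8)
  expect_equal(lof$ss_lof, 8)
  expect_equal(lof$F, 2)
  expect_equal(lof$p, pf(2, 2, 4, lower.tail = FALSE))
  # ANOVA conservation: SS_tot = SS_model + SS_lof + SS_pe
  ss_tot <- sum((resp$height - mean(resp$height))^2)
  ss_model <- ss_tot - sum(fit$residuals^2)
  expect_equal(ss_tot, ss_model + lof$ss_lof + lof$ss_pe)
})

test_that("lack of fit flags cubic contamination and passes clean data", {
  d <- line_design(c(-1, -0.5, 0, 0.5, 1))
  # replicate-noise-only data: on-surface responses, p should not be small
  set.seed(4)
  mu <- 2 + 0.5 * d$runs$X
  y <- cbind(mu + rnorm(5, 0, 0.1), mu + rnorm(5, 0, 0.1))
  fit <- rsm_fit(d, make_responses(d, y), terms = "X")
  expect_gt(lack_of_fit(fit)$p, 0.01)
  # strong cubic contamination: significant in >= 95 % of seeded simulations
  hits <- 0
  for (s in 1:200) {
    set.seed(s)
    yy <- cbind(mu + 1.5 * d$runs$X^3 + rnorm(5, 0, 0.1),
                mu + 1.5 * d$runs$X^3 + rnorm(5, 0, 0.1))
    f2 <- rsm_fit(d, make_responses(d, yy), terms = "X")
    hits <- hits + (lack_of_fit(f2)$p < 0.05)
  }
  expect_gte(hits / 200, 0.95)
  # exact surface with identical replicates has no pure error df -> error
  exact <- make_responses(d, mu, n_replicates = 1)
  f3 <- rsm_fit(d, exact, terms = "X")
  expect_error(lack_of_fit(f3), "pure-error")
})

test_that("Q2 equals an explicit leave-one-out refit loop and Q2 <= R2", {
  d <- line_design(c(1, 2, 3, 4, 5) / 2 - 1.5)
  y <- c(1.1, 1.9, 3.2, 4.0, 9.0)  # line with an outlier
  fit <- rsm_fit(d, make_responses(d, y), terms = "X")
  x <- d$runs$X
  press <- 0
  for (i in seq_along(y)) {
    cf <- coef(lm(y[-i] ~ x[-i]))
    press <- press + (y[i] - cf[1] - cf[2] * x[i])^2
  }
  q2_loo <- 1 - press / sum((y - mean(y))^2)
  expect_equal(q2_press(fit), unname(q2_loo), tolerance = 1e-10)
  expect_lte(fit$q2, fit$r2)
  # property: Q2 <= R2 for random data under a fixed seed
  set.seed(11)
  for (i in 1:20) {
    yy <- rnorm(5)
    f <- rsm_fit(d, make_responses(d, yy), terms = "X")
    expect_lte(f$q2, f$r2 + 1e-12)
  }
})

test_that("reproducibility follows the mean-square convention", {
  d <- line_design(c(-1, 0, 1))
  # identical replicates -> 1
  f1 <- rsm_fit(d, make_responses(d, cbind(c(1, 2, 3), c(1, 2, 3))),
                terms = "X")
  expect_equal(reproducibility(f1), 1)
  # constructed so MS_pe equals MS_total exactly -> 0
  d2 <- line_design(c(-1, 1))
  delta <- sqrt(2)
  y <- cbind(c(0 - 1, delta - 1), c(0 + 1, delta + 1))
  f2 <- rsm_fit(d2, make_responses(d2, y), terms = "X")
  expect_equal(reproducibility(f2), 0, tolerance = 1e-12)
  # single replicate everywhere -> not computable
  f3 <- rsm_fit(d, make_responses(d, c(1, 2, 3)), terms = "X")
  expect_error(reproducibility(f3), "not computable")
  # matches a direct sums-of-squares recomputation on synthetic CCD data
  cc <- ccd_design(optimization_factors())
  resp <- simulate_responses(cc, seed = 7)
  fit <- rsm_fit(cc, resp, analyte = "LTB4-d4", transform = "log")
  yv <- log(resp$height[resp$analyte == "LTB4-d4"])
  run <- resp$run_id[resp$analyte == "LTB4-d4"]
  ss_pe <- sum((yv - ave(yv, run))^2)
  expect_equal(reproducibility(fit),
               1 - (ss_pe / (length(yv) - 17)) / var(yv), tolerance = 1e-10)
})

test_that("backward refinement prunes noise terms and respects heredity", {
  cc <- ccd_design(optimization_factors())
  X <- build_model_matrix(cc, quadratic_terms(names(cc$factors)))
  # ground truth drives the response through IntT and CID only; a
  # main-effects model refines to exactly {IntT, CID} in >= 90 % of runs,
  # and with the full quadratic candidate set the true terms are never lost
  keep <- c("CID", "IntT", "CID^2", "IntT^2")
  hits_main <- 0; hits_keep <- 0
  for (s in 1:200) {
    set.seed(s)
    mu <- 5 + X[, "CID"] * 0.4 + X[, "IntT"] * 0.3 -
      0.25 * X[, "CID^2"] - 0.2 * X[, "IntT^2"]
    y <- cbind(mu + rnorm(17, 0, 0.04), mu + rnorm(17, 0, 0.04))
    resp <- make_responses(cc, y)
    fmain <- refine_rsm(rsm_fit(cc, resp,
                                terms = linear_terms(names(cc$factors))))
    hits_main <- hits_main +
      setequal(setdiff(fmain$terms, "(Intercept)"), c("CID", "IntT"))
    ffull <- refine_rsm(rsm_fit(cc, resp))
    hits_keep <- hits_keep + all(keep %in% ffull$terms)
  }
  expect_gte(hits_main / 200, 0.9)
  expect_gte(hits_keep / 200, 0.99)
})

test_that("refinement handles pure noise, weak-heredity and is idempotent", {
  cc <- ccd_design(optimization_factors())
  # pure noise: each null term survives backward elimination with roughly
  # the 5 % test size, so the modal outcome is the intercept-only model
  n_int_only <- 0
  for (s in 1:100) {
    set.seed(s)
    y <- cbind(rnorm(17, 10, 0.5), rnorm(17, 10, 0.5))
    fit <- refine_rsm(rsm_fit(cc, make_responses(cc, y)))
    n_int_only <- n_int_only + identical(fit$terms, "(Intercept)")
  }
  expect_gte(n_int_only / 100, 0.5)
  # strong IntT:CID interaction with a negligible IntT main effect:
  # IntT stays in the model by weak heredity
  X <- build_model_matrix(cc, quadratic_terms(names(cc$factors)))
  set.seed(5)
  mu <- 5 + 0.5 * X[, "CID"] + 0.001 * X[, "IntT"] + 0.4 * X[, "CID:IntT"]
  y2 <- cbind(mu + rnorm(17, 0, 0.03), mu + rnorm(17, 0, 0.03))
  f2 <- refine_rsm(rsm_fit(cc, make_responses(cc, y2)))
  expect_true("CID:IntT" %in% f2$terms)
  expect_true("IntT" %in% f2$terms)
  # idempotence
  f3 <- refine_rsm(f2)
  expect_identical(f3$terms, f2$terms)
  expect_equal(f3$coefficients, f2$coefficients)
})

test_that("prediction back-transforms, warns on extrapolation, finds optima", {
  cc <- ccd_design(optimization_factors())
  resp <- simulate_responses(cc, seed = 3)
  fit <- rsm_fit(cc, resp, analyte = "PGE2-d4", transform = "log")
  ctr <- data.frame(CID = 195, IntT = 350, IntV = 2.5)
  expect_equal(predict(fit, ctr),
               exp(unname(fit$coefficients["(Intercept)"])))
  p <- predict(fit, ctr, se.fit = TRUE)
  expect_true(p$se.fit > 0)
  expect_warning(predict(fit, data.frame(CID = 400, IntT = 350, IntV = 2.5)),
                 "extrapolation")
  # pure quadratic f = 1 - x^2 has its stationary point at the centre
  m <- rsm_model(c("(Intercept)" = 1, "X" = 0, "X^2" = -1),
                 list(unit_factor("X")))
  xs <- seq(-1, 1, by = 0.01)
  pr <- predict(m, data.frame(X = xs))
  expect_equal(xs[which.max(pr)], 0)
  # on the calibrated synthetic fit, the PGE2 CID optimum at 2 kV lies in
  # the 210-270 kPa window
  grid <- data.frame(CID = seq(140, 250, by = 1), IntT = 380, IntV = 2)
  pg <- predict(fit, grid)
  cid_opt <- grid$CID[which.max(pg)]
  expect_gte(cid_opt, 210)
  expect_lte(cid_opt, 270)
})

test_that("screening fits expose a lumped curvature contrast", {
  d <- ffd_design(screening_factors())
  resp <- simulate_responses(d, seed = 1)
  fit <- rsm_fit(d, resp, analyte = "PGE2-d4",
                 terms = c(linear_terms(names(d$factors)), "curvature"),
                 transform = "log")
  expect_true("curvature" %in% fit$terms)
  # the ground truth is curved, so the contrast is significant
  i <- match("curvature", fit$terms)
  expect_gt(abs(fit$coefficients[i]), fit$ci95[i])
  expect_error(build_model_matrix(matrix(0, 1, 1, dimnames = list(NULL, "X")),
                                  c("X", "curvature")),
               "curvature")
})
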