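test_that("quadratic root classifier reproduces constructed reference cases", {
  cases <- list(
    # interior (non-boundary) cases, roots stated in the comments
    list(0, 0.25, "both_inside"),                        # +-0.5i
    list(0, -2, "one_beyond_one_other_below_minus_one"), # +-sqrt(2)
    list(-3.5, 1.5, "one_beyond_one_other_inside"),      # 0.5 and 3
    list(1.6, -0.4, "split_inside_outside"),             # approx -1.8, 0.2
    list(-3, 2.5, "both_outside"),                       # complex, |.|^2 = 2.5
    # boundary cases, exact equalities
    list(-3, 2, "root_at_one_other_outside"),            # 1 and 2
    list(-1.5, 0.5, "root_at_one_other_inside"),         # 1 and 0.5
    list(0, -1, "root_at_one_other_on"),                 # 1 and -1
    list(0.5, -0.5, "one_on_minus_one"),                 # -1 and 0.5
    list(2, 1, "double_minus_one"),                      # -1 double
    list(0, 1, "conjugate_on_unit_circle"),              # +-i
    list(-1, -2, "one_beyond_one_other_at_minus_one"))   # 2 and -1
  for (cs in cases) {
    got <- classify_quadratic_roots(cs[[1]], cs[[2]])
    expect_identical(got$case_label, cs[[3]])
  }
  # boundary flag raised exactly on the constructed equality cases
  expect_false(classify_quadratic_roots(0, 0.25)$boundary_flag)
  expect_true(classify_quadratic_roots(-3, 2)$boundary_flag)
  expect_true(classify_quadratic_roots(0, 1 + 1e-12)$boundary_flag)
  expect_error(classify_quadratic_roots(NaN, 1), "finite")
})

test_that("classifier agrees with the numerically-solved-roots oracle on random coefficients", {
  set.seed(2024)
  B <- runif(10000, -3, 3); C <- runif(10000, -3, 3)
  for (k in seq_along(B)) {
    got <- classify_quadratic_roots(B[k], C[k])
    if (!got$boundary_flag)
      expect_identical(got$case_label, oracle_classify(B[k], C[k]))
  }
})

test_that("epsilon0 closed form, sign relation and domain errors", {
  expect_equal(epsilon0(16/11, 0.5), 0.5, tolerance = 1e-14)
  expect_equal(epsilon0(1.4, 0.5), 2/7, tolerance = 1e-14)
  expect_lt(epsilon0(1, 0.3), 0)                        # numerator = -delta^2
  set.seed(5)
  for (k in 1:200) {
    a <- runif(1, 0.3, 3); d <- runif(1, 0.05, 0.95)
    e0 <- epsilon0(a, d)
    expect_identical(e0 <= 0, d^2 >= (a - 1) / a)
  }
  expect_error(epsilon0(1.4, 1), "delta")
  expect_error(epsilon0(1.4, 0), "delta")
  expect_error(epsilon0(-2, 0.5), "'a'")
})

test_that("delta_star solves the cubic on the required bracket", {
  for (a in c(1.05, 1.4, 16/11, 2, 3)) {
    ds <- delta_star(a)
    cc <- (a - 1) / a
    expect_lt(abs(ds^3 - ds^2 + ds - cc), 1e-12)
    expect_gt(ds, cc); expect_lt(ds, sqrt(cc))
    expect_equal(ds, bisect_delta_star(a), tolerance = 1e-10)
  }
  expect_equal(delta_star(1.4), 0.3729, tolerance = 1e-3)
  expect_equal(delta_star(16/11), 0.4125, tolerance = 1e-3)
  expect_lt(delta_star(1 + 1e-4), 1e-3)   # delta_star -> 0 as a -> 1+
  expect_error(delta_star(1), "a > 1")
})

test_that("fixed-point verdicts follow the stability theorems", {
  expect_identical(
    classify_fixed_point(list(label = "E0"), model_params(2, 0.7, 0.3))$label,
    "saddle")
  p_lo <- model_params(1.4, 0.5, 0.5)
  p_eq <- model_params(1.4, 1, 0.5)
  p_hi <- model_params(1.4, 1.5, 0.5)
  e1 <- function(p) classify_fixed_point(fixed_points(p)$E1, p)
  expect_identical(e1(p_lo)$label, "saddle")
  expect_identical(e1(p_eq)$label, "non_hyperbolic")
  expect_identical(e1(p_hi)$label, "stable_node")

  e2v <- function(a, d, e)
    classify_fixed_point(fixed_points(model_params(a, d, e))$E2,
                         model_params(a, d, e))$label
  expect_identical(e2v(0.8, 0.5, 0.3), "sink")         # a <= 1 case
  expect_identical(e2v(16/11, 0.5, 0.3), "source")     # eps below eps0 = 0.5
  expect_identical(e2v(16/11, 0.5, 0.7), "sink")       # eps above eps0
  expect_identical(e2v(16/11, 0.5, 0.5), "non_hyperbolic")
  expect_identical(e2v(1.4, 0.9, 0.1), "sink")         # delta > sqrt((a-1)/a)
  expect_error(
    classify_fixed_point(list(label = "E2"), model_params(2, 0.4, 0.5)),
    "does not exist")
})

test_that("E2 verdict agrees with eigenvalue moduli of the simplified Jacobian", {
  set.seed(77)
  pars <- sample_e2_pairs(1000)
  for (k in seq_len(nrow(pars))) {
    p <- model_params(pars[k, 1], pars[k, 2], runif(1, 0.05, 0.95))
    v <- classify_fixed_point(fixed_points(p)$E2, p)
    m <- Mod(eigen(jacobian_at_e2(p), only.values = TRUE)$values)
    expected <- if (all(m < 1)) "sink" else if (all(m > 1)) "source" else NA
    if (!v$boundary_flag && !is.na(expected))
      expect_identical(v$label, expected)
  }
})

test_that("characteristic polynomial at E2: F(1) > 0, F(-1) > 0, and q vs 1 tracks eps vs eps0", {
  set.seed(88)
  pars <- sample_e2_pairs(300)
  for (k in seq_len(nrow(pars))) {
    a <- pars[k, 1]; d <- pars[k, 2]; e <- runif(1, 0.05, 0.95)
    J <- jacobian_at_e2(model_params(a, d, e))
    pp <- sum(diag(J)); qq <- det(J)
    expect_gt(1 - pp + qq, 0)   # F(1)
    expect_gt(1 + pp + qq, 0)   # F(-1)
    e0 <- epsilon0(a, d)
    if (abs(e - e0) > 1e-9) expect_identical(qq > 1, e < e0)
  }
})

test_that("critical_values bundles the three surfaces consistently", {
  cv <- critical_values(16/11, 0.5)
  expect_equal(cv$epsilon0, 0.5, tolerance = 1e-14)
  expect_equal(cv$delta_sqrt, sqrt(5/16), tolerance = 1e-14)
  expect_gt(cv$delta_star, (16/11 - 1) / (16/11))
  cv1 <- critical_values(0.8, 0.5)
  expect_true(is.na(cv1$delta_star) && is.na(cv1$delta_sqrt))
  expect_lt(cv1$epsilon0, 0)
})
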