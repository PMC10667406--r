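test_that("eigen path: q(0) = 1, complex pair, closed-form transversality", {
  ep <- eigen_path(16/11, 0.5)
  expect_equal(ep$q_of(0), 1, tolerance = 1e-12)
  expect_lt(ep$p_of(0)^2 - 4 * ep$q_of(0), 0)
  expect_equal(ep$eps0, 0.5, tolerance = 1e-14)
  expect_equal(Mod(ep$lambda_of(0))[1], 1, tolerance = 1e-12)
  expect_equal(eigen_path(1.4, 0.5)$modulus_derivative_at_0, -0.0875,
               tolerance = 1e-14)

  set.seed(21)
  pars <- sample_ns_pairs(100)
  for (k in seq_len(nrow(pars))) {
    ep <- eigen_path(pars[k, 1], pars[k, 2])
    expect_lt(abs(ep$q_of(0) - 1), 1e-10)
    expect_lt(ep$p_of(0)^2 - 4, 0)                 # |p(0)| < 2
    expect_lt(ep$modulus_derivative_at_0, 0)
    expect_equal(ep$alpha1^2 + ep$alpha2^2, 1, tolerance = 1e-10)
    # determinant of the simplified Jacobian at criticality equals q(0)
    p <- model_params(pars[k, 1], pars[k, 2], min(max(ep$eps0, 0.01), 0.99))
    if (ep$eps0 > 0 && ep$eps0 < 1) {
      p$epsilon <- ep$eps0
      expect_equal(det(jacobian_at_e2(p)), ep$q_of(0), tolerance = 1e-12)
    }
  }
})

test_that("transversality closed form matches the numerical modulus derivative", {
  set.seed(22)
  pars <- sample_ns_pairs(20)
  h <- 1e-5
  for (k in seq_len(nrow(pars))) {
    ep <- eigen_path(pars[k, 1], pars[k, 2])
    mod_of <- function(es) Mod(ep$lambda_of(es))[1]
    fd <- (mod_of(h) - mod_of(-h)) / (2 * h)
    expect_lt(abs(fd - ep$modulus_derivative_at_0), 1e-6)
  }
})

test_that("eigen_path names the violated region inequality", {
  expect_error(eigen_path(0.9, 0.3), "a > 1")
  expect_error(eigen_path(2, 0.3), "delta_star")
  expect_error(eigen_path(2, 0.8), "sqrt")
})

test_that("no strong resonances at criticality for the canonical configuration", {
  nd <- nondegeneracy_check(16/11, 0.5)
  expect_true(all(nd))
  expect_named(nd, c("m1", "m2", "m3", "m4"))
  set.seed(23)
  pars <- sample_ns_pairs(20)
  for (k in seq_len(nrow(pars)))
    expect_length(nondegeneracy_check(pars[k, 1], pars[k, 2]), 4L)
})

test_that("shifted-map Taylor table: linear part equals the simplified Jacobian", {
  set.seed(24)
  pars <- sample_ns_pairs(6)
  for (k in seq_len(nrow(pars))) {
    a <- pars[k, 1]; d <- pars[k, 2]
    e0 <- epsilon0(a, d)
    if (e0 <= 0 || e0 >= 1) next
    co <- taylor_coefficients_e2(model_params(a, d, e0))
    expect_equal(co$c[["c10"]], a * (1 - d^2), tolerance = 1e-10)
    expect_equal(co$c[["c01"]], -a * d^2, tolerance = 1e-10)
    expect_equal(co$d[["d10"]], e0 * (1 - d)^2, tolerance = 1e-10)
    expect_equal(co$d[["d01"]], 1 - d * e0 * (1 - d), tolerance = 1e-10)
  }
})

test_that("all shifted-map series coefficients agree with a finite-difference oracle", {
  for (pars in list(c(16/11, 0.5), c(1.4, 0.5))) {
    a <- pars[1]; d <- pars[2]
    e0 <- epsilon0(a, d)
    p <- model_params(a, d, e0)
    co <- taylor_coefficients_e2(p)
    x0 <- 1 - a + a * d; y0 <- x0 * (1 - d) / d
    shifted <- function(u, v) map_step(c(u + x0, v + y0), p) - c(x0, y0)
    fit <- fd_series_coeffs(shifted)
    for (nm in names(fit$c)) {
      expect_equal(co$c[[paste0("c", nm)]], fit$c[[nm]], tolerance = 1e-6)
      expect_equal(co$d[[paste0("d", nm)]], fit$d[[nm]], tolerance = 1e-6)
    }
    expect_equal(shifted(0, 0), c(0, 0), tolerance = 1e-14)  # E2 fixed
  }
})

test_that("normal-form transform yields the rotation linear part and no low-order terms", {
  co <- taylor_coefficients_e2(model_params(16/11, 0.5, 0.5))
  ep <- eigen_path(16/11, 0.5)
  nf <- normal_form_transform(co, ep$alpha1, ep$alpha2)
  rot <- matrix(c(ep$alpha1, -ep$alpha2, ep$alpha2, ep$alpha1), 2, 2,
                byrow = TRUE)
  expect_lt(max(abs(nf$linear - rot)), 1e-10)
  # second partials encode the e/f tables: Fbar_XX = 2 e20 etc.
  expect_equal(nf$partials$FXX, 2 * nf$e[["e20"]], tolerance = 1e-14)
  expect_equal(nf$partials$GYY, 2 * nf$f[["f02"]], tolerance = 1e-14)
  expect_error(normal_form_transform(co, ep$alpha1, 0), "alpha2")
})

test_that("a linear map has degenerate normal-form coefficients (L = 0)", {
  co <- taylor_coefficients_e2(model_params(16/11, 0.5, 0.5))
  co$c[!(names(co$c) %in% c("c10", "c01"))] <- 0
  co$d[!(names(co$d) %in% c("d10", "d01"))] <- 0
  ep <- eigen_path(16/11, 0.5)
  nf <- normal_form_transform(co, ep$alpha1, ep$alpha2)
  z <- slowfastpp:::ns_zetas(nf$partials)
  lam1 <- complex(real = ep$alpha1, imaginary = ep$alpha2)
  expect_identical(slowfastpp:::ns_L_from_zetas(z, lam1), 0)
})

test_that("discriminant pipeline agrees with the Fourier circle-sampling oracle", {
  co <- ns_discriminant(model_params(16/11, 0.5, 0.5))
  expect_lt(co$L, 0)                       # attracting curve on the unstable side
  expect_equal(co$L, -0.0176911, tolerance = 1e-4)
  orc <- oracle_ns_L(16/11, 0.5)
  expect_equal(co$zeta20, orc$zeta20, tolerance = 1e-5)
  expect_equal(co$zeta11, orc$zeta11, tolerance = 1e-5)
  expect_equal(co$zeta02, orc$zeta02, tolerance = 1e-5)
  expect_equal(co$zeta21, orc$zeta21, tolerance = 1e-4)

  set.seed(26)
  pars <- sample_ns_pairs(25)
  done <- 0
  for (k in seq_len(nrow(pars))) {
    if (done >= 10) break
    a <- pars[k, 1]; d <- pars[k, 2]
    e0 <- epsilon0(a, d)
    if (e0 <= 0 || e0 >= 1) next
    L_pkg <- ns_discriminant(model_params(a, d, e0))$L
    L_orc <- oracle_ns_L(a, d)$L
    expect_identical(sign(L_pkg), sign(L_orc))
    expect_equal(L_pkg, L_orc, tolerance = 1e-3)
    done <- done + 1
  }
  expect_gte(done, 10)
})

test_that("epsilon supplied away from criticality is ignored with a warning", {
  expect_warning(taylor_coefficients_e2(model_params(16/11, 0.5, 0.3)),
                 "epsilon0")
})

test_that("ns_report assembles verdict and side bookkeeping", {
  r <- ns_report(16/11, 0.5)
  expect_true(r$transversal_ok)
  expect_true(r$nondegenerate_ok)
  expect_equal(r$eps0, 0.5, tolerance = 1e-14)
  expect_identical(r$params$epsilon, r$eps0)
  expect_identical(r$verdict, "supercritical_attracting_curve_for_eps_below")
  # the opposite-side clause quoted for this family does not match the
  # resolved crossing direction; recorded, not adopted
  expect_false(r$paper_statement_agrees)
  r2 <- ns_report(1.4, 0.5)
  expect_equal(r2$eps0, 2/7, tolerance = 1e-14)
  expect_error(ns_report(0.8, 0.5), "a > 1")
})
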