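test_that("Adomian levels are the bilinear convolution", {
  sys <- default_system()
  sol <- ntdm_solve(sys, kernel_spec("caputo", mu = 1), K = 2)
  # level 0 of V*T is the constant V0*T0 = 800
  a0 <- adomian_level(sol$components, p = 1, q = 3, k = 0)
  expect_equal(tidy(a0), tibble::tibble(a = 0L, b = 0L, coef = 800))
  # level 1 is V0*T1 + V1*T0
  a1 <- adomian_level(sol$components, p = 1, q = 3, k = 1)
  want <- fs_add(fs_multiply(sol$components$V[[1]], sol$components$T[[2]]),
                 fs_multiply(sol$components$V[[2]], sol$components$T[[1]]))
  expect_equal(a1, want)
  # zero factors give the empty series
  zero_sys <- frac_ode_system(c("x", "y"), constants = c(0, 0),
                              linear = matrix(0, 2, 2),
                              bilinear = tibble::tibble(target = 1, p = 1,
                                                        q = 2, coef = 1),
                              initial = c(0, 1))
  zsol <- ntdm_solve(zero_sys, kernel_spec("caputo", 0.5), K = 1)
  expect_length(adomian_level(zsol$components, 1, 2, 1)$coef, 0L)
  expect_error(adomian_level(sol$components, 1, 3, 5), "not yet computed")
})

test_that("first recursion levels match hand-derived components", {
  sys <- default_system()
  mu <- 0.8
  # Caputo: V1 = -113 tau^mu / Gamma(1+mu)
  sol <- ntdm_solve(sys, kernel_spec("caputo", mu), K = 1)
  expect_equal(tidy(sol$components$V[[2]]),
               tibble::tibble(a = 0L, b = 1L, coef = -113 / gamma(1 + mu)),
               tolerance = 1e-12)
  # CF: W1 = 1.35 (1 - mu + mu tau)
  solcf <- ntdm_solve(sys, kernel_spec("cf", mu), K = 1)
  expect_equal(tidy(solcf$components$W[[2]]),
               tibble::tibble(a = c(0L, 1L), b = c(0L, 0L),
                              coef = c(1.35 * (1 - mu), 1.35 * mu)),
               tolerance = 1e-12)
  # ABC: V1 = -113 [1 - mu + mu tau^mu / Gamma(1+mu)]
  solabc <- ntdm_solve(sys, kernel_spec("abc", mu), K = 1)
  expect_equal(tidy(solabc$components$V[[2]]),
               tibble::tibble(a = c(0L, 0L), b = c(0L, 1L),
                              coef = c(-113 * (1 - mu),
                                       -113 * mu / gamma(1 + mu))),
               tolerance = 1e-12)
})

test_that("an all-zero system stays at its initial state", {
  sys <- frac_ode_system(c("x", "y"), constants = c(0, 0),
                         linear = matrix(0, 2, 2), initial = c(3, -1))
  sol <- ntdm_solve(sys, kernel_spec("abc", 0.6), K = 4)
  for (k in 2:5) {
    expect_length(sol$components$x[[k]]$coef, 0L)
    expect_length(sol$components$y[[k]]$coef, 0L)
  }
  expect_equal(evaluate_solution(sol, "x", c(0, 0.5, 2)), c(3, 3, 3))
})

test_that("K = 0 partial sums equal the initial values everywhere", {
  sys <- default_system()
  for (kern in c("caputo", "cf", "abc")) {
    sol <- ntdm_solve(sys, kernel_spec(kern, 0.7), K = 0)
    for (i in 1:5) {
      expect_equal(evaluate_solution(sol, i, c(0, 0.25, 0.5)),
                   rep(sys$initial[i], 3))
    }
  }
})

test_that("solve is deterministic: repeated calls are bit-identical", {
  sys <- default_system()
  s1 <- ntdm_solve(sys, kernel_spec("abc", 0.8), K = 3)
  s2 <- ntdm_solve(sys, kernel_spec("abc", 0.8), K = 3)
  expect_identical(s1, s2)
})

test_that("order-k components never exceed k operator applications", {
  sys <- default_system()
  for (mu in c(0.5, 0.9)) {
    solc <- ntdm_solve(sys, kernel_spec("caputo", mu), K = 3)
    solf <- ntdm_solve(sys, kernel_spec("cf", mu), K = 3)
    sola <- ntdm_solve(sys, kernel_spec("abc", mu), K = 3)
    for (i in 1:5) {
      for (k in 0:3) {
        expect_true(all(solc$components[[i]][[k + 1]]$b <= k))
        expect_true(all(solf$components[[i]][[k + 1]]$a <= k))
        expect_true(all(sola$components[[i]][[k + 1]]$b <= k))
      }
    }
  }
})

test_that("partial sums at tau = 0 return the initial values (Caputo)", {
  sys <- default_system()
  sol <- ntdm_solve(sys, kernel_spec("caputo", 0.8), K = 2)
  for (i in 1:5) {
    expect_equal(evaluate_solution(sol, i, 0), sys$initial[i])
  }
  expect_error(evaluate_solution(sol, "Z", 0.1), "unknown state")
  expect_error(evaluate_solution(sol, "V", 0.1, upto_k = 5), "upto_k")
})

test_that("mu = 1 partial sums coincide across the three kernels", {
  sys <- default_system()
  sols <- lapply(c("caputo", "cf", "abc"),
                 function(k) ntdm_solve(sys, kernel_spec(k, 1), K = 2))
  taus <- seq(0, 0.5, by = 0.1)
  for (i in 1:5) {
    vc <- evaluate_solution(sols[[1]], i, taus)
    expect_equal(evaluate_solution(sols[[2]], i, taus), vc,
                 tolerance = 1e-10)
    expect_equal(evaluate_solution(sols[[3]], i, taus), vc,
                 tolerance = 1e-10)
  }
})

test_that("level sums solve the scalar total-population recursion", {
  # Summing the five equations cancels all transfers: D^mu N = alpha -
  # vartheta N with N(0) = 85. Level components must match coefficient-wise.
  p <- smoking_parameters()
  sys <- smoking_system(p)
  scalar <- frac_ode_system("N", constants = p$alpha,
                            linear = matrix(-p$vartheta, 1, 1),
                            initial = sum(sys$initial))
  for (kern in c("caputo", "cf", "abc")) {
    for (mu in c(0.8, 1)) {
      sol <- ntdm_solve(sys, kernel_spec(kern, mu), K = 2)
      ssol <- ntdm_solve(scalar, kernel_spec(kern, mu), K = 2)
      for (k in 0:2) {
        lvl <- Reduce(fs_add,
                      lapply(sol$components, function(cs) cs[[k + 1]]),
                      fs_constant(0))
        expect_lt(fs_max_coef_diff(lvl, ssol$components$N[[k + 1]]), 1e-10)
      }
    }
  }
  # hand anchor: level-1 coefficient sum at mu = 1 is alpha - vartheta*85
  sol1 <- ntdm_solve(sys, kernel_spec("caputo", 1), K = 1)
  lvl1 <- Reduce(fs_add, lapply(sol1$components, function(cs) cs[[2]]),
                 fs_constant(0))
  expect_equal(lvl1$coef, -3.25, tolerance = 1e-12)
})

test_that("first-level sourcing reproduces the Maclaurin polynomial at mu = 1", {
  sys <- default_system()
  sol <- ntdm_solve(sys, kernel_spec("caputo", 1), K = 2,
                    source_mode = "first_level")
  rk <- rk4_classical(sys, t_end = 0.05, h = 1e-4)
  taus <- c(0.01, 0.02, 0.05)
  err <- vapply(taus, function(t) {
    abs(evaluate_solution(sol, "V", t) - rk$V[abs(rk$tau - t) < 1e-9])
  }, 0)
  expect_lt(abs(loglog_slope(taus, err) - 3), 0.3)
})

test_that("truncation diagnostic flags and refuses correctly", {
  sys <- default_system()
  sol0 <- ntdm_solve(sys, kernel_spec("caputo", 1), K = 0)
  expect_error(truncation_diagnostic(sol0), "at least two components")
  sol <- ntdm_solve(sys, kernel_spec("caputo", 1), K = 2)
  d <- truncation_diagnostic(sol, tau = c(0.01, 0.1, 0.5))
  v <- dplyr::filter(d$by_point, state == "V", tau == 0.01)
  expect_true(v$converged)
  expect_lt(v$ratio, 0.05)
  # ratio is monotone in tau when all components have one sign:
  # scalar growth D^mu x = x, x0 = 1 has all-positive components
  g <- frac_ode_system("x", 0, matrix(1, 1, 1), initial = 1)
  gd <- truncation_diagnostic(ntdm_solve(g, kernel_spec("caputo", 0.7), K = 3),
                              tau = seq(0.05, 1, by = 0.05))
  expect_true(all(diff(gd$by_point$ratio) >= 0))
})

test_that("solution export round-trips series and writes tidy CSV", {
  sys <- default_system()
  sol <- ntdm_solve(sys, kernel_spec("abc", 0.85), K = 2)
  json <- solution_to_json(sol)
  comp <- solution_from_json(json)
  taus <- seq(0, 0.5, by = 0.1)
  for (i in 1:5) {
    for (k in 1:3) {
      orig <- fs_evaluate(sol$components[[i]][[k]], taus, 0.85)
      back <- fs_evaluate(comp[[i]][[k]], taus, 0.85)
      expect_equal(back, orig, tolerance = 1e-15)
    }
  }
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_solution_csv(sol, path, tau = taus)
  re <- utils::read.csv(path)
  expect_equal(nrow(re), 5 * length(taus))
  expect_equal(re$value, df$value, tolerance = 1e-12)
  expect_named(re, c("tau", "state", "value", "kernel", "mu", "K"))
})

test_that("tidy, glance and autoplot summarise a solution", {
  sol <- ntdm_solve(default_system(), kernel_spec("cf", 0.9), K = 2)
  td <- tidy(sol, tau = c(0, 0.1))
  expect_equal(nrow(td), 10L)
  expect_equal(td$value[td$state == "V" & td$tau == 0],
               40 - 113 * (1 - 0.9) + fs_evaluate(sol$components$V[[3]], 0, 0.9))
  g <- glance(sol)
  expect_equal(g$kernel, "cf")
  expect_equal(g$n_states, 5L)
  expect_s3_class(autoplot(sol, tau = seq(0, 0.2, by = 0.1)), "ggplot")
})
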