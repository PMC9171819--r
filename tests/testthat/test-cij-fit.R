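test_that("gradient fits recover exact, flat and noisy lines, rejecting bad designs", {
  base <- tibble::tibble(chelator = "EDTA", metal = "Ca2+")

  # exact line of slope -0.5
  exact <- dplyr::mutate(base[rep(1, 5), ],
                         c_o = c(0, 10, 20, 30, 40), c_n = 65.9,
                         dg_sim = -30 - 0.5 * c_o)
  f <- fit_gradient(exact)
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$varied, "c_o")

  # flat response -> zero slope
  flat <- dplyr::mutate(exact, dg_sim = -30)
  expect_equal(fit_gradient(flat)$slope, 0, tolerance = 1e-12)

  # noisy line: slope must equal the closed-form normal-equations oracle
  set.seed(4)
  x <- c(0, 15, 34.4, 50, 70, 90)
  y <- -41 - 0.593 * x + rnorm(6, 0, 1)
  noisy <- tibble::tibble(chelator = "EDTA", metal = "Ca2+",
                          c_o = x, c_n = 65.9, dg_sim = y)
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fn <- fit_gradient(noisy)
  expect_equal(fn$slope, slope_oracle, tolerance = 1e-10)
  expect_equal(fn$intercept, mean(y) - slope_oracle * mean(x),
               tolerance = 1e-10)

  # anchored variant passes through the anchor observation
  fa <- fit_gradient(noisy, anchor = TRUE, anchor_at = 34.4)
  y0 <- y[abs(x - 34.4) < 1e-9]
  expect_equal(fa$intercept + fa$slope * 34.4, y0, tolerance = 1e-10)

  # degenerate and mixed designs are errors
  expect_error(fit_gradient(dplyr::mutate(exact, c_o = 10)), "degenerate")
  expect_error(fit_gradient(dplyr::mutate(exact, c_n = c_o)), "mixed")
  expect_error(fit_gradient(exact[1, ]), "two observations")
})

test_that("back-extrapolation reproduces the algebra and round trips through predict_dg", {
  g <- ca_gradient_set()
  expect_equal(g$dg_zero, -56.0 - (-0.593 * 34.4) - (-0.177 * 65.9),
               tolerance = 1e-12)

  # zero gradients: reference equals the default-parameter energy
  g0 <- gradient_set("EDTA", "Ca2+", 0, 0, -56.0, 34.4, 65.9)
  expect_equal(g0$dg_zero, -56.0)

  # exact round trip at the default C4 pair
  for (gs in all_gradient_sets()) {
    expect_equal(predict_dg(gs, gs$c_o_default, gs$c_n_default),
                 gs$dg_default, tolerance = 1e-12)
  }

  # prediction is strictly decreasing in c_o when m_o < 0
  expect_true(all(diff(predict_dg(g, seq(0, 100, 10), 65.9)) < 0))
})

test_that("reference rescaling follows the experimental ratio", {
  expect_equal(scale_reference_zero(-23.94, -60.8, -60.8), -23.94)
  expect_equal(scale_reference_zero(-23.94, -60.8, 0), 0)
  # frozen arithmetic oracle: -23.94 * (37.5 / 60.8)
  expect_equal(scale_reference_zero(-23.94, -60.8, -37.5), -14.766,
               tolerance = 5e-3)
  expect_error(scale_reference_zero(-23.94, 0, -37.5), "nonzero")
})

test_that("the two-chelator solve is exact, self-consistent and flags singularity", {
  g <- ca_gradient_set()
  fit <- solve_cij(g, -60.8, -37.5)

  # exactly determined: residuals vanish and the reference equation is
  # reproduced through predict_dg
  expect_lt(max(abs(fit$residuals)), 1e-9)
  expect_lt(abs(predict_dg(g, fit$c_o, fit$c_n) - (-60.8)), 1e-9)
  expect_true(fit$physical)

  # consistent-zero case: experimental energies already satisfied at (0, 0)
  dg0 <- g$dg_zero
  fit0 <- solve_cij(g, dg0, scale_reference_zero(dg0, dg0, dg0 * 0.6))
  expect_equal(fit0$c_o, 0, tolerance = 1e-9)
  expect_equal(fit0$c_n, 0, tolerance = 1e-9)

  # equal denticity ratios make the two rows proportional
  expect_error(solve_cij(g, -60.8, -37.5, ratios = denticity_ratios(1, 1)),
               "singular")
  expect_error(denticity_ratios(0, 0.5), "in \\(0, 1\\]")
  expect_error(denticity_ratios(3 / 4, 1.2), "in \\(0, 1\\]")
})

test_that("solve_cij recovers known coefficients from synthetic two-chelator systems", {
  set.seed(91)
  for (trial in 1:25) {
    g <- gradient_set(
      chelator = "REF", metal = "X",
      m_o = -runif(1, 0.2, 1.5), m_n = -runif(1, 0.02, 0.3),
      dg_default = -runif(1, 30, 160),
      c_o_default = runif(1, 20, 90), c_n_default = runif(1, 50, 170)
    )
    ratios <- denticity_ratios(runif(1, 0.55, 0.95), runif(1, 0.3, 0.5))
    c_star <- c(runif(1, 5, 60), runif(1, 20, 200))
    dg_exp_ref <- g$dg_zero + g$m_o * c_star[1] + g$m_n * c_star[2]
    # second chelator generated by the same denticity-scaled model:
    # other = zero*(other/ref) + rho_o m_o C_o + rho_n m_n C_n

    lin <- ratios$rho_o * g$m_o * c_star[1] + ratios$rho_n * g$m_n * c_star[2]
    dg_exp_other <- lin / (1 - g$dg_zero / dg_exp_ref)
    fit <- solve_cij(g, dg_exp_ref, dg_exp_other, ratios = ratios)
    expect_lt(abs(fit$c_o - c_star[1]), 1e-6)
    expect_lt(abs(fit$c_n - c_star[2]), 1e-6)
  }
})

test_that("solver agrees with a brute-force grid minimizer for all four metals", {
  # independent oracle: minimize the sum of squared residuals of the two
  # equations over C_O, C_N in [0, 300] at 0.05 resolution, scanning in
  # C_O chunks to bound memory. The grid minimizer can sit a few cells away
  # from the analytic solution along the valley of this ill-conditioned
  # quadratic, so agreement is asserted with the provable bound
  # cond(M) * dr on each coordinate, plus non-inferiority: no grid point
  # beats the analytic solution's residual.
  summary <- chbe_table1()
  dr_grid <- 0.05
  grid <- seq(0, 300, by = dr_grid)
  for (i in seq_len(nrow(summary))) {
    row <- summary[i, ]
    g <- gradient_set_from_summary(
      row, chbe_default_cij()[chbe_default_cij()$metal == row$metal, ])
    fit <- solve_cij(g, row$dg_exp_edta_kj_mol, row$dg_exp_nta_kj_mol)
    rhs1 <- row$dg_exp_edta_kj_mol - g$dg_zero
    rhs2 <- row$dg_exp_nta_kj_mol -
      scale_reference_zero(g$dg_zero, row$dg_exp_edta_kj_mol,
                           row$dg_exp_nta_kj_mol)
    best <- c(val = Inf, c_o = NA, c_n = NA)
    for (block in split(grid, ceiling(seq_along(grid) / 500))) {
      r1 <- outer(g$m_o * block, g$m_n * grid, "+") - rhs1
      r2 <- outer(0.75 * g$m_o * block, 0.5 * g$m_n * grid, "+") - rhs2
      ss <- r1^2 + r2^2
      k <- arrayInd(which.min(ss), dim(ss))
      if (ss[k] < best["val"]) {
        best <- c(val = ss[k], c_o = block[k[1]], c_n = grid[k[2]])
      }
    }
    # the analytic solution is never beaten by the exhaustive scan
    ss_fit <- (g$m_o * fit$c_o + g$m_n * fit$c_n - rhs1)^2 +
      (0.75 * g$m_o * fit$c_o + 0.5 * g$m_n * fit$c_n - rhs2)^2
    expect_lte(ss_fit, best[["val"]] + 1e-12)
    # and the grid minimizer localizes it up to the system's conditioning
    sv <- svd(rbind(c(g$m_o, g$m_n), c(0.75 * g$m_o, 0.5 * g$m_n)))$d
    bound <- (sv[1] / sv[2]) * dr_grid
    expect_lt(abs(fit$c_o - best[["c_o"]]), bound)
    expect_lt(abs(fit$c_n - best[["c_n"]]), bound)
    # the stiff (oxygen) coordinate resolves to a single cell
    expect_lt(abs(fit$c_o - best[["c_o"]]), dr_grid + 1e-9)
  }
})

test_that("direct solving with unreliable zero-C4 references flags non-physical solutions", {
  row <- chbe_table1()[chbe_table1()$metal == "Mg2+", ]
  def <- chbe_default_cij()[chbe_default_cij()$metal == "Mg2+", ]
  # use the directly simulated zero-C4 energies and each chelator's own
  # gradients, with no denticity substitution
  g_edta <- gradient_set("EDTA", "Mg2+",
                         m_o = row$m_o_edta_kj_mol_per_c4,
                         m_n = row$m_n_edta_kj_mol_per_c4,
                         dg_default = row$dg_sim_default_edta_kj_mol,
                         c_o_default = def$c_o_default_kcal_mol_A4,
                         c_n_default = def$c_n_default_kcal_mol_A4,
                         dg_zero = row$dg_sim_zero_edta_kj_mol)
  g_nta <- gradient_set("NTA", "Mg2+",
                        m_o = row$m_o_nta_kj_mol_per_c4,
                        m_n = row$m_n_nta_kj_mol_per_c4,
                        dg_default = row$dg_sim_default_nta_kj_mol,
                        c_o_default = def$c_o_default_kcal_mol_A4,
                        c_n_default = def$c_n_default_kcal_mol_A4,
                        dg_zero = row$dg_sim_zero_nta_kj_mol)
  fit <- solve_cij_direct(g_edta, g_nta,
                          row$dg_exp_edta_kj_mol, row$dg_exp_nta_kj_mol)
  expect_false(fit$physical)
  expect_lt(min(fit$c_o, fit$c_n), 0)
})

test_that("contour line is self-consistent and passes through the solved point", {
  g <- ca_gradient_set()
  grid <- seq(0, 120, by = 2.5)
  line <- contour_line(g, dg_target = -60.8, c_o_grid = grid)
  back <- predict_dg(g, line$c_o_kcal_mol_A4, line$c_n_kcal_mol_A4)
  expect_lt(max(abs(back - (-60.8))), 1e-9)

  fit <- solve_cij(g, -60.8, -37.5)
  on_line <- contour_line(g, -60.8, fit$c_o)
  expect_lt(abs(on_line$c_n_kcal_mol_A4 - fit$c_n), 1e-9)

  g_flat <- gradient_set("EDTA", "Ca2+", -0.5, 0, -56, 34.4, 65.9)
  expect_error(contour_line(g_flat, -60, grid), "degenerate")
})

test_that("multi-chelator least squares reduces to the 2x2 solve and fit_gradients recovers its generator", {
  g <- ca_gradient_set()
  lsq <- solve_cij_lsq(g, -60.8, c(NTA = -37.5),
                       list(denticity_ratios()))
  two <- solve_cij(g, -60.8, -37.5)
  expect_equal(lsq$c_o, two$c_o, tolerance = 1e-9)
  expect_equal(lsq$c_n, two$c_n, tolerance = 1e-9)

  # table-driven gradient fitting reproduces the generating model exactly
  # for noise-free scans
  tbl <- synthetic_scan_table(g, c_o_values = c(0, 17, 34.4, 51, 70),
                              c_n_values = c(0, 33, 65.9, 99, 130))
  fits <- fit_gradients(tbl)
  expect_equal(fits$m_o_kj_mol_per_c4, g$m_o, tolerance = 1e-10)
  expect_equal(fits$m_n_kj_mol_per_c4, g$m_n, tolerance = 1e-10)
  expect_equal(fits$c_o_default_kcal_mol_A4, 34.4)
  expect_equal(fits$dg_default_kj_mol, g$dg_default, tolerance = 1e-10)
  expect_equal(fits$dg_zero_kj_mol, g$dg_zero, tolerance = 1e-10)
})

test_that("tidy and glance expose the solved system as tibbles", {
  fit <- solve_cij(ca_gradient_set(), -60.8, -37.5)
  td <- tidy(fit)
  expect_equal(td$term, c("c_o", "c_n"))
  expect_equal(td$estimate, c(fit$c_o, fit$c_n))
  gl <- glance(fit)
  expect_true(gl$physical)
  expect_equal(gl$c_o_kcal_mol_A4, fit$c_o)
  expect_s3_class(autoplot(fit), "ggplot")
})
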