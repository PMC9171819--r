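# Core parameterization engine: linear dG-vs-C4 gradients from TI scans,
# back-extrapolation to the zero-C4 reference, experimental-ratio rescaling
# between chelators, and the denticity-scaled two-chelator 2x2 solve for the
# ligating-oxygen and ligating-nitrogen C4 coefficients.

#' Denticity ratios between a reference and a second chelator
#'
#' Scaling factors applied to the reference chelator's oxygen and nitrogen
#' gradients when writing the second chelator's equation. The defaults 3/4
#' and 1/2 are the ratios of the maximum numbers of ligating oxygens and
#' tertiary nitrogens that NTA offers relative to EDTA (3 vs 4 carboxylate
#' oxygens, 1 vs 2 nitrogens). Other chelator pairs take other ratios.
#'
#' @param rho_o Oxygen-gradient ratio, in (0, 1].
#' @param rho_n Nitrogen-gradient ratio, in (0, 1].
#' @return An object of class `denticity_ratios`.
#' @export
denticity_ratios <- function(rho_o = 3 / 4, rho_n = 1 / 2) {
  for (nm in c("rho_o", "rho_n")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v > 1) {
      stop("`", nm, "` must be a single number in (0, 1]", call. = FALSE)
    }
  }
  structure(list(rho_o = rho_o, rho_n = rho_n), class = "denticity_ratios")
}

#' Per chelator-metal linear response model
#'
#' Bundles the fitted gradients of the simulated binding free energy with
#' respect to the ligating-oxygen and ligating-nitrogen C4 coefficients,
#' the binding energy computed at the default C4 values, and the default C4
#' values themselves. When `dg_zero` is not supplied it is filled in by
#' back-extrapolation ([back_extrapolate_zero()]), which makes the
#' `predict_dg()` round trip through the default point exact.
#'
#' @param chelator,metal Labels.
#' @param m_o,m_n Gradients, kJ mol^-1 per (kcal mol^-1 A^4).
#' @param dg_default Binding energy at the default C4 pair, kJ/mol.
#' @param c_o_default,c_n_default Default C4 values, kcal mol^-1 A^4.
#' @param dg_zero Zero-C4 reference energy, kJ/mol; back-extrapolated when
#'   `NULL`.
#' @return An object of class `gradient_set`.
#' @export
gradient_set <- function(chelator, metal, m_o, m_n, dg_default,
                         c_o_default, c_n_default, dg_zero = NULL) {
  g <- structure(
    list(chelator = chelator, metal = metal,
         m_o = m_o, m_n = m_n, dg_default = dg_default,
         c_o_default = c_o_default, c_n_default = c_n_default,
         dg_zero = dg_zero),
    class = "gradient_set"
  )
  if (is.null(dg_zero)) g$dg_zero <- back_extrapolate_zero(g)
  g
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %s / %s\n", x$chelator, x$metal))
  cat(sprintf("  m(O) = %.4g, m(N) = %.4g kJ/mol per kcal/mol A^4\n",
              x$m_o, x$m_n))
  cat(sprintf("  dG(default C4 = %.4g, %.4g) = %.4g kJ/mol; dG'(0,0) = %.6g kJ/mol\n",
              x$c_o_default, x$c_n_default, x$dg_default, x$dg_zero))
  invisible(x)
}

#' Back-extrapolate the zero-C4 reference binding energy
#'
#' Removes the linear C4 contributions from the binding energy computed at
#' the default C4 pair:
#' `dG'(0,0) = dG(default) - m_O * C_O,default - m_N * C_N,default`.
#' This replaces the directly simulated zero-C4 energies, which are
#' unreliable because the ion can leave the chelation pocket once the
#' attractive C4 terms are switched off.
#'
#' @param g A `gradient_set`.
#' @return The reference energy in kJ/mol.
#' @export
back_extrapolate_zero <- function(g) {
  stopifnot(inherits(g, "gradient_set"))
  g$dg_default - g$m_o * g$c_o_default - g$m_n * g$c_n_default
}

#' Predict the binding energy of a C4 pair under the linear model
#'
#' `dG(C_O, C_N) = dG'(0,0) + m_O * C_O + m_N * C_N`, vectorized over the
#' coefficient pair.
#'
#' @param g A `gradient_set`.
#' @param c_o,c_n C4 coefficients, kcal mol^-1 A^4.
#' @return Predicted binding energies, kJ/mol.
#' @export
predict_dg <- function(g, c_o, c_n) {
  stopifnot(inherits(g, "gradient_set"))
  g$dg_zero + g$m_o * c_o + g$m_n * c_n
}

#' Rescale a zero-C4 reference energy to a second chelator
#'
#' The reference chelator's back-extrapolated zero-C4 energy is scaled by
#' the ratio of the experimental binding energies so that the zero-C4
#' references of the two chelators follow the experimental trend.
#'
#' @param dg_zero_ref Reference chelator zero-C4 energy, kJ/mol.
#' @param dg_exp_ref,dg_exp_other Experimental binding energies, kJ/mol.
#' @return The second chelator's zero-C4 reference, kJ/mol.
#' @export
scale_reference_zero <- function(dg_zero_ref, dg_exp_ref, dg_exp_other) {
  if (dg_exp_ref == 0) {
    stop("reference experimental binding energy must be nonzero", call. = FALSE)
  }
  dg_zero_ref * (dg_exp_other / dg_exp_ref)
}

new_chbe_fit <- function(metal, c_o, c_n, residuals, determinant,
                         gradient_sets, ratios, dg_exp, method) {
  structure(
    list(metal = metal, c_o = c_o, c_n = c_n,
         physical = c_o >= 0 && c_n >= 0,
         residuals = residuals, determinant = determinant,
         gradient_sets = gradient_sets, ratios = ratios,
         dg_exp = dg_exp, method = method),
    class = "chbe_fit"
  )
}

solve_2x2 <- function(m, b, det_tol) {
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(d) < det_tol) {
    stop("singular chelator system: |det| = ", format(abs(d)),
         " below tolerance ", format(det_tol),
         " (are the two equations proportional?)", call. = FALSE)
  }
  x <- solve(m, b)
  list(x = x, det = d, residuals = as.numeric(b - m %*% x))
}

#' Solve the two-chelator system for oxygen and nitrogen C4 coefficients
#'
#' Builds and solves the 2x2 linear system
#' \deqn{dG_{exp,ref} = dG'(0,0) + m_O C_O + m_N C_N}
#' \deqn{dG_{exp,2} = dG'(0,0) \frac{dG_{exp,2}}{dG_{exp,ref}}
#'       + \rho_O m_O C_O + \rho_N m_N C_N}
#' where everything on the right except \eqn{(C_O, C_N)} comes from the
#' reference chelator's TI data: its zero-C4 energy is rescaled to the
#' second chelator by the experimental ratio and its gradients are scaled by
#' the denticity ratios. Solutions with a negative coefficient are flagged
#' `physical = FALSE` (an attractive r^-4 term cannot have negative weight).
#'
#' @param g_ref `gradient_set` for the reference chelator, with `dg_zero`
#'   carried at full precision from [back_extrapolate_zero()].
#' @param dg_exp_ref,dg_exp_other Experimental binding energies of the
#'   reference and second chelator, kJ/mol.
#' @param ratios A [denticity_ratios()] object.
#' @param det_tol Determinant magnitude below which the system is treated as
#'   singular.
#' @return An object of class `chbe_fit` with elements `c_o`, `c_n`
#'   (kcal mol^-1 A^4), `physical`, `residuals` (kJ/mol, zero to numerical
#'   precision for this exactly determined solve) and `determinant`.
#' @seealso [tidy.chbe_fit()], [glance.chbe_fit()], [autoplot.chbe_fit()]
#' @export
solve_cij <- function(g_ref, dg_exp_ref, dg_exp_other,
                      ratios = denticity_ratios(), det_tol = 1e-10) {
  stopifnot(inherits(g_ref, "gradient_set"), inherits(ratios, "denticity_ratios"))
  m <- rbind(
    c(g_ref$m_o, g_ref$m_n),
    c(ratios$rho_o * g_ref$m_o, ratios$rho_n * g_ref$m_n)
  )
  dg_zero_other <- scale_reference_zero(g_ref$dg_zero, dg_exp_ref, dg_exp_other)
  b <- c(dg_exp_ref - g_ref$dg_zero, dg_exp_other - dg_zero_other)
  s <- solve_2x2(m, b, det_tol)
  new_chbe_fit(
    metal = g_ref$metal, c_o = s$x[1], c_n = s$x[2],
    residuals = stats::setNames(s$residuals, c(g_ref$chelator, "scaled")),
    determinant = s$det, gradient_sets = list(ref = g_ref),
    ratios = ratios,
    dg_exp = c(ref = dg_exp_ref, other = dg_exp_other),
    method = "denticity-scaled"
  )
}

#' Direct two-chelator solve from each chelator's own linear model
#'
#' Solves the pair of linear-response equations using each chelator's own
#' gradients and zero-C4 reference, with no denticity scaling and no
#' experimental-ratio substitution. With directly simulated zero-C4
#' references this is the naive route that can produce negative (flagged
#' non-physical) coefficients when the zero-C4 simulations are unreliable -
#' the failure mode that motivates [solve_cij()].
#'
#' @param g_a,g_b `gradient_set` objects for the two chelators.
#' @param dg_exp_a,dg_exp_b Experimental binding energies, kJ/mol.
#' @inheritParams solve_cij
#' @return A `chbe_fit`.
#' @export
solve_cij_direct <- function(g_a, g_b, dg_exp_a, dg_exp_b, det_tol = 1e-10) {
  stopifnot(inherits(g_a, "gradient_set"), inherits(g_b, "gradient_set"))
  m <- rbind(c(g_a$m_o, g_a$m_n), c(g_b$m_o, g_b$m_n))
  b <- c(dg_exp_a - g_a$dg_zero, dg_exp_b - g_b$dg_zero)
  s <- solve_2x2(m, b, det_tol)
  new_chbe_fit(
    metal = g_a$metal, c_o = s$x[1], c_n = s$x[2],
    residuals = stats::setNames(s$residuals, c(g_a$chelator, g_b$chelator)),
    determinant = s$det, gradient_sets = list(g_a, g_b), ratios = NULL,
    dg_exp = c(dg_exp_a, dg_exp_b), method = "direct"
  )
}

#' Over-determined multi-chelator least-squares solve
#'
#' Extension beyond the exactly determined two-chelator design: with k >= 3
#' chelators (one reference plus denticity ratios for each of the others)
#' the k x 2 system is solved in the least-squares sense via QR. This is an
#' extrapolation of the method, provided for sensitivity analysis; the
#' canonical parameterization is the 2x2 [solve_cij()].
#'
#' @inheritParams solve_cij
#' @param dg_exp_others Named numeric vector of experimental binding
#'   energies for the non-reference chelators, kJ/mol.
#' @param ratios_list List of [denticity_ratios()], one per entry of
#'   `dg_exp_others`.
#' @return A `chbe_fit` with `residuals` of length `1 + length(dg_exp_others)`.
#' @export
solve_cij_lsq <- function(g_ref, dg_exp_ref, dg_exp_others, ratios_list,
                          det_tol = 1e-10) {
  stopifnot(inherits(g_ref, "gradient_set"),
            length(dg_exp_others) == length(ratios_list))
  rho_o <- vapply(ratios_list, function(r) r$rho_o, numeric(1))
  rho_n <- vapply(ratios_list, function(r) r$rho_n, numeric(1))
  m <- rbind(
    c(g_ref$m_o, g_ref$m_n),
    cbind(rho_o * g_ref$m_o, rho_n * g_ref$m_n)
  )
  b <- c(
    dg_exp_ref - g_ref$dg_zero,
    dg_exp_others - vapply(dg_exp_others, function(d) {
      scale_reference_zero(g_ref$dg_zero, dg_exp_ref, d)
    }, numeric(1))
  )
  qrm <- qr(m)
  if (qrm$rank < 2L || abs(prod(diag(qr.R(qrm)))) < det_tol) {
    stop("rank-deficient multi-chelator system", call. = FALSE)
  }
  x <- qr.coef(qrm, b)
  new_chbe_fit(
    metal = g_ref$metal, c_o = x[1], c_n = x[2],
    residuals = as.numeric(b - m %*% x),
    determinant = abs(prod(diag(qr.R(qrm)))),
    gradient_sets = list(ref = g_ref), ratios = ratios_list,
    dg_exp = c(ref = dg_exp_ref, dg_exp_others),
    method = "least-squares"
  )
}

#' @export
print.chbe_fit <- function(x, ...) {
  cat(sprintf("<chbe_fit> %s (%s)\n", x$metal, x$method))
  cat(sprintf("  C4(O) = %.4g, C4(N) = %.4g kcal/mol A^4%s\n",
              x$c_o, x$c_n,
              if (x$physical) "" else "  [NON-PHYSICAL: negative coefficient]"))
  cat(sprintf("  |det| = %.4g, max |residual| = %.3g kJ/mol\n",
              abs(x$determinant), max(abs(x$residuals))))
  invisible(x)
}

#' Tidy a solved C4 system
#'
#' @param x A `chbe_fit`.
#' @param ... Unused.
#' @return A tibble with one row per solved coefficient (`term`,
#'   `estimate`, `unit`).
#' @exportS3Method generics::tidy
tidy.chbe_fit <- function(x, ...) {
  tibble::tibble(
    metal = x$metal,
    term = c("c_o", "c_n"),
    estimate = c(x$c_o, x$c_n),
    unit = "kcal mol-1 A4"
  )
}

#' One-row summary of a solved C4 system
#'
#' @param x A `chbe_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the solution, physicality flag and solve
#'   diagnostics.
#' @exportS3Method generics::glance
glance.chbe_fit <- function(x, ...) {
  tibble::tibble(
    metal = x$metal,
    c_o_kcal_mol_A4 = x$c_o,
    c_n_kcal_mol_A4 = x$c_n,
    physical = x$physical,
    determinant = x$determinant,
    max_abs_residual_kj_mol = max(abs(x$residuals)),
    method = x$method
  )
}

#' Predicted binding energy at the solved coefficients
#'
#' @param object A `chbe_fit` produced by [solve_cij()].
#' @param c_o,c_n Optional coefficients at which to predict; defaults to the
#'   solved pair.
#' @param ... Unused.
#' @return Predicted reference-chelator binding energy, kJ/mol.
#' @export
predict.chbe_fit <- function(object, c_o = object$c_o, c_n = object$c_n, ...) {
  g <- object$gradient_sets[[1]]
  predict_dg(g, c_o, c_n)
}

#' Iso-binding-energy contour of the linear model
#'
#' For each grid value of the oxygen coefficient, the nitrogen coefficient
#' that reproduces `dg_target` under the linear model:
#' `C_N = (dG_target - dG'(0,0) - m_O C_O) / m_N`.
#'
#' @param g A `gradient_set` with nonzero `m_n`.
#' @param dg_target Target binding energy, kJ/mol.
#' @param c_o_grid Numeric vector of oxygen C4 values, kcal mol^-1 A^4.
#' @return A tibble with columns `c_o_kcal_mol_A4`, `c_n_kcal_mol_A4`.
#' @export
contour_line <- function(g, dg_target, c_o_grid) {
  stopifnot(inherits(g, "gradient_set"))
  if (g$m_n == 0) {
    stop("degenerate contour: nitrogen gradient is zero", call. = FALSE)
  }
  tibble::tibble(
    c_o_kcal_mol_A4 = c_o_grid,
    c_n_kcal_mol_A4 = (dg_target - g$dg_zero - g$m_o * c_o_grid) / g$m_n
  )
}

# ---- gradient fitting from TI scan tables -----------------------------------

scan_design <- function(c_o, c_n) {
  vo <- length(unique(c_o)) > 1L
  vn <- length(unique(c_n)) > 1L
  if (vo && vn) {
    stop("mixed design: both c_o and c_n vary; fit one scan at a time",
         call. = FALSE)
  }
  if (!vo && !vn) {
    stop("degenerate design: neither c_o nor c_n varies", call. = FALSE)
  }
  if (vo) "c_o" else "c_n"
}

#' Fit the linear gradient of one C4 scan
#'
#' Ordinary least-squares fit of the simulated binding energy against the
#' single C4 coordinate that varies in `data` (the other one must be held
#' fixed, at its default value in the canonical design). By default the
#' intercept is free, matching a straight-line fit through the scan points;
#' `anchor = TRUE` instead forces the line through the observation at the
#' scan's default point, for sensitivity checks.
#'
#' @param data Data frame with columns `chelator`, `metal`, `c_o`, `c_n`,
#'   `dg_sim` (unit-suffixed spellings accepted) for one chelator-metal
#'   scan.
#' @param anchor Logical; if `TRUE` the fit is anchored at the observation
#'   whose varied coordinate equals `anchor_at` (no free intercept).
#' @param anchor_at Varied-coordinate value of the anchor point (required
#'   when `anchor = TRUE`; must match one observation).
#' @return An object of class `gradient_fit` with elements `slope`
#'   (kJ mol^-1 per kcal mol^-1 A^4), `intercept`, `r_squared`, `n`,
#'   `varied`, `held_value`, `chelator`, `metal`.
#' @export
fit_gradient <- function(data, anchor = FALSE, anchor_at = NULL) {
  data <- tibble::as_tibble(data)
  c_o <- data[[match_column(data, "c_o")]]
  c_n <- data[[match_column(data, "c_n")]]
  dg <- data[[match_column(data, "dg_sim")]]
  if (nrow(data) < 2L) stop("need at least two observations", call. = FALSE)
  varied <- scan_design(c_o, c_n)
  x <- if (varied == "c_o") c_o else c_n
  held <- unique(if (varied == "c_o") c_n else c_o)
  if (anchor) {
    if (is.null(anchor_at)) {
      stop("`anchor_at` must be given when `anchor = TRUE`", call. = FALSE)
    }
    i0 <- which(abs(x - anchor_at) < 1e-9)
    if (length(i0) == 0L) {
      stop("no observation at the anchor point", call. = FALSE)
    }
    x0 <- anchor_at
    y0 <- mean(dg[i0])
    fit <- stats::lm(I(dg - y0) ~ 0 + I(x - x0))
    slope <- unname(stats::coef(fit)[1])
    intercept <- y0 - slope * x0
    tss <- sum((dg - y0)^2)  # uncentered, as for intercept-free fits
  } else {
    fit <- stats::lm(dg ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    tss <- sum((dg - mean(dg))^2)
  }
  rss <- sum(stats::resid(fit)^2)
  r2 <- if (tss <= .Machine$double.eps * max(1, sum(dg^2))) 1
        else 1 - rss / tss
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         n = length(x), varied = varied, held_value = held,
         chelator = if ("chelator" %in% names(data)) unique(data$chelator) else NA_character_,
         metal = if ("metal" %in% names(data)) unique(data$metal) else NA_character_),
    class = "gradient_fit"
  )
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("<gradient_fit> %s / %s: d(dG)/d(%s) = %.4g kJ/mol per kcal/mol A^4 (R^2 = %.4f, n = %d)\n",
              x$chelator, x$metal, x$varied, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gradient_fit <- function(x, ...) {
  tibble::tibble(
    chelator = x$chelator, metal = x$metal, varied = x$varied,
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @exportS3Method generics::glance
glance.gradient_fit <- function(x, ...) {
  tibble::tibble(
    chelator = x$chelator, metal = x$metal, varied = x$varied,
    slope_kj_mol_per_c4 = x$slope, intercept_kj_mol = x$intercept,
    r_squared = x$r_squared, n = x$n
  )
}

#' Fit gradients for every chelator-metal scan in a TI observation table
#'
#' Splits the table into (chelator, metal, varied-coordinate) scans, fits
#' each with [fit_gradient()], and assembles one linear model per
#' chelator-metal: both gradients, the binding energy at the default C4
#' pair (the observation where both coordinates sit at their held scan
#' values, averaged over the two scans), and the back-extrapolated zero-C4
#' reference.
#'
#' @param data TI observation table with columns `chelator`, `metal`,
#'   `c_o`, `c_n`, `dg_sim`.
#' @param anchor Passed to [fit_gradient()] (anchored at the default point).
#' @return A tibble with one row per chelator-metal: gradients, defaults,
#'   `dg_default_kj_mol`, `dg_zero_kj_mol` and per-scan fit diagnostics.
#' @export
fit_gradients <- function(data, anchor = FALSE) {
  data <- tibble::as_tibble(data)
  co_col <- match_column(data, "c_o")
  cn_col <- match_column(data, "c_n")
  dg_col <- match_column(data, "dg_sim")
  groups <- dplyr::group_split(dplyr::group_by(
    data, .data$chelator, .data$metal))
  purrr::map_dfr(groups, function(grp) {
    c_o <- grp[[co_col]]
    c_n <- grp[[cn_col]]
    dg <- grp[[dg_col]]
    # the held value of each scan is the modal value of the other coordinate
    o_default <- as.numeric(names(sort(table(c_o), decreasing = TRUE))[1])
    n_default <- as.numeric(names(sort(table(c_n), decreasing = TRUE))[1])
    scan_o <- grp[abs(c_n - n_default) < 1e-9, ]
    scan_n <- grp[abs(c_o - o_default) < 1e-9, ]
    fo <- fit_gradient(scan_o, anchor = anchor,
                       anchor_at = if (anchor) o_default else NULL)
    fn <- fit_gradient(scan_n, anchor = anchor,
                       anchor_at = if (anchor) n_default else NULL)
    at_default <- abs(c_o - o_default) < 1e-9 & abs(c_n - n_default) < 1e-9
    if (!any(at_default)) {
      stop("scan for ", unique(grp$chelator), "/", unique(grp$metal),
           " has no observation at the default C4 pair", call. = FALSE)
    }
    dg_default <- mean(dg[at_default])
    g <- gradient_set(unique(grp$chelator), unique(grp$metal),
                      m_o = fo$slope, m_n = fn$slope,
                      dg_default = dg_default,
                      c_o_default = o_default, c_n_default = n_default)
    tibble::tibble(
      chelator = g$chelator, metal = g$metal,
      m_o_kj_mol_per_c4 = g$m_o, m_n_kj_mol_per_c4 = g$m_n,
      c_o_default_kcal_mol_A4 = o_default,
      c_n_default_kcal_mol_A4 = n_default,
      dg_default_kj_mol = dg_default,
      dg_zero_kj_mol = g$dg_zero,
      r_squared_o = fo$r_squared, n_o = fo$n,
      r_squared_n = fn$r_squared, n_n = fn$n
    )
  })
}

# ---- packaged reference fixtures --------------------------------------------

#' Packaged chelator TI summary table
#'
#' Experimental EDTA/NTA binding energies, simulated binding energies at the
#' default and zero C4 pairs, and fitted gradients for Ca2+, Mg2+, Y3+ and
#' La3+, shipped as a package fixture. These are the canonical inputs of the
#' two-chelator parameterization.
#'
#' @return A tibble with one row per metal.
#' @export
chbe_table1 <- function() {
  readr::read_csv(
    system.file("extdata", "chelator_ti_summary.csv", package = "chbe",
                mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' Packaged default and solved C4 coefficient table
#'
#' Default 12-6-4 C4 coefficients for ligating oxygen and tertiary nitrogen,
#' and the published chelator-derived values, per metal.
#'
#' @return A tibble with one row per metal.
#' @export
chbe_cij_table <- function() {
  readr::read_csv(
    system.file("extdata", "cij_coefficients.csv", package = "chbe",
                mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' @rdname chbe_cij_table
#' @export
chbe_default_cij <- function() {
  dplyr::select(chbe_cij_table(), "metal",
                "c_o_default_kcal_mol_A4", "c_n_default_kcal_mol_A4")
}

#' Build a gradient set from a summary-table row
#'
#' @param summary_row One row of a table shaped like [chbe_table1()].
#' @param defaults_row Matching row of [chbe_default_cij()].
#' @param chelator Which chelator's columns to read (`"edta"` or `"nta"`).
#' @return A `gradient_set` with back-extrapolated `dg_zero`.
#' @export
gradient_set_from_summary <- function(summary_row, defaults_row,
                                      chelator = "edta") {
  pick <- function(base) summary_row[[paste0(base, "_", chelator, "_kj_mol")]]
  gradient_set(
    chelator = toupper(chelator), metal = summary_row$metal,
    m_o = summary_row[[paste0("m_o_", chelator, "_kj_mol_per_c4")]],
    m_n = summary_row[[paste0("m_n_", chelator, "_kj_mol_per_c4")]],
    dg_default = pick("dg_sim_default"),
    c_o_default = defaults_row$c_o_default_kcal_mol_A4,
    c_n_default = defaults_row$c_n_default_kcal_mol_A4
  )
}

#' Run the full two-chelator parameterization for every metal
#'
#' For each metal in the summary table: back-extrapolate the reference
#' (EDTA) zero-C4 energy, rescale it to the second chelator by the
#' experimental ratio, and solve the denticity-scaled 2x2 system for the
#' oxygen and nitrogen C4 coefficients.
#'
#' @param summary Summary table shaped like [chbe_table1()] (the default).
#' @param defaults Default C4 table shaped like [chbe_default_cij()].
#' @param ratios A [denticity_ratios()] object.
#' @return A tibble with one row per metal: solved coefficients,
#'   physicality flag and solve diagnostics.
#' @examples
#' solve_chbe()
#' @export
solve_chbe <- function(summary = chbe_table1(),
                       defaults = chbe_default_cij(),
                       ratios = denticity_ratios()) {
  purrr::map_dfr(seq_len(nrow(summary)), function(i) {
    row <- summary[i, ]
    def <- defaults[defaults$metal == row$metal, ]
    if (nrow(def) != 1L) {
      stop("no default C4 row for metal ", row$metal, call. = FALSE)
    }
    g <- gradient_set_from_summary(row, def, chelator = "edta")
    fit <- solve_cij(g, row$dg_exp_edta_kj_mol, row$dg_exp_nta_kj_mol,
                     ratios = ratios)
    glance(fit)
  })
}
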