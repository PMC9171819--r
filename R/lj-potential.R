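# Pairwise 12-6 / 12-6-4 Lennard-Jones + Coulomb energies and the parameter
# containers they act on. Energies are in kcal/mol, distances in Angstrom,
# charges in elementary-charge units throughout this module.

#' AMBER Coulomb conversion constant
#'
#' The e^2 prefactor that converts `q_i * q_j / r` (charges in elementary
#' charge units, r in Angstrom) to kcal/mol, as used by the AMBER family of
#' force fields.
#'
#' @return A single number, kcal mol^-1 A e^-2.
#' @export
amber_coulomb_constant <- function() 332.0522

#' Unit conversion between kcal/mol and kJ/mol
#'
#' @param x Numeric vector of energies.
#' @return Converted numeric vector.
#' @export
kcal_to_kj <- function(x) x * 4.184

#' @rdname kcal_to_kj
#' @export
kj_to_kcal <- function(x) x / 4.184

#' Pairwise nonbonded parameters for one atom-type pair
#'
#' Bundles the repulsion (`a_ij`, kcal mol^-1 A^12), dispersion (`b_ij`,
#' kcal mol^-1 A^6) and ion-induced-dipole (`c_ij`, kcal mol^-1 A^4)
#' coefficients together with the partial charges of the two partners.
#' Negative coefficients are rejected: an attractive r^-4 term with
#' negative weight has no physical interpretation in this model.
#'
#' @param a_ij Repulsive A coefficient, kcal mol^-1 A^12.
#' @param b_ij Dispersive B coefficient, kcal mol^-1 A^6.
#' @param c_ij Ion-induced-dipole C coefficient, kcal mol^-1 A^4.
#' @param q_i,q_j Partial charges, e.
#' @param coulomb_constant Conversion factor for the Coulomb term,
#'   kcal mol^-1 A e^-2.
#' @return An object of class `lj_pair`.
#' @examples
#' p <- lj_pair(a_ij = 1e5, b_ij = 600, c_ij = 35, q_i = 2, q_j = -0.8)
#' lj_energy(2.4, p)
#' @export
lj_pair <- function(a_ij, b_ij, c_ij = 0, q_i = 0, q_j = 0,
                    coulomb_constant = amber_coulomb_constant()) {
  for (nm in c("a_ij", "b_ij", "c_ij")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single non-negative finite number", call. = FALSE)
    }
  }
  stopifnot(is.numeric(q_i), is.numeric(q_j), is.numeric(coulomb_constant))
  structure(
    list(a_ij = a_ij, b_ij = b_ij, c_ij = c_ij, q_i = q_i, q_j = q_j,
         coulomb_constant = coulomb_constant),
    class = "lj_pair"
  )
}

#' @export
print.lj_pair <- function(x, ...) {
  cat("<lj_pair>\n")
  cat(sprintf("  A = %.6g kcal/mol A^12, B = %.6g kcal/mol A^6, C4 = %.6g kcal/mol A^4\n",
              x$a_ij, x$b_ij, x$c_ij))
  cat(sprintf("  q_i = %.4g e, q_j = %.4g e\n", x$q_i, x$q_j))
  invisible(x)
}

#' Per-atom-type Lennard-Jones parameters
#'
#' Holds the half minimum-distance / well-depth parameterization used by
#' AMBER-style force fields, plus an optional table of pair-specific C4
#' coefficients keyed by partner atom-type name. C4 terms are never derived
#' from combining rules: the point of the 12-6-4 model is that they are
#' pair-specific, so they are looked up (0 when absent).
#'
#' @param name Atom-type label.
#' @param r_min_half Half the energy-minimum distance of the homo pair, A.
#' @param epsilon Well depth, kcal/mol.
#' @param charge Partial charge, e.
#' @param c4 Named numeric vector of pairwise C4 overrides, kcal mol^-1 A^4,
#'   keyed by partner atom-type name.
#' @return An object of class `atom_type`.
#' @export
atom_type <- function(name, r_min_half, epsilon, charge = 0, c4 = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(r_min_half) || r_min_half <= 0) {
    stop("`r_min_half` must be > 0", call. = FALSE)
  }
  if (!is.numeric(epsilon) || epsilon < 0) {
    stop("`epsilon` must be >= 0", call. = FALSE)
  }
  if (!is.null(c4)) {
    if (!is.numeric(c4) || is.null(names(c4)) || any(c4 < 0)) {
      stop("`c4` must be a named numeric vector of non-negative overrides",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, r_min_half = r_min_half, epsilon = epsilon,
         charge = charge, c4 = c4),
    class = "atom_type"
  )
}

#' Combine two atom types into pairwise parameters
#'
#' Applies Lorentz-Berthelot combining rules (arithmetic mean of minimum
#' distances, geometric mean of well depths) to produce the A and B
#' coefficients, and looks up the pairwise C4 override from either partner's
#' table (0 when neither defines one). The result is symmetric in its
#' arguments.
#'
#' @param i,j `atom_type` objects.
#' @return An `lj_pair`.
#' @export
lj_pair_from_types <- function(i, j) {
  stopifnot(inherits(i, "atom_type"), inherits(j, "atom_type"))
  eps <- sqrt(i$epsilon * j$epsilon)
  r_min <- i$r_min_half + j$r_min_half
  c4 <- 0
  if (!is.null(i$c4) && j$name %in% names(i$c4)) {
    c4 <- unname(i$c4[[j$name]])
  } else if (!is.null(j$c4) && i$name %in% names(j$c4)) {
    c4 <- unname(j$c4[[i$name]])
  }
  lj_pair(
    a_ij = eps * r_min^12,
    b_ij = 2 * eps * r_min^6,
    c_ij = c4,
    q_i = i$charge,
    q_j = j$charge
  )
}

check_r <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    stop("`r` must be positive and finite", call. = FALSE)
  }
  r
}

#' Pairwise nonbonded energy
#'
#' Evaluates the 12-6 form `A/r^12 - B/r^6 + k q_i q_j / r` or the 12-6-4
#' form, which subtracts the additional ion-induced-dipole term `C/r^4`.
#' With `c_ij = 0` the two forms are identical at every distance.
#'
#' @param r Distance(s), A. Must be positive.
#' @param pair An `lj_pair`.
#' @param form `"12-6-4"` (default) or `"12-6"`.
#' @return Energy in kcal/mol, vectorized over `r`.
#' @export
lj_energy <- function(r, pair, form = c("12-6-4", "12-6")) {
  form <- match.arg(form)
  check_r(r)
  stopifnot(inherits(pair, "lj_pair"))
  e <- pair$a_ij / r^12 - pair$b_ij / r^6 +
    pair$coulomb_constant * pair$q_i * pair$q_j / r
  if (form == "12-6-4") e <- e - pair$c_ij / r^4
  e
}

#' @rdname lj_energy
#' @export
energy_12_6 <- function(r, pair) lj_energy(r, pair, form = "12-6")

#' @rdname lj_energy
#' @export
energy_12_6_4 <- function(r, pair) lj_energy(r, pair, form = "12-6-4")

#' Analytic pairwise force
#'
#' Radial force `F(r) = -dU/dr` for the chosen potential form; positive
#' values are repulsive.
#'
#' @inheritParams lj_energy
#' @return Force in kcal mol^-1 A^-1, vectorized over `r`.
#' @export
lj_force <- function(r, pair, form = c("12-6-4", "12-6")) {
  form <- match.arg(form)
  check_r(r)
  stopifnot(inherits(pair, "lj_pair"))
  f <- 12 * pair$a_ij / r^13 - 6 * pair$b_ij / r^7 +
    pair$coulomb_constant * pair$q_i * pair$q_j / r^2
  if (form == "12-6-4") f <- f - 4 * pair$c_ij / r^5
  f
}

#' Locate the potential minimum
#'
#' One-dimensional minimization of the pair energy over `interval` via
#' [stats::optimize()].
#'
#' @inheritParams lj_energy
#' @param interval Search interval in A.
#' @return A list with `r_min` (A) and `depth` (kcal/mol, energy at `r_min`).
#' @export
lj_minimum <- function(pair, form = c("12-6-4", "12-6"),
                       interval = c(0.3, 30)) {
  form <- match.arg(form)
  opt <- stats::optimize(function(r) lj_energy(r, pair, form = form),
                         interval = interval, tol = 1e-10)
  list(r_min = opt$minimum, depth = opt$objective)
}

# ---- parameter table I/O ----------------------------------------------------

# Readers tolerate unit-suffixed headers (e.g. "r_min_half_A") by matching on
# the bare prefix; writers always emit the suffixed form.
match_column <- function(data, base) {
  hit <- which(names(data) == base | startsWith(names(data), paste0(base, "_")))
  if (length(hit) == 0L) {
    stop("input table lacks required column `", base, "`", call. = FALSE)
  }
  names(data)[hit[1]]
}

#' Read an atom-type parameter table
#'
#' Expects columns `atom_type`, `r_min_half` (A), `epsilon` (kcal/mol) and
#' `charge` (e); unit-suffixed spellings such as `r_min_half_A` are accepted.
#'
#' @param path CSV file path.
#' @return A tibble with columns `atom_type`, `r_min_half_A`,
#'   `epsilon_kcal_mol`, `charge_e`.
#' @export
read_atom_types <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    atom_type = as.character(raw[[match_column(raw, "atom_type")]]),
    r_min_half_A = as.numeric(raw[[match_column(raw, "r_min_half")]]),
    epsilon_kcal_mol = as.numeric(raw[[match_column(raw, "epsilon")]]),
    charge_e = as.numeric(raw[[match_column(raw, "charge")]])
  )
}

#' Read a pairwise C4 coefficient table
#'
#' Expects columns `ion`, `atom_type` and `c_ij` (kcal mol^-1 A^4).
#'
#' @param path CSV file path.
#' @return A tibble with columns `ion`, `atom_type`, `c_ij_kcal_mol_A4`.
#' @export
read_c4_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    ion = as.character(raw[[match_column(raw, "ion")]]),
    atom_type = as.character(raw[[match_column(raw, "atom_type")]]),
    c_ij_kcal_mol_A4 = as.numeric(raw[[match_column(raw, "c_ij")]])
  )
}

#' Export C4 terms as a plain-text amendment block
#'
#' Writes one `ion atom_type c_ij` triple per line, the format used to amend
#' the C4 section of an MD engine's nonbonded parameter set.
#'
#' @param c4_table Tibble with columns `ion`, `atom_type` and a `c_ij` column
#'   (unit-suffixed accepted).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_c4_block <- function(c4_table, path) {
  cij <- c4_table[[match_column(c4_table, "c_ij")]]
  lines <- sprintf("%s %s %.6g",
                   c4_table[[match_column(c4_table, "ion")]],
                   c4_table[[match_column(c4_table, "atom_type")]],
                   cij)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_c4_block
#' @export
read_c4_block <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop("malformed C4 block at line ", bad[1], call. = FALSE)
  }
  tibble::tibble(
    ion = vapply(parts, `[[`, character(1), 1L),
    atom_type = vapply(parts, `[[`, character(1), 2L),
    c_ij_kcal_mol_A4 = as.numeric(vapply(parts, `[[`, character(1), 3L))
  )
}
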