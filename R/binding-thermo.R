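# Conversion of experimental stability / dissociation constants to binding
# free energies, and bookkeeping for thermodynamic-cycle binding energies
# assembled from alchemical decoupling components.

#' Molar gas constant in kJ mol^-1 K^-1
#' @return A single number.
#' @export
gas_constant_kj <- function() 8.31446e-3

#' Convert an equilibrium constant to a binding free energy
#'
#' Stability constants (K1, complex formation) convert as
#' `dG = -RT ln(10) * log10(K1)`; dissociation constants convert with the
#' opposite sign, so that in both conventions a more negative `dG` means
#' tighter binding.
#'
#' @param log10_k Base-10 logarithm of the equilibrium constant.
#' @param kind `"stability"` (K1) or `"dissociation"` (Kd).
#' @param temperature Temperature in K (default 298).
#' @return Binding free energy in kJ/mol, vectorized over `log10_k`.
#' @examples
#' dg_from_affinity(10.65, "stability")   # EDTA-like log K1
#' @export
dg_from_affinity <- function(log10_k, kind = c("stability", "dissociation"),
                             temperature = 298) {
  if (length(kind) != 1L || !kind %in% c("stability", "dissociation")) {
    stop("`kind` must be \"stability\" or \"dissociation\"", call. = FALSE)
  }
  if (any(!is.finite(log10_k))) {
    stop("`log10_k` must be finite", call. = FALSE)
  }
  if (any(temperature <= 0)) {
    stop("`temperature` must be > 0", call. = FALSE)
  }
  sgn <- if (kind == "stability") -1 else 1
  sgn * gas_constant_kj() * temperature * log(10) * log10_k
}

#' Invert a binding free energy back to log10 K
#'
#' Exact inverse of [dg_from_affinity()].
#'
#' @param dg Binding free energy, kJ/mol.
#' @inheritParams dg_from_affinity
#' @return log10 of the equilibrium constant.
#' @export
affinity_from_dg <- function(dg, kind = c("stability", "dissociation"),
                             temperature = 298) {
  kind <- match.arg(kind)
  sgn <- if (kind == "stability") -1 else 1
  dg / (sgn * gas_constant_kj() * temperature * log(10))
}

#' Convert a table of experimental affinities to binding free energies
#'
#' Data-frame-first wrapper around [dg_from_affinity()]. The input needs
#' columns `species`, `metal`, `kind` and `log10K`; an optional `T` (or
#' `temperature`) column defaults to 298 K.
#'
#' @param data Data frame of affinities.
#' @return The input as a tibble with an added `dg_exp_kj_mol` column.
#' @export
affinity_to_dg <- function(data) {
  data <- tibble::as_tibble(data)
  for (col in c("species", "metal", "kind", "log10K")) {
    if (!col %in% names(data)) {
      stop("affinity table lacks required column `", col, "`", call. = FALSE)
    }
  }
  temp <- if ("T" %in% names(data)) {
    data[["T"]]
  } else if ("temperature" %in% names(data)) {
    data[["temperature"]]
  } else {
    rep(298, nrow(data))
  }
  temp[is.na(temp)] <- 298
  bad <- setdiff(unique(data$kind), c("stability", "dissociation"))
  if (length(bad) > 0L) {
    stop("unknown constant kind: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(
    data,
    temperature_K = temp,
    dg_exp_kj_mol = purrr::pmap_dbl(
      list(.data$log10K, .data$kind, temp),
      function(l, k, tt) dg_from_affinity(l, k, tt)
    )
  )
}

#' Read an experimental affinity table
#'
#' CSV with columns `species`, `metal`, `kind` (`stability` or
#' `dissociation`), `log10K` and optionally `T` in K.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_affinity <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(raw) == 0L) stop("affinity table is empty", call. = FALSE)
  raw
}

#' Combine thermodynamic-cycle components into a binding energy
#'
#' The simulated binding free energy is assembled from the electrostatic +
#' polarization decoupling legs (run in replicate) and a van der Waals leg.
#' Under the default `"subtract-vdw"` convention the vdW leg enters with a
#' minus sign, so the common fixed-contribution shortcut (a constant
#' `dg_vdw = 9` kJ/mol for every metal) reduces the binding energy by
#' 9 kJ/mol. `"add-vdw"` expresses the opposite cycle orientation.
#'
#' @param dg_ele_pol Numeric vector of replicate electrostatic+polarization
#'   free energies, kJ/mol.
#' @param dg_vdw Van der Waals component, kJ/mol (default the fixed 9 kJ/mol
#'   preset).
#' @param convention `"subtract-vdw"` (default) or `"add-vdw"`.
#' @return A one-row tibble with `dg_binding_kj_mol`, `dg_sd_kj_mol`,
#'   `dg_vdw_kj_mol`, `n_replicates` and `convention`. The standard
#'   deviation is the sample SD of the replicates (0 for a single one).
#' @export
combine_cycle <- function(dg_ele_pol, dg_vdw = 9,
                          convention = c("subtract-vdw", "add-vdw")) {
  convention <- match.arg(convention)
  if (length(dg_ele_pol) == 0L || any(!is.finite(dg_ele_pol))) {
    stop("`dg_ele_pol` must contain at least one finite replicate",
         call. = FALSE)
  }
  sgn <- if (convention == "subtract-vdw") -1 else 1
  sd_rep <- if (length(dg_ele_pol) == 1L) 0 else stats::sd(dg_ele_pol)
  tibble::tibble(
    dg_binding_kj_mol = mean(dg_ele_pol) + sgn * dg_vdw,
    dg_sd_kj_mol = sd_rep,
    dg_vdw_kj_mol = dg_vdw,
    n_replicates = length(dg_ele_pol),
    convention = convention
  )
}
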