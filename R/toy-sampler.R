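# Seedable Metropolis Monte Carlo sampler of an ion in a bath of
# solvent-like sites interacting through the 12-6-4 potential. The sampler
# targets correct equilibrium ensembles at desk scale; it makes no claim
# about dynamics.

kb_kcal <- 0.0019872041  # Boltzmann constant, kcal mol^-1 K^-1

# evaluate and restore the global RNG stream around a seeded computation,
# so public calls take explicit seeds without leaking state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' A TIP3P-like water-oxygen site type
#'
#' Fixture convention for the toy sampler: an oxygen-like Lennard-Jones
#' site (r_min/2 = 1.768 A, epsilon = 0.152 kcal/mol, charge -0.834 e with
#' an implicit neutralizing background). Not a physics claim - a convenient
#' stand-in for an aqueous bath.
#'
#' @return An [atom_type()].
#' @export
tip3p_oxygen <- function() {
  atom_type("OW", r_min_half = 1.768, epsilon = 0.152, charge = -0.834)
}

#' Define a toy ion-solvation system
#'
#' One ion fixed at the origin of a cubic periodic box of solvent-like
#' sites. The ion-site interaction is the 12-6-4 potential with the given
#' pairwise C4 coefficient; site-site interactions use the plain 12-6 form
#' from Lorentz-Berthelot combination.
#'
#' @param n_sites Number of solvent sites (>= 1).
#' @param box_length Cubic box edge, A. Must exceed four times the combined
#'   minimum-distance radius of ion and site so that a first shell fits.
#' @param temperature Temperature in K.
#' @param ion,site [atom_type()] objects.
#' @param c4 Ion-site C4 coefficient, kcal mol^-1 A^4.
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(n_sites, box_length, temperature = 300,
                       ion = atom_type("M", r_min_half = 1.7,
                                       epsilon = 0.1, charge = 2),
                       site = tip3p_oxygen(), c4 = 0) {
  if (n_sites < 1L) stop("`n_sites` must be >= 1", call. = FALSE)
  min_box <- 4 * (ion$r_min_half + site$r_min_half)
  if (box_length <= min_box) {
    stop("`box_length` must exceed ", format(min_box),
         " A for these atom types", call. = FALSE)
  }
  if (temperature <= 0) stop("`temperature` must be > 0", call. = FALSE)
  ion$c4 <- stats::setNames(c4, site$name)
  structure(
    list(n_sites = as.integer(n_sites), box_length = box_length,
         temperature = temperature, ion = ion, site = site, c4 = c4,
         pair_ion_site = lj_pair_from_types(ion, site),
         pair_site_site = lj_pair_from_types(site, site)),
    class = "toy_system"
  )
}

min_image <- function(d, box) d - box * round(d / box)

# interaction energy of site i with the ion and all other sites
site_energy <- function(pos, i, sites, sys) {
  d_ion <- sqrt(sum(min_image(pos, sys$box_length)^2))
  e <- lj_energy(d_ion, sys$pair_ion_site)
  if (nrow(sites) > 1L) {
    others <- sites[-i, , drop = FALSE]
    dv <- min_image(sweep(others, 2, pos), sys$box_length)
    r <- sqrt(rowSums(dv^2))
    e <- e + sum(lj_energy(r, sys$pair_site_site, form = "12-6"))
  }
  e
}

place_initial <- function(sys, min_sep = 1.8, retry_budget = 2000L) {
  sites <- matrix(NA_real_, sys$n_sites, 3L)
  tries <- 0L
  i <- 1L
  while (i <= sys$n_sites) {
    p <- stats::runif(3, -sys$box_length / 2, sys$box_length / 2)
    ok <- sqrt(sum(p^2)) >= min_sep
    if (ok && i > 1L) {
      dv <- min_image(sweep(sites[seq_len(i - 1L), , drop = FALSE], 2, p),
                      sys$box_length)
      ok <- min(sqrt(rowSums(dv^2))) >= min_sep
    }
    if (ok) {
      sites[i, ] <- p
      i <- i + 1L
    } else {
      tries <- tries + 1L
      if (tries > retry_budget) {
        stop("could not place ", sys$n_sites, " sites without overlap after ",
             retry_budget, " retries; box too crowded", call. = FALSE)
      }
    }
  }
  sites
}

#' Run Metropolis Monte Carlo on a toy system
#'
#' Single-site displacement moves with uniform proposals in a cube of side
#' `2 * step_size`, accepted with the Metropolis criterion at the system
#' temperature on the total pairwise 12-6-4 + Coulomb energy under the
#' minimum-image convention. The ion stays fixed at the origin. The same
#' seed reproduces the trace bitwise.
#'
#' @param sys A [toy_system()].
#' @param n_steps Number of MC moves.
#' @param step_size Maximum per-coordinate displacement, A.
#' @param save_interval Save a frame (and the running energy) every this
#'   many steps.
#' @param seed Integer RNG seed (mandatory: every run is reproducible).
#' @return An object of class `mc_trace`: `frames` (a [frame_set()]),
#'   `energies` (kcal/mol, one per saved frame), `acceptance_rate`,
#'   `n_steps`, `save_interval`.
#' @export
run_mc <- function(sys, n_steps, step_size = 0.3, save_interval = 100L,
                   seed) {
  stopifnot(inherits(sys, "toy_system"))
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  if (n_steps < save_interval) {
    stop("`n_steps` must be >= `save_interval`", call. = FALSE)
  }
  with_seed(seed, {
    sites <- place_initial(sys)
    beta <- 1 / (kb_kcal * sys$temperature)
    n_accept <- 0L
    frames <- vector("list", n_steps %/% save_interval)
    energies <- numeric(length(frames))
    total_energy <- function(sites) {
      es <- vapply(seq_len(sys$n_sites), function(i) {
        site_energy(sites[i, ], i, sites, sys)
      }, numeric(1))
      d_ion <- sqrt(rowSums(min_image(sites, sys$box_length)^2))
      e_is <- sum(lj_energy(d_ion, sys$pair_ion_site))
      # sum(es) double-counts site-site pairs and counts ion-site once each
      (sum(es) + e_is) / 2
    }
    k <- 0L
    for (step in seq_len(n_steps)) {
      i <- if (sys$n_sites == 1L) 1L else sample.int(sys$n_sites, 1L)
      old_pos <- sites[i, ]
      prop <- old_pos + stats::runif(3, -step_size, step_size)
      prop <- min_image(prop, sys$box_length)
      e_old <- site_energy(old_pos, i, sites, sys)
      e_new <- site_energy(prop, i, sites, sys)
      d_e <- e_new - e_old
      if (d_e <= 0 || stats::runif(1) < exp(-beta * d_e)) {
        sites[i, ] <- prop
        n_accept <- n_accept + 1L
      }
      if (step %% save_interval == 0L) {
        k <- k + 1L
        frames[[k]] <- list(ion = c(0, 0, 0), sites = sites)
        energies[k] <- total_energy(sites)
      }
    }
    structure(
      list(frames = frame_set(frames, box_length = sys$box_length),
           energies = energies,
           acceptance_rate = n_accept / n_steps,
           n_steps = n_steps, save_interval = save_interval, seed = seed),
      class = "mc_trace"
    )
  })
}

#' @export
print.mc_trace <- function(x, ...) {
  cat(sprintf("<mc_trace> %d steps, %d saved frames, acceptance %.1f%%\n",
              x$n_steps, length(x$energies), 100 * x$acceptance_rate))
  invisible(x)
}

#' Energy trace plot of an MC run
#'
#' @param object An `mc_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mc_trace <- function(object, ...) {
  tab <- tibble::tibble(
    step = seq_along(object$energies) * object$save_interval,
    energy_kcal_mol = object$energies
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$step,
                                    y = .data$energy_kcal_mol)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "MC step", y = "total energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Generate a jittered spherical-shell fixture
#'
#' Frames with `n_shell` sites placed uniformly on a sphere around the ion,
#' with Gaussian radial jitter. Ground truth for RDF analysis: the
#' ion-oxygen distance equals `radius` and the coordination number equals
#' `n_shell`.
#'
#' @param n_shell Sites per frame (>= 1).
#' @param radius Shell radius, A.
#' @param jitter Radial Gaussian standard deviation, A.
#' @param n_frames Number of frames.
#' @param seed Integer RNG seed.
#' @return A [frame_set()] with open boundary.
#' @export
make_shell_fixture <- function(n_shell, radius, jitter = 0, n_frames = 1L,
                               seed) {
  if (n_shell < 1L) stop("`n_shell` must be >= 1", call. = FALSE)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  if (jitter < 0) stop("`jitter` must be >= 0", call. = FALSE)
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      dirs <- matrix(stats::rnorm(3 * n_shell), n_shell, 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      r <- radius + if (jitter > 0) stats::rnorm(n_shell, 0, jitter) else 0
      list(ion = c(0, 0, 0), sites = dirs * r)
    })
    frame_set(frames, box_length = NULL)
  })
}

#' Boltzmann radial density of the two-body system
#'
#' Unnormalized equilibrium radial probability density
#' `p(r) proportional to r^2 exp(-u(r) / kT)` of a single site around a
#' fixed ion, the closed-form target the MC sampler must reproduce.
#'
#' @param r Distances, A.
#' @param pair An [lj_pair()] for the ion-site interaction.
#' @param temperature Temperature, K.
#' @return Unnormalized density values, vectorized over `r`.
#' @export
boltzmann_radial_density <- function(r, pair, temperature = 300) {
  beta <- 1 / (kb_kcal * temperature)
  r^2 * exp(-beta * lj_energy(r, pair))
}
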