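# Shared fixtures built in code.

# Linear-response model for EDTA chelation of Ca2+ assembled from the
# packaged summary table's printed inputs.
ca_gradient_set <- function() {
  gradient_set("EDTA", "Ca2+", m_o = -0.593, m_n = -0.177,
               dg_default = -56.0, c_o_default = 34.4, c_n_default = 65.9)
}

# All four metals' reference (EDTA) gradient sets from the packaged tables.
all_gradient_sets <- function() {
  summary <- chbe_table1()
  defaults <- chbe_default_cij()
  lapply(seq_len(nrow(summary)), function(i) {
    gradient_set_from_summary(summary[i, ],
                              defaults[defaults$metal == summary$metal[i], ])
  })
}

# Two-scan TI observation table generated from a known gradient set plus
# optional Gaussian noise; ground truth for fit_gradients().
synthetic_scan_table <- function(g, c_o_values, c_n_values, sigma = 0,
                                 seed = 1) {
  stopifnot(inherits(g, "gradient_set"))
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    scan_o <- tibble::tibble(
      chelator = g$chelator, metal = g$metal,
      c_o = c_o_values, c_n = g$c_n_default,
      dg_sim = predict_dg(g, c_o_values, g$c_n_default) +
        stats::rnorm(length(c_o_values), 0, sigma)
    )
    scan_n <- tibble::tibble(
      chelator = g$chelator, metal = g$metal,
      c_o = g$c_o_default, c_n = c_n_values,
      dg_sim = predict_dg(g, g$c_o_default, c_n_values) +
        stats::rnorm(length(c_n_values), 0, sigma)
    )
    dplyr::bind_rows(scan_o, scan_n)
  })
}

# Uniform ideal-gas frames in a cubic periodic box: the null case whose RDF
# must be flat at 1.
ideal_gas_frames <- function(n_sites, box_length, n_frames, seed) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    list(
      ion = c(0, 0, 0),
      sites = matrix(stats::runif(3 * n_sites, -box_length / 2, box_length / 2),
                     n_sites, 3L)
    )
  })
  frame_set(frames, box_length = box_length)
}

# Merge the per-frame sites of two frame sets (same frame count).
merge_frame_sets <- function(a, b) {
  stopifnot(length(a$frames) == length(b$frames))
  frames <- lapply(seq_along(a$frames), function(i) {
    list(ion = a$frames[[i]]$ion,
         sites = rbind(a$frames[[i]]$sites, b$frames[[i]]$sites))
  })
  frame_set(frames, box_length = a$box_length)
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
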