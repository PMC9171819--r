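# Radial distribution functions of ion-site distances, ion-oxygen distances
# from a quadratic fit to the first peak, and coordination numbers from
# integration of g(r) to the first minimum.

#' Coordinate frames of one ion in a solvent-site bath
#'
#' @param frames List of frames, each a list with `ion` (length-3 numeric,
#'   A) and `sites` (n x 3 numeric matrix, A).
#' @param box_length Cubic periodic box edge in A, or `NULL` for an open
#'   (non-periodic) system.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(frames, box_length = NULL) {
  if (length(frames) == 0L) stop("need at least one frame", call. = FALSE)
  for (f in frames) {
    if (!is.numeric(f$ion) || length(f$ion) != 3L || any(!is.finite(f$ion))) {
      stop("each frame needs a finite length-3 `ion` position", call. = FALSE)
    }
    if (!is.matrix(f$sites) || ncol(f$sites) != 3L || any(!is.finite(f$sites))) {
      stop("each frame needs a finite n x 3 `sites` matrix", call. = FALSE)
    }
  }
  if (!is.null(box_length) && (!is.numeric(box_length) || box_length <= 0)) {
    stop("`box_length` must be a positive number or NULL", call. = FALSE)
  }
  structure(
    list(frames = frames, box_length = box_length,
         site_count = nrow(frames[[1]]$sites)),
    class = "frame_set"
  )
}

#' @export
length.frame_set <- function(x) length(x$frames)

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frame(s), %d site(s), %s\n",
              length(x$frames), x$site_count,
              if (is.null(x$box_length)) "open boundary"
              else sprintf("periodic box %.3g A", x$box_length)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.frame_set <- function(x, ...) {
  purrr::map_dfr(seq_along(x$frames), function(i) {
    f <- x$frames[[i]]
    tibble::tibble(
      frame = i,
      atom = c("ion", rep("site", nrow(f$sites))),
      x_A = c(f$ion[1], f$sites[, 1]),
      y_A = c(f$ion[2], f$sites[, 2]),
      z_A = c(f$ion[3], f$sites[, 3])
    )
  })
}

# minimum-image ion-site distances for one frame
ion_site_distances <- function(frame, box_length) {
  d <- sweep(frame$sites, 2, frame$ion)
  if (!is.null(box_length)) {
    d <- d - box_length * round(d / box_length)
  }
  sqrt(rowSums(d^2))
}

#' Compute a radial distribution function
#'
#' Histograms the ion-site distances over all frames into half-open bins
#' `[r, r + dr)` and normalizes by the spherical shell volume
#' `4 pi r_c^2 dr` (at the bin center), the bulk site density and the frame
#' count. Under periodic boundaries the minimum-image convention is applied
#' and the bulk density is the site count over the box volume; for open
#' systems the density is estimated from the outer 10% of the `r_max`
#' sphere (falling back to the mean density of the whole sphere when that
#' shell is empty, as for an isolated solvation shell).
#'
#' @param fs A [frame_set()].
#' @param dr Bin width in A (default 0.01).
#' @param r_max Histogram range in A; must not exceed half the box length
#'   when periodic. Defaults to half the box, or to the largest observed
#'   distance for open systems.
#' @return An `rdf_curve`: a tibble with columns `r_A` (bin centers) and
#'   `g`, carrying `dr`, `bulk_density`, `n_frames`, `n_sites` and `r_max`
#'   as attributes.
#' @export
compute_rdf <- function(fs, dr = 0.01, r_max = NULL) {
  stopifnot(inherits(fs, "frame_set"))
  if (dr <= 0) stop("`dr` must be positive", call. = FALSE)
  dists <- lapply(fs$frames, ion_site_distances, box_length = fs$box_length)
  all_d <- unlist(dists)
  if (is.null(r_max)) {
    r_max <- if (!is.null(fs$box_length)) fs$box_length / 2
             else max(all_d) * 1.05
  }
  if (!is.null(fs$box_length) && r_max > fs$box_length / 2 + 1e-9) {
    stop("`r_max` exceeds half the periodic box length", call. = FALSE)
  }
  n_bins <- ceiling(r_max / dr)
  edges <- seq(0, by = dr, length.out = n_bins + 1L)
  centers <- edges[-1L] - dr / 2
  counts <- tabulate(findInterval(all_d[all_d < n_bins * dr], edges,
                                  rightmost.closed = FALSE),
                     nbins = n_bins)
  n_frames <- length(fs$frames)
  if (!is.null(fs$box_length)) {
    rho <- fs$site_count / fs$box_length^3
  } else {
    inner <- 0.9 * r_max
    shell_count <- sum(all_d >= inner & all_d < r_max) / n_frames
    shell_vol <- 4 / 3 * pi * (r_max^3 - inner^3)
    rho <- shell_count / shell_vol
    if (rho <= 0) rho <- fs$site_count / (4 / 3 * pi * r_max^3)
  }
  g <- counts / (n_frames * rho * 4 * pi * centers^2 * dr)
  rdf_curve(centers, g, bulk_density = rho, n_frames = n_frames,
            n_sites = fs$site_count)
}

#' Construct an RDF curve from binned values
#'
#' Assembles an `rdf_curve` from uniformly spaced bin centers and g values,
#' e.g. for curves imported from other tools or built analytically in
#' tests. [compute_rdf()] uses this constructor internally.
#'
#' @param r Bin centers, A, uniformly spaced.
#' @param g Radial distribution values, all non-negative.
#' @param bulk_density Bulk site density, sites per A^3.
#' @param n_frames Number of frames behind the histogram.
#' @param n_sites Sites per frame.
#' @return An `rdf_curve` tibble with `dr`, `bulk_density`, `n_frames`,
#'   `n_sites` and `r_max` attributes.
#' @export
rdf_curve <- function(r, g, bulk_density, n_frames = 1L, n_sites = NA_integer_) {
  if (length(r) < 2L || length(r) != length(g)) {
    stop("`r` and `g` must be equal-length vectors (>= 2 bins)", call. = FALSE)
  }
  dr <- diff(r)
  if (any(abs(dr - dr[1]) > 1e-9 * dr[1])) {
    stop("`r` must be uniformly spaced bin centers", call. = FALSE)
  }
  if (any(g < 0)) stop("g(r) must be non-negative", call. = FALSE)
  out <- tibble::tibble(r_A = r, g = g)
  structure(out,
            dr = dr[1], bulk_density = bulk_density, n_frames = n_frames,
            n_sites = n_sites, r_max = r[length(r)] + dr[1] / 2,
            class = c("rdf_curve", class(out)))
}

rdf_attrs <- function(c) {
  list(dr = attr(c, "dr"), rho = attr(c, "bulk_density"),
       n_frames = attr(c, "n_frames"))
}

# Count-weighted running mean over a `window`-bin neighborhood: smoothed
# g = (summed counts) / (summed expected counts at g = 1). Weighting each
# bin by its shell population keeps single counts in tiny small-r shells
# from blowing up the smoothed curve the way a plain mean of g values would.
smooth_rdf <- function(c, window = 5L) {
  at <- rdf_attrs(c)
  lam <- at$n_frames * at$rho * 4 * pi * c$r_A^2 * at$dr
  cnt <- c$g * lam
  half <- window %/% 2L
  n <- length(cnt)
  g_s <- numeric(n)
  lam_s <- numeric(n)
  for (i in seq_len(n)) {
    win <- max(1L, i - half):min(n, i + half)
    lam_s[i] <- sum(lam[win])
    g_s[i] <- sum(cnt[win]) / lam_s[i]
  }
  list(g = g_s, lam = lam_s)
}

# First-peak detection on the count-weighted smoothed curve: the first bin
# that (a) is the maximum of its `window`-bin neighborhood, (b) exceeds
# `threshold`, (c) exceeds the g = 1 bulk level by at least `z_min` Poisson
# standard errors of its smoothing window, and (d) is followed somewhere by
# a drop below half its height. (c) and (d) together reject statistical
# ripples around g = 1 in structureless data while keeping any genuine
# first solvation peak, which towers over both gates. Returns the raw-curve
# argmax within the neighborhood, or NA when no peak qualifies.
find_first_peak <- function(c, threshold = 1, window = 5L, z_min = 3) {
  sm <- smooth_rdf(c, window)
  g_s <- sm$g
  n <- length(g_s)
  half <- window %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    if (g_s[i] < threshold) next
    if (g_s[i] < max(g_s[lo:hi])) next
    if ((g_s[i] - 1) * sqrt(sm$lam[i]) < z_min) next
    if (i < n && min(g_s[(i + 1L):n]) >= g_s[i] / 2) next
    win <- lo:hi
    return(win[which.max(c$g[win])])
  }
  NA_integer_
}

no_peak_error <- function() {
  stop(structure(
    class = c("chbe_no_peak", "error", "condition"),
    list(message = "no first peak detected in g(r)", call = NULL)
  ))
}

#' Ion-site distance from the first RDF peak
#'
#' Least-squares quadratic fitted to the raw g(r) bins within `window` A of
#' the detected first-peak bin; the fitted parabola's vertex abscissa is
#' returned. If the fitted quadratic opens upward (degenerate data) the raw
#' peak-bin center is returned instead.
#'
#' @param c An `rdf_curve`.
#' @param window Half-width of the fit window in A (default 0.1).
#' @param peak_threshold Minimum smoothed g for peak detection.
#' @return The ion-site distance in A.
#' @export
iod_from_rdf <- function(c, window = 0.1, peak_threshold = 1) {
  stopifnot(inherits(c, "rdf_curve"))
  ipk <- find_first_peak(c, threshold = peak_threshold)
  if (is.na(ipk)) no_peak_error()
  sel <- abs(c$r_A - c$r_A[ipk]) <= window + 1e-12
  r <- c$r_A[sel]
  g <- c$g[sel]
  fit <- stats::lm(g ~ r + I(r^2))
  a <- stats::coef(fit)[["I(r^2)"]]
  b <- stats::coef(fit)[["r"]]
  if (!is.finite(a) || a >= 0) return(c$r_A[ipk])
  -b / (2 * a)
}

# local minima (window-bin neighborhood) of the smoothed curve after the
# peak: the bin must be the smallest of its window AND have a strictly
# larger neighbor in it (a flat plateau is not a dip). Ties broken toward
# smaller r by the scan order.
local_minima_after <- function(g_s, start, window = 5L) {
  half <- window %/% 2L
  n <- length(g_s)
  idx <- integer(0)
  i <- start + 1L
  while (i <= n - 1L) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    win <- g_s[lo:hi]
    if (g_s[i] <= min(win) && max(win) > g_s[i]) {
      idx <- c(idx, i)
      i <- hi + 1L
    } else {
      i <- i + 1L
    }
  }
  idx
}

#' Integrate an RDF to an explicit cutoff radius
#'
#' `n(r_cut) = 4 pi rho sum r^2 g(r) dr` over all bins below `r_cut`;
#' the building block of [cn_from_rdf()], exposed for integration to a
#' user-chosen shell boundary.
#'
#' @param c An `rdf_curve`.
#' @param r_cut Integration cutoff, A.
#' @return The accumulated site count (dimensionless).
#' @export
cn_to <- function(c, r_cut) {
  stopifnot(inherits(c, "rdf_curve"))
  at <- rdf_attrs(c)
  keep <- c$r_A < r_cut
  sum(4 * pi * at$rho * c$r_A[keep]^2 * c$g[keep] * at$dr)
}

#' Coordination number from the first solvation shell
#'
#' Accumulates `n(r) = 4 pi rho sum r^2 g(r) dr` from 0 to the first local
#' minimum after the first peak. Minimum detection runs on a 5-bin smoothed
#' copy of g (the integration always uses the raw curve) and requires the
#' minimum to fall below half the peak height; when no candidate qualifies
#' the result is flagged `minimum_clear = FALSE` and `cn_range` spans the
#' coordination numbers at all candidate minima, mirroring the reporting of
#' a CN range when no clear minimum exists.
#'
#' @param c An `rdf_curve`.
#' @param peak_threshold Minimum smoothed g for peak detection.
#' @return An object of class `coordination_result`: a list with `iod`
#'   (A, `NA` if no peak), `cn`, `first_min_r` (A), `minimum_clear`,
#'   `cn_range` (`NULL` when the minimum is clear) and `peak_found`.
#' @export
cn_from_rdf <- function(c, peak_threshold = 1) {
  stopifnot(inherits(c, "rdf_curve"))
  at <- rdf_attrs(c)
  n_cum <- cumsum(4 * pi * at$rho * c$r_A^2 * c$g * at$dr)
  ipk <- find_first_peak(c, threshold = peak_threshold)
  if (is.na(ipk)) {
    res <- list(iod = NA_real_, cn = NA_real_, first_min_r = NA_real_,
                minimum_clear = FALSE, cn_range = NULL, peak_found = FALSE)
    class(res) <- "coordination_result"
    return(res)
  }
  iod <- iod_from_rdf(c, peak_threshold = peak_threshold)
  g_s <- smooth_rdf(c)$g
  half_height <- g_s[ipk] / 2
  cand <- local_minima_after(g_s, ipk)
  clear <- cand[g_s[cand] < half_height]
  if (length(clear) > 0L) {
    imin <- clear[1]
    res <- list(iod = iod, cn = n_cum[imin], first_min_r = c$r_A[imin],
                minimum_clear = TRUE, cn_range = NULL, peak_found = TRUE)
  } else if (length(cand) > 0L) {
    res <- list(iod = iod, cn = mean(range(n_cum[cand])),
                first_min_r = c$r_A[cand[1]],
                minimum_clear = FALSE, cn_range = range(n_cum[cand]),
                peak_found = TRUE)
  } else {
    last <- length(n_cum)
    res <- list(iod = iod, cn = n_cum[last], first_min_r = NA_real_,
                minimum_clear = FALSE, cn_range = range(n_cum[last]),
                peak_found = TRUE)
  }
  class(res) <- "coordination_result"
  res
}

#' @export
print.coordination_result <- function(x, ...) {
  cat("<coordination_result>\n")
  if (!x$peak_found) {
    cat("  no first peak detected (structureless g(r))\n")
    return(invisible(x))
  }
  cat(sprintf("  IOD = %.3f A, CN = %.2f (first minimum at %.2f A)%s\n",
              x$iod, x$cn, x$first_min_r,
              if (x$minimum_clear) "" else sprintf(
                "  [no clear minimum; CN range %.2f-%.2f]",
                x$cn_range[1], x$cn_range[2])))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coordination_result <- function(x, ...) {
  tibble::tibble(
    iod_A = x$iod,
    cn = x$cn,
    first_min_r_A = x$first_min_r,
    minimum_clear = x$minimum_clear,
    cn_low = if (is.null(x$cn_range)) x$cn else x$cn_range[1],
    cn_high = if (is.null(x$cn_range)) x$cn else x$cn_range[2],
    peak_found = x$peak_found
  )
}

#' Tabulate an RDF with its running coordination number
#'
#' @param c An `rdf_curve`.
#' @return A tibble with columns `r_A`, `g` and the cumulative `n_cum`.
#' @export
rdf_table <- function(c) {
  stopifnot(inherits(c, "rdf_curve"))
  at <- rdf_attrs(c)
  tibble::tibble(
    r_A = c$r_A, g = c$g,
    n_cum = cumsum(4 * pi * at$rho * c$r_A^2 * c$g * at$dr)
  )
}

#' Plot an RDF
#'
#' Line plot of g(r), optionally overlaying the running coordination number
#' `n(r)` on a secondary axis.
#'
#' @param object An `rdf_curve`.
#' @param show_cn Overlay the cumulative coordination number.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rdf_curve <- function(object, show_cn = FALSE, ...) {
  tab <- rdf_table(object)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$r_A, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "g(r)") +
    ggplot2::theme_minimal()
  if (show_cn) {
    scale <- max(tab$g) / max(tab$n_cum, 1e-12)
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$n_cum * scale),
                         linetype = "dashed") +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / scale, name = "n(r)")
      )
  }
  p
}

# ---- XYZ trajectory I/O -----------------------------------------------------

#' Read a frame set from an XYZ trajectory
#'
#' Standard multi-frame XYZ: an atom-count line, a comment line (a
#' `box_length=<L>` token there is honored), then one `element x y z` line
#' per atom. The ion is identified by its element label; every frame must
#' contain exactly one.
#'
#' @param path XYZ file path.
#' @param ion_element Element label of the ion (default `"M"`).
#' @return A [frame_set()].
#' @export
read_xyz <- function(path, ion_element = "M") {
  lines <- readLines(path)
  frames <- list()
  box_length <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L) {
      stop("XYZ parse error at line ", i, ": expected an atom count",
           call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop("XYZ parse error at line ", i, ": truncated frame (",
           nat, " atoms declared)", call. = FALSE)
    }
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec("box_length=([0-9.eE+-]+)", comment))[[1]]
    if (length(m) == 2L) box_length <- as.numeric(m[2])
    elems <- character(nat)
    xyz <- matrix(NA_real_, nat, 3L)
    for (k in seq_len(nat)) {
      ln <- i + 1L + k
      parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(parts) < 4L) {
        stop("XYZ parse error at line ", ln, ": expected `element x y z`",
             call. = FALSE)
      }
      coords <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(coords))) {
        stop("XYZ parse error at line ", ln, ": non-numeric coordinate",
             call. = FALSE)
      }
      elems[k] <- parts[1]
      xyz[k, ] <- coords
    }
    is_ion <- elems == ion_element
    if (sum(is_ion) != 1L) {
      stop("XYZ frame starting at line ", i, " has ", sum(is_ion),
           " atoms labeled `", ion_element, "`; expected exactly one ion",
           call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- list(
      ion = xyz[is_ion, ],
      sites = xyz[!is_ion, , drop = FALSE]
    )
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) stop("XYZ file contains no frames", call. = FALSE)
  frame_set(frames, box_length = box_length)
}

#' Write a frame set as an XYZ trajectory
#'
#' @param fs A [frame_set()].
#' @param path Output file path.
#' @param ion_element,site_element Element labels to emit.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(fs, path, ion_element = "M", site_element = "O") {
  stopifnot(inherits(fs, "frame_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in fs$frames) {
    nat <- nrow(f$sites) + 1L
    comment <- if (is.null(fs$box_length)) "open boundary"
               else sprintf("box_length=%.8g", fs$box_length)
    writeLines(c(
      as.character(nat), comment,
      sprintf("%s %.8f %.8f %.8f", ion_element, f$ion[1], f$ion[2], f$ion[3]),
      sprintf("%s %.8f %.8f %.8f", site_element,
              f$sites[, 1], f$sites[, 2], f$sites[, 3])
    ), con)
  }
  invisible(path)
}
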