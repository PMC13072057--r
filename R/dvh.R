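# Cumulative dose-volume histograms on a uniform dose grid.

#' Cumulative dose-volume histogram
#'
#' A cumulative DVH gives, for each dose level, the fraction of a structure's
#' volume receiving at least that dose. The representation is a uniform dose
#' grid starting at 0 Gy with a non-increasing volume-fraction vector whose
#' first value is 1.
#'
#' @param dose dose grid in Gy: strictly increasing, uniform spacing,
#'   starting at 0.
#' @param volume volume fractions in \[0, 1\]: `volume[1] == 1`, monotone
#'   non-increasing.
#' @param check validate the invariants (default TRUE).
#' @return an object of class `dvh` with elements `dose`, `volume` and
#'   `bin_width`.
#' @examples
#' d <- delta_dvh(2)          # all of the volume receives exactly 2 Gy
#' mean_dose(d)
#' @export
dvh <- function(dose, volume, check = TRUE) {
  dose <- as.numeric(dose)
  volume <- as.numeric(volume)
  if (check) {
    if (length(dose) < 2 || length(dose) != length(volume)) {
      stop("'dose' and 'volume' must be equal-length vectors of length >= 2")
    }
    if (any(!is.finite(dose)) || any(!is.finite(volume))) stop("non-finite values in DVH")
    if (abs(dose[1]) > 1e-12) stop("dose grid must start at 0 Gy")
    bw <- diff(dose)
    if (any(bw <= 0)) stop("dose grid must be strictly increasing")
    if (max(bw) - min(bw) > 1e-6 * max(bw)) stop("dose grid must be uniform")
    if (abs(volume[1] - 1) > 1e-9) stop("volume fraction at 0 Gy must be 1")
    if (any(diff(volume) > 1e-9)) {
      stop("volume fractions must be non-increasing (first violation at index ",
           which(diff(volume) > 1e-9)[1] + 1, ")")
    }
    if (volume[length(volume)] < -1e-12 || any(volume > 1 + 1e-9)) {
      stop("volume fractions must lie in [0, 1]")
    }
  }
  volume <- pmin(pmax(volume, 0), 1)
  structure(list(dose = dose, volume = volume, bin_width = dose[2] - dose[1]),
            class = "dvh")
}

#' Degenerate (single-dose) DVH
#'
#' A step DVH in which the whole volume receives exactly `d` Gy: the volume
#' fraction is 1 up to `d` and 0 beyond. On a grid of width `bin_width` the
#' step is resolved to within one bin.
#'
#' @param d the dose received by the entire volume, Gy.
#' @param bin_width dose grid spacing, Gy.
#' @return a `dvh`.
#' @export
delta_dvh <- function(d, bin_width = 0.01) {
  stopifnot(d >= 0, bin_width > 0)
  n_up <- max(1L, ceiling(d / bin_width - 1e-9))
  grid <- seq(0, by = bin_width, length.out = n_up + 2L)
  dvh(grid, as.numeric(grid <= d + 1e-12))
}

#' Evaluate a survival function on a uniform grid as a DVH
#'
#' @param fn vectorized function of dose returning volume fractions.
#' @param max_dose upper end of the grid, Gy.
#' @param bin_width grid spacing, Gy.
#' @return a `dvh`.
#' @export
dvh_from_function <- function(fn, max_dose, bin_width = 0.01) {
  grid <- seq(0, by = bin_width, length.out = ceiling(max_dose / bin_width) + 1L)
  v <- fn(grid)
  v[1] <- 1
  v <- cummin(pmin(pmax(v, 0), 1))  # guard against fp wiggle in the tail
  dvh(grid, v)
}

#' Scale the dose axis of a DVH
#'
#' Multiplies every dose by `factor`, leaving volume fractions untouched;
#' the grid stays uniform with bin width scaled accordingly. The mean dose
#' scales exactly by `factor`.
#'
#' @param x a `dvh`.
#' @param factor positive scale factor.
#' @return a `dvh`.
#' @export
scale_dose <- function(x, factor) {
  stopifnot(inherits(x, "dvh"), is.numeric(factor), factor > 0)
  dvh(x$dose * factor, x$volume, check = FALSE)
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("Cumulative DVH: %d bins of %.4g Gy, max dose %.3f Gy, mean dose %.3f Gy\n",
              length(x$dose), x$bin_width, max_dose(x), mean_dose(x)))
  invisible(x)
}

#' @export
as.data.frame.dvh <- function(x, ...) {
  data.frame(dose_gy = x$dose, volume_fraction = x$volume)
}

#' @export
plot.dvh <- function(x, ..., xlab = "Dose (Gy)", ylab = "Volume fraction", type = "l") {
  plot(x$dose, x$volume, type = type, xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

# ---- CSV I/O --------------------------------------------------------------

#' Read or write organ DVH maps as CSV
#'
#' The CSV dialect has columns `organ,dose_gy,volume_fraction`, one row per
#' grid point, grouped by organ. Writing uses a round-trippable decimal
#' representation so that `read_dvh_csv(write_dvh_csv(x))` reproduces `x`
#' bit-exactly on the same grid.
#'
#' @param path file path.
#' @param x named list of `dvh` objects (possibly empty).
#' @return `read_dvh_csv` returns a named list of `dvh` objects;
#'   `write_dvh_csv` returns `path` invisibly.
#' @export
read_dvh_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- data.table::fread(path, colClasses = list(character = "organ"), showProgress = FALSE)
  need <- c("organ", "dose_gy", "volume_fraction")
  if (!all(need %in% names(tab))) {
    stop("DVH CSV must have header columns: ", paste(need, collapse = ","))
  }
  if (nrow(tab) == 0) return(stats::setNames(list(), character(0)))
  out <- list()
  # row bookkeeping so invariant violations can cite the offending file row
  row0 <- cumsum(c(0, rle(tab$organ)$lengths))
  organs <- rle(tab$organ)$values
  if (anyDuplicated(organs)) stop("DVH CSV: rows for each organ must be contiguous")
  for (i in seq_along(organs)) {
    idx <- (row0[i] + 1):row0[i + 1]
    d <- tab$dose_gy[idx]
    v <- tab$volume_fraction[idx]
    bad <- which(diff(v) > 1e-9)
    if (length(bad)) {
      stop(sprintf("DVH CSV: volume_fraction increases for organ '%s' at file row %d",
                   organs[i], idx[bad[1] + 1] + 1L))  # +1 for the header line
    }
    out[[organs[i]]] <- tryCatch(dvh(d, v), error = function(e) {
      stop(sprintf("DVH CSV: invalid DVH for organ '%s' (rows %d-%d): %s",
                   organs[i], idx[1] + 1L, idx[length(idx)] + 1L, conditionMessage(e)))
    })
  }
  out
}

#' @rdname read_dvh_csv
#' @export
write_dvh_csv <- function(x, path) {
  stopifnot(is.list(x))
  if (length(x) == 0) {
    data.table::fwrite(data.table::data.table(organ = character(0), dose_gy = numeric(0),
                                              volume_fraction = numeric(0)), path)
    return(invisible(path))
  }
  if (is.null(names(x)) || any(names(x) == "")) stop("DVH list must be named by organ")
  parts <- lapply(names(x), function(o) {
    stopifnot(inherits(x[[o]], "dvh"))
    # 17 significant digits: doubles survive the text round trip bit-exactly
    data.table::data.table(organ = o,
                           dose_gy = sprintf("%.17g", x[[o]]$dose),
                           volume_fraction = sprintf("%.17g", x[[o]]$volume))
  })
  data.table::fwrite(data.table::rbindlist(parts), path)
  invisible(path)
}

# ---- scalar metrics -------------------------------------------------------

# Inverse of the survival curve, as a piecewise-linear quantile table with q
# ascending. The leading plateau at 1 keeps only its upper-dose end (so the
# uniform-dose DVH returns its dose for every n, including n = 100) and the
# trailing zeros keep only the first zero; interior flat runs keep both
# ends, and a query exactly at a run's level resolves to the lower dose.
# Queries below the smallest positive volume fraction return the maximum
# grid dose.
.dvh_inverse <- function(x) {
  v <- x$volume
  d <- x$dose
  n <- length(v)
  i0 <- max(which(v >= 1 - 1e-12))          # end of the leading plateau at 1
  iz <- which(v <= 1e-12)
  i1 <- if (length(iz)) iz[1] else n        # first zero (or grid end)
  if (i1 <= i0) i1 <- min(i0 + 1L, n)
  v <- v[i0:i1]
  d <- d[i0:i1]
  m <- length(v)
  if (m > 2) {
    first <- c(TRUE, v[-1] != v[-m])        # first point of each flat run
    last <- c(v[-m] != v[-1], TRUE)         # last point of each flat run
    keep <- first | last
    v <- v[keep]
    d <- d[keep]
  }
  list(q = rev(v), dose = rev(d))           # q ascending, dose descending
}

.dvh_quantile <- function(x, q) {
  inv <- .dvh_inverse(x)
  xv <- inv$q
  yv <- inv$dose
  if (length(xv) == 1L) return(rep(yv, length(q)))
  j <- findInterval(q, xv, all.inside = TRUE)
  dx <- xv[j + 1] - xv[j]
  out <- yv[j] + (yv[j + 1] - yv[j]) * (q - xv[j]) / dx
  out[q <= xv[1]] <- yv[1]                  # below curve minimum: max dose
  out[q >= xv[length(xv)]] <- yv[length(yv)]
  out
}

#' Dose at volume (Dn%)
#'
#' The minimum dose received by the most-irradiated `n` percent of the
#' volume, obtained by linear interpolation of the cumulative DVH. For an
#' idealized step DVH the result is exact to within one grid bin.
#'
#' @param x a `dvh`.
#' @param n percent of volume, in (0, 100\]; may be a vector.
#' @return dose(s) in Gy.
#' @export
d_at_volume <- function(x, n) {
  stopifnot(inherits(x, "dvh"))
  if (any(!is.finite(n)) || any(n <= 0) || any(n > 100)) {
    stop("'n' must lie in (0, 100]")
  }
  .dvh_quantile(x, n / 100)
}

#' Volume at dose (VxGy)
#'
#' The fraction of the volume receiving at least `d` Gy, by linear
#' interpolation; doses beyond the grid return the final grid value.
#'
#' @param x a `dvh`.
#' @param d dose(s) in Gy, non-negative.
#' @return volume fraction(s) in \[0, 1\].
#' @export
v_at_dose <- function(x, d) {
  stopifnot(inherits(x, "dvh"))
  if (any(!is.finite(d)) || any(d < 0)) stop("'d' must be non-negative")
  stats::approx(x$dose, x$volume, xout = d, rule = 2)$y
}

#' Mean and maximum dose of a DVH
#'
#' The mean dose is the area under the cumulative DVH (trapezoidal rule on
#' the grid); the maximum dose is the highest grid dose whose volume
#' fraction exceeds `tol`.
#'
#' @param x a `dvh`.
#' @param tol volume-fraction tolerance for `max_dose`.
#' @return dose in Gy.
#' @export
mean_dose <- function(x) {
  stopifnot(inherits(x, "dvh"))
  v <- x$volume
  sum((v[-1] + v[-length(v)]) / 2) * x$bin_width
}

#' @rdname mean_dose
#' @export
max_dose <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "dvh"))
  i <- which(x$volume > tol)
  if (!length(i)) return(0)
  x$dose[max(i)]
}

#' Homogeneity index (HI)
#'
#' `HI = D5% / D95%` within a target volume; values closer to 1 indicate a
#' more homogeneous dose.
#'
#' @param x a `dvh` for a planning target volume.
#' @return unitless HI (>= 1 up to interpolation error).
#' @export
homogeneity_index <- function(x) {
  d95 <- d_at_volume(x, 95)
  if (d95 <= 0) stop("homogeneity index undefined: D95% is zero")
  d_at_volume(x, 5) / d95
}

#' Conformity index (CI)
#'
#' The ratio of the tissue volume receiving at least 95% of the prescription
#' dose to the planning target volume, reported in percent.
#'
#' @param volume_95_isodose volume inside the 95% isodose, cm^3 (> 0).
#' @param ptv_volume planning target volume, cm^3 (> 0).
#' @return CI in percent.
#' @export
conformity_index <- function(volume_95_isodose, ptv_volume) {
  if (any(volume_95_isodose <= 0) || any(ptv_volume <= 0)) {
    stop("volumes must be positive")
  }
  100 * volume_95_isodose / ptv_volume
}
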