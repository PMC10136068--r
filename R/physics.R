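#' Uniform photon-energy grid
#'
#' The polychromatic forward model discretizes the tube spectrum on a uniform
#' energy grid; all spectra and attenuation tables in a simulation share one
#' grid so that per-energy weights line up index by index.
#'
#' @param e_min,e_max Grid limits in keV, `0 < e_min < e_max`.
#' @param step Energy spacing in keV.
#' @return An object of class `energy_grid` with fields `energies` (keV vector)
#'   and `step` (keV scalar).
#' @examples
#' g <- make_energy_grid(20, 120, 1)
#' length(g$energies)  # 101
#' @export
make_energy_grid <- function(e_min, e_max, step) {
  if (!is.numeric(e_min) || !is.numeric(e_max) || !is.numeric(step) ||
      length(e_min) != 1L || length(e_max) != 1L || length(step) != 1L) {
    stop("e_min, e_max and step must be numeric scalars", call. = FALSE)
  }
  if (e_min <= 0 || e_max <= e_min || step <= 0) {
    stop("require 0 < e_min < e_max and step > 0", call. = FALSE)
  }
  m <- round((e_max - e_min) / step) + 1L
  energies <- e_min + step * (seq_len(m) - 1)
  structure(list(energies = energies, step = step), class = "energy_grid")
}

is_energy_grid <- function(x) inherits(x, "energy_grid")

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("<energy_grid> %d energies, %.4g..%.4g keV, step %.4g keV\n",
              length(x$energies), min(x$energies), max(x$energies), x$step))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$energies) == length(b$energies) &&
    isTRUE(all.equal(a$energies, b$energies, tolerance = 1e-12))
}

# ---------------------------------------------------------------------------
# Embedded mass-attenuation tables (cm^2/g), coarse knots over 20--150 keV.
# Standard published values for water (soft-tissue surrogate), cortical bone,
# elemental iodine and aluminum, with gaps filled by log-log interpolation at
# table-authoring time. The iodine K edge at 33.1694 keV is represented by a
# pair of adjacent knots so interpolation never bridges the discontinuity.
# ---------------------------------------------------------------------------

.matdb <- local({
  water_e <- c(20, 25, 30, 35, 40, 50, 60, 70, 80, 90, 100, 120, 150)
  water_m <- c(0.8096, 0.5305, 0.3756, 0.3138, 0.2683, 0.2269, 0.2059,
               0.1937, 0.1837, 0.1767, 0.1707, 0.1613, 0.1505)
  bone_m  <- c(4.001, 2.1817, 1.331, 0.9186, 0.6655, 0.4242, 0.3148,
               0.2617, 0.2229, 0.2023, 0.1855, 0.1676, 0.1480)
  al_m    <- c(3.441, 1.861, 1.128, 0.7819, 0.5685, 0.3681, 0.2778,
               0.2341, 0.2018, 0.1846, 0.1704, 0.1549, 0.1378)
  iod_e <- c(20, 25, 30, 33.1694, 33.1695, 36, 40, 45, 50, 60, 70, 80,
             90, 100, 120, 150)
  iod_m <- c(25.43, 13.96, 8.561, 6.553, 36.33, 29.25, 22.10, 16.22,
             12.32, 7.579, 5.021, 3.510, 2.568, 1.942, 1.235, 0.7079)
  list(
    water    = list(e = water_e, mu_rho = water_m, density = 1.00),
    tissue   = list(e = water_e, mu_rho = water_m, density = 1.00),
    bone     = list(e = water_e, mu_rho = bone_m,  density = 1.92),
    # basis coefficient 1.0 corresponds to the 10 mg/mL reference
    # concentration (0.010 g/cm^3 of iodine in solution)
    iodine   = list(e = iod_e,   mu_rho = iod_m,   density = 0.010),
    aluminum = list(e = water_e, mu_rho = al_m,    density = 2.699)
  )
})

# log-log linear interpolation of a mass-attenuation table
loglog_interp <- function(e_knots, mu_knots, e_query) {
  if (any(e_query < min(e_knots) - 1e-9) || any(e_query > max(e_knots) + 1e-9)) {
    stop("requested energy outside embedded table range (",
         min(e_knots), "-", max(e_knots), " keV)", call. = FALSE)
  }
  out <- stats::approx(log(e_knots), log(mu_knots), xout = log(e_query),
                       method = "linear", rule = 2)$y
  exp(out)
}

#' Built-in linear attenuation table for basis materials
#'
#' Interpolates embedded coarse mass-attenuation tables (water/tissue,
#' cortical bone, iodine, aluminum) onto an energy grid and scales them to
#' linear attenuation in 1/mm per unit basis coefficient. The basis
#' coefficient convention is dimensionless: 1.0 equals the material's
#' reference density (tissue 1.0 g/cm3, bone 1.92 g/cm3, iodine 10 mg/mL).
#'
#' @param materials Character vector of labels among
#'   `"tissue"`, `"water"`, `"bone"`, `"iodine"`, `"aluminum"`.
#' @param grid An [make_energy_grid()] object.
#' @return An `attenuation_table` with fields `grid`, `names`,
#'   `mu` (M energies x K materials, 1/mm) and `reference_density` (g/cm3).
#' @export
builtin_attenuation_table <- function(materials, grid) {
  stopifnot(is_energy_grid(grid))
  unknown <- setdiff(materials, names(.matdb))
  if (length(unknown)) {
    stop("unknown material label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mu <- vapply(materials, function(m) {
    db <- .matdb[[m]]
    # cm^2/g * g/cm^3 = 1/cm; /10 -> 1/mm
    loglog_interp(db$e, db$mu_rho, grid$energies) * db$density / 10
  }, numeric(length(grid$energies)))
  mu <- matrix(mu, nrow = length(grid$energies),
               dimnames = list(NULL, materials))
  structure(list(grid = grid, names = materials, mu = mu,
                 reference_density = vapply(materials,
                                            function(m) .matdb[[m]]$density,
                                            numeric(1))),
            class = "attenuation_table")
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat(sprintf("<attenuation_table> %d energies x %d materials (%s)\n",
              nrow(x$mu), ncol(x$mu), paste(x$names, collapse = ", ")))
  invisible(x)
}

# Kramers-form bremsstrahlung fluence on the grid (unnormalized), zero above
# the tube potential.
kramers_fluence <- function(kvp, energies) {
  n <- pmax(kvp / energies - 1, 0)
  n[energies > kvp] <- 0
  n
}

#' Parametric binned X-ray spectrum
#'
#' Generates a 120 kVp-class tube spectrum from a Kramers-form bremsstrahlung
#' model, applies aluminum filtration, splits it at the photon-counting
#' detector thresholds, and normalizes each bin to unit sum. Bin `s` has
#' support `[thresholds[s], thresholds[s+1])`; the last bin extends to the
#' tube potential inclusive.
#'
#' @param kvp Tube potential in keV (also the spectrum endpoint).
#' @param al_filter_mm Aluminum filtration thickness in mm.
#' @param thresholds Strictly increasing detector thresholds in keV; the
#'   number of bins equals `length(thresholds)`.
#' @param grid Energy grid covering `[min(thresholds), kvp]`.
#' @return A `binned_spectra` object: `grid`, `S` (bins x energies weight
#'   matrix, rows summing to 1), `thresholds` (S+1 bin edges).
#' @export
make_spectrum <- function(kvp, al_filter_mm, thresholds, grid) {
  stopifnot(is_energy_grid(grid))
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  e <- grid$energies
  if (kvp > max(e) + 1e-9) stop("kvp exceeds the energy grid", call. = FALSE)
  if (min(thresholds) < min(e) - 1e-9 || max(thresholds) > kvp + 1e-9) {
    stop("thresholds must lie within [grid minimum, kvp]", call. = FALSE)
  }
  raw <- kramers_fluence(kvp, e)
  if (al_filter_mm > 0) {
    al <- .matdb$aluminum
    mu_al <- loglog_interp(al$e, al$mu_rho, pmin(e, max(al$e))) * al$density / 10
    raw <- raw * exp(-mu_al * al_filter_mm)
  }
  edges <- c(thresholds, kvp)
  ns <- length(thresholds)
  S <- matrix(0, nrow = ns, ncol = length(e))
  for (s in seq_len(ns)) {
    inside <- if (s < ns) e >= edges[s] & e < edges[s + 1]
              else        e >= edges[s] & e <= edges[s + 1] + 1e-9
    w <- raw * inside
    tot <- sum(w)
    if (tot <= 0) {
      stop(sprintf("degenerate bin %d: no spectral weight in [%g, %g) keV",
                   s, edges[s], edges[s + 1]), call. = FALSE)
    }
    S[s, ] <- w / tot
  }
  structure(list(grid = grid, S = S, thresholds = edges),
            class = "binned_spectra")
}

#' @export
print.binned_spectra <- function(x, ...) {
  cat(sprintf("<binned_spectra> %d bins on %d energies; edges %s keV\n",
              nrow(x$S), ncol(x$S),
              paste(format(x$thresholds), collapse = ", ")))
  invisible(x)
}

#' Per-bin mean energies of a binned spectrum (keV)
#' @param spectra A `binned_spectra` object.
#' @export
bin_mean_energy <- function(spectra) {
  as.numeric(spectra$S %*% spectra$grid$energies)
}

#' Spectrum-weighted effective attenuation per bin
#'
#' Effective (bin-mean) linear attenuation of each basis material under each
#' bin's normalized spectrum: `mu_bar[s, k] = sum_m S[s, m] * mu[m, k]`. This
#' is the decomposition matrix used by the image-domain baseline and equals
#' the linearization weights of the polychromatic model at zero material
#' images.
#'
#' @param spectra A `binned_spectra`.
#' @param table An `attenuation_table` on the same grid.
#' @return Numeric matrix, bins x materials, 1/mm.
#' @export
bin_mean_mu <- function(spectra, table) {
  stopifnot(inherits(spectra, "binned_spectra"),
            inherits(table, "attenuation_table"))
  if (!same_grid(spectra$grid, table$grid)) {
    stop("spectra and attenuation table use different energy grids",
         call. = FALSE)
  }
  m <- spectra$S %*% table$mu
  dimnames(m) <- list(NULL, table$names)
  m
}

# ---------------------------------------------------------------------------
# Plain-text import/export: (energy, value) or (energy, value x K) columns,
# '#' comments, full double precision so a write/read cycle is bit-exact.
# ---------------------------------------------------------------------------

#' Write an energy-indexed table as plain text
#'
#' @param path Output file.
#' @param energies keV vector.
#' @param values Vector or matrix (one column per series) conformable with
#'   `energies`.
#' @param comments Character vector written as leading `#` comment lines.
#' @export
write_energy_table <- function(path, energies, values, comments = character()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(energies))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  rows <- cbind(energies, values)
  txt <- apply(rows, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(txt, con)
  invisible(path)
}

#' Read an energy-indexed plain-text table
#'
#' @param path Input file written by [write_energy_table()] or any
#'   whitespace/CSV table of `(energy, value, ...)` rows with `#` comments.
#' @return List with `energies`, `values` (matrix), `comments`.
#' @export
read_energy_table <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  comments <- sub("^\\s*#\\s?", "", lines[is_comment])
  body <- lines[!is_comment & nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(body), "[,[:space:]]+"), as.numeric)
  mat <- do.call(rbind, rows)
  list(energies = mat[, 1], values = mat[, -1, drop = FALSE],
       comments = comments)
}

#' Export / import binned spectra as plain text
#'
#' The text form has one row per grid energy and one column per bin, plus a
#' header comment carrying the bin edges so the object round-trips exactly.
#' @param spectra A `binned_spectra`.
#' @param path File path.
#' @export
export_spectra <- function(spectra, path) {
  write_energy_table(path, spectra$grid$energies, t(spectra$S),
                     comments = c("binned_spectra",
                                  paste("thresholds:",
                                        paste(sprintf("%.17g", spectra$thresholds),
                                              collapse = " "))))
}

#' @rdname export_spectra
#' @export
import_spectra <- function(path) {
  tb <- read_energy_table(path)
  th_line <- grep("^thresholds:", tb$comments, value = TRUE)
  if (!length(th_line)) stop("not a spectra table: missing thresholds header",
                             call. = FALSE)
  thresholds <- as.numeric(strsplit(sub("^thresholds:\\s*", "", th_line),
                                    "\\s+")[[1]])
  step <- tb$energies[2] - tb$energies[1]
  grid <- structure(list(energies = tb$energies, step = step),
                    class = "energy_grid")
  structure(list(grid = grid, S = t(tb$values), thresholds = thresholds),
            class = "binned_spectra")
}

#' Export / import an attenuation table as plain text
#' @param table An `attenuation_table`.
#' @param path File path.
#' @export
export_attenuation <- function(table, path) {
  write_energy_table(path, table$grid$energies, table$mu,
                     comments = c("attenuation_table",
                                  paste("materials:",
                                        paste(table$names, collapse = " ")),
                                  paste("reference_density:",
                                        paste(sprintf("%.17g", table$reference_density),
                                              collapse = " "))))
}

#' @rdname export_attenuation
#' @export
import_attenuation <- function(path) {
  tb <- read_energy_table(path)
  nm_line <- grep("^materials:", tb$comments, value = TRUE)
  rd_line <- grep("^reference_density:", tb$comments, value = TRUE)
  names <- strsplit(sub("^materials:\\s*", "", nm_line), "\\s+")[[1]]
  rd <- as.numeric(strsplit(sub("^reference_density:\\s*", "", rd_line),
                            "\\s+")[[1]])
  step <- tb$energies[2] - tb$energies[1]
  grid <- structure(list(energies = tb$energies, step = step),
                    class = "energy_grid")
  mu <- tb$values
  dimnames(mu) <- list(NULL, names)
  structure(list(grid = grid, names = names, mu = mu,
                 reference_density = stats::setNames(rd, names)),
            class = "attenuation_table")
}
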