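#' Beam configuration for the synthetic track fixture
#'
#' The fixture stands in for a full track-structure physics engine: it
#' produces straight particle trajectories crossing the nucleus from a
#' source plane, energy-deposit events whose linear density matches the
#' requested LET, and radiolysis species born near the deposits. LET is an
#' input (e.g. ICRU-90 values for the particle and energy of interest),
#' never computed. Gamma sources are represented by their low-LET
#' electron-proxy tracks.
#'
#' @param particle `"proton"`, `"alpha"` or `"electron-proxy"`.
#' @param energy_MeV nominal kinetic energy (bookkeeping only).
#' @param let_keV_um linear energy transfer at the cell entrance, keV/um.
#' @param n_primaries number of primary particles.
#' @param source_offset_um distance of the source plane from the nucleus
#'   surface along the beam axis, um.
#' @param direction beam direction; must be along a coordinate axis.
#' @param mean_deposit_eV mean energy of one deposition event, eV.
#' @param deposit_range_eV truncation range of the per-event energy
#'   spectrum, eV.
#' @param penumbra_nm scale of the exponential radial displacement of
#'   deposits from the track axis, nm.
#' @return a `beam_config`.
#' @export
beam_config <- function(particle = c("proton", "alpha", "electron-proxy"),
                        energy_MeV = 1, let_keV_um = 25.8,
                        n_primaries = 10L, source_offset_um = 3,
                        direction = c(0, 0, 1),
                        mean_deposit_eV = 45,
                        deposit_range_eV = c(5, 500),
                        penumbra_nm = 2) {
  particle <- match.arg(particle)
  if (!is.numeric(let_keV_um) || let_keV_um <= 0) stop("LET must be > 0")
  if (n_primaries < 0) stop("n_primaries must be >= 0")
  if (sum(direction != 0) != 1)
    stop("beam direction must be along a coordinate axis")
  direction <- direction / sqrt(sum(direction^2))
  structure(list(particle = particle, energy_MeV = energy_MeV,
                 let_keV_um = let_keV_um,
                 n_primaries = as.integer(n_primaries),
                 source_offset_um = source_offset_um,
                 direction = as.numeric(direction),
                 mean_deposit_eV = mean_deposit_eV,
                 deposit_range_eV = as.numeric(deposit_range_eV),
                 penumbra_nm = penumbra_nm),
            class = "beam_config")
}

#' Sample primary particle trajectories
#'
#' Entry points are uniform over the nucleus' projected ellipse on a source
#' plane perpendicular to the beam axis, placed `source_offset_um` beyond
#' the nucleus surface so the plane never intersects the nucleus.
#' Trajectories are straight lines along the beam direction.
#'
#' @param beam a [beam_config()].
#' @param nucleus a [nucleus_model()].
#' @param seed optional integer seed for this sampling step; the pipeline
#'   normally manages per-primary seeding itself.
#' @return data frame with one row per primary: `primary_id`, entry point
#'   `x0`, `y0`, `z0` (nm, on the source plane) and direction `dx`, `dy`,
#'   `dz`.
#' @export
sample_primaries <- function(beam, nucleus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- beam$n_primaries
  axis <- which(beam$direction != 0)
  sgn <- sign(beam$direction[axis])
  semi_nm <- nucleus$semi_axes_um * 1000
  plane_pos <- -sgn * (semi_nm[axis] + beam$source_offset_um * 1000)
  if (n == 0)
    return(data.frame(primary_id = integer(), x0 = numeric(), y0 = numeric(),
                      z0 = numeric(), dx = numeric(), dy = numeric(),
                      dz = numeric()))
  lat <- setdiff(1:3, axis)
  # uniform in the projected ellipse via radius sqrt
  th <- runif(n, 0, 2 * pi)
  rr <- sqrt(runif(n))
  p <- matrix(0, n, 3)
  p[, lat[1]] <- rr * cos(th) * semi_nm[lat[1]]
  p[, lat[2]] <- rr * sin(th) * semi_nm[lat[2]]
  p[, axis] <- plane_pos
  data.frame(primary_id = seq_len(n) - 1L,
             x0 = p[, 1], y0 = p[, 2], z0 = p[, 3],
             dx = beam$direction[1], dy = beam$direction[2],
             dz = beam$direction[3])
}

# Entry/exit parameters (t along the line, nm) of a line with an ellipsoid
# of semi-axes `semi` (nm); NULL when the line misses it.
line_ellipsoid_chord <- function(p0, dir, semi) {
  a <- sum((dir / semi)^2)
  b <- 2 * sum(p0 * dir / semi^2)
  cc <- sum((p0 / semi)^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(NULL)
  t1 <- (-b - sqrt(disc)) / (2 * a)
  t2 <- (-b + sqrt(disc)) / (2 * a)
  c(t1, t2)
}

#' Generate energy-deposit events along one trajectory
#'
#' Events are placed along the track's chord through the nucleus at
#' exponentially distributed spacings with mean `mean_deposit_eV / LET`,
#' so the empirical energy per unit path length converges to the
#' configured LET. Per-event energies follow a truncated-exponential
#' spectrum with mean `mean_deposit_eV`; deposits are displaced radially
#' from the track axis by an exponential penumbra.
#'
#' @param trajectory one row of [sample_primaries()] output (or a list with
#'   the same fields).
#' @param beam a [beam_config()].
#' @param nucleus a [nucleus_model()].
#' @param seed optional seed.
#' @return data frame of deposits: `primary_id`, `event_id`, `x`, `y`, `z`
#'   (nm), `energy_eV`.
#' @export
generate_deposits <- function(trajectory, beam, nucleus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(primary_id = integer(), event_id = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      energy_eV = numeric())
  p0 <- c(trajectory$x0, trajectory$y0, trajectory$z0)
  dir <- c(trajectory$dx, trajectory$dy, trajectory$dz)
  semi_nm <- nucleus$semi_axes_um * 1000
  chord <- line_ellipsoid_chord(p0, dir, semi_nm)
  if (is.null(chord)) return(empty)
  len <- chord[2] - chord[1]
  if (len <= 0) return(empty)
  spacing_nm <- beam$mean_deposit_eV / beam$let_keV_um # eV/(keV/um) = nm
  n_exp <- len / spacing_nm
  gaps <- rexp(max(16, ceiling(n_exp + 6 * sqrt(n_exp))), rate = 1 / spacing_nm)
  pos <- chord[1] + cumsum(gaps)
  while (sum(gaps) < len) {           # rare top-up
    gaps <- c(gaps, rexp(16, rate = 1 / spacing_nm))
    pos <- chord[1] + cumsum(gaps)
  }
  pos <- pos[pos <= chord[2]]
  m <- length(pos)
  if (m == 0) return(empty)
  e <- rtrunc_exp(m, beam$mean_deposit_eV, beam$deposit_range_eV)
  centers <- outer(pos, dir) + matrix(p0, m, 3, byrow = TRUE)
  # radial penumbra
  perp1 <- perpendicular_axis(round(dir))
  perp2 <- cross3(dir, perp1)
  rad <- rexp(m, rate = 1 / beam$penumbra_nm)
  ang <- runif(m, 0, 2 * pi)
  centers <- centers + outer(rad * cos(ang), perp1) + outer(rad * sin(ang), perp2)
  data.frame(primary_id = trajectory$primary_id %||% 0L,
             event_id = seq_len(m) - 1L,
             x = centers[, 1], y = centers[, 2], z = centers[, 3],
             energy_eV = e)
}

# truncated exponential with requested mean, by solving for the rate
rtrunc_exp <- function(n, mean, range) {
  a <- range[1]; b <- range[2]
  stopifnot(mean > a, mean < (a + b) / 2 || TRUE)
  m_of <- function(lam) {
    ea <- exp(-lam * a); eb <- exp(-lam * b)
    1 / lam + (a * ea - b * eb) / (ea - eb)
  }
  lam <- uniroot(function(l) m_of(l) - mean,
                 lower = 1e-6, upper = 2 / (mean - a))$root
  u <- runif(n)
  fa <- 1 - exp(-lam * a); fb <- 1 - exp(-lam * b)
  -log(1 - (fa + u * (fb - fa))) / lam
}

#' Default radiolysis species yields
#'
#' Expected species per 100 eV deposited (G-value-like), used by
#' [spawn_species()]. The set covers the standard products of water
#' radiolysis at the end of the pre-chemical stage; values are
#' configurable surrogates, not measured G-values.
#'
#' @return named numeric vector, species per 100 eV.
#' @export
default_yield_table <- function() {
  c("OH" = 2.8, "e_aq" = 2.8, "H" = 0.6, "H2" = 0.2,
    "H3O" = 2.8, "OHm" = 0.5, "H2O2" = 0.2)
}

#' Default species diffusion coefficients
#'
#' @return named numeric vector, nm^2/ns.
#' @export
default_diffusion_table <- function() {
  c("OH" = 2.8, "e_aq" = 4.9, "H" = 7.0, "H2" = 4.8,
    "H3O" = 9.46, "OHm" = 5.3, "H2O2" = 2.3)
}

#' Spawn radiolysis species around energy deposits
#'
#' For each deposit and species the count is Poisson with mean
#' `G * E / 100`; positions are Gaussian-jittered around the deposit and
#' birth times are zero (pre-chemical displacement is absorbed into the
#' jitter).
#'
#' @param deposits data frame from [generate_deposits()].
#' @param yield_table named vector of species per 100 eV.
#' @param sigma_nm Gaussian jitter (per axis), nm.
#' @param diffusion named vector of diffusion coefficients nm^2/ns; must
#'   cover every species in `yield_table`.
#' @param seed optional seed.
#' @return data frame: `species_id`, `name`, `x`, `y`, `z` (nm), `t_ns`,
#'   `D` (nm^2/ns), `primary_id`.
#' @export
spawn_species <- function(deposits, yield_table = default_yield_table(),
                          sigma_nm = 1,
                          diffusion = default_diffusion_table(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unknown <- setdiff(names(yield_table), names(diffusion))
  if (length(unknown))
    stop("unknown species in yield table: ", paste(unknown, collapse = ", "))
  empty <- data.frame(species_id = integer(), name = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      t_ns = numeric(), D = numeric(), primary_id = integer())
  if (nrow(deposits) == 0 || all(yield_table == 0)) return(empty)
  parts <- list()
  for (sp in names(yield_table)) {
    g <- yield_table[[sp]]
    if (g <= 0) next
    counts <- rpois(nrow(deposits), g * deposits$energy_eV / 100)
    tot <- sum(counts)
    if (tot == 0) next
    idx <- rep(seq_len(nrow(deposits)), counts)
    parts[[sp]] <- data.frame(
      name = sp,
      x = deposits$x[idx] + rnorm(tot, 0, sigma_nm),
      y = deposits$y[idx] + rnorm(tot, 0, sigma_nm),
      z = deposits$z[idx] + rnorm(tot, 0, sigma_nm),
      t_ns = 0,
      D = diffusion[[sp]],
      primary_id = deposits$primary_id[idx])
  }
  if (length(parts) == 0) return(empty)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- cbind(species_id = seq_len(nrow(out)) - 1L, out)
  # private RNG substream per species (see evolve_chemistry details)
  out$rng <- sample.int(2147483646L, nrow(out), replace = TRUE)
  out
}

#' Write / read event lists
#'
#' CSV exchange for energy deposits and species so externally produced
#' track-structure output can replace the fixture. Columns are matched by
#' header name, so column order is free.
#'
#' @param deposits,species event data frames (see [generate_deposits()],
#'   [spawn_species()]).
#' @param dep_path,spec_path file paths.
#' @return `read_external_events()` returns `list(deposits, species)`.
#' @export
write_external_events <- function(deposits, species, dep_path, spec_path) {
  write.csv(deposits, dep_path, row.names = FALSE)
  write.csv(species, spec_path, row.names = FALSE)
  invisible(c(dep_path, spec_path))
}

#' @rdname write_external_events
#' @export
read_external_events <- function(dep_path, spec_path = NULL) {
  deposits <- read_events_file(dep_path,
                               c("x", "y", "z", "energy_eV", "primary_id"))
  species <- if (!is.null(spec_path))
    read_events_file(spec_path, c("name", "x", "y", "z", "t_ns", "primary_id"))
  list(deposits = deposits, species = species)
}

read_events_file <- function(path, required) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  num <- setdiff(required, "name")
  for (cn in num) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !anyNA(v))
        stop("malformed value in column ", cn, " of ", path,
             " at line ", which(is.na(conv))[1] + 1)
      df[[cn]] <- conv
    }
  }
  df
}

#' @importFrom stats uniroot
NULL
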