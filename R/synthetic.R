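# --- toy retinal geometry -------------------------------------------------

# Place atom D from A, B, C with bond length b (C-D), bond angle theta
# (B-C-D, degrees) and dihedral phi (A-B-C-D, degrees): the standard
# internal-coordinate extension step.
place_atom <- function(A, B, C, b, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-b * cos(th), b * sin(th) * cos(ph), b * sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Generate a toy all-trans retinal chromophore
#'
#' Builds a planar zigzag polyene chain C5..C15 plus a Schiff-base nitrogen
#' (NZ) and lysine epsilon carbon (CE) (serialised as a single `RET` PDB
#' residue by `make_retinal_pdb`), with
#' single/double bond lengths chosen symmetrically about 1.40 angstrom so
#' that the bond-length alternation equals `bla_target` exactly, and any
#' requested dihedral twists applied about their central bonds. The output
#' is a stand-in for a crystallographic retinal suitable for exercising the
#' geometry and electrostatics modules.
#'
#' @param bla_target Target BLA in \eqn{\mathrm{\AA}} (0 to 0.2).
#' @param twists Named numeric vector of target signed dihedral angles in
#'   degrees, named by central bond (e.g. `c("C15=N" = 160)`); unnamed bonds
#'   stay trans (180 degrees).
#' @param seed Unused placeholder kept for a uniform generator signature
#'   (the builder is deterministic).
#' @param file Optional path; when given, the PDB text is also written there.
#' @return `make_retinal_geometry` returns the exact
#'   `chromophore_geometry`; `make_retinal_pdb` returns PDB text as a single
#'   string (and writes `file` if given). PDB records carry three decimals,
#'   so metrics recovered through the PDB route match targets to about
#'   1e-3 \eqn{\mathrm{\AA}} per coordinate; use the geometry route when
#'   exact round-trips matter.
#' @export
#' @examples
#' bla(make_retinal_geometry(bla_target = 0.116))
make_retinal_geometry <- function(bla_target = 0.1160, twists = NULL,
                                  seed = NULL) {
  if (!is.finite(bla_target) || bla_target < 0 || bla_target > 0.2) {
    abort("`bla_target` must lie in [0, 0.2].",
          class = "chromotune_generation_error")
  }
  if (!is.null(twists)) {
    bad <- setdiff(names(twists), chain_bond_names)
    if (length(bad) > 0 || is.null(names(twists))) {
      abort(paste0("Unknown twist bond(s): ", paste(bad, collapse = ", ")),
            class = "chromotune_generation_error")
    }
  }
  n_atoms <- length(extended_atoms)
  # bonds 1..11 alternate double/single starting at C5=C6; bond 12 is N-CE
  b_len <- ifelse(seq_len(n_atoms - 1) %% 2 == 1,
                  1.40 - bla_target / 2, 1.40 + bla_target / 2)
  b_len[12] <- 1.47
  phi <- setNames(rep(180, n_atoms - 3), chain_bond_names[2:(n_atoms - 2)])
  if (!is.null(twists)) phi[names(twists)] <- twists

  xyz <- matrix(0, n_atoms, 3)
  xyz[2, ] <- c(b_len[1], 0, 0)
  xyz[3, ] <- xyz[2, ] + b_len[2] * c(cos(pi / 3), sin(pi / 3), 0)
  for (i in 4:n_atoms) {
    xyz[i, ] <- place_atom(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ],
                           b_len[i - 1], 120, phi[i - 3])
  }
  dmin <- min(stats::dist(xyz))
  if (dmin < 1.0) {
    abort("Requested twist combination folds the chain onto itself.",
          class = "chromotune_generation_error")
  }
  new_chromophore_geometry(
    tibble(atom = extended_atoms, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    source_label = sprintf("toy retinal (BLA %.4f)", bla_target)
  )
}

#' @rdname make_retinal_geometry
#' @export
make_retinal_pdb <- function(bla_target = 0.1160, twists = NULL, seed = NULL,
                             file = NULL) {
  geom <- make_retinal_geometry(bla_target, twists, seed)
  txt <- write_pdb_text(geom)
  if (!is.null(file)) writeLines(strsplit(txt, "\n")[[1]], file)
  txt
}

# Fixed-width PDB HETATM records for a single toy residue.
write_pdb_text <- function(geom, resname = "RET", chain = "A", resno = 301) {
  lines <- vapply(seq_len(nrow(geom)), function(i) {
    name <- geom$atom[i]
    elem <- substr(name, 1, 1)
    sprintf("HETATM%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name, resname, chain, resno,
            geom$x[i], geom$y[i], geom$z[i], 1.00, 0.00, elem)
  }, character(1))
  paste(c(lines, "END", ""), collapse = "\n")
}

# --- point-charge environments -------------------------------------------

#' Generate a residue point-charge environment around a chromophore
#'
#' Builds small, net-neutral hydroxyl-like dipoles (a -q/+q pair 0.96
#' angstrom apart, the O-H bond length) or a bare anion at stereotyped
#' positions relative to the chromophore:
#'
#' * `thr_near_ionone` — a Thr-like side-chain dipole with its negative
#'   (oxygen) pole facing the beta-ionone end (C5): the red-shifting
#'   arrangement created by a Pro-to-Thr substitution near the ring.
#' * `ser_near_schiff` — a Ser-like dipole with its negative pole facing the
#'   Schiff-base nitrogen: the ground-state-stabilising (blue-shifting)
#'   dipole whose removal mimics a Ser-to-Ala substitution.
#' * `anion_at` — a single -1 e charge at the given anchor.
#'
#' Placement is along the local normal of the chain plane at the anchor
#' atom, `distance` angstrom away; anything closer than 2.5 angstrom to any
#' chromophore atom is refused.
#'
#' @param geom A `chromophore_geometry`.
#' @param style One of `"thr_near_ionone"`, `"ser_near_schiff"`,
#'   `"anion_at"`.
#' @param distance Distance from the anchor atom, \eqn{\mathrm{\AA}}.
#' @param q Dipole partial charge magnitude, e (default 0.4, hydroxyl-like).
#' @param residue_id,residue_name Identifiers for the generated residue
#'   (defaults depend on `style`).
#' @param anchor Chromophore atom the site is positioned against (default
#'   C5 for ionone-side styles, NZ for the Schiff-base style).
#' @return A point-charge environment tibble (columns `residue_id`,
#'   `residue_name`, `atom_name`, `x`, `y`, `z`, `charge`, `formal_charge`).
#' @export
make_charge_env <- function(geom, style = c("thr_near_ionone",
                                            "ser_near_schiff", "anion_at"),
                            distance = 3.5, q = 0.4,
                            residue_id = NULL, residue_name = NULL,
                            anchor = NULL) {
  style <- match.arg(style)
  defaults <- switch(style,
    thr_near_ionone = list(id = 219L, name = "THR", anchor = "C5",
                           atoms = c("OG1", "HG1")),
    ser_near_schiff = list(id = 254L, name = "SER", anchor = "NZ",
                           atoms = c("OG", "HG")),
    anion_at = list(id = 999L, name = "ION", anchor = "C5", atoms = "X")
  )
  residue_id <- residue_id %||% defaults$id
  residue_name <- residue_name %||% defaults$name
  anchor <- anchor %||% defaults$anchor
  xyz <- geom_xyz(geom)
  a <- xyz[anchor, ]
  nrm <- local_normal(xyz, anchor)
  pos_neg <- a + distance * nrm
  env <- if (style == "anion_at") {
    tibble(residue_id = residue_id, residue_name = residue_name,
           atom_name = "X", x = pos_neg[1], y = pos_neg[2], z = pos_neg[3],
           charge = -1, formal_charge = -1)
  } else {
    pos_pos <- pos_neg + 0.96 * nrm # H further from the chromophore
    tibble(residue_id = residue_id, residue_name = residue_name,
           atom_name = defaults$atoms,
           x = c(pos_neg[1], pos_pos[1]),
           y = c(pos_neg[2], pos_pos[2]),
           z = c(pos_neg[3], pos_pos[3]),
           charge = c(-q, q), formal_charge = 0)
  }
  exyz <- as.matrix(env[, c("x", "y", "z")])
  dmin <- min(sqrt(pmax(outer(rowSums(xyz^2), rowSums(exyz^2), "+") -
                        2 * tcrossprod(xyz, exyz), 0)))
  if (dmin < 2.5) {
    abort("Generated site clashes with the chromophore (< 2.5 A).",
          class = "chromotune_generation_error")
  }
  validate_charge_env(env)
  env
}

# unit normal of the local chain plane at an anchor atom
local_normal <- function(xyz, anchor) {
  i <- match(anchor, rownames(xyz))
  j <- if (i == 1) c(1, 2, 3) else if (i == nrow(xyz)) (nrow(xyz) - 2):nrow(xyz)
       else (i - 1):(i + 1)
  n <- cross3(xyz[j[2], ] - xyz[j[1], ], xyz[j[3], ] - xyz[j[2], ])
  n / sqrt(sum(n^2))
}

# --- printed decomposition table ------------------------------------------

#' Published vertical-excitation decomposition table
#'
#' The five (variant, protein energy, vacuum energy) rows of the published
#' QM/MM decomposition for the sodium pump KR2 and its colour mutants,
#' together with the parenthetical delta columns exactly as printed
#' (kcal·mol\eqn{^{-1}}; NA on the wild-type reference row). These printed
#' numbers are bookkeeping inputs, not quantities this package can compute
#' from first principles.
#'
#' @return Tibble with columns `label`, `dE_protein`, `dE_vacuum`,
#'   `printed_electrostatic`, `printed_delta_protein`,
#'   `printed_delta_vacuum`, `printed_delta_electrostatic`.
#' @export
make_table1 <- function() {
  tibble(
    label = c("KR2 WT", "P219G", "P219T", "S254A", "P219T/S254A"),
    dE_protein = c(55.2, 54.3, 53.5, 53.1, 51.5),
    dE_vacuum = c(43.1, 43.8, 44.5, 43.6, 45.9),
    printed_electrostatic = c(12.1, 10.5, 9.0, 9.5, 5.6),
    printed_delta_protein = c(NA, -0.9, -1.7, -2.1, -3.7),
    printed_delta_vacuum = c(NA, 0.7, 1.3, 0.5, 2.7),
    printed_delta_electrostatic = c(NA, -1.6, -3.1, -2.6, -6.5)
  )
}

# --- assay and photocycle fixture wrappers --------------------------------

#' Generate a synthetic before/after hydroxylamine-bleach spectrum pair
#'
#' The "before" spectrum holds a Gaussian (in wavenumber) chromophore band
#' at `lambda_max` on a flat baseline; "after" replaces it with a near-UV
#' retinal-oxime band. Independent white noise is added to both.
#'
#' @param lambda_max Chromophore absorption maximum, nm.
#' @param amplitude Chromophore band peak absorbance, AU.
#' @param width_wn Chromophore band Gaussian width, cm\eqn{^{-1}}.
#' @param oxime_center,oxime_amplitude,oxime_width_wn Retinal-oxime product
#'   band parameters.
#' @param baseline Flat baseline absorbance, AU.
#' @param noise_sd Noise standard deviation per spectrum, AU.
#' @param wavelengths Wavelength grid, nm.
#' @param seed Optional RNG seed.
#' @return List with tibbles `before` and `after` (columns `wavelength_nm`,
#'   `absorbance`) and the generating `lambda_max`.
#' @export
make_spectrum_pair <- function(lambda_max = 542, amplitude = 0.5,
                               width_wn = 1600, oxime_center = 360,
                               oxime_amplitude = 0.55, oxime_width_wn = 1200,
                               baseline = 0.02, noise_sd = 0.002,
                               wavelengths = seq(330, 750, by = 1),
                               seed = NULL) {
  check_positive_wavelength(lambda_max)
  if (!is.null(seed)) set.seed(seed)
  band <- gaussian_band(wavelengths, lambda_max, width_wn, amplitude)
  oxime <- gaussian_band(wavelengths, oxime_center, oxime_width_wn,
                         oxime_amplitude)
  noise <- function() if (noise_sd > 0) rnorm(length(wavelengths),
                                              sd = noise_sd) else 0
  list(
    before = tibble(wavelength_nm = wavelengths,
                    absorbance = baseline + band + noise()),
    after = tibble(wavelength_nm = wavelengths,
                   absorbance = baseline + oxime + noise()),
    lambda_max = lambda_max
  )
}

#' Generate a synthetic light-induced pH trace
#'
#' pH is flat before light-on, rises as a saturating exponential
#' \eqn{A (1 - e^{-(t - t_{on})/\tau})} with initial slope
#' `slope` = A / \eqn{\tau} during illumination, and relaxes back afterwards.
#'
#' @param slope Initial slope of the pH rise, pH s\eqn{^{-1}}.
#' @param t_on,t_off Illumination window, s (default 0-150 s).
#' @param duration Total trace length, s.
#' @param dt Sampling interval, s (default 1 s, i.e. 1 Hz).
#' @param tau Saturation time constant, s.
#' @param ph0 Starting pH.
#' @param noise_sd Noise standard deviation, pH units.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `time_s`, `pH` and an `illumination`
#'   attribute `c(t_on, t_off)`.
#' @export
make_ph_trace <- function(slope = 0.002, t_on = 0, t_off = 150,
                          duration = 300, dt = 1, tau = 60, ph0 = 7,
                          noise_sd = 0, seed = NULL) {
  stopifnot(t_on >= 0, t_off > t_on, duration >= t_off, tau > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = dt)
  A <- slope * tau
  rise <- ifelse(t >= t_on & t <= t_off,
                 A * (1 - exp(-(t - t_on) / tau)), 0)
  peak <- A * (1 - exp(-(t_off - t_on) / tau))
  decay <- ifelse(t > t_off, peak * exp(-(t - t_off) / tau), 0)
  ph <- ph0 + rise + decay +
    if (noise_sd > 0) rnorm(length(t), sd = noise_sd) else 0
  out <- tibble(time_s = t, pH = ph)
  attr(out, "illumination") <- c(t_on, t_off)
  out
}

#' Generate a synthetic KR2-like transient-absorption matrix
#'
#' Thin wrapper around [simulate_ta()] with the default four-intermediate
#' scheme of [kr2_scheme()], a 50-point visible wavelength grid and 200
#' log-spaced times spanning 1 us to 100 ms.
#'
#' @param turnover Slowest (ground-state recovery) lifetime, s.
#' @param wavelengths,times Grids passed to [simulate_ta()].
#' @param noise_sigma,n_averages,seed Noise model passed to [simulate_ta()].
#' @return A `ta_data` object.
#' @export
make_ta <- function(turnover = 4.8e-3,
                    wavelengths = seq(380, 700, length.out = 50),
                    times = 10^seq(-6, -1, length.out = 200),
                    noise_sigma = 0.002, n_averages = 90, seed = NULL) {
  simulate_ta(kr2_scheme(turnover = turnover), wavelengths, times,
              noise_sigma = noise_sigma, n_averages = n_averages, seed = seed)
}

#' Write a point-charge environment to TSV
#'
#' @param env Environment tibble (see [make_charge_env()]).
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_charge_env <- function(env, path) {
  validate_charge_env(env)
  readr::write_tsv(env, path)
  invisible(path)
}
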