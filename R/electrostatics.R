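#' Default two-state partial charges of the chromophore chain
#'
#' An illustrative (sign- and trend-correct, not ab initio) charge model of
#' the protonated retinal Schiff base. In S0 the +1 e net charge is
#' concentrated on the Schiff-base end (N 0.45, C15 0.25, C13 0.15, the
#' remainder spread evenly); in S1 it delocalises toward the beta-ionone ring
#' (N 0.15, C13/C11/C9/C7 0.15 each, C5 0.25). Each state sums to +1 e and
#' the S1 charge centroid lies closer to C5 than the S0 centroid, the
#' property that drives all sign laws in this module. Quantitative work
#' should load computed charges with [read_chromophore_charges()].
#'
#' @return Tibble with columns `atom`, `q_s0`, `q_s1` (e).
#' @export
default_chromophore_charges <- function() {
  q0 <- setNames(rep(0.15 / 9, length(chain_atoms)), chain_atoms)
  q0[c("NZ", "C15", "C13")] <- c(0.45, 0.25, 0.15)
  q1 <- setNames(rep(0, length(chain_atoms)), chain_atoms)
  q1[c("NZ", "C13", "C11", "C9", "C7")] <- 0.15
  q1["C5"] <- 0.25
  tibble(atom = chain_atoms, q_s0 = unname(q0), q_s1 = unname(q1))
}

#' Read a two-state chromophore charge table
#'
#' TSV with columns `atom`, `q_s0`, `q_s1`. Each state must sum to +1 e
#' (tolerance 1e-6), the net charge of a protonated Schiff base.
#'
#' @param path TSV file path.
#' @return Tibble with columns `atom`, `q_s0`, `q_s1`.
#' @export
read_chromophore_charges <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  validate_chromophore_charges(x)
}

validate_chromophore_charges <- function(x) {
  stopifnot(all(c("atom", "q_s0", "q_s1") %in% names(x)))
  for (st in c("q_s0", "q_s1")) {
    if (abs(sum(x[[st]]) - 1) > 1e-6) {
      abort(sprintf("Charges in %s must sum to +1 e.", st),
            class = "chromotune_domain_error")
    }
  }
  as_tibble(x)
}

#' Coulomb interaction energy of one chromophore state with an environment
#'
#' \eqn{\sum_a \sum_s k_e q_a q_s / r_{as}} with
#' \eqn{k_e = 332.0636} kcal·\eqn{\mathrm{\AA}}·mol\eqn{^{-1}}·e\eqn{^{-2}},
#' no cutoff and a uniform dielectric (1 by default). This is the engine
#' beneath the excitation-energy decomposition: the S1-minus-S0 difference of
#' two such sums is the electrostatic part of the vertical excitation energy.
#'
#' @param geom A `chromophore_geometry`.
#' @param charges Numeric vector of per-atom charges named by chain atom, or
#'   a charge tibble column subset via `state`.
#' @param env Point-charge environment tibble (columns `residue_id`,
#'   `residue_name`, `atom_name`, `x`, `y`, `z`, `charge`).
#' @param state When `charges` is a two-state tibble: `"s0"` or `"s1"`.
#' @param dielectric Relative dielectric constant (default 1, vacuum
#'   Coulomb).
#' @return Energy in kcal·mol\eqn{^{-1}}.
#' @export
state_potential_energy <- function(geom, charges, env, state = NULL,
                                   dielectric = 1) {
  q <- state_charges(charges, state)
  if (is.null(env) || nrow(env) == 0) return(0)
  validate_charge_env(env)
  xyz <- geom_xyz(geom, names(q))
  exyz <- as.matrix(env[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(exyz^2), "+") -
    2 * tcrossprod(xyz, exyz)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 0.5)) {
    abort("Environment site within 0.5 A of a chromophore atom.",
          class = "chromotune_singularity_error")
  }
  chromotune_constants$coulomb_kcal / dielectric *
    sum(outer(q, env$charge) / r)
}

state_charges <- function(charges, state) {
  if (is.data.frame(charges)) {
    stopifnot(!is.null(state))
    col <- switch(tolower(state), s0 = "q_s0", s1 = "q_s1",
                  abort("`state` must be 's0' or 's1'.",
                        class = "chromotune_domain_error"))
    setNames(charges[[col]], charges$atom)
  } else {
    stopifnot(!is.null(names(charges)))
    charges
  }
}

validate_charge_env <- function(env) {
  need <- c("residue_id", "atom_name", "x", "y", "z", "charge")
  missing <- setdiff(need, names(env))
  if (length(missing) > 0) {
    abort(paste0("Environment lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "chromotune_format_error")
  }
  if ("formal_charge" %in% names(env)) {
    chk <- env %>%
      group_by(.data$residue_id) %>%
      summarise(net = sum(.data$charge),
                formal = .data$formal_charge[1], .groups = "drop")
    if (any(abs(chk$net - chk$formal) > 1e-6)) {
      abort("Per-residue net charge differs from declared formal charge.",
            class = "chromotune_domain_error")
    }
  }
  invisible(env)
}

#' Vertical excitation energy in a point-charge environment
#'
#' Adds the electrostatic S1-minus-S0 interaction difference to a supplied
#' gas-phase (vacuum) excitation energy: the protein value is
#' `dE_vacuum + (V_S1 - V_S0)`. The vacuum energy comes from a printed table,
#' an external electronic-structure engine, or [surrogate_vacuum_energy()].
#'
#' @inheritParams state_potential_energy
#' @param charges Two-state charge tibble (see
#'   [default_chromophore_charges()]).
#' @param dE_vacuum Gas-phase excitation energy, kcal·mol\eqn{^{-1}}.
#' @param label Label for the resulting row.
#' @return One-row tibble with `label`, `dE_protein`, `dE_vacuum`,
#'   `dE_electrostatic` (all kcal·mol\eqn{^{-1}}).
#' @export
vertical_excitation <- function(geom, charges, env, dE_vacuum,
                                label = "model", dielectric = 1) {
  v0 <- state_potential_energy(geom, charges, env, "s0", dielectric)
  v1 <- state_potential_energy(geom, charges, env, "s1", dielectric)
  tibble(label = label, dE_protein = dE_vacuum + (v1 - v0),
         dE_vacuum = dE_vacuum, dE_electrostatic = v1 - v0)
}

#' Decompose printed excitation energies into geometric and electrostatic parts
#'
#' Pure bookkeeping on a printed table of protein and vacuum excitation
#' energies: the electrostatic part is protein minus vacuum, and each
#' mutant's deltas are taken against the reference row. Values are computed
#' exactly from the inputs, never read from parenthetical columns.
#'
#' @param table Tibble with columns `label`, `dE_protein`, `dE_vacuum`
#'   (kcal·mol\eqn{^{-1}}); e.g. [make_table1()] or [read_decomposition_table()].
#' @param reference Label of the reference row (default "KR2 WT"); `NULL`
#'   for no deltas.
#' @return The table with added `dE_electrostatic` and (if a reference is
#'   given) `delta_protein`, `delta_vacuum`, `delta_electrostatic` (NA on the
#'   reference row).
#' @export
#' @examples
#' decompose_printed(make_table1())
decompose_printed <- function(table, reference = "KR2 WT") {
  stopifnot(all(c("label", "dE_protein", "dE_vacuum") %in% names(table)))
  out <- as_tibble(table) %>%
    mutate(dE_electrostatic = .data$dE_protein - .data$dE_vacuum)
  if (!is.null(reference)) {
    i <- which(out$label == reference)
    if (length(i) != 1) {
      abort(sprintf("Reference label '%s' must occur exactly once.", reference),
            class = "chromotune_consistency_error")
    }
    out <- out %>%
      mutate(
        delta_protein = .data$dE_protein - .data$dE_protein[i],
        delta_vacuum = .data$dE_vacuum - .data$dE_vacuum[i],
        delta_electrostatic = .data$dE_electrostatic -
          .data$dE_electrostatic[i]
      )
    out[i, c("delta_protein", "delta_vacuum", "delta_electrostatic")] <- NA_real_
  }
  out
}

#' Flag printed delta columns inconsistent with recomputed ones
#'
#' Compares recomputed deltas (from [decompose_printed()]) against
#' parenthetical values printed alongside a table, flagging any discrepancy
#' at or above `tol` (default 0.05 kcal·mol\eqn{^{-1}}, half a printed
#' decimal). Rounding slips in published tables are reported, not silently
#' matched.
#'
#' @param table Table carrying printed columns `printed_delta_protein`,
#'   `printed_delta_vacuum`, `printed_delta_electrostatic` (and optionally
#'   `printed_electrostatic`), e.g. [make_table1()].
#' @param reference Reference row label passed to [decompose_printed()].
#' @param tol Flagging threshold, kcal·mol\eqn{^{-1}}.
#' @return Tibble with one row per (row, column) pair compared: `label`,
#'   `quantity`, `printed`, `recomputed`, `discrepancy`, `flagged`.
#' @export
check_printed_deltas <- function(table, reference = "KR2 WT", tol = 0.05) {
  dec <- decompose_printed(table, reference)
  pairs <- c(printed_delta_protein = "delta_protein",
             printed_delta_vacuum = "delta_vacuum",
             printed_delta_electrostatic = "delta_electrostatic",
             printed_electrostatic = "dE_electrostatic")
  pairs <- pairs[names(pairs) %in% names(table)]
  purrr::imap(pairs, function(comp, printed) {
    keep <- !is.na(table[[printed]])
    tibble(label = dec$label[keep],
           quantity = comp,
           printed = table[[printed]][keep],
           recomputed = dec[[comp]][keep])
  }) %>%
    bind_rows() %>%
    mutate(discrepancy = .data$recomputed - .data$printed,
           flagged = abs(.data$discrepancy) >= tol)
}

#' Excitation-energy change from switching one residue's charges off
#'
#' Re-evaluates the vertical excitation energy with every point charge of one
#' residue set to zero; the residue's contribution is the full-model protein
#' energy minus this charge-off energy. Because the Coulomb sum is linear in
#' the environment charges, per-residue contributions sum exactly to the
#' total electrostatic term.
#'
#' @inheritParams vertical_excitation
#' @param residue_id Residue identifier(s) present in `env`; all listed
#'   residues are analysed (default: every residue in `env`).
#' @return Tibble with one row per residue: `residue_id`, `residue_name`,
#'   `dE_off`, `contribution` (kcal·mol\eqn{^{-1}}).
#' @export
charge_off <- function(geom, charges, env, dE_vacuum,
                       residue_id = unique(env$residue_id), dielectric = 1) {
  validate_charge_env(env)
  unknown <- setdiff(residue_id, env$residue_id)
  if (length(unknown) > 0) {
    abort(paste0("Residue(s) not in environment: ",
                 paste(unknown, collapse = ", ")),
          class = "chromotune_lookup_error")
  }
  full <- vertical_excitation(geom, charges, env, dE_vacuum,
                              dielectric = dielectric)
  purrr::map_dfr(residue_id, function(rid) {
    off_env <- env %>% mutate(charge = ifelse(.data$residue_id == rid, 0,
                                              .data$charge))
    if ("formal_charge" %in% names(off_env)) {
      off_env$formal_charge[off_env$residue_id == rid] <- 0
    }
    off <- vertical_excitation(geom, charges, off_env, dE_vacuum,
                               dielectric = dielectric)
    tibble(
      residue_id = rid,
      residue_name = resname_of(env, rid),
      dE_off = off$dE_protein,
      contribution = full$dE_protein - off$dE_protein
    )
  })
}

resname_of <- function(env, rid) {
  if (!"residue_name" %in% names(env)) return(NA_character_)
  env$residue_name[match(rid, env$residue_id)]
}

#' Compare per-residue charge-off contributions between two models
#'
#' Classifies contribution changes between a variant and a reference model:
#' rows at declared mutated sites are `direct` (the point charges themselves
#' changed); conserved residues whose contribution moved by more than `tol`
#' are `indirect` (environmental reorganisation); the rest are `unchanged`.
#'
#' @param variant,reference Charge-off tibbles from [charge_off()].
#' @param mutated_sites Residue ids declared mutated (required, non-empty).
#' @param tol Indirect-change tolerance, kcal·mol\eqn{^{-1}} (default 0.01,
#'   chosen to separate numerical noise from genuine reorganisation).
#' @return Tibble with `residue_id`, `contribution_variant`,
#'   `contribution_reference`, `delta_contribution`, `classification`.
#' @export
compare_charge_off <- function(variant, reference, mutated_sites,
                               tol = 0.01) {
  if (missing(mutated_sites) || length(mutated_sites) == 0) {
    abort("`mutated_sites` must name at least one residue.",
          class = "chromotune_configuration_error")
  }
  joined <- full_join(
    variant %>% select("residue_id", contribution_variant = "contribution"),
    reference %>% select("residue_id",
                         contribution_reference = "contribution"),
    by = "residue_id"
  ) %>%
    mutate(
      contribution_variant = tidyr::replace_na(.data$contribution_variant, 0),
      contribution_reference =
        tidyr::replace_na(.data$contribution_reference, 0),
      delta_contribution = .data$contribution_variant -
        .data$contribution_reference,
      classification = dplyr::case_when(
        .data$residue_id %in% mutated_sites ~ "direct",
        abs(.data$delta_contribution) > tol ~ "indirect",
        TRUE ~ "unchanged"
      )
    )
  joined
}

# Least-squares calibration (intercept, BLA slope) of the surrogate gas-phase
# excitation model against the four published (BLA, vacuum dE) pairs;
# distortion coefficient left at zero for lack of published distortion values.
surrogate_default <- list(a = 88.8593, b = -396.658, c = 0)

#' Surrogate gas-phase excitation energy from chromophore geometry
#'
#' An affine stand-in for an electronic-structure gas-phase calculation:
#' `dE_vac = a + b * BLA + c * total_distortion`. The default calibration
#' (a = 88.8593, b = -396.658, c = 0) is a least-squares fit to the four
#' published (BLA, vacuum energy) pairs and carries residuals of a few tenths
#' of a kcal·mol\eqn{^{-1}}; the distortion coefficient is zero because no
#' distortion values are published to calibrate it against. Use for trend
#' analysis, not prediction.
#'
#' @param metrics A `conjugation_metrics` object, or a numeric BLA value.
#' @param total_distortion Sum of dihedral distortions in degrees (ignored
#'   when `metrics` is a metrics object, which supplies its own).
#' @param params List with elements `a`, `b`, `c`.
#' @return Gas-phase excitation energy in kcal·mol\eqn{^{-1}}.
#' @export
surrogate_vacuum_energy <- function(metrics, total_distortion = 0,
                                    params = surrogate_default) {
  if (!all(c("a", "b", "c") %in% names(params %||% list()))) {
    abort("`params` must supply a, b and c.",
          class = "chromotune_configuration_error")
  }
  if (inherits(metrics, "conjugation_metrics")) {
    bla_val <- metrics$bla
    total_distortion <- sum(metrics$dihedrals$distortion)
  } else {
    bla_val <- metrics
  }
  params$a + params$b * bla_val + params$c * total_distortion
}

#' Read a point-charge environment from TSV
#'
#' Columns `residue_id`, `residue_name`, `atom_name`, `x`, `y`, `z`,
#' `charge` (optionally `formal_charge`).
#'
#' @param path TSV file path.
#' @return Validated environment tibble.
#' @export
read_charge_env <- function(path) {
  env <- readr::read_tsv(path, show_col_types = FALSE)
  validate_charge_env(env)
  as_tibble(env)
}

#' Read a printed decomposition table from CSV
#'
#' Columns `label`, `dE_protein`, `dE_vacuum` plus any `printed_*` columns.
#'
#' @param path CSV file path.
#' @return Tibble for [decompose_printed()] / [check_printed_deltas()].
#' @export
read_decomposition_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("label", "dE_protein", "dE_vacuum") %in% names(x)))
  as_tibble(x)
}
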