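# Canonical atom ordering of the conjugated chain: C5 at the beta-ionone end,
# through C15 to the Schiff-base nitrogen; CE is the lysine epsilon carbon,
# kept (when present) only so the dihedral about the C15=N bond is defined.
chain_atoms <- c("C5", "C6", "C7", "C8", "C9", "C10", "C11", "C12",
                 "C13", "C14", "C15", "NZ")
extended_atoms <- c(chain_atoms, "CE")

chain_bond_names <- c("C5=C6", "C6-C7", "C7=C8", "C8-C9", "C9=C10",
                      "C10-C11", "C11=C12", "C12-C13", "C13=C14",
                      "C14-C15", "C15=N")
# formal bond classification entering the BLA; the Schiff-base C15=N counts
# as a double bond
bla_single_bonds <- c("C6-C7", "C8-C9", "C10-C11", "C12-C13", "C14-C15")
bla_double_bonds <- c("C5=C6", "C7=C8", "C9=C10", "C11=C12", "C13=C14", "C15=N")

#' Extract the retinal chromophore chain from PDB coordinates
#'
#' Reads PDB text or a file (ATOM and HETATM records alike), locates the
#' retinal residue and returns the conjugated-chain atoms in canonical
#' C5 -> Schiff-base-N order. Alternate locations are resolved by highest
#' occupancy; the Schiff-base nitrogen may be named `NZ` or `N`; a lysine
#' `CE` atom, if present in the same residue, is appended so that the C15=N
#' dihedral can be computed.
#'
#' @param pdb Path to a PDB file, or a character string of PDB text
#'   (recognised by embedded newlines).
#' @param retinal_residue Residue name of the retinal chromophore
#'   (default "RET").
#' @param source_label Free-text label attached to the result.
#' @return A tibble of class `chromophore_geometry` with columns `atom`,
#'   `x`, `y`, `z` (\eqn{\mathrm{\AA}}).
#' @export
read_chromophore <- function(pdb, retinal_residue = "RET",
                             source_label = retinal_residue) {
  path <- pdb
  if (length(pdb) == 1 && grepl("\n", pdb)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(pdb, "\n", fixed = TRUE)[[1]], path)
  } else if (!file.exists(pdb)) {
    abort(sprintf("PDB file '%s' not found.", pdb),
          class = "chromotune_io_error")
  }
  # rm.alt = FALSE: keep all alternate locations; occupancy is resolved here
  parsed <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                             rm.alt = FALSE))
  at <- parsed$atom
  at <- at[trimws(at$resid) == retinal_residue, , drop = FALSE]
  if (nrow(at) == 0) {
    abort(sprintf("No residue '%s' in the PDB input.", retinal_residue),
          class = "chromotune_format_error")
  }
  at$elety <- trimws(at$elety)

  pick <- function(names_ok, required, canonical) {
    rows <- at[at$elety %in% names_ok, , drop = FALSE]
    if (nrow(rows) == 0) {
      if (required) {
        abort(sprintf("Chain atom '%s' missing from residue '%s'.",
                      canonical, retinal_residue),
              class = "chromotune_format_error", atom = canonical)
      }
      return(NULL)
    }
    if (nrow(rows) > 1) {
      alt <- trimws(ifelse(is.na(rows$alt), "", rows$alt))
      if (any(alt == "")) {
        abort(sprintf("Duplicate atom '%s' without altloc identifiers.",
                      canonical),
              class = "chromotune_format_error", atom = canonical)
      }
      rows <- rows[which.max(rows$o), , drop = FALSE]
    }
    tibble(atom = canonical, x = rows$x, y = rows$y, z = rows$z)
  }

  got <- purrr::map_dfr(chain_atoms, function(a) {
    pick(if (a == "NZ") c("NZ", "N") else a, required = TRUE, canonical = a)
  })
  ce <- pick("CE", required = FALSE, canonical = "CE")
  geom <- bind_rows(got, ce)
  new_chromophore_geometry(geom, source_label)
}

new_chromophore_geometry <- function(geom, source_label = "chromophore") {
  geom <- as_tibble(geom[, c("atom", "x", "y", "z")])
  if (!identical(geom$atom[seq_along(chain_atoms)], chain_atoms)) {
    abort("Chain atoms must be exactly C5..C15, NZ in order.",
          class = "chromotune_format_error")
  }
  xyz <- as.matrix(geom[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[2:length(chain_atoms), , drop = FALSE] -
                     xyz[1:(length(chain_atoms) - 1), , drop = FALSE])^2))
  if (any(d < 1.2 | d > 1.7)) {
    abort("Consecutive chain atoms must lie 1.2-1.7 A apart.",
          class = "chromotune_format_error")
  }
  structure(geom, class = c("chromophore_geometry", class(geom)),
            source_label = source_label)
}

geom_xyz <- function(geom, atoms = geom$atom) {
  m <- as.matrix(geom[match(atoms, geom$atom), c("x", "y", "z")])
  rownames(m) <- atoms
  m
}

#' Conjugated-chain bond lengths
#'
#' Euclidean lengths of the eleven chain bonds C5=C6 ... C15=N.
#'
#' @param geom A `chromophore_geometry` from [read_chromophore()] or
#'   [make_retinal_pdb()] round-trips.
#' @return Tibble with columns `bond`, `length` (\eqn{\mathrm{\AA}}).
#' @export
bond_lengths <- function(geom) {
  xyz <- geom_xyz(geom, chain_atoms)
  len <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                       xyz[-nrow(xyz), , drop = FALSE])^2))
  tibble(bond = chain_bond_names, length = unname(len))
}

#' Bond-length alternation of the conjugated chain
#'
#' BLA = mean formal single-bond length - mean formal double-bond length.
#' Singles: C6-C7, C8-C9, C10-C11, C12-C13, C14-C15. Doubles: C5=C6, C7=C8,
#' C9=C10, C11=C12, C13=C14 and the Schiff-base C15=N. Lower BLA means more
#' conjugation and correlates with red-shifted absorption.
#'
#' @param lengths A bond-length tibble from [bond_lengths()], or a
#'   `chromophore_geometry` (lengths are computed first).
#' @param single_bonds,double_bonds Bond-name sets entering the two means;
#'   override to use a different formal classification.
#' @return BLA in \eqn{\mathrm{\AA}} (a single number).
#' @export
bla <- function(lengths, single_bonds = bla_single_bonds,
                double_bonds = bla_double_bonds) {
  if (inherits(lengths, "chromophore_geometry")) lengths <- bond_lengths(lengths)
  stopifnot(is.data.frame(lengths), all(c("bond", "length") %in% names(lengths)))
  need <- c(single_bonds, double_bonds)
  missing <- setdiff(need, lengths$bond)
  if (length(missing) > 0) {
    abort(paste0("Missing bond(s): ", paste(missing, collapse = ", ")),
          class = "chromotune_format_error")
  }
  lu <- setNames(lengths$length, lengths$bond)
  mean(lu[single_bonds]) - mean(lu[double_bonds])
}

# signed dihedral (degrees) for points p1..p4
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    abort("Collinear atoms: dihedral undefined.",
          class = "chromotune_degenerate_geometry_error")
  }
  atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Chain dihedral angles and their distortion from planarity
#'
#' Signed dihedrals for every consecutive atom quadruple along the chain
#' (named by their central bond, C6-C7 through C14-C15, plus C15=N when a
#' lysine CE atom is present). The distortion is the absolute deviation from
#' the nearest planar value (0 or 180 degrees), so it lies in \[0, 90\].
#'
#' @inheritParams bond_lengths
#' @return Tibble with columns `dihedral`, `angle` (signed degrees in
#'   (-180, 180\]) and `distortion` (degrees).
#' @export
chain_dihedrals <- function(geom) {
  atoms <- intersect(extended_atoms, geom$atom)
  xyz <- geom_xyz(geom, atoms)
  n <- nrow(xyz)
  idx <- seq_len(n - 3)
  ang <- vapply(idx, function(i) {
    dihedral_angle(xyz[i, ], xyz[i + 1, ], xyz[i + 2, ], xyz[i + 3, ])
  }, numeric(1))
  # central bond of quadruple (i, i+1, i+2, i+3) is bond i+1; the quadruple
  # ending at CE twists about the Schiff-base C15=N bond
  nm <- chain_bond_names[idx + 1]
  tibble(dihedral = nm, angle = ang,
         distortion = planar_distortion(ang))
}

planar_distortion <- function(angle_deg) {
  a <- abs(((angle_deg + 180) %% 360) - 180) # fold into [0, 180]
  pmin(a, 180 - a)
}

#' Dihedral distortions only
#'
#' Convenience wrapper around [chain_dihedrals()] returning the
#' `dihedral`/`distortion` columns.
#'
#' @inheritParams bond_lengths
#' @return Tibble with columns `dihedral`, `distortion` (degrees).
#' @export
dihedral_distortions <- function(geom) {
  chain_dihedrals(geom)[, c("dihedral", "distortion")]
}

#' All conjugation metrics of a chromophore geometry
#'
#' @inheritParams bond_lengths
#' @return A list of class `conjugation_metrics` with elements `bonds`
#'   (tibble), `bla` (\eqn{\mathrm{\AA}}), `dihedrals` (tibble) and
#'   `source_label`.
#' @export
conjugation_metrics <- function(geom) {
  b <- bond_lengths(geom)
  structure(
    list(bonds = b, bla = bla(b), dihedrals = chain_dihedrals(geom),
         source_label = attr(geom, "source_label") %||% "chromophore"),
    class = "conjugation_metrics"
  )
}

#' @export
print.conjugation_metrics <- function(x, ...) {
  cat("Conjugation metrics for", x$source_label, "\n")
  cat(sprintf("  BLA: %.4f A over %d bonds; max distortion %.2f deg\n",
              x$bla, nrow(x$bonds), max(x$dihedrals$distortion)))
  invisible(x)
}

#' Per-bond and per-dihedral differences between two metric tables
#'
#' Elementwise variant minus reference, matched on the name column: the
#' quantity plotted when comparing each mutant chromophore with the wild
#' type.
#'
#' @param variant,reference Tibbles sharing a key column (`bond` or
#'   `dihedral`) and identical key sets, e.g. outputs of [bond_lengths()] or
#'   [chain_dihedrals()]; or two `conjugation_metrics` objects, in which case
#'   bond, dihedral and BLA differences are all returned.
#' @return For tibble inputs, a tibble with the key column, `variant`,
#'   `reference` and `delta` per numeric column; for metric objects, a list
#'   with `bonds`, `dihedrals` and `delta_bla`.
#' @export
compare_to_reference <- function(variant, reference) {
  if (inherits(variant, "conjugation_metrics")) {
    stopifnot(inherits(reference, "conjugation_metrics"))
    return(list(
      bonds = compare_to_reference(variant$bonds, reference$bonds),
      dihedrals = compare_to_reference(variant$dihedrals, reference$dihedrals),
      delta_bla = variant$bla - reference$bla
    ))
  }
  key <- intersect(c("bond", "dihedral"), names(variant))[1]
  if (is.na(key) || !key %in% names(reference)) {
    abort("Inputs must share a 'bond' or 'dihedral' key column.",
          class = "chromotune_consistency_error")
  }
  if (!setequal(variant[[key]], reference[[key]]) ||
      nrow(variant) != nrow(reference)) {
    abort("Key sets differ between variant and reference.",
          class = "chromotune_consistency_error")
  }
  vals <- setdiff(intersect(names(variant), names(reference)), key)
  vals <- vals[vapply(variant[vals], is.numeric, logical(1))]
  out <- variant[, key, drop = FALSE]
  for (v in vals) {
    ref_v <- reference[[v]][match(variant[[key]], reference[[key]])]
    out[[paste0(v, "_variant")]] <- variant[[v]]
    out[[paste0(v, "_reference")]] <- ref_v
    out[[paste0("delta_", v)]] <- variant[[v]] - ref_v
  }
  out
}
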