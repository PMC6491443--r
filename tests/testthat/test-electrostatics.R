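test_that("default charge model satisfies its invariants", {
  ch <- default_chromophore_charges()
  expect_equal(sum(ch$q_s0), 1, tolerance = 1e-9)
  expect_equal(sum(ch$q_s1), 1, tolerance = 1e-9)
  g <- wt_geometry()
  xyz <- as.matrix(g[match(ch$atom, g$atom), c("x", "y", "z")])
  cen0 <- colSums(xyz * ch$q_s0)
  cen1 <- colSums(xyz * ch$q_s1)
  c5 <- unlist(g[g$atom == "C5", c("x", "y", "z")])
  expect_lt(sum((cen1 - c5)^2), sum((cen0 - c5)^2))
})

test_that("Coulomb engine matches the single-pair closed form and is linear", {
  g <- wt_geometry()
  # put +1 e on C5 only, a -1 e site 3.320636 A away: k_e/r = -100 kcal/mol
  q <- setNames(c(1, rep(0, 11)), c("C5", paste0("C", 6:15), "NZ"))
  env <- tibble::tibble(residue_id = 1L, residue_name = "ION",
                        atom_name = "X",
                        x = g$x[1], y = g$y[1], z = g$z[1] + 3.320636,
                        charge = -1)
  expect_equal(state_potential_energy(g, q, env), -100, tolerance = 1e-9)
  expect_identical(state_potential_energy(g, q, env[0, ]), 0)
  env2 <- env; env2$charge <- 2 * env2$charge
  expect_equal(state_potential_energy(g, q, env2),
               2 * state_potential_energy(g, q, env), tolerance = 1e-12)
  # dielectric scales energies down
  expect_equal(state_potential_energy(g, q, env, dielectric = 2), -50,
               tolerance = 1e-9)
  # near-coincident site is a singularity
  env_close <- env; env_close$z <- g$z[1] + 0.2
  expect_error(state_potential_energy(g, q, env_close),
               class = "chromotune_singularity_error")
})

test_that("negative charges blue-shift at the Schiff base, red-shift at the ring", {
  g <- wt_geometry()
  ch <- default_chromophore_charges()
  nrm <- c(0, 0, 1) # chain is planar in z = 0
  for (r in seq(3, 8, by = 1)) {
    for (anchor in c("NZ", "C5")) {
      a <- unlist(g[g$atom == anchor, c("x", "y", "z")])
      env <- tibble::tibble(residue_id = 1L, residue_name = "ION",
                            atom_name = "X",
                            x = a[1], y = a[2], z = a[3] + r,
                            charge = -0.1)
      de <- vertical_excitation(g, ch, env, 43.1)$dE_electrostatic
      # brute-force pair sum as the independent oracle
      oracle <- sum(sapply(seq_len(12), function(i) {
        rr <- sqrt(sum((unlist(g[i, c("x", "y", "z")]) -
                        c(a[1], a[2], a[3] + r))^2))
        332.0636 * (-0.1) * (ch$q_s1[i] - ch$q_s0[i]) / rr
      }))
      expect_equal(de, oracle, tolerance = 1e-9)
      if (anchor == "NZ") expect_gt(de, 0) else expect_lt(de, 0)
    }
  }
})

test_that("dipole orientation laws hold and flipping negates the term", {
  g <- wt_geometry()
  ch <- default_chromophore_charges()
  env_thr <- make_charge_env(g, "thr_near_ionone")
  de_thr <- vertical_excitation(g, ch, env_thr, 43.1)$dE_electrostatic
  expect_lt(de_thr, 0) # Thr-like dipole facing the ring red-shifts
  flipped <- env_thr
  flipped$charge <- -flipped$charge
  de_flip <- vertical_excitation(g, ch, flipped, 43.1)$dE_electrostatic
  expect_equal(de_flip, -de_thr, tolerance = 1e-12)
  # Ser-like dipole near the Schiff base blue-shifts; removing it (the
  # Ser-to-Ala analogue) lowers the excitation energy
  env_ser <- make_charge_env(g, "ser_near_schiff")
  with_ser <- vertical_excitation(g, ch, env_ser, 43.1)
  without <- vertical_excitation(g, ch, env_ser[0, ], 43.1)
  expect_gt(with_ser$dE_electrostatic, 0)
  expect_lt(without$dE_protein, with_ser$dE_protein)
})

test_that("empty environments leave the vacuum energy untouched", {
  g <- wt_geometry()
  ch <- default_chromophore_charges()
  ve <- vertical_excitation(g, ch, NULL, 43.1)
  expect_equal(ve$dE_protein, 43.1)
  expect_equal(ve$dE_electrostatic, 0)
})

test_that("per-residue contributions superpose to the total electrostatic term", {
  g <- wt_geometry()
  ch <- default_chromophore_charges()
  set.seed(11)
  for (rep in 1:5) {
    n_res <- sample(2:6, 1)
    env <- purrr::map_dfr(seq_len(n_res), function(rid) {
      q <- runif(1, -0.5, 0.5)
      tibble::tibble(
        residue_id = rid, residue_name = "RND",
        atom_name = c("A", "B"),
        x = runif(2, -5, 20), y = runif(2, -8, 8),
        z = sample(c(-1, 1), 1) * runif(2, 4, 9),
        charge = c(q, -q),
        formal_charge = 0
      )
    })
    total <- vertical_excitation(g, ch, env, 43.1)$dE_electrostatic
    co <- charge_off(g, ch, env, 43.1)
    expect_equal(sum(co$contribution), total, tolerance = 1e-9)
  }
})

test_that("charge_off handles degenerate and single-residue environments", {
  g <- wt_geometry()
  ch <- default_chromophore_charges()
  env <- make_charge_env(g, "thr_near_ionone")
  co <- charge_off(g, ch, env, 43.1)
  expect_equal(co$contribution,
               vertical_excitation(g, ch, env, 43.1)$dE_electrostatic,
               tolerance = 1e-12)
  zero <- env; zero$charge <- 0; zero$formal_charge <- 0
  expect_equal(charge_off(g, ch, zero, 43.1)$contribution, 0)
  expect_error(charge_off(g, ch, env, 43.1, residue_id = 999),
               class = "chromotune_lookup_error")
})

test_that("direct/indirect classification separates mutation from reorganisation", {
  g <- wt_geometry()
  ch <- default_chromophore_charges()
  water <- make_charge_env(g, "ser_near_schiff", residue_id = 500L,
                           residue_name = "HOH", distance = 4.5)
  ser <- make_charge_env(g, "ser_near_schiff")
  thr <- make_charge_env(g, "thr_near_ionone")
  ref_env <- dplyr::bind_rows(ser, water)
  # variant 1: only residue 254's charges change (Ser -> Ala, charges off)
  ala <- ser; ala$charge <- 0
  var_env <- dplyr::bind_rows(ala, water)
  cmp <- compare_charge_off(
    charge_off(g, ch, var_env, 43.1),
    charge_off(g, ch, ref_env, 43.1),
    mutated_sites = 254L
  )
  expect_identical(cmp$classification[cmp$residue_id == 254], "direct")
  expect_identical(cmp$classification[cmp$residue_id == 500], "unchanged")
  # variant 2: mutation plus a displaced conserved water -> one indirect row
  water_moved <- water
  water_moved$z <- water_moved$z + 1.5
  var2 <- dplyr::bind_rows(thr, water_moved)
  ref2 <- dplyr::bind_rows(make_charge_env(g, "thr_near_ionone",
                                           q = 0.2), water)
  cmp2 <- compare_charge_off(
    charge_off(g, ch, var2, 43.1),
    charge_off(g, ch, ref2, 43.1),
    mutated_sites = 219L
  )
  expect_identical(cmp2$classification[cmp2$residue_id == 219], "direct")
  expect_identical(cmp2$classification[cmp2$residue_id == 500], "indirect")
  expect_error(compare_charge_off(charge_off(g, ch, var2, 43.1),
                                  charge_off(g, ch, ref2, 43.1)),
               class = "chromotune_configuration_error")
  # identical models: all deltas zero, nothing indirect
  same <- compare_charge_off(charge_off(g, ch, ref_env, 43.1),
                             charge_off(g, ch, ref_env, 43.1),
                             mutated_sites = 254L)
  expect_true(all(same$delta_contribution == 0))
  expect_false(any(same$classification == "indirect"))
})

test_that("printed-table bookkeeping reproduces every electrostatic value", {
  dec <- decompose_printed(make_table1())
  expect_equal(dec$dE_electrostatic, c(12.1, 10.5, 9.0, 9.5, 5.6),
               tolerance = 1e-9)
  expect_equal(dec$delta_protein[-1], c(-0.9, -1.7, -2.1, -3.7),
               tolerance = 1e-9)
  expect_equal(dec$delta_electrostatic[-1], c(-1.6, -3.1, -2.6, -6.5),
               tolerance = 1e-9)
  expect_true(is.na(dec$delta_protein[1]))
  # invariant: electrostatic = protein - vacuum, exactly
  expect_identical(dec$dE_electrostatic, dec$dE_protein - dec$dE_vacuum)
  same <- decompose_printed(tibble::tibble(label = "x", dE_protein = 50,
                                           dE_vacuum = 50), reference = NULL)
  expect_equal(same$dE_electrostatic, 0)
})

test_that("inconsistent printed parentheticals are flagged, not matched", {
  flags <- check_printed_deltas(make_table1())
  bad <- flags[flags$flagged, ]
  # the P219T vacuum parenthetical prints +1.3 but recomputes to +1.4
  expect_true(any(bad$label == "P219T" & bad$quantity == "delta_vacuum"))
  p219t <- bad[bad$label == "P219T" & bad$quantity == "delta_vacuum", ]
  expect_equal(p219t$recomputed, 1.4, tolerance = 1e-6)
  # every protein and electrostatic delta is consistent
  expect_false(any(bad$quantity %in%
                     c("delta_protein", "delta_electrostatic",
                       "dE_electrostatic")))
})

test_that("surrogate vacuum energies reproduce trends with documented residuals", {
  # constant when slopes are zero
  expect_equal(surrogate_vacuum_energy(0.2, 100,
                                       params = list(a = 5, b = 0, c = 0)), 5)
  # monotone in distortion for positive c
  p <- list(a = 40, b = 0, c = 0.05)
  vals <- sapply(c(0, 10, 30), surrogate_vacuum_energy, metrics = 0.11,
                 params = p)
  expect_true(all(diff(vals) > 0))
  # default calibration: least-squares against the four published pairs
  blas <- c(0.1160, 0.1123, 0.1120, 0.1093)
  vac <- c(43.1, 44.5, 43.6, 45.9)
  pred <- sapply(blas, surrogate_vacuum_energy)
  resid <- vac - pred
  ls <- lm(vac ~ blas)
  expect_equal(pred, unname(fitted(ls)), tolerance = 1e-3)
  expect_lt(max(abs(resid)), 1)
  expect_error(surrogate_vacuum_energy(0.1, params = list(a = 1)),
               class = "chromotune_configuration_error")
})

test_that("charge tables and environments round-trip through TSV", {
  g <- wt_geometry()
  env <- make_charge_env(g, "thr_near_ionone")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_charge_env(env, path)
  expect_equal(as.data.frame(read_charge_env(path)), as.data.frame(env),
               tolerance = 1e-12)
  chpath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(default_chromophore_charges(), chpath)
  expect_equal(as.data.frame(read_chromophore_charges(chpath)),
               as.data.frame(default_chromophore_charges()),
               tolerance = 1e-12)
  badch <- default_chromophore_charges()
  badch$q_s0 <- badch$q_s0 * 2
  readr::write_tsv(badch, chpath)
  expect_error(read_chromophore_charges(chpath),
               class = "chromotune_domain_error")
})
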