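# ARG A1 guanidinium facing GLU A2 carboxylate with closest N-O pair at d
salt_pair <- function(d) {
  new_structure(data.frame(
    elety = c("CA", "CB", "NE", "NH1", "NH2", "CA", "CB", "OE1", "OE2"),
    resid = c(rep("ARG", 5), rep("GLU", 4)),
    chain = "A", resno = c(rep(1, 5), rep(2, 4)),
    x = c(0, 1.5, 2.9, 3.7, 3.9, 3.7 + d + 3.7, 3.7 + d + 2.0,
          3.7 + d, 3.7 + d + 0.4),
    y = c(0, 0, 0, 0, 2.0, 0, 0, 0, 1.1),
    z = 0,
    element = c("C", "C", "N", "N", "N", "C", "C", "O", "O"),
    stringsAsFactors = FALSE))
}

test_that("a constructed Arg-Glu pair is detected at 3.0 A and rejected at 5.0 A", {
  b <- find_salt_bridges(salt_pair(3.0), cutoff = 4.0)
  expect_equal(nrow(b), 1)
  expect_equal(b$min_distance, 3.0, tolerance = 1e-9)
  expect_identical(b$basic_resid, "ARG")
  expect_identical(b$acidic_resid, "GLU")
  expect_false(b$interchain)
  expect_equal(nrow(find_salt_bridges(salt_pair(5.0), cutoff = 4.0)), 0)
})

test_that("salt-bridge detection equals the all-pairs brute force and is rigid-motion invariant", {
  set.seed(17)
  n <- 30
  types <- sample(c("ARG", "LYS", "HIS", "ASP", "GLU", "SER"), n,
                  replace = TRUE)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    base <- runif(3, 0, 25)
    tips <- switch(types[i],
      ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
      ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), SER = "OG")
    el <- c("C", substr(tips, 1, 1))
    data.frame(elety = c("CA", tips), resid = types[i],
               chain = sample(c("A", "B"), 1), resno = i,
               x = base[1] + c(0, runif(length(tips), -2, 2)),
               y = base[2] + c(0, runif(length(tips), -2, 2)),
               z = base[3] + c(0, runif(length(tips), -2, 2)),
               element = el, stringsAsFactors = FALSE)
  }))
  s <- new_structure(rows)
  found <- find_salt_bridges(s, cutoff = 4.0)
  oracle <- saltbridge_oracle(s, cutoff = 4.0)
  expect_equal(nrow(found), length(oracle))
  if (nrow(found) > 0) {
    keys <- paste(found$basic_chain, found$basic_resno,
                  found$acidic_chain, found$acidic_resno)
    expect_setequal(keys, names(oracle))
    expect_equal(found$min_distance[order(keys)],
                 unlist(oracle)[sort(keys)], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  moved <- transform_structure(s, random_rotation(4), c(3, -8, 1))
  found2 <- find_salt_bridges(moved, cutoff = 4.0)
  expect_equal(found2$min_distance, found$min_distance, tolerance = 1e-9)
})

test_that("charge-relay calls follow the central residue and anchor identity", {
  intact <- detect_charge_relay(
    make_closed_bundle(bundle_spec("closed", central = "R")), "A")
  expect_identical(intact$status, "intact")
  expect_lte(intact$d_E_central, 4.0)
  expect_lte(intact$d_central_D, 4.0)
  wt <- detect_charge_relay(
    make_closed_bundle(bundle_spec("closed", central = "L")), "A")
  expect_identical(wt$status, "broken")
  expect_true(is.na(wt$d_E_central))
  dv <- detect_charge_relay(
    make_closed_bundle(bundle_spec("closed", central = "R", pos86 = "V")), "A")
  expect_identical(dv$status, "broken")
  # a lysine central residue also completes the bridge
  lys <- detect_charge_relay(
    make_closed_bundle(bundle_spec("closed", central = "K")), "A")
  expect_identical(lys$status, "intact")
})

test_that("relay calls are stable across noise seeds", {
  for (seed in 1:10) {
    r <- detect_charge_relay(make_closed_bundle(
      bundle_spec("closed", central = "R", noise_sigma = 0.2, seed = seed)), "A")
    b <- detect_charge_relay(make_closed_bundle(
      bundle_spec("closed", central = "L", noise_sigma = 0.2, seed = seed)), "A")
    expect_identical(r$status, "intact")
    expect_identical(b$status, "broken")
  }
})

test_that("a missing anchor residue reports absent, not an error", {
  s <- make_closed_bundle(bundle_spec("closed", central = "R"))
  s$atoms <- s$atoms[s$atoms$resno != 26, , drop = FALSE]
  s <- new_structure(s$atoms, id = s$id)
  expect_identical(detect_charge_relay(s, "A")$status, "absent")
  expect_error(detect_charge_relay(s, "Q"), "no such chain")
})

test_that("hydrophobic-core burial separates folded, open and extended chains", {
  # fully extended chain: all residues essentially exposed
  ext <- make_ideal_helix(40, rise = 3.4, radius = 1.0, twist = 150,
                          sequence = paste(rep("L", 40), collapse = ""))
  hc_ext <- hydrophobic_core(ext, "A", core_residues = c(10, 15, 20, 25),
                             n_points = 480)
  expect_true(all(hc_ext$per_residue$burial_fraction < 0.2))
  closed <- make_closed_bundle(bundle_spec("closed"))
  hc <- hydrophobic_core(closed, "A", n_points = 480)
  surface <- hydrophobic_core(closed, "A",
                              core_residues = c(37, 47, 60, 64, 92),
                              n_points = 480)
  expect_gt(mean(hc$per_residue$burial_fraction),
            mean(surface$per_residue$burial_fraction))
  # the closed bundle packs its core more tightly than the open monomer
  open_d <- make_open_dimer(bundle_spec("open-dimer"))
  open_a <- new_structure(open_d$atoms[open_d$atoms$chain == "A", ,
                                       drop = FALSE], id = "open_monomer")
  hc_open <- hydrophobic_core(open_a, "A", n_points = 480)
  expect_gt(hc$core_contact_area, hc_open$core_contact_area)
  expect_error(hydrophobic_core(closed, "A", core_residues = integer(0)),
               "empty core")
})

test_that("switching residues engage the core when closed and the interface when open", {
  closed <- make_closed_bundle(bundle_spec("closed"))
  open_d <- make_open_dimer(bundle_spec("open-dimer"))
  rep_ <- switching_elements(closed, "A", open_d, n_points = 480)
  expect_identical(rep_$verdict, rep("switching", 3))
  expect_true(all(rep_$closed_core_area > 1))
  expect_true(all(rep_$open_interface_area > 1))
  # a residue far from the dimer interface is core-only
  far <- switching_elements(closed, "A", open_d, residues = 50,
                            n_points = 480)
  expect_identical(far$verdict, "core-engaged")
  # a residue missing from one input is reported absent
  miss <- switching_elements(closed, "A", open_d, residues = 999,
                             n_points = 480)
  expect_identical(miss$verdict, "absent")
})

test_that("the dimer twofold axis is recovered exactly on a noise-free C2 dimer", {
  od <- make_open_dimer(bundle_spec("open-dimer"))
  ax <- dimer_symmetry_axis(od, "A", "B")
  expect_true(ax$twofold)
  expect_equal(ax$angle, 180, tolerance = 0.1)
  expect_lt(interhelix_angle(ax$axis_direction,
                             od$metadata$labels$c2_axis_direction) %% 180, 1)
  expect_true(all(c("chain", "resno", "dist_to_axis") %in%
                    names(ax$distance_table)))
  expect_false(is.unsorted(ax$distance_table$dist_to_axis))
})

test_that("a translated copy is flagged as not twofold", {
  h <- make_ideal_helix(12)
  b <- h$atoms; b$chain <- "B"; b$x <- b$x + 30
  s <- new_structure(rbind(h$atoms, b))
  expect_warning(ax <- dimer_symmetry_axis(s, "A", "B"), "not twofold")
  expect_lt(ax$angle, 15)
})

test_that("interface charge summaries count residue classes per chain", {
  s <- facing_pair_structure(separation = 1.5, resid = "ASP")
  ifc <- buried_interface_area(s, "A", "B", n_points = 480)
  cs <- interface_charge_summary(s, ifc)
  expect_equal(unname(cs$per_side["A", "acidic"]), 3)
  expect_equal(unname(cs$per_side["A", "net_charge"]), -3)
  expect_equal(unname(cs$per_side["B", "net_charge"]), -3)
  # empty interface: all zeros
  far <- buried_interface_area(facing_pair_structure(100), "A", "B",
                               n_points = 480)
  cs0 <- interface_charge_summary(facing_pair_structure(100), far)
  expect_true(all(cs0$per_side == 0))
})

test_that("the D86V substitution removes exactly one acidic interface residue per chain", {
  wt <- make_open_dimer(bundle_spec("open-dimer", pos86 = "D"))
  mut <- make_open_dimer(bundle_spec("open-dimer", pos86 = "V"))
  cs_wt <- interface_charge_summary(
    wt, buried_interface_area(wt, "A", "B", n_points = 480))
  cs_mut <- interface_charge_summary(
    mut, buried_interface_area(mut, "A", "B", n_points = 480))
  expect_equal(sum(cs_wt$per_side[, "acidic"]) -
                 sum(cs_mut$per_side[, "acidic"]), 2)
  expect_equal(unname(cs_wt$per_side["A", "acidic"] -
                        cs_mut$per_side["A", "acidic"]), 1)
  expect_equal(unname(cs_wt$per_side["B", "acidic"] -
                        cs_mut$per_side["B", "acidic"]), 1)
})
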