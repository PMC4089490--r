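test_that("an ideal 20-residue helix yields one segment covering residues 2-19", {
  h <- make_ideal_helix(20)
  segs <- assign_helices(h, "A")
  expect_equal(nrow(segs), 1)
  expect_lte(segs$start_res, 2)
  expect_gte(segs$end_res, 19)
  expect_equal(segs$rise_per_residue, 1.5, tolerance = 0.02)
})

test_that("a 4-residue extended linker splits two helices into two segments", {
  h1 <- make_ideal_helix(12)
  h2 <- make_ideal_helix(12, origin = c(25, 0, 0), direction = c(1, 0, 0),
                         start_res = 17)
  ca12 <- h1$atoms[h1$atoms$elety == "CA" & h1$atoms$resno == 12,
                   c("x", "y", "z")]
  ca17 <- h2$atoms[h2$atoms$elety == "CA" & h2$atoms$resno == 17,
                   c("x", "y", "z")]
  f <- (1:4) / 5
  linker <- data.frame(
    elety = "CA", resid = "SER", chain = "A", resno = 13:16,
    x = as.numeric(ca12$x + f * (ca17$x - ca12$x)),
    y = as.numeric(ca12$y + f * (ca17$y - ca12$y)),
    z = as.numeric(ca12$z + f * (ca17$z - ca12$z)),
    element = "C", stringsAsFactors = FALSE)
  s <- new_structure(rbind(
    h1$atoms[, names(linker)], linker, h2$atoms[, names(linker)]))
  segs <- assign_helices(s, "A")
  expect_equal(nrow(segs), 2)
  expect_lte(segs$end_res[1], 13)
  expect_gte(segs$start_res[2], 16)
})

test_that("helix axis fits recover direction, rise and equivariance", {
  h <- make_ideal_helix(20, direction = c(1, 0, 0))
  ca <- as.matrix(h$atoms[h$atoms$elety == "CA", c("x", "y", "z")])
  fit <- fit_helix_axis(ca)
  expect_lt(interhelix_angle(fit$axis_direction, c(1, 0, 0)), 1)
  expect_equal(fit$rise_per_residue, 1.5, tolerance = 0.02)
  for (seed in 1:3) {
    R <- random_rotation(seed)
    fr <- fit_helix_axis(t(R %*% t(ca)))
    expect_lt(interhelix_angle(fr$axis_direction,
                               as.numeric(R %*% c(1, 0, 0))), 1)
  }
})

test_that("axis direction survives 0.3-Angstrom coordinate noise within 5 degrees", {
  h <- make_ideal_helix(20)
  ca <- as.matrix(h$atoms[h$atoms$elety == "CA", c("x", "y", "z")])
  for (seed in 1:20) {
    set.seed(seed)
    noisy <- ca + matrix(rnorm(length(ca), 0, 0.3), ncol = 3)
    fit <- fit_helix_axis(noisy)
    expect_lt(interhelix_angle(fit$axis_direction, c(0, 0, 1)), 5)
  }
})

test_that("helix assignment is invariant under rigid motion and stable under noise", {
  s <- make_closed_bundle(bundle_spec("closed"))
  base <- assign_helices(s, "A")
  sm <- transform_structure(s, random_rotation(9), c(-4, 7, 2))
  moved <- assign_helices(sm, "A")
  expect_identical(moved$start_res, base$start_res)
  expect_identical(moved$end_res, base$end_res)
  noisy <- assign_helices(make_closed_bundle(
    bundle_spec("closed", noise_sigma = 0.1, seed = 11)), "A")
  expect_equal(nrow(noisy), nrow(base))
  expect_true(all(abs(noisy$start_res - base$start_res) <= 1))
  expect_true(all(abs(noisy$end_res - base$end_res) <= 1))
})

test_that("inter-axis angles respect N-to-C orientation", {
  expect_equal(interhelix_angle(c(0, 0, 1), c(0, 0, 1)), 0, tolerance = 1e-9)
  expect_equal(interhelix_angle(c(0, 0, 1), c(0, 0, -1)), 180,
               tolerance = 1e-9)
  a <- make_ideal_helix(16)
  b <- make_ideal_helix(16, origin = c(12, 0, 0), direction = c(0, 1, 0))
  fa <- fit_helix_axis(as.matrix(a$atoms[a$atoms$elety == "CA", c("x", "y", "z")]))
  fb <- fit_helix_axis(as.matrix(b$atoms[b$atoms$elety == "CA", c("x", "y", "z")]))
  expect_equal(interhelix_angle(fa$axis_direction, fb$axis_direction), 90,
               tolerance = 3)
})

test_that("stem conformation calls match generator labels and validate ranges", {
  closed <- make_closed_bundle(bundle_spec("closed"))
  open_d <- make_open_dimer(bundle_spec("open-dimer"))
  cc <- call_conformation(closed, "A")
  expect_identical(cc$state, "closed")
  expect_gte(cc$inter_axis_angle, 70)
  expect_false(cc$junction_helical)
  oc <- call_conformation(open_d, "B")
  expect_identical(oc$state, "open")
  expect_lt(oc$inter_axis_angle, 35)
  expect_true(oc$junction_helical)
  expect_error(call_conformation(closed, "A", alpha5_range = c(300, 320)),
               "absent")
})

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(1)
  X <- matrix(rnorm(30), ncol = 3)
  for (seed in 1:10) {
    R <- random_rotation(seed)
    tvec <- rnorm(3, sd = 10)
    Y <- t(R %*% t(X)) + matrix(tvec, nrow(X), 3, byrow = TRUE)
    sup <- superpose(X, Y)
    expect_lt(sup$rmsd, 1e-9)
    expect_lt(max(abs(sup$rotation - R)), 1e-6)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  }
})

test_that("mirror images still give a proper rotation, degenerate input errors", {
  set.seed(2)
  X <- matrix(rnorm(15), ncol = 3)
  Y <- X %*% diag(c(-1, 1, 1)) # reflection
  sup <- superpose(X, Y)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_gt(sup$rmsd, 0.1)
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 1), "collinear")
  expect_error(superpose(X[1:2, ], Y[1:2, ]), ">= 3")
})

test_that("superposition rmsd satisfies the triangle inequality on a common pairing", {
  set.seed(3)
  A <- matrix(rnorm(24), ncol = 3)
  B <- A + matrix(rnorm(24, sd = 0.5), ncol = 3)
  C <- A + matrix(rnorm(24, sd = 0.8), ncol = 3)
  rab <- superpose(A, B)$rmsd
  rbc <- superpose(B, C)$rmsd
  rac <- superpose(A, C)$rmsd
  expect_lte(rac, rab + rbc + 1e-9)
  expect_lt(superpose(A, A)$rmsd, 1e-12)
})
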