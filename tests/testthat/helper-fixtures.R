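# Programmatic fixtures shared across the suite. Everything is generated in
# code; no binary files.

# random cluster of one-atom residues with mixed C/N/O/S elements
random_cluster <- function(n, seed, box = 8) {
  set.seed(seed)
  repeat {
    xyz <- matrix(runif(3 * n, 0, box), ncol = 3)
    if (n < 2 || min(dist(xyz)) > 0.8) break
  }
  elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  new_structure(data.frame(
    elety = "CA", resid = "ALA", chain = "A", resno = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = elements, stringsAsFactors = FALSE
  ), id = sprintf("cluster_n%d_s%d", n, seed))
}

# minimal hand-written PDB with an altloc pair and a water
altloc_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA AALA A   1       1.400   0.000   0.000  0.60  0.00           C",
  "ATOM      3  CA BALA A   1       1.500   0.000   0.000  0.40  0.00           C",
  "ATOM      4  C   ALA A   1       2.400   0.800   0.000  1.00  0.00           C",
  "ATOM      5  O   ALA A   1       2.400   2.030   0.000  1.00  0.00           O",
  "HETATM    6  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
  "TER",
  "END")

# two single-residue chains at a controllable separation; each residue is a
# GLU whose carboxylate faces the partner
facing_pair_structure <- function(separation = 4, resid = "ASP") {
  oatoms <- if (resid == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
  one_res <- function(chain, resno, ybase, sign) {
    data.frame(
      elety = c("N", "CA", "C", "O", "CB", oatoms),
      resid = resid, chain = chain, resno = resno,
      x = c(-1.2, 0, 1.2, 1.8, 0, -0.55, 0.55) + resno * 5,
      y = ybase + sign * c(0, 0, 0, 0.5, 1.5, 2.9, 2.9),
      z = 0, element = c("N", "C", "C", "O", "C", "O", "O"),
      stringsAsFactors = FALSE)
  }
  rows <- rbind(
    do.call(rbind, lapply(1:3, function(i) one_res("A", i, 0, +1))),
    do.call(rbind, lapply(1:3, function(i) one_res("B", i, 2.9 * 2 + separation, -1)))
  )
  new_structure(rows, id = sprintf("facing_%s_%g", resid, separation))
}

# translate a set of chains of a structure by a vector
translate_chains <- function(s, chains, shift) {
  i <- s$atoms$chain %in% chains
  s$atoms$x[i] <- s$atoms$x[i] + shift[1]
  s$atoms$y[i] <- s$atoms$y[i] + shift[2]
  s$atoms$z[i] <- s$atoms$z[i] + shift[3]
  s
}

# apply a rigid motion (rotation matrix + translation) to all atoms
transform_structure <- function(s, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  xyz <- t(R %*% t(xyz)) + matrix(t, nrow(xyz), 3, byrow = TRUE)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
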