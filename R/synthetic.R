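# Ground-truth-labelled synthetic inputs: ideal alpha-helices, closed
# six-helix bundles, open stem-helix C2 dimers and planted-anchor family
# alignments.
#
# The bundles are schematic, not physical folds: helices are arranged on a
# circle, linkers are interpolated, side chains are represented to CB except
# for the charged residue types (Arg, Lys, Asp, Glu, His), which carry their
# charged-tip atoms (guanidinium N, carboxylate O, ...) so that salt-bridge
# and charge-relay detectors operate on real atom names. Areas measured on
# synthetic structures are therefore never compared with areas of deposited
# crystal structures; only labels (state, relay status, engagement) are.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.perp_frame <- function(d) {
  d <- .unit(d)
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(.cross3(ref, d))
  e2 <- .cross3(d, e1)
  list(e1 = e1, e2 = e2)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Right-handed alpha-helix C-alpha trace. `phase` is the angular position
# (degrees) of the first residue in the (e1, e2) plane of `direction`.
.helix_ca <- function(n, rise = 1.5, twist = 100, radius = 2.3,
                      origin = c(0, 0, 0), direction = c(0, 0, 1),
                      phase = 0) {
  d <- .unit(direction)
  fr <- .perp_frame(d)
  i <- seq_len(n) - 1
  theta <- (phase - twist * i) * pi / 180
  t(sapply(seq_len(n), function(k) {
    origin + d * rise * i[k] +
      radius * (cos(theta[k]) * fr$e1 + sin(theta[k]) * fr$e2)
  }))
}

# charged-tip geometry per residue type: reach along the side-chain
# direction and lateral half-spacing of the paired tip atoms
.TIP_GEOM <- list(
  ARG = list(atoms = c("NE", "NH1", "NH2"), reach = c(2.9, 3.7, 3.7),
             lat = c(0, 1.0, -1.0)),
  LYS = list(atoms = "NZ", reach = 3.5, lat = 0),
  ASP = list(atoms = c("OD1", "OD2"), reach = c(2.9, 2.9), lat = c(0.55, -0.55)),
  GLU = list(atoms = c("OE1", "OE2"), reach = c(3.3, 3.3), lat = c(0.55, -0.55)),
  HIS = list(atoms = c("ND1", "NE2"), reach = c(3.2, 3.2), lat = c(1.1, -1.1))
)

# Build full atom rows from a CA trace. `w` gives per-residue outward unit
# vectors used to offset the schematic N/C/O backbone; `cb_dir` the
# side-chain direction.
.chain_atoms <- function(ca, w, cb_dir, seq1, resno, chain_id) {
  n <- nrow(ca)
  stopifnot(length(seq1) == n, length(resno) == n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - (ca[i + 1, ] - ca[i, ])
    nxt <- if (i < n) ca[i + 1, ] else ca[i, ] + (ca[i, ] - ca[i - 1, ])
    wi <- w[i, ]
    pos <- list(
      N = (prev + ca[i, ]) / 2 - 0.55 * wi,
      CA = ca[i, ],
      C = (ca[i, ] + nxt) / 2 + 0.55 * wi,
      O = (ca[i, ] + nxt) / 2 + 0.55 * wi + 1.23 * wi
    )
    aa <- seq1[i]
    if (aa != "G") {
      pos$CB <- ca[i, ] + 1.53 * cb_dir[i, ]
    }
    res3 <- aa_one_to_three(aa)
    if (res3 %in% names(.TIP_GEOM)) {
      g <- .TIP_GEOM[[res3]]
      chain_dir <- .unit(nxt - prev)
      v <- .cross3(cb_dir[i, ], chain_dir)
      v <- if (sqrt(sum(v^2)) < 1e-6) .perp_frame(cb_dir[i, ])$e1 else .unit(v)
      for (k in seq_along(g$atoms)) {
        pos[[g$atoms[k]]] <- ca[i, ] + g$reach[k] * cb_dir[i, ] + g$lat[k] * v
      }
    }
    el <- names(pos)
    rows[[i]] <- data.frame(
      elety = el,
      resid = res3, chain = chain_id, resno = resno[i],
      x = vapply(pos, `[`, numeric(1), 1),
      y = vapply(pos, `[`, numeric(1), 2),
      z = vapply(pos, `[`, numeric(1), 3),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate an ideal alpha-helix
#'
#' @param n_res number of residues (>= 4).
#' @param rise rise per residue, Angstrom.
#' @param twist right-handed twist per residue, degrees.
#' @param radius C-alpha helix radius, Angstrom.
#' @param origin 3-vector, position of the helical axis at the first residue.
#' @param direction axis direction (any non-zero 3-vector).
#' @param phase angular position of the first residue, degrees.
#' @param sequence optional one-letter sequence (length `n_res`); default
#'   poly-alanine.
#' @param chain_id,start_res chain id and first author residue number.
#' @return a `pyd_structure` with schematic backbone (N, CA, C, O), CB, and
#'   charged-tip atoms for Arg/Lys/Asp/Glu/His. Consecutive C-alpha
#'   distances are 3.8 +/- 0.05 Angstrom at the default parameters.
#' @export
make_ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                             origin = c(0, 0, 0), direction = c(0, 0, 1),
                             phase = 0, sequence = NULL, chain_id = "A",
                             start_res = 1) {
  if (n_res < 4) stop("an ideal helix needs at least 4 residues")
  seq1 <- if (is.null(sequence)) rep("A", n_res) else strsplit(sequence, "")[[1]]
  if (length(seq1) != n_res) stop("sequence length must equal n_res")
  ca <- .helix_ca(n_res, rise, twist, radius, origin, direction, phase)
  d <- .unit(direction)
  axis_pts <- t(sapply(seq_len(n_res) - 1, function(i) origin + d * rise * i))
  w <- t(vapply(seq_len(n_res), function(i) .unit(ca[i, ] - axis_pts[i, ]),
                numeric(3)))
  atoms <- .chain_atoms(ca, w, w, seq1, start_res + seq_len(n_res) - 1, chain_id)
  new_structure(atoms, id = "ideal_helix",
                metadata = list(generator = "make_ideal_helix",
                                rise = rise, twist = twist, radius = radius))
}

#' Specification of a synthetic pyrin-domain bundle
#'
#' @param state `"closed"` (six-helix bundle) or `"open-dimer"` (extended
#'   stem-helix C2 dimer).
#' @param central one-letter code at the central relay position 84
#'   (`"L"` wild-type-like, `"R"` reconstitutes the charge bridge).
#' @param pos86 one-letter code at the acidic anchor 86 (`"D"` wild-type,
#'   `"V"` the clinical mutant).
#' @param helix_lengths six helix lengths; the defaults reproduce the
#'   NLRP14 spans alpha1 10-21, alpha2 24-39, alpha3 44-52, alpha4 55-65,
#'   alpha5 70-83, alpha6 84-96.
#' @param noise_sigma Gaussian coordinate noise (Angstrom, per coordinate).
#' @param seed integer seed for the noise (mandatory; no hidden randomness).
#' @param sequence optional full one-letter sequence for residues 7-96;
#'   default [default_pyd_sequence()].
#' @return list of class `bundle_spec`.
#' @export
bundle_spec <- function(state = c("closed", "open-dimer"), central = "L",
                        pos86 = "D", helix_lengths = c(12, 16, 9, 11, 14, 13),
                        noise_sigma = 0, seed = 1, sequence = NULL) {
  state <- match.arg(state)
  stopifnot(length(helix_lengths) == 6, all(helix_lengths >= 4),
            noise_sigma >= 0)
  if (is.null(sequence)) sequence <- default_pyd_sequence(central, pos86)
  structure(list(state = state, central = central, pos86 = pos86,
                 helix_lengths = helix_lengths, noise_sigma = noise_sigma,
                 seed = as.integer(seed), sequence = sequence),
            class = "bundle_spec")
}

#' Default synthetic pyrin-domain sequence (residues 7-96)
#'
#' Serine background threaded with the NLRP14 landmarks: the hydrophobic
#' core (Leu15/19/22/27, Phe30, Leu34/58, Met62, Ala71, Phe79, Met82), the
#' switching element Trp72/Leu76/Leu87, the charge-relay anchors Glu26 and
#' Asp86 around the M82-N83-X84 motif, the interface pair Glu21/Arg90 and
#' the helix-boundary residues (Phe10, Lys24, Glu39, Leu44, Lys52, Arg55,
#' Tyr65, Lys70, Asn96).
#'
#' @param central residue at position 84 (`"L"` or `"R"`).
#' @param pos86 residue at position 86 (`"D"` or `"V"`).
#' @return one-letter string of length 90 (positions 7 to 96).
#' @export
default_pyd_sequence <- function(central = "L", pos86 = "D") {
  aa <- rep("S", 90)
  at <- function(resno) resno - 6
  fixed <- c(
    `10` = "F", `15` = "L", `19` = "L", `21` = "E", `22` = "L", `24` = "K",
    `26` = "E", `27` = "L", `30` = "F", `34` = "L", `39` = "E", `44` = "L",
    `52` = "K", `55` = "R", `58` = "L", `62` = "M", `65` = "Y", `70` = "K",
    `71` = "A", `72` = "W", `76` = "L", `79` = "F", `82` = "M", `83` = "N",
    `87` = "L", `88` = "C", `90` = "R", `96` = "N")
  aa[at(as.integer(names(fixed)))] <- fixed
  aa[at(84)] <- central
  aa[at(86)] <- pos86
  paste(aa, collapse = "")
}

.helix_ranges <- function(helix_lengths) {
  starts <- c(10, 24, 44, 55, 70, 84)
  data.frame(helix = 1:6, start = starts,
             end = starts + helix_lengths - 1)
}

# straight-line linker CAs between two anchor points, bowed slightly
# along `out` so linker atoms do not coincide with helix ends
.linker_ca <- function(from, to, n, out) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  f <- seq_len(n) / (n + 1)
  t(sapply(f, function(ff) from + ff * (to - from) + 1.5 * sin(pi * ff) * out))
}

.apply_noise <- function(s, sigma, seed) {
  if (sigma <= 0) return(s)
  n <- nrow(s$atoms)
  eps <- .with_seed(seed, matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3))
  s$atoms$x <- s$atoms$x + eps[, 1]
  s$atoms$y <- s$atoms$y + eps[, 2]
  s$atoms$z <- s$atoms$z + eps[, 3]
  s
}

# reposition the side chain of `resno` so its charged tips sit around
# `target`; used to plant the relay geometry
.place_sidechain_at <- function(atoms, chain_id, resno, target, lat_dir) {
  sel <- which(atoms$chain == chain_id & atoms$resno == resno)
  if (length(sel) == 0) return(atoms)
  res3 <- toupper(atoms$resid[sel[1]])
  ca <- unlist(atoms[sel[atoms$elety[sel] == "CA"][1], c("x", "y", "z")])
  dir <- .unit(target - ca)
  set_atom <- function(atoms, name, xyz) {
    i <- sel[atoms$elety[sel] == name]
    if (length(i) == 1) atoms[i, c("x", "y", "z")] <- as.list(xyz)
    atoms
  }
  atoms <- set_atom(atoms, "CB", ca + 1.53 * dir)
  v <- .unit(.cross3(dir, lat_dir))
  if (res3 == "ARG") {
    atoms <- set_atom(atoms, "NH1", target)
    atoms <- set_atom(atoms, "NH2", target + 1.0 * v)
    atoms <- set_atom(atoms, "NE", target - 1.0 * dir)
  } else if (res3 == "LYS") {
    atoms <- set_atom(atoms, "NZ", target)
  } else if (res3 %in% c("ASP", "GLU")) {
    o <- if (res3 == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
    atoms <- set_atom(atoms, o[1], target)
    atoms <- set_atom(atoms, o[2], target + 1.1 * v)
  }
  atoms
}

# Assemble one chain (closed-bundle or open-monomer geometry) and return
# its atom table plus the CA bookkeeping needed for relay placement.
.build_pyd_chain <- function(spec, geometry = c("closed", "open"),
                             chain_id = "A") {
  geometry <- match.arg(geometry)
  hr <- .helix_ranges(spec$helix_lengths)
  seq1 <- strsplit(spec$sequence, "")[[1]]
  resno_all <- 7:96
  stopifnot(length(seq1) == length(resno_all))

  ca <- matrix(NA_real_, length(resno_all), 3)
  axis_pt <- matrix(NA_real_, length(resno_all), 3) # per-residue axis point
  rowof <- function(no) match(no, resno_all)

  place_helix <- function(h, origin, direction, phase) {
    n <- hr$end[h] - hr$start[h] + 1
    cc <- .helix_ca(n, origin = origin, direction = direction, phase = phase)
    d <- .unit(direction)
    for (k in seq_len(n)) {
      i <- rowof(hr$start[h] + k - 1)
      ca[i, ] <<- cc[k, ]
      axis_pt[i, ] <<- origin + d * 1.5 * (k - 1)
    }
  }

  if (geometry == "closed") {
    # six helices on a 10-Angstrom-spaced circle; adjacent helices
    # antiparallel; alpha2 and alpha6 adjacent so the relay anchors face
    # each other; alpha5 and alpha6 adjacent across the stem junction
    phi <- c(`1` = 0, `2` = 60, `6` = 120, `5` = 180, `3` = 240, `4` = 300)
    rho <- 10
    for (h in 1:6) {
      L <- (spec$helix_lengths[h] - 1) * 1.5
      a <- phi[[as.character(h)]] * pi / 180
      center <- c(rho * cos(a), rho * sin(a), 0)
      up <- h %% 2 == 1
      origin <- center + c(0, 0, if (up) -L / 2 else L / 2)
      place_helix(h, origin, c(0, 0, if (up) 1 else -1), phase = 0)
    }
  } else {
    # open monomer: alpha1-alpha4 bundle offset from an extended alpha5/6
    # stem-helix along +x; the stem phase puts the switching residues on
    # the face at negative y, where the dimer partner will sit
    stem_first <- hr$start[5] # 70
    stem_phase <- 50 # theta(i) = 50 - 100*(i - 70); theta(72) = 210 deg
    stem_origin <- c((stem_first - 79.5) * 1.5, 4.75, 0)
    n_stem <- hr$end[6] - stem_first + 1
    cc <- .helix_ca(n_stem, origin = stem_origin, direction = c(1, 0, 0),
                    phase = stem_phase)
    for (k in seq_len(n_stem)) {
      i <- rowof(stem_first + k - 1)
      ca[i, ] <- cc[k, ]
      axis_pt[i, ] <- stem_origin + c(1.5 * (k - 1), 0, 0)
    }
    bc <- c(-26, 16, 0)
    psi <- c(45, 135, 225, 315)
    for (h in 1:4) {
      L <- (spec$helix_lengths[h] - 1) * 1.5
      a <- psi[h] * pi / 180
      center <- bc + c(0, 6.5 * cos(a), 6.5 * sin(a))
      fwd <- h %% 2 == 1
      origin <- center + c(if (fwd) -L / 2 else L / 2, 0, 0)
      place_helix(h, origin, c(if (fwd) 1 else -1, 0, 0), phase = 0)
    }
  }

  # linkers (and the leading 7-9 tail) by interpolation
  fill_gap <- function(res_from, res_to) {
    n <- res_to - res_from - 1
    if (n <= 0) return()
    from <- ca[rowof(res_from), ]; to <- ca[rowof(res_to), ]
    out <- .unit(.cross3(to - from, c(0, 0, 1) + 1e-3))
    cc <- .linker_ca(from, to, n, out)
    for (k in seq_len(n)) {
      i <- rowof(res_from + k)
      ca[i, ] <<- cc[k, ]
      axis_pt[i, ] <<- cc[k, ] + out # outward = -out direction handle below
    }
  }
  gaps <- rbind(c(21, 24), c(39, 44), c(52, 55), c(65, 70))
  if (.helix_ranges(spec$helix_lengths)$end[5] + 1 != hr$start[6]) {
    gaps <- rbind(gaps, c(hr$end[5], hr$start[6]))
  }
  for (g in seq_len(nrow(gaps))) fill_gap(gaps[g, 1], gaps[g, 2])
  # leading tail 7..9 extends back from the alpha1 start
  a1 <- ca[rowof(10), ]
  back <- .unit(ca[rowof(10), ] - ca[rowof(11), ])
  for (k in 1:3) ca[rowof(10 - k), ] <- a1 + 3.8 * k * back
  axis_pt[rowof(7:9), ] <- ca[rowof(7:9), ] + c(0, 0, 1)

  if (any(!is.finite(ca))) stop("internal error: unplaced residues")

  # outward vectors; core residues point their CB inward instead
  w <- t(vapply(seq_len(nrow(ca)), function(i) {
    v <- ca[i, ] - axis_pt[i, ]
    if (sqrt(sum(v^2)) < 1e-6) c(1, 0, 0) else .unit(v)
  }, numeric(3)))
  cb_dir <- w
  if (geometry == "closed") {
    core_axis <- function(i) c(0, 0, ca[i, 3])
    for (no in .CORE_RESIDUES) {
      i <- rowof(no)
      cb_dir[i, ] <- .unit(core_axis(i) - ca[i, ])
    }
  } else {
    # switching residues and their antiparallel stem partners face the
    # C2-related chain (the partner of residue i sits at the 180-degree
    # rotation of residue 159 - i about z)
    pair <- c(`72` = 87, `87` = 72, `76` = 83, `83` = 76)
    rot_z180 <- function(p) c(-p[1], -p[2], p[3])
    for (no_chr in names(pair)) {
      no <- as.integer(no_chr)
      i <- rowof(no)
      tgt <- rot_z180(ca[rowof(pair[[no_chr]]), ])
      cb_dir[i, ] <- .unit(tgt - ca[i, ])
    }
    # the acidic anchor 86 points at its antiparallel partner position
    i86 <- rowof(86)
    cb_dir[i86, ] <- .unit(rot_z180(ca[rowof(73), ]) - ca[i86, ])
    # bundle core residues of alpha1-alpha4 point into their mini-bundle
    for (no in intersect(.CORE_RESIDUES, 7:65)) {
      i <- rowof(no)
      cb_dir[i, ] <- .unit(c(ca[i, 1], 16, 0) * c(1, 1, 0) +
                             c(0, 0, 0) - ca[i, ]) # toward bundle axis line
    }
  }

  atoms <- .chain_atoms(ca, w, cb_dir, seq1, resno_all, chain_id)

  if (geometry == "closed") {
    # plant the charge relay: tips of 26/84/86 meet near their centroid
    p <- (ca[rowof(26), ] + ca[rowof(84), ] + ca[rowof(86), ]) / 3
    lat <- .unit(ca[rowof(84), ] - ca[rowof(26), ])
    atoms <- .place_sidechain_at(atoms, chain_id, 84, p, lat)
    atoms <- .place_sidechain_at(atoms, chain_id, 26,
                                 p + 2.75 * .unit(ca[rowof(26), ] - p), lat)
    atoms <- .place_sidechain_at(atoms, chain_id, 86,
                                 p + 2.75 * .unit(ca[rowof(86), ] - p), lat)
  }
  list(atoms = atoms, ca = ca)
}

#' Generate a closed six-helix-bundle monomer
#'
#' @param spec a [bundle_spec()] with `state = "closed"`.
#' @return a single-chain `pyd_structure` (chain A, residues 7-96) whose
#'   metadata records the ground-truth labels: `state = "closed"` and the
#'   expected relay status (`"intact"` iff the central residue is Arg/Lys
#'   and position 86 is acidic). The relay side chains are planted so that
#'   with central `"R"` the N-O legs fall well inside the 4.0-Angstrom
#'   cutoff.
#' @export
make_closed_bundle <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  if (spec$state != "closed") stop("spec state must be 'closed'")
  built <- .build_pyd_chain(spec, "closed", "A")
  s <- new_structure(built$atoms, id = sprintf("closed_%s84_%s86_s%d",
                                               spec$central, spec$pos86,
                                               spec$seed),
                     metadata = list(
                       generator = "make_closed_bundle", spec = spec,
                       labels = list(
                         state = "closed",
                         relay = if (spec$central %in% c("R", "K") &&
                                     spec$pos86 %in% c("D", "E"))
                           "intact" else "broken")))
  .apply_noise(s, spec$noise_sigma, spec$seed)
}

#' Generate an open stem-helix C2 dimer
#'
#' @param spec a [bundle_spec()] with `state = "open-dimer"`.
#' @return a two-chain `pyd_structure` (chains A and B, residues 7-96 each).
#'   The chains are related by an exact 180-degree rotation about the z axis
#'   (before noise); the switching residues Trp72/Leu76/Leu87 face the
#'   partner stem with inter-chain CB-CB contacts, and the acidic anchor 86
#'   sits in the interface. Metadata records `state = "open"` and the C2
#'   axis used.
#' @export
make_open_dimer <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  if (spec$state != "open-dimer") stop("spec state must be 'open-dimer'")
  built <- .build_pyd_chain(spec, "open", "A")
  a_atoms <- built$atoms
  b_atoms <- a_atoms
  b_atoms$chain <- "B"
  b_atoms$x <- -a_atoms$x
  b_atoms$y <- -a_atoms$y
  s <- new_structure(rbind(a_atoms, b_atoms),
                     id = sprintf("open_%s84_%s86_s%d", spec$central,
                                  spec$pos86, spec$seed),
                     metadata = list(
                       generator = "make_open_dimer", spec = spec,
                       labels = list(
                         state = "open",
                         c2_axis_point = c(0, 0, 0),
                         c2_axis_direction = c(0, 0, 1))))
  .apply_noise(s, spec$noise_sigma, spec$seed)
}

#' Generate a synthetic pyrin-domain family alignment with planted anchors
#'
#' @param n_rows number of sequences (>= 1). Row 1 is always an
#'   NLRP14-like numbering reference: its anchors are E26, M82, N83 and D86
#'   with the central position given by its label (L when broken).
#' @param intact_rows integer indices of rows to plant with an intact
#'   charge relay (acidic E-anchor, basic central, acidic D-anchor); all
#'   other rows are planted broken, either by a non-basic central residue
#'   or by Val at the D anchor.
#' @param seed integer seed.
#' @param n_res ungapped sequence length (>= 90).
#' @param gap_columns number of randomly inserted gap columns (gaps in the
#'   reference row and a random subset of the other rows).
#' @return a `cre_alignment` whose `labels` element carries the planted
#'   ground truth (`"intact"`/`"broken"` per row) and `reference_id` names
#'   row 1.
#' @export
make_family_alignment <- function(n_rows = 14, intact_rows = integer(0),
                                  seed = 1, n_res = 96, gap_columns = 9) {
  stopifnot(n_rows >= 1, n_res >= 90)
  intact_rows <- as.integer(intact_rows)
  if (any(intact_rows < 1 | intact_rows > n_rows))
    stop("intact_rows out of range")
  ids <- sprintf("SYN%02d", seq_len(n_rows))
  aa20 <- names(.AA1TO3)
  .with_seed(seed, {
    m <- matrix(sample(aa20, n_rows * n_res, replace = TRUE),
                nrow = n_rows)
    labels <- ifelse(seq_len(n_rows) %in% intact_rows, "intact", "broken")
    for (r in seq_len(n_rows)) {
      m[r, 82] <- "M"
      m[r, 83] <- "N"
      if (labels[r] == "intact") {
        m[r, 26] <- sample(c("E", "D"), 1)
        m[r, 84] <- sample(c("R", "K"), 1)
        m[r, 86] <- sample(c("D", "E"), 1)
      } else if (stats::runif(1) < 0.5) {
        m[r, 26] <- "E"
        m[r, 84] <- sample(setdiff(aa20, c("R", "K")), 1)
        m[r, 86] <- sample(c("D", "E"), 1)
      } else {
        m[r, 26] <- "E"
        m[r, 84] <- sample(aa20, 1)
        m[r, 86] <- "V"
      }
    }
    # row 1 is the NLRP14-like reference
    m[1, 26] <- "E"; m[1, 86] <- if (labels[1] == "intact") "D" else "D"
    if (labels[1] == "broken") m[1, 84] <- "L"
    # insert gap columns: gap in the reference and a random subset of rows
    cols <- lapply(seq_len(n_res), function(j) m[, j, drop = TRUE])
    if (gap_columns > 0) {
      at <- sort(sample(n_res + 1, gap_columns, replace = TRUE))
      for (k in rev(seq_len(gap_columns))) {
        newcol <- sample(aa20, n_rows, replace = TRUE)
        gaprow <- c(1, which(stats::runif(n_rows) < 0.5))
        newcol[unique(gaprow)] <- "-"
        cols <- append(cols, list(newcol), after = at[k] - 1 + 0)
      }
    }
    seqs <- vapply(seq_len(n_rows), function(r)
      paste(vapply(cols, `[`, character(1), r), collapse = ""), character(1))
    aln <- new_alignment(ids, seqs)
    aln$labels <- structure(labels, names = ids)
    aln$reference_id <- ids[1]
    aln
  })
}
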