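# Electrostatic and hydrophobic interaction accounting: salt bridges, the
# Glu-Arg-Asp charge relay that locks the closed bundle, hydrophobic-core
# burial, the switching-element report, the dimer twofold axis and the
# residue-level interface charge summary.

.BASIC_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))
.ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.HYDROPHOBIC_AA <- strsplit("AVLIMFWPC", "")[[1]]

# Default hydrophobic core of the pyrin-domain six-helix bundle (NLRP14
# numbering): the 11 invariant core residues plus the three switching
# residues Trp72/Leu76/Leu87.
.CORE_RESIDUES <- c(15, 19, 22, 27, 30, 34, 58, 62, 71, 79, 82, 72, 76, 87)
.SWITCH_RESIDUES <- c(72, 76, 87)

.charged_atom_rows <- function(atoms, table) {
  res <- toupper(atoms$resid)
  keep <- rep(FALSE, nrow(atoms))
  for (rn in names(table)) {
    keep <- keep | (res == rn & atoms$elety %in% table[[rn]])
  }
  which(keep)
}

#' Detect salt bridges in a structure
#'
#' Enumerates all (basic side-chain N, acidic side-chain O) atom pairs within
#' a distance cutoff and aggregates them per residue pair. Basic atoms are
#' Arg NE/NH1/NH2, Lys NZ and His ND1/NE2; acidic atoms are Asp OD1/OD2 and
#' Glu OE1/OE2.
#'
#' @param s a `pyd_structure`.
#' @param cutoff maximum N-O distance in Angstrom (default 4.0, the common
#'   structural-biology convention).
#' @return data.frame with one row per bridged residue pair: basic and acidic
#'   chain/resno/resid, `min_distance`, `n_contacts` (atom pairs within the
#'   cutoff) and `interchain`.
#' @export
find_salt_bridges <- function(s, cutoff = 4.0) {
  stopifnot(inherits(s, "pyd_structure"))
  a <- s$atoms
  bi <- .charged_atom_rows(a, .BASIC_ATOMS)
  ai <- .charged_atom_rows(a, .ACIDIC_ATOMS)
  empty <- data.frame(
    basic_chain = character(), basic_resno = integer(),
    basic_resid = character(), acidic_chain = character(),
    acidic_resno = integer(), acidic_resid = character(),
    min_distance = numeric(), n_contacts = integer(),
    interchain = logical(), stringsAsFactors = FALSE)
  if (length(bi) == 0 || length(ai) == 0) return(empty)
  bx <- .atom_xyz(s, bi); ax <- .atom_xyz(s, ai)
  d2 <- outer(rowSums(bx^2), rep(1, length(ai))) +
    outer(rep(1, length(bi)), rowSums(ax^2)) - 2 * (bx %*% t(ax))
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  bres <- a[bi[hit[, 1]], c("chain", "resno", "resid")]
  ares <- a[ai[hit[, 2]], c("chain", "resno", "resid")]
  key <- paste(bres$chain, bres$resno, ares$chain, ares$resno, sep = "\r")
  dist <- sqrt(d2[hit])
  first <- !duplicated(key)
  out <- data.frame(
    basic_chain = bres$chain[first], basic_resno = bres$resno[first],
    basic_resid = bres$resid[first],
    acidic_chain = ares$chain[first], acidic_resno = ares$resno[first],
    acidic_resid = ares$resid[first],
    min_distance = as.numeric(tapply(dist, factor(key, levels = key[first]), min)),
    n_contacts = as.integer(tapply(dist, factor(key, levels = key[first]), length)),
    interchain = bres$chain[first] != ares$chain[first],
    stringsAsFactors = FALSE)
  out <- out[order(out$basic_chain, out$basic_resno,
                   out$acidic_chain, out$acidic_resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.min_no_distance <- function(s, chain_id, resno_n, resno_o) {
  a <- s$atoms
  ni <- which(a$chain == chain_id & a$resno == resno_n)
  oi <- which(a$chain == chain_id & a$resno == resno_o)
  ni <- ni[.is_basic_tip(a[ni, , drop = FALSE])]
  oi <- oi[.is_acidic_tip(a[oi, , drop = FALSE])]
  if (length(ni) == 0 || length(oi) == 0) return(NA_real_)
  nx <- .atom_xyz(s, ni); ox <- .atom_xyz(s, oi)
  d2 <- outer(rowSums(nx^2), rep(1, length(oi))) +
    outer(rep(1, length(ni)), rowSums(ox^2)) - 2 * (nx %*% t(ox))
  sqrt(max(0, min(d2)))
}

.is_basic_tip <- function(atoms) {
  res <- toupper(atoms$resid)
  mapply(function(r, e) r %in% names(.BASIC_ATOMS) && e %in% .BASIC_ATOMS[[r]],
         res, atoms$elety, USE.NAMES = FALSE)
}

.is_acidic_tip <- function(atoms) {
  res <- toupper(atoms$resid)
  mapply(function(r, e) r %in% names(.ACIDIC_ATOMS) && e %in% .ACIDIC_ATOMS[[r]],
         res, atoms$elety, USE.NAMES = FALSE)
}

#' Detect the Glu-Arg-Asp charge relay of a pyrin-domain chain
#'
#' The closed six-helix bundle is stabilized by a charge bridge in which a
#' central basic residue (position 84 in NLRP14 numbering) bridges two acidic
#' anchors (positions 26 and 86). This function reports the structural status
#' of that relay.
#'
#' @param s a `pyd_structure`.
#' @param chain_id chain identifier.
#' @param anchors named integer vector `c(E = 26, central = 84, D = 86)` of
#'   author residue numbers.
#' @param cutoff maximum side-chain N-O distance (Angstrom) for an intact leg.
#' @return list of class `charge_relay_call`: `status` (`"intact"`,
#'   `"broken"` or `"absent"`), the anchor residue names found,
#'   `d_E_central` and `d_central_D` (Angstrom, `NA` when a leg has no
#'   charged atoms), and the cutoff used.
#' @details `absent` means an anchor residue is missing from the model;
#'   `intact` requires the central residue to be Arg or Lys with both
#'   N-O legs within the cutoff; everything else is `broken` (wild-type
#'   NLRP14 carries Leu at the central position, breaking the bridge; the
#'   D86V mutation removes one acidic anchor with the same effect).
#' @export
detect_charge_relay <- function(s, chain_id,
                                anchors = c(E = 26, central = 84, D = 86),
                                cutoff = 4.0) {
  stopifnot(inherits(s, "pyd_structure"))
  if (!chain_id %in% chain_ids(s)) stop("no such chain: '", chain_id, "'")
  stopifnot(all(c("E", "central", "D") %in% names(anchors)))
  res <- chain_residues(s, chain_id)
  name_at <- function(no) {
    r <- res$resid[res$resno == no]
    if (length(r) == 0) NA_character_ else toupper(r[1])
  }
  rE <- name_at(anchors[["E"]])
  rC <- name_at(anchors[["central"]])
  rD <- name_at(anchors[["D"]])
  call <- list(chain_id = chain_id, anchors = anchors,
               anchor_E = rE, anchor_central = rC, anchor_D = rD,
               d_E_central = NA_real_, d_central_D = NA_real_,
               cutoff = cutoff)
  if (any(is.na(c(rE, rC, rD)))) {
    call$status <- "absent"
    class(call) <- "charge_relay_call"
    return(call)
  }
  central_basic <- rC %in% c("ARG", "LYS")
  if (central_basic) {
    call$d_E_central <- .min_no_distance(s, chain_id, anchors[["central"]],
                                         anchors[["E"]])
    call$d_central_D <- .min_no_distance(s, chain_id, anchors[["central"]],
                                         anchors[["D"]])
  }
  intact <- central_basic &&
    !is.na(call$d_E_central) && call$d_E_central <= cutoff &&
    !is.na(call$d_central_D) && call$d_central_D <= cutoff
  call$status <- if (intact) "intact" else "broken"
  class(call) <- "charge_relay_call"
  call
}

#' @export
print.charge_relay_call <- function(x, ...) {
  cat("Charge relay chain ", x$chain_id, " [",
      x$anchor_E, x$anchors[["E"]], "-", x$anchor_central,
      x$anchors[["central"]], "-", x$anchor_D, x$anchors[["D"]], "]: ",
      toupper(x$status), sep = "")
  if (!is.na(x$d_E_central))
    cat(sprintf(" (d_E-central %.2f, d_central-D %.2f A)",
                x$d_E_central, x$d_central_D))
  cat("\n")
  invisible(x)
}

#' Hydrophobic-core burial of a chain
#'
#' @param s a `pyd_structure`.
#' @param chain_id chain identifier.
#' @param core_residues author residue numbers of the core set; the default
#'   is the 14-residue pyrin-domain core (11 invariant residues plus the
#'   Trp72/Leu76/Leu87 switching element, NLRP14 numbering).
#' @param probe_radius,n_points surface quadrature parameters.
#' @return list with `per_residue` (data.frame: `resno`, `resid`,
#'   `sasa_in_chain`, `sasa_extracted`, `burial_fraction`) and
#'   `core_contact_area` (Angstrom^2, core side chains against the rest of
#'   the monomer, averaged convention).
#' @details The burial fraction of residue i is
#'   `1 - SASA(i in chain)/SASA(i in its extracted tripeptide i-1..i+1)`, a
#'   relative-accessibility measure that isolates tertiary (not local
#'   backbone) burial.
#' @export
hydrophobic_core <- function(s, chain_id, core_residues = .CORE_RESIDUES,
                             probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(s, "pyd_structure"))
  if (length(core_residues) == 0) stop("empty core residue list")
  res <- chain_residues(s, chain_id)
  present <- intersect(core_residues, res$resno)
  if (length(present) == 0)
    stop("none of the core residues are present in chain '", chain_id, "'")
  chain_sel <- select_atoms(s, chains = chain_id)
  full <- sasa(s, chain_sel, probe_radius, n_points)
  rows <- lapply(present, function(no) {
    key <- paste0(chain_id, ":", no)
    in_chain <- unname(full$per_residue[key])
    tri <- select_atoms(s, chains = chain_id, resno = (no - 1):(no + 1))
    ext <- sasa(s, tri, probe_radius, n_points)
    extracted <- unname(ext$per_residue[key])
    data.frame(resno = no, resid = res$resid[match(no, res$resno)],
               sasa_in_chain = in_chain, sasa_extracted = extracted,
               burial_fraction = if (extracted > 0) 1 - in_chain / extracted
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_res <- do.call(rbind, rows)
  core_sc <- select_atoms(s, chains = chain_id, resno = present,
                          part = "sidechain")
  env <- setdiff(chain_sel, core_sc)
  area <- if (length(core_sc) > 0 && length(env) > 0)
    group_contact_area(s, core_sc, env, probe_radius, n_points) else 0
  list(chain_id = chain_id, per_residue = per_res, core_contact_area = area,
       probe_radius = probe_radius, n_points = n_points)
}

#' Switching-element report: core burial versus dimer-interface burial
#'
#' The Trp72/Leu76/Leu87 switching element either packs into the
#' intramolecular hydrophobic core (closed monomer) or buries into the
#' intermolecular dimer interface (open stem-helix dimer). This report
#' quantifies both engagements for matched closed and open structures.
#'
#' @param closed a `pyd_structure` in the closed state.
#' @param closed_chain chain id within `closed`.
#' @param open_dimer a two-chain `pyd_structure` in the open dimer state.
#' @param open_chains the dimer chain pair (default first two chains).
#' @param residues switching residue numbers (default 72, 76, 87).
#' @param engagement_threshold contact/burial area (Angstrom^2) above which a
#'   residue counts as engaged.
#' @param probe_radius,n_points surface quadrature parameters.
#' @return data.frame of class `switch_report`: per residue,
#'   `closed_core_area` (side chain against the rest of the closed monomer),
#'   `open_interface_area` (per-residue burial in the dimer interface, first
#'   open chain), and `verdict` (`"switching"` when engaged in both contexts,
#'   else `"core-engaged"`, `"dimer-engaged"`, `"neither"`, or `"absent"`).
#' @export
switching_elements <- function(closed, closed_chain, open_dimer,
                               open_chains = NULL,
                               residues = .SWITCH_RESIDUES,
                               engagement_threshold = 1.0,
                               probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(closed, "pyd_structure"),
            inherits(open_dimer, "pyd_structure"))
  if (is.null(open_chains)) open_chains <- chain_ids(open_dimer)[1:2]
  if (length(open_chains) != 2 || anyNA(open_chains))
    stop("open_dimer must provide two chains")
  iface <- buried_interface_area(open_dimer, open_chains[1], open_chains[2],
                                 probe_radius, n_points)
  closed_sel <- select_atoms(closed, chains = closed_chain)
  closed_res <- chain_residues(closed, closed_chain)
  open_res <- chain_residues(open_dimer, open_chains[1])
  rows <- lapply(residues, function(no) {
    in_closed <- no %in% closed_res$resno
    in_open <- no %in% open_res$resno
    if (!in_closed || !in_open) {
      return(data.frame(resno = no, resid = NA_character_,
                        closed_core_area = NA_real_,
                        open_interface_area = NA_real_,
                        verdict = "absent", stringsAsFactors = FALSE))
    }
    sc <- select_atoms(closed, chains = closed_chain, resno = no,
                       part = "sidechain")
    env <- setdiff(closed_sel, select_atoms(closed, chains = closed_chain,
                                            resno = no))
    core_area <- if (length(sc) > 0)
      group_contact_area(closed, sc, env, probe_radius, n_points) else 0
    pr <- iface$per_residue
    hitA <- pr$side == "A" & pr$resno == no
    open_area <- if (any(hitA)) sum(pr$burial[hitA]) else 0
    core_on <- core_area > engagement_threshold
    open_on <- open_area > engagement_threshold
    verdict <- if (core_on && open_on) "switching"
    else if (core_on) "core-engaged"
    else if (open_on) "dimer-engaged"
    else "neither"
    data.frame(resno = no,
               resid = closed_res$resid[match(no, closed_res$resno)],
               closed_core_area = core_area, open_interface_area = open_area,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "engagement_threshold") <- engagement_threshold
  class(out) <- c("switch_report", "data.frame")
  out
}

.rotation_axis <- function(R) {
  # axis of a 3x3 rotation: eigenvector for eigenvalue +1
  ev <- eigen(R)
  k <- which.min(abs(ev$values - 1))
  ax <- Re(ev$vectors[, k])
  ax / .vnorm(ax)
}

#' Twofold symmetry axis of a homodimer
#'
#' Superposes chain A onto chain B over number-matched C-alpha atoms,
#' extracts the rotation axis and angle, and ranks all residues of both
#' chains by side-chain centroid distance to the axis.
#'
#' @param s a `pyd_structure` containing both chains.
#' @param chain_a,chain_b the two chain ids.
#' @return list of class `dimer_axis`: `angle` (degrees), `axis_point`,
#'   `axis_direction` (unit), `twofold` (angle within 180 +/- 15 degrees;
#'   a warning is emitted otherwise), `rmsd` of the superposition, and
#'   `distance_table` (residues of both chains sorted by distance to the
#'   axis). Proximity is reported as a ranked table, not a binary call.
#' @export
dimer_symmetry_axis <- function(s, chain_a, chain_b) {
  stopifnot(inherits(s, "pyd_structure"))
  ca_a <- .chain_ca(s, chain_a)
  ca_b <- .chain_ca(s, chain_b)
  common <- intersect(ca_a$resno, ca_b$resno)
  if (length(common) < 3) stop("fewer than 3 number-matched residues")
  A <- as.matrix(ca_a[match(common, ca_a$resno), c("x", "y", "z")])
  B <- as.matrix(ca_b[match(common, ca_b$resno), c("x", "y", "z")])
  sup <- superpose(A, B)
  ang <- acos(max(-1, min(1, (sum(diag(sup$rotation)) - 1) / 2))) * 180 / pi
  twofold <- abs(ang - 180) <= 15
  if (!twofold)
    warning(sprintf("chain pair is not twofold-related (rotation %.1f deg)",
                    ang))
  ax <- .rotation_axis(sup$rotation)
  # fixed line of the screw transform: solve (I - R) p = t_perp
  t_perp <- sup$translation - sum(sup$translation * ax) * ax
  M <- diag(3) - sup$rotation
  sv <- svd(M)
  dinv <- ifelse(sv$d > 1e-8 * max(sv$d), 1 / sv$d, 0)
  p0 <- as.numeric(sv$v %*% (dinv * (t(sv$u) %*% t_perp)))
  dist_to_axis <- function(x) {
    v <- sweep(x, 2, p0)
    proj <- as.numeric(v %*% ax)
    sqrt(pmax(0, rowSums(v^2) - proj^2))
  }
  tabs <- lapply(c(chain_a, chain_b), function(cc) {
    res <- chain_residues(s, cc)
    cen <- t(vapply(seq_len(nrow(res)), function(i) {
      sel <- select_atoms(s, chains = cc, resno = res$resno[i],
                          part = "sidechain")
      if (length(sel) == 0)
        sel <- select_atoms(s, chains = cc, resno = res$resno[i])
      colMeans(.atom_xyz(s, sel))
    }, numeric(3)))
    data.frame(chain = cc, resno = res$resno, resid = res$resid,
               dist_to_axis = dist_to_axis(cen), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab <- tab[order(tab$dist_to_axis), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(chain_a = chain_a, chain_b = chain_b, angle = ang,
         axis_point = p0, axis_direction = ax, twofold = twofold,
         rmsd = sup$rmsd, distance_table = tab),
    class = "dimer_axis"
  )
}

#' @export
print.dimer_axis <- function(x, ...) {
  cat(sprintf("Dimer %s/%s: rotation %.1f deg (%s), superposition rmsd %.2f A\n",
              x$chain_a, x$chain_b, x$angle,
              if (x$twofold) "twofold" else "NOT twofold", x$rmsd))
  cat("Residues closest to the axis:\n")
  print(utils::head(x$distance_table, 5))
  invisible(x)
}

.classify_residue <- function(one_letter) {
  ifelse(one_letter %in% c("D", "E"), "acidic",
         ifelse(one_letter %in% c("K", "R", "H"), "basic",
                ifelse(one_letter %in% .HYDROPHOBIC_AA, "hydrophobic",
                       "polar")))
}

#' Residue-level charge summary of an interface
#'
#' A residue-type surrogate for continuum electrostatics: counts acidic
#' (D/E), basic (K/R/H), hydrophobic (AVLIMFWPC) and polar interface
#' residues per chain side and reports the net formal charge
#' (basic minus acidic, His excluded from the net charge because of its
#' ambiguous protonation).
#'
#' @param s the `pyd_structure` the interface was computed on.
#' @param interface an [buried_interface_area()] result.
#' @return list of class `interface_charge_summary` with `per_side` (counts
#'   and net charge for sides A and B) and `total` counts.
#' @export
interface_charge_summary <- function(s, interface) {
  stopifnot(inherits(interface, "interface_result"))
  ir <- interface$interface_residues
  count_side <- function(side_label) {
    rows <- ir[ir$side == side_label, , drop = FALSE]
    cls <- .classify_residue(aa_three_to_one(rows$resid))
    n <- function(k) sum(cls == k)
    basic_net <- sum(aa_three_to_one(rows$resid) %in% c("K", "R"))
    c(acidic = n("acidic"), basic = n("basic"),
      hydrophobic = n("hydrophobic"), polar = n("polar"),
      net_charge = basic_net - n("acidic"))
  }
  per_side <- rbind(A = count_side("A"), B = count_side("B"))
  structure(
    list(per_side = per_side,
         total = colSums(per_side[, c("acidic", "basic", "hydrophobic",
                                      "polar"), drop = FALSE])),
    class = "interface_charge_summary"
  )
}

#' @export
print.interface_charge_summary <- function(x, ...) {
  cat("Interface residue classes per side:\n")
  print(x$per_side)
  invisible(x)
}
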