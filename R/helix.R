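# Helix assignment and stem-helix conformation calling from C-alpha geometry.
#
# The secondary-structure criterion is deliberately C-alpha-only (no
# hydrogen-bond energies): deposited pyrin-domain structures at 2-3 Angstrom
# lack hydrogens, and the synthetic bundles carry schematic backbones. A
# residue window i passes when d(CA_i, CA_{i+3}) lies in [4.5, 6.0] Angstrom
# and the virtual torsion CA(i-1)..CA(i+2) lies in [35, 75] degrees; ideal
# right-handed alpha-helices sit near 5.05 Angstrom and +50 degrees.

.HELIX_D13_RANGE <- c(4.5, 6.0)
.HELIX_TORSION_RANGE <- c(35, 75)

.vnorm <- function(v) sqrt(sum(v^2))

.virtual_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / .vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.chain_ca <- function(s, chain_id) {
  a <- s$atoms[s$atoms$chain == chain_id & s$atoms$elety == "CA", , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain_id, "' has no CA atoms")
  res <- chain_residues(s, chain_id)
  ca <- merge(res, a[, c("resno", "icode", "x", "y", "z")],
              by = c("resno", "icode"), sort = FALSE)
  missing <- setdiff(res$resno, ca$resno)
  if (length(missing) > 0) {
    warning("chain '", chain_id, "': skipping ", length(missing),
            " residue(s) without CA atoms")
  }
  ca[order(match(paste(ca$resno, ca$icode), paste(res$resno, res$icode))), ,
     drop = FALSE]
}

# Per-window helicity: window i covers residues (i-1)..(i+3) of the CA trace.
# Windows touching sequence-number gaps are invalid (never pass).
.helical_windows <- function(ca) {
  n <- nrow(ca)
  d13 <- rep(NA_real_, n)
  tors <- rep(NA_real_, n)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  contiguous <- function(i, j) all(diff(ca$resno[i:j]) == 1)
  for (i in seq_len(n)) {
    if (i + 3 <= n && contiguous(i, i + 3)) {
      d13[i] <- .vnorm(xyz[i + 3, ] - xyz[i, ])
    }
    if (i >= 2 && i + 2 <= n && contiguous(i - 1, i + 2)) {
      tors[i] <- .virtual_torsion(xyz[i - 1, ], xyz[i, ], xyz[i + 1, ], xyz[i + 2, ])
    }
  }
  pass <- !is.na(d13) & !is.na(tors) &
    d13 >= .HELIX_D13_RANGE[1] & d13 <= .HELIX_D13_RANGE[2] &
    tors >= .HELIX_TORSION_RANGE[1] & tors <= .HELIX_TORSION_RANGE[2]
  list(d13 = d13, torsion = tors, pass = pass)
}

#' Fit a straight axis through a helical segment
#'
#' @param ca_xyz n x 3 matrix of consecutive C-alpha coordinates (n >= 5).
#' @return list with `axis_point` (centroid of local helix centers),
#'   `axis_direction` (unit vector, oriented N-terminus to C-terminus),
#'   `rise_per_residue` (Angstrom) and `fit_rms` (RMS distance of local
#'   centers from the fitted line, Angstrom).
#' @details Local helix centers are means of 4 consecutive C-alphas, which
#'   cancels the helical wobble; the axis is their principal direction.
#' @export
fit_helix_axis <- function(ca_xyz) {
  ca_xyz <- as.matrix(ca_xyz)
  n <- nrow(ca_xyz)
  if (n < 5) stop("helix axis fit needs >= 5 CA atoms")
  k <- n - 3
  centers <- t(vapply(seq_len(k), function(i)
    colMeans(ca_xyz[i:(i + 3), , drop = FALSE]), numeric(3)))
  ctr <- colMeans(centers)
  cc <- sweep(centers, 2, ctr)
  sv <- svd(cc)
  if (sv$d[1] < 1e-8) stop("degenerate helix geometry: collapsed local centers")
  dir <- sv$v[, 1]
  span <- centers[k, ] - centers[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  proj <- as.numeric(centers %*% dir)
  rise <- if (k > 1) mean(diff(proj)) else NA_real_
  perp <- cc - outer(as.numeric(cc %*% dir), dir)
  list(axis_point = ctr, axis_direction = dir,
       rise_per_residue = rise,
       fit_rms = sqrt(mean(rowSums(perp^2))))
}

#' Assign helical segments of a chain from C-alpha geometry
#'
#' @param s a `pyd_structure`.
#' @param chain_id chain identifier.
#' @return data.frame of class `helix_segments`, one row per segment:
#'   `chain_id`, `start_res`, `end_res`, `n_res`, axis point/direction
#'   columns, `rise_per_residue`, `fit_rms`.
#' @details A 4-residue window passes the helical test when its
#'   CA(i)-CA(i+3) distance is in \[4.5, 6.0\] Angstrom and its virtual
#'   torsion is in \[35, 75\] degrees; maximal runs of passing windows are
#'   dilated to full residue coverage (a run of windows i = a..b yields the
#'   segment a..b+3), so every segment has >= 4 residues. Axes are fitted to
#'   segments with >= 5 residues.
#' @export
assign_helices <- function(s, chain_id) {
  ca <- .chain_ca(s, chain_id)
  if (nrow(ca) < 5) stop("chain '", chain_id, "' too short for helix assignment")
  hw <- .helical_windows(ca)
  n <- nrow(ca)
  # a residue is helical when covered by at least one passing window
  helical <- rep(FALSE, n)
  for (i in which(hw$pass)) helical[i:min(i + 3, n)] <- TRUE
  rl <- rle(helical)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  segs <- Map(c, starts[rl$values], ends[rl$values])
  out <- lapply(segs, function(se) {
    idx <- se[1]:se[2]
    fit <- if (length(idx) >= 5)
      fit_helix_axis(as.matrix(ca[idx, c("x", "y", "z")]))
    else list(axis_point = rep(NA_real_, 3), axis_direction = rep(NA_real_, 3),
              rise_per_residue = NA_real_, fit_rms = NA_real_)
    data.frame(chain_id = chain_id,
               start_res = ca$resno[se[1]], end_res = ca$resno[se[2]],
               n_res = length(idx),
               axis_x = fit$axis_point[1], axis_y = fit$axis_point[2],
               axis_z = fit$axis_point[3],
               dir_x = fit$axis_direction[1], dir_y = fit$axis_direction[2],
               dir_z = fit$axis_direction[3],
               rise_per_residue = fit$rise_per_residue,
               fit_rms = fit$fit_rms, stringsAsFactors = FALSE)
  })
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(chain_id = character(), start_res = integer(),
               end_res = integer(), n_res = integer(),
               axis_x = numeric(), axis_y = numeric(), axis_z = numeric(),
               dir_x = numeric(), dir_y = numeric(), dir_z = numeric(),
               rise_per_residue = numeric(), fit_rms = numeric())
  class(res) <- c("helix_segments", "data.frame")
  res
}

#' Angle between two helix axes
#'
#' @param dir_a,dir_b 3-vectors (need not be normalized); N-to-C orientation
#'   is respected, so antiparallel helices give 180 degrees.
#' @return angle in degrees, in \[0, 180\].
#' @export
interhelix_angle <- function(dir_a, dir_b) {
  if (any(!is.finite(dir_a)) || any(!is.finite(dir_b)))
    stop("axis direction not available")
  ca <- sum(dir_a * dir_b) / (.vnorm(dir_a) * .vnorm(dir_b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Call the open/closed state of the alpha5-alpha6 stem region
#'
#' Decides whether the two C-terminal helices of a pyrin-domain chain form a
#' single extended stem-helix (open, dimerization-competent state) or two
#' separate helices packed back into the six-helix bundle (closed state).
#'
#' @param s a `pyd_structure`.
#' @param chain_id chain identifier.
#' @param alpha5_range,alpha6_range author residue-number ranges
#'   `c(first, last)`; defaults are the NLRP14 numbering (stem 70-96 with the
#'   junction at 83/84) and must be overridden for other numbering schemes.
#' @param open_angle_max axis angle (degrees) below which a helical junction
#'   is called open.
#' @param closed_angle_min axis angle at or above which a broken junction is
#'   called closed.
#' @return list of class `stem_helix_call`: `state` (`"open"`, `"closed"` or
#'   `"intermediate"`), `inter_axis_angle`, `junction_helical`, the two
#'   half-range axis fits, the helix segmentation, and an `evidence` record
#'   (junction window statistics and all thresholds used).
#' @details Junction helicity is judged on the windows spanning the
#'   alpha5/alpha6 boundary, aggregated as means so that the call is robust
#'   to coordinate noise: the mean CA(i)-CA(i+3) spacing over the 8 windows
#'   centered on the junction must stay below 6.2 Angstrom (ideal helix 5.05;
#'   turns and loops give >= 6.5) and the mean virtual torsion must stay in
#'   \[25, 85\] degrees. The state is `open` iff the junction is helical and
#'   the alpha5/alpha6 axis angle is below `open_angle_max`; `closed` iff the
#'   junction is broken and the angle is at least `closed_angle_min`;
#'   anything else is `intermediate` (half-open).
#' @export
call_conformation <- function(s, chain_id, alpha5_range = c(70, 83),
                              alpha6_range = c(84, 96),
                              open_angle_max = 35, closed_angle_min = 70) {
  ca <- .chain_ca(s, chain_id)
  have <- ca$resno
  for (rg in list(alpha5_range, alpha6_range)) {
    if (!any(have >= rg[1] & have <= rg[2]))
      stop("range ", rg[1], "-", rg[2], " absent from chain '", chain_id, "'")
  }
  hw <- .helical_windows(ca)
  segs <- assign_helices(s, chain_id)

  fit_range <- function(rg) {
    idx <- which(ca$resno >= rg[1] & ca$resno <= rg[2])
    if (length(idx) < 5) stop("fewer than 5 CA atoms in range ",
                              rg[1], "-", rg[2])
    fit_helix_axis(as.matrix(ca[idx, c("x", "y", "z")]))
  }
  fit5 <- fit_range(alpha5_range)
  fit6 <- fit_range(alpha6_range)
  angle <- interhelix_angle(fit5$axis_direction, fit6$axis_direction)

  # junction windows: centered on the first alpha6 residue
  jc <- which(ca$resno == alpha6_range[1])[1]
  if (is.na(jc)) jc <- which.min(abs(ca$resno - alpha6_range[1]))
  jwin <- seq(max(1, jc - 5), min(length(hw$pass), jc + 2))
  jd <- hw$d13[jwin]
  jt <- hw$torsion[jwin]
  mean_d <- mean(jd, na.rm = TRUE)
  mean_t <- mean(jt, na.rm = TRUE)
  junction_helical <- is.finite(mean_d) && is.finite(mean_t) &&
    mean_d <= 6.2 && mean_t >= 25 && mean_t <= 85

  state <- if (junction_helical && angle < open_angle_max) "open"
  else if (!junction_helical && angle >= closed_angle_min) "closed"
  else "intermediate"

  structure(
    list(chain_id = chain_id, state = state,
         inter_axis_angle = angle, junction_helical = junction_helical,
         alpha5_fit = fit5, alpha6_fit = fit6, segments = segs,
         evidence = list(
           alpha5_range = alpha5_range, alpha6_range = alpha6_range,
           open_angle_max = open_angle_max,
           closed_angle_min = closed_angle_min,
           junction_mean_d13 = mean_d, junction_mean_torsion = mean_t,
           junction_d13 = jd, junction_torsion = jt,
           junction_d13_max = 6.2, junction_torsion_range = c(25, 85))),
    class = "stem_helix_call"
  )
}

#' @export
print.stem_helix_call <- function(x, ...) {
  cat("Stem-helix call, chain ", x$chain_id, ": ", toupper(x$state),
      " (axis angle ", format(round(x$inter_axis_angle, 1)),
      " deg, junction ", if (x$junction_helical) "helical" else "broken",
      ")\n", sep = "")
  invisible(x)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' @param mobile,reference n x 3 coordinate matrices of paired points
#'   (n >= 3, non-collinear).
#' @return list of class `superposition`: `rotation` (3 x 3, proper,
#'   det = +1), `translation`, `rmsd`, `n_pairs`, and `transformed`
#'   (the mobile set after applying the fit).
#' @details The least-squares rotation comes from the SVD of the coordinate
#'   covariance with the standard determinant correction, so a proper
#'   rotation is returned even for mirror-image inputs.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have the same number of points")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs >= 3 point pairs")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  pm <- sweep(mobile, 2, cm); pr <- sweep(reference, 2, cr)
  sv <- svd(t(pm) %*% pr)
  if (sv$d[1] < 1e-12 || sv$d[2] / sv$d[1] < 1e-9)
    stop("degenerate (collinear) point set: rotation not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  moved <- t(R %*% t(mobile)) + matrix(tr, n, 3, byrow = TRUE)
  structure(
    list(rotation = R, translation = tr,
         rmsd = sqrt(mean(rowSums((moved - reference)^2))),
         n_pairs = n, transformed = moved),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat("Superposition over", x$n_pairs, "pairs: rmsd",
      format(signif(x$rmsd, 4)), "A\n")
  invisible(x)
}
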