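# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: the grid search enumerates rotations, and the salt-bridge
# scan loops over every atom pair.

# best rmsd over a ZYZ Euler grid (degrees). Uses the identity
# sum_k |R a_k - b_k|^2 = C - 2 <R, M>, M = t(B0) %*% A0, to vectorize.
grid_rmsd_oracle <- function(mobile, reference, step = 2) {
  A0 <- scale(mobile, scale = FALSE)
  B0 <- scale(reference, scale = FALSE)
  n <- nrow(A0)
  C <- sum(A0^2) + sum(B0^2)
  M <- t(B0) %*% A0
  alphas <- seq(0, 360 - step, by = step) * pi / 180
  betas <- seq(0, 180, by = step) * pi / 180
  gammas <- seq(0, 360 - step, by = step) * pi / 180
  bg <- expand.grid(b = betas, g = gammas)
  cb <- cos(bg$b); sb <- sin(bg$b); cg <- cos(bg$g); sg <- sin(bg$g)
  best <- -Inf
  for (a in alphas) {
    ca <- cos(a); sa <- sin(a)
    obj <- M[1, 1] * (ca * cb * cg - sa * sg) +
      M[1, 2] * (-ca * cb * sg - sa * cg) +
      M[1, 3] * (ca * sb) +
      M[2, 1] * (sa * cb * cg + ca * sg) +
      M[2, 2] * (-sa * cb * sg + ca * cg) +
      M[2, 3] * (sa * sb) +
      M[3, 1] * (-sb * cg) +
      M[3, 2] * (sb * sg) +
      M[3, 3] * cb
    best <- max(best, max(obj))
  }
  sqrt(max(0, C - 2 * best) / n)
}

# all-pairs salt-bridge enumeration over the raw atom table
saltbridge_oracle <- function(s, cutoff = 4.0) {
  basic <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                HIS = c("ND1", "NE2"))
  acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  a <- s$atoms
  hits <- list()
  for (i in seq_len(nrow(a))) {
    ri <- toupper(a$resid[i])
    if (!(ri %in% names(basic)) || !(a$elety[i] %in% basic[[ri]])) next
    for (j in seq_len(nrow(a))) {
      rj <- toupper(a$resid[j])
      if (!(rj %in% names(acidic)) || !(a$elety[j] %in% acidic[[rj]])) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d <= cutoff) {
        key <- paste(a$chain[i], a$resno[i], a$chain[j], a$resno[j])
        if (is.null(hits[[key]]) || d < hits[[key]]) hits[[key]] <- d
      }
    }
  }
  hits
}

# brute-force ungapped-position -> column scan
ungap_column_oracle <- function(gapped_row, k) {
  ch <- strsplit(gapped_row, "")[[1]]
  seen <- 0
  for (col in seq_along(ch)) {
    if (!(ch[col] %in% c("-", "."))) {
      seen <- seen + 1
      if (seen == k) return(col)
    }
  }
  NA_integer_
}
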