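# Shared geometric primitives: Kabsch superposition, atom keys, selections.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `mobile %*% t(R) + t` and `reference` over paired rows.
#'
#' @param mobile,reference numeric n x 3 coordinate matrices with matched
#'   rows (n >= 3, not collinear).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @keywords internal
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have the same number of atoms")
  if (nrow(mobile) < 3)
    stop("insufficient pairing: need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  # collinearity check: rank of the centered reference cloud
  sv <- svd(B)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: paired atoms are collinear")
  H <- crossprod(A, B)              # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)         # maps mobile rows: v %*% t(R)
  tr <- as.numeric(cr - R %*% cm)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

# apply a superposition (rotation + translation) to an n x 3 matrix
applyTransform <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, translation, `+`)
}

# circumradius of a triangle given a 3 x 3 matrix of vertex coordinates
circumradius <- function(v) {
  a <- sqrt(sum((v[1, ] - v[2, ])^2))
  b <- sqrt(sum((v[2, ] - v[3, ])^2))
  c <- sqrt(sum((v[3, ] - v[1, ])^2))
  cr <- crossprodVec(v[2, ] - v[1, ], v[3, ] - v[1, ])
  area2 <- sqrt(sum(cr^2))          # twice the triangle area
  if (area2 < 1e-9)
    stop("degenerate geometry: gate triangle is collinear")
  a * b * c / (2 * area2)
}

crossprodVec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# random proper rotation matrix (uniform via QR of Gaussian matrix)
randomRotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Atom keys
#'
#' Atoms are addressed throughout as `"chain:resno:atomname"` (e.g.
#' `"A:1:N"`); residues as `"chain:resno"`.
#'
#' @param model a [StructureModel-class].
#' @return character vector of atom keys, one per atom row.
#' @export
atomKeys <- function(model) {
  a <- atoms(model)
  paste(a$chain, a$resno, a$elety, sep = ":")
}

# split "chain:resno[:elety]" keys into a data.frame
parseKeys <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 2)) stop("malformed key(s): ", keys[n < 2][1])
  data.frame(chain = vapply(parts, `[`, "", 1),
             resno = as.integer(vapply(parts, `[`, "", 2)),
             elety = vapply(parts, function(p) if (length(p) >= 3) p[3]
                            else NA_character_, ""))
}

# row indices of atoms matching a key; errors if absent
atomIndex <- function(model, key) {
  idx <- match(key, atomKeys(model))
  if (anyNA(idx))
    stop("atom not found: ", paste(key[is.na(idx)], collapse = ", "))
  idx
}

# logical selection of atom rows: "calpha", "heavy", "backbone", or "all"
selectAtoms <- function(atomTable, selection = c("calpha", "heavy",
                                                 "backbone", "all")) {
  if (is.logical(selection)) return(selection)
  selection <- match.arg(selection)
  water <- atomTable$resid %in% c("HOH", "WAT", "TIP3")
  switch(selection,
    calpha   = atomTable$elety == "CA" & !water,
    heavy    = atomTable$element != "H" & !water,
    backbone = atomTable$elety %in% c("N", "CA", "C", "O") & !water,
    all      = rep(TRUE, nrow(atomTable))
  )
}
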