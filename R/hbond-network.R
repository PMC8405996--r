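# Geometric hydrogen-bond detection and per-frame bond frequencies for
# donor-acceptor residue pairs.

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow the common trajectory-analysis convention: donor-acceptor
#' heavy-atom distance no more than 3.0 Angstrom and a donor-centred angle
#' (between the D->H and D->A vectors, i.e. deviation from linearity at the
#' donor) no more than 30 degrees. An H-centred alternative (supplement of
#' the D-H-A angle) is available for sensitivity checks.
#'
#' @param maxDist maximum donor-acceptor distance, Angstrom (> 0).
#' @param maxAngle maximum angle, degrees (0 < angle <= 180).
#' @param convention "donor" (default) or "hydrogen".
#' @return list of class criteria used by [hbondPresent()] and
#'   [hbondFrequency()].
#' @export
hbondCriteria <- function(maxDist = 3.0, maxAngle = 30,
                          convention = c("donor", "hydrogen")) {
  if (maxDist < 0) stop("maxDist must be >= 0")
  if (maxAngle <= 0 || maxAngle > 180)
    stop("maxAngle must be in (0, 180]")
  list(maxDist = maxDist, maxAngle = maxAngle,
       convention = match.arg(convention))
}

#' Test a single donor-hydrogen-acceptor geometry
#'
#' @param donor,hydrogen,acceptor length-3 coordinate vectors, Angstrom.
#' @param criteria from [hbondCriteria()].
#' @return TRUE iff the distance and angle criteria both hold. Warns if the
#'   donor-hydrogen distance is not covalently plausible (>= 1.5 A); errors
#'   if donor and acceptor coincide.
#' @export
#' @examples
#' hbondPresent(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0))  # TRUE
hbondPresent <- function(donor, hydrogen, acceptor,
                         criteria = hbondCriteria()) {
  dDA <- sqrt(sum((acceptor - donor)^2))
  if (dDA < 1e-9) stop("degenerate geometry: donor and acceptor coincide")
  dDH <- sqrt(sum((hydrogen - donor)^2))
  if (dDH >= 1.5)
    warning("donor-hydrogen distance ", round(dDH, 2),
            " A is not covalently plausible")
  if (dDA > criteria$maxDist) return(FALSE)
  ang <- if (criteria$convention == "donor") {
    vecAngle(hydrogen - donor, acceptor - donor)
  } else {
    180 - vecAngle(donor - hydrogen, acceptor - hydrogen)
  }
  ang <= criteria$maxAngle + 1e-9
}

vecAngle <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

# donor/acceptor chemistry for protein backbone, common side chains, water;
# plain data so it can be extended by the caller
#' Built-in donor/acceptor atom chemistry table
#'
#' @return data.frame with columns `resid` ("*" matches any residue),
#'   `elety`, `donor`, `acceptor`.
#' @export
hbondChemistry <- function() {
  rbind(
    data.frame(resid = "*", elety = "N", donor = TRUE, acceptor = FALSE),
    data.frame(resid = "*", elety = "O", donor = FALSE, acceptor = TRUE),
    data.frame(resid = "SER", elety = "OG", donor = TRUE, acceptor = TRUE),
    data.frame(resid = "THR", elety = "OG1", donor = TRUE, acceptor = TRUE),
    data.frame(resid = "TYR", elety = "OH", donor = TRUE, acceptor = TRUE),
    data.frame(resid = "ASP", elety = c("OD1", "OD2"), donor = FALSE,
               acceptor = TRUE),
    data.frame(resid = "GLU", elety = c("OE1", "OE2"), donor = FALSE,
               acceptor = TRUE),
    data.frame(resid = "ASN", elety = "ND2", donor = TRUE, acceptor = FALSE),
    data.frame(resid = "ASN", elety = "OD1", donor = FALSE, acceptor = TRUE),
    data.frame(resid = "GLN", elety = "NE2", donor = TRUE, acceptor = FALSE),
    data.frame(resid = "GLN", elety = "OE1", donor = FALSE, acceptor = TRUE),
    data.frame(resid = "HIS", elety = c("ND1", "NE2"), donor = TRUE,
               acceptor = TRUE),
    data.frame(resid = "ARG", elety = c("NE", "NH1", "NH2"), donor = TRUE,
               acceptor = FALSE),
    data.frame(resid = "LYS", elety = "NZ", donor = TRUE, acceptor = FALSE),
    data.frame(resid = "TRP", elety = "NE1", donor = TRUE, acceptor = FALSE),
    data.frame(resid = c("HOH", "WAT", "TIP3"), elety = "O", donor = TRUE,
               acceptor = TRUE)
  )
}

# atoms of a residue playing a role ("donor"/"acceptor") under the table
roleAtoms <- function(atomTable, residueId, role,
                      chemistry = hbondChemistry()) {
  k <- parseKeys(residueId)
  rows <- which(atomTable$chain == k$chain[1] &
                atomTable$resno == k$resno[1])
  if (length(rows) == 0) stop("residue not found: ", residueId)
  ok <- vapply(rows, function(r) {
    hit <- chemistry[(chemistry$resid == "*" |
                      chemistry$resid == atomTable$resid[r]) &
                     chemistry$elety == atomTable$elety[r], ]
    nrow(hit) > 0 && any(hit[[role]])
  }, logical(1))
  rows[ok]
}

#' Mean hydrogen bonds per frame between two residues
#'
#' For each frame in the window, counts donor-hydrogen/acceptor triples
#' between the donor residue's donor-capable heavy atoms (with their
#' covalently attached hydrogens, found by a 1.2 A distance association in
#' each frame) and the acceptor residue's acceptor-capable heavy atoms that
#' satisfy the geometric criteria; multiple hydrogens on one donor can each
#' contribute, so per-frame counts may exceed 1. Donor and acceptor roles
#' are directional: swapping the selections is a different measurement.
#'
#' @param traj a [Trajectory-class] with hydrogens in the topology.
#' @param donorResidue,acceptorResidue residue ids `"chain:resno"`.
#' @param criteria from [hbondCriteria()].
#' @param window integer frame indices (default all).
#' @param chemistry donor/acceptor table, see [hbondChemistry()].
#' @return list with `bondsPerFrame` (mean count), `perFrame` (integer
#'   vector) and the echoed selections.
#' @export
hbondFrequency <- function(traj, donorResidue, acceptorResidue,
                           criteria = hbondCriteria(), window = NULL,
                           chemistry = hbondChemistry()) {
  a <- atoms(traj)
  if (is.null(window)) window <- seq_len(nFrames(traj))
  don <- roleAtoms(a, donorResidue, "donor", chemistry)
  acc <- roleAtoms(a, acceptorResidue, "acceptor", chemistry)
  if (length(don) == 0)
    stop("no donor-capable atoms in ", donorResidue)
  if (length(acc) == 0)
    stop("no acceptor-capable atoms in ", acceptorResidue)
  kd <- parseKeys(donorResidue)
  hyd <- which(a$element == "H" & a$chain == kd$chain[1] &
               a$resno == kd$resno[1])

  counts <- vapply(window, function(f) {
    xyz <- traj@coords[f, , ]
    n <- 0L
    for (d in don) {
      dh <- hyd[sqrt(rowSums((xyz[hyd, , drop = FALSE] -
               matrix(xyz[d, ], length(hyd), 3, byrow = TRUE))^2)) < 1.2]
      for (h in dh) for (ac in acc) {
        if (sqrt(sum((xyz[ac, ] - xyz[d, ])^2)) < 1e-9) next
        if (suppressWarnings(
              hbondPresent(xyz[d, ], xyz[h, ], xyz[ac, ], criteria)))
          n <- n + 1L
      }
    }
    n
  }, integer(1))
  list(bondsPerFrame = mean(counts), perFrame = counts,
       donor = donorResidue, acceptor = acceptorResidue,
       criteria = criteria, nFrames = length(window))
}
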