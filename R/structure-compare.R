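# Crystal-structure comparison: file I/O, Kabsch superposition RMSD,
# post-superposition atom displacements, interatomic distances, and
# ligand-contact residue sets.

#' Read a structure from PDB or mmCIF
#'
#' All ATOM/HETATM records are retained with chain/residue/atom identity, so
#' waters and ligands (e.g. tartrate) remain addressable by residue name.
#' Alternate locations are resolved per (chain, residue, atom): either the
#' highest-occupancy conformer (ties broken by altloc letter) or the first
#' encountered.
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file. Format is chosen
#'   by extension; override with `format`.
#' @param altloc "highest" (default) or "first".
#' @param format "auto", "pdb" or "cif".
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, altloc = c("highest", "first"),
                          format = c("auto", "pdb", "cif")) {
  altloc <- match.arg(altloc)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  tab <- if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                    error = function(e)
                      stop("failed to parse PDB file ", path, ": ",
                           conditionMessage(e)))
    a <- pdb$atom
    data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
               elety = a$elety,
               element = ifelse(is.na(a$elesy) | a$elesy == "",
                                substr(trimws(a$elety), 1, 1), a$elesy),
               altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
               occ = ifelse(is.na(a$o), 1, a$o),
               x = a$x, y = a$y, z = a$z)
  } else {
    readCifAtomSite(path)
  }
  if (nrow(tab) == 0) stop("no atom records in ", path)
  if (any(!is.finite(as.matrix(tab[, c("x", "y", "z")]))))
    stop("missing or non-numeric coordinates in ", path)
  tab$chain <- ifelse(is.na(tab$chain) | tab$chain == "", "A", tab$chain)

  # altloc resolution
  key <- paste(tab$chain, tab$resno, tab$elety)
  if (anyDuplicated(key)) {
    ord <- if (altloc == "highest")
      order(key, -tab$occ, tab$altloc) else order(key, tab$altloc)
    tab <- tab[ord, ]
    tab <- tab[!duplicated(paste(tab$chain, tab$resno, tab$elety)), ]
  }
  tab$altloc <- NULL
  rownames(tab) <- NULL
  new("StructureModel", atoms = tab, source = path)
}

# minimal mmCIF _atom_site loop parser (coordinates + identity only)
readCifAtomSite <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\s*loop_\\s*$", lines)
  for (s in starts) {
    i <- s + 1
    fields <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      fields <- c(fields, trimws(lines[i])); i <- i + 1
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(loop_|_|#|data_)", ln)) break
      toks <- scan(text = ln, what = "", quiet = TRUE)
      if (length(toks) != length(fields))
        stop("mmCIF _atom_site row has ", length(toks),
             " tokens, expected ", length(fields), " (line ", i, ")")
      rows[[length(rows) + 1]] <- toks
      i <- i + 1
    }
    m <- do.call(rbind, rows)
    colnames(m) <- fields
    getcol <- function(nm, default = NA) {
      if (nm %in% fields) m[, nm] else rep(default, nrow(m))
    }
    chain <- getcol("auth_asym_id"); alt_ch <- getcol("label_asym_id")
    chain <- ifelse(is.na(chain) | chain %in% c(".", "?"), alt_ch, chain)
    resno <- getcol("auth_seq_id"); alt_r <- getcol("label_seq_id")
    resno <- ifelse(is.na(resno) | resno %in% c(".", "?"), alt_r, resno)
    alt <- getcol("label_alt_id", ".")
    occ <- suppressWarnings(as.numeric(getcol("occupancy", "1")))
    return(data.frame(
      chain = as.character(chain),
      resno = as.integer(resno),
      resid = as.character(getcol("auth_comp_id",
                                  getcol("label_comp_id"))),
      elety = as.character(getcol("auth_atom_id",
                                  getcol("label_atom_id"))),
      element = as.character(getcol("type_symbol")),
      altloc = ifelse(alt %in% c(".", "?"), "", alt),
      occ = ifelse(is.na(occ), 1, occ),
      x = as.numeric(getcol("Cartn_x")),
      y = as.numeric(getcol("Cartn_y")),
      z = as.numeric(getcol("Cartn_z"))))
  }
  stop("no _atom_site loop found in ", path)
}

#' Write a structure to PDB or mmCIF
#'
#' @param model a [StructureModel-class].
#' @param path output file; `.cif` selects mmCIF, anything else PDB.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(model, path) {
  a <- atoms(model)
  if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    hdr <- c("data_model", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_seq_id", "auth_seq_id", "Cartn_x", "Cartn_y",
                      "Cartn_z", "occupancy", "auth_asym_id",
                      "auth_comp_id", "auth_atom_id")))
    grp <- ifelse(a$resid %in% c("HOH", "WAT", "TIP3") | a$chain == "L",
                  "HETATM", "ATOM")
    body <- sprintf("%s %d %s %s . %s %s %d %d %.3f %.3f %.3f %.2f %s %s %s",
                    grp, seq_len(nrow(a)), a$element, a$elety, a$resid,
                    a$chain, a$resno, a$resno, a$x, a$y, a$z, a$occ,
                    a$chain, a$resid, a$elety)
    writeLines(c(hdr, body, "#"), path)
  } else {
    writeLines(c(pdbAtomLines(a), "END"), path)
  }
  invisible(path)
}

# format atom rows as fixed-width PDB ATOM/HETATM records
pdbAtomLines <- function(a) {
  het <- a$resid %in% c("HOH", "WAT", "TIP3") |
    !a$elety %in% c("N", "CA", "C", "O", "CB")
  rec <- ifelse(a$resid %in% c("HOH", "WAT", "TIP3"), "HETATM", "ATOM  ")
  name <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                 sprintf("%-4s", a$elety))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(nrow(a)) %% 100000, name, a$resid,
          substr(a$chain, 1, 1), a$resno, a$x, a$y, a$z, a$occ, 0,
          substr(a$element, 1, 2))
}

#' Superpose two structures by least squares (Kabsch)
#'
#' Pairs atoms by (chain, residue number, atom name) after applying an
#' optional chain mapping to the mobile structure, then computes the rigid
#' rotation and translation minimizing the RMSD over the paired atoms.
#' Neither input is modified.
#'
#' @param mobile,reference [StructureModel-class] objects.
#' @param selection "calpha" (default), "heavy", "backbone", or "all".
#' @param chainMap named character vector mapping mobile chain ids to
#'   reference chain ids (default identity).
#' @return a [SuperpositionResult-class].
#' @export
superpose <- function(mobile, reference, selection = "calpha",
                      chainMap = NULL) {
  am <- atoms(mobile); ar <- atoms(reference)
  if (!is.null(chainMap)) {
    mapped <- chainMap[am$chain]
    am$chain <- ifelse(is.na(mapped), am$chain, mapped)
  }
  am <- am[selectAtoms(am, selection), ]
  ar <- ar[selectAtoms(ar, selection), ]
  keyM <- paste(am$chain, am$resno, am$elety, sep = ":")
  keyR <- paste(ar$chain, ar$resno, ar$elety, sep = ":")
  common <- intersect(keyM, keyR)
  if (length(common) < 3)
    stop("insufficient pairing: only ", length(common),
         " paired atoms under the selection")
  mi <- match(common, keyM); ri <- match(common, keyR)
  fit <- kabsch(as.matrix(am[mi, c("x", "y", "z")]),
                as.matrix(ar[ri, c("x", "y", "z")]))
  new("SuperpositionResult", rotation = fit$rotation,
      translation = fit$translation, rmsd = fit$rmsd,
      nAtomsUsed = length(common), pairing = common)
}

#' Post-superposition displacement of a single atom
#'
#' Euclidean distance between an atom of the mobile structure, transformed
#' by a previously computed superposition, and the same atom of the
#' reference structure.
#'
#' @param mobile,reference [StructureModel-class] objects.
#' @param superposition a [SuperpositionResult-class] (caller-chosen frame,
#'   e.g. a trimer C-alpha superposition).
#' @param key atom key `"chain:resno:atomname"`; must exist in both models.
#' @return displacement in Angstrom.
#' @export
atomDisplacement <- function(mobile, reference, superposition, key) {
  am <- atoms(mobile); ar <- atoms(reference)
  im <- atomIndex(mobile, key); ir <- atomIndex(reference, key)
  pm <- applyTransform(as.matrix(am[im, c("x", "y", "z")]),
                       superposition@rotation, superposition@translation)
  pr <- as.matrix(ar[ir, c("x", "y", "z")])
  sqrt(sum((pm - pr)^2))
}

#' Protein residues in contact with a ligand
#'
#' Distinct protein residues having at least one atom within `cutoff` of at
#' least one ligand atom. Waters are excluded; hydrogens are excluded by
#' default.
#'
#' @param model a [StructureModel-class].
#' @param ligand ligand residue name (e.g. "TLA" for tartrate).
#' @param cutoff contact distance, Angstrom (> 0 for a non-empty result).
#' @param includeHydrogens include hydrogen atoms in the distance test.
#' @return character vector of residue ids `"chain:resno"` (sorted).
#' @export
ligandContacts <- function(model, ligand, cutoff = 4.0,
                           includeHydrogens = FALSE) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  a <- atoms(model)
  lig <- a[a$resid == ligand, ]
  if (nrow(lig) == 0) stop("ligand not found: ", ligand)
  prot <- a[a$resid != ligand & !a$resid %in% c("HOH", "WAT", "TIP3"), ]
  if (!includeHydrogens) {
    lig <- lig[lig$element != "H", ]
    prot <- prot[prot$element != "H", ]
  }
  if (nrow(prot) == 0 || cutoff == 0) return(character(0))
  pl <- as.matrix(prot[, c("x", "y", "z")])
  ll <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(pl^2), rep(1, nrow(ll))) +
    outer(rep(1, nrow(pl)), rowSums(ll^2)) - 2 * pl %*% t(ll)
  hit <- apply(d2 <= cutoff^2 + 1e-12, 1, any)
  sort(unique(paste(prot$chain[hit], prot$resno[hit], sep = ":")))
}

#' Distance between two atoms of one structure
#'
#' @param model a [StructureModel-class].
#' @param keyA,keyB atom keys `"chain:resno:atomname"`.
#' @return Euclidean distance, Angstrom.
#' @export
atomDistance <- function(model, keyA, keyB) {
  a <- atoms(model)
  ia <- atomIndex(model, keyA); ib <- atomIndex(model, keyB)
  sqrt(sum((as.numeric(a[ia, c("x", "y", "z")]) -
            as.numeric(a[ib, c("x", "y", "z")]))^2))
}
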