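#' Parse fixed-column PDB coordinates
#'
#' Reads `ATOM`/`HETATM` records by the fixed column layout of the PDB
#' format. Alternate locations are resolved by keeping the highest
#' occupancy (ties prefer altLoc `A`); hydrogens are kept in the table but
#' ignored by every distance rule. The element is taken from columns 77-78
#' when present and inferred from the atom name otherwise.
#'
#' @param x Path to a PDB file, or a character vector of PDB lines.
#' @return data.frame of `AtomRecord`s: `serial`, `atom_name`, `alt_loc`,
#'   `residue_name`, `chain_id`, `residue_number`, `x`, `y`, `z`,
#'   `occupancy`, `element`.
#' @export
parse_coordinates <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("argument error: input contains no ATOM/HETATM record")
  idx <- which(sel)
  recs <- lines[sel]
  fw <- function(l, a, b) substr(l, a, b)
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & !grepl("^\\s*$", s)
    if (any(bad))
      stop("parse error: malformed ", what, " at line ", ln[bad][1])
    v
  }
  recs <- vapply(recs, function(l) formatC(l, width = 80, flag = "-"), "",
                 USE.NAMES = FALSE)
  df <- data.frame(
    serial = as.integer(num(fw(recs, 7, 11), "serial", idx)),
    atom_name = trimws(fw(recs, 13, 16)),
    alt_loc = fw(recs, 17, 17),
    residue_name = trimws(fw(recs, 18, 20)),
    chain_id = fw(recs, 22, 22),
    residue_number = as.integer(num(fw(recs, 23, 26), "residue number", idx)),
    x = num(fw(recs, 31, 38), "x coordinate", idx),
    y = num(fw(recs, 39, 46), "y coordinate", idx),
    z = num(fw(recs, 47, 54), "z coordinate", idx),
    occupancy = num(fw(recs, 55, 60), "occupancy", idx),
    element = trimws(fw(recs, 77, 78)),
    stringsAsFactors = FALSE)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("parse error: missing coordinates")
  df$occupancy[is.na(df$occupancy)] <- 1
  infer <- df$element == ""
  if (any(infer)) {
    nm <- gsub("[0-9']", "", df$atom_name[infer])
    df$element[infer] <- ifelse(substr(nm, 1, 1) == "H", "H",
                                substr(nm, 1, 1))
  }
  # alternate locations: keep highest occupancy, ties -> altLoc 'A' (or first)
  if (any(df$alt_loc != " ")) {
    key <- paste(df$chain_id, df$residue_number, df$residue_name, df$atom_name)
    o <- order(key, -df$occupancy, df$alt_loc)
    df <- df[o, ][!duplicated(key[o]), , drop = FALSE]
    df <- df[order(df$serial), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write atoms as fixed-column PDB text
#'
#' @param atoms data.frame of atom records (see [parse_coordinates()]).
#' @param path Optional output file; if `NULL` the lines are returned.
#' @return The PDB lines, invisibly when written to a file.
#' @export
write_pdb <- function(atoms, path = NULL) {
  lines <- sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   atoms$serial,
                   ifelse(nchar(atoms$atom_name) < 4,
                          paste0(" ", atoms$atom_name), atoms$atom_name),
                   ifelse(is.na(atoms$alt_loc) | atoms$alt_loc == "", " ", atoms$alt_loc),
                   atoms$residue_name, atoms$chain_id, atoms$residue_number,
                   atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
                   atoms$element)
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Apolar side-chain carbons (carbons not bonded to N or O), per residue.
APOLAR_CARBONS <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  PRO = c("CB", "CG"), THR = "CG2",
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"), GLN = c("CB", "CG"),
  GLU = c("CB", "CG"), ASN = "CB", ASP = "CB", HIS = "CB", CYS = "CB",
  SER = character(0), GLY = character(0))

side_chain_heavy <- function(atoms) {
  atoms[!(atoms$atom_name %in% BACKBONE_ATOMS) & atoms$element != "H", ,
        drop = FALSE]
}

res_key <- function(atoms) paste(atoms$chain_id, atoms$residue_number)

min_dist <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(Inf)
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 + outer(a$z, b$z, "-")^2
  sqrt(min(d2))
}

#' Residues in side-chain contact with a center residue
#'
#' A residue is a neighbor iff any of its side-chain heavy atoms (CB
#' included; glycine has none) lies within `cutoff` of any side-chain heavy
#' atom of the center residue. Backbone-only proximity is deliberately
#' excluded: the variant site's side chain is what changes between Ala and
#' Thr. Partners carry their minimum heavy-atom distance and whether they
#' sit on the same chain.
#'
#' @param atoms Atom table from [parse_coordinates()].
#' @param chain Chain id of the center residue.
#' @param residue_number Residue number of the center residue.
#' @param cutoff Neighborhood radius in Angstrom (default 5.5).
#' @return A `contact_report`: `center` and a `partners` data.frame with
#'   `chain_id`, `residue_number`, `residue_name`, `min_dist`,
#'   `contact_class` (all `"proximal_only"` here), `scope`.
#' @export
neighbor_residues <- function(atoms, chain, residue_number, cutoff = 5.5) {
  ctr <- atoms[atoms$chain_id == chain & atoms$residue_number == residue_number, ,
               drop = FALSE]
  if (!nrow(ctr))
    stop("lookup error: no residue ", residue_number, " in chain ", chain)
  ctr_sc <- side_chain_heavy(ctr)
  center <- list(chain = chain, residue_number = residue_number,
                 residue_name = ctr$residue_name[1])
  partners <- data.frame(chain_id = character(0), residue_number = integer(0),
                         residue_name = character(0), min_dist = numeric(0),
                         contact_class = character(0), scope = character(0),
                         stringsAsFactors = FALSE)
  if (nrow(ctr_sc)) {
    other <- atoms[res_key(atoms) != paste(chain, residue_number), , drop = FALSE]
    osc <- side_chain_heavy(other)
    if (nrow(osc)) {
      for (key in unique(res_key(osc))) {
        grp <- osc[res_key(osc) == key, , drop = FALSE]
        d <- min_dist(ctr_sc, grp)
        if (d <= cutoff) {
          partners <- rbind(partners, data.frame(
            chain_id = grp$chain_id[1],
            residue_number = grp$residue_number[1],
            residue_name = grp$residue_name[1],
            min_dist = d, contact_class = "proximal_only",
            scope = if (grp$chain_id[1] == chain) "intra_chain" else "inter_chain",
            stringsAsFactors = FALSE))
        }
      }
      partners <- partners[order(partners$chain_id, partners$residue_number), ,
                           drop = FALSE]
      rownames(partners) <- NULL
    }
  }
  structure(list(center = center, partners = partners, cutoff = cutoff,
                 hbond_cutoff = NA_real_, hydrophobic_cutoff = NA_real_),
            class = "contact_report")
}

#' Classify contacts as hydrogen-bonding and/or hydrophobic
#'
#' Geometric stand-ins for the interaction assignment of structure viewers:
#' a pair is `hbond` if any N/O heavy atom of one residue (backbone
#' included; hydrogens implicit, no angle term) is within `hbond_cutoff` of
#' an N/O of the other, and `hydrophobic` if an apolar carbon (a carbon not
#' bonded to N or O, by a per-residue name table) of one is within
#' `hydrophobic_cutoff` of an apolar carbon of the other. A pair can carry
#' both labels (rendered `"hbond+hydrophobic"`); otherwise it stays
#' `proximal_only`.
#'
#' @param report A `contact_report` from [neighbor_residues()].
#' @param atoms The same atom table the report was computed from.
#' @param hbond_cutoff Donor-acceptor distance cutoff, default 3.5 A.
#' @param hydrophobic_cutoff Apolar C-C cutoff, default 4.5 A.
#' @return The report with `contact_class` filled in.
#' @export
classify_contacts <- function(report, atoms, hbond_cutoff = 3.5,
                              hydrophobic_cutoff = 4.5) {
  stopifnot(inherits(report, "contact_report"))
  ctr <- atoms[atoms$chain_id == report$center$chain &
                 atoms$residue_number == report$center$residue_number, ,
               drop = FALSE]
  heavy <- function(a) a[a$element != "H", , drop = FALSE]
  polar <- function(a) a[a$element %in% c("N", "O"), , drop = FALSE]
  apolar <- function(a) {
    ok <- mapply(function(rn, an) an %in% (APOLAR_CARBONS[[rn]] %||% character(0)),
                 a$residue_name, a$atom_name)
    a[a$element == "C" & ok, , drop = FALSE]
  }
  ctr_h <- heavy(ctr)
  cls <- character(nrow(report$partners))
  for (i in seq_len(nrow(report$partners))) {
    p <- report$partners[i, ]
    grp <- heavy(atoms[atoms$chain_id == p$chain_id &
                         atoms$residue_number == p$residue_number, , drop = FALSE])
    hb <- min_dist(polar(ctr_h), polar(grp)) <= hbond_cutoff
    hp <- min_dist(apolar(ctr_h), apolar(grp)) <= hydrophobic_cutoff
    cls[i] <- if (hb && hp) "hbond+hydrophobic"
      else if (hb) "hbond" else if (hp) "hydrophobic" else "proximal_only"
  }
  report$partners$contact_class <- cls
  report$hbond_cutoff <- hbond_cutoff
  report$hydrophobic_cutoff <- hydrophobic_cutoff
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("contact environment of %s %s%d (cutoff %.2f A)\n",
              x$center$residue_name, x$center$chain, x$center$residue_number,
              x$cutoff))
  if (nrow(x$partners)) print(x$partners, row.names = FALSE)
  else cat("  no side-chain contacts\n")
  invisible(x)
}

# Place atom D given A-B-C with |CD| = bond, angle(B,C,D) and
# torsion(A,B,C,D) in degrees (standard internal-coordinate construction).
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- ab - sum(ab * bc) * bc
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(bc, n)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * (-n) + d2[3] * m
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])

#' Swap alanine and threonine at a site by ideal-geometry construction
#'
#' Forward (`ALA` center): builds `OG1` (C-O bond 1.43 A) and `CG2`
#' (C-C bond 1.52 A) onto the existing `CB` with tetrahedral angles, chi1
#' fixed at the common gauche- rotamer (-60 deg; `CG2` at +60 deg) and
#' renames the residue `THR`. Reverse (`THR` center): deletes side-chain
#' atoms beyond `CB` and renames to `ALA`. The two operations are exact
#' inverses up to serial renumbering.
#'
#' @param atoms Atom table.
#' @param chain,residue_number The site to mutate.
#' @param chi1 Torsion N-CA-CB-OG1 in degrees (default -60).
#' @return The modified atom table (serials renumbered consecutively).
#' @export
mutate_ala_thr <- function(atoms, chain, residue_number, chi1 = -60) {
  sel <- atoms$chain_id == chain & atoms$residue_number == residue_number
  if (!any(sel)) stop("lookup error: no residue ", residue_number,
                      " in chain ", chain)
  res <- atoms[sel, , drop = FALSE]
  type <- res$residue_name[1]
  get <- function(nm) {
    r <- res[res$atom_name == nm, , drop = FALSE]
    if (!nrow(r)) stop("structure error: residue lacks backbone atom ", nm)
    c(r$x[1], r$y[1], r$z[1])
  }
  if (type == "ALA") {
    N <- get("N"); CA <- get("CA"); get("C"); CB <- get("CB")
    og1 <- place_atom(N, CA, CB, 1.43, 109.5, chi1)
    cg2 <- place_atom(N, CA, CB, 1.52, 109.5, chi1 + 120)
    atoms$residue_name[sel] <- "THR"
    new <- res[c(1, 1), , drop = FALSE]
    new$atom_name <- c("OG1", "CG2")
    new$element <- c("O", "C")
    new$alt_loc <- " "
    new$occupancy <- 1
    new[, c("x", "y", "z")] <- rbind(og1, cg2)
    new$residue_name <- "THR"
    last <- max(which(sel))
    atoms <- rbind(atoms[seq_len(last), , drop = FALSE], new,
                   if (last < nrow(atoms))
                     atoms[seq(last + 1, nrow(atoms)), , drop = FALSE])
  } else if (type == "THR") {
    for (nm in c("N", "CA", "C", "CB")) get(nm)
    drop <- sel & !(atoms$atom_name %in% c(BACKBONE_ATOMS, "CB")) &
      atoms$element != "H"
    atoms <- atoms[!drop, , drop = FALSE]
    atoms$residue_name[atoms$chain_id == chain &
                         atoms$residue_number == residue_number] <- "ALA"
  } else {
    stop("argument error: residue is ", type, ", expected ALA or THR")
  }
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  atoms
}

#' Inter-chain contacts of a residue position in a dimer
#'
#' Runs [neighbor_residues()] plus [classify_contacts()] for the given
#' residue number on every chain that carries it, keeping only partners on
#' other chains — the analysis used for the dimer-interface question.
#'
#' @param atoms Atom table with at least two chains.
#' @param residue_number Residue number (looked up per chain).
#' @param cutoff Neighborhood radius (A).
#' @param hbond_cutoff,hydrophobic_cutoff Classification cutoffs.
#' @return Named list of `contact_report`s, one per chain copy, each
#'   restricted to `inter_chain` partners.
#' @export
interface_contacts <- function(atoms, residue_number, cutoff = 5.5,
                               hbond_cutoff = 3.5, hydrophobic_cutoff = 4.5) {
  chains <- unique(atoms$chain_id)
  if (length(chains) < 2)
    stop("argument error: single-chain input; use neighbor_residues() instead")
  out <- list()
  for (ch in chains) {
    if (!any(atoms$chain_id == ch & atoms$residue_number == residue_number))
      next
    rep <- neighbor_residues(atoms, ch, residue_number, cutoff)
    rep <- classify_contacts(rep, atoms, hbond_cutoff, hydrophobic_cutoff)
    rep$partners <- rep$partners[rep$partners$scope == "inter_chain", ,
                                 drop = FALSE]
    rownames(rep$partners) <- NULL
    out[[ch]] <- rep
  }
  if (!length(out))
    stop("lookup error: residue ", residue_number, " absent from every chain")
  out
}
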