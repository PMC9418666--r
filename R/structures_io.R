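#' @section Atom tables:
#' Receptor structures and ligand poses both carry their atoms as a
#' data.frame with one row per atom and columns `atom_index`, `atom_name`,
#' `element`, `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`,
#' `formal_charge` and a list-column `roles` holding the chemical roles the
#' contact typer consumes (see [atom_roles_universe()]).
#' @name atom-tables
NULL

new_atom_table <- function(atom_name, element, residue_name, residue_number,
                           chain_id, xyz, formal_charge = 0L) {
  n <- length(atom_name)
  element <- toupper(element)
  stopifnot(nrow(xyz) == n)
  if (any(!is.finite(xyz))) stop("non-finite atom coordinates")
  df <- data.frame(
    atom_index = seq_len(n),
    atom_name = atom_name,
    element = element,
    residue_name = residue_name,
    residue_number = as.integer(residue_number),
    chain_id = chain_id,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    formal_charge = as.integer(rep_len(formal_charge, n)),
    stringsAsFactors = FALSE
  )
  df$roles <- rep(list(character(0)), n)
  df
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Receptor structure
#'
#' Container for an annotated receptor: an atom table plus a residue index
#' mapping `(chain_id, residue_number)` to atom rows. Residue numbers are kept
#' verbatim from the source file (no renumbering, no generic-numbering
#' conversion).
#'
#' @param atoms atom table (see `new_atom_table`).
#' @return object of class `aifp_receptor`.
#' @keywords internal
new_receptor <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_number, sep = "|")
  structure(
    list(
      atoms = atoms,
      residue_index = split(atoms$atom_index, key),
      rings = list()
    ),
    class = "aifp_receptor"
  )
}

#' @export
print.aifp_receptor <- function(x, ...) {
  cat(sprintf("<aifp_receptor> %d atoms, %d residues\n",
              nrow(x$atoms), length(x$residue_index)))
  invisible(x)
}

#' Atoms of one receptor residue
#'
#' @param receptor an `aifp_receptor`.
#' @param chain_id single chain identifier.
#' @param residue_number residue number as in the source PDB.
#' @return atom-table subset (zero rows if the residue is absent).
#' @export
residue_atoms <- function(receptor, chain_id, residue_number) {
  idx <- receptor$residue_index[[paste(chain_id, residue_number, sep = "|")]]
  receptor$atoms[receptor$atoms$atom_index %in% idx, , drop = FALSE]
}

#' Read a receptor structure from a PDB file
#'
#' Parses ATOM records (waters and non-protein HETATM records are excluded by
#' default) and returns an [new_receptor] container. Coordinates are in
#' Angstrom; residue numbering is preserved verbatim.
#'
#' @param path PDB file.
#' @param keep_hydrogens keep hydrogen atoms (default TRUE; docking receptors
#'   often omit them anyway).
#' @return an `aifp_receptor` (roles unassigned; see [assign_atom_roles()]).
#' @export
read_receptor <- function(path, keep_hydrogens = TRUE) {
  if (!file.exists(path)) stop("receptor file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file: ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (!keep_hydrogens) at <- at[toupper(at$elesy) != "H", , drop = FALSE]
  if (nrow(at) == 0) stop("no protein atoms in ", path)
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(trimws(at$elety[miss]), 1, 1)
  atoms <- new_atom_table(
    atom_name = trimws(at$elety),
    element = elem,
    residue_name = trimws(at$resid),
    residue_number = at$resno,
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    xyz = cbind(at$x, at$y, at$z)
  )
  new_receptor(atoms)
}

#' Write a receptor structure to a PDB file
#'
#' @param receptor an `aifp_receptor`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_receptor_pdb <- function(receptor, path) {
  a <- receptor$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(atom_xyz(a))),
    resno = a$residue_number,
    chain = a$chain_id,
    resid = a$residue_name,
    eleno = a$atom_index,
    elety = a$atom_name,
    elesy = a$element
  )
  invisible(path)
}

#' Ligand docking pose
#'
#' One docked ligand conformation: identity (`ligand_id`, `pose_number`), an
#' atom table and a bond table (`atom_1`, `atom_2`, `order`, `aromatic`).
#' The sample identifier renders as `"<ligand_id>_<poseNumber>"`.
#'
#' @keywords internal
new_pose <- function(ligand_id, pose_number, atoms, bonds) {
  pose_number <- as.integer(pose_number)
  if (is.na(pose_number) || pose_number < 1) {
    stop("pose_number must be a positive integer")
  }
  if (nrow(bonds) > 0 &&
      (any(bonds$atom_1 > nrow(atoms)) || any(bonds$atom_2 > nrow(atoms)) ||
       any(bonds$atom_1 < 1) || any(bonds$atom_2 < 1))) {
    stop("bond endpoints outside the atom table")
  }
  structure(
    list(ligand_id = ligand_id, pose_number = pose_number,
         atoms = atoms, bonds = bonds, rings = list()),
    class = "aifp_pose"
  )
}

#' @export
print.aifp_pose <- function(x, ...) {
  cat(sprintf("<aifp_pose> %s: %d atoms, %d bonds\n",
              sample_id(x), nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Sample identifier of a pose ("ligandID_poseNumber")
#' @param pose an `aifp_pose`.
#' @export
sample_id <- function(pose) make_sample_id(pose$ligand_id, pose$pose_number)

# MDL ctab charge codes <-> formal charges.
.ctab_code_to_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
           `6` = -2L, `7` = -3L)
  out <- map[as.character(as.integer(code))]
  out[is.na(out)] <- 0L
  unname(out)
}

.charge_to_ctab_code <- function(charge) {
  map <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L, `-2` = 6L,
           `-3` = 7L)
  out <- map[as.character(as.integer(charge))]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Read ligand docking poses from a multi-record SDF (V2000)
#'
#' Each record's title line must carry the sample identity as
#' `"ligandID_poseNumber"` (e.g. `"lig 752_04"`); the pose number is split off
#' at the last underscore. Bond orders and aromatic flags (bond type 4) are
#' retained; formal charges are taken from the atom-block charge codes.
#'
#' @param path SDF file.
#' @return list of `aifp_pose` objects (roles unassigned).
#' @export
read_poses <- function(path) {
  if (!file.exists(path)) stop("pose file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0 || !any(grepl("\\$\\$\\$\\$", raw))) {
    warning("empty SDF: ", path)
    return(list())
  }
  sdfset <- ChemmineR::read.SDFset(path)
  ok <- ChemmineR::validSDF(sdfset)
  if (any(!ok)) {
    stop("malformed SDF record(s) at index ",
         paste(which(!ok), collapse = ", "),
         " (atom/bond blocks inconsistent with the counts line)")
  }
  poses <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    title <- unname(ChemmineR::header(sdf)["Molecule_Name"])
    if (is.na(title) || !nzchar(trimws(title))) {
      stop("SDF record ", i, " has no title; expected \"ligandID_poseNumber\"")
    }
    title <- trimws(title)
    if (!grepl("_[0-9]+$", title)) {
      stop("SDF record ", i, " title ", dQuote(title),
           " does not end in _<poseNumber>")
    }
    id <- split_sample_id(title)
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elem <- toupper(sub("_[0-9]+$", "", rownames(ab)))
    charge <- if ("C6" %in% colnames(ab)) .ctab_code_to_charge(ab[, "C6"]) else 0L
    atoms <- new_atom_table(
      atom_name = paste0(elem, seq_len(nrow(ab))),
      element = elem,
      residue_name = id$ligand_id,
      residue_number = id$pose_number,
      chain_id = "L",
      xyz = ab[, c("C1", "C2", "C3"), drop = FALSE],
      formal_charge = charge
    )
    bonds <- if (is.null(bb) || nrow(bb) == 0) {
      data.frame(atom_1 = integer(0), atom_2 = integer(0),
                 order = integer(0), aromatic = logical(0))
    } else {
      data.frame(
        atom_1 = as.integer(bb[, "C1"]),
        atom_2 = as.integer(bb[, "C2"]),
        order = as.integer(bb[, "C3"]),
        aromatic = as.integer(bb[, "C3"]) == 4L
      )
    }
    poses[[i]] <- new_pose(id$ligand_id, id$pose_number, atoms, bonds)
  }
  poses
}

#' Write ligand poses to a multi-record SDF (V2000)
#'
#' Inverse of [read_poses()]: record titles are the sample identifiers,
#' formal charges go to the atom-block charge codes, aromatic bonds are bond
#' type 4.
#'
#' @param poses list of `aifp_pose`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_poses_sdf <- function(poses, path) {
  cols16 <- c("C1", "C2", "C3", "C5", "C6", "C7", "C8", "C9", "C10", "C11",
              "C12", "C13", "C14", "C15", "C16", "C17")
  sdfs <- lapply(poses, function(pose) {
    a <- pose$atoms
    ab <- matrix(0, nrow(a), length(cols16),
                 dimnames = list(paste(a$element, seq_len(nrow(a)), sep = "_"),
                                 cols16))
    ab[, "C1"] <- round(a$x, 4)
    ab[, "C2"] <- round(a$y, 4)
    ab[, "C3"] <- round(a$z, 4)
    ab[, "C6"] <- .charge_to_ctab_code(a$formal_charge)
    b <- pose$bonds
    btype <- ifelse(b$aromatic, 4L, b$order)
    bb <- matrix(c(b$atom_1, b$atom_2, btype, rep(0L, nrow(b))),
                 nrow(b), 4, dimnames = list(seq_len(max(1, nrow(b)))[seq_len(nrow(b))],
                                             c("C1", "C2", "C3", "C4")))
    hd <- c(Molecule_Name = sample_id(pose), Source = "aifp", Comment = "",
            Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                  nrow(a), nrow(b)))
    methods::new("SDF", header = hd, atomblock = ab, bondblock = bb,
                 datablock = character(0))
  })
  sdfset <- methods::new("SDFset", SDF = sdfs,
                         ID = vapply(poses, sample_id, character(1)))
  ChemmineR::write.SDF(sdfset, path)
  invisible(path)
}

#' Read the ligand label table
#'
#' @param path CSV with columns `ligand_id`, `label`
#'   (agonist / antagonist / binder).
#' @return data.frame.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand_id", "label") %in% names(df))) {
    stop("label table must have columns ligand_id, label")
  }
  bad <- setdiff(unique(df$label), c("agonist", "antagonist", "binder"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  df
}

#' Assign chemical roles to every atom
#'
#' Populates the `roles` list-column of a receptor or pose. Protein atoms get
#' roles from fixed per-residue templates (e.g. Asp OD1/OD2 anion + acceptor,
#' Lys NZ cation + donor, Ser OG donor + acceptor) plus shared backbone roles;
#' ligand atoms get roles from element, formal charge and bonded neighbours
#' (protonated or H-bearing nitrogen is a donor, oxygen an acceptor, carbon
#' bonded only to C/H a hydrophobe, aromatic-flagged ring atoms aromatic).
#' Assignment is a pure function of the input: identical structures always
#' receive identical roles.
#'
#' @param x an `aifp_receptor` or `aifp_pose`.
#' @return `x` with roles populated (and aromatic ring membership recorded in
#'   `$rings`).
#' @export
assign_atom_roles <- function(x) UseMethod("assign_atom_roles")

#' @export
assign_atom_roles.aifp_receptor <- function(x) {
  atoms <- x$atoms
  roles <- rep(list(character(0)), nrow(atoms))
  rings <- list()
  unknown <- character(0)
  key <- paste(atoms$chain_id, atoms$residue_number, sep = "|")
  for (idx in split(seq_len(nrow(atoms)), key)) {
    resname <- atoms$residue_name[idx[1]]
    tmpl <- .SIDECHAIN_ROLES[[resname]]
    if (is.null(tmpl) && !(resname %in% .AA3)) {
      unknown <- c(unknown, resname)
      # element-only fallback
      for (i in idx) {
        roles[[i]] <- switch(atoms$element[i],
                             O = "acceptor", N = "donor",
                             C = character(0), character(0))
        if (atoms$element[i] %in% .METALS) roles[[i]] <- "cation"
      }
      next
    }
    bb <- backbone_roles(resname)
    for (i in idx) {
      nm <- atoms$atom_name[i]
      r <- character(0)
      if (!is.null(bb[[nm]])) r <- bb[[nm]]
      if (!is.null(tmpl[[nm]])) r <- union(r, tmpl[[nm]])
      roles[[i]] <- r
    }
    ringdef <- .RESIDUE_RINGS[[resname]]
    if (!is.null(ringdef)) {
      for (ringnames in ringdef) {
        members <- idx[match(ringnames, atoms$atom_name[idx])]
        members <- members[!is.na(members)]
        if (length(members) >= 5) rings[[length(rings) + 1L]] <- members
      }
    }
  }
  if (length(unknown)) {
    warning("unknown residue template(s): ",
            paste(unique(unknown), collapse = ", "),
            "; element-only roles assigned")
  }
  x$atoms$roles <- roles
  x$rings <- rings
  x
}

#' @export
assign_atom_roles.aifp_pose <- function(x) {
  atoms <- x$atoms
  bonds <- x$bonds
  n <- nrow(atoms)
  nbrs <- vector("list", n)
  border <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$atom_1[k]; j <- bonds$atom_2[k]
      nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
      border[[i]] <- c(border[[i]], bonds$order[k])
      border[[j]] <- c(border[[j]], bonds$order[k])
    }
  }
  elem <- atoms$element
  n_h <- vapply(nbrs, function(nb) sum(elem[nb] == "H"), integer(1))
  heavy_val <- vapply(nbrs, function(nb) sum(elem[nb] != "H"), integer(1))
  has_double_o <- function(i) {
    nb <- nbrs[[i]]; bo <- border[[i]]
    any(elem[nb] == "O" & bo == 2L)
  }
  # aromatic flags from bond type 4
  arom_atom <- rep(FALSE, n)
  if (nrow(bonds)) {
    af <- bonds[bonds$aromatic, , drop = FALSE]
    arom_atom[unique(c(af$atom_1, af$atom_2))] <- TRUE
  }
  roles <- vector("list", n)
  for (i in seq_len(n)) {
    e <- elem[i]; q <- atoms$formal_charge[i]
    r <- character(0)
    if (e == "N") {
      if (q > 0) r <- c(r, "cation", "donor")
      else {
        if (n_h[i] >= 1 || heavy_val[i] < 3) r <- c(r, "donor")
        r <- c(r, "acceptor")
      }
      if (q < 0) r <- c(r, "anion")
    } else if (e == "O") {
      r <- c(r, "acceptor")
      if (q < 0) r <- c(r, "anion")
      dbl <- any(border[[i]] == 2L)
      if (dbl) r <- c(r, "carbonyl_oxygen")
      if (q == 0 && !dbl && (n_h[i] >= 1 || heavy_val[i] <= 1)) r <- c(r, "donor")
    } else if (e == "S") {
      r <- c(r, "acceptor")
      if (n_h[i] >= 1) r <- c(r, "donor")
    } else if (e == "C") {
      nb_heavy <- nbrs[[i]][elem[nbrs[[i]]] != "H"]
      if (length(nb_heavy) == 0 || all(elem[nb_heavy] == "C")) {
        r <- c(r, "hydrophobe")
      }
      if (has_double_o(i)) r <- c(r, "carbonyl_carbon")
      if (q > 0) r <- c(r, "cation")
    } else if (e %in% .HALOGENS) {
      r <- c(r, "halogen")
    } else if (e %in% .METALS) {
      r <- c(r, "cation")
    }
    if (arom_atom[i]) r <- union(r, "aromatic")
    roles[[i]] <- r
  }
  x$atoms$roles <- roles
  # rings: connected components over aromatic bonds
  rings <- list()
  if (any(arom_atom)) {
    parent <- seq_len(n)
    findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    ab <- bonds[bonds$aromatic, , drop = FALSE]
    for (k in seq_len(nrow(ab))) {
      ri <- findp(ab$atom_1[k]); rj <- findp(ab$atom_2[k])
      if (ri != rj) parent[ri] <- rj
    }
    comp <- vapply(seq_len(n), findp, integer(1))
    for (grp in split(which(arom_atom), comp[arom_atom])) {
      if (length(grp) >= 5) rings[[length(rings) + 1L]] <- as.integer(grp)
    }
  }
  x$rings <- rings
  x
}
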