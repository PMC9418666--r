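# Toy binding-pocket generator: a sparse open shell of probe residues on a
# sphere (one fixed icosahedral direction per residue), with ligand atoms
# placed radially inward of their probe atoms at controlled distances, so
# every planted contact types deterministically and no unplanned
# receptor-ligand pair falls inside the neighbour cutoff. The receptor
# layout is fixed; planting a contact adds the ligand-side partner.

# icosahedron vertex directions (unit vectors, minimum pairwise angle 63.4 deg)
.ICO_DIRECTIONS <- local({
  p <- (1 + sqrt(5)) / 2
  m <- rbind(
    c(0, 1, p), c(0, -1, p), c(0, 1, -p), c(0, -1, -p),
    c(1, p, 0), c(-1, p, 0), c(1, -p, 0), c(-1, -p, 0),
    c(p, 0, 1), c(-p, 0, 1), c(p, 0, -1), c(-p, 0, -1)
  )
  m / sqrt(rowSums(m^2))
})

# Registry of plantable interactions: which probe residue hosts each slot
# (slot i sits on direction i), which ligand partner realises it, and the
# distance window inside which the rule table types the pair as intended
# (margins keep clear of neighbouring thresholds).
.PLANT_REGISTRY <- list(
  ionic = list(residue = 113, resname = "ASP", probe = "OD2",
               partner = "N_plus", window = c(3.10, 3.95), type = "ionic"),
  hydrogen_bond = list(residue = 312, resname = "ASN", probe = "OD1",
                       partner = "O_hydroxyl", window = c(2.85, 3.45),
                       type = "hydrogen_bond"),
  polar = list(residue = 301, resname = "GLN", probe = "OE1",
               partner = "O_carbonyl", window = c(2.85, 3.45),
               type = "polar"),
  weak_polar = list(residue = 293, resname = "ASN", probe = "OD1",
                    partner = "O_carbonyl", window = c(3.55, 3.95),
                    type = "weak_polar"),
  carbonyl = list(residue = 315, resname = "GLY", probe = "C",
                  partner = "O_hydroxyl", window = c(3.00, 3.55),
                  type = "carbonyl"),
  halogen_bond = list(residue = 193, resname = "PHE", probe = "O",
                      partner = "Cl", window = c(3.10, 3.95),
                      type = "halogen_bond"),
  hydrophobic = list(residue = 114, resname = "VAL", probe = "CG1",
                     partner = "C_alkyl", window = c(3.20, 4.45),
                     type = "hydrophobic"),
  vdw = list(residue = 82, resname = "MET", probe = "SD",
             partner = "C_alkyl", window = c(3.40, 3.75), type = "vdw"),
  proximal = list(residue = 118, resname = "VAL", probe = "CG2",
                  partner = "O_hydroxyl", window = c(4.30, 4.95),
                  type = "proximal"),
  aromatic = list(residue = 290, resname = "PHE", probe = "ring",
                  partner = "benzene", window = c(3.40, 3.80),
                  type = "aromatic"),
  hbond_203 = list(residue = 203, resname = "SER", probe = "OG",
                   partner = "O_hydroxyl", window = c(2.85, 3.45),
                   type = "hydrogen_bond"),
  aromatic_286 = list(residue = 286, resname = "TRP", probe = "ring",
                      partner = "benzene", window = c(3.40, 3.80),
                      type = "aromatic")
)

#' Interaction slots plantable in a toy complex
#'
#' Each slot names a probe residue of the fixed toy pocket and the
#' interaction type it realises; most slots are named after their type
#' (`hbond_203` and `aromatic_286` are alternate pocket locations for
#' hydrogen bonds and aromatic stacks).
#'
#' @return data.frame of slot name, residue, probe atom and planted type.
#' @export
plantable_interactions <- function() {
  data.frame(
    slot = names(.PLANT_REGISTRY),
    residue_number = vapply(.PLANT_REGISTRY, function(s) as.integer(s$residue),
                            integer(1)),
    residue_name = vapply(.PLANT_REGISTRY, `[[`, character(1), "resname"),
    probe = vapply(.PLANT_REGISTRY, `[[`, character(1), "probe"),
    type = vapply(.PLANT_REGISTRY, `[[`, character(1), "type"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Specification of a toy receptor-ligand complex
#'
#' Chooses which interactions to plant (by slot name, see
#' [plantable_interactions()]) and at which distance (`NA` draws uniformly
#' from that slot's admissible window under `seed`). `motif = TRUE`
#' prepends the two binding-anchor contacts (113 ionic, 312 hydrogen bond)
#' that the pose filter requires.
#'
#' @param planted character vector of slot names (each at most once: a probe
#'   residue hosts one ligand partner).
#' @param distances optional numeric vector (same length as the final
#'   planted set) of target probe-partner distances; `NA` entries sampled.
#' @param motif prepend the two anchor interactions.
#' @param ligand_id,pose_number identity of the generated pose.
#' @param seed integer seed.
#' @return object of class `aifp_complex_spec`.
#' @export
complex_spec <- function(planted = character(0), distances = NULL,
                         motif = TRUE, ligand_id = "toy 001",
                         pose_number = 1, seed = 1) {
  if (motif) {
    planted <- c("ionic", "hydrogen_bond",
                 setdiff(planted, c("ionic", "hydrogen_bond")))
  }
  bad <- setdiff(planted, names(.PLANT_REGISTRY))
  if (length(bad)) stop("unknown plantable slot(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(planted)) {
    dup <- planted[duplicated(planted)][1]
    stop("incompatible planting request: residue ",
         .PLANT_REGISTRY[[dup]]$residue, " (slot ", dup,
         ") would host two ligand partners")
  }
  if (!is.null(distances) && length(distances) != length(planted)) {
    stop("distances must match planted in length")
  }
  structure(list(planted = planted,
                 distances = distances %||% rep(NA_real_, length(planted)),
                 ligand_id = ligand_id, pose_number = as.integer(pose_number),
                 seed = as.integer(seed)),
            class = "aifp_complex_spec")
}

# in-plane orthonormal basis perpendicular to u
.plane_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / vec_norm(e1)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

.RPROBE <- 8.0      # probe-shell radius, Angstrom
.RBACK <- 2.6       # radial offset of supporting atoms behind their probe

# Build one toy residue: probe atom at .RPROBE*u (or a ring centred there),
# supporting side-chain/backbone atoms strictly further out along u so only
# the probe can come within the cutoff of a planted ligand atom.
.build_residue <- function(slot, u) {
  basis <- .plane_basis(u)
  out <- function(s, lat1 = 0, lat2 = 0) {
    (.RPROBE + s) * u + lat1 * basis$e1 + lat2 * basis$e2
  }
  atoms <- list()
  add <- function(name, pos) {
    atoms[[length(atoms) + 1L]] <<- list(name = name, pos = pos)
  }
  if (identical(slot$probe, "ring")) {
    ringnames <- if (slot$resname == "PHE") {
      c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    } else c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
    for (k in seq_along(ringnames)) {
      ang <- 2 * pi * (k - 1) / 6
      add(ringnames[k], out(0, 1.39 * cos(ang), 1.39 * sin(ang)))
    }
    if (slot$resname == "TRP") {  # five-ring atoms, tucked behind
      add("CG", out(.RBACK, 0.8, 0))
      add("CD1", out(.RBACK, 1.6, 0.8))
      add("NE1", out(.RBACK, 2.0, 0))
    }
    add("CB", out(.RBACK + 0.8, -0.8, 0))
  } else {
    add(slot$probe, out(0))
    sib <- switch(slot$resname,
                  ASP = list(c("OD1", 0.9), c("CG", 0.3)),
                  ASN = list(c("ND2", 0.9), c("CG", 0.3)),
                  GLN = list(c("NE2", 0.9), c("CD", 0.3)),
                  SER = list(c("CB", 0.3)),
                  VAL = list(c("CB", 0.3), c("CG1", 1.2), c("CG2", -1.2)),
                  MET = list(c("CG", 0.3), c("CE", 1.2)),
                  list())
    seen <- slot$probe
    for (sb in sib) {
      if (sb[1] %in% seen) next
      seen <- c(seen, sb[1])
      add(sb[1], out(.RBACK, as.numeric(sb[2]), 0))
    }
  }
  # backbone, further out still (unless the probe is itself a backbone atom)
  for (bb in list(c("N", 4.2, 0.5), c("CA", 4.6, -0.5), c("C", 5.0, 0.4),
                  c("O", 5.4, -0.4))) {
    nm <- bb[1]
    if (any(vapply(atoms, function(a) identical(a$name, nm), logical(1)))) next
    add(nm, out(as.numeric(bb[2]), as.numeric(bb[3]), 0))
  }
  data.frame(
    atom_name = vapply(atoms, `[[`, character(1), "name"),
    element = substr(vapply(atoms, `[[`, character(1), "name"), 1, 1),
    residue_name = slot$resname, residue_number = slot$residue,
    t(vapply(atoms, `[[`, numeric(3), "pos")),
    stringsAsFactors = FALSE
  )
}

# The fixed toy receptor: every registry residue on its own direction.
.build_toy_receptor <- function() {
  rec_df <- do.call(rbind, lapply(seq_along(.PLANT_REGISTRY), function(i) {
    .build_residue(.PLANT_REGISTRY[[i]], .ICO_DIRECTIONS[i, ])
  }))
  rec_df$element[rec_df$element == "S"] <- "S"  # SD: first letter is S
  receptor <- new_receptor(new_atom_table(
    atom_name = rec_df$atom_name, element = rec_df$element,
    residue_name = rec_df$residue_name,
    residue_number = rec_df$residue_number,
    chain_id = "A", xyz = as.matrix(rec_df[, c("X1", "X2", "X3")])
  ))
  assign_atom_roles(receptor)
}

# ligand partner atoms for one planted slot; returns atom rows, bonds to the
# central scaffold carbon (atom index 1), and the expected AIF record(s)
.build_partner <- function(slot, u, d, atom_offset) {
  basis <- .plane_basis(u)
  mk <- function(elem, pos, charge = 0L) {
    data.frame(element = elem, x = pos[1], y = pos[2], z = pos[3],
               formal_charge = charge, stringsAsFactors = FALSE)
  }
  if (identical(slot$partner, "benzene")) {
    centre <- (.RPROBE - d) * u
    at <- do.call(rbind, lapply(seq_len(6), function(k) {
      ang <- 2 * pi * (k - 1) / 6
      mk("C", centre + 1.39 * cos(ang) * basis$e1 + 1.39 * sin(ang) * basis$e2)
    }))
    idx <- atom_offset + seq_len(6)
    bonds <- rbind(
      data.frame(atom_1 = idx, atom_2 = c(idx[-1], idx[1]), order = 4L,
                 aromatic = TRUE),
      data.frame(atom_1 = idx[1], atom_2 = 1L, order = 1L, aromatic = FALSE)
    )
    ringnames <- if (slot$resname == "PHE") {
      c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    } else c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
    expected <- data.frame(
      residue_number = slot$residue, receptor_atom = ringnames,
      ligand_element = "C", type = "aromatic", stringsAsFactors = FALSE)
    return(list(atoms = at, bonds = bonds, expected = expected))
  }
  pos <- (.RPROBE - d) * u
  spec <- switch(slot$partner,
                 N_plus = list(elem = "N", charge = 1L, order = 1L),
                 O_hydroxyl = list(elem = "O", charge = 0L, order = 1L),
                 O_carbonyl = list(elem = "O", charge = 0L, order = 2L),
                 O_minus = list(elem = "O", charge = -1L, order = 1L),
                 Cl = list(elem = "CL", charge = 0L, order = 1L),
                 C_alkyl = list(elem = "C", charge = 0L, order = 1L),
                 stop("unknown partner kind: ", slot$partner))
  idx <- atom_offset + 1L
  list(
    atoms = mk(spec$elem, pos, spec$charge),
    bonds = data.frame(atom_1 = idx, atom_2 = 1L, order = spec$order,
                       aromatic = FALSE),
    expected = data.frame(residue_number = slot$residue,
                          receptor_atom = slot$probe,
                          ligand_element = spec$elem, type = slot$type,
                          stringsAsFactors = FALSE)
  )
}

#' Generate a toy receptor-ligand complex with known interactions
#'
#' Builds the fixed sparse-shell pocket (twelve probe residues on
#' icosahedral directions, 8 A from the ligand scaffold) and a ligand whose
#' atoms sit at the requested distances from their probes. By construction
#' [compute_aif()] on the output recovers exactly the planted records: the
#' layout keeps every unplanned receptor-ligand pair outside the neighbour
#' cutoff, which the generator re-verifies, raising an error that names any
#' conflicting pair.
#'
#' @param spec an [complex_spec()].
#' @param rules rule table used to validate the construction.
#' @return list of class `aifp_toy_complex`: `receptor` (`aifp_receptor`,
#'   roles assigned), `pose` (`aifp_pose`, roles assigned), `truth`
#'   (expected AIF records), `distances`, `spec`.
#' @export
generate_toy_complex <- function(spec = complex_spec(),
                                 rules = geometry_rules()) {
  stopifnot(inherits(spec, "aifp_complex_spec"))
  slot_pos <- match(spec$planted, names(.PLANT_REGISTRY))
  slots <- .PLANT_REGISTRY[slot_pos]
  dists <- with_seed(spec$seed, {
    vapply(seq_along(slots), function(i) {
      if (!is.na(spec$distances[i])) spec$distances[i]
      else runif(1, slots[[i]]$window[1], slots[[i]]$window[2])
    }, numeric(1))
  })
  receptor <- .build_toy_receptor()
  lig_atom_rows <- list(data.frame(element = "C", x = 0, y = 0, z = 0,
                                   formal_charge = 0L,
                                   stringsAsFactors = FALSE))  # scaffold
  bonds <- list()
  expected <- list()
  exp_dist <- list()
  for (i in seq_along(slots)) {
    u <- .ICO_DIRECTIONS[slot_pos[i], ]
    offset <- sum(vapply(lig_atom_rows, nrow, integer(1)))
    part <- .build_partner(slots[[i]], u, dists[i], offset)
    lig_atom_rows[[length(lig_atom_rows) + 1L]] <- part$atoms
    bonds[[length(bonds) + 1L]] <- part$bonds
    expected[[i]] <- part$expected
    exp_dist[[i]] <- rep(dists[i], nrow(part$expected))
  }
  lig_df <- do.call(rbind, lig_atom_rows)
  pose <- new_pose(
    spec$ligand_id, spec$pose_number,
    new_atom_table(
      atom_name = paste0(lig_df$element, seq_len(nrow(lig_df))),
      element = lig_df$element, residue_name = spec$ligand_id,
      residue_number = spec$pose_number, chain_id = "L",
      xyz = as.matrix(lig_df[, c("x", "y", "z")]),
      formal_charge = lig_df$formal_charge
    ),
    do.call(rbind, bonds) %||% data.frame(atom_1 = integer(0),
                                          atom_2 = integer(0),
                                          order = integer(0),
                                          aromatic = logical(0))
  )
  pose <- assign_atom_roles(pose)
  truth <- do.call(rbind, expected) %||%
    data.frame(residue_number = integer(0), receptor_atom = character(0),
               ligand_element = character(0), type = character(0))
  if (nrow(truth)) {
    truth$distance <- unlist(exp_dist)
    rownames(truth) <- NULL
  }
  # construction guarantee: no unplanned pair within the cutoff
  pairs <- enumerate_pairs(receptor, pose, rules)
  if (nrow(pairs)) {
    pk <- paste(receptor$atoms$residue_number[pairs$rec_idx],
                receptor$atoms$atom_name[pairs$rec_idx],
                pose$atoms$element[pairs$lig_idx])
    tk <- paste(truth$residue_number, truth$receptor_atom,
                truth$ligand_element)
    stray <- setdiff(unique(pk), tk)
    if (length(stray)) {
      stop("incompatible geometry: unplanned contact pair(s) ",
           paste(stray, collapse = "; "))
    }
  }
  structure(list(receptor = receptor, pose = pose, truth = truth,
                 spec = spec, distances = dists),
            class = "aifp_toy_complex")
}

#' Write a toy docking study to disk in standard formats
#'
#' Emits a shared receptor PDB, a multi-record SDF of ligand poses and a
#' label CSV, so the real file readers can be exercised end to end. Each
#' ligand gets `poses_per_ligand` poses; a pose carries the anchor motif
#' with probability `motif_fraction`, and class-signal contacts are planted
#' according to its ligand's class (agonists: serine hydrogen bond, often a
#' polar glutamine contact; antagonists: tryptophan aromatic stack, often a
#' valine hydrophobic contact), so the downstream matrix carries real
#' signal.
#'
#' @param dir output directory (created if needed).
#' @param n_ligands,poses_per_ligand study size.
#' @param agonist_fraction probability a ligand is an agonist.
#' @param motif_fraction probability a pose carries both anchors.
#' @param seed integer seed.
#' @return list with `receptor_path`, `poses_path`, `labels_path`, `truth`
#'   (per-pose motif and class table).
#' @export
generate_toy_dataset <- function(dir, n_ligands = 12, poses_per_ligand = 3,
                                 agonist_fraction = 0.75,
                                 motif_fraction = 0.6, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    classes <- ifelse(runif(n_ligands) < agonist_fraction,
                      "agonist", "antagonist")
    lig_ids <- sprintf("toy %03d", seq_len(n_ligands))
    receptor <- NULL
    poses <- list()
    truth <- list()
    for (i in seq_len(n_ligands)) {
      for (p in seq_len(poses_per_ligand)) {
        motif <- runif(1) < motif_fraction
        extra <- if (classes[i] == "agonist") {
          c("hbond_203", if (runif(1) < 0.5) "polar")
        } else {
          c("aromatic_286", if (runif(1) < 0.5) "hydrophobic")
        }
        decoys <- sample(c("vdw", "proximal", "halogen_bond", "carbonyl"),
                         sample(0:2, 1))
        cs <- complex_spec(planted = unique(c(extra, decoys)), motif = motif,
                           ligand_id = lig_ids[i], pose_number = p,
                           seed = sample.int(1e6, 1))
        tc <- generate_toy_complex(cs)
        if (is.null(receptor)) receptor <- tc$receptor
        poses[[length(poses) + 1L]] <- tc$pose
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sample_id(tc$pose), ligand_id = lig_ids[i],
          class = classes[i], motif = motif, stringsAsFactors = FALSE)
      }
    }
    receptor_path <- file.path(dir, "receptor.pdb")
    poses_path <- file.path(dir, "poses.sdf")
    labels_path <- file.path(dir, "labels.csv")
    write_receptor_pdb(receptor, receptor_path)
    write_poses_sdf(poses, poses_path)
    write.csv(data.frame(ligand_id = lig_ids, label = classes),
              labels_path, row.names = FALSE)
    list(receptor_path = receptor_path, poses_path = poses_path,
         labels_path = labels_path, truth = do.call(rbind, truth))
  })
}
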