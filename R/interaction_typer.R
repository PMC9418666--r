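#' The closed set of interaction subtypes
#'
#' Fifteen interatomic interaction subtypes, ordered by classification
#' precedence (most specific first): a pair of atoms receives the first type
#' whose rule fires. The triple clash / vdw_clash / proximal is flagged as
#' excluded from the downstream binary matrix: those contacts are typed but
#' carry essentially no pharmacological information.
#'
#' @return character vector of the 15 type names, attribute
#'   `excluded_from_matrix` naming the excluded triple.
#' @export
interaction_types <- function() {
  structure(
    c("clash", "covalent", "vdw_clash", "ionic", "hydrogen_bond",
      "halogen_bond", "weak_hydrogen_bond", "metal_complex", "aromatic",
      "carbonyl", "polar", "weak_polar", "hydrophobic", "vdw", "proximal"),
    excluded_from_matrix = c("clash", "vdw_clash", "proximal")
  )
}

excluded_interaction_types <- function() {
  attr(interaction_types(), "excluded_from_matrix")
}

#' Geometric rule table for contact typing
#'
#' Distance (Angstrom) and angle (degrees) thresholds for every interaction
#' subtype, all overridable. The defaults follow the conventions of published
#' structural interaction fingerprint tools: hydrogen bond donor-acceptor
#' within 3.5 A with a D-H...A angle of at least 120 deg (heavy-atom
#' surrogate: neighbour-D-A of at least 90 deg when hydrogens are absent),
#' ionic within 4.0 A between opposite formal charges, aromatic
#' ring-centroid distance within 5.0 A, hydrophobic carbon-carbon within
#' 4.5 A, and so on. Clash/covalent/vdw thresholds derive
#' from element van der Waals and covalent radii.
#'
#' @param ... named overrides of any listed threshold.
#' @return object of class `aifp_rules`.
#' @examples
#' rules <- geometry_rules(hydrogen_bond_max = 3.2)
#' @export
geometry_rules <- function(...) {
  rules <- list(
    neighbor_cutoff = 5.0,
    clash_vdw_factor = 0.5,       # clash: d < factor * (r_vdw sum)
    covalent_tolerance = 0.2,     # covalent: d < r_cov sum + tol
    vdw_clash_tolerance = 0.3,    # vdw_clash: d < r_vdw sum - tol
    vdw_tolerance = 0.5,          # vdw: d <= r_vdw sum + tol
    ionic_max = 4.0,
    hydrogen_bond_max = 3.5,
    hydrogen_bond_min_angle = 120,          # D-H...A, explicit H
    hydrogen_bond_min_surrogate_angle = 90, # neighbour-D-A, no H
    weak_hydrogen_bond_max = 3.8,
    halogen_bond_max = 4.0,
    halogen_bond_min_angle = 140,           # C-X...A
    metal_complex_max = 2.8,
    aromatic_centroid_max = 5.0,
    carbonyl_max = 3.6,
    polar_max = 3.5,
    weak_polar_max = 4.0,
    hydrophobic_max = 4.5,
    proximal_max = 5.0
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(rules))
  if (length(bad)) stop("unknown rule(s): ", paste(bad, collapse = ", "))
  rules[names(dots)] <- dots
  dist_fields <- grep("_max$", names(rules), value = TRUE)
  if (any(unlist(rules[dist_fields]) <= 0) || rules$neighbor_cutoff <= 0) {
    stop("all rule distances must be positive")
  }
  # the enumeration radius also caps every per-type distance: lowering
  # neighbor_cutoff below a type's maximum simply truncates that rule
  structure(rules, class = "aifp_rules")
}

#' Load / save a rule table as YAML
#' @param path YAML file of threshold overrides.
#' @return an `aifp_rules` object.
#' @export
read_geometry_rules <- function(path) {
  do.call(geometry_rules, yaml::read_yaml(path))
}

#' @rdname read_geometry_rules
#' @param rules an `aifp_rules` object.
#' @export
write_geometry_rules <- function(rules, path) {
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

# ---- typing context ---------------------------------------------------------

# Per-atom lookup structure the classifier needs: role flags, radii, a bonded
# heavy-atom neighbour (angle surrogate), explicit-H positions, ring ids.
typing_context <- function(x) {
  atoms <- x$atoms
  n <- nrow(atoms)
  has <- function(role) vapply(atoms$roles, function(r) role %in% r, logical(1))
  ctx <- list(
    xyz = atom_xyz(atoms),
    element = atoms$element,
    charge = atoms$formal_charge,
    donor = has("donor"), acceptor = has("acceptor"),
    cation = has("cation"), anion = has("anion"),
    aromatic = has("aromatic"), hydrophobe = has("hydrophobe"),
    halogen = has("halogen"),
    carbonyl_c = has("carbonyl_carbon"), carbonyl_o = has("carbonyl_oxygen"),
    metal = atoms$element %in% .METALS,
    vdw = element_vdw(atoms$element),
    cov = element_cov(atoms$element),
    ring_id = rep(NA_integer_, n),
    nbr = rep(NA_integer_, n),
    h_idx = rep(list(integer(0)), n)
  )
  for (k in seq_along(x$rings)) ctx$ring_id[x$rings[[k]]] <- k
  ctx$ring_centroid <- if (length(x$rings)) {
    t(vapply(x$rings, function(m) colMeans(ctx$xyz[m, , drop = FALSE]),
             numeric(3)))
  } else matrix(numeric(0), 0, 3)
  if (inherits(x, "aifp_pose")) {
    if (nrow(x$bonds)) {
      for (k in seq_len(nrow(x$bonds))) {
        i <- x$bonds$atom_1[k]; j <- x$bonds$atom_2[k]
        if (ctx$element[j] == "H") ctx$h_idx[[i]] <- c(ctx$h_idx[[i]], j)
        else if (is.na(ctx$nbr[i])) ctx$nbr[i] <- j
        if (ctx$element[i] == "H") ctx$h_idx[[j]] <- c(ctx$h_idx[[j]], i)
        else if (is.na(ctx$nbr[j])) ctx$nbr[j] <- i
      }
    }
  } else {
    # receptor: template parent within the residue; nearest heavy atom fallback
    key <- paste(atoms$chain_id, atoms$residue_number, sep = "|")
    for (idx in split(seq_len(n), key)) {
      nm <- atoms$atom_name[idx]
      for (i in seq_along(idx)) {
        parent <- unname(.ATOM_PARENT[nm[i]])
        hit <- if (!is.na(parent)) idx[match(parent, nm)] else NA_integer_
        if (is.na(hit) && length(idx) > 1) {
          d2 <- rowSums((ctx$xyz[idx, , drop = FALSE] -
                           matrix(ctx$xyz[idx[i], ], length(idx), 3,
                                  byrow = TRUE))^2)
          d2[i] <- Inf
          d2[atoms$element[idx] == "H"] <- Inf
          hit <- if (all(!is.finite(d2))) NA_integer_ else idx[which.min(d2)]
        }
        ctx$nbr[idx[i]] <- hit
        hs <- idx[atoms$element[idx] == "H"]
        if (length(hs)) {
          d2h <- rowSums((ctx$xyz[hs, , drop = FALSE] -
                            matrix(ctx$xyz[idx[i], ], length(hs), 3,
                                   byrow = TRUE))^2)
          ctx$h_idx[[idx[i]]] <- hs[d2h < 1.3^2]
        }
      }
    }
  }
  ctx
}

# ---- pair enumeration -------------------------------------------------------

#' Enumerate receptor-ligand atom pairs within the neighbour cutoff
#'
#' Uses a uniform spatial grid (cell size = cutoff) over the receptor atoms;
#' exact Euclidean distances are reported. Hydrogens are not enumerated as
#' pair members (they enter only through angle terms).
#'
#' @param receptor `aifp_receptor` with roles assigned.
#' @param pose `aifp_pose` with roles assigned.
#' @param rules an [geometry_rules()] table.
#' @return data.frame `rec_idx`, `lig_idx`, `distance`.
#' @export
enumerate_pairs <- function(receptor, pose, rules = geometry_rules()) {
  rxyz <- atom_xyz(receptor$atoms)
  lxyz <- atom_xyz(pose$atoms)
  rheavy <- which(receptor$atoms$element != "H")
  lheavy <- which(pose$atoms$element != "H")
  cutoff <- rules$neighbor_cutoff
  if (length(rheavy) == 0 || length(lheavy) == 0) {
    return(data.frame(rec_idx = integer(0), lig_idx = integer(0),
                      distance = numeric(0)))
  }
  cell <- function(m) floor(m / cutoff)
  rcell <- cell(rxyz[rheavy, , drop = FALSE])
  rkey <- paste(rcell[, 1], rcell[, 2], rcell[, 3])
  grid <- split(rheavy, rkey)
  out_r <- integer(0); out_l <- integer(0); out_d <- numeric(0)
  lcell <- cell(lxyz[lheavy, , drop = FALSE])
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (li in seq_along(lheavy)) {
    keys <- paste(lcell[li, 1] + offs[, 1], lcell[li, 2] + offs[, 2],
                  lcell[li, 3] + offs[, 3])
    cand <- unlist(grid[keys], use.names = FALSE)
    if (length(cand) == 0) next
    d <- sqrt(rowSums((rxyz[cand, , drop = FALSE] -
                         matrix(lxyz[lheavy[li], ], length(cand), 3,
                                byrow = TRUE))^2))
    keep <- d <= cutoff
    out_r <- c(out_r, cand[keep])
    out_l <- c(out_l, rep(lheavy[li], sum(keep)))
    out_d <- c(out_d, d[keep])
  }
  data.frame(rec_idx = out_r, lig_idx = out_l, distance = out_d)
}

# ---- classification ---------------------------------------------------------

# Complementary donor/acceptor orientation with angle check.
.hbond_ok <- function(di, ai, dctx, actx, max_angle_needed, rules) {
  # di: donor atom index in dctx; ai: acceptor atom index in actx
  dpos <- dctx$xyz[di, ]
  apos <- actx$xyz[ai, ]
  hs <- dctx$h_idx[[di]]
  if (length(hs)) {
    for (h in hs) {
      ang <- angle_deg(dpos, dctx$xyz[h, ], apos)  # D-H...A, vertex at H
      if (!is.na(ang) && ang >= rules$hydrogen_bond_min_angle) return(TRUE)
    }
    return(FALSE)
  }
  nb <- dctx$nbr[di]
  if (is.na(nb)) return(NA)  # geometry unavailable: distance-only fallback
  ang <- angle_deg(dctx$xyz[nb, ], dpos, apos)     # neighbour-D-A, vertex at D
  !is.na(ang) && ang >= rules$hydrogen_bond_min_surrogate_angle
}

# Classify one receptor-ligand atom pair. `i` indexes rctx, `j` indexes lctx.
# Returns the type name or NA. `state` (environment) collects fallback notes.
.classify_one <- function(i, j, d, rctx, lctx, rules, state = NULL) {
  vdw_sum <- rctx$vdw[i] + lctx$vdw[j]
  if (d < rules$clash_vdw_factor * vdw_sum) return("clash")
  if (d < rctx$cov[i] + lctx$cov[j] + rules$covalent_tolerance) return("covalent")
  if (d < vdw_sum - rules$vdw_clash_tolerance) return("vdw_clash")
  if (d <= rules$ionic_max &&
      ((rctx$cation[i] && lctx$anion[j]) || (rctx$anion[i] && lctx$cation[j]))) {
    return("ionic")
  }
  if (d <= rules$hydrogen_bond_max) {
    ok <- FALSE; fell_back <- FALSE
    if (rctx$donor[i] && lctx$acceptor[j]) {
      res <- .hbond_ok(i, j, rctx, lctx, rules$hydrogen_bond_min_angle, rules)
      if (is.na(res)) { fell_back <- TRUE; res <- TRUE }
      ok <- ok || res
    }
    if (!ok && lctx$donor[j] && rctx$acceptor[i]) {
      res <- .hbond_ok(j, i, lctx, rctx, rules$hydrogen_bond_min_angle, rules)
      if (is.na(res)) { fell_back <- TRUE; res <- TRUE }
      ok <- ok || res
    }
    if (ok) {
      if (fell_back && !is.null(state)) state$angle_fallback <- TRUE
      return("hydrogen_bond")
    }
  }
  if (d <= rules$halogen_bond_max &&
      ((lctx$halogen[j] && rctx$acceptor[i]) ||
       (rctx$halogen[i] && lctx$acceptor[j]))) {
    if (lctx$halogen[j]) { xctx <- lctx; xi <- j; api <- rctx$xyz[i, ] }
    else { xctx <- rctx; xi <- i; api <- lctx$xyz[j, ] }
    nb <- xctx$nbr[xi]
    ang_ok <- if (is.na(nb)) {
      if (!is.null(state)) state$angle_fallback <- TRUE
      TRUE
    } else {
      ang <- angle_deg(xctx$xyz[nb, ], xctx$xyz[xi, ], api)  # C-X...A at X
      !is.na(ang) && ang >= rules$halogen_bond_min_angle
    }
    if (ang_ok) return("halogen_bond")
  }
  if (d <= rules$weak_hydrogen_bond_max) {
    weak_d_rec <- rctx$element[i] == "C" && length(rctx$h_idx[[i]]) > 0
    weak_d_lig <- lctx$element[j] == "C" && length(lctx$h_idx[[j]]) > 0
    if ((weak_d_rec && lctx$acceptor[j]) || (weak_d_lig && rctx$acceptor[i])) {
      return("weak_hydrogen_bond")
    }
  }
  if (d <= rules$metal_complex_max &&
      ((rctx$metal[i] && lctx$element[j] %in% c("N", "O", "S")) ||
       (lctx$metal[j] && rctx$element[i] %in% c("N", "O", "S")))) {
    return("metal_complex")
  }
  ri <- rctx$ring_id[i]; rj <- lctx$ring_id[j]
  if (rctx$aromatic[i] && lctx$aromatic[j] && !is.na(ri) && !is.na(rj)) {
    cd <- vec_norm(rctx$ring_centroid[ri, ] - lctx$ring_centroid[rj, ])
    if (cd <= rules$aromatic_centroid_max) return("aromatic")
  }
  if (d <= rules$carbonyl_max &&
      ((rctx$carbonyl_c[i] && lctx$acceptor[j] && lctx$element[j] == "O") ||
       (lctx$carbonyl_c[j] && rctx$acceptor[i] && rctx$element[i] == "O"))) {
    return("carbonyl")
  }
  polar_i <- rctx$donor[i] || rctx$acceptor[i]
  polar_j <- lctx$donor[j] || lctx$acceptor[j]
  if (polar_i && polar_j) {
    if (d <= rules$polar_max) return("polar")
    if (d <= rules$weak_polar_max) return("weak_polar")
  }
  if (d <= rules$hydrophobic_max && rctx$hydrophobe[i] && lctx$hydrophobe[j] &&
      rctx$element[i] == "C" && lctx$element[j] == "C") {
    return("hydrophobic")
  }
  if (d <= vdw_sum + rules$vdw_tolerance) return("vdw")
  if (d <= rules$proximal_max) return("proximal")
  NA_character_
}

#' Classify a single receptor-ligand atom pair
#'
#' Applies the rule table in fixed precedence order (clash > covalent >
#' vdw_clash > ionic > hydrogen_bond > halogen_bond > weak_hydrogen_bond >
#' metal_complex > aromatic > carbonyl > polar > weak_polar > hydrophobic >
#' vdw > proximal) and returns the first type that fires, so every pair maps
#' to at most one subtype. When an angle rule needs geometry that the
#' structures cannot provide (no hydrogens and no bonded neighbour), that rule
#' degrades to its distance criterion.
#'
#' @param receptor,pose role-assigned structures.
#' @param rec_index,lig_index atom indices into the respective atom tables.
#' @param rules rule table.
#' @return type name (character) or `NA` if no rule fires.
#' @export
classify_pair <- function(receptor, pose, rec_index, lig_index,
                          rules = geometry_rules()) {
  rctx <- typing_context(receptor)
  lctx <- typing_context(pose)
  d <- vec_norm(rctx$xyz[rec_index, ] - lctx$xyz[lig_index, ])
  if (d > rules$neighbor_cutoff) return(NA_character_)
  .classify_one(rec_index, lig_index, d, rctx, lctx, rules)
}

#' Compute the atomic interaction fingerprint (AIF) of one pose
#'
#' Enumerates all receptor-ligand atom pairs within the neighbour cutoff,
#' classifies each, and deduplicates records on (residue number, receptor
#' atom name, ligand element, type), keeping the shortest distance per key.
#' Ligand atom identity in a record is the element symbol, matching the
#' feature-key convention used downstream.
#'
#' @inheritParams enumerate_pairs
#' @return object of class `aifp_aif`: `sample_id` plus a `records`
#'   data.frame (`residue_number`, `receptor_atom`, `ligand_element`,
#'   `ligand_atom_index`, `type`, `distance`).
#' @export
compute_aif <- function(receptor, pose, rules = geometry_rules()) {
  pairs <- enumerate_pairs(receptor, pose, rules)
  rctx <- typing_context(receptor)
  lctx <- typing_context(pose)
  state <- new.env(parent = emptyenv())
  state$angle_fallback <- FALSE
  types <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    types[k] <- .classify_one(pairs$rec_idx[k], pairs$lig_idx[k],
                              pairs$distance[k], rctx, lctx, rules, state)
  }
  if (state$angle_fallback) {
    warning("angle geometry unavailable for some pairs; ",
            "distance-only fallback used")
  }
  keep <- !is.na(types)
  rec <- data.frame(
    residue_number = receptor$atoms$residue_number[pairs$rec_idx[keep]],
    receptor_atom = receptor$atoms$atom_name[pairs$rec_idx[keep]],
    ligand_element = pose$atoms$element[pairs$lig_idx[keep]],
    ligand_atom_index = pairs$lig_idx[keep],
    type = types[keep],
    distance = pairs$distance[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(rec)) {
    key <- paste(rec$residue_number, rec$receptor_atom, rec$ligand_element,
                 rec$type, sep = "|")
    rec <- rec[order(key, rec$distance), , drop = FALSE]
    rec <- rec[!duplicated(paste(rec$residue_number, rec$receptor_atom,
                                 rec$ligand_element, rec$type, sep = "|")), ,
               drop = FALSE]
    rownames(rec) <- NULL
  }
  new_aif(sample_id(pose), rec)
}

new_aif <- function(sample_id, records) {
  structure(list(sample_id = sample_id, records = records),
            class = "aifp_aif")
}

#' @export
print.aifp_aif <- function(x, ...) {
  cat(sprintf("<aifp_aif> %s: %d records\n", x$sample_id, nrow(x$records)))
  if (nrow(x$records)) print(head(x$records, 10))
  invisible(x)
}

#' Export a collection of AIFs as a tidy table
#'
#' @param aifs list of `aifp_aif`.
#' @return data.frame with one row per record
#'   (`sample_id`, `residue_number`, `receptor_atom`, `ligand_element`,
#'   `type`, `distance`).
#' @export
aifs_to_table <- function(aifs) {
  do.call(rbind, lapply(aifs, function(a) {
    if (nrow(a$records) == 0) return(NULL)
    cbind(data.frame(sample_id = a$sample_id, stringsAsFactors = FALSE),
          a$records[, c("residue_number", "receptor_atom", "ligand_element",
                        "type", "distance")])
  })) %||% data.frame(sample_id = character(0), residue_number = integer(0),
                      receptor_atom = character(0), ligand_element = character(0),
                      type = character(0), distance = numeric(0))
}
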