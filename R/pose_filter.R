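#' Anchor-interaction filter criteria
#'
#' The binding-pocket anchor filter keeps only poses whose fingerprints show
#' the beta-hydroxy-amine anchor contacts: by default (1) an ionic / polar /
#' hydrogen-bond contact between a carboxylate oxygen of residue 113 (Asp,
#' OD1 or OD2) and a ligand nitrogen, and (2) a hydrogen-bond / polar contact
#' between the side-chain oxygen of residue 312 (Asn, OD1) and a ligand
#' nitrogen or oxygen. ND2 matches for the second anchor are not accepted
#' unless requested via `anchor2_atoms`.
#'
#' @param anchor1_residue,anchor2_residue receptor residue numbers.
#' @param anchor1_atoms,anchor2_atoms admissible receptor atom names.
#' @param anchor1_elements,anchor2_elements admissible ligand elements.
#' @param anchor1_types,anchor2_types admissible interaction types.
#' @return object of class `aifp_filter_criteria` (a list of two anchors).
#' @export
filter_criteria <- function(anchor1_residue = 113,
                            anchor1_atoms = c("OD1", "OD2"),
                            anchor1_elements = "N",
                            anchor1_types = c("ionic", "polar", "hydrogen_bond"),
                            anchor2_residue = 312,
                            anchor2_atoms = "OD1",
                            anchor2_elements = c("N", "O"),
                            anchor2_types = c("hydrogen_bond", "polar")) {
  anchors <- list(
    anchor_1 = list(residue = as.integer(anchor1_residue),
                    atoms = anchor1_atoms, elements = anchor1_elements,
                    types = anchor1_types),
    anchor_2 = list(residue = as.integer(anchor2_residue),
                    atoms = anchor2_atoms, elements = anchor2_elements,
                    types = anchor2_types)
  )
  for (a in anchors) {
    if (!length(a$atoms) || !length(a$elements) || !length(a$types)) {
      stop("each anchor needs non-empty atoms, elements and types")
    }
    bad <- setdiff(a$types, interaction_types())
    if (length(bad)) stop("unknown interaction type(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(anchors, class = "aifp_filter_criteria")
}

.anchor_hit <- function(records, anchor) {
  any(records$residue_number == anchor$residue &
        records$receptor_atom %in% anchor$atoms &
        records$ligand_element %in% anchor$elements &
        records$type %in% anchor$types)
}

#' Does a fingerprint pass the anchor filter?
#'
#' TRUE iff both anchor conditions have at least one matching record. The
#' returned value carries a `reason` attribute naming the first missing
#' anchor (or `"ok"`).
#'
#' @param aif an `aifp_aif`.
#' @param criteria a [filter_criteria()] object.
#' @return logical scalar with attribute `reason`.
#' @export
passes_filter <- function(aif, criteria = filter_criteria()) {
  for (nm in names(criteria)) {
    if (!.anchor_hit(aif$records, criteria[[nm]])) {
      return(structure(FALSE, reason = paste(nm, "missing")))
    }
  }
  structure(TRUE, reason = "ok")
}

#' Filter a pose set on the anchor criteria
#'
#' @param aifs list of `aifp_aif`.
#' @param criteria a [filter_criteria()] object.
#' @return list with `retained` (sub-list of `aifs`) and `report`: counts,
#'   overall removed fraction, failure reasons, and per-ligand pose survival.
#' @export
filter_dataset <- function(aifs, criteria = filter_criteria()) {
  if (length(aifs) == 0) stop("empty AIF collection")
  verdicts <- lapply(aifs, passes_filter, criteria = criteria)
  pass <- vapply(verdicts, as.logical, logical(1))
  reasons <- vapply(verdicts, attr, character(1), "reason")
  ids <- vapply(aifs, function(a) a$sample_id, character(1))
  lig <- split_sample_id(ids)$ligand_id
  per_ligand <- aggregate(pass, by = list(ligand_id = lig),
                          FUN = function(v) c(sum(v), length(v)))
  per_ligand <- data.frame(ligand_id = per_ligand$ligand_id,
                           n_retained = per_ligand$x[, 1],
                           n_poses = per_ligand$x[, 2],
                           stringsAsFactors = FALSE)
  report <- list(
    n_input = length(aifs),
    n_retained = sum(pass),
    removed_fraction = 1 - mean(pass),
    reasons = table(reasons[!pass]),
    per_ligand = per_ligand
  )
  if (report$n_retained == 0) {
    warning("anchor filter removed every pose; check criteria residues/atoms")
  }
  list(retained = aifs[pass], report = report)
}

#' Write a filter report as JSON
#' @param report the `report` element from [filter_dataset()].
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  out <- report
  out$reasons <- as.list(report$reasons)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
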