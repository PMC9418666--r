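#' Canonical feature keys
#'
#' A matrix column is identified by the string
#' `"<residueNumber>/<receptorAtomName>\u2014<ligandElement> <type>"`
#' (em-dash separator), e.g. `"301/O\u2014N polar"`. [parse_feature_key()]
#' recovers the four components.
#'
#' @param residue_number,receptor_atom,ligand_element,type key components.
#' @return character vector of keys.
#' @export
feature_key <- function(residue_number, receptor_atom, ligand_element, type) {
  sprintf("%d/%s\u2014%s %s", as.integer(residue_number), receptor_atom,
          ligand_element, type)
}

#' @rdname feature_key
#' @param key character vector of feature keys.
#' @export
parse_feature_key <- function(key) {
  m <- regexec("^([0-9]+)/([^\u2014]+)\u2014([A-Za-z]+) ([a-z_]+)$", key)
  parts <- regmatches(key, m)
  bad <- lengths(parts) != 5
  if (any(bad)) stop("unparseable feature key(s): ",
                     paste(key[bad], collapse = ", "))
  data.frame(
    residue_number = as.integer(vapply(parts, `[`, character(1), 2)),
    receptor_atom = vapply(parts, `[`, character(1), 3),
    ligand_element = vapply(parts, `[`, character(1), 4),
    type = vapply(parts, `[`, character(1), 5),
    stringsAsFactors = FALSE
  )
}

new_interaction_matrix <- function(values, label, ligand_id) {
  stopifnot(is.matrix(values), nrow(values) == length(label),
            nrow(values) == length(ligand_id))
  structure(
    list(values = values,
         label = factor(label, levels = c("agonist", "antagonist", "binder")),
         ligand_id = ligand_id),
    class = "aifp_matrix"
  )
}

#' @export
print.aifp_matrix <- function(x, ...) {
  cat(sprintf("<aifp_matrix> %d poses x %d features; labels: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", levels(x$label), table(x$label)),
                    collapse = " ")))
  invisible(x)
}

#' @export
dim.aifp_matrix <- function(x) dim(x$values)

#' Build the binary pose-by-feature interaction matrix
#'
#' The union of all observed feature keys defines the columns; a cell is 1
#' when that pose's fingerprint contains the interaction and 0 otherwise
#' (absent interactions are zeros, never missing). Contacts typed as clash,
#' vdw_clash or proximal are dropped before encoding. Each pose row inherits
#' its ligand's pharmacology label (agonist / antagonist / binder).
#'
#' @param aifs list of `aifp_aif`.
#' @param labels data.frame `ligand_id`, `label` covering every ligand.
#' @return an `aifp_matrix` (rownames = sample ids, colnames = feature keys).
#' @export
build_matrix <- function(aifs, labels) {
  ids <- vapply(aifs, function(a) a$sample_id, character(1))
  lig <- split_sample_id(ids)$ligand_id
  missing <- setdiff(unique(lig), labels$ligand_id)
  if (length(missing)) {
    stop("ligand id(s) missing from label table: ",
         paste(missing, collapse = ", "))
  }
  excl <- excluded_interaction_types()
  tab <- aifs_to_table(aifs)
  tab <- tab[!(tab$type %in% excl), , drop = FALSE]
  keys <- sort(unique(feature_key(tab$residue_number, tab$receptor_atom,
                                  tab$ligand_element, tab$type)))
  values <- matrix(0L, length(aifs), length(keys),
                   dimnames = list(ids, keys))
  if (nrow(tab)) {
    rk <- feature_key(tab$residue_number, tab$receptor_atom,
                      tab$ligand_element, tab$type)
    values[cbind(match(tab$sample_id, ids), match(rk, keys))] <- 1L
  }
  label <- labels$label[match(lig, labels$ligand_id)]
  new_interaction_matrix(values, label, lig)
}

#' Drop rare interaction features
#'
#' Keeps exactly the columns whose presence frequency over all poses is at
#' least `threshold` (default 0.10: a feature must occur in 10 percent of
#' docking poses to survive). Column order is preserved; the operation is
#' idempotent at fixed threshold.
#'
#' @param matrix an `aifp_matrix`.
#' @param threshold frequency in (0, 1].
#' @return filtered `aifp_matrix`.
#' @export
frequency_filter <- function(matrix, threshold = 0.10) {
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]")
  }
  keep <- colMeans(matrix$values) >= threshold
  matrix$values <- matrix$values[, keep, drop = FALSE]
  matrix
}

#' Subset an interaction matrix by row
#' @param matrix an `aifp_matrix`.
#' @param rows logical or integer row selector.
#' @export
matrix_rows <- function(matrix, rows) {
  new_interaction_matrix(matrix$values[rows, , drop = FALSE],
                         as.character(matrix$label[rows]),
                         matrix$ligand_id[rows])
}

#' Stratified hold-out split
#'
#' Splits the labelled poses (binders are excluded from supervised splits)
#' into a cross-validation part and an untouched hold-out part, stratified by
#' class. By default grouping is at ligand level: all poses of a ligand land
#' on the same side, so no pose of a hold-out ligand is ever seen in
#' training. `grouping = "pose"` stratifies at pose level instead.
#'
#' @param matrix an `aifp_matrix`.
#' @param holdout_fraction fraction of ligands (or poses) held out,
#'   default 0.20.
#' @param seed integer seed; the same seed always yields the same split.
#' @param grouping `"ligand"` (default) or `"pose"`.
#' @return list `cv` and `holdout`, both `aifp_matrix`.
#' @export
split_holdout <- function(matrix, holdout_fraction = 0.20, seed = 1,
                          grouping = c("ligand", "pose")) {
  grouping <- match.arg(grouping)
  stopifnot_scalar_number(holdout_fraction, "holdout_fraction", 0, 1)
  labelled <- matrix$label %in% c("agonist", "antagonist")
  m <- matrix_rows(matrix, labelled)
  units <- if (grouping == "ligand") {
    u <- unique(data.frame(id = m$ligand_id, label = as.character(m$label)))
    u
  } else {
    data.frame(id = rownames(m$values), label = as.character(m$label))
  }
  counts <- table(units$label)
  if (any(counts < 2)) {
    stop("each class needs at least 2 ", grouping, "s to split; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = " "))
  }
  hold_ids <- with_seed(seed, {
    unlist(lapply(split(units$id, units$label), function(ids) {
      n_hold <- round(length(ids) * holdout_fraction)
      sample(ids, n_hold)
    }), use.names = FALSE)
  })
  key <- if (grouping == "ligand") m$ligand_id else rownames(m$values)
  in_hold <- key %in% hold_ids
  list(cv = matrix_rows(m, !in_hold), holdout = matrix_rows(m, in_hold))
}

#' Write / read an interaction matrix as CSV
#'
#' First column `sample_id`, last column `label`, feature columns in between.
#' `read_matrix_csv(write_matrix_csv(m, f))` reproduces `m`.
#'
#' @param matrix an `aifp_matrix`.
#' @param path CSV file.
#' @export
write_matrix_csv <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix$values),
                   matrix$values,
                   label = as.character(matrix$label),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "sample_id", names(df)[ncol(df)] == "label")
  values <- as.matrix(df[, -c(1, ncol(df)), drop = FALSE])
  storage.mode(values) <- "integer"
  rownames(values) <- df$sample_id
  new_interaction_matrix(values, df$label, split_sample_id(df$sample_id)$ligand_id)
}
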