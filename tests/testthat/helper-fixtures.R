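# Shared fixtures and independent oracles used across the suite.

# Build a labelled interaction matrix directly from a 0/1 matrix.
make_matrix <- function(values, label, ligand_id = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("lig %03d_01", seq_len(n))
  }
  if (is.null(colnames(values)) || any(!nzchar(colnames(values)))) {
    colnames(values) <- feature_key(seq_len(ncol(values)), "CA", "C",
                                    "hydrophobic")
  }
  if (is.null(ligand_id)) ligand_id <- sub("_[0-9]+$", "", rownames(values))
  aifp:::new_interaction_matrix(values, label, ligand_id)
}

# Closed-form phi coefficient of the 2x2 table
#   a = x1y1, b = x1y0, c = x0y1, d = x0y0.
phi_oracle <- function(a, b, c, d) {
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(NA_real_)
  (a * d - b * c) / sqrt(den)
}

# Literal transcription of the MCC formula, independent of mcc().
mcc_oracle <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# Literal transcription of the Shapley sum, independent of exact_shapley():
# iterates subsets as index vectors and accumulates the weighted marginals.
shapley_oracle <- function(value_function, m) {
  players <- seq_len(m)
  phi <- numeric(m)
  for (i in players) {
    others <- setdiff(players, i)
    subsets <- unlist(lapply(0:length(others), function(k)
      combn(others, k, simplify = FALSE)), recursive = FALSE)
    for (S in subsets) {
      w <- factorial(length(S)) * factorial(m - length(S) - 1) / factorial(m)
      phi[i] <- phi[i] + w * (value_function(sort(c(S, i))) -
                                value_function(S))
    }
  }
  phi
}

# Permute the ligand -> label assignment of a matrix (class shuffle that
# preserves the pose-per-ligand structure).
permute_ligand_labels <- function(matrix, seed) {
  ligs <- unique(matrix$ligand_id)
  lab_of <- vapply(ligs, function(l)
    as.character(matrix$label[match(l, matrix$ligand_id)]), character(1))
  shuffled <- aifp:::with_seed(seed, sample(lab_of))
  make_matrix(matrix$values, shuffled[match(matrix$ligand_id, ligs)],
              matrix$ligand_id)
}

# Small planted-signal study used by several tests: all poses correct, so
# the class signal is strong and runtimes stay low.
small_planted_study <- function(seed = 5, n_ligands = 120,
                                n_noise_features = 30) {
  generate_matrix(matrix_spec(
    n_ligands = n_ligands, poses_per_ligand = 4, correct_pose_fraction = 1,
    n_noise_features = n_noise_features, seed = seed))
}
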