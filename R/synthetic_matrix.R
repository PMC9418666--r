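#' Specification of a synthetic planted-signal fingerprint matrix
#'
#' Describes a pose-by-feature binary matrix that emulates the statistical
#' structure of a docked ligand set: about three quarters of ligands are
#' agonists, each ligand contributes up to ten poses of which only a
#' minority are "correct" (carry the ligand's true binding mode and hence
#' its class-discriminative interactions), a handful of signal features are
#' over-represented in correct poses of their associated class, and the
#' remaining features are class-independent noise.
#'
#' Defaults: 500 ligands x 10 poses, 75% agonists, 5 signal + 95 noise
#' features, correct-pose fraction 0.1 (one in ten docking solutions),
#' signal presence 0.9 in correct poses of the matching class and 0.05
#' elsewhere, noise base rates uniform on \[0.05, 0.40\].
#'
#' @param n_ligands number of ligands.
#' @param poses_per_ligand poses per ligand (at most 10).
#' @param agonist_fraction probability a ligand is an agonist.
#' @param n_signal_features,n_noise_features feature counts.
#' @param p_signal_in_class presence probability of a signal feature in a
#'   correct pose of its class.
#' @param p_signal_out_class presence probability elsewhere.
#' @param correct_pose_fraction fraction of each ligand's poses that carry
#'   its class signal.
#' @param noise_rate_range range of per-feature noise base rates.
#' @param seed integer seed (recorded in the output).
#' @return object of class `aifp_matrix_spec`.
#' @export
matrix_spec <- function(n_ligands = 500, poses_per_ligand = 10,
                        agonist_fraction = 0.75,
                        n_signal_features = 5, n_noise_features = 95,
                        p_signal_in_class = 0.9, p_signal_out_class = 0.05,
                        correct_pose_fraction = 0.1,
                        noise_rate_range = c(0.05, 0.40), seed = 1) {
  stopifnot_scalar_number(agonist_fraction, "agonist_fraction", 0, 1)
  stopifnot_scalar_number(p_signal_in_class, "p_signal_in_class", 0, 1)
  stopifnot_scalar_number(p_signal_out_class, "p_signal_out_class", 0, 1)
  stopifnot_scalar_number(correct_pose_fraction, "correct_pose_fraction", 0, 1)
  if (poses_per_ligand < 1 || poses_per_ligand > 10) {
    stop("poses_per_ligand must lie in 1..10")
  }
  structure(
    list(n_ligands = n_ligands, poses_per_ligand = as.integer(poses_per_ligand),
         agonist_fraction = agonist_fraction,
         n_signal_features = n_signal_features,
         n_noise_features = n_noise_features,
         p_signal_in_class = p_signal_in_class,
         p_signal_out_class = p_signal_out_class,
         correct_pose_fraction = correct_pose_fraction,
         noise_rate_range = noise_rate_range, seed = as.integer(seed)),
    class = "aifp_matrix_spec"
  )
}

# Plausible binding-pocket feature keys for planted signal: agonist-
# associated serine/lysine contacts, antagonist-associated aromatic /
# tyrosine contacts, cycled as often as needed.
.signal_key_pool <- function() {
  list(
    agonist = c(
      feature_key(203, "OG", "O", "hydrogen_bond"),
      feature_key(207, "OG", "O", "polar"),
      feature_key(305, "NZ", "C", "hydrophobic"),
      feature_key(204, "OG", "O", "hydrogen_bond"),
      feature_key(296, "NE2", "N", "polar")
    ),
    antagonist = c(
      feature_key(286, "CD2", "C", "aromatic"),
      feature_key(316, "OH", "N", "polar"),
      feature_key(316, "CZ", "C", "hydrophobic"),
      feature_key(113, "OD1", "N", "polar"),
      feature_key(312, "ND2", "N", "polar")
    )
  )
}

#' Generate a planted-signal interaction matrix
#'
#' Draws ligand classes, marks a `correct_pose_fraction` subset of each
#' ligand's poses as correct, and fills the binary matrix: a signal feature
#' associated with class c is present with `p_signal_in_class` in correct
#' poses of class-c ligands and with `p_signal_out_class` everywhere else;
#' noise features are present at a per-feature base rate independent of
#' class. Output is byte-identical under a fixed spec (including seed).
#'
#' @param spec an [matrix_spec()].
#' @return list of class `aifp_synth_matrix`: `matrix` (an `aifp_matrix`),
#'   `truth` (signal feature table, per-pose correctness, the spec).
#' @export
generate_matrix <- function(spec = matrix_spec()) {
  stopifnot(inherits(spec, "aifp_matrix_spec"))
  with_seed(spec$seed, {
    n_lig <- spec$n_ligands
    classes <- ifelse(runif(n_lig) < spec$agonist_fraction,
                      "agonist", "antagonist")
    if (length(unique(classes)) < 2) {
      stop("generated zero ligands of one class; ",
           "increase n_ligands or adjust agonist_fraction")
    }
    lig_ids <- sprintf("lig %03d", seq_len(n_lig))
    ppl <- spec$poses_per_ligand
    n_correct <- max(0L, round(spec$correct_pose_fraction * ppl))
    sample_ids <- as.vector(t(outer(lig_ids, seq_len(ppl), make_sample_id)))
    row_lig <- rep(lig_ids, each = ppl)
    row_class <- rep(classes, each = ppl)
    correct <- as.vector(vapply(seq_len(n_lig), function(i) {
      v <- logical(ppl)
      if (n_correct > 0) v[sample.int(ppl, n_correct)] <- TRUE
      v
    }, logical(ppl)))
    pool <- .signal_key_pool()
    n_sig <- spec$n_signal_features
    sig_class <- rep(c("agonist", "antagonist"), length.out = n_sig)
    sig_class <- sort(sig_class, decreasing = FALSE)  # agonists first
    counts <- table(factor(sig_class, levels = c("agonist", "antagonist")))
    sig_keys <- c(rep_len(pool$agonist, counts["agonist"]),
                  rep_len(pool$antagonist, counts["antagonist"]))
    noise_keys <- .noise_keys(spec$n_noise_features, avoid = sig_keys)
    n_rows <- length(sample_ids)
    values <- matrix(0L, n_rows, n_sig + spec$n_noise_features,
                     dimnames = list(sample_ids, c(sig_keys, noise_keys)))
    for (j in seq_len(n_sig)) {
      p <- ifelse(row_class == sig_class[j] & correct,
                  spec$p_signal_in_class, spec$p_signal_out_class)
      values[, j] <- rbinom(n_rows, 1L, p)
    }
    rates <- runif(spec$n_noise_features, spec$noise_rate_range[1],
                   spec$noise_rate_range[2])
    for (j in seq_len(spec$n_noise_features)) {
      values[, n_sig + j] <- rbinom(n_rows, 1L, rates[j])
    }
    mat <- new_interaction_matrix(values, row_class, row_lig)
    structure(
      list(matrix = mat,
           truth = list(
             signal = data.frame(feature_key = sig_keys, class = sig_class,
                                 stringsAsFactors = FALSE),
             correct_pose = stats::setNames(correct, sample_ids),
             noise_rates = stats::setNames(rates, noise_keys),
             ligand_class = stats::setNames(classes, lig_ids),
             spec = spec)),
      class = "aifp_synth_matrix"
    )
  })
}

# distinct plausible noise feature keys, disjoint from the signal keys
.noise_keys <- function(n, avoid = character(0)) {
  residues <- c(79, 82, 86, 93, 109, 110, 113, 114, 117, 118, 164, 191, 192,
                193, 194, 195, 199, 200, 203, 204, 207, 208, 286, 289, 290,
                293, 296, 305, 308, 309, 311, 312, 313, 316)
  atoms <- c("CA", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "O", "N",
             "OD1", "OD2", "OG", "OH", "NZ", "NE2", "ND2", "SD")
  elems <- c("C", "N", "O")
  types <- setdiff(interaction_types(), excluded_interaction_types())
  grid <- expand.grid(r = residues, a = atoms, e = elems, t = types,
                      stringsAsFactors = FALSE)
  keys <- feature_key(grid$r, grid$a, grid$e, grid$t)
  keys <- setdiff(keys, avoid)
  keys[sample.int(length(keys), n)]
}

#' Simulate fingerprint sets with or without the anchor motif
#'
#' Builds lightweight AIF objects for exercising the anchor filter at scale:
#' each fingerprint carries a few random pocket contacts, and a
#' `motif_fraction` share of them additionally carries both anchor records
#' (113/OD2-N ionic and 312/OD1-O hydrogen bond).
#'
#' @param n number of fingerprints.
#' @param motif_fraction probability a fingerprint carries both anchors.
#' @param seed integer seed.
#' @return list of `aifp_aif` with attribute `motif` (logical ground truth).
#' @export
simulate_anchor_aifs <- function(n, motif_fraction = 0.45, seed = 1) {
  with_seed(seed, {
    motif <- runif(n) < motif_fraction
    aifs <- vector("list", n)
    lig <- sprintf("lig %04d", ceiling(seq_len(n) / 10))
    pose <- ((seq_len(n) - 1L) %% 10L) + 1L
    for (i in seq_len(n)) {
      k <- sample(2:6, 1)
      rec <- data.frame(
        residue_number = sample(c(82, 193, 203, 207, 290, 316), k,
                                replace = TRUE),
        receptor_atom = sample(c("CB", "OG", "CZ", "O"), k, replace = TRUE),
        ligand_element = sample(c("C", "N", "O"), k, replace = TRUE),
        ligand_atom_index = seq_len(k),
        type = sample(c("hydrophobic", "polar", "vdw"), k, replace = TRUE),
        distance = round(runif(k, 3, 4.8), 3),
        stringsAsFactors = FALSE
      )
      if (motif[i]) {
        rec <- rbind(rec, data.frame(
          residue_number = c(113L, 312L),
          receptor_atom = c("OD2", "OD1"),
          ligand_element = c("N", "O"),
          ligand_atom_index = k + 1:2,
          type = c("ionic", "hydrogen_bond"),
          distance = c(3.5, 3.0)))
      }
      aifs[[i]] <- new_aif(make_sample_id(lig[i], pose[i]), rec)
    }
    attr(aifs, "motif") <- motif
    aifs
  })
}
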