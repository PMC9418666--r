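rules <- geometry_rules()

# handmade two-atom structures for single-pair classification
micro_receptor <- function(atom_name, element, residue_name, residue_number,
                           xyz, extra = NULL) {
  df <- data.frame(atom_name = atom_name, element = element,
                   residue_name = residue_name,
                   residue_number = residue_number, stringsAsFactors = FALSE)
  rec <- aifp:::new_receptor(aifp:::new_atom_table(
    atom_name = df$atom_name, element = df$element,
    residue_name = df$residue_name, residue_number = df$residue_number,
    chain_id = "A", xyz = xyz))
  assign_atom_roles(rec)
}

micro_pose <- function(element, xyz, charge = 0L, bonds = NULL) {
  n <- length(element)
  bonds <- bonds %||% data.frame(atom_1 = integer(0), atom_2 = integer(0),
                                 order = integer(0), aromatic = logical(0))
  pose <- aifp:::new_pose("lig 001", 1L, aifp:::new_atom_table(
    atom_name = paste0(element, seq_len(n)), element = element,
    residue_name = "lig 001", residue_number = 1L, chain_id = "L",
    xyz = xyz, formal_charge = charge), bonds)
  assign_atom_roles(pose)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pair enumeration finds exactly the in-range pairs", {
  rec <- micro_receptor("CB", "C", "ALA", 10L, rbind(c(0, 0, 0)))
  far <- micro_pose("C", rbind(c(50, 0, 0)))
  expect_identical(nrow(enumerate_pairs(rec, far, rules)), 0L)
  near <- micro_pose("C", rbind(c(3, 0, 0)))
  pairs <- enumerate_pairs(rec, near, rules)
  expect_identical(nrow(pairs), 1L)
  expect_equal(pairs$distance, 3.000, tolerance = 1e-12)
})

test_that("grid enumeration equals a brute-force all-pairs scan", {
  for (seed in 1:3) {
    n_rec <- 120; n_lig <- 60
    coords <- aifp:::with_seed(seed, list(
      r = matrix(runif(n_rec * 3, 0, 18), n_rec, 3),
      l = matrix(runif(n_lig * 3, 0, 18), n_lig, 3)))
    rec <- micro_receptor(rep("CB", n_rec), rep("C", n_rec), "ALA",
                          seq_len(n_rec), coords$r)
    pose <- micro_pose(rep("C", n_lig), coords$l)
    pairs <- enumerate_pairs(rec, pose, rules)
    got <- sort(paste(pairs$rec_idx, pairs$lig_idx,
                      round(pairs$distance, 9)))
    # brute force oracle
    want <- character(0)
    for (i in seq_len(n_rec)) for (j in seq_len(n_lig)) {
      d <- sqrt(sum((coords$r[i, ] - coords$l[j, ])^2))
      if (d <= rules$neighbor_cutoff) {
        want <- c(want, paste(i, j, round(d, 9)))
      }
    }
    expect_identical(got, sort(want))
  }
})

test_that("charged, hydrogen-bonded and far pairs classify per the rule table", {
  # Asp OD2 (anion) vs ammonium N at 3.5 A -> ionic
  rec <- micro_receptor(c("CB", "CG", "OD1", "OD2"), c("C", "C", "O", "O"),
                        "ASP", 113L,
                        rbind(c(0, 0, 3.8), c(0, 0, 2.5), c(0, 1.1, 1.8),
                              c(0, 0, 0)))
  lig <- micro_pose("N", rbind(c(0, 0, -3.5)), charge = 1L)
  expect_identical(classify_pair(rec, lig, 4L, 1L), "ionic")

  # Ser OG donor vs ligand O acceptor at 2.8 A, D-H-A 165 deg -> hydrogen bond
  ang <- (180 - 165) * pi / 180
  rec2 <- micro_receptor(c("CB", "OG", "HG"), c("C", "O", "H"), "SER", 203L,
                         rbind(c(0, 0, 1.4), c(0, 0, 0),
                               c(0.97 * sin(ang), 0, -0.97 * cos(ang))))
  lig2 <- micro_pose(c("C", "O"), rbind(c(0, 0, -4.2), c(0, 0, -2.8)),
                     bonds = data.frame(atom_1 = 1L, atom_2 = 2L,
                                        order = 2L, aromatic = FALSE))
  expect_identical(classify_pair(rec2, lig2, 2L, 2L), "hydrogen_bond")
  # same geometry but angle collapsed to ~65 deg -> demoted to polar
  ang2 <- (180 - 65) * pi / 180
  rec3 <- micro_receptor(c("CB", "OG", "HG"), c("C", "O", "H"), "SER", 203L,
                         rbind(c(0, 0, 1.4), c(0, 0, 0),
                               c(0.97 * sin(ang2), 0, -0.97 * cos(ang2))))
  expect_identical(classify_pair(rec3, lig2, 2L, 2L), "polar")

  # beyond the neighbour cutoff nothing is enumerated or typed
  lig3 <- micro_pose("C", rbind(c(0, 0, -6)))
  expect_true(is.na(classify_pair(rec, lig3, 4L, 1L)))
})

test_that("typing is deterministic and the planted ground truth is recovered", {
  tc <- generate_toy_complex(complex_spec(
    planted = c("polar", "hydrophobic", "aromatic"), seed = 11))
  a1 <- compute_aif(tc$receptor, tc$pose, rules)
  a2 <- compute_aif(tc$receptor, tc$pose, rules)
  expect_identical(a1$records, a2$records)
  key <- function(df) sort(paste(df$residue_number, df$receptor_atom,
                                 df$ligand_element, df$type))
  expect_identical(key(a1$records), key(tc$truth))
})

test_that("classification agrees with an independent per-pair re-evaluation", {
  tc <- generate_toy_complex(complex_spec(
    planted = c("carbonyl", "halogen_bond", "vdw", "weak_polar"), seed = 12))
  pairs <- enumerate_pairs(tc$receptor, tc$pose, rules)
  redone <- vapply(seq_len(nrow(pairs)), function(k) {
    classify_pair(tc$receptor, tc$pose, pairs$rec_idx[k], pairs$lig_idx[k],
                  rules)
  }, character(1))
  rebuilt <- data.frame(
    residue_number = tc$receptor$atoms$residue_number[pairs$rec_idx],
    receptor_atom = tc$receptor$atoms$atom_name[pairs$rec_idx],
    ligand_element = tc$pose$atoms$element[pairs$lig_idx],
    type = redone, stringsAsFactors = FALSE)
  rebuilt <- unique(rebuilt[!is.na(rebuilt$type), ])
  aif <- compute_aif(tc$receptor, tc$pose, rules)
  key <- function(df) sort(paste(df$residue_number, df$receptor_atom,
                                 df$ligand_element, df$type))
  expect_identical(key(rebuilt), key(aif$records))
})

test_that("shrinking the enumeration radius empties the fingerprint", {
  tc <- generate_toy_complex(complex_spec(seed = 13))
  tiny <- geometry_rules(neighbor_cutoff = 0.1)
  aif <- compute_aif(tc$receptor, tc$pose, tiny)
  expect_identical(nrow(aif$records), 0L)
})

test_that("enlarging the neighbour cutoff never removes records", {
  tc <- generate_toy_complex(complex_spec(
    planted = c("hydrophobic", "proximal"), seed = 14))
  small <- compute_aif(tc$receptor, tc$pose, geometry_rules())
  big <- compute_aif(tc$receptor, tc$pose, geometry_rules(neighbor_cutoff = 7))
  key <- function(df) paste(df$residue_number, df$receptor_atom,
                            df$ligand_element, df$type)
  expect_true(all(key(small$records) %in% key(big$records)))
})

test_that("a hydrogen bond crossing its distance threshold is retyped", {
  thr <- rules$hydrogen_bond_max
  below <- generate_toy_complex(complex_spec(
    planted = "hydrogen_bond", motif = FALSE, distances = thr - 0.1,
    seed = 1))
  above <- suppressWarnings(generate_toy_complex(complex_spec(
    planted = "hydrogen_bond", motif = FALSE, distances = thr + 0.1,
    seed = 1)))
  a_below <- compute_aif(below$receptor, below$pose, rules)
  a_above <- compute_aif(above$receptor, above$pose, rules)
  expect_true("hydrogen_bond" %in% a_below$records$type)
  expect_false("hydrogen_bond" %in% a_above$records$type)
  expect_true("weak_polar" %in% a_above$records$type)
})

test_that("the interaction taxonomy is a closed set of 15 with the excluded triple", {
  types <- interaction_types()
  expect_length(types, 15)
  expect_setequal(attr(types, "excluded_from_matrix"),
                  c("clash", "vdw_clash", "proximal"))
  expect_error(geometry_rules(bogus_max = 3), "unknown rule")
  expect_error(geometry_rules(ionic_max = -1), "positive")
})
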