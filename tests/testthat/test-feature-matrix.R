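labels2 <- data.frame(ligand_id = c("lig 001", "lig 002"),
                      label = c("agonist", "antagonist"))

aif_with <- function(sample, keys) {
  parsed <- parse_feature_key(keys)
  parsed$ligand_atom_index <- seq_len(nrow(parsed))
  parsed$distance <- 3.2
  aifp:::new_aif(sample, parsed[, c("residue_number", "receptor_atom",
                                    "ligand_element", "ligand_atom_index",
                                    "type", "distance")])
}

test_that("feature keys render canonically and parse back to their components", {
  key <- feature_key(301, "O", "N", "polar")
  parsed <- parse_feature_key(key)
  expect_identical(parsed$residue_number, 301L)
  expect_identical(parsed$receptor_atom, "O")
  expect_identical(parsed$ligand_element, "N")
  expect_identical(parsed$type, "polar")
  expect_error(parse_feature_key("garbage"), "unparseable")
})

test_that("the matrix is the union of observed keys with absent contacts as 0", {
  k <- feature_key(c(113, 203, 301), c("OD2", "OG", "O"), c("N", "O", "N"),
                   c("ionic", "hydrogen_bond", "polar"))
  aifs <- list(aif_with("lig 001_01", k[1]), aif_with("lig 002_01", k))
  m <- build_matrix(aifs, labels2)
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(unname(rowSums(m$values)), c(1, 3))
  expect_setequal(colnames(m$values), k)
  expect_identical(as.character(m$label), c("agonist", "antagonist"))
})

test_that("clash, vdw clash and proximal contacts never become columns", {
  k <- c(feature_key(113, "OD2", "N", "ionic"),
         feature_key(118, "CG2", "O", "proximal"),
         feature_key(82, "SD", "C", "clash"),
         feature_key(82, "SD", "C", "vdw_clash"))
  aifs <- list(aif_with("lig 001_01", k), aif_with("lig 002_01", k[1]))
  m <- build_matrix(aifs, labels2)
  expect_identical(colnames(m$values), k[1])
})

test_that("a missing ligand label is a hard error listing the id", {
  aifs <- list(aif_with("lig 009_01", feature_key(113, "OD2", "N", "ionic")))
  expect_error(build_matrix(aifs, labels2), "lig 009")
})

test_that("column count equals an independent recount of distinct keys", {
  d <- generate_toy_dataset(withr::local_tempdir(), n_ligands = 8,
                            poses_per_ligand = 2, seed = 21)
  rec <- assign_atom_roles(read_receptor(d$receptor_path))
  aifs <- lapply(lapply(read_poses(d$poses_path), assign_atom_roles),
                 function(p) compute_aif(rec, p))
  m <- build_matrix(aifs, read_labels(d$labels_path))
  tab <- aifs_to_table(aifs)
  tab <- tab[!(tab$type %in% c("clash", "vdw_clash", "proximal")), ]
  n_distinct <- length(unique(paste(tab$residue_number, tab$receptor_atom,
                                    tab$ligand_element, tab$type)))
  expect_identical(ncol(m$values), n_distinct)
})

test_that("frequency filter keeps exactly the columns at or above threshold", {
  vals <- cbind(rep(1L, 11),                  # frequency 1
                c(1L, rep(0L, 10)),           # 1/11 < 0.10 -> dropped
                c(rep(1L, 2), rep(0L, 9)))    # 2/11 -> kept
  m <- make_matrix(vals, rep(c("agonist", "antagonist"), c(6, 5)))
  f <- frequency_filter(m, 0.10)
  expect_identical(ncol(f$values), 2L)
  expect_identical(colnames(f$values), colnames(m$values)[c(1, 3)])
  # idempotent at fixed threshold
  expect_identical(frequency_filter(f, 0.10)$values, f$values)
  # an all-zero column is dropped at any positive threshold
  m0 <- make_matrix(cbind(c(1L, 1L), c(0L, 0L)), c("agonist", "antagonist"))
  expect_identical(ncol(frequency_filter(m0, 1e-9)$values), 1L)
  expect_error(frequency_filter(m, 0), "threshold")
  expect_error(frequency_filter(m, 1.2), "threshold")
})

test_that("stratified hold-out arithmetic, determinism and ligand grouping hold", {
  # 100 ligands at 75/25: the 20% hold-out takes 15 + 5 ligands
  lab <- rep(c("agonist", "antagonist"), c(75, 25))
  vals <- matrix(rbinom(200 * 3, 1, 0.5), 200, 3)
  rownames(vals) <- as.vector(t(outer(sprintf("lig %03d", 1:100), 1:2,
                                      function(l, p) sprintf("%s_%02d", l, p))))
  m <- make_matrix(vals, rep(lab, each = 2))
  spl <- split_holdout(m, 0.20, seed = 9)
  hold_ligs <- unique(spl$holdout$ligand_id)
  expect_length(hold_ligs, 20)
  hold_lab <- spl$holdout$label[!duplicated(spl$holdout$ligand_id)]
  expect_identical(sort(as.integer(table(droplevels(hold_lab)))), c(5L, 15L))
  # no ligand on both sides
  expect_length(intersect(spl$cv$ligand_id, spl$holdout$ligand_id), 0)
  # same seed, same split
  spl2 <- split_holdout(m, 0.20, seed = 9)
  expect_identical(rownames(spl$holdout$values), rownames(spl2$holdout$values))
  # binders are excluded from supervised splits
  mb <- make_matrix(vals, c(rep("binder", 4), rep(lab, each = 2))[1:200])
  splb <- split_holdout(mb, 0.20, seed = 1)
  expect_false("binder" %in% as.character(splb$cv$label))
  expect_false("binder" %in% as.character(splb$holdout$label))
  # degenerate class sizes error
  tiny <- make_matrix(vals[1:4, ], c("agonist", "agonist", "agonist",
                                     "antagonist"))
  expect_error(split_holdout(tiny, 0.2, seed = 1), "at least 2")
})

test_that("CSV export and re-import is the identity on the matrix", {
  g <- generate_matrix(matrix_spec(n_ligands = 20, poses_per_ligand = 2,
                                   n_noise_features = 10, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(g$matrix, path)
  back <- read_matrix_csv(path)
  expect_identical(back$values, g$matrix$values)
  expect_identical(as.character(back$label), as.character(g$matrix$label))
  expect_identical(back$ligand_id, g$matrix$ligand_id)
})
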