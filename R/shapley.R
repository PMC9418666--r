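#' Exact Shapley values by subset enumeration
#'
#' Evaluates \deqn{\phi_i = \sum_{S \subseteq M \setminus i}
#'   \frac{|S|!\,(|M|-|S|-1)!}{|M|!}\,(f(S \cup i) - f(S))}
#' over every feature subset. The cost doubles with each feature, so the
#' enumeration is capped (default 15 features); beyond the cap use
#' [tree_shapley()]. The result satisfies the efficiency, symmetry and dummy
#' axioms by construction.
#'
#' @param value_function function taking an integer vector of feature
#'   indices (a coalition, possibly empty) and returning a scalar model
#'   value. How absent features are marginalised is the value function's
#'   contract; [model_value_function()] averages over a background dataset.
#' @param n_features number of players.
#' @param max_features enumeration cap.
#' @return object of class `aifp_shapley_sample`: `phi` (length
#'   `n_features`), `base_value` = f(empty set), `total` = f(full set).
#' @export
exact_shapley <- function(value_function, n_features, max_features = 15) {
  if (n_features > max_features) {
    stop("exact enumeration capped at ", max_features,
         " features; use tree_shapley() for larger models")
  }
  m <- n_features
  n_masks <- bitwShiftL(1L, m)
  members <- lapply(seq_len(n_masks) - 1L, function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
  })
  v <- vapply(members, value_function, numeric(1))
  sizes <- lengths(members)
  # weight by coalition size: |S|! (m-|S|-1)! / m!
  wt <- exp(lfactorial(0:(m - 1)) + lfactorial(m - 1 - (0:(m - 1))) -
              lfactorial(m))
  phi <- numeric(m)
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(seq_len(n_masks) - 1L, bit) == 0L)
    with_i <- without + bit / 1L
    phi[i] <- sum(wt[sizes[without] + 1L] * (v[with_i] - v[without]))
  }
  structure(list(phi = phi, base_value = v[1L], total = v[n_masks]),
            class = "aifp_shapley_sample")
}

#' Background-marginalised value function of a fitted model
#'
#' Returns the coalition value function f(S) = mean over background rows b
#' of the model output on the hybrid input taking the sample's values on S
#' and the background's values elsewhere (interventional marginalisation).
#' Output is on the model's attribution scale: log-odds margin for boosted
#' trees, positive-class probability for random forests.
#'
#' @param model an `aifp_model`.
#' @param x numeric vector, one sample (training feature order).
#' @param background numeric matrix of background rows (same columns).
#' @return function of an integer coalition vector.
#' @export
model_value_function <- function(model, x, background) {
  force(model); force(x); force(background)
  function(S) {
    hybrid <- background
    if (length(S)) hybrid[, S] <- matrix(x[S], nrow(background), length(S),
                                         byrow = TRUE)
    mean(.raw_model_output(model, hybrid))
  }
}

# model output on the attribution scale for a plain numeric matrix
.raw_model_output <- function(model, X) {
  colnames(X) <- model$safe_names
  if (model$family == "random_forest") {
    predict(model$fit, data = as.data.frame(X),
            num.threads = 1)$predictions[, model$positive]
  } else {
    predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1),
            outputmargin = TRUE)
  }
}

# Batched exact enumeration for a fitted model: evaluates all coalition
# values with a single model predict call per sample.
exact_shapley_model <- function(model, X, background, max_features = 15) {
  m <- ncol(X)
  if (m > max_features) stop("exact enumeration capped at ", max_features)
  n_masks <- bitwShiftL(1L, m)
  masks <- seq_len(n_masks) - 1L
  nb <- nrow(background)
  phi <- matrix(0, nrow(X), m,
                dimnames = list(rownames(X), colnames(X)))
  base <- numeric(nrow(X))
  sizes <- vapply(masks, function(mask) sum(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) != 0), numeric(1))
  wt <- exp(lfactorial(0:(m - 1)) + lfactorial(m - 1 - (0:(m - 1))) -
              lfactorial(m))
  inmask <- vapply(seq_len(m), function(i)
    bitwAnd(masks, bitwShiftL(1L, i - 1L)) != 0L, logical(n_masks))
  for (s in seq_len(nrow(X))) {
    big <- background[rep(seq_len(nb), n_masks), , drop = FALSE]
    sel <- inmask[rep(seq_len(n_masks), each = nb), , drop = FALSE]
    xrep <- matrix(X[s, ], nrow(big), m, byrow = TRUE)
    big[sel] <- xrep[sel]
    out <- .raw_model_output(model, big)
    v <- colMeans(matrix(out, nb, n_masks))  # column-major: nb rows per mask
    for (i in seq_len(m)) {
      without <- which(!inmask[, i])
      with_i <- without + bitwShiftL(1L, i - 1L)
      phi[s, i] <- sum(wt[sizes[without] + 1L] * (v[with_i] - v[without]))
    }
    base[s] <- v[1L]
  }
  list(phi = phi, base_value = base[1L])
}

# ---- tree extraction --------------------------------------------------------

# Flatten a fitted ensemble into parallel node arrays for the C++ kernel.
# Node semantics: feature == -1 marks a leaf (value in `value`); otherwise a
# sample goes to `yes` when x[feature] < split (strict = TRUE, boosted trees)
# or x[feature] <= split (strict = FALSE, ranger forests).
extract_trees <- function(model) {
  if (model$family == "gradient_boosted_trees") {
    dt <- xgboost::xgb.model.dt.tree(model = model$fit)
    dt <- as.data.frame(dt)
    if (!"Gain" %in% names(dt) && "Quality" %in% names(dt)) {
      dt$Gain <- dt$Quality
    }
    id2row <- function(ids) match(ids, dt$ID)
    leaf <- dt$Feature == "Leaf"
    list(
      tree = dt$Tree,
      feature = ifelse(leaf, -1L,
                       match(dt$Feature, model$safe_names) - 1L),
      split = ifelse(leaf, 0, dt$Split),
      yes = ifelse(leaf, -1L, id2row(dt$Yes) - 1L),
      no = ifelse(leaf, -1L, id2row(dt$No) - 1L),
      value = ifelse(leaf, dt$Gain, 0),
      root = match(unique(dt$Tree), dt$Tree) - 1L,
      strict = TRUE
    )
  } else if (model$family == "random_forest") {
    ntree <- model$fit$num.trees
    rows <- vector("list", ntree)
    offset <- 0L
    roots <- integer(ntree)
    predcol <- paste0("pred.", model$positive)
    for (t in seq_len(ntree)) {
      ti <- ranger::treeInfo(model$fit, t)
      leaf <- ti$terminal
      rows[[t]] <- data.frame(
        tree = t - 1L,
        feature = ifelse(leaf, -1L,
                         match(ti$splitvarName, model$safe_names) - 1L),
        split = ifelse(leaf, 0, ti$splitval),
        yes = ifelse(leaf, -1L, ti$leftChild + offset),
        no = ifelse(leaf, -1L, ti$rightChild + offset),
        value = ifelse(leaf, ti[[predcol]] / ntree, 0)
      )
      roots[t] <- offset
      offset <- offset + nrow(ti)
    }
    all <- do.call(rbind, rows)
    list(tree = all$tree, feature = all$feature, split = all$split,
         yes = all$yes, no = all$no, value = all$value,
         root = roots, strict = FALSE)
  } else {
    stop("not a tree-ensemble model")
  }
}

#' Interventional Shapley values for tree-ensemble models
#'
#' Computes, for each sample, the exact Shapley attribution of the ensemble
#' output with absent features marginalised over a background dataset: for
#' every (sample, background row) pair the tree structure yields the
#' coalition game in closed form (each leaf contributes through the features
#' on which sample and background diverge), and contributions are averaged
#' over the background. This equals exact subset enumeration of the same
#' value function at polynomial rather than exponential cost. Attribution
#' scale: log-odds margin for boosted trees, positive-class probability for
#' random forests (local accuracy base + sum(phi) = model output holds on
#' that scale).
#'
#' @param model an `aifp_model` (tree ensemble; anything else is an error).
#' @param matrix an `aifp_matrix` (or plain numeric matrix with the training
#'   columns) of samples to explain.
#' @param background an `aifp_matrix` or numeric matrix of background rows;
#'   defaults to the explained samples themselves.
#' @return object of class `aifp_shapley`: `phi` (samples x features, named
#'   by feature key), `base_value`, `values` (the explained 0/1 matrix),
#'   `units` ("log-odds" or "probability").
#' @export
tree_shapley <- function(model, matrix, background = NULL) {
  if (!inherits(model, "aifp_model")) stop("not a tree-ensemble model")
  X <- if (inherits(matrix, "aifp_matrix")) {
    matrix$values[, model$feature_names, drop = FALSE]
  } else matrix
  B <- if (is.null(background)) X else {
    if (inherits(background, "aifp_matrix")) {
      background$values[, model$feature_names, drop = FALSE]
    } else background
  }
  trees <- extract_trees(model)
  res <- cpp_tree_shap(
    as.integer(trees$feature), as.numeric(trees$split),
    as.integer(trees$yes), as.integer(trees$no), as.numeric(trees$value),
    as.integer(trees$root), isTRUE(trees$strict),
    unname(as.matrix(X)) * 1.0, unname(as.matrix(B)) * 1.0
  )
  phi <- res$phi
  dimnames(phi) <- list(rownames(X), model$feature_names)
  # model offset not represented in the leaves (boosted-tree intercept)
  raw <- .raw_model_output(model, X[1, , drop = FALSE])
  offset <- raw - (res$base + sum(phi[1, ]))
  structure(
    list(phi = phi, base_value = res$base + offset,
         values = X,
         units = if (model$family == "gradient_boosted_trees") "log-odds"
                 else "probability"),
    class = "aifp_shapley"
  )
}

#' @export
print.aifp_shapley <- function(x, ...) {
  cat(sprintf("<aifp_shapley> %d samples x %d features (%s), base %.4f\n",
              nrow(x$phi), ncol(x$phi), x$units, x$base_value))
  invisible(x)
}

#' Global feature importance from Shapley values
#'
#' Ranks features by mean absolute attribution over the explained samples
#' and summarises, per feature, whether its presence (value 1) pushes the
#' prediction toward the positive (antagonist) class.
#'
#' @param shap an `aifp_shapley`.
#' @return data.frame sorted by `mean_abs_phi` descending: feature, mean
#'   |phi|, mean phi when the feature is present / absent, and
#'   `presence_direction` ("antagonist" when presence raises the positive
#'   log-odds, "agonist" otherwise).
#' @export
global_importance <- function(shap) {
  if (!nrow(shap$phi)) stop("no Shapley values to summarise")
  present <- shap$values == 1
  mean_present <- vapply(seq_len(ncol(shap$phi)), function(j) {
    if (any(present[, j])) mean(shap$phi[present[, j], j]) else NA_real_
  }, numeric(1))
  mean_absent <- vapply(seq_len(ncol(shap$phi)), function(j) {
    if (any(!present[, j])) mean(shap$phi[!present[, j], j]) else NA_real_
  }, numeric(1))
  out <- data.frame(
    feature_key = colnames(shap$phi),
    mean_abs_phi = colMeans(abs(shap$phi)),
    mean_phi_present = mean_present,
    mean_phi_absent = mean_absent,
    presence_direction = ifelse(is.na(mean_present), "undefined",
                                ifelse(mean_present > 0, "antagonist",
                                       "agonist")),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$mean_abs_phi, out$feature_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export per-sample Shapley values as a tidy table
#' @param shap an `aifp_shapley`.
#' @return data.frame `sample_id`, `feature_key`, `phi`, `value`.
#' @export
shapley_to_table <- function(shap) {
  data.frame(
    sample_id = rep(rownames(shap$phi) %||% seq_len(nrow(shap$phi)),
                    times = ncol(shap$phi)),
    feature_key = rep(colnames(shap$phi), each = nrow(shap$phi)),
    phi = as.vector(shap$phi),
    value = as.vector(shap$values),
    stringsAsFactors = FALSE
  )
}
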