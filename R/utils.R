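# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v^2))

# Angle at vertex b (degrees) for points a, b, c.
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu == 0 || nv == 0) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# "ligandID_poseNumber" sample identifiers; the ligand id itself may contain
# underscores and spaces, so the pose number is split off from the right.
make_sample_id <- function(ligand_id, pose_number) {
  sprintf("%s_%02d", ligand_id, as.integer(pose_number))
}

split_sample_id <- function(sample_id) {
  m <- regmatches(sample_id, regexpr("_[0-9]+$", sample_id))
  bad <- lengths(regmatches(sample_id, gregexpr("_[0-9]+$", sample_id))) == 0
  if (any(bad)) {
    stop("sample id(s) without a trailing _<poseNumber>: ",
         paste(sample_id[bad], collapse = ", "))
  }
  data.frame(
    ligand_id = sub("_[0-9]+$", "", sample_id),
    pose_number = as.integer(sub("^_", "", m)),
    stringsAsFactors = FALSE
  )
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
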