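# Internal helpers shared across the pipeline stages.

# Derive a child seed from a root seed and a counter. Computed in double
# precision (exact below 2^53), reduced modulo 2^31 - 1 so it is always a
# valid 32-bit R integer.
derive_seed <- function(seed, k) {
  m <- 2147483647
  h <- ((as.numeric(seed) %% m) * 1000003) %% m
  as.integer((h + (as.numeric(k) %% m) * 7919) %% m)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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

# Integer partition sizes by the largest-remainder (Hamilton) method.
largest_remainder <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  ideal <- n * fractions
  sizes <- floor(ideal)
  short <- n - sum(sizes)
  if (short > 0) {
    extra <- order(ideal - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

# Canonical two-level diagnosis factor; autism is the positive class.
as_diagnosis <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!all(labels %in% c("ASD", "TD"))) {
    stop("labels must be 'ASD' or 'TD'", call. = FALSE)
  }
  factor(labels, levels = c("TD", "ASD"))
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin. Retries with perturbed seeds until every training fold
# contains both classes (at most `max_tries` attempts).
make_folds <- function(labels, k, seed = 1, max_tries = 10) {
  labels <- as_diagnosis(labels)
  n <- length(labels)
  if (k < 2 || k > n) stop("fold count must be in [2, n]", call. = FALSE)
  for (try in seq_len(max_tries)) {
    folds <- integer(n)
    with_seed(derive_seed(seed, try - 1), {
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- labels[folds != f]
      length(unique(tr)) == 2
    }, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build folds with both classes in every training fold",
       call. = FALSE)
}

# Promote a subjects x bins matrix (single area) to subjects x 1 x bins.
as_feature_array <- function(features) {
  if (length(dim(features)) == 2) {
    features <- array(features, c(nrow(features), 1, ncol(features)))
  }
  stopifnot(length(dim(features)) == 3)
  features
}

# Flatten a 4D (x, y, z, t) BOLD array to a timepoints x voxels matrix.
vol4d_to_matrix <- function(vol) {
  d <- dim(vol)
  if (length(d) != 4) stop("expected a 4D volume", call. = FALSE)
  t(matrix(vol, nrow = prod(d[1:3]), ncol = d[4]))
}

# Inverse of vol4d_to_matrix.
matrix_to_vol4d <- function(x, grid_shape) {
  array(t(x), dim = c(grid_shape, nrow(x)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Tiny FNV-1a hash of a deparsed object; used to stamp output manifests with
# a config fingerprint without adding a digest dependency.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
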