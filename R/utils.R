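# Internal helpers shared across modules.

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# A NULL seed runs expr as-is (caller-controlled randomness).
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Coerce to a general sparse double matrix with explicit zeros dropped.
asSparse <- function(x) {
  m <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  Matrix::drop0(m)
}

# 0/1 integer phenotype from a 0/1 vector, logical, or two-level factor
# (second level = case). Names, when present, are preserved.
asPhenotype <- function(phenotype) {
  nm <- names(phenotype)
  if (is.factor(phenotype)) {
    if (nlevels(phenotype) != 2) {
      stop("phenotype factor must have exactly two levels", call. = FALSE)
    }
    y <- as.integer(phenotype) - 1L
  } else if (is.logical(phenotype)) {
    y <- as.integer(phenotype)
  } else {
    y <- as.integer(phenotype)
    if (!all(y %in% c(0L, 1L) | is.na(y))) {
      stop("phenotype must be coded 0 (control) / 1 (case)", call. = FALSE)
    }
  }
  names(y) <- nm
  y
}

# Frobenius norm that works for base and Matrix matrices.
frobenius <- function(x) sqrt(sum(x * x))
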