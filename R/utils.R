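# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Derive a per-stage seed from a master seed and a character tag.
## Keeps every derived seed inside the 32-bit integer range.
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(master) * 2654435 + h * 97 + 13) %% .Machine$integer.max)
}

## Linear cell index (column-major, as R matrices) <-> (row, col).
cell_index <- function(row, col, n_rows) {
  (col - 1L) * n_rows + row
}

cell_rowcol <- function(cell, n_rows) {
  cell <- as.integer(cell)
  cbind(row = ((cell - 1L) %% n_rows) + 1L,
        col = ((cell - 1L) %/% n_rows) + 1L)
}

## 4-neighbours of cells on an n_rows x n_cols grid, as linear indices.
cell_neighbours <- function(cell, n_rows, n_cols) {
  rc <- cell_rowcol(cell, n_rows)
  out <- rbind(
    cbind(rc[, 1] - 1L, rc[, 2]),
    cbind(rc[, 1] + 1L, rc[, 2]),
    cbind(rc[, 1], rc[, 2] - 1L),
    cbind(rc[, 1], rc[, 2] + 1L)
  )
  keep <- out[, 1] >= 1L & out[, 1] <= n_rows & out[, 2] >= 1L & out[, 2] <= n_cols
  unique(cell_index(out[keep, 1], out[keep, 2], n_rows))
}

## Gaussian smoothing of a matrix by separable kernel matrices with
## edge renormalisation (weights truncated at the grid boundary).
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  kmat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2)
    k <- exp(-d / (2 * sigma^2))
    k / rowSums(k)
  }
  kr <- kmat(nrow(m))
  kc <- kmat(ncol(m))
  kr %*% m %*% t(kc)
}

## Standardise a layer to zero mean, unit variance (used for abundance
## surfaces so coefficients are comparable across landscapes).
standardise <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

## Evaluate under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  expr
}
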