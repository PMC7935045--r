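# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards (so seeded functions do not perturb the
# global random stream). `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_finite <- function(x, what = "input") {
  stop_if(!all(is.finite(x)), what, " contains non-finite values")
  invisible(x)
}

# Coerce a per-row block labelling to a factor with levels in order of first
# appearance; optionally require rows of each block to be contiguous.
as_blocks <- function(blocks, n, contiguous = FALSE) {
  stop_if(length(blocks) != n,
          "block index length (", length(blocks),
          ") does not match the number of rows (", n, ")")
  f <- factor(blocks, levels = unique(blocks))
  if (contiguous) {
    runs <- rle(as.integer(f))$values
    stop_if(anyDuplicated(runs) > 0L,
            "rows of each block must be contiguous")
  }
  f
}

# All permutations of seq_len(n) as a matrix (n! rows); n is kept small by
# callers (enumeration is used only when the whole group is enumerable).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    ins <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 if (pos <= n - 1L) sub[, pos:(n - 1L), drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(ins)
    r <- r + nrow(sub)
  }
  out
}

# log multivariate gamma
lmvgamma <- function(d, a) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}
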