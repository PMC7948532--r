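# Run code with a private RNG stream: seeds deterministically, restores the
# caller's .Random.seed afterwards so library functions never perturb user code.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

# Shift a matrix by (dr, dc) with replicate (nearest-edge) padding:
# out[r, c] = u[clamp(r + dr), clamp(c + dc)].
shift_mat <- function(u, dr, dc) {
  nr <- nrow(u); nc <- ncol(u)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  u[ri, ci, drop = FALSE]
}

stopifnot_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("expected a logical matrix mask")
  }
}

stopifnot_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
}
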