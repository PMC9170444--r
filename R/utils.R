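# Internal helpers shared across modules.

# Classed errors so the CLI can map failures onto exit codes:
#   usage -> 1, data/format -> 2, numerical -> 3.
ik_stop <- function(msg, class = c("data", "usage", "numeric")) {
  class <- match.arg(class)
  cls <- paste0("ikfcm_", class, "_error")
  stop(errorCondition(msg, class = c(cls, "ikfcm_error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Mirror-reflect out-of-range indices into 1..n (border not repeated).
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  j <- ifelse(j < 1L, 2L - j, j)
  j <- ifelse(j > n, 2L * n - j, j)
  pmin(pmax(j, 1L), n)
}

# Shift an n-D array by an integer offset vector, filling vacated cells.
shift_fill <- function(x, off, fill) {
  d <- dim(x)
  out <- array(fill, d)
  tgt <- vector("list", length(d))
  src <- vector("list", length(d))
  for (k in seq_along(d)) {
    lo <- max(1L, 1L - off[k])
    hi <- min(d[k], d[k] - off[k])
    if (lo > hi) return(out)
    tgt[[k]] <- lo:hi
    src[[k]] <- (lo:hi) + off[k]
  }
  block <- do.call(`[`, c(list(x), src, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), tgt, list(block)))
  out
}

# Window offsets for a (2p+1)^d box, optionally without the central cell.
box_offsets <- function(ndim, radius, drop_center = TRUE) {
  grid <- do.call(expand.grid, rep(list(-radius:radius), ndim))
  grid <- as.matrix(grid)
  if (drop_center) grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  grid
}
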