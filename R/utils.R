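# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_flag_array <- function(x, dim3, name) {
  if (!is.array(x) || !is.logical(x) || length(dim(x)) != 3L)
    stop_field(name, "must be a logical 3D array")
  if (!identical(dim(x), as.integer(dim3)))
    stop_field(name, sprintf("dimensions (%s) do not match volume (%s)",
                             paste(dim(x), collapse = "x"),
                             paste(dim3, collapse = "x")))
  invisible(TRUE)
}

# Shift a 3D array by `by` voxels along `axis`, filling with `fill`.
shift_array <- function(a, by, axis, fill = 0) {
  d <- dim(a)
  if (by == 0L) return(a)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0L) seq_len(n - by) else seq.int(1L - by, n)
  dst <- if (by > 0L) seq.int(1L + by, n) else seq_len(n + by)
  ix <- function(idx, ax) if (ax == axis) idx else TRUE
  out[ix(dst, 1L), ix(dst, 2L), ix(dst, 3L)] <-
    a[ix(src, 1L), ix(src, 2L), ix(src, 3L)]
  out
}

# subject-index matrix of voxel coordinates for a 3D grid
grid_coords <- function(dim3) {
  as.matrix(expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                        z = seq_len(dim3[3])))
}
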