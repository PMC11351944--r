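#' @noRd
is_binary_mask <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

#' @noRd
assert_binary_mask <- function(x, name = deparse(substitute(x))) {
  if (!is_binary_mask(x)) {
    stop(sprintf("'%s' must be a binary (0/1) volume", name), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
assert_same_dim <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share one grid: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(NULL)
}

# Coordinates (n x 3, 1-based) of TRUE/1 voxels in a 3D mask.
#' @noRd
mask_coords <- function(mask) {
  which(mask == 1, arr.ind = TRUE)
}

# 26/18/6-neighbourhood integer offsets (n x 3).
#' @noRd
neighbour_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity must be one of 6, 18, 26", call. = FALSE)
  )
  g[keep, , drop = FALSE]
}
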