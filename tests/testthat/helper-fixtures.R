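# Shared fixtures and independent brute-force oracles.

# Small phantom profile used across tests: 64^3 grid, fewer WML components,
# no confounders unless a test asks for them.
test_phantom_config <- function(n_confounders = 0L, ...) {
  phantom_config(grid_shape = c(64L, 64L, 64L), n_wml = 3L,
                 wml_volume_range_mm3 = c(100, 600),
                 n_confounders = n_confounders, ...)
}

# One cached positive bundle so expensive generation happens once per run.
.fixture_env <- new.env(parent = emptyenv())
test_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- generate_scan(test_phantom_config(), seed = 101,
                                         force_positive = TRUE)
  }
  .fixture_env$bundle
}

# Hand-built bundle on an arbitrary grid for pure geometry tests.
fake_bundle <- function(gs = c(96L, 96L, 96L), wml_voxels = NULL,
                        cel_voxels = NULL) {
  z <- array(0, gs)
  wml <- z; cel <- z
  if (!is.null(wml_voxels)) wml[wml_voxels] <- 1
  if (!is.null(cel_voxels)) cel[cel_voxels] <- 1
  structure(list(t1_pre = z + 1, t1_post = z + 2, flair = z + 3,
                 wml_mask = wml, cel_mask = cel,
                 brain_mask = z + 1, patient_id = "P", scan_id = "S",
                 voxel_size_mm = 1), class = "scan_bundle")
}

# Tiny network profile for fast training checks.
tiny_net <- function(f1 = 4L, f2 = 8L) {
  network_config(encoder_filters = c(f1, f2), decoder_filters = c(f2, f1))
}

# Brute-force connected components by repeated flood fill over an explicit
# voxel adjacency graph (igraph), independent of the package's BFS labelling.
oracle_components <- function(mask, connectivity = 26L) {
  co <- which(mask == 1, arr.ind = TRUE)
  n <- nrow(co)
  if (n == 0) return(list())
  off <- switch(as.character(connectivity),
    "6" = 1, "18" = 2, "26" = 3)
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d <- abs(sweep(co[(i + 1):n, , drop = FALSE], 2, co[i, ]))
      adj <- switch(as.character(connectivity),
        "6"  = rowSums(d) == 1,
        "18" = apply(d, 1, max) == 1 & rowSums(d) <= 2,
        "26" = apply(d, 1, max) == 1)
      for (j in which(adj)) edges <- c(edges, i, i + j)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  lapply(sort(unique(memb)), function(m) unname(co[memb == m, , drop = FALSE]))
}

# Canonical form of a voxel partition for set comparison.
canonical_partition <- function(comp_list, gs) {
  lin <- lapply(comp_list, function(v)
    sort(v[, 1] + (v[, 2] - 1) * gs[1] + (v[, 3] - 1) * gs[1] * gs[2]))
  lin[order(vapply(lin, `[`, numeric(1), 1))]
}

# Random small binary mask.
random_mask <- function(gs, p = 0.15) {
  array(as.numeric(runif(prod(gs)) < p), dim = gs)
}

# Direct one-pass normalization oracle.
oracle_zscore <- function(volume, mask) {
  out <- array(0, dim(volume))
  vals <- c()
  for (i in which(mask == 1)) vals <- c(vals, volume[i])
  m <- sum(vals) / length(vals)
  s <- sqrt(sum((vals - m)^2) / (length(vals) - 1))
  for (i in which(mask == 1)) out[i] <- (volume[i] - m) / s
  out
}
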