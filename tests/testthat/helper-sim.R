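# Shared fixtures for the suite.  Everything is generated in code; the
# heavier simulated objects are cached per test run.

# Small geometries keep the simulations fast; nCCV is normalized to a
# reference volume, so results at a cropped field are comparable to the
# standard 750 um acquisition.
tiny_geom <- function(field_um = 64, n_slices = 10L, pixel_size_um = 1,
                      step_um = 2.8) {
  acquisition_geometry(pixel_size_um = pixel_size_um, step_um = step_um,
                       n_slices = n_slices, field_um = field_um)
}

small_geom <- function(field_um = 160) {
  acquisition_geometry(pixel_size_um = 1, field_um = field_um)
}

# A stack built directly from an array (bypasses the simulator) for
# hand-constructed scenes.
manual_stack <- function(voxels, geometry) image_stack(voxels, geometry)

# Plant a hard-edged disc of given radius (px) on a matrix.
add_disc <- function(m, cy, cx, r_px, value) {
  yy <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  xx <- t(matrix(seq_len(ncol(m)), ncol(m), nrow(m)))
  m[(yy - cy)^2 + (xx - cx)^2 <= r_px^2] <- value
  m
}

.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Independent oracle for connected components: breadth-first search over
# an explicit neighbour list.  Deliberately naive.
bfs_components <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(array(0L, d))
  key <- function(p) paste(p, collapse = ",")
  unvisited <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(idx))) assign(key(idx[i, ]), idx[i, ], unvisited)
  out <- array(0L, d)
  lab <- 0L
  for (i in seq_len(nrow(idx))) {
    k0 <- key(idx[i, ])
    if (!exists(k0, unvisited)) next
    lab <- lab + 1L
    queue <- list(idx[i, ])
    rm(list = k0, envir = unvisited)
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      out[matrix(p, 1)] <- lab
      for (j in seq_len(nrow(offs))) {
        q <- p + offs[j, ]
        if (any(q < 1) || any(q > d)) next
        kq <- key(q)
        if (exists(kq, unvisited)) {
          rm(list = kq, envir = unvisited)
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  out
}

# Brute-force AUC oracle: pairwise win fraction with ties counted 1/2.
auc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}
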