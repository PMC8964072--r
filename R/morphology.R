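# Internal 3D binary morphology and connected-component helpers.
# Box (Chebyshev) structuring elements are implemented as separable running
# max/min filters along each axis, so dilate/erode cost is O(N * radius).

shift_array <- function(a, axis, by, fill) {
  if (by == 0L) return(a)
  d <- dim(a)
  n <- d[axis]
  if (abs(by) >= n) return(array(fill, dim = d))
  idx_src <- if (by > 0L) seq_len(n - by) else seq.int(1L + (-by), n)
  idx_dst <- if (by > 0L) seq.int(1L + by, n) else seq_len(n + by)
  out <- array(fill, dim = d)
  src <- dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  src[[axis]] <- idx_src
  dst[[axis]] <- idx_dst
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(a), src, list(drop = FALSE))))))
  out
}

.axis_filter <- function(a, axis, r, op, fill) {
  out <- a
  for (by in seq.int(-r, r)) {
    if (by == 0L) next
    out <- op(out, shift_array(a, axis, by, fill))
  }
  out
}

binary_dilate <- function(mask, radius = 1L) {
  if (radius < 1L) return(mask)
  out <- mask
  for (ax in 1:3) out <- .axis_filter(out, ax, radius, `|`, FALSE)
  out
}

binary_erode <- function(mask, radius = 1L) {
  if (radius < 1L) return(mask)
  out <- mask
  for (ax in 1:3) out <- .axis_filter(out, ax, radius, `&`, TRUE)
  out
}

binary_close <- function(mask, radius = 1L) {
  if (radius < 1L) return(mask)
  binary_erode(binary_dilate(mask, radius), radius)
}

# 6-connected component labelling by frontier breadth-first search on linear
# indices; returns an integer array (0 = background) and component sizes.
label_components <- function(mask) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  n <- length(mask)
  labels <- integer(n)
  cand <- which(mask)
  if (length(cand) == 0L)
    return(list(labels = array(0L, d), sizes = integer(0)))
  in_mask <- logical(n)
  in_mask[cand] <- TRUE
  # precompute coordinates for boundary guards
  ix <- ((cand - 1L) %% nx) + 1L
  iy <- (((cand - 1L) %/% nx) %% ny) + 1L
  iz <- ((cand - 1L) %/% (nx * ny)) + 1L
  coord <- matrix(0L, nrow = n, ncol = 3)
  coord[cand, ] <- cbind(ix, iy, iz)
  sizes <- integer(0)
  lab <- 0L
  remaining <- cand
  visited <- logical(n)
  offs <- c(-1L, 1L, -nx, nx, -nx * ny, nx * ny)
  repeat {
    remaining <- remaining[!visited[remaining]]
    if (length(remaining) == 0L) break
    lab <- lab + 1L
    seed <- remaining[1L]
    visited[seed] <- TRUE
    labels[seed] <- lab
    frontier <- seed
    size <- 1L
    while (length(frontier) > 0L) {
      nbr <- integer(0)
      fx <- coord[frontier, 1L]; fy <- coord[frontier, 2L]; fz <- coord[frontier, 3L]
      for (k in 1:6) {
        ok <- switch(k,
                     fx > 1L, fx < nx,
                     fy > 1L, fy < ny,
                     fz > 1L, fz < nz)
        nbr <- c(nbr, frontier[ok] + offs[k])
      }
      nbr <- unique(nbr[in_mask[nbr] & !visited[nbr]])
      if (length(nbr) > 0L) {
        visited[nbr] <- TRUE
        labels[nbr] <- lab
        size <- size + length(nbr)
      }
      frontier <- nbr
    }
    sizes <- c(sizes, size)
  }
  list(labels = array(labels, d), sizes = sizes)
}

# TRUE for components having at least one voxel on the volume boundary
components_touching_boundary <- function(labels, n_components) {
  d <- dim(labels)
  faces <- c(
    labels[1, , ], labels[d[1], , ],
    labels[, 1, ], labels[, d[2], ],
    labels[, , 1], labels[, , d[3]]
  )
  touch <- logical(n_components)
  hit <- unique(faces[faces > 0L])
  touch[hit] <- TRUE
  touch
}

component_centroid <- function(labels, lab) {
  idx <- which(labels == lab)
  d <- dim(labels)
  nx <- d[1]; ny <- d[2]
  ix <- ((idx - 1L) %% nx) + 1L
  iy <- (((idx - 1L) %/% nx) %% ny) + 1L
  iz <- ((idx - 1L) %/% (nx * ny)) + 1L
  c(mean(ix), mean(iy), mean(iz))
}
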