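# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# shift a 3D array by an integer offset, filling exposed planes
shift3 <- function(a, off, fill = Inf) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    if (off[i] >= 0) {
      src[[i]] <- seq_len(d[i] - off[i])
      dst[[i]] <- src[[i]] + off[i]
    } else {
      src[[i]] <- seq_len(d[i] + off[i]) - off[i]
      dst[[i]] <- seq_len(d[i] + off[i])
    }
    if (length(src[[i]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# flood-fill labeling by iterative neighbor-min propagation until fixpoint
oracle_label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    m <- abs(dx) + abs(dy) + abs(dz)
    if (m == 0) next
    if (connectivity == 6 && m > 1) next
    if (connectivity == 18 && m > 2) next
    offs[[length(offs) + 1L]] <- c(dx, dy, dz)
  }
  lab <- array(Inf, dim = d)
  lab[mask] <- which(mask)
  repeat {
    new <- lab
    for (off in offs) new <- pmin(new, shift3(lab, off))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- 0
  lab
}

# canonical form of a labeling: each voxel tagged by the smallest voxel
# index in its component, so two labelings agree iff partitions agree
canonical_labels <- function(lab) {
  out <- array(0, dim = dim(lab))
  for (l in setdiff(unique(as.vector(lab)), 0)) {
    idx <- which(lab == l)
    out[idx] <- min(idx)
  }
  out
}

# trapezoid rule written independently
oracle_trapz <- function(y, dx) dx * sum((y[-1] + y[-length(y)]) / 2)

# build a concentration series directly (no simulator) from C0, k
exact_series <- function(C0, k, times, id = "oracle") {
  concentration_series(id, times, C0 * 10^(-k * times))
}
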