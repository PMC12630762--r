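# shared fixtures, built in code at test time

flat_bathy <- function(depth = 1300, half = 6000, cell = 100)
  generate_bathymetry("flat", list(depth = depth),
                      c(-half, half, -half, half), cell)

array_pair <- function(depth = 1300, separation = 1000, altitude = 6) {
  z <- -(depth - altitude)
  list(tetrahedral_array(c(-separation / 2, 0, z), array_id = "A"),
       tetrahedral_array(c(separation / 2, 0, z), array_id = "B"))
}

# straight constant-velocity track table
straight_track <- function(t, p0, v, depth0 = 1150, vz = 0) {
  data.frame(time = t,
             x = p0[1] + v[1] * t,
             y = p0[2] + v[2] * t,
             depth = depth0 + vz * t)
}

# from-scratch single-linkage clustering oracle: iteratively merge the two
# clusters with the smallest cross-pair distance while it is <= cutoff
single_linkage_oracle <- function(D, cutoff) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  repeat {
    if (length(groups) == 1L) break
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      d <- min(D[groups[[i]], groups[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    if (!is.finite(best[1]) || best[1] > cutoff) break
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# do two labelings describe the same partition?
same_partition <- function(a, b) {
  identical(outer(a, a, `==`), outer(b, b, `==`))
}
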