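# Brute-force neighbourhood average used as the independent oracle.
# axes: which data axes (of the voxel_major array) each kernel axis maps to.
oracle_weighted_mean <- function(D, weights, r, axes) {
  dm <- dim(D)
  out <- array(NA_real_, dm)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-r:r), length(axes))))
  for (i1 in seq_len(dm[1])) for (i2 in seq_len(dm[2]))
    for (i3 in seq_len(dm[3])) for (i4 in seq_len(dm[4])) {
      pos <- c(i1, i2, i3, i4)
      num <- 0; den <- 0
      for (k in seq_len(nrow(offsets))) {
        p <- pos
        p[axes] <- p[axes] + offsets[k, ]
        if (any(p < 1L) || any(p > dm)) next
        w <- weights[matrix(offsets[k, ] + r + 1L, nrow = 1)]
        num <- num + w * D[p[1], p[2], p[3], p[4]]
        den <- den + w
      }
      out[i1, i2, i3, i4] <- if (den > 0) num / den else D[i1, i2, i3, i4]
    }
  out
}
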