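# Independent reference implementations, deliberately naive: explicit
# double loops and direct formula evaluation. They never share code with
# the package paths they check.

oracle_pair_counts <- function(atoms, scheme = binning_scheme(),
                               min_res_sep = 1L) {
  typed <- type_protein_atoms(atoms)
  typed <- typed[!is.na(typed$type_index), ]
  counts <- array(0L, dim = c(167L, 167L, scheme$n_bins))
  n <- nrow(typed)
  if (n < 2L) return(counts)
  rkey <- paste(typed$chain_id, typed$residue_seq)
  rrank <- match(rkey, unique(rkey))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (abs(rrank[a] - rrank[b]) < min_res_sep) next
      r <- sqrt((typed$x[a] - typed$x[b])^2 + (typed$y[a] - typed$y[b])^2 +
                (typed$z[a] - typed$z[b])^2)
      if (r >= scheme$r_cut) next
      bb <- floor(r / scheme$delta_r) + 1L
      i <- typed$type_index[a]; j <- typed$type_index[b]
      counts[i, j, bb] <- counts[i, j, bb] + 1L
      counts[j, i, bb] <- counts[j, i, bb] + 1L
    }
  }
  counts
}

oracle_score <- function(receptor, pose, potential) {
  rec <- type_protein_atoms(receptor)
  rec <- rec[!is.na(rec$type_index), ]
  ty <- type_ligand_atoms(pose$sybyl)
  lig <- pose[ty$status == "typed", ]
  lidx <- ty$type_index[ty$status == "typed"]
  scheme <- potential$params$scheme
  e <- 0
  for (a in seq_len(nrow(rec))) {
    for (b in seq_len(nrow(lig))) {
      r <- sqrt((rec$x[a] - lig$x[b])^2 + (rec$y[a] - lig$y[b])^2 +
                (rec$z[a] - lig$z[b])^2)
      if (r < scheme$r_cut) {
        e <- e + potential$energies[rec$type_index[a], lidx[b],
                                    floor(r / scheme$delta_r) + 1L]
      }
    }
  }
  e
}

oracle_auc <- function(set) {
  a <- set$score[set$is_active]
  d <- set$score[!set$is_active]
  tot <- 0
  for (x in a) for (y in d) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(d))
}

# random rigid rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_atoms <- function(df, rot, shift) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
  df$x <- xyz[, 1] + shift[1]
  df$y <- xyz[, 2] + shift[2]
  df$z <- xyz[, 3] + shift[3]
  df
}
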