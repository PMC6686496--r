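#' Distance binning scheme
#'
#' Half-open shells `[b*delta_r, (b+1)*delta_r)` up to the cutoff; the
#' representative distance of a bin is its midpoint. Defaults are the
#' production values: 0.5 Angstrom shells to a 15 Angstrom cutoff (30
#' bins, last midpoint 14.75 Angstrom).
#'
#' @param delta_r Shell width in Angstrom.
#' @param r_cut Cutoff in Angstrom; must be an exact multiple of
#'   `delta_r`.
#' @return An object of class `binning_scheme` with fields `delta_r`,
#'   `r_cut`, `n_bins`, `midpoints`.
#' @export
binning_scheme <- function(delta_r = 0.5, r_cut = 15.0) {
  n_bins <- r_cut / delta_r
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop_dfire("r_cut must be an exact multiple of delta_r", "dfire_config")
  }
  n_bins <- as.integer(round(n_bins))
  structure(list(delta_r = delta_r, r_cut = r_cut, n_bins = n_bins,
                 midpoints = (seq_len(n_bins) - 0.5) * delta_r),
            class = "binning_scheme")
}

#' Map distances to shell indices
#'
#' @param r Numeric vector of distances (Angstrom), non-negative.
#' @param scheme A [binning_scheme()].
#' @return Integer bin indices in `1..n_bins`; `NA` for `r >= r_cut`
#'   (outside the potential's support).
#' @examples
#' bin_index(c(0.3, 14.999, 15), binning_scheme())
#' @export
bin_index <- function(r, scheme = binning_scheme()) {
  if (any(r < 0)) stop_dfire("distances must be non-negative", "dfire_domain")
  b <- as.integer(floor(r / scheme$delta_r)) + 1L
  b[r >= scheme$r_cut] <- NA_integer_
  b
}

#' Empty protein-protein pair-count table
#'
#' A 167 x 167 x `n_bins` integer histogram of inter-residue heavy-atom
#' pair counts, symmetric in the two type indices (each unordered pair is
#' stored in both orientations so the one-sided mol2 collapse is well
#' defined for every protein index).
#'
#' @param scheme A [binning_scheme()].
#' @return An object of class `pair_counts`.
#' @export
empty_counts <- function(scheme = binning_scheme()) {
  structure(list(
    counts = array(0L, dim = c(167L, 167L, scheme$n_bins)),
    scheme = scheme, n_chains = 0L, provenance = character()
  ), class = "pair_counts")
}

#' Accumulate pair counts from one protein chain
#'
#' Types the atoms with [type_protein_atoms()] (untypeable atoms are
#' skipped; their count is recorded in the `n_untypeable` attribute of
#' the result), then adds every unordered atom pair from residues at
#' least `min_res_sep` apart with distance below the cutoff, incrementing
#' both `(i,j,b)` and `(j,i,b)`. `min_res_sep = 1` (default) excludes
#' only intra-residue pairs. Distances are evaluated with a vectorized
#' all-pairs kernel; a double-loop reference is kept in the test suite.
#'
#' @param atoms Atom tibble (one chain) as from [read_pdb_chain()].
#' @param table A `pair_counts` to update; a fresh one by default.
#' @param min_res_sep Minimum |residue rank| separation for a pair to
#'   count (1 = different residues).
#' @param id Provenance label for this chain.
#' @return The updated `pair_counts` (counts, `n_chains`, provenance),
#'   with attribute `n_untypeable`.
#' @export
count_pairs <- function(atoms, table = empty_counts(), min_res_sep = 1L,
                        id = NULL) {
  stopifnot(inherits(table, "pair_counts"))
  scheme <- table$scheme
  typed <- type_protein_atoms(atoms)
  n_unty <- sum(is.na(typed$type_index))
  typed <- filter(typed, !is.na(.data$type_index))
  table$n_chains <- table$n_chains + 1L
  table$provenance <- c(table$provenance, id %||% paste0("chain", table$n_chains))
  attr(table, "n_untypeable") <- n_unty
  if (nrow(typed) < 2L) {
    return(table)
  }

  # residue rank in chain order, so min_res_sep acts on residue identity
  rkey <- paste(typed$chain_id, typed$residue_seq)
  rrank <- match(rkey, unique(rkey))

  xyz <- cbind(typed$x, typed$y, typed$z)
  d <- cross_dist(xyz, xyz)
  sep <- abs(outer(rrank, rrank, "-"))
  keep <- upper.tri(d) & sep >= min_res_sep & d < scheme$r_cut
  if (!any(keep)) {
    return(table)
  }
  pr <- which(keep, arr.ind = TRUE)
  i <- typed$type_index[pr[, 1]]
  j <- typed$type_index[pr[, 2]]
  b <- bin_index(d[keep], scheme)

  # symmetric double storage via linear-index tabulation
  li <- c(i + 167L * (j - 1L), j + 167L * (i - 1L)) +
    (167L * 167L) * rep(b - 1L, 2L)
  inc <- tabulate(li, nbins = 167L * 167L * scheme$n_bins)
  table$counts <- table$counts + array(as.integer(inc), dim = dim(table$counts))
  table
}

#' Merge pair-count tables
#'
#' Cell-wise integer sum; chain counts and provenance concatenate. All
#' tables must share one binning scheme. Order-independent.
#'
#' @param tables List of `pair_counts`.
#' @return A single `pair_counts`.
#' @export
merge_counts <- function(tables) {
  stopifnot(length(tables) >= 1L, all(vapply(tables, inherits, TRUE,
                                             "pair_counts")))
  s0 <- tables[[1]]$scheme
  same <- vapply(tables, function(t)
    isTRUE(all.equal(t$scheme, s0)), TRUE)
  if (!all(same)) stop_dfire("binning schemes differ", "dfire_config")
  out <- tables[[1]]
  for (t in tables[-1]) {
    out$counts <- out$counts + t$counts
    out$n_chains <- out$n_chains + t$n_chains
    out$provenance <- c(out$provenance, t$provenance)
  }
  out
}

#' Collapse protein-protein counts onto mol2 ligand types
#'
#' Sums the second type index over all protein types mapping to the same
#' mol2 type: `N'(i, k, b) = sum_j N(i, j, b) [map(j) = k]`. Integer
#' exact; for every `(i, b)` the collapsed row sums equal the full row
#' sums.
#'
#' @param table A `pair_counts`.
#' @param map A `type_map`.
#' @return An object of class `collapsed_counts` with a
#'   167 x 11 x `n_bins` `counts` array, the scheme, `n_chains` and the
#'   map hash.
#' @export
collapse_counts <- function(table, map = default_type_map()) {
  stopifnot(inherits(table, "pair_counts"))
  k_of_j <- collapse_index(1:167, map)
  z <- matrix(0L, 167L, 11L)
  z[cbind(1:167, k_of_j)] <- 1L
  nb <- table$scheme$n_bins
  out <- array(0L, dim = c(167L, 11L, nb))
  for (b in seq_len(nb)) {
    out[, , b] <- table$counts[, , b] %*% z
  }
  if (is.integer(table$counts) && max(out) <= .Machine$integer.max) {
    storage.mode(out) <- "integer"
  }
  structure(list(counts = out, scheme = table$scheme,
                 n_chains = table$n_chains, map_hash = map$hash),
            class = "collapsed_counts")
}

#' Build a collapsed-count table from a raw array
#'
#' Mostly useful for synthetic counts (e.g. multinomial draws from a
#' known potential) that enter [derive_potential()] without passing
#' through [count_pairs()]. Counts may be non-integer (expectations).
#'
#' @param counts Numeric array, 167 x 11 x `n_bins`, non-negative.
#' @param scheme A [binning_scheme()].
#' @param map_hash Optional type-map hash to stamp on the table.
#' @return A `collapsed_counts`.
#' @export
as_collapsed_counts <- function(counts, scheme = binning_scheme(),
                                map_hash = NULL) {
  stopifnot(is.array(counts),
            identical(dim(counts), c(167L, 11L, scheme$n_bins)),
            all(counts >= 0))
  structure(list(counts = counts, scheme = scheme, n_chains = NA_integer_,
                 map_hash = map_hash), class = "collapsed_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("<pair_counts> ", sum(x$counts), " stored pair observations from ",
      x$n_chains, " chain(s); ", x$scheme$n_bins, " bins to ",
      x$scheme$r_cut, " A\n", sep = "")
  invisible(x)
}

#' Tidy a pair-count table
#'
#' @param x A `pair_counts`.
#' @param ... Unused.
#' @return Sparse long tibble `i`, `j`, `bin`, `bin_mid`, `count`
#'   (nonzero cells only).
#' @export
tidy.pair_counts <- function(x, ...) {
  nz <- which(x$counts > 0L, arr.ind = TRUE)
  tibble(i = nz[, 1], j = nz[, 2], bin = nz[, 3],
         bin_mid = x$scheme$midpoints[nz[, 3]],
         count = x$counts[nz]) |>
    arrange(.data$i, .data$j, .data$bin)
}

.counts_header <- function(x) {
  c(paste0("# dfirescore pair counts v1"),
    sprintf("# delta_r=%.17g r_cut=%.17g n_bins=%d n_chains=%d",
            x$scheme$delta_r, x$scheme$r_cut, x$scheme$n_bins, x$n_chains),
    paste0("# provenance=", paste(x$provenance, collapse = ",")))
}

#' Write / read a pair-count table
#'
#' Plain-text sparse format: header comments carrying the scheme, chain
#' count and provenance, then `i j b count` lines for nonzero cells in
#' row-major order. `read_counts(write_counts(x))` is bit-exact.
#'
#' @param x A `pair_counts`.
#' @param path File path.
#' @return `write_counts`: `path` invisibly; `read_counts`: a
#'   `pair_counts`.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "pair_counts"))
  td <- tidy(x)
  writeLines(c(.counts_header(x),
               sprintf("%d %d %d %d", td$i, td$j, td$bin, td$count)), path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !startsWith(lines[1], "# dfirescore pair counts")) {
    stop_dfire(paste0("not a pair-counts file: ", path), "dfire_io")
  }
  hdr <- lines[2]
  num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[0-9eE.+-]+"), hdr))
    if (!length(m)) stop_dfire(paste0("header missing ", key), "dfire_io")
    as.numeric(sub(".*=", "", m))
  }
  scheme <- binning_scheme(num("delta_r"), num("r_cut"))
  n_chains <- as.integer(num("n_chains"))
  prov <- sub("# provenance=", "", lines[3], fixed = TRUE)
  prov <- if (nzchar(prov)) strsplit(prov, ",", fixed = TRUE)[[1]] else character()
  body <- lines[-(1:3)]
  out <- empty_counts(scheme)
  out$n_chains <- n_chains
  out$provenance <- prov
  if (length(body)) {
    m <- matrix(as.integer(unlist(strsplit(body, " ", fixed = TRUE))),
                ncol = 4L, byrow = TRUE)
    if (anyNA(m)) {
      stop_dfire(paste0("malformed count line near line ",
                        3L + which(is.na(m[, 1]))[1]), "dfire_io")
    }
    out$counts[m[, 1:3, drop = FALSE]] <- m[, 4]
  }
  out
}
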