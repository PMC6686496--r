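#' Parameters of the DFIRE potential derivation
#'
#' The reference state grows as `(r/r_cut)^alpha` with `alpha = 1.61`
#' rather than the ideal-gas `r^2`, compensating for the finite size of
#' folded molecules. Energies carry the overall factor `eta*R*T`; with
#' the production scaling `eta = 0.01/(R*T)` the stored energies are the
#' dimensionless scores `0.01 * log-odds`, so `eta_rt` is exposed
#' directly (default 0.01) and `T = 300 K` enters only through it.
#'
#' @param alpha Reference-state distance exponent (dimensionless).
#' @param delta_r,r_cut Binning, Angstrom (see [binning_scheme()]).
#' @param eta_rt The product eta*R*T multiplying the log-odds.
#' @param sigma Additive pseudo-count applied to observed and reference
#'   counts (low-count smoothing); `sigma = 0` recovers the uncorrected
#'   log-odds but is only valid when every needed count is positive.
#' @return An object of class `dfire_params`.
#' @export
dfire_params <- function(alpha = 1.61, delta_r = 0.5, r_cut = 15.0,
                         eta_rt = 0.01, sigma = 0.5) {
  stopifnot(alpha > 0, eta_rt > 0, sigma >= 0)
  structure(list(alpha = alpha, scheme = binning_scheme(delta_r, r_cut),
                 eta_rt = eta_rt, sigma = sigma),
            class = "dfire_params")
}

#' Reference-state expected counts
#'
#' For each protein type `i` and mol2 type `k`, the expected pair count
#' in bin `b` under no interaction:
#' `(r_b / r_last)^alpha * N'(i, k, last bin)`, with bin midpoints as
#' representative distances (the last midpoint stands for `r_cut`, which
#' pins the potential to zero at the cutoff bin). The shell-width ratio
#' is 1 since all bins share `delta_r`.
#'
#' @param collapsed A `collapsed_counts` (counts may be non-integer, e.g.
#'   synthetic expectations).
#' @param params A [dfire_params()].
#' @return Numeric array, same shape as `collapsed$counts`.
#' @export
reference_counts <- function(collapsed, params = dfire_params()) {
  stopifnot(inherits(collapsed, "collapsed_counts"))
  .check_scheme(collapsed, params)
  mids <- params$scheme$midpoints
  shape <- (mids / mids[length(mids)])^params$alpha
  nlast <- collapsed$counts[, , params$scheme$n_bins]
  outer(nlast, shape)   # [i, k, b]
}

.check_scheme <- function(collapsed, params) {
  s <- collapsed$scheme
  p <- params$scheme
  if (s$n_bins != p$n_bins || abs(s$delta_r - p$delta_r) > 1e-12 ||
      abs(s$r_cut - p$r_cut) > 1e-12) {
    stop_dfire("counts and params use different binning schemes",
               "dfire_config")
  }
}

#' Derive the DFIRE potential from collapsed counts
#'
#' The energy of protein type `i` against mol2 type `k` in shell `b` is
#' the smoothed log-odds of observed versus reference counts,
#'
#' `u(i,k,b) = -eta_rt * log( (N'(i,k,b) + sigma) / (ref(i,k,b) + sigma) )`
#'
#' for `b` below the cutoff and exactly 0 at and beyond it. With
#' `sigma > 0` the energy is finite everywhere and pairs with no
#' observations at all get identically zero energy. With `sigma = 0` any
#' zero observed or reference count is an error (the uncorrected
#' log-odds would diverge); the offending cell is named.
#'
#' @param collapsed A `collapsed_counts`.
#' @param params A [dfire_params()].
#' @return An object of class `dfire_potential`: `energies`
#'   (167 x 11 x `n_bins`, in `eta_rt` units), `params`, `map_hash`.
#' @export
derive_potential <- function(collapsed, params = dfire_params()) {
  stopifnot(inherits(collapsed, "collapsed_counts"))
  .check_scheme(collapsed, params)
  nb <- params$scheme$n_bins
  obs <- collapsed$counts
  ref <- reference_counts(collapsed, params)
  both_zero <- obs == 0 & ref == 0
  if (params$sigma == 0) {
    # pairs with no data anywhere are defined to zero energy; a single
    # zero against a positive partner would diverge without smoothing
    mixed <- (obs == 0 | ref == 0) & !both_zero
    if (any(mixed)) {
      cell <- which(mixed, arr.ind = TRUE)[1, ]
      stop_dfire(sprintf(
        "sigma = 0 with a zero count at (i=%d, k=%d, b=%d); use sigma > 0",
        cell[1], cell[2], cell[3]), "dfire_zero_count")
    }
  }
  u <- -params$eta_rt * log((obs + params$sigma) / (ref + params$sigma))
  u[both_zero] <- 0          # covers the 0/0 case when sigma = 0
  u[, , nb] <- 0     # boundary condition, exact
  structure(list(energies = u, params = params,
                 map_hash = collapsed$map_hash),
            class = "dfire_potential")
}

#' @export
print.dfire_potential <- function(x, ...) {
  p <- x$params
  cat("<dfire_potential> 167 x 11 x ", p$scheme$n_bins,
      " energies (eta_rt = ", p$eta_rt, ", alpha = ", p$alpha,
      ", sigma = ", p$sigma, ")\n", sep = "")
  invisible(x)
}

#' Tidy a derived potential
#'
#' @param x A `dfire_potential`.
#' @param ... Unused.
#' @return Long tibble `protein_type`, `ligand_type`, `bin`, `bin_mid`,
#'   `energy` over all cells, with readable type labels.
#' @export
tidy.dfire_potential <- function(x, ...) {
  ab <- protein_alphabet()
  lb <- ligand_alphabet()
  nb <- x$params$scheme$n_bins
  tibble(
    protein_type = rep(paste(ab$residue_name, ab$atom_name, sep = "."),
                       times = 11L * nb),
    ligand_type = rep(rep(lb$sybyl_name, each = 167L), times = nb),
    bin = rep(seq_len(nb), each = 167L * 11L),
    bin_mid = rep(x$params$scheme$midpoints, each = 167L * 11L),
    energy = as.vector(x$energies)
  )
}

#' @rdname tidy.dfire_potential
#' @param x A `dfire_potential`.
#' @return `glance`: one-row tibble of parameters and simple summaries.
#' @export
glance.dfire_potential <- function(x, ...) {
  tibble(alpha = x$params$alpha, delta_r = x$params$scheme$delta_r,
         r_cut = x$params$scheme$r_cut, eta_rt = x$params$eta_rt,
         sigma = x$params$sigma, n_bins = x$params$scheme$n_bins,
         n_nonzero = sum(x$energies != 0),
         min_energy = min(x$energies), max_energy = max(x$energies))
}

#' Plot distance profiles of a derived potential
#'
#' Draws `energy` against shell midpoint for chosen (protein type, mol2
#' type) pairs — the standard way to inspect how a residue-specific type
#' differentiates an interaction (e.g. `ASP.O` vs `ARG.O` against
#' `S.3`).
#'
#' @param object A `dfire_potential`.
#' @param protein_types Character vector like `"GLU.CB"`; default picks
#'   the two most attractive pairs.
#' @param ligand_types Character vector of mol2 type names, recycled
#'   against `protein_types`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dfire_potential <- function(object, protein_types = NULL,
                                     ligand_types = NULL, ...) {
  td <- tidy(object)
  if (is.null(protein_types)) {
    best <- td |> arrange(.data$energy) |>
      dplyr::distinct(.data$protein_type, .data$ligand_type) |> head(2)
    protein_types <- best$protein_type
    ligand_types <- best$ligand_type
  }
  sel <- tibble(protein_type = protein_types, ligand_type = ligand_types)
  td <- dplyr::inner_join(td, sel, by = c("protein_type", "ligand_type")) |>
    mutate(pair = paste(.data$protein_type, .data$ligand_type, sep = " : "))
  ggplot2::ggplot(td, ggplot2::aes(.data$bin_mid, .data$energy,
                                   colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "distance (Angstrom)",
                  y = "energy (eta*R*T units)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write / read a derived potential
#'
#' Text format: a header line
#' `# alpha=... r_cut=... delta_r=... etaRT=... sigma=... map_hash=...`
#' followed by `i k b energy` lines (nonzero cells, full precision).
#' Round-trips reproduce energies bit-exactly. On read, if a `type_map`
#' is supplied its hash must match the stored one.
#'
#' @param x A `dfire_potential`.
#' @param path File path.
#' @param map Optional `type_map` to validate against on read.
#' @return `write_potential`: `path` invisibly; `read_potential`: a
#'   `dfire_potential`.
#' @export
write_potential <- function(x, path) {
  stopifnot(inherits(x, "dfire_potential"))
  p <- x$params
  hdr <- sprintf(
    "# dfirescore potential v1 alpha=%.17g r_cut=%.17g delta_r=%.17g etaRT=%.17g sigma=%.17g map_hash=%s",
    p$alpha, p$scheme$r_cut, p$scheme$delta_r, p$eta_rt, p$sigma,
    x$map_hash %||% "none")
  nz <- which(x$energies != 0, arr.ind = TRUE)
  ord <- order(nz[, 1], nz[, 2], nz[, 3])
  nz <- nz[ord, , drop = FALSE]
  writeLines(c(hdr, sprintf("%d %d %d %.17g", nz[, 1], nz[, 2], nz[, 3],
                            x$energies[nz])), path)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path, map = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "# dfirescore potential")) {
    stop_dfire(paste0("not a potential file: ", path), "dfire_io")
  }
  hdr <- lines[1]
  get <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (!length(m)) stop_dfire(paste0("header missing ", key, " (line 1)"),
                               "dfire_io")
    sub(".*=", "", m)
  }
  params <- dfire_params(alpha = as.numeric(get("alpha")),
                         delta_r = as.numeric(get("delta_r")),
                         r_cut = as.numeric(get("r_cut")),
                         eta_rt = as.numeric(get("etaRT")),
                         sigma = as.numeric(get("sigma")))
  map_hash <- get("map_hash")
  if (!is.null(map) && !identical(map$hash, map_hash)) {
    stop_dfire("potential was derived under a different type map", "dfire_config")
  }
  u <- array(0, dim = c(167L, 11L, params$scheme$n_bins))
  body <- lines[-1]
  if (length(body)) {
    parts <- strsplit(body, " ", fixed = TRUE)
    bad <- which(lengths(parts) != 4L)
    if (length(bad)) {
      stop_dfire(paste0("malformed potential line ", bad[1] + 1L), "dfire_io")
    }
    m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
    idx <- cbind(as.integer(m[, 1]), as.integer(m[, 2]), as.integer(m[, 3]))
    if (anyNA(idx)) {
      stop_dfire(paste0("malformed potential line ",
                        which(is.na(idx[, 1]))[1] + 1L), "dfire_io")
    }
    u[idx] <- as.numeric(m[, 4])
  }
  structure(list(energies = u, params = params, map_hash = map_hash),
            class = "dfire_potential")
}
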