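#' Lorentz-Berthelot mixing of Lennard-Jones parameters
#'
#' Cross-interaction parameters between two bead types: geometric mean for
#' the well depth, arithmetic mean for the contact distance. Well depths are
#' mixed on magnitudes so either sign convention (positive well depth, or the
#' negative values CHARMM parameter files print) passes through unchanged.
#'
#' @param eps_i,eps_j Well depths, kcal/mol.
#' @param sigma_i,sigma_j Zero-crossing distances, Angstrom. Must be positive.
#' @return A tibble with columns `epsilon` and `sigma`.
#' @examples
#' lb_mix(1.0, 3.0, 4.0, 5.0)  # epsilon 2.0, sigma 4.0
#' @export
lb_mix <- function(eps_i, sigma_i, eps_j, sigma_j) {
  if (any(c(sigma_i, sigma_j) <= 0)) {
    abort("sigma values must be positive", class = "cgm_invalid_parameter")
  }
  sgn <- ifelse(sign(eps_i) < 0 | sign(eps_j) < 0, -1, 1)
  tibble(
    epsilon = sgn * sqrt(abs(eps_i) * abs(eps_j)),
    sigma   = (sigma_i + sigma_j) / 2
  )
}

#' Convert between the LJ minimum distance and sigma
#'
#' The 12-6 potential has its minimum at `r_min = 2^(1/6) * sigma`. First
#' peaks of mapped radial distribution functions estimate `r_min`, from which
#' `sigma` bounds for nonbonded optimization are derived.
#'
#' @param rmin,sigma Distances in Angstrom, positive.
#' @return A numeric vector.
#' @examples
#' rmin_to_sigma(2^(1/6))  # 1
#' sigma_to_rmin(4.95)     # 5.556
#' @export
rmin_to_sigma <- function(rmin) {
  if (any(rmin <= 0)) abort("rmin must be positive", class = "cgm_invalid_parameter")
  rmin / 2^(1 / 6)
}

#' @rdname rmin_to_sigma
#' @export
sigma_to_rmin <- function(sigma) {
  if (any(sigma <= 0)) abort("sigma must be positive", class = "cgm_invalid_parameter")
  sigma * 2^(1 / 6)
}

#' Lennard-Jones 12-6 pair energy
#'
#' @param r Pair distance, Angstrom (> 0).
#' @param eps Well depth, kcal/mol (positive convention).
#' @param sigma Zero crossing, Angstrom.
#' @param cutoff Optional truncation distance; energies beyond it are 0.
#' @param shift If `TRUE`, subtract the cutoff energy so the potential is
#'   continuous at the cutoff (plain truncation by default).
#' @return Energy in kcal/mol, vectorized over `r`.
#' @export
pair_lj_energy <- function(r, eps, sigma, cutoff = Inf, shift = FALSE) {
  if (any(r <= 0)) abort("r must be positive", class = "cgm_singular_geometry")
  sr6 <- (sigma / r)^6
  e <- 4 * eps * (sr6^2 - sr6)
  if (shift && is.finite(cutoff)) {
    sc6 <- (sigma / cutoff)^6
    e <- e - 4 * eps * (sc6^2 - sc6)
  }
  e[r >= cutoff] <- 0
  e
}

#' Construct a CG force field
#'
#' Holds the parameter tables of the harmonic-bond / harmonic-angle /
#' Lennard-Jones model: per-bead-type LJ self terms, explicit pair overrides,
#' bonded tables, the nonbonded exclusion policy and cutoff. Any bead pair
#' absent from `lj_pairs` resolves through Lorentz-Berthelot mixing of the
#' self terms. Harmonics use the CHARMM `K (x - x0)^2` convention (no 1/2);
#' `theta0` is stored in degrees, converted to radians internally.
#'
#' @param bead_types Tibble with columns `name`, `mass` (amu), `charge`
#'   (must be 0 for every bead), `epsilon` (kcal/mol, positive well depth),
#'   `sigma` (Angstrom), `arity` (atoms-per-bead class).
#' @param bonds Tibble with columns `i`, `j` (bead type names), `kb`
#'   (kcal/mol/A^2), `b0` (Angstrom).
#' @param angles Tibble with columns `i`, `j`, `k`, `ktheta`
#'   (kcal/mol/rad^2), `theta0` (degrees).
#' @param lj_pairs Optional tibble of explicit pair overrides: `i`, `j`,
#'   `epsilon`, `sigma`.
#' @param exclusion_policy `"exclude-1-2"` (directly bonded pairs only, the
#'   model's default) or `"exclude-1-3"` (also pairs joined by two bonds).
#' @param cutoff Nonbonded cutoff, Angstrom (default 12).
#' @param lj_shift Shift LJ energies to zero at the cutoff (default FALSE,
#'   plain truncation).
#' @return A `cg_forcefield` object.
#' @export
force_field <- function(bead_types, bonds = NULL, angles = NULL,
                        lj_pairs = NULL,
                        exclusion_policy = c("exclude-1-2", "exclude-1-3"),
                        cutoff = 12, lj_shift = FALSE) {
  exclusion_policy <- match.arg(exclusion_policy)
  bead_types <- as_tibble(bead_types)
  stopifnot(all(c("name", "mass", "epsilon", "sigma") %in% names(bead_types)))
  if (!"charge" %in% names(bead_types)) bead_types$charge <- 0
  if (!"arity" %in% names(bead_types)) bead_types$arity <- NA_integer_
  if (any(bead_types$charge != 0)) {
    abort("all CG beads carry zero charge in this model", class = "cgm_invalid_parameter")
  }
  if (any(bead_types$sigma <= 0) || any(bead_types$mass <= 0)) {
    abort("bead sigma and mass must be positive", class = "cgm_invalid_parameter")
  }
  empty_bond <- tibble(i = character(), j = character(),
                       kb = numeric(), b0 = numeric())
  empty_ang <- tibble(i = character(), j = character(), k = character(),
                      ktheta = numeric(), theta0 = numeric())
  empty_pair <- tibble(i = character(), j = character(),
                       epsilon = numeric(), sigma = numeric())
  ff <- structure(
    list(
      bead_types = bead_types,
      bonds = if (is.null(bonds)) empty_bond else as_tibble(bonds),
      angles = if (is.null(angles)) empty_ang else as_tibble(angles),
      lj_pairs = if (is.null(lj_pairs)) empty_pair else as_tibble(lj_pairs),
      exclusion_policy = exclusion_policy,
      cutoff = cutoff,
      lj_shift = lj_shift
    ),
    class = "cg_forcefield"
  )
  if (cutoff <= max(bead_types$sigma)) {
    warn("cutoff does not exceed the largest sigma; nonbonded shells are truncated inside contact")
  }
  ff
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat("<cg_forcefield> ", nrow(x$bead_types), " bead types, ",
      nrow(x$bonds), " bond types, ", nrow(x$angles), " angle types, ",
      nrow(x$lj_pairs), " explicit LJ pairs\n", sep = "")
  cat("  exclusion: ", x$exclusion_policy, ", cutoff ", x$cutoff, " A",
      if (x$lj_shift) ", shifted LJ" else ", truncated LJ", "\n", sep = "")
  invisible(x)
}

# Order-insensitive pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Resolve the full LJ pair tables of a force field
#'
#' Expands self terms through Lorentz-Berthelot mixing and applies explicit
#' pair overrides, returning dense matrices indexed by bead type.
#'
#' @param ff A `cg_forcefield`.
#' @return List with `types` (name vector), `eps` and `sigma` matrices.
#' @export
lj_tables <- function(ff) {
  tn <- ff$bead_types$name
  nt <- length(tn)
  eps <- outer(ff$bead_types$epsilon, ff$bead_types$epsilon,
               function(a, b) sqrt(a * b))
  sig <- outer(ff$bead_types$sigma, ff$bead_types$sigma, function(a, b) (a + b) / 2)
  dimnames(eps) <- dimnames(sig) <- list(tn, tn)
  if (nrow(ff$lj_pairs)) {
    for (r in seq_len(nrow(ff$lj_pairs))) {
      i <- ff$lj_pairs$i[r]; j <- ff$lj_pairs$j[r]
      if (!(i %in% tn) || !(j %in% tn)) {
        abort(paste0("explicit LJ pair references unknown bead type: ", i, "-", j),
              class = "cgm_missing_parameter")
      }
      eps[i, j] <- eps[j, i] <- abs(ff$lj_pairs$epsilon[r])
      sig[i, j] <- sig[j, i] <- ff$lj_pairs$sigma[r]
    }
  }
  list(types = tn, eps = eps, sigma = sig)
}

lookup_bond <- function(ff, a, b) {
  key <- pair_key(a, b)
  have <- pair_key(ff$bonds$i, ff$bonds$j)
  idx <- match(key, have)
  if (anyNA(idx)) {
    abort(paste0("missing bond parameter for type pair ",
                 paste(unique(paste0(a, "-", b)[is.na(idx)]), collapse = ", ")),
          class = "cgm_missing_parameter")
  }
  ff$bonds[idx, ]
}

lookup_angle <- function(ff, a, b, c) {
  # order-insensitive in the outer beads
  key  <- paste(pmin(a, c), b, pmax(a, c), sep = "|")
  have <- paste(pmin(ff$angles$i, ff$angles$k), ff$angles$j,
                pmax(ff$angles$i, ff$angles$k), sep = "|")
  idx <- match(key, have)
  if (anyNA(idx)) {
    abort(paste0("missing angle parameter for type triple ",
                 paste(unique(paste0(a, "-", b, "-", c)[is.na(idx)]), collapse = ", ")),
          class = "cgm_missing_parameter")
  }
  ff$angles[idx, ]
}

#' Nonbonded exclusion pairs of a bonded topology
#'
#' Under `"exclude-1-2"` only directly bonded pairs are excluded from
#' nonbonded interactions, so beads joined through an angle (1-3 pairs) still
#' feel van der Waals forces; `"exclude-1-3"` additionally removes every pair
#' connected by a two-bond path.
#'
#' @param bonds Integer matrix/data frame of bead index pairs (1-based,
#'   within one molecule), or a `cg_template`.
#' @param policy `"exclude-1-2"` or `"exclude-1-3"`.
#' @return Tibble of excluded pairs `i < j`.
#' @export
build_exclusions <- function(bonds, policy = c("exclude-1-2", "exclude-1-3")) {
  policy <- match.arg(policy)
  if (inherits(bonds, "cg_template")) bonds <- bonds$bonds
  bonds <- as.matrix(bonds)
  if (!nrow(bonds)) return(tibble(i = integer(), j = integer()))
  storage.mode(bonds) <- "integer"
  ex <- tibble(i = pmin(bonds[, 1], bonds[, 2]),
               j = pmax(bonds[, 1], bonds[, 2]))
  if (policy == "exclude-1-3") {
    adj <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
    one3 <- list()
    for (ctr in names(adj)) {
      nb <- sort(unique(adj[[ctr]]))
      if (length(nb) >= 2) {
        cmb <- utils::combn(nb, 2)
        one3[[ctr]] <- tibble(i = cmb[1, ], j = cmb[2, ])
      }
    }
    ex <- dplyr::bind_rows(ex, dplyr::bind_rows(one3))
  }
  dplyr::distinct(ex)
}

#' Packaged synthetic CG lipid parameter set
#'
#' Loads the parameter file shipped with the package
#' (`extdata/cg_lipid_synthetic.prm`): a synthetic, best-effort parameter
#' set for the packaged bead library in the CHARMM/NAMD dialect, suitable
#' for demos and toy simulations. It is not an optimized production force
#' field.
#'
#' @param exclusion_policy,cutoff Passed to [read_ff_prm()].
#' @return A `cg_forcefield`.
#' @export
default_forcefield <- function(exclusion_policy = "exclude-1-2", cutoff = 12) {
  read_ff_prm(system.file("extdata", "cg_lipid_synthetic.prm",
                          package = "cgmembrane"),
              exclusion_policy = exclusion_policy, cutoff = cutoff)
}
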