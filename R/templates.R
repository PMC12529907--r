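# CG bead library and phosphatidylcholine lipid templates.
#
# The mapping groups 2-4 heavy atoms (plus their hydrogens) per bead:
#   CHO  choline N(CH3)3 + CH2           (4:1)
#   PO2  phosphate P + two ester oxygens (3:1)
#   COH  glycerol CH2-CH-CH2 backbone    (3:1)
#   MTF  ester C(=O)O + alpha carbon     (4:1, one per acyl chain)
#   C3M / C2M  mid-chain runs of 3 / 2 saturated carbons
#   D3M  3-carbon segment containing a cis double bond
#   C3E / C2E  terminal 3- / 2-carbon segment including the methyl end
#   W    water bead, two H2O molecules   (2:1)

MASS_CH2 <- 14.0266
MASS_CH3 <- 15.0345
MASS_CH  <- 13.0186
MASS_H2O <- 18.0153

#' Standard CG bead types
#'
#' The bead-type table of the phosphocholine CG model: masses are sums of the
#' mapped atom masses (hydrogens included), charges are identically zero, and
#' the LJ self terms are placeholders to be filled by a parameter file or by
#' optimization.
#'
#' @param epsilon,sigma Default LJ self terms applied to every bead type
#'   (well depth kcal/mol, contact distance Angstrom); a loaded or optimized
#'   parameter set normally overrides these.
#' @return Tibble with columns `name`, `mass`, `charge`, `epsilon`, `sigma`,
#'   `arity`.
#' @export
cg_bead_types <- function(epsilon = 0.5, sigma = 4.5) {
  tibble(
    name   = c("CHO", "PO2", "COH", "MTF", "C3M", "C2M", "D3M", "C3E", "C2E", "W"),
    mass   = c(3 * MASS_CH3 + MASS_CH2 + 14.0067,       # N(CH3)3-CH2
               30.9738 + 2 * 15.9994,                   # P + 2 O
               2 * MASS_CH2 + MASS_CH,                  # glycerol CH2-CH-CH2
               12.011 + 15.9994 + 15.9994 + MASS_CH2,   # C(=O)-O + CH2
               3 * MASS_CH2,
               2 * MASS_CH2,
               2 * MASS_CH + MASS_CH2,                  # CH=CH + CH2
               2 * MASS_CH2 + MASS_CH3,
               MASS_CH2 + MASS_CH3,
               2 * MASS_H2O),
    charge = 0,
    epsilon = epsilon,
    sigma   = sigma,
    arity  = c(4L, 3L, 3L, 4L, 3L, 2L, 3L, 3L, 2L, 2L)
  )
}

# Systematic atom naming for the synthetic all-atom reference used by the
# mapping fixtures: each heavy atom "X<n>" carries hydrogens "HX<n>A/B/C".
chain_beads <- function(n_carbons, double_bond = NULL) {
  # Partition an acyl chain (carbons after the two ester-bead carbons) into
  # 3-carbon mid beads, 2-carbon filler and a terminal bead with the methyl.
  stopifnot(n_carbons >= 4)
  segs <- list()
  remaining <- n_carbons
  pos <- 1L
  while (remaining > 0) {
    if (remaining %in% c(3L, 2L)) {          # terminal bead
      take <- remaining
      type <- if (take == 3L) "C3E" else "C2E"
    } else if (remaining == 4L) {            # avoid leaving a 1-carbon tail
      take <- 2L; type <- "C2M"
    } else {
      take <- 3L; type <- "C3M"
    }
    carbons <- pos:(pos + take - 1L)
    if (!is.null(double_bond) && any(double_bond %in% carbons)) type <- "D3M"
    segs[[length(segs) + 1L]] <- list(type = type, carbons = carbons)
    pos <- pos + take
    remaining <- remaining - take
  }
  segs
}

acyl_atoms <- function(prefix, carbons, terminal) {
  atoms <- character(0)
  for (c_i in carbons) {
    nm <- paste0("C", prefix, c_i)
    nh <- if (terminal && c_i == max(carbons)) 3L else 2L
    atoms <- c(atoms, nm, paste0("H", prefix, c_i, LETTERS[seq_len(nh)]))
  }
  atoms
}

#' Build a phosphatidylcholine CG lipid template
#'
#' Constructs the ordered bead list, bond graph, angle list, per-bead atom
#' groups of the synthetic all-atom naming scheme, head bead indices (PO2 and
#' CHO) and per-tail definitions for a PC lipid with the given acyl chains.
#'
#' @param name Lipid identifier, e.g. `"DOPC"`.
#' @param sn1,sn2 Acyl chain specs: list with `n` (total carbons including
#'   the carbonyl carbon) and optional `db` (1-based positions, counted from
#'   the carbonyl, of double-bonded carbons).
#' @return A `cg_template` object.
#' @export
pc_lipid_template <- function(name, sn1, sn2 = sn1) {
  beads <- tibble(
    bead = c("CHO", "PO2", "COH"),
    atoms = list(
      c("N", "C13", "H13A", "H13B", "H13C", "C14", "H14A", "H14B", "H14C",
        "C15", "H15A", "H15B", "H15C", "C12", "H12A", "H12B"),
      c("P", "O13", "O14"),
      c("C1", "H1A", "H1B", "C2", "H2", "C3", "H3A", "H3B")
    )
  )
  bonds <- matrix(c(1L, 2L, 2L, 3L), ncol = 2, byrow = TRUE)
  tails <- list()
  for (t in 1:2) {
    spec <- if (t == 1) sn1 else sn2
    prefix <- if (t == 1) "3" else "2"
    mtf_idx <- nrow(beads) + 1L
    beads <- dplyr::bind_rows(beads, tibble(
      bead = "MTF",
      atoms = list(c(paste0("C", prefix, 1), paste0("O", prefix, 1),
                     paste0("O", prefix, 2), paste0("C", prefix, 2),
                     paste0("H", prefix, 2, c("A", "B"))))
    ))
    bonds <- rbind(bonds, c(3L, mtf_idx))
    # chain carbons after the two carbons held by MTF
    nc <- spec$n - 2L
    db <- if (!is.null(spec$db)) spec$db - 2L else NULL
    segs <- chain_beads(nc, db)
    prev <- mtf_idx
    for (si in seq_along(segs)) {
      seg <- segs[[si]]
      idx <- nrow(beads) + 1L
      terminal <- si == length(segs)
      beads <- dplyr::bind_rows(beads, tibble(
        bead = seg$type,
        atoms = list(acyl_atoms(prefix, seg$carbons + 2L, terminal))
      ))
      bonds <- rbind(bonds, c(prev, idx))
      prev <- idx
    }
    tails[[t]] <- c(first = mtf_idx + 1L, last = prev)
  }
  # angles: every bonded path i-j-k
  adj <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
  angles <- list()
  for (ctr in as.integer(names(adj))) {
    nb <- sort(unique(adj[[as.character(ctr)]]))
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      angles[[length(angles) + 1L]] <-
        cbind(cmb[1, ], rep.int(ctr, ncol(cmb)), cmb[2, ])
    }
  }
  angles <- do.call(rbind, angles)
  structure(
    list(
      name = name,
      beads = beads$bead,
      atom_groups = setNames(beads$atoms, paste0(beads$bead, seq_along(beads$bead))),
      bonds = unname(bonds),
      angles = unname(angles),
      head_beads = c(PO2 = 2L, CHO = 1L),
      tails = tails
    ),
    class = "cg_template"
  )
}

#' @export
print.cg_template <- function(x, ...) {
  cat("<cg_template> ", x$name, ": ", length(x$beads), " beads (",
      paste(x$beads, collapse = "-"), "), ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles\n", sep = "")
  invisible(x)
}

#' Built-in PC lipid templates
#'
#' Templates for the lipids of the CG model family: the development set
#' (DOPC, POPC, DMPC) and the transferability set (DLPC, DPPC, DSPC, SOPC).
#'
#' @param name Lipid identifier.
#' @return A `cg_template`.
#' @examples
#' cg_lipid_template("DMPC")
#' @export
cg_lipid_template <- function(name = c("DOPC", "POPC", "DMPC", "DLPC",
                                       "DPPC", "DSPC", "SOPC")) {
  name <- match.arg(name)
  oleoyl    <- list(n = 18L, db = c(9L, 10L))
  palmitoyl <- list(n = 16L)
  myristoyl <- list(n = 14L)
  lauroyl   <- list(n = 12L)
  stearoyl  <- list(n = 18L)
  switch(name,
    DOPC = pc_lipid_template("DOPC", oleoyl, oleoyl),
    POPC = pc_lipid_template("POPC", palmitoyl, oleoyl),
    DMPC = pc_lipid_template("DMPC", myristoyl, myristoyl),
    DLPC = pc_lipid_template("DLPC", lauroyl, lauroyl),
    DPPC = pc_lipid_template("DPPC", palmitoyl, palmitoyl),
    DSPC = pc_lipid_template("DSPC", stearoyl, stearoyl),
    SOPC = pc_lipid_template("SOPC", stearoyl, oleoyl)
  )
}

#' Validate a CG template
#'
#' Checks the structural invariants: connected bond graph, every angle's
#' outer beads bonded to its center, and bead types known to the bead table.
#'
#' @param template A `cg_template`.
#' @param bead_types Optional bead-type table to check names against.
#' @return `TRUE` invisibly; aborts on violation.
#' @export
validate_template <- function(template, bead_types = cg_bead_types()) {
  n <- length(template$beads)
  stopifnot(n >= 1)
  if (!all(template$beads %in% bead_types$name)) {
    abort(paste0("unknown bead types: ",
                 paste(setdiff(template$beads, bead_types$name), collapse = ", ")),
          class = "cgm_invalid_parameter")
  }
  # connectivity by breadth-first search
  if (n > 1) {
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (r in seq_len(nrow(template$bonds))) {
      i <- template$bonds[r, 1]; j <- template$bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (!all(seen)) abort("bond graph is not connected", class = "cgm_invalid_parameter")
  }
  if (!is.null(template$angles) && nrow(template$angles)) {
    bk <- pair_key(template$bonds[, 1], template$bonds[, 2])
    ok <- pair_key(template$angles[, 1], template$angles[, 2]) %in% bk &
      pair_key(template$angles[, 2], template$angles[, 3]) %in% bk
    if (!all(ok)) abort("angle outer beads must be bonded to the center",
                        class = "cgm_invalid_parameter")
  }
  invisible(TRUE)
}

#' Mass of a template's beads
#'
#' @param template A `cg_template`.
#' @param bead_types Bead table supplying per-type masses.
#' @return Numeric vector of per-bead masses (amu).
#' @export
template_masses <- function(template, bead_types = cg_bead_types()) {
  bead_types$mass[match(template$beads, bead_types$name)]
}
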