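# Shared fixtures and independent brute-force oracles. The oracles are
# written in plain R with their own geometry code so they stay independent
# of the compiled implementation they check.

library(tibble)

# --- toy templates ---------------------------------------------------------

toy_template <- function(n_beads = 3, bead = "C3M", name = "TOY") {
  bonds <- if (n_beads > 1) cbind(1:(n_beads - 1), 2:n_beads) else
    matrix(integer(), 0, 2)
  angles <- if (n_beads > 2) cbind(1:(n_beads - 2), 2:(n_beads - 1), 3:n_beads) else
    matrix(integer(), 0, 3)
  structure(list(
    name = name, beads = rep(bead, n_beads),
    atom_groups = replicate(n_beads, c("C1", "C2"), simplify = FALSE),
    bonds = bonds, angles = angles,
    head_beads = c(PO2 = 1L, CHO = 1L),
    tails = list(c(first = 1L, last = n_beads))
  ), class = "cg_template")
}

toy_ff <- function(eps = 0.5, sigma = 4, kb = 5, b0 = 3, ktheta = 2,
                   theta0 = 150, cutoff = 12, policy = "exclude-1-2",
                   shift = FALSE) {
  bt <- cg_bead_types(epsilon = eps, sigma = sigma)
  force_field(
    bt,
    bonds = tibble(i = "C3M", j = "C3M", kb = kb, b0 = b0),
    angles = tibble(i = "C3M", j = "C3M", k = "C3M",
                    ktheta = ktheta, theta0 = theta0),
    exclusion_policy = policy, cutoff = cutoff, lj_shift = shift
  )
}

# Random configuration of n_mol chain molecules in a cubic box
random_chain_config <- function(n_mol = 5, n_beads = 4, L = 50, seed = 1,
                                tpl = toy_template(4)) {
  set.seed(seed)
  rows <- lapply(seq_len(n_mol), function(m) {
    origin <- runif(3, 10, L - 10)
    step <- matrix(rnorm(3 * length(tpl$beads), 0, 1.5),
                   length(tpl$beads), 3)
    xyz <- apply(step, 2, cumsum) + matrix(origin, length(tpl$beads), 3,
                                           byrow = TRUE)
    tibble(bead = tpl$beads, molecule = m, template = tpl$name,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  cg_configuration(dplyr::bind_rows(rows), c(L, L, L),
                   setNames(list(tpl), tpl$name))
}

# --- independent oracles ---------------------------------------------------

min_image_r <- function(d, box) d - box * round(d / box)

# Brute-force energy oracle: plain R double loops, own exclusion logic.
oracle_energy <- function(config, ff) {
  b <- config$beads
  xyz <- as.matrix(b[, c("x", "y", "z")])
  box <- config$box
  tabs <- lj_tables(ff)
  n <- nrow(b)
  excl <- matrix(FALSE, n, n)
  e_bond <- 0; e_angle <- 0
  for (mol in split(seq_len(n), b$molecule)) {
    tpl <- config$templates[[b$template[mol[1]]]]
    if (is.null(tpl)) next
    nm <- tpl$beads
    bd <- tpl$bonds
    for (r in seq_len(nrow(bd))) {
      i <- mol[bd[r, 1]]; j <- mol[bd[r, 2]]
      excl[i, j] <- excl[j, i] <- TRUE
      p <- ff$bonds[match(paste(pmin(nm[bd[r, 1]], nm[bd[r, 2]]),
                                pmax(nm[bd[r, 1]], nm[bd[r, 2]])),
                          paste(pmin(ff$bonds$i, ff$bonds$j),
                                pmax(ff$bonds$i, ff$bonds$j))), ]
      d <- sqrt(sum(min_image_r(xyz[i, ] - xyz[j, ], box)^2))
      e_bond <- e_bond + p$kb * (d - p$b0)^2
    }
    an <- tpl$angles
    for (r in seq_len(nrow(an))) {
      i <- mol[an[r, 1]]; j <- mol[an[r, 2]]; k <- mol[an[r, 3]]
      if (ff$exclusion_policy == "exclude-1-3") {
        excl[i, k] <- excl[k, i] <- TRUE
      }
      key <- paste(pmin(nm[an[r, 1]], nm[an[r, 3]]), nm[an[r, 2]],
                   pmax(nm[an[r, 1]], nm[an[r, 3]]))
      have <- paste(pmin(ff$angles$i, ff$angles$k), ff$angles$j,
                    pmax(ff$angles$i, ff$angles$k))
      p <- ff$angles[match(key, have), ]
      v1 <- min_image_r(xyz[i, ] - xyz[j, ], box)
      v2 <- min_image_r(xyz[k, ] - xyz[j, ], box)
      th <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
      e_angle <- e_angle + p$ktheta * (th - p$theta0 * pi / 180)^2
    }
  }
  e_lj <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (excl[i, j]) next
      r <- sqrt(sum(min_image_r(xyz[i, ] - xyz[j, ], box)^2))
      if (r >= ff$cutoff) next
      eps <- tabs$eps[b$bead[i], b$bead[j]]
      sg <- tabs$sigma[b$bead[i], b$bead[j]]
      e <- 4 * eps * ((sg / r)^12 - (sg / r)^6)
      if (ff$lj_shift) {
        e <- e - 4 * eps * ((sg / ff$cutoff)^12 - (sg / ff$cutoff)^6)
      }
      e_lj <- e_lj + e
    }
  }
  c(bond = e_bond, angle = e_angle, lj = e_lj, total = e_bond + e_angle + e_lj)
}

# Mass-weighted centroid oracle
oracle_centroid <- function(xyz, mass) colSums(xyz * mass) / sum(mass)

# Exhaustive minimum-weight perfect matching oracle (n <= 8, even)
oracle_best_matching <- function(xyz, box) {
  n <- nrow(xyz)
  stopifnot(n %% 2 == 0)
  dmat <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dmat[i, j] <- sqrt(sum(min_image_r(xyz[i, ] - xyz[j, ], box)^2))
  }
  best <- Inf
  rec <- function(avail, acc) {
    if (!length(avail)) { best <<- min(best, acc); return() }
    i <- avail[1]
    for (j in avail[-1]) {
      rec(setdiff(avail, c(i, j)), acc + dmat[i, j])
    }
  }
  rec(1:n, 0)
  best
}

# Brute-force RDF oracle (same-molecule pairs excluded)
oracle_rdf <- function(config, sel, dr, rmax) {
  b <- config$beads
  idx <- which(b$bead == sel)
  xyz <- as.matrix(b[, c("x", "y", "z")])
  edges <- seq(0, rmax, by = dr)
  cnt <- numeric(length(edges) - 1)
  for (i in idx) for (j in idx) {
    if (i >= j) next
    if (b$molecule[i] == b$molecule[j]) next
    r <- sqrt(sum(min_image_r(xyz[i, ] - xyz[j, ], config$box)^2))
    if (r < rmax) cnt[findInterval(r, edges)] <- cnt[findInterval(r, edges)] + 1
  }
  V <- prod(config$box)
  nA <- length(idx)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  2 * cnt / (nA * (nA - 1) / V * shell)
}

# Analytic second moment of the truncated splay density by quadrature
oracle_splay_moment2 <- function(kappa, area_A2) {
  a <- kappa * (area_A2 / 100) / 2
  num <- integrate(function(s) s^2 * exp(-a * s^2), 0, pi / 2,
                   rel.tol = 1e-12)$value
  den <- integrate(function(s) exp(-a * s^2), 0, pi / 2, rel.tol = 1e-12)$value
  num / den
}

# Partial correlation from the precision matrix of a joint Gaussian
oracle_pcc_precision <- function(Sigma, j, y_idx) {
  Om <- solve(Sigma)
  -Om[j, y_idx] / sqrt(Om[j, j] * Om[y_idx, y_idx])
}
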