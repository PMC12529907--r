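# Center-of-mass mapping of all-atom structures and 2:1 water pairing.

make_two_atom_frame <- function(xyz, mass, box = c(50, 50, 50)) {
  atom_frame(tibble(name = c("C1", "C2"), mass = mass, residue = 1L,
                    resname = "TOY", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
             box)
}

one_bead_template <- structure(list(
  name = "TOY", beads = "C3M", atom_groups = list(c("C1", "C2")),
  bonds = matrix(integer(), 0, 2), angles = matrix(integer(), 0, 3),
  head_beads = c(PO2 = 1L, CHO = 1L), tails = list(c(first = 1L, last = 1L))
), class = "cg_template")

test_that("beads sit at the mass-weighted centroid of their atom group", {
  fr <- make_two_atom_frame(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1))
  cfg <- map_structure(fr, one_bead_template)
  expect_equal(c(cfg$beads$x, cfg$beads$y, cfg$beads$z), c(1, 0, 0))

  fr <- make_two_atom_frame(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 3))
  cfg <- map_structure(fr, one_bead_template)
  expect_equal(cfg$beads$x, 3)
})

test_that("mapping matches an independent centroid oracle on a toy residue set", {
  set.seed(21)
  tpl <- toy_template(3)
  rows <- list()
  for (res in 1:3) {
    for (b in 1:3) {
      rows[[length(rows) + 1L]] <- tibble(
        name = c("C1", "C2"), mass = c(12, 2), residue = res, resname = "TOY",
        x = rnorm(2, res * 5), y = rnorm(2), z = rnorm(2)
      )
    }
  }
  # 3 beads per residue need distinct atom names per group
  atoms <- dplyr::bind_rows(rows)
  atoms$name <- paste0(atoms$name, rep(rep(1:3, each = 2), times = 3))
  tpl$atom_groups <- list(c("C11", "C21"), c("C12", "C22"), c("C13", "C23"))
  fr <- atom_frame(atoms, c(100, 100, 100))
  cfg <- map_structure(fr, tpl)
  for (res in 1:3) {
    sub <- atoms[atoms$residue == res, ]
    for (b in 1:3) {
      grp <- sub[sub$name %in% tpl$atom_groups[[b]], ]
      want <- oracle_centroid(as.matrix(grp[, c("x", "y", "z")]), grp$mass)
      got <- unlist(cfg$beads[cfg$beads$molecule == res, c("x", "y", "z")][b, ])
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
    }
  }
})

test_that("mapping conserves mass and commutes with rigid translation", {
  cfg0 <- build_bilayer(4, 64, 34, cg_lipid_template("DMPC"), seed = 5)
  fr <- explode_to_atoms(cfg0, seed = 5)
  # mass conservation: per-residue atom mass equals the template bead mass sum
  tpl <- cg_lipid_template("DMPC")
  want_mass <- sum(template_masses(tpl))
  for (res in split(fr$atoms, fr$atoms$residue)) {
    expect_equal(sum(res$mass), want_mass, tolerance = 1e-9)
  }
  mapped <- map_structure(fr, tpl)
  shift <- c(3.2, -1.1, 7.9)
  at2 <- fr$atoms
  at2$x <- at2$x + shift[1]; at2$y <- at2$y + shift[2]; at2$z <- at2$z + shift[3]
  mapped2 <- map_structure(atom_frame(at2, fr$box), tpl)
  expect_equal(mapped2$beads$x, mapped$beads$x + shift[1], tolerance = 1e-9)
  expect_equal(mapped2$beads$z, mapped$beads$z + shift[3], tolerance = 1e-9)
})

test_that("a missing atom in a group names the residue, bead and atom", {
  fr <- make_two_atom_frame(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1))
  tpl <- one_bead_template
  tpl$atom_groups <- list(c("C1", "CX"))
  expect_error(map_structure(fr, tpl), "CX", class = "cgm_mapping_error")
})

test_that("trajectory mapping applies the structure mapping frame by frame", {
  cfg0 <- build_bilayer(4, 64, 34, cg_lipid_template("DMPC"), seed = 2)
  frames <- lapply(1:4, function(i) explode_to_atoms(cfg0, seed = i))
  traj <- map_trajectory(frames, cg_lipid_template("DMPC"),
                         times_ns = c(0, 0.1, 0.2, 0.3))
  expect_equal(n_frames(traj), 4)
  expect_equal(traj$frames$time_ns, c(0, 0.1, 0.2, 0.3))
  for (i in c(1, 3)) {
    solo <- map_structure(frames[[i]], cg_lipid_template("DMPC"))
    fr <- get_frame(traj, i)
    expect_equal(fr$beads$x, solo$beads$x, tolerance = 1e-12)
  }
  # inconsistent topology across frames is a format error
  bad <- frames
  bad[[2]]$atoms <- bad[[2]]$atoms[-1, ]
  expect_error(map_trajectory(bad, cg_lipid_template("DMPC")),
               class = "cgm_format_error")
})

test_that("water pairing picks closest pairs and handles odd counts", {
  box <- c(50, 50, 50)
  # 2 waters -> midpoint bead
  w <- pair_waters(rbind(c(0, 0, 0), c(1, 0, 0)), box)
  expect_equal(unlist(w$beads), c(x = 0.5, y = 0, z = 0))
  # two tight, well-separated pairs: never the cross pairing
  xyz <- rbind(c(1, 1, 1), c(1.8, 1, 1), c(20, 20, 20), c(20, 20.7, 20))
  w <- pair_waters(xyz, box)
  got <- apply(w$pairs, 1, function(p) paste(sort(p), collapse = "-"))
  expect_setequal(got, c("1-2", "3-4"))
  # odd count: one unpaired with a warning
  expect_warning(w3 <- pair_waters(xyz[1:3, ], box))
  expect_equal(nrow(w3$beads), 1)
  expect_length(w3$unpaired, 1)
  expect_equal(nrow(pair_waters(matrix(numeric(), 0, 3), box)$beads), 0)
})

test_that("greedy pairing stays within 2x of the optimal matching (n <= 8)", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(c(4, 6, 8), 1)
    box <- c(12, 12, 12)
    xyz <- matrix(runif(3 * n, 0, 12), n, 3)
    w <- pair_waters(xyz, box)
    greedy_total <- sum(vapply(seq_len(nrow(w$pairs)), function(r) {
      sqrt(sum(min_image_r(xyz[w$pairs[r, 1], ] - xyz[w$pairs[r, 2], ], box)^2))
    }, 1.0))
    expect_lte(greedy_total, 2 * oracle_best_matching(xyz, box) + 1e-9)
  }
})

test_that("water pairing respects periodic images", {
  box <- c(10, 10, 10)
  # closest partner only through the boundary
  xyz <- rbind(c(0.4, 5, 5), c(9.8, 5, 5), c(5, 2, 5), c(5, 3, 5))
  w <- pair_waters(xyz, box)
  got <- apply(w$pairs, 1, function(p) paste(sort(p), collapse = "-"))
  expect_true("1-2" %in% got)
})
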