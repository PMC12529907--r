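# Standard-format readers/writers: PDB structures, CHARMM-flavored DCD
# trajectories (with unit-cell records), the CHARMM/NAMD parameter-file
# dialect, and JSON round-trips for force fields, templates and frames.

#' Write a CG configuration to PDB
#'
#' Bead names become atom names, molecule ids become residue numbers, the
#' template name the residue name; box edges go to the CRYST1 record.
#'
#' @param config A `cg_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cg_pdb <- function(config, path) {
  b <- config$beads
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   config$box[1], config$box[2], config$box[3], 90, 90, 90)
  nm <- substr(b$bead, 1, 4)
  nm <- ifelse(nchar(nm) < 4, paste0(" ", nm), nm)   # short names start col 14
  atoms <- sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   seq_len(nrow(b)) %% 100000, nm,
                   substr(b$template, 1, 4), "A", b$molecule %% 10000,
                   b$x, b$y, b$z, 1, 0)
  writeLines(c(cryst, atoms, "END"), path)
  invisible(path)
}

#' Read a CG configuration from PDB
#'
#' @param path PDB file with CG bead records (4-character bead names
#'   supported).
#' @param templates Named template list to attach.
#' @param box Override box; default parses CRYST1.
#' @return A `cg_config`.
#' @export
read_cg_pdb <- function(path, templates = list(), box = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.null(box)) {
    cl <- grep("^CRYST1", readLines(path), value = TRUE)
    if (length(cl)) {
      box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                          substr(cl[1], 25, 33)))
    } else {
      abort("no CRYST1 record and no box given", class = "cgm_parse_error")
    }
  }
  beads <- tibble(bead = trimws(at$elety), molecule = at$resno,
                  template = trimws(at$resid), x = at$x, y = at$y, z = at$z)
  cg_configuration(beads, box, templates)
}

#' Write a trajectory as CHARMM-flavored DCD
#'
#' Binary DCD with the CORD magic, a unit-cell (CRYSTAL) record per frame
#' and single-precision coordinates — the dialect NAMD and VMD read.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cg_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nfr <- n_frames(traj)
  nat <- nrow(traj$beads) / nfr
  wrec <- function(writer) {
    # Fortran unformatted record: length, payload, length
    raw <- writer()
    writeBin(length(raw), con, size = 4, endian = "little")
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4, endian = "little")
  }
  hdr <- raw(0)
  icntrl <- integer(20)
  icntrl[1] <- nfr; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nfr
  icntrl[11] <- 1L          # unit-cell records present
  icntrl[20] <- 24L         # CHARMM version stamp
  wrec(function() c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4, endian = "little")))
  title <- formatC("generated by cgmembrane", width = 80, flag = "-")
  wrec(function() c(writeBin(1L, raw(), size = 4, endian = "little"),
                    charToRaw(title)))
  wrec(function() writeBin(as.integer(nat), raw(), size = 4, endian = "little"))
  for (fi in traj$frames$frame) {
    bx <- unlist(traj$frames[fi, c("lx", "ly", "lz")])
    # CHARMM cell record: a, gamma, b, beta, alpha, c (cosines for angles)
    cell <- c(bx[1], 0, bx[2], 0, 0, bx[3])
    wrec(function() writeBin(cell, raw(), size = 8, endian = "little"))
    fr <- dplyr::filter(traj$beads, .data$frame == fi)
    for (crd in list(fr$x, fr$y, fr$z)) {
      wrec(function() writeBin(as.numeric(crd), raw(), size = 4, endian = "little"))
    }
  }
  invisible(path)
}

#' Read a CHARMM-flavored DCD trajectory
#'
#' Little-endian CHARMM DCD with optional unit-cell records, as written by
#' [write_cg_dcd()], NAMD or CHARMM.
#'
#' @param path DCD file.
#' @param beads Tibble of per-bead identity (`bead`, `molecule`,
#'   `template`) in file atom order.
#' @param templates Template list for the resulting trajectory.
#' @param times_ns,temperature Metadata.
#' @return A `cg_trajectory`.
#' @export
read_cg_dcd <- function(path, beads, templates = list(), times_ns = NULL,
                        temperature = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rrec <- function() {
    len <- readBin(con, "integer", 1, 4, endian = "little")
    if (!length(len)) return(NULL)
    payload <- readBin(con, "raw", len)
    len2 <- readBin(con, "integer", 1, 4, endian = "little")
    if (!identical(len, len2)) abort("corrupt DCD record framing",
                                     class = "cgm_parse_error")
    payload
  }
  hdr <- rrec()
  if (rawToChar(hdr[1:4]) != "CORD") abort("not a DCD file (missing CORD)",
                                           class = "cgm_parse_error")
  icntrl <- readBin(hdr[-(1:4)], "integer", 20, 4, endian = "little")
  nfr <- icntrl[1]
  has_cell <- icntrl[11] == 1L
  invisible(rrec())                     # title block
  nat <- readBin(rrec(), "integer", 1, 4, endian = "little")
  if (nat != nrow(beads)) {
    abort(sprintf("DCD has %d atoms, bead table has %d", nat, nrow(beads)),
          class = "cgm_format_error")
  }
  cfgs <- vector("list", nfr)
  for (fi in seq_len(nfr)) {
    box <- c(NA, NA, NA)
    if (has_cell) {
      cell <- readBin(rrec(), "double", 6, 8, endian = "little")
      box <- cell[c(1, 3, 6)]
    }
    x <- readBin(rrec(), "double", nat, 4, endian = "little")
    y <- readBin(rrec(), "double", nat, 4, endian = "little")
    z <- readBin(rrec(), "double", nat, 4, endian = "little")
    b <- as_tibble(beads)
    b$x <- x; b$y <- y; b$z <- z
    cfgs[[fi]] <- cg_configuration(b, box, templates)
  }
  cg_trajectory(cfgs, times_ns = times_ns, temperature = temperature,
                metadata = list(source = path))
}

#' Write a force field in the CHARMM/NAMD parameter dialect
#'
#' Emits BONDS, ANGLES and NONBONDED blocks. Following the CHARMM parameter
#' format, well depths are written as negative numbers and the distance
#' column is `r_min / 2`; the package stores positive well depths and sigma,
#' converting at this boundary. Explicit pair overrides go to an NBFIX
#' block.
#'
#' @param ff A `cg_forcefield`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ff_prm <- function(ff, path) {
  ln <- c("* CG lipid force field parameters",
          sprintf("* cutoff %.1f A, %s", ff$cutoff, ff$exclusion_policy),
          "*", "")
  if (nrow(ff$bonds)) {
    ln <- c(ln, "BONDS",
            sprintf("%-6s %-6s %10.4f %10.4f", ff$bonds$i, ff$bonds$j,
                    ff$bonds$kb, ff$bonds$b0), "")
  }
  if (nrow(ff$angles)) {
    ln <- c(ln, "ANGLES",
            sprintf("%-6s %-6s %-6s %10.4f %10.4f", ff$angles$i, ff$angles$j,
                    ff$angles$k, ff$angles$ktheta, ff$angles$theta0), "")
  }
  bt <- ff$bead_types
  ln <- c(ln, "NONBONDED",
          sprintf("%-6s %10.1f %10.6f %10.4f", bt$name, 0,
                  -abs(bt$epsilon), sigma_to_rmin(bt$sigma) / 2), "")
  if (nrow(ff$lj_pairs)) {
    ln <- c(ln, "NBFIX",
            sprintf("%-6s %-6s %10.6f %10.4f", ff$lj_pairs$i, ff$lj_pairs$j,
                    -abs(ff$lj_pairs$epsilon),
                    sigma_to_rmin(ff$lj_pairs$sigma)), "")
  }
  writeLines(c(ln, "END"), path)
  invisible(path)
}

#' Read a CHARMM/NAMD-dialect parameter file
#'
#' Parses BONDS, ANGLES, NONBONDED and NBFIX blocks; comment lines (`*`,
#' `!`) are ignored. Masses default to the packaged bead table for known
#' bead names and 72 amu otherwise.
#'
#' @param path Parameter file.
#' @param bead_masses Optional named mass vector.
#' @param cutoff,exclusion_policy Passed to [force_field()].
#' @return A `cg_forcefield`.
#' @export
read_ff_prm <- function(path, bead_masses = NULL, cutoff = 12,
                        exclusion_policy = "exclude-1-2") {
  lines <- readLines(path)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "*")]
  section <- NA_character_
  bonds <- list(); angles <- list(); nb <- list(); nbfix <- list()
  for (i in seq_along(lines)) {
    l <- lines[i]
    up <- toupper(l)
    if (up %in% c("BONDS", "ANGLES", "NONBONDED", "NBFIX", "END") ||
        startsWith(up, "NONBONDED")) {
      section <- if (startsWith(up, "NONBONDED")) "NONBONDED" else up
      next
    }
    tok <- strsplit(l, "\\s+")[[1]]
    parsed <- suppressWarnings(tryCatch(switch(
      section,
      BONDS = tibble(i = tok[1], j = tok[2], kb = as.numeric(tok[3]),
                     b0 = as.numeric(tok[4])),
      ANGLES = tibble(i = tok[1], j = tok[2], k = tok[3],
                      ktheta = as.numeric(tok[4]), theta0 = as.numeric(tok[5])),
      NONBONDED = tibble(name = tok[1], epsilon = abs(as.numeric(tok[3])),
                         sigma = rmin_to_sigma(2 * as.numeric(tok[4]))),
      NBFIX = tibble(i = tok[1], j = tok[2], epsilon = abs(as.numeric(tok[3])),
                     sigma = rmin_to_sigma(as.numeric(tok[4]))),
      NULL
    ), error = function(e) NA))
    if (identical(parsed, NA) || (!is.null(parsed) && anyNA(parsed))) {
      abort(sprintf("malformed %s record at line: %s", section, l),
            class = "cgm_parse_error")
    }
    if (is.null(parsed)) next
    tgt <- switch(section, BONDS = "bonds", ANGLES = "angles",
                  NONBONDED = "nb", NBFIX = "nbfix")
    assign(tgt, c(get(tgt), list(parsed)))
  }
  nb <- dplyr::bind_rows(nb)
  if (!nrow(nb)) abort("no NONBONDED block found", class = "cgm_parse_error")
  known <- cg_bead_types()
  mass <- bead_masses %||% setNames(known$mass, known$name)
  bead_types <- dplyr::mutate(
    nb,
    mass = ifelse(nb$name %in% names(mass), mass[nb$name], 72),
    charge = 0,
    arity = known$arity[match(nb$name, known$name)]
  )
  force_field(bead_types,
              bonds = if (length(bonds)) dplyr::bind_rows(bonds) else NULL,
              angles = if (length(angles)) dplyr::bind_rows(angles) else NULL,
              lj_pairs = if (length(nbfix)) dplyr::bind_rows(nbfix) else NULL,
              exclusion_policy = exclusion_policy, cutoff = cutoff)
}

#' JSON round-trip for force fields and templates
#'
#' @param x A `cg_forcefield` or `cg_template`.
#' @param path Output JSON file.
#' @return `path` invisibly (writers); the restored object (readers).
#' @export
write_ff_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ff_json
#' @export
read_ff_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  force_field(as_tibble(raw$bead_types),
              bonds = if (length(raw$bonds)) as_tibble(raw$bonds) else NULL,
              angles = if (length(raw$angles)) as_tibble(raw$angles) else NULL,
              lj_pairs = if (length(raw$lj_pairs)) as_tibble(raw$lj_pairs) else NULL,
              exclusion_policy = raw$exclusion_policy,
              cutoff = raw$cutoff, lj_shift = isTRUE(raw$lj_shift))
}

#' @rdname write_ff_json
#' @export
write_template_json <- function(x, path) {
  out <- list(name = x$name, beads = x$beads,
              atom_groups = unname(x$atom_groups),
              bonds = x$bonds, angles = x$angles,
              head_beads = as.list(x$head_beads),
              tails = lapply(x$tails, as.list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ff_json
#' @export
read_template_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(name = raw$name, beads = raw$beads,
         atom_groups = setNames(raw$atom_groups,
                                paste0(raw$beads, seq_along(raw$beads))),
         bonds = matrix(as.integer(raw$bonds), ncol = 2),
         angles = matrix(as.integer(raw$angles), ncol = 3),
         head_beads = unlist(raw$head_beads),
         tails = if (is.data.frame(raw$tails)) {
           lapply(seq_len(nrow(raw$tails)), function(r) {
             c(first = as.integer(raw$tails$first[r]),
               last = as.integer(raw$tails$last[r]))
           })
         } else {
           lapply(raw$tails, unlist)
         }),
    class = "cg_template"
  )
}

#' Internal JSON frame format
#'
#' Lossless round-trip of a `cg_trajectory` (bead table, boxes, times,
#' temperature) as plain JSON — the text fixture format of the package.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output file.
#' @export
write_frames_json <- function(traj, path) {
  jsonlite::write_json(
    list(beads = traj$beads, frames = traj$frames,
         temperature = traj$temperature),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_frames_json
#' @param templates Template list to attach on read.
#' @export
read_frames_json <- function(path, templates = list()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  beads <- as_tibble(raw$beads)
  frames <- as_tibble(raw$frames)
  cfgs <- lapply(frames$frame, function(fi) {
    b <- dplyr::filter(beads, .data$frame == fi)
    cg_configuration(dplyr::select(b, -"frame"),
                     unlist(frames[frames$frame == fi, c("lx", "ly", "lz")]),
                     templates)
  })
  cg_trajectory(cfgs, times_ns = frames$time_ns,
                temperature = raw$temperature %||% NA_real_)
}
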