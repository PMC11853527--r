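#' Structural ensemble container
#'
#' A lightweight trajectory container: a constant topology (atom table) plus
#' per-frame coordinates. Atom ordering must be identical across frames.
#'
#' @param atoms data frame with columns `resno` (residue number), `resid`
#'   (residue name, e.g. "ARG", "HOH"), `elety` (atom name, e.g. "CA", "O").
#' @param coords numeric array `[n_atoms, 3, n_frames]` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param label free-text label (e.g. "deactivated", "activated").
#' @return An object of class `"structure_ensemble"`.
#' @export
structure_ensemble <- function(atoms, coords, label = "") {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("resno", "resid", "elety") %in% names(atoms)))
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3, 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[1] == nrow(atoms),
            dim(coords)[2] == 3, all(is.finite(coords)))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, coords = coords, label = label),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("Structure ensemble '%s': %d atoms, %d frame(s)\n",
              x$label, dim(x$coords)[1], dim(x$coords)[3]))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `"structure_ensemble"`.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Coordinates of one frame
#' @param ensemble a `"structure_ensemble"`.
#' @param i frame index.
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(ensemble, i = 1) ensemble$coords[, , i, drop = TRUE]

#' Select atom indices in an ensemble
#'
#' @param ensemble a `"structure_ensemble"`.
#' @param resno optional residue numbers.
#' @param resid optional residue names.
#' @param elety optional atom names.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(ensemble, resno = NULL, resid = NULL, elety = NULL) {
  a <- ensemble$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  which(keep)
}

#' Write / read a multi-model PDB trajectory
#'
#' Thin wrappers around bio3d that map a `"structure_ensemble"` onto a
#' multi-model PDB file (one MODEL per frame) and back.
#'
#' @param ensemble a `"structure_ensemble"`.
#' @param path output/input file path.
#' @return `read_ensemble_pdb()` returns a `"structure_ensemble"`;
#'   `write_ensemble_pdb()` returns `path` invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  nf <- n_frames(ensemble)
  xyz <- t(vapply(seq_len(nf),
                  function(i) as.numeric(t(frame_coords(ensemble, i))),
                  numeric(3 * nrow(ensemble$atoms))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ensemble$atoms$resno,
                   resid = ensemble$atoms$resid,
                   eleno = seq_len(nrow(ensemble$atoms)),
                   elety = ensemble$atoms$elety)
  invisible(path)
}

#' @rdname write_ensemble_pdb
#' @param label label for the returned ensemble.
#' @export
read_ensemble_pdb <- function(path, label = basename(path)) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  atoms <- data.frame(resno = pdb$atom$resno, resid = pdb$atom$resid,
                      elety = pdb$atom$elety)
  nf <- nrow(pdb$xyz)
  n_atoms <- nrow(atoms)
  coords <- array(NA_real_, c(n_atoms, 3, nf))
  for (i in seq_len(nf)) {
    coords[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  }
  structure_ensemble(atoms, coords, label = label)
}

## Kabsch optimal rotation: returns the rotation matrix mapping centered P
## onto centered Q (both n x 3).
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  ## applied to row-vector coordinates as P %*% R
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Rigid-body least-squares superposition of two frames
#'
#' Optimal translation + rotation (Kabsch algorithm via singular value
#' decomposition, with the proper-rotation determinant correction) of a
#' mobile frame onto a reference, minimizing the RMSD over the selected
#' atoms. The whole mobile frame is transformed; the RMSD is reported over
#' the selection.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices.
#' @param sel_mobile,sel_reference integer atom indices (1:1 correspondence,
#'   >= 3 atoms). Default: all atoms.
#' @return A list with `xyz` (transformed mobile frame) and `rmsd`
#'   (Angstrom).
#' @export
superpose <- function(mobile, reference,
                      sel_mobile = seq_len(nrow(mobile)),
                      sel_reference = sel_mobile) {
  if (length(sel_mobile) != length(sel_reference)) {
    stop("selections must map 1:1")
  }
  if (length(sel_mobile) < 3) stop("need at least 3 atoms to superpose")
  P <- mobile[sel_mobile, , drop = FALSE]
  Q <- reference[sel_reference, , drop = FALSE]
  cP <- colMeans(P); cQ <- colMeans(Q)
  R <- kabsch_rotation(sweep(P, 2, cP), sweep(Q, 2, cQ))
  xyz <- sweep(sweep(mobile, 2, cP) %*% R, 2, cQ, `+`)
  dd <- xyz[sel_mobile, , drop = FALSE] - Q
  list(xyz = xyz, rmsd = sqrt(mean(rowSums(dd^2))))
}

#' Per-frame RMSD of an ensemble against a reference frame
#'
#' Each frame is superposed onto the reference over the selection before the
#' deviation is measured.
#'
#' @param ensemble a `"structure_ensemble"`.
#' @param reference reference coordinates (`n_atoms x 3` matrix) or a frame
#'   index into `ensemble`.
#' @param sel atom selection (indices); default all atoms.
#' @return Numeric vector of per-frame RMSDs (Angstrom).
#' @export
rmsd_series <- function(ensemble, reference = 1,
                        sel = seq_len(nrow(ensemble$atoms))) {
  ref <- if (is.matrix(reference)) reference else frame_coords(ensemble, reference)
  vapply(seq_len(n_frames(ensemble)), function(i) {
    superpose(frame_coords(ensemble, i), ref, sel)$rmsd
  }, numeric(1))
}

#' Root-mean-square fluctuation per selected atom
#'
#' Frames are superposed (over the selection) onto their mean structure,
#' the mean is recomputed, and the fluctuation of each selected atom about
#' its mean position is reported:
#' \eqn{RMSF_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}}.
#'
#' @param ensemble a `"structure_ensemble"` with at least 2 frames.
#' @param sel atom selection (indices) whose fluctuations are reported;
#'   default all atoms.
#' @param fit_sel atoms used for the superposition (default `sel`); a rigid
#'   core here prevents a mobile selection from leaking into the alignment.
#' @param n_iter mean-structure refinement passes.
#' @return Data frame with `resno`, `elety`, `rmsf` (Angstrom) for the
#'   selection.
#' @export
rmsf <- function(ensemble, sel = seq_len(nrow(ensemble$atoms)),
                 fit_sel = sel, n_iter = 2) {
  nf <- n_frames(ensemble)
  if (nf < 2) stop("RMSF needs at least 2 frames")
  frames <- lapply(seq_len(nf), function(i) frame_coords(ensemble, i))
  ref <- frames[[1]]
  for (it in seq_len(n_iter + 1)) {
    fitted <- lapply(frames, function(fr) {
      superpose(fr, ref, sel_mobile = fit_sel, sel_reference = fit_sel)$xyz
    })
    ref <- Reduce(`+`, fitted) / nf
  }
  sub <- lapply(fitted, function(fr) fr[sel, , drop = FALSE])
  mean_xyz <- ref[sel, , drop = FALSE]
  msd <- Reduce(`+`, lapply(sub, function(fr) rowSums((fr - mean_xyz)^2))) / nf
  data.frame(resno = ensemble$atoms$resno[sel],
             elety = ensemble$atoms$elety[sel],
             rmsf = sqrt(msd))
}

.BASIC_DONORS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                      HIS = c("ND1", "NE2"))
.ACIDIC_ACCEPTORS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Salt-bridge occupancy over an ensemble
#'
#' A basic-acidic residue pair is in contact in a frame when the minimum
#' distance between any side-chain nitrogen of the basic residue (Arg
#' NE/NH1/NH2, Lys NZ, His ND1/NE2 — both ring nitrogens, regardless of
#' protonation) and any carboxylate oxygen of the acidic residue (Asp
#' OD1/OD2, Glu OE1/OE2) is at most `d_on`. The occupancy is the fraction of
#' frames in contact, classified strong (>= `s_hi`), weak (>= `s_lo`) or
#' none. The cutoff and thresholds are configurable screening defaults.
#'
#' @param ensemble a `"structure_ensemble"`.
#' @param pairs optional data frame with columns `basic`, `acidic` (residue
#'   numbers); by default all basic x acidic residue pairs present are
#'   scanned. Pairs with missing side-chain atoms are skipped with a warning.
#' @param d_on contact cutoff (Angstrom, default 4.0).
#' @param s_hi,s_lo strong/weak occupancy thresholds (defaults 0.65 / 0.25).
#' @return Data frame with columns `basic`, `basic_resid`, `acidic`,
#'   `acidic_resid`, `occupancy`, `klass`.
#' @export
salt_bridge_occupancy <- function(ensemble, pairs = NULL, d_on = 4.0,
                                  s_hi = 0.65, s_lo = 0.25) {
  a <- ensemble$atoms
  donor_atoms <- function(rn) {
    rid <- a$resid[a$resno == rn][1]
    which(a$resno == rn & a$elety %in% .BASIC_DONORS[[rid]])
  }
  acceptor_atoms <- function(rn) {
    rid <- a$resid[a$resno == rn][1]
    which(a$resno == rn & a$elety %in% .ACIDIC_ACCEPTORS[[rid]])
  }
  if (is.null(pairs)) {
    basics <- unique(a$resno[a$resid %in% names(.BASIC_DONORS)])
    acidics <- unique(a$resno[a$resid %in% names(.ACIDIC_ACCEPTORS)])
    pairs <- expand.grid(basic = basics, acidic = acidics)
  }
  pairs <- as.data.frame(pairs)
  nf <- n_frames(ensemble)
  out <- list(); skipped <- character(0)
  for (j in seq_len(nrow(pairs))) {
    di <- donor_atoms(pairs$basic[j])
    ai <- acceptor_atoms(pairs$acidic[j])
    if (length(di) == 0 || length(ai) == 0) {
      skipped <- c(skipped, sprintf("%s-%s", pairs$basic[j], pairs$acidic[j]))
      next
    }
    contact <- vapply(seq_len(nf), function(f) {
      xyz <- ensemble$coords[, , f]
      dmin <- min(sqrt(outer(rowSums(xyz[di, , drop = FALSE]^2),
                             rowSums(xyz[ai, , drop = FALSE]^2), `+`) -
                       2 * xyz[di, , drop = FALSE] %*% t(xyz[ai, , drop = FALSE])))
      dmin <= d_on
    }, logical(1))
    occ <- mean(contact)
    out[[length(out) + 1]] <- data.frame(
      basic = pairs$basic[j], basic_resid = a$resid[a$resno == pairs$basic[j]][1],
      acidic = pairs$acidic[j], acidic_resid = a$resid[a$resno == pairs$acidic[j]][1],
      occupancy = occ,
      klass = if (occ >= s_hi) "strong" else if (occ >= s_lo) "weak" else "none")
  }
  if (length(skipped) > 0) {
    warning("skipped pair(s) with missing side-chain atoms: ",
            paste(skipped, collapse = ", "))
  }
  if (length(out) == 0) {
    return(data.frame(basic = integer(0), basic_resid = character(0),
                      acidic = integer(0), acidic_resid = character(0),
                      occupancy = numeric(0), klass = character(0)))
  }
  do.call(rbind, out)
}

#' Assemble a salt-bridge classification table across channels
#'
#' Builds the interaction-pair x (channel, configuration) matrix of
#' strong/weak/none classifications, together with the per-column counts of
#' strong and weak interactions.
#'
#' @param occupancies named list of data frames from
#'   [salt_bridge_occupancy()] (or any data frame with columns `pair` or
#'   `basic`/`acidic`, and `klass`); names become column labels, e.g.
#'   `"WT.d"`, `"WT.a"`.
#' @return An object of class `"salt_bridge_table"`: `cells` (character
#'   matrix, rows = pairs, columns = conditions) and `sums` (data frame
#'   `column`, `n_strong`, `n_weak`).
#' @export
build_salt_bridge_table <- function(occupancies) {
  stopifnot(is.list(occupancies), length(names(occupancies)) == length(occupancies))
  tabs <- lapply(occupancies, function(d) {
    d <- as.data.frame(d)
    if (!"pair" %in% names(d)) {
      d$pair <- sprintf("%s%d-%s%d",
                        substr(d$basic_resid, 1, 1), d$basic,
                        substr(d$acidic_resid, 1, 1), d$acidic)
    }
    d[, c("pair", "klass")]
  })
  all_pairs <- unique(unlist(lapply(tabs, function(d) d$pair)))
  cells <- matrix("none", nrow = length(all_pairs), ncol = length(tabs),
                  dimnames = list(all_pairs, names(tabs)))
  for (j in seq_along(tabs)) {
    d <- tabs[[j]]
    cells[d$pair, j] <- d$klass
  }
  new_salt_bridge_table(cells)
}

new_salt_bridge_table <- function(cells, printed_sums = NULL) {
  sums <- data.frame(column = colnames(cells),
                     n_strong = as.integer(colSums(cells == "strong")),
                     n_weak = as.integer(colSums(cells == "weak")),
                     row.names = NULL)
  structure(list(cells = cells, sums = sums, printed_sums = printed_sums),
            class = "salt_bridge_table")
}

#' @export
print.salt_bridge_table <- function(x, ...) {
  cat(sprintf("Salt-bridge table: %d pairs x %d conditions\n",
              nrow(x$cells), ncol(x$cells)))
  print(x$sums, row.names = FALSE)
  invisible(x)
}

#' Read or write a glyph-encoded salt-bridge table
#'
#' The on-disk format is a UTF-8 TSV whose first column names the
#' interaction pair and whose remaining columns hold one glyph per cell:
#' `✓` (check mark) for a strong interaction, `∨` (logical-or
#' symbol) for a weak one, empty for none. An optional final `Sum` row
#' stores the printed per-column counts as e.g. `7✓5∨`; the parser
#' keeps it (as `printed_sums`) and always recomputes `sums` from the cells.
#'
#' @param path TSV file path.
#' @return `parse_salt_bridge_table()` returns a `"salt_bridge_table"`;
#'   `write_salt_bridge_table()` returns `path` invisibly.
#' @export
parse_salt_bridge_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]][-1]
  body <- fields[-1]
  pad <- function(x, n) c(x, rep("", n - length(x)))
  glyph_map <- c("✓" = "strong", "∨" = "weak")
  rows <- list(); printed <- NULL
  for (f in body) {
    name <- f[1]
    vals <- pad(f[-1], length(header))
    if (identical(name, "Sum")) {
      printed <- data.frame(
        column = header,
        n_strong = as.integer(sub("^(\\d+)✓.*$", "\\1", vals)),
        n_weak = as.integer(sub("^.*✓(\\d+)∨$", "\\1", vals)),
        row.names = NULL)
      next
    }
    bad <- !(vals %in% c(names(glyph_map), ""))
    if (any(bad)) {
      stop("unknown cell glyph '", vals[bad][1], "' in row ", name)
    }
    rows[[name]] <- ifelse(vals == "", "none", glyph_map[vals])
  }
  cells <- do.call(rbind, rows)
  if (is.null(cells)) {
    cells <- matrix(character(0), nrow = 0, ncol = length(header),
                    dimnames = list(NULL, header))
  } else {
    colnames(cells) <- header
  }
  new_salt_bridge_table(cells, printed_sums = printed)
}

#' @rdname parse_salt_bridge_table
#' @param table a `"salt_bridge_table"`.
#' @param include_sums write a `Sum` row recomputed from the cells.
#' @export
write_salt_bridge_table <- function(table, path, include_sums = TRUE) {
  glyph <- c(strong = "✓", weak = "∨", none = "")
  lines <- c(paste(c("pair", colnames(table$cells)), collapse = "\t"),
             vapply(rownames(table$cells), function(p) {
               paste(c(p, glyph[table$cells[p, ]]), collapse = "\t")
             }, character(1)))
  if (include_sums) {
    s <- table$sums
    lines <- c(lines, paste(c("Sum", sprintf("%d✓%d∨",
                                             s$n_strong, s$n_weak)),
                            collapse = "\t"))
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

.HG_RESNO <- c(109, 150, 178, 179)

#' Hydrophobic-gasket reference frame
#'
#' The four gasket residues (V109, F150, V178, V179) define the axial origin
#' and the pore axis position: `z0` is the mean z of their Calpha atoms and
#' `axis_xy` the mean (x, y). All axial geometry in the package is reported
#' relative to this plane, with the membrane normal assumed to be the z axis
#' of the input coordinates.
#'
#' @param ensemble a `"structure_ensemble"`.
#' @param frame frame index, or `NULL` to average over all frames.
#' @return A list with `z0` (Angstrom) and `axis_xy` (length-2 vector).
#' @export
hg_reference <- function(ensemble, frame = NULL) {
  sel <- select_atoms(ensemble, resno = .HG_RESNO, elety = "CA")
  found <- unique(ensemble$atoms$resno[sel])
  if (length(found) < 4) {
    stop("missing gasket residue(s): ",
         paste(setdiff(.HG_RESNO, found), collapse = ", "))
  }
  xyz <- if (is.null(frame)) {
    apply(ensemble$coords[sel, , , drop = FALSE], c(1, 2), mean)
  } else {
    frame_coords(ensemble, frame)[sel, , drop = FALSE]
  }
  list(z0 = mean(xyz[, 3]), axis_xy = colMeans(xyz[, 1:2, drop = FALSE]))
}

#' Axial displacement of a selection between two ensembles
#'
#' Measures, per ensemble, the frame-averaged z position of a residue (or a
#' helix range, averaged over its Calpha atoms) relative to the
#' hydrophobic-gasket plane, and reports the difference b minus a. Both
#' ensembles must be oriented with the membrane normal along z.
#'
#' @param ensemble_a,ensemble_b `"structure_ensemble"` objects (e.g.
#'   deactivated and activated configurations).
#' @param resno residue number(s) of the selection.
#' @param atom_mode `"CA"` (backbone) or `"sidechain_tip"` (guanidinium CZ
#'   for Arg, NZ for Lys).
#' @return Axial shift in Angstrom (positive = outward along +z).
#' @export
axial_shift <- function(ensemble_a, ensemble_b, resno,
                        atom_mode = c("CA", "sidechain_tip")) {
  atom_mode <- match.arg(atom_mode)
  sel_of <- function(ens) {
    if (atom_mode == "CA") {
      sel <- select_atoms(ens, resno = resno, elety = "CA")
    } else {
      a <- ens$atoms
      sel <- which(a$resno %in% resno &
                   ((a$resid == "ARG" & a$elety == "CZ") |
                    (a$resid == "LYS" & a$elety == "NZ")))
    }
    if (length(sel) == 0) stop("selection absent from ensemble '", ens$label, "'")
    sel
  }
  mean_rel_z <- function(ens) {
    sel <- sel_of(ens)
    mean(vapply(seq_len(n_frames(ens)), function(f) {
      ref <- hg_reference(ens, f)
      mean(frame_coords(ens, f)[sel, 3]) - ref$z0
    }, numeric(1)))
  }
  mean_rel_z(ensemble_b) - mean_rel_z(ensemble_a)
}

#' Water count profile along the pore axis
#'
#' Counts water oxygens (residue name HOH/WAT/TIP3, atom O/OW/OH2) inside a
#' cylinder about the pore axis, bins them along z relative to the
#' hydrophobic-gasket plane, and averages over frames.
#'
#' @param ensemble a `"structure_ensemble"`.
#' @param radius cylinder radius (Angstrom, default 8).
#' @param bin_width axial bin width (Angstrom, default 1).
#' @param z_range optional `c(lo, hi)` (Angstrom, relative to the gasket);
#'   defaults to the water z extent.
#' @return An object of class `"axial_profile"`: data frame with `z`
#'   (bin center) and `count` (mean waters per frame per bin); bin width and
#'   radius kept as attributes. A water-free ensemble yields an all-zero
#'   profile with a warning.
#' @export
water_axial_profile <- function(ensemble, radius = 8, bin_width = 1,
                                z_range = NULL) {
  a <- ensemble$atoms
  wat <- which(a$resid %in% c("HOH", "WAT", "TIP3") &
               a$elety %in% c("O", "OW", "OH2"))
  nf <- n_frames(ensemble)
  if (length(wat) == 0) {
    warning("no water molecules found; profile is all zero")
    if (is.null(z_range)) z_range <- c(-10, 10)
  }
  if (is.null(z_range)) {
    zs <- as.numeric(ensemble$coords[wat, 3, ])
    ref0 <- hg_reference(ensemble)
    z_range <- range(zs - ref0$z0)
  }
  breaks <- seq(floor(z_range[1] / bin_width) * bin_width,
                ceiling(z_range[2] / bin_width) * bin_width,
                by = bin_width)
  mids <- breaks[-length(breaks)] + bin_width / 2
  total <- numeric(length(mids))
  for (f in seq_len(nf)) {
    ref <- hg_reference(ensemble, f)
    xyz <- frame_coords(ensemble, f)[wat, , drop = FALSE]
    if (length(wat) == 0) break
    r2 <- (xyz[, 1] - ref$axis_xy[1])^2 + (xyz[, 2] - ref$axis_xy[2])^2
    z <- xyz[r2 <= radius^2, 3] - ref$z0
    z <- z[z >= breaks[1] & z <= breaks[length(breaks)]]
    if (length(z) > 0) {
      h <- graphics::hist(z, breaks = breaks, plot = FALSE)
      total <- total + h$counts
    }
  }
  structure(data.frame(z = mids, count = total / nf),
            class = c("axial_profile", "data.frame"),
            bin_width = bin_width, radius = radius)
}

#' Width of the dewetted region of an axial water profile
#'
#' Finds the contiguous interval around the lowest minimum of the profile
#' where the mean water count stays below `level` (default 1 molecule per
#' bin), with the endpoints located by linear interpolation of the level
#' crossing between bin centers.
#'
#' @param profile an `"axial_profile"`.
#' @param level water-count level defining dewetting (default 1.0).
#' @return A list with `width` (Angstrom), `z_lo`, `z_hi`, and `flagged`
#'   (TRUE when the dewetted region spans the whole profile, e.g. for a
#'   water-free ensemble).
#' @export
dewetted_width <- function(profile, level = 1.0) {
  z <- profile$z; v <- profile$count
  if (all(v < level)) {
    return(list(width = diff(range(z)), z_lo = min(z), z_hi = max(z),
                flagged = TRUE))
  }
  if (min(v) >= level) {
    return(list(width = 0, z_lo = NA_real_, z_hi = NA_real_, flagged = FALSE))
  }
  i_min <- which.min(v)
  ## walk left to the crossing
  i <- i_min
  while (i > 1 && v[i - 1] < level) i <- i - 1
  z_lo <- if (i == 1) z[1] else {
    z[i - 1] + (level - v[i - 1]) / (v[i] - v[i - 1]) * (z[i] - z[i - 1])
  }
  j <- i_min
  n <- length(z)
  while (j < n && v[j + 1] < level) j <- j + 1
  z_hi <- if (j == n) z[n] else {
    z[j] + (level - v[j]) / (v[j + 1] - v[j]) * (z[j + 1] - z[j])
  }
  list(width = z_hi - z_lo, z_lo = z_lo, z_hi = z_hi,
       flagged = i == 1 || j == n)
}
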