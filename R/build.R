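# Glycosidic rotamer enumeration and idealized 3-D building.
#
# Residue templates are idealized pyranose geometries generated in code:
# a closed six-membered chair (bond length 1.54 A, alternating ring pucker)
# with substituents on the remaining tetrahedral directions and exocyclic
# chains placed by natural-extension geometry. Bond lengths and angles are
# fixed; only the glycosidic torsions vary between built structures.
# Stereochemistry is carried as residue/atom labels, not as exact
# force-field geometry, which is all the downstream pose metrics need.

# ---- rotamer library --------------------------------------------------

#' Default glycosidic rotamer library
#'
#' Torsion values (degrees) per linkage class. The alpha-2,6 sialyl entry
#' carries the six-rotamer phi/omega grid (phi in \{-60, 180\}; omega in
#' \{-60, 60, 180\}) that describes the solution behaviour of
#' Neu5Ac-alpha-2,6 linkages; phi is defined over C1-C2-O6'-C6' and omega
#' over O6-C6-C5-O5 of the aglycon residue. Other linkages default to the
#' exo-anomeric phi well.
#'
#' @return named list: linkage class (e.g. `"a2-6"`) to a named list of
#'   torsion-value vectors.
#' @export
default_rotamer_library <- function() {
  exo <- list(phi = c(-60))
  list(
    "a2-6" = list(phi = c(-60, 180), omega = c(-60, 60, 180)),
    "a2-3" = list(phi = c(-60, 180)),
    "a2-8" = list(phi = c(-60, 180)),
    "a1-2" = exo, "a1-3" = exo, "a1-4" = exo, "a1-6" = list(phi = c(-60), omega = c(-60, 60, 180)),
    "b1-2" = exo, "b1-3" = exo, "b1-4" = exo, "b1-6" = list(phi = c(-60), omega = c(-60, 60, 180))
  )
}

.linkage_class <- function(tree, edge) {
  ch <- tree$residues[tree$residues$id == edge$child, ]
  paste0(ch$anomer, edge$child_pos, "-", edge$parent_pos)
}

.torsion_names <- function(tree) {
  # full torsion identifier: "<kind>.<child>-<parent>"
  ed <- tree$edges
  unlist(lapply(seq_len(nrow(ed)), function(k) {
    paste0(c("phi", "psi", "omega"), ".", ed$child[k], "-", ed$parent[k])
  }))
}

#' Construct a TorsionSet
#'
#' @param values named numeric vector of torsions in degrees, names of the
#'   form `"phi.<child>-<parent>"`.
#' @param rotamer integer provenance label.
#' @param tree optional `glycan_tree` the torsions belong to (validated).
#' @return object of class `torsion_set`.
#' @export
torsion_set <- function(values, rotamer = NA_integer_, tree = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(values <= -180 | values > 180)) {
    stop("torsion values must lie in (-180, 180]", call. = FALSE)
  }
  if (!is.null(tree)) {
    legal <- .torsion_names(tree)
    bad <- setdiff(names(values), legal)
    if (length(bad) > 0) {
      stop("torsions do not belong to an edge of the tree: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(torsions = values, rotamer = as.integer(rotamer)),
            class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat(sprintf("<torsion_set rotamer %s> %s\n", x$rotamer,
              paste(sprintf("%s=%g", names(x$torsions), x$torsions),
                    collapse = " ")))
  invisible(x)
}

#' Enumerate glycosidic rotamers of a glycan tree
#'
#' Forms the Cartesian product of the per-torsion value lists supplied by
#' the rotamer library, one entry per linkage of the tree. Order is
#' deterministic: torsion names sorted lexicographically, values sorted
#' ascending, earlier names varying slowest.
#'
#' @param tree a `glycan_tree`.
#' @param library rotamer library as from [default_rotamer_library()].
#' @return list of `torsion_set` objects (rotamer indices 1..K).
#' @examples
#' stn <- parse_glycan("Neu5Ac(a2-6)GalNAc(a1-")
#' length(enumerate_rotamers(stn))  # 6
#' @export
enumerate_rotamers <- function(tree, library = default_rotamer_library()) {
  ed <- tree$edges
  if (nrow(ed) == 0) {
    return(list(torsion_set(stats::setNames(numeric(0), character(0)),
                            rotamer = 1L)))
  }
  valmap <- list()
  for (k in seq_len(nrow(ed))) {
    cls <- .linkage_class(tree, ed[k, ])
    entry <- library[[cls]]
    if (is.null(entry)) {
      stop("rotamer library has no entry for linkage ", cls, call. = FALSE)
    }
    for (tn in names(entry)) {
      full <- paste0(tn, ".", ed$child[k], "-", ed$parent[k])
      valmap[[full]] <- sort(entry[[tn]])
    }
  }
  nm <- sort(names(valmap))
  vals <- valmap[nm]
  # expand.grid varies the first factor fastest; feed reversed so the
  # first (lexicographically smallest) torsion name varies slowest.
  grid <- do.call(expand.grid, rev(vals))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  names(grid) <- nm
  lapply(seq_len(nrow(grid)), function(i) {
    torsion_set(stats::setNames(as.numeric(grid[i, ]), nm), rotamer = i,
                tree = tree)
  })
}

# ---- residue templates ------------------------------------------------

# Closed chair ring: six positions with exact equal adjacent distances.
.ring6 <- function(bond = 1.54, dz = 0.25) {
  r <- sqrt(bond^2 - (2 * dz)^2 + dz^2 * 0)  # chord in plane
  r <- sqrt(bond^2 - 4 * dz^2)
  t(vapply(0:5, function(i) {
    th <- pi * i / 3
    c(r / (2 * sin(pi / 6)) * 0, 0, 0) # placeholder (overwritten below)
  }, numeric(3)))
}

# Substituent directions at ring position i (1-based) of a ring matrix.
.ring_subdirs <- function(ring, i) {
  n <- nrow(ring)
  prev <- ring[(i - 2) %% n + 1, ]
  nxt <- ring[i %% n + 1, ]
  here <- ring[i, ]
  b1 <- .unit(prev - here)
  b2 <- .unit(nxt - here)
  m <- .unit(b1 + b2)
  a <- .unit(.xprod(b1, b2))
  s <- if (here[3] >= 0) 1 else -1
  if (a[3] * s < 0) a <- -a
  half <- 54.75 * pi / 180
  list(ax = .unit(-m * cos(half) + a * sin(half)),
       eq = .unit(-m * cos(half) - a * sin(half)))
}

.make_ring <- function(bond = 1.54, dz = 0.25) {
  r <- sqrt(bond^2 - 4 * dz^2)
  # chord between adjacent hexagon vertices of radius R is R; we need
  # chord = r, so R = r.
  t(vapply(0:5, function(i) {
    th <- pi * i / 3
    c(r * cos(th), r * sin(th), dz * (-1)^i)
  }, numeric(3)))
}

.acetamido <- function(atoms, Aname, Bname, Nname, names, glycolyl = FALSE) {
  # amide C(=O)-CH3 (or CH2OH for the glycolyl variant) on nitrogen
  # Nname; `names` gives the carbonyl C, carbonyl O, methyl C and (for
  # glycolyl) hydroxyl O atom names -- all at most 4 characters so the
  # derived hydrogen names still fit the PDB atom-name field
  g <- function(nm) unlist(atoms[atoms$name == nm, c("x", "y", "z")])
  CC <- .nerf_place(g(Aname), g(Bname), g(Nname), 1.33, 122, 180)
  rows <- data.frame(name = names[1], element = "C",
                     x = CC[1], y = CC[2], z = CC[3])
  OO <- .nerf_place(g(Bname), g(Nname), CC, 1.23, 121, 0)
  CM <- .nerf_place(g(Bname), g(Nname), CC, 1.50, 116, 180)
  rows <- rbind(rows,
                data.frame(name = names[2], element = "O",
                           x = OO[1], y = OO[2], z = OO[3]),
                data.frame(name = names[3], element = "C",
                           x = CM[1], y = CM[2], z = CM[3]))
  if (glycolyl) {
    OH <- .nerf_place(g(Nname), CC, CM, 1.43, 109.5, 180)
    rows <- rbind(rows, data.frame(name = names[4], element = "O",
                                   x = OH[1], y = OH[2], z = OH[3]))
  }
  rows
}

# Template for an aldopyranose (Gal/GalNAc/Glc/GlcNAc/Man/Fuc family).
.template_aldose <- function(name, anomer) {
  ring <- .make_ring()
  nm <- c("C1", "C2", "C3", "C4", "C5", "O5")
  el <- c("C", "C", "C", "C", "C", "O")
  atoms <- data.frame(name = nm, element = el,
                      x = ring[, 1], y = ring[, 2], z = ring[, 3])
  addsub <- function(i, aname, elem, kind, len = 1.43) {
    d <- .ring_subdirs(ring, i)[[kind]]
    p <- ring[i, ] + len * d
    rbind(atoms, data.frame(name = aname, element = elem,
                            x = p[1], y = p[2], z = p[3]))
  }
  atoms <- addsub(1, "O1", "O", if (anomer == "a") "ax" else "eq")
  nacetyl <- name %in% c("GalNAc", "GlcNAc")
  atoms <- if (nacetyl) {
    addsub(2, "N2", "N", "eq", 1.47)
  } else {
    addsub(2, "O2", "O", "eq")
  }
  atoms <- addsub(3, "O3", "O", "eq")
  atoms <- addsub(4, "O4", "O", if (name %in% c("Gal", "GalNAc")) "ax" else "eq")
  atoms <- addsub(5, "C6", "C", "eq", 1.53)
  if (name != "Fuc") {
    g <- function(a) unlist(atoms[atoms$name == a, c("x", "y", "z")])
    O6 <- .nerf_place(g("C4"), g("C5"), g("C6"), 1.43, 109.5, 60)
    atoms <- rbind(atoms, data.frame(name = "O6", element = "O",
                                     x = O6[1], y = O6[2], z = O6[3]))
  }
  if (nacetyl) {
    atoms <- rbind(atoms, .acetamido(atoms, "C1", "C2", "N2",
                                     c("C7", "O7", "C8")))
  }
  atoms
}

# Template for a sialic acid (Neu5Ac / Neu5Gc): ring C2..C6 + ring oxygen
# O6, carboxylate C1/O1A/O1B, anomeric O2, glycerol arm C7-C8-C9 with
# hydroxyls O7/O8/O9, and the N5 acyl group.
.template_sialic <- function(name) {
  ring <- .make_ring()
  nm <- c("C2", "C3", "C4", "C5", "C6", "O6")
  el <- c("C", "C", "C", "C", "C", "O")
  atoms <- data.frame(name = nm, element = el,
                      x = ring[, 1], y = ring[, 2], z = ring[, 3])
  addsub <- function(i, aname, elem, kind, len = 1.43) {
    d <- .ring_subdirs(ring, i)[[kind]]
    p <- ring[i, ] + len * d
    rbind(atoms, data.frame(name = aname, element = elem,
                            x = p[1], y = p[2], z = p[3]))
  }
  g <- function(a) unlist(atoms[atoms$name == a, c("x", "y", "z")])
  atoms <- addsub(1, "C1", "C", "eq", 1.53)   # carboxylate carbon
  atoms <- addsub(1, "O2", "O", "ax")          # anomeric oxygen
  atoms <- addsub(3, "O4", "O", "eq")
  atoms <- addsub(4, "N5", "N", "eq", 1.47)
  atoms <- addsub(5, "C7", "C", "eq", 1.53)    # glycerol arm start
  O1A <- .nerf_place(g("C3"), g("C2"), g("C1"), 1.25, 118, 0)
  O1B <- .nerf_place(g("C3"), g("C2"), g("C1"), 1.25, 118, 180)
  atoms <- rbind(atoms,
                 data.frame(name = "O1A", element = "O",
                            x = O1A[1], y = O1A[2], z = O1A[3]),
                 data.frame(name = "O1B", element = "O",
                            x = O1B[1], y = O1B[2], z = O1B[3]))
  O7 <- .nerf_place(g("C5"), g("C6"), g("C7"), 1.43, 109.5, 60)
  C8 <- .nerf_place(g("C5"), g("C6"), g("C7"), 1.53, 109.5, 180)
  atoms <- rbind(atoms,
                 data.frame(name = "O7", element = "O",
                            x = O7[1], y = O7[2], z = O7[3]),
                 data.frame(name = "C8", element = "C",
                            x = C8[1], y = C8[2], z = C8[3]))
  O8 <- .nerf_place(g("C6"), g("C7"), C8, 1.43, 109.5, -60)
  C9 <- .nerf_place(g("C6"), g("C7"), C8, 1.53, 109.5, 180)
  atoms <- rbind(atoms,
                 data.frame(name = "O8", element = "O",
                            x = O8[1], y = O8[2], z = O8[3]),
                 data.frame(name = "C9", element = "C",
                            x = C9[1], y = C9[2], z = C9[3]))
  O9 <- .nerf_place(g("C7"), C8, C9, 1.43, 109.5, 180)
  atoms <- rbind(atoms, data.frame(name = "O9", element = "O",
                                   x = O9[1], y = O9[2], z = O9[3]))
  atoms <- rbind(atoms, .acetamido(atoms, "C4", "C5", "N5",
                                   c("C10", "O10", "C11", "O11"),
                                   glycolyl = (name == "Neu5Gc")))
  atoms
}

#' Idealized heavy-atom template for one residue
#'
#' @param name residue name from [residue_names()].
#' @param anomer `"a"` or `"b"` (sets the anomeric oxygen direction for
#'   aldoses).
#' @return data frame with columns name, element, x, y, z.
#' @export
residue_template <- function(name, anomer = "a") {
  if (!name %in% residue_names()) {
    stop("no template for residue '", name, "'", call. = FALSE)
  }
  if (grepl("^Neu", name)) .template_sialic(name) else .template_aldose(name, anomer)
}

#' Default template set covering all dictionary residues
#' @return named list of template closures keyed by residue name.
#' @export
default_templates <- function() {
  nms <- residue_names()
  stats::setNames(lapply(nms, function(n) {
    function(anomer) residue_template(n, anomer)
  }), nms)
}

# Apply a positional modification (currently 9Ac on sialic acids):
# acetyl ester C(=O)CH3 grown on the modified oxygen.
.apply_modification <- function(atoms, mod) {
  pos <- as.integer(sub("[A-Za-z]+$", "", mod))
  kind <- sub("^[0-9]+", "", mod)
  if (kind != "Ac") {
    stop("unsupported modification '", mod, "'", call. = FALSE)
  }
  oname <- paste0("O", pos)
  cname <- paste0("C", pos)
  if (!oname %in% atoms$name || !cname %in% atoms$name) {
    stop("modification ", mod, " targets a position without an oxygen",
         call. = FALSE)
  }
  g <- function(a) unlist(atoms[atoms$name == a, c("x", "y", "z")])
  # pick any heavy neighbour of the carbon bearing the oxygen
  cc <- g(cname)
  cand <- atoms[atoms$name != cname & atoms$name != oname, ]
  dd <- sqrt((cand$x - cc[1])^2 + (cand$y - cc[2])^2 + (cand$z - cc[3])^2)
  ref <- unlist(cand[which.min(dd), c("x", "y", "z")])
  CA <- .nerf_place(ref, cc, g(oname), 1.36, 117, 180)
  OA <- .nerf_place(cc, g(oname), CA, 1.23, 121, 0)
  CB <- .nerf_place(cc, g(oname), CA, 1.50, 116, 180)
  rbind(atoms,
        data.frame(name = paste0("CA", pos), element = "C",
                   x = CA[1], y = CA[2], z = CA[3]),
        data.frame(name = paste0("OA", pos), element = "O",
                   x = OA[1], y = OA[2], z = OA[3]),
        data.frame(name = paste0("CB", pos), element = "C",
                   x = CB[1], y = CB[2], z = CB[3]))
}

# ---- assembly ---------------------------------------------------------

# Atom names used for the phi reference, anomeric oxygen, and the
# (Cp, Cprev) pair serving a given parent attachment position.
.anomeric_oxygen <- function(ano_pos) paste0("O", ano_pos)
.phi_reference <- function(ano_pos) if (ano_pos == 2L) "C1" else "O5"

.attachment_chain <- function(sialic, pos) {
  if (sialic) {
    switch(as.character(pos),
           "4" = c("C4", "C3"), "7" = c("C7", "C6"),
           "8" = c("C8", "C7"), "9" = c("C9", "C8"),
           stop("unsupported attachment position ", pos,
                " on a sialic acid", call. = FALSE))
  } else {
    switch(as.character(pos),
           "2" = c("C2", "C1"), "3" = c("C3", "C2"), "4" = c("C4", "C3"),
           "6" = c("C6", "C5"),
           stop("unsupported attachment position ", pos, call. = FALSE))
  }
}

.default_psi <- -120

#' Build idealized 3-D coordinates for a glycan
#'
#' Assembles per-residue templates along the tree, placing each child at
#' its parent's attachment oxygen with bond length 1.43 A and a 117 deg
#' glycosidic bond angle, then rotating about the glycosidic bonds so the
#' built structure reproduces the requested torsions: phi about the
#' anomeric bond (reference C1 for sialic acids, ring O5 otherwise), psi
#' at the placement step (fixed at the template value of -120 deg when the
#' torsion set does not name it), and omega (O6-C6-C5-O5) by rotation
#' about the exocyclic C5-C6 bond for 6-linked children.
#'
#' @param tree a `glycan_tree`.
#' @param torsions a `torsion_set`; must cover at least `phi` for every
#'   edge (as produced by [enumerate_rotamers()]).
#' @param templates template set as from [default_templates()].
#' @param hard_clash_tol heavy-atom pairs (more than two bonds apart)
#'   closer than this distance abort the build; default 1.0 A.
#' @return a `structure3d` of the glycan heavy atoms.
#' @export
build_structure <- function(tree, torsions, templates = default_templates(),
                            hard_clash_tol = 1.0) {
  stopifnot(inherits(tree, "glycan_tree"), inherits(torsions, "torsion_set"))
  res <- tree$residues
  placed <- list()  # per residue id: data.frame of atoms with coords

  place_residue <- function(id) {
    r <- res[res$id == id, ]
    tf <- templates[[r$name]]
    if (is.null(tf)) stop("no template for residue '", r$name, "'",
                          call. = FALSE)
    a <- tf(r$anomer)
    for (mod in .mod_list(r$mods)) a <- .apply_modification(a, mod)
    a
  }

  tget <- function(kind, child, parent, default = NA_real_) {
    nm <- paste0(kind, ".", child, "-", parent)
    if (nm %in% names(torsions$torsions)) torsions$torsions[[nm]] else default
  }

  attach_child <- function(edge) {
    pid <- edge$parent
    cid <- edge$child
    pa <- placed[[as.character(pid)]]
    child <- place_residue(cid)
    rc <- res[res$id == cid, ]
    sial_parent <- grepl("^Neu", res$name[res$id == pid])
    gp <- function(nm) {
      row <- pa[pa$name == nm, ]
      if (nrow(row) == 0) {
        stop("parent residue lacks attachment atom ", nm, call. = FALSE)
      }
      unlist(row[, c("x", "y", "z")])
    }
    gc_ <- function(df, nm) unlist(df[df$name == nm, c("x", "y", "z")])

    oname <- paste0("O", edge$parent_pos)
    chain <- .attachment_chain(sial_parent, edge$parent_pos)
    Op <- gp(oname)
    Cp <- gp(chain[1])
    Cprev <- gp(chain[2])

    psi <- tget("psi", cid, pid, .default_psi)
    phi <- tget("phi", cid, pid)
    if (is.na(phi)) {
      stop("torsion set does not cover phi for edge ", cid, "->", pid,
           call. = FALSE)
    }
    # target position of the child's anomeric carbon (sets psi)
    ca_name <- paste0("C", rc$ano_pos)
    target_ca <- .nerf_place(Cprev, Cp, Op, 1.43, 117, psi)

    # rigid-align the child: anomeric carbon onto target, anomeric oxygen
    # direction onto the bond toward Op
    oa_name <- .anomeric_oxygen(rc$ano_pos)
    ca <- gc_(child, ca_name)
    oa <- gc_(child, oa_name)
    v_from <- .unit(oa - ca)
    v_to <- .unit(Op - target_ca)
    axis <- .xprod(v_from, v_to)
    cosang <- max(-1, min(1, sum(v_from * v_to)))
    ang <- acos(cosang) * 180 / pi
    xyz <- as.matrix(child[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, ca)
    if (.vnorm(axis) > 1e-9 && ang > 1e-9) {
      xyz <- xyz %*% t(.rotation_matrix(axis, ang))
    } else if (ang > 90) {
      perp <- .unit(.xprod(v_from, c(1, 0, 0) + 1e-3))
      xyz <- xyz %*% t(.rotation_matrix(perp, 180))
    }
    xyz <- sweep(xyz, 2, target_ca, `+`)
    child[, c("x", "y", "z")] <- xyz

    # roll about the glycosidic bond to set phi: ref-Ca-Op-Cp
    refname <- .phi_reference(rc$ano_pos)
    cur <- torsion_angle(gc_(child, refname), gc_(child, ca_name), Op, Cp)
    delta <- phi - cur
    xyz <- .rotate_about(as.matrix(child[, c("x", "y", "z")]),
                         Op, gc_(child, ca_name) - Op, -delta)
    child[, c("x", "y", "z")] <- xyz
    child <- child[child$name != oa_name, , drop = FALSE]
    placed[[as.character(cid)]] <<- child

    # omega for exocyclic 6-attachments: rotate O6 + child subtree about
    # the parent C5-C6 bond (sialic parents expose no 6-O attachment)
    omega <- tget("omega", cid, pid)
    if (!is.na(omega) && edge$parent_pos == 6L && !sial_parent) {
      O5p <- gp("O5")
      C5p <- gp("C5")
      C6p <- gp("C6")
      cur_om <- torsion_angle(Op, C6p, C5p, O5p)
      dlt <- omega - cur_om
      rot <- function(df) {
        df[, c("x", "y", "z")] <- .rotate_about(
          as.matrix(df[, c("x", "y", "z")]), C6p, C5p - C6p, dlt)
        df
      }
      pa[pa$name == oname, c("x", "y", "z")] <-
        .rotate_about(rbind(Op), C6p, C5p - C6p, dlt)
      placed[[as.character(pid)]] <<- pa
      placed[[as.character(cid)]] <<- rot(placed[[as.character(cid)]])
    }
    invisible(NULL)
  }

  # depth-first from the root so omega rotations precede deeper growth
  placed[[as.character(tree$root)]] <- place_residue(tree$root)
  recurse <- function(id) {
    kids <- .child_edges(tree, id)
    for (k in seq_len(nrow(kids))) {
      attach_child(kids[k, ])
      recurse(kids$child[k])
    }
  }
  recurse(tree$root)

  order_ids <- res$id[order(res$id)]
  allatoms <- do.call(rbind, lapply(order_ids, function(id) {
    df <- placed[[as.character(id)]]
    df$resid <- id
    df$residue <- res$name[res$id == id]
    df
  }))
  out <- structure3d(allatoms[, c("name", "element", "resid", "residue",
                                  "x", "y", "z")])

  # hard-clash guard: non-bonded heavy pairs > 2 bonds apart
  heavy <- which(.is_heavy(out))
  if (length(heavy) > 3) {
    D <- as.matrix(stats::dist(coords(out)[heavy, , drop = FALSE]))
    B <- .bond_distances(out, maxdist = 2)[heavy, heavy, drop = FALSE]
    bad <- which(D < hard_clash_tol & !is.finite(B) == FALSE & B > 2 &
                   upper.tri(D), arr.ind = TRUE)
    bad <- which(D < hard_clash_tol & B > 2 & upper.tri(D), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      i <- heavy[bad[1, 1]]
      j <- heavy[bad[1, 2]]
      stop(sprintf("build error: hard internal clash between %s/%d:%s and %s/%d:%s (%.2f A)",
                   out$atoms$residue[i], out$atoms$resid[i], out$atoms$name[i],
                   out$atoms$residue[j], out$atoms$resid[j], out$atoms$name[j],
                   D[bad[1, 1], bad[1, 2]]), call. = FALSE)
    }
  }
  out
}

#' Measure glycosidic torsions of a built structure
#'
#' Inverse of the builder's torsion placement: reports phi (and omega for
#' 6-linked children of aldoses) for every edge of the tree.
#'
#' @param struct a `structure3d` from [build_structure()].
#' @param tree the `glycan_tree` it was built from.
#' @return named numeric vector of torsions in degrees.
#' @export
measure_torsions <- function(struct, tree) {
  res <- tree$residues
  at <- struct$atoms
  g <- function(id, nm) {
    row <- at[at$resid == id & at$name == nm, ]
    if (nrow(row) == 0) return(NULL)
    unlist(row[, c("x", "y", "z")])
  }
  out <- numeric(0)
  for (k in seq_len(nrow(tree$edges))) {
    e <- tree$edges[k, ]
    rc <- res[res$id == e$child, ]
    sial_parent <- grepl("^Neu", res$name[res$id == e$parent])
    chain <- .attachment_chain(sial_parent, e$parent_pos)
    Op <- g(e$parent, paste0("O", e$parent_pos))
    Cp <- g(e$parent, chain[1])
    ca <- g(e$child, paste0("C", rc$ano_pos))
    ref <- g(e$child, .phi_reference(rc$ano_pos))
    out[paste0("phi.", e$child, "-", e$parent)] <-
      torsion_angle(ref, ca, Op, Cp)
    if (e$parent_pos == 6L && !sial_parent) {
      out[paste0("omega.", e$child, "-", e$parent)] <-
        torsion_angle(Op, g(e$parent, "C6"), g(e$parent, "C5"),
                      g(e$parent, "O5"))
    }
  }
  out
}
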