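# Computational carbohydrate grafting: find embeddings of a bound antigen
# core inside glycome entries, grow the extra residues out of the posed
# core with a grid search over the new glycosidic torsions, score steric
# overlap with the receptor, and screen a whole glycome for putative
# off-targets.
#
# Clash definition used throughout: a heavy-atom pair overlaps when their
# distance falls below 0.6 x (sum of van der Waals radii); the clash score
# is the sum of overlap depths (A) and a glycan "fits" when the minimal
# score over the torsion grid is <= the tolerance (0 by default).

.CLASH_FACTOR <- 0.6

# Free attachment oxygen positions of a residue within a tree: positions
# that carry an oxygen in the template and are not used by an edge or a
# modification. Position 1 of the root (the aglycon direction) is
# included.
.free_positions <- function(tree, id) {
  r <- tree$residues[tree$residues$id == id, ]
  sialic <- grepl("^Neu", r$name)
  cand <- if (sialic) c(4L, 7L, 8L, 9L) else c(2L, 3L, 4L, 6L)
  if (r$name %in% c("GalNAc", "GlcNAc")) cand <- setdiff(cand, 2L)
  if (r$name == "Fuc") cand <- setdiff(cand, 6L)
  used <- tree$edges$parent_pos[tree$edges$parent == id]
  modp <- as.integer(sub("[A-Za-z]+$", "", .mod_list(r$mods)))
  cand <- setdiff(cand, c(used, modp))
  if (id == tree$root) cand <- c(1L, cand)
  cand
}

# Human-readable attachment label, e.g. "Neu5Ac#1:O8".
.position_label <- function(tree, id, pos) {
  sprintf("%s#%d:O%d", tree$residues$name[tree$residues$id == id], id, pos)
}

#' Find embeddings of an antigen core inside a glycan
#'
#' An embedding maps every core residue to a glycan residue preserving
#' residue name, anomeric configuration and linkage positions (so
#' Neu5Gc never matches a Neu5Ac core). For each embedding the extensions
#' are enumerated: glycan subtrees hanging off matched residues at
#' positions the core leaves free, including the reducing-end
#' continuation below the core root (attachment position 1).
#'
#' @param glycan a `glycan_tree` (the glycome entry).
#' @param core a `glycan_tree` (the bound antigen, e.g.
#'   `parse_glycan("Neu5Ac(a2-6)GalNAc(a1-")`).
#' @return list of matches; each has `mapping` (named integer vector,
#'   core id -> glycan id) and `extensions` (data frame: `core_residue`,
#'   `position`, `ext_root` = glycan residue id rooting the extension,
#'   `reducing` flag, `label`).
#' @export
match_core <- function(glycan, core) {
  gres <- glycan$residues
  cres <- core$residues
  match_at <- function(cid, gid) {
    cr <- cres[cres$id == cid, ]
    gr <- gres[gres$id == gid, ]
    if (cr$name != gr$name || cr$anomer != gr$anomer) return(NULL)
    mapping <- stats::setNames(gid, cid)
    for (k in seq_len(nrow(core$edges))) {
      e <- core$edges[k, ]
      if (e$parent != cid) next
      ge <- glycan$edges[glycan$edges$parent == gid &
                           glycan$edges$parent_pos == e$parent_pos &
                           glycan$edges$child_pos == e$child_pos, ,
                         drop = FALSE]
      if (nrow(ge) != 1) return(NULL)
      sub <- match_at(e$child, ge$child[1])
      if (is.null(sub)) return(NULL)
      mapping <- c(mapping, sub)
    }
    mapping
  }
  matches <- list()
  for (gid in gres$id) {
    mapping <- match_at(core$root, gid)
    if (is.null(mapping)) next
    # extensions: unmatched glycan children of matched residues
    ext <- list()
    for (cid in as.integer(names(mapping))) {
      gid2 <- mapping[[as.character(cid)]]
      kids <- glycan$edges[glycan$edges$parent == gid2, , drop = FALSE]
      core_kids <- core$edges[core$edges$parent == cid, , drop = FALSE]
      for (k in seq_len(nrow(kids))) {
        if (kids$parent_pos[k] %in% core_kids$parent_pos) next
        ext[[length(ext) + 1]] <- data.frame(
          core_residue = cid, position = kids$parent_pos[k],
          ext_root = kids$child[k], reducing = FALSE,
          label = .position_label(core, cid, kids$parent_pos[k]))
      }
    }
    # reducing-end continuation: the core root's image has a parent
    up <- glycan$edges[glycan$edges$child == mapping[[as.character(core$root)]], ,
                       drop = FALSE]
    if (nrow(up) == 1) {
      ext[[length(ext) + 1]] <- data.frame(
        core_residue = core$root, position = 1L,
        ext_root = up$parent[1], reducing = TRUE,
        label = .position_label(core, core$root, 1L))
    }
    extensions <- if (length(ext) > 0) {
      do.call(rbind, ext)
    } else {
      data.frame(core_residue = integer(0), position = integer(0),
                 ext_root = integer(0), reducing = logical(0),
                 label = character(0))
    }
    matches[[length(matches) + 1]] <- list(mapping = mapping,
                                           extensions = extensions)
  }
  matches
}

# Extract the subtree of `glycan` rooted at `root_id`, excluding the ids
# in `exclude`, as a standalone glycan_tree (ids preserved).
.subtree <- function(glycan, root_id, exclude = integer(0)) {
  keep <- root_id
  repeat {
    nxt <- glycan$edges$child[glycan$edges$parent %in% keep &
                                !glycan$edges$child %in% c(keep, exclude)]
    if (length(nxt) == 0) break
    keep <- c(keep, nxt)
  }
  res <- glycan$residues[glycan$residues$id %in% keep, , drop = FALSE]
  ed <- glycan$edges[glycan$edges$parent %in% keep &
                       glycan$edges$child %in% keep, , drop = FALSE]
  .new_glycan_tree(res, ed, root = root_id)
}

# Default torsions for a subtree from the rotamer library (first value of
# each torsion list).
.default_torsions <- function(tree, library = default_rotamer_library()) {
  if (nrow(tree$edges) == 0) {
    return(torsion_set(stats::setNames(numeric(0), character(0)), 1L))
  }
  enumerate_rotamers(tree, library)[[1]]
}

# Rigidly place a prebuilt subtree at an attachment oxygen. `sub` is a
# structure3d containing the subtree root's anomeric oxygen (oa_name);
# Op/Cp/Cprev are the attachment oxygen and its carbon chain on the fixed
# side. Returns the placed structure with the anomeric oxygen removed.
.place_subtree <- function(sub, ca_name, oa_name, ref_name, root_resid,
                           Op, Cp, Cprev, phi, psi) {
  g <- function(nm) {
    unlist(sub$atoms[sub$atoms$resid == root_resid & sub$atoms$name == nm,
                     c("x", "y", "z")])
  }
  target_ca <- .nerf_place(Cprev, Cp, Op, 1.43, 117, psi)
  ca <- g(ca_name)
  oa <- g(oa_name)
  v_from <- .unit(oa - ca)
  v_to <- .unit(Op - target_ca)
  axis <- .xprod(v_from, v_to)
  ang <- acos(max(-1, min(1, sum(v_from * v_to)))) * 180 / pi
  xyz <- sweep(coords(sub), 2, ca)
  if (.vnorm(axis) > 1e-9 && ang > 1e-9) {
    xyz <- xyz %*% t(.rotation_matrix(axis, ang))
  }
  xyz <- sweep(xyz, 2, target_ca, `+`)
  coords(sub) <- xyz
  cur <- torsion_angle(g(ref_name), g(ca_name), Op, Cp)
  coords(sub) <- .rotate_about(coords(sub), Op, g(ca_name) - Op,
                               -(phi - cur))
  sub$atoms <- sub$atoms[!(sub$atoms$resid == root_resid &
                             sub$atoms$name == oa_name), , drop = FALSE]
  sub
}

# Overlap-depth clash score between extension heavy atoms and the
# environment (receptor + core heavy atoms, minus the attachment
# neighbourhood).
.clash_score <- function(ext_xyz, ext_r, env_xyz, env_r,
                         factor = .CLASH_FACTOR) {
  total <- 0
  for (i in seq_len(nrow(ext_xyz))) {
    d <- sqrt(rowSums(sweep(env_xyz, 2, ext_xyz[i, ])^2))
    thr <- factor * (ext_r[i] + env_r)
    total <- total + sum(pmax(0, thr - d))
  }
  total
}

# Attachment geometry (Op, Cp, Cprev coordinates) for a position on the
# posed core.
.attachment_geometry <- function(core_pose, core_tree, cid, pos) {
  at <- core_pose$atoms
  r <- core_tree$residues[core_tree$residues$id == cid, ]
  sialic <- grepl("^Neu", r$name)
  g <- function(nm) {
    row <- at[at$resid == cid & at$name == nm, ]
    if (nrow(row) == 0) {
      stop("core pose lacks atom ", nm, " on residue ", cid, call. = FALSE)
    }
    unlist(row[, c("x", "y", "z")])
  }
  if (pos == 1L) {
    ref <- if (sialic) "C1" else "O5"
    list(Op = g("O1"), Cp = g("C1"), Cprev = g(ref))
  } else {
    chain <- .attachment_chain(sialic, pos)
    list(Op = g(paste0("O", pos)), Cp = g(chain[1]), Cprev = g(chain[2]))
  }
}

#' Occluded attachment positions of a bound core
#'
#' For each free attachment oxygen of the posed core, probe spheres are
#' placed one bond length from the oxygen along the chemically accessible
#' cone of next-atom directions (117 deg glycosidic bond angle, 12
#' azimuths). A position is occluded when every sampled direction clashes
#' with a receptor atom under the package-wide overlap rule.
#'
#' @param receptor `structure3d` of the receptor.
#' @param core_pose `structure3d` of the bound core (in the receptor
#'   frame).
#' @param core_tree the `glycan_tree` of the core.
#' @param probe_radius probe van der Waals radius in Angstrom (default
#'   1.7, a carbon-sized next atom).
#' @return character vector of occluded position labels (e.g.
#'   `"Neu5Ac#1:O8"`); attribute `"all_positions"` lists every position
#'   probed.
#' @export
occlusion_map <- function(receptor, core_pose, core_tree,
                          probe_radius = 1.7) {
  env_heavy <- receptor$atoms$element != "H"
  env_xyz <- coords(receptor)[env_heavy, , drop = FALSE]
  env_r <- vdw_radius(receptor$atoms$element[env_heavy])
  occluded <- character(0)
  all_pos <- character(0)
  for (cid in core_tree$residues$id) {
    for (pos in .free_positions(core_tree, cid)) {
      lab <- .position_label(core_tree, cid, pos)
      all_pos <- c(all_pos, lab)
      geo <- .attachment_geometry(core_pose, core_tree, cid, pos)
      v <- .unit(geo$Op - geo$Cp)
      ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      p1 <- .unit(.xprod(v, ref))
      p2 <- .xprod(v, p1)
      tilt <- (180 - 117) * pi / 180
      blocked <- TRUE
      for (az in seq(0, 330, by = 30) * pi / 180) {
        dir <- .unit(v * cos(tilt) +
                       sin(tilt) * (cos(az) * p1 + sin(az) * p2))
        centre <- geo$Op + 1.43 * dir
        d <- sqrt(rowSums(sweep(env_xyz, 2, centre)^2))
        if (!any(d < .CLASH_FACTOR * (probe_radius + env_r))) {
          blocked <- FALSE
          break
        }
      }
      if (blocked) occluded <- c(occluded, lab)
    }
  }
  attr(occluded, "all_positions") <- all_pos
  occluded
}

#' Graft a matched glycan onto the bound core
#'
#' The core never moves. Each extension subtree is built from idealized
#' templates at library-default internal torsions and attached at its
#' core position; the attaching linkage's phi and psi are grid-searched
#' within +/-`range_deg` of the library rotamer values in `step_deg`
#' steps, and the verdict uses the minimal clash score found. Extensions
#' are scored independently against receptor plus core (they are disjoint
#' subtrees; extension-extension contacts are not counted).
#'
#' @param match one element of [match_core()] output.
#' @param glycan the glycome entry the match refers to.
#' @param core_tree,core_pose the bound core (tree and posed structure).
#' @param receptor receptor `structure3d`.
#' @param library rotamer library for torsion wells.
#' @param range_deg,step_deg torsion grid half-width and step (degrees).
#' @param tol clash-score tolerance for "fits" (default 0).
#' @return list of class `graft_verdict`: `fits`, `clash_score`,
#'   `blocking` (labels of extensions with positive minimal clash),
#'   `per_extension` (data frame with minimal clash and torsions used).
#' @export
graft <- function(match, glycan, core_tree, core_pose, receptor,
                  library = default_rotamer_library(),
                  range_deg = 30, step_deg = 20, tol = 0) {
  rec_heavy <- receptor$atoms$element != "H"
  rec_parts <- cbind(coords(receptor),
                     vdw_radius(receptor$atoms$element))[rec_heavy, ,
                                                         drop = FALSE]
  core_heavy <- core_pose$atoms$element != "H"
  ext <- match$extensions
  rows <- list()
  total <- 0
  for (k in seq_len(nrow(ext))) {
    cid <- ext$core_residue[k]
    pos <- ext$position[k]
    geo <- .attachment_geometry(core_pose, core_tree, cid, pos)
    # clash environment: all receptor heavy atoms plus the core heavy
    # atoms minus the attachment oxygen's bonded neighbourhood
    sialic_att <- grepl("^Neu",
                        core_tree$residues$name[core_tree$residues$id == cid])
    excl_names <- if (pos == 1L) {
      c("O1", "C1", if (sialic_att) "C2" else "O5")
    } else {
      c(paste0("O", pos), .attachment_chain(sialic_att, pos))
    }
    keep_core <- core_heavy & !(core_pose$atoms$resid == cid &
                                  core_pose$atoms$name %in% excl_names)
    env_parts <- rbind(rec_parts,
                       cbind(coords(core_pose),
                             vdw_radius(core_pose$atoms$element))[keep_core, ,
                                                                  drop = FALSE])
    sub_ids <- if (ext$reducing[k]) {
      setdiff(glycan$residues$id, unname(match$mapping))
    } else {
      NULL
    }
    sub_tree <- if (ext$reducing[k]) {
      .subtree(glycan, ext$ext_root[k], exclude = unname(match$mapping))
    } else {
      .subtree(glycan, ext$ext_root[k])
    }
    sub_struct <- build_structure(sub_tree, .default_torsions(sub_tree, library))
    rootres <- sub_tree$residues[sub_tree$residues$id == sub_tree$root, ]
    if (ext$reducing[k]) {
      # attach by the subtree's own oxygen O<q>, where q is the position
      # the core root hangs from in the full glycan
      upe <- glycan$edges[glycan$edges$child == match$mapping[[as.character(core_tree$root)]], ]
      q <- upe$parent_pos[1]
      sialic <- grepl("^Neu", rootres$name)
      chain <- .attachment_chain(sialic, q)
      ca_name <- chain[1]                # carbon bearing O<q>
      oa_name <- paste0("O", q)
      ref_name <- chain[2]
      cls <- paste0(core_tree$residues$anomer[core_tree$residues$id == core_tree$root],
                    core_tree$residues$ano_pos[core_tree$residues$id == core_tree$root],
                    "-", q)
    } else {
      ca_name <- paste0("C", rootres$ano_pos)
      oa_name <- paste0("O", rootres$ano_pos)
      ref_name <- .phi_reference(rootres$ano_pos)
      upe <- glycan$edges[glycan$edges$child == ext$ext_root[k], ]
      cls <- paste0(rootres$anomer, upe$child_pos[1], "-", upe$parent_pos[1])
    }
    entry <- library[[cls]]
    phi_centres <- if (!is.null(entry$phi)) entry$phi else c(-60)
    grid_off <- seq(-range_deg, range_deg, by = step_deg)
    phis <- unique(as.vector(outer(phi_centres, grid_off, `+`)))
    psis <- unique(.default_psi + grid_off)
    best <- Inf
    best_t <- c(NA_real_, NA_real_)
    for (phi in phis) {
      for (psi in psis) {
        placed <- .place_subtree(sub_struct, ca_name, oa_name, ref_name,
                                 sub_tree$root, geo$Op, geo$Cp, geo$Cprev,
                                 phi, psi)
        heavy <- placed$atoms$element != "H"
        sc <- .clash_score(coords(placed)[heavy, , drop = FALSE],
                           vdw_radius(placed$atoms$element[heavy]),
                           env_parts[, 1:3, drop = FALSE],
                           env_parts[, 4])
        if (sc < best) {
          best <- sc
          best_t <- c(phi, psi)
        }
        if (best <= tol) break
      }
      if (best <= tol) break
    }
    rows[[k]] <- data.frame(label = ext$label[k], min_clash = best,
                            phi = best_t[1], psi = best_t[2])
    total <- total + best
  }
  per_ext <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(label = character(0), min_clash = numeric(0),
               phi = numeric(0), psi = numeric(0))
  }
  structure(list(fits = total <= tol, clash_score = total,
                 blocking = per_ext$label[per_ext$min_clash > tol],
                 per_extension = per_ext),
            class = "graft_verdict")
}

#' @export
print.graft_verdict <- function(x, ...) {
  cat(sprintf("<graft: %s, clash %.3g%s>\n",
              if (x$fits) "fits" else "does not fit", x$clash_score,
              if (length(x$blocking) > 0) {
                paste0(", blocked at ", paste(x$blocking, collapse = ", "))
              } else ""))
  invisible(x)
}

#' Screen a glycome against a bound antigen core
#'
#' Runs [match_core()] and [graft()] for every glycome entry and
#' summarizes how many entries contain the core, how many of those can
#' fit in the binding site, and which attachment positions block the
#' rest. An entry fits when any of its embeddings fits.
#'
#' @param glycome named list of `glycan_tree` objects (see
#'   [read_glycome()]).
#' @param receptor,core_pose,core_tree as in [graft()].
#' @param ... passed to [graft()].
#' @return list of class `glycome_screen`: `per_glycan` data frame
#'   (`glycan_id`, `n_matches`, `fits`, `clash_score`), `summary`
#'   (`n_glycans`, `matched`, `fitting`, `blocked`) and
#'   `blocking_histogram` (named counts by position label).
#' @export
screen_glycome <- function(glycome, receptor, core_pose, core_tree, ...) {
  rows <- list()
  blocking <- character(0)
  for (id in names(glycome)) {
    matches <- match_core(glycome[[id]], core_tree)
    if (length(matches) == 0) {
      rows[[id]] <- data.frame(glycan_id = id, n_matches = 0L,
                               fits = NA, clash_score = NA_real_)
      next
    }
    verdicts <- lapply(matches, graft, glycan = glycome[[id]],
                       core_tree = core_tree, core_pose = core_pose,
                       receptor = receptor, ...)
    scores <- vapply(verdicts, `[[`, numeric(1), "clash_score")
    best <- which.min(scores)
    rows[[id]] <- data.frame(glycan_id = id, n_matches = length(matches),
                             fits = verdicts[[best]]$fits,
                             clash_score = scores[best])
    if (!verdicts[[best]]$fits) {
      blocking <- c(blocking, verdicts[[best]]$blocking)
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  matched <- sum(per$n_matches > 0)
  fitting <- sum(per$fits, na.rm = TRUE)
  structure(list(
    per_glycan = per,
    summary = c(n_glycans = length(glycome), matched = matched,
                fitting = fitting, blocked = matched - fitting),
    blocking_histogram = if (length(blocking) > 0) table(blocking) else table(character(0))),
    class = "glycome_screen")
}

#' @export
print.glycome_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<glycome screen: %d glycans, %d contain the core, %d fit, %d blocked>\n",
              s[["n_glycans"]], s[["matched"]], s[["fitting"]],
              s[["blocked"]]))
  invisible(x)
}
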