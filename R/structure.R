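# Structure3D: a light coordinate carrier for glycan poses, synthetic
# receptor pockets and grafted extensions. Atoms live in a data frame with
# columns name, element, resid (1-based integer), residue (full residue
# name, e.g. "Neu5Ac" or "pocket"), x, y, z (Angstrom).

#' Construct a Structure3D object
#'
#' @param atoms data frame with columns `name`, `element`, `resid`,
#'   `residue`, `x`, `y`, `z`.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms) {
  need <- c("name", "element", "resid", "residue", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("structure3d: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("structure3d: non-finite coordinates", call. = FALSE)
  }
  dup <- duplicated(paste(atoms$resid, atoms$name))
  if (any(dup)) {
    stop("structure3d: duplicate atom names within a residue: ",
         paste(unique(atoms$name[dup]), collapse = ", "), call. = FALSE)
  }
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d: %d atoms, %d residues (%s)>\n",
              nrow(x$atoms), length(unique(x$atoms$resid)),
              paste(unique(x$atoms$residue), collapse = ", ")))
  invisible(x)
}

#' Coordinate matrix of a Structure3D
#' @param x a `structure3d`.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Replace coordinates of a Structure3D
#' @param x a `structure3d`.
#' @param value n x 3 numeric matrix.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(nrow(value) == nrow(x$atoms), ncol(value) == 3)
  x$atoms$x <- value[, 1]
  x$atoms$y <- value[, 2]
  x$atoms$z <- value[, 3]
  x
}

#' Van der Waals radius by element symbol
#' @param element character vector of element symbols.
#' @return numeric vector of radii (Angstrom); 1.7 for unknown elements.
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  r <- unname(tab[element])
  r[is.na(r)] <- 1.70
  r
}

# Element symbol from an atom name: first alphabetic character.
.guess_element <- function(name) {
  toupper(substr(gsub("[^A-Za-z].*$", "",
                      sub("^[0-9]+", "", name)), 1, 1))
}

# Heavy-atom logical index.
.is_heavy <- function(x) x$atoms$element != "H"

# Bond list detected from interatomic distances (0.75-1.85 A between heavy
# atoms, 0.75-1.25 A when a hydrogen is involved). Adequate for idealized
# template geometry; not a perception algorithm for arbitrary chemistry.
.detect_bonds <- function(x) {
  xyz <- coords(x)
  n <- nrow(xyz)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0)))
  d <- as.matrix(stats::dist(xyz))
  hyd <- x$atoms$element == "H"
  hi <- outer(hyd, hyd, `|`)
  upper <- upper.tri(d)
  ok <- upper & d > 0.75 & ifelse(hi, d < 1.25, d < 1.85)
  idx <- which(ok, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

# Pairwise bond-graph distances (number of bonds) up to `maxdist`;
# entries beyond maxdist are Inf.
.bond_distances <- function(x, maxdist = 3) {
  n <- nrow(x$atoms)
  b <- .detect_bonds(x)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  for (s in seq_len(n)) {
    frontier <- s
    for (step in seq_len(maxdist)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      if (length(nxt) == 0) break
      D[s, nxt] <- step
      frontier <- nxt
    }
  }
  D
}

#' Apply a rigid transformation to a structure
#'
#' @param x a `structure3d`.
#' @param R 3x3 rotation matrix (default identity).
#' @param t length-3 translation vector (default zero).
#' @return transformed `structure3d`.
#' @export
transform_structure <- function(x, R = diag(3), t = c(0, 0, 0)) {
  coords(x) <- sweep(coords(x) %*% t(R), 2, t, `+`)
  x
}

#' Merge several structures into one, renumbering residues consecutively
#' @param ... `structure3d` objects.
#' @return a single `structure3d`.
#' @export
merge_structures <- function(...) {
  parts <- list(...)
  off <- 0L
  out <- lapply(parts, function(p) {
    a <- p$atoms
    a$resid <- a$resid - min(a$resid) + 1L + off
    off <<- max(a$resid)
    a
  })
  structure3d(do.call(rbind, out))
}

#' Add idealized hydrogens to carbon atoms
#'
#' Fills each carbon to four-fold valence with C-H bonds of 1.09 Angstrom
#' placed along the remaining tetrahedral directions. Oxygen and nitrogen
#' protons are not added: in D2O STD experiments only carbon-bound protons
#' are observed.
#'
#' @param x a `structure3d` (heavy atoms).
#' @return `structure3d` with hydrogens appended.
#' @export
add_hydrogens <- function(x) {
  xyz <- coords(x)
  b <- .detect_bonds(x)
  n <- nrow(xyz)
  nb <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    nb[[b$i[k]]] <- c(nb[[b$i[k]]], b$j[k])
    nb[[b$j[k]]] <- c(nb[[b$j[k]]], b$i[k])
  }
  newrows <- list()
  for (i in seq_len(n)) {
    if (x$atoms$element[i] != "C") next
    deg <- length(nb[[i]])
    deficit <- 4L - deg
    if (deficit <= 0) next
    ci <- xyz[i, ]
    dirs <- lapply(nb[[i]], function(j) .unit(xyz[j, ] - ci))
    hdirs <- .fill_tetrahedral(dirs, deficit)
    base <- sub("^C", "H", x$atoms$name[i])
    for (k in seq_len(deficit)) {
      nm <- if (deficit == 1) base else paste0(base, k)
      newrows[[length(newrows) + 1]] <- data.frame(
        name = nm, element = "H", resid = x$atoms$resid[i],
        residue = x$atoms$residue[i],
        x = ci[1] + 1.09 * hdirs[[k]][1],
        y = ci[2] + 1.09 * hdirs[[k]][2],
        z = ci[3] + 1.09 * hdirs[[k]][3])
    }
  }
  if (length(newrows) == 0) return(x)
  structure3d(rbind(x$atoms, do.call(rbind, newrows)))
}

# Remaining tetrahedral directions at a centre given unit vectors to the
# bonded neighbours. Returns a list of `k` unit vectors.
.fill_tetrahedral <- function(bonded, k) {
  nb <- length(bonded)
  if (nb == 0) stop("cannot place hydrogens on an unbonded carbon")
  if (nb >= 3) {
    return(list(-.unit(Reduce(`+`, bonded))))
  }
  if (nb == 2) {
    m <- -.unit(bonded[[1]] + bonded[[2]])
    a <- .unit(.xprod(bonded[[1]], bonded[[2]]))
    half <- 54.75 * pi / 180
    out <- list(.unit(m * cos(half) + a * sin(half)),
                .unit(m * cos(half) - a * sin(half)))
    return(out[seq_len(k)])
  }
  # one neighbour: up to three staggered directions at 109.5 deg
  v <- bonded[[1]]
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p1 <- .unit(.xprod(v, ref))
  p2 <- .xprod(v, p1)
  ang <- 109.5 * pi / 180
  out <- lapply(c(0, 120, 240) * pi / 180, function(phi) {
    .unit(-v * cos(ang) + sin(ang) * (cos(phi) * p1 + sin(phi) * p2))
  })
  out[seq_len(k)]
}
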