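# PDB and tabular I/O. Reading goes through bio3d; a small fixed-width
# writer is included because multi-model HETATM output is needed for pose
# ensembles and trajectories.

.resname3 <- function(residue) {
  map <- c(Neu5Ac = "SIA", Neu5Gc = "NGC", GalNAc = "NGA", GlcNAc = "NAG",
           Gal = "GAL", Glc = "GLC", Man = "MAN", Fuc = "FUC",
           pocket = "POC")
  out <- unname(map[residue])
  ifelse(is.na(out), toupper(substr(residue, 1, 3)), out)
}

.resname_full <- function(res3) {
  map <- c(SIA = "Neu5Ac", NGC = "Neu5Gc", NGA = "GalNAc", NAG = "GlcNAc",
           GAL = "Gal", GLC = "Glc", MAN = "Man", FUC = "Fuc",
           POC = "pocket")
  out <- unname(map[res3])
  ifelse(is.na(out), res3, out)
}

.pdb_atom_line <- function(serial, name, res3, resid, x, y, z, element,
                           record = "HETATM") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000, substr(nm, 1, 4), res3, "A", resid %% 10000,
          x, y, z, 1.00, 0.00, element)
}

.structure_lines <- function(s) {
  a <- s$atoms
  res3 <- .resname3(a$residue)
  rec <- ifelse(a$residue == "pocket", "ATOM", "HETATM")
  vapply(seq_len(nrow(a)), function(i) {
    .pdb_atom_line(i, a$name[i], res3[i], a$resid[i],
                   a$x[i], a$y[i], a$z[i], a$element[i], rec[i])
  }, character(1))
}

#' Write one structure or a multi-model ensemble to a PDB file
#'
#' @param x a `structure3d`, or a list of `structure3d` objects sharing
#'   the same atom table (written as MODEL/ENDMDL blocks).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "structure3d")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x) > 1
  for (m in seq_along(x)) {
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    writeLines(.structure_lines(x[[m]]), con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  if (multi) writeLines("END", con)
  invisible(path)
}

# Convert one frame of a bio3d pdb object into a structure3d.
.bio3d_to_structure <- function(pdb, xyz_row = NULL) {
  a <- pdb$atom
  elem <- a$elesy
  missing_el <- is.na(elem) | !nzchar(trimws(elem))
  if (any(missing_el)) {
    warning("PDB element column missing for ", sum(missing_el),
            " atoms; inferred from atom names", call. = FALSE)
    elem[missing_el] <- .guess_element(a$elety[missing_el])
  }
  df <- data.frame(name = trimws(a$elety), element = trimws(elem),
                   resid = a$resno, residue = .resname_full(trimws(a$resid)),
                   x = a$x, y = a$y, z = a$z)
  if (!is.null(xyz_row)) {
    m <- matrix(xyz_row, ncol = 3, byrow = TRUE)
    df$x <- m[, 1]; df$y <- m[, 2]; df$z <- m[, 3]
  }
  structure3d(df)
}

#' Read a single-model PDB file
#' @param path PDB file path.
#' @return a `structure3d`.
#' @export
read_structure_pdb <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  .bio3d_to_structure(pdb)
}

#' Read a multi-model PDB file
#' @param path PDB file path.
#' @return list of `structure3d`, one per MODEL.
#' @export
read_multimodel_pdb <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) .bio3d_to_structure(pdb, pdb$xyz[m, ]))
}

#' Write a pose ensemble (multi-model PDB plus CSV sidecar)
#'
#' @param poses list of `pose_record` objects.
#' @param pdb_path multi-model PDB output path.
#' @param csv_path CSV sidecar path (pose id, model, protocol, rotamer,
#'   snapshot, score).
#' @return invisibly, the two paths.
#' @export
write_pose_ensemble <- function(poses, pdb_path, csv_path) {
  write_pdb(lapply(poses, function(p) p$structure), pdb_path)
  meta <- do.call(rbind, lapply(poses, function(p) {
    data.frame(pose_id = p$id, model = p$model, protocol = p$protocol,
               rotamer = p$rotamer, snapshot = p$snapshot, score = p$score)
  }))
  utils::write.csv(meta, csv_path, row.names = FALSE)
  invisible(c(pdb_path, csv_path))
}

#' Read a pose ensemble written by [write_pose_ensemble()]
#' @param pdb_path multi-model PDB path.
#' @param csv_path CSV sidecar path.
#' @return list of `pose_record` objects.
#' @export
read_pose_ensemble <- function(pdb_path, csv_path) {
  structs <- read_multimodel_pdb(pdb_path)
  meta <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (nrow(meta) != length(structs)) {
    stop("pose CSV rows (", nrow(meta), ") do not match PDB models (",
         length(structs), ")", call. = FALSE)
  }
  lapply(seq_len(nrow(meta)), function(i) {
    pose_record(id = meta$pose_id[i], structure = structs[[i]],
                model = meta$model[i], protocol = meta$protocol[i],
                rotamer = meta$rotamer[i], snapshot = meta$snapshot[i],
                score = meta$score[i])
  })
}

#' Read a titration CSV (glycan_id, glycan_name, concentration_nM, rfu)
#'
#' One row per replicate spot. Out-of-order concentrations are accepted
#' and sorted internally.
#'
#' @param path CSV path.
#' @return named list of `titration_series` objects.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("glycan_id", "glycan_name", "concentration_nM", "rfu")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("titration CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (id in unique(df$glycan_id)) {
    sub <- df[df$glycan_id == id, ]
    sub <- sub[order(sub$concentration_nM), ]
    out[[as.character(id)]] <- titration_series(
      glycan_id = id, glycan_name = sub$glycan_name[1],
      conc_nM = sub$concentration_nM, rfu = sub$rfu)
  }
  out
}

#' Write titration series to CSV
#' @param series named list of `titration_series`.
#' @param path output CSV path.
#' @export
write_titration_csv <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(glycan_id = s$glycan_id, glycan_name = s$glycan_name,
               concentration_nM = s$data$conc_nM, rfu = s$data$rfu)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an experimental STD CSV (label, residue, atom, integral)
#' @param path CSV path.
#' @return named numeric vector of integrals keyed by label.
#' @export
read_std_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "integral") %in% names(df))) {
    stop("STD CSV must have 'label' and 'integral' columns", call. = FALSE)
  }
  stats::setNames(df$integral, df$label)
}

#' Write an STD dataset to CSV
#' @param ds an `std_dataset`.
#' @param path output CSV path.
#' @export
write_std_csv <- function(ds, path) {
  utils::write.csv(ds$data, path, row.names = FALSE)
  invisible(path)
}
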