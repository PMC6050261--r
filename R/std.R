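# Saturation-transfer-difference (STD) NMR support: normalization of
# experimental integrals, a proximity model for predicted enhancements
# (frame-averaged sum of r^-6 over receptor protons within a cutoff),
# the Pearson agreement score, and the final combined pose ranking.

#' Normalize STD integrals to percent of maximum
#'
#' @param integrals named numeric vector of per-proton integrals
#'   (labels unique, values >= 0).
#' @return object of class `std_dataset`: data frame `data` with columns
#'   `label`, `integral`, `intensity` (percent of maximum, max = 100).
#' @export
normalize_std <- function(integrals) {
  stopifnot(is.numeric(integrals), !is.null(names(integrals)))
  if (anyDuplicated(names(integrals)) > 0) {
    stop("STD labels must be unique", call. = FALSE)
  }
  if (any(integrals < 0)) {
    stop("STD integrals must be non-negative", call. = FALSE)
  }
  mx <- max(integrals)
  if (mx <= 0) {
    stop("cannot normalize an all-zero STD dataset (no reference signal)",
         call. = FALSE)
  }
  structure(list(data = data.frame(label = names(integrals),
                                   integral = unname(integrals),
                                   intensity = unname(integrals) * 100 / mx)),
            class = "std_dataset")
}

#' @export
print.std_dataset <- function(x, ...) {
  cat(sprintf("<std_dataset: %d protons, max intensity 100>\n",
              nrow(x$data)))
  invisible(x)
}

# Ligand proton labels: "<Residue><resid>.<name>".
.proton_labels <- function(atoms) {
  sprintf("%s%d.%s", atoms$residue, atoms$resid, atoms$name)
}

#' Predicted STD enhancements for a ligand pose in a receptor
#'
#' Minimal proximity model: for ligand proton j the raw enhancement is
#' S_j = sum over receptor protons i within `cutoff` of r_ij^-6, averaged
#' over frames when a trajectory window is supplied, then normalized to a
#' maximum of 100. Hydrogens are placed with idealized geometry via
#' [add_hydrogens()] when a structure carries none.
#'
#' @param receptor `structure3d` of the receptor (protons added if
#'   absent).
#' @param ligand a `structure3d`, or a list of `structure3d` frames over
#'   which predictions are averaged.
#' @param cutoff proton-proton distance cutoff in Angstrom (default 8).
#' @return an `std_dataset` of predicted intensities, with the raw sums in
#'   attribute-free column `integral`.
#' @export
predict_std <- function(receptor, ligand, cutoff = 8) {
  if (!any(receptor$atoms$element == "H")) receptor <- add_hydrogens(receptor)
  frames <- if (inherits(ligand, "structure3d")) list(ligand) else ligand
  frames <- lapply(frames, function(fr) {
    if (!any(fr$atoms$element == "H")) add_hydrogens(fr) else fr
  })
  lh <- frames[[1]]$atoms$element == "H"
  if (!any(lh)) stop("ligand has no protons", call. = FALSE)
  labels <- .proton_labels(frames[[1]]$atoms[lh, , drop = FALSE])
  rxyz <- coords(receptor)[receptor$atoms$element == "H", , drop = FALSE]
  raw <- rowMeans(vapply(frames, function(fr) {
    lxyz <- coords(fr)[fr$atoms$element == "H", , drop = FALSE]
    vapply(seq_len(nrow(lxyz)), function(j) {
      d2 <- rowSums(sweep(rxyz, 2, lxyz[j, ])^2)
      d2 <- d2[d2 <= cutoff^2]
      if (length(d2) == 0) 0 else sum(d2^-3)
    }, numeric(1))
  }, numeric(sum(lh))))
  if (max(raw) <= 0) {
    # pose entirely out of contact: an all-zero prediction is a valid
    # answer (its agreement with any experimental dataset is undefined)
    return(structure(list(data = data.frame(label = labels, integral = raw,
                                            intensity = raw)),
                     class = "std_dataset"))
  }
  normalize_std(stats::setNames(raw, labels))
}

#' Agreement between predicted and experimental STD intensities
#'
#' Pearson correlation over the shared proton labels of the two
#' normalized datasets, with normalized RMSD as a secondary diagnostic.
#'
#' @param predicted,experimental `std_dataset` objects sharing >= 3
#'   labels.
#' @return list with `score` (Pearson r in `[-1, 1]`, NA when either
#'   vector has zero variance), `nrmsd`, `n_shared` and `undefined`.
#' @export
std_agreement <- function(predicted, experimental) {
  p <- predicted$data
  e <- experimental$data
  shared <- intersect(p$label, e$label)
  if (length(shared) < 3) {
    stop("STD agreement needs at least 3 shared proton labels (got ",
         length(shared), ")", call. = FALSE)
  }
  pv <- p$intensity[match(shared, p$label)]
  ev <- e$intensity[match(shared, e$label)]
  undefined <- stats::sd(pv) == 0 || stats::sd(ev) == 0
  score <- if (undefined) NA_real_ else stats::cor(pv, ev)
  list(score = score,
       nrmsd = sqrt(mean((pv - ev)^2)) / 100,
       n_shared = length(shared),
       undefined = undefined)
}

#' Final combined pose ranking
#'
#' Excludes poses failing the RMSF or docking-rescore thresholds, then
#' ranks survivors by STD agreement (descending), breaking ties by
#' rescore (ascending, i.e. more favourable first).
#'
#' @param cards data frame with columns `pose_id`, `rescore`, `agreement`,
#'   `rmsf`.
#' @param rmsf_max RMSF threshold in Angstrom (default 1.0).
#' @param rescore_max docking rescore threshold in kcal/mol (default 0:
#'   only favourable scores pass).
#' @return list with `selection` (ordered data frame of survivors with a
#'   `rank` column), `top` (best pose id, NA when empty) and `empty`.
#' @export
final_ranking <- function(cards, rmsf_max = 1.0, rescore_max = 0) {
  need <- c("pose_id", "rescore", "agreement", "rmsf")
  miss <- setdiff(need, names(cards))
  if (length(miss) > 0) {
    stop("score cards missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- cards$rmsf <= rmsf_max & cards$rescore <= rescore_max &
    !is.na(cards$agreement)
  surv <- cards[ok, , drop = FALSE]
  if (nrow(surv) == 0) {
    return(list(selection = cbind(surv, rank = integer(0)),
                top = NA_character_, empty = TRUE))
  }
  surv <- surv[order(-surv$agreement, surv$rescore, surv$pose_id), ,
               drop = FALSE]
  surv$rank <- seq_len(nrow(surv))
  rownames(surv) <- NULL
  list(selection = surv, top = surv$pose_id[1], empty = FALSE)
}
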