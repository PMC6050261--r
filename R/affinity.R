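# Glycan-microarray quantification: one-site apparent-KD fits on
# titration series, relative-RFU ranking across antibody concentrations,
# alanine-scan ddG = RT ln(KD/KD_ref), and mutant classification.

# Gas constant in kcal mol^-1 K^-1 and the assay temperature (room
# temperature, 298.15 K) used throughout.
.R_KCAL <- 1.987e-3
.T_DEFAULT <- 298.15

#' Construct a TitrationSeries
#'
#' @param glycan_id identifier.
#' @param glycan_name display name.
#' @param conc_nM concentrations in nM (one per row, > 0).
#' @param rfu relative fluorescence units (replicate measurements; one
#'   value per row of `conc_nM`).
#' @return object of class `titration_series`.
#' @export
titration_series <- function(glycan_id, glycan_name, conc_nM, rfu) {
  stopifnot(length(conc_nM) == length(rfu))
  if (any(conc_nM <= 0)) stop("concentrations must be > 0", call. = FALSE)
  structure(list(glycan_id = glycan_id, glycan_name = glycan_name,
                 data = data.frame(conc_nM = conc_nM, rfu = rfu),
                 fit = NULL),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration %s (%s): %d points", x$glycan_id, x$glycan_name,
              nrow(x$data)))
  if (!is.null(x$fit)) {
    if (x$fit$undetectable) {
      cat(", undetectable binding")
    } else {
      cat(sprintf(", KD = %.4g nM", x$fit$kd))
    }
  }
  cat(">\n")
  invisible(x)
}

#' One-site specific-binding fit of a titration series
#'
#' Least-squares fit of B(C) = Bmax C / (KD + C) to replicate-averaged
#' RFU. Initialization uses Bmax0 = max mean RFU and KD0 = the
#' concentration nearest half-maximal signal, with a deterministic grid
#' fallback over decades when the first attempt fails. The undetectable
#' flag is set when the fit does not converge, the fitted KD exceeds the
#' top tested concentration by more than 100-fold, or an F-test cannot
#' distinguish the fitted curve from a flat (no dose-response) signal at
#' p <= 0.01 -- the regime in which an apparent KD is not calculable.
#'
#' @param series a `titration_series` with >= 4 distinct concentrations.
#' @return the series with a `fit` element: `kd`, `bmax`, `se_kd`,
#'   `se_bmax`, `resid_norm`, `converged`, `undetectable`.
#' @export
fit_one_site <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  df <- series$data
  if (any(df$rfu < 0)) {
    warning("negative RFUs clipped to 0", call. = FALSE)
    df$rfu[df$rfu < 0] <- 0
  }
  agg <- stats::aggregate(rfu ~ conc_nM, data = df, FUN = mean)
  agg <- agg[order(agg$conc_nM), ]
  if (nrow(agg) < 4) {
    stop("one-site fit needs at least 4 distinct concentrations",
         call. = FALSE)
  }
  bmax0 <- max(agg$rfu)
  half <- bmax0 / 2
  kd0 <- agg$conc_nM[which.min(abs(agg$rfu - half))]
  starts <- c(list(c(kd = kd0, bmax = bmax0)),
              lapply(10^seq(-3, 4), function(k) c(kd = k, bmax = bmax0)))
  fit <- NULL
  for (st in starts) {
    if (st[["kd"]] <= 0) next
    fit <- tryCatch(
      minpack.lm::nlsLM(rfu ~ bmax * conc_nM / (kd + conc_nM), data = agg,
                        start = as.list(st),
                        lower = c(kd = 1e-12, bmax = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    series$fit <- list(kd = NA_real_, bmax = NA_real_, se_kd = NA_real_,
                       se_bmax = NA_real_, resid_norm = NA_real_,
                       converged = FALSE, undetectable = TRUE)
    return(series)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kd = NA_real_, bmax = NA_real_))
  res <- stats::resid(fit)
  # F-test of the one-site model against a flat (no-binding) response:
  # when the binding curve does not beat the constant model at p <= 0.01
  # the apparent KD is not calculable from the data.
  rss <- sum(res^2)
  rss0 <- sum((agg$rfu - mean(agg$rfu))^2)
  n <- nrow(agg)
  fstat <- (rss0 - rss) / max(rss / (n - 2), 1e-12)
  p_flat <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  undet <- cf[["kd"]] > 100 * max(agg$conc_nM) || p_flat > 0.01
  series$fit <- list(kd = if (undet) NA_real_ else unname(cf[["kd"]]),
                     bmax = unname(cf[["bmax"]]),
                     se_kd = unname(se[["kd"]]),
                     se_bmax = unname(se[["bmax"]]),
                     resid_norm = sqrt(sum(res^2)),
                     converged = TRUE, undetectable = undet)
  series
}

#' Relative-RFU ranking of array glycans across antibody concentrations
#'
#' Per concentration, each glycan's replicate-mean RFU is expressed as a
#' percentage of that concentration's maximum and converted to a rank
#' (1 = strongest binder); ranks are then averaged across concentrations
#' with their SEM. Both the rank aggregation and the underlying mean
#' percentages are reported.
#'
#' @param df data frame with columns `glycan_id`, `concentration`, `rfu`
#'   (one row per replicate).
#' @return data frame per glycan: `mean_rank`, `sem_rank`, `mean_pct`,
#'   `sem_pct`.
#' @export
relative_rfu_rank <- function(df) {
  need <- c("glycan_id", "concentration", "rfu")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  concs <- unique(df$concentration)
  if (length(concs) < 2) {
    stop("need at least 2 antibody concentrations", call. = FALSE)
  }
  glycans <- unique(df$glycan_id)
  rank_mat <- pct_mat <- matrix(NA_real_, length(glycans), 0)
  for (cc in concs) {
    sub <- df[df$concentration == cc, ]
    means <- vapply(glycans, function(g) mean(sub$rfu[sub$glycan_id == g]),
                    numeric(1))
    if (all(means <= 0)) {
      warning("concentration ", cc, " has all-zero signal; dropped",
              call. = FALSE)
      next
    }
    pct <- means * 100 / max(means)
    rk <- rank(-pct, ties.method = "average")
    rank_mat <- cbind(rank_mat, rk)
    pct_mat <- cbind(pct_mat, pct)
  }
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  data.frame(glycan_id = glycans,
             mean_rank = rowMeans(rank_mat),
             sem_rank = apply(rank_mat, 1, sem),
             mean_pct = rowMeans(pct_mat),
             sem_pct = apply(pct_mat, 1, sem))
}

#' Relative binding free energy from two apparent KDs
#'
#' ddG = RT ln(KD_mut / KD_ref) in kcal/mol with
#' R = 1.987e-3 kcal mol^-1 K^-1; positive values mean the mutation (or
#' glycan variant) weakens binding.
#'
#' @param kd_mut,kd_ref apparent KDs in the same units (nM), > 0.
#' @param temperature assay temperature in K (default 298.15).
#' @return ddG in kcal/mol (vectorized; antisymmetric under swap).
#' @export
ddG <- function(kd_mut, kd_ref, temperature = .T_DEFAULT) {
  if (any(kd_mut <= 0, na.rm = TRUE) || any(kd_ref <= 0, na.rm = TRUE)) {
    stop("KD values must be positive", call. = FALSE)
  }
  .R_KCAL * temperature * log(kd_mut / kd_ref)
}

#' Classify a mutation by its ddG
#'
#' @param ddg ddG in kcal/mol (NA = undetectable binding on either side).
#' @param tol tolerance band around zero in kcal/mol (default 0.5).
#' @return character vector over `minimal`, `destabilizing`,
#'   `stabilizing`, `undetectable`.
#' @export
classify_mutant <- function(ddg, tol = 0.5) {
  out <- ifelse(is.na(ddg), "undetectable",
                ifelse(abs(ddg) <= tol, "minimal",
                       ifelse(ddg > tol, "destabilizing", "stabilizing")))
  unname(out)
}

# KD (or NA when undetectable/missing) out of a fitted series.
.fit_kd <- function(series) {
  if (is.null(series$fit)) {
    stop("titration series for ", series$glycan_id,
         " has not been fitted; call fit_one_site() first", call. = FALSE)
  }
  if (series$fit$undetectable) NA_real_ else series$fit$kd
}

#' Fold-change / ddG table for an alanine-scan panel
#'
#' One record per (mutant, glycan): relative apparent KD
#' (mutant / wild-type), ddG and its class. Undetectable fits propagate
#' as class `"undetectable"` with no number.
#'
#' @param wt_fits named list (by glycan id) of fitted
#'   `titration_series` for the reference antibody.
#' @param mutant_fits named list (by mutant label) of named lists of
#'   fitted `titration_series`.
#' @param temperature assay temperature in K.
#' @param tol classification tolerance in kcal/mol.
#' @return data frame: `mutant`, `glycan_id`, `fold_change`, `ddG`,
#'   `class`.
#' @export
fold_change_table <- function(wt_fits, mutant_fits,
                              temperature = .T_DEFAULT, tol = 0.5) {
  rows <- list()
  for (mut in names(mutant_fits)) {
    for (gly in names(mutant_fits[[mut]])) {
      if (!gly %in% names(wt_fits)) {
        warning("glycan ", gly, " absent from the wild-type panel; skipped",
                call. = FALSE)
        next
      }
      kd_w <- .fit_kd(wt_fits[[gly]])
      kd_m <- .fit_kd(mutant_fits[[mut]][[gly]])
      if (is.na(kd_w) || is.na(kd_m)) {
        rows[[length(rows) + 1]] <- data.frame(
          mutant = mut, glycan_id = gly, fold_change = NA_real_,
          ddG = NA_real_, class = "undetectable")
      } else {
        fc <- kd_m / kd_w
        dg <- ddG(kd_m, kd_w, temperature)
        rows[[length(rows) + 1]] <- data.frame(
          mutant = mut, glycan_id = gly, fold_change = fc, ddG = dg,
          class = classify_mutant(dg, tol))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a fold-change table into a heatmap-ready ddG matrix
#' @param table output of [fold_change_table()].
#' @return numeric matrix mutants x glycans of ddG values (NA where
#'   undetectable).
#' @export
ddG_matrix <- function(table) {
  muts <- unique(table$mutant)
  glys <- unique(table$glycan_id)
  m <- matrix(NA_real_, length(muts), length(glys),
              dimnames = list(muts, glys))
  for (k in seq_len(nrow(table))) {
    m[table$mutant[k], table$glycan_id[k]] <- table$ddG[k]
  }
  m
}
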