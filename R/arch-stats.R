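# Compartment-level aggregation (Table-2-shaped summaries), derived
# whole-muscle quantities, change-with-lengthening statistics, and linear
# mixed models.

ARCH_METRICS <- c("volume_cm3", "pcsa_cm2", "fascicle_length_mm",
                  "pennation_deg", "curvature_per_m")
SUM_METRICS <- c("volume_cm3", "pcsa_cm2")  # summed over compartments

#' Published soleus architecture table (printed cells)
#'
#' The printed per-compartment and whole-muscle architecture cells
#' (mean and SD at short and long muscle lengths, plus the printed
#' long-minus-short change rows) shipped as a plain-text fixture. Used as
#' the input for aggregation checks; all values are as printed, i.e.
#' rounded to one decimal.
#'
#' @return data frame with columns `compartment`, `condition` and
#'   mean/SD pairs for volume, PCSA, fascicle length, pennation and
#'   curvature
#' @export
soleus_table2 <- function() {
  path <- system.file("extdata", "soleus_table2.csv", package = "myotract",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Whole-muscle cells from printed compartment cells
#'
#' Recomputes, from the four printed compartment cells, every derivable
#' whole-muscle mean cell: volume and PCSA by summation over compartments,
#' fascicle length, pennation and curvature by averaging, and change rows
#' as long minus short. This mirrors the per-subject-then-average order of
#' the published table, which is exact for these linear summaries. SDs are
#' not derivable from compartment cells and are not returned.
#'
#' @param cells data frame in the layout of [soleus_table2()] (compartment
#'   rows only; a `Whole-muscle` row is ignored if present)
#' @param digits rounding (half away from zero) applied to the result;
#'   `NULL` for full precision
#' @return data frame with rows Short, Long, Change and one column per
#'   metric
#' @export
whole_muscle_from_cells <- function(cells, digits = 1) {
  cells <- cells[cells$compartment != "Whole-muscle", ]
  stopifnot(all(c("Short", "Long") %in% cells$condition))
  agg <- function(cond, metric) {
    v <- cells[cells$condition == cond, metric]
    if (metric %in% SUM_METRICS) sum(v) else mean(v)
  }
  out <- data.frame(condition = c("Short", "Long", "Change"))
  for (m in ARCH_METRICS) {
    s <- agg("Short", m)
    l <- agg("Long", m)
    out[[m]] <- c(s, l, l - s)
  }
  if (!is.null(digits)) {
    for (m in ARCH_METRICS) out[[m]] <- round_half_up(out[[m]], digits)
  }
  out
}

#' Derived whole-muscle quantities from printed cells
#'
#' Computes, from the printed compartment cells: the posterior volume
#' fraction (MP + LP as a percentage of total volume, each compartment
#' volume taken as the mean of its short- and long-length measurements),
#' the mean total muscle volume on the same averaging, and the
#' posterior-minus-anterior difference in short-length pennation.
#'
#' @param cells data frame in the layout of [soleus_table2()]
#' @param posterior,anterior compartment names
#' @return list with `posterior_fraction_pct`, `total_volume_cm3` and
#'   `pennation_posterior_minus_anterior_deg` (full precision; round for
#'   presentation)
#' @export
derive_abstract_quantities <- function(cells,
                                       posterior = c("MP", "LP"),
                                       anterior = c("MA", "LA")) {
  cells <- cells[cells$compartment != "Whole-muscle", ]
  vol <- function(comp) {
    mean(cells[cells$compartment == comp & cells$condition %in% c("Short", "Long"),
               "volume_cm3"])
  }
  vols <- vapply(c(anterior, posterior), vol, numeric(1))
  total <- sum(vols)
  post <- sum(vols[posterior])
  penn <- function(comp) {
    cells[cells$compartment == comp & cells$condition == "Short", "pennation_deg"]
  }
  list(
    posterior_fraction_pct = 100 * post / total,
    total_volume_cm3 = total,
    pennation_posterior_minus_anterior_deg =
      mean(vapply(posterior, penn, numeric(1))) -
      mean(vapply(anterior, penn, numeric(1)))
  )
}

# validate and complete a records frame; drops subject/compartment pairs
# missing a condition (with a warning)
validate_records <- function(records, metrics = ARCH_METRICS) {
  needed <- c("subject_id", "compartment", "condition", metrics)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(records$condition %in% c("short", "long"))) {
    stop("condition must be 'short' or 'long'")
  }
  key <- interaction(records$subject_id, records$compartment, drop = TRUE)
  keep <- rep(TRUE, nrow(records))
  for (k in levels(key)) {
    rows <- which(key == k)
    if (!setequal(records$condition[rows], c("short", "long"))) {
      keep[rows] <- FALSE
    }
  }
  if (any(!keep)) {
    warning(sum(!keep), " record(s) excluded: subject/compartment pairs ",
            "missing one condition")
  }
  records[keep, , drop = FALSE]
}

# per-subject whole-muscle records (sum volume/PCSA, average the rest)
whole_muscle_records <- function(records) {
  out <- list()
  for (s in unique(records$subject_id)) {
    for (cond in c("short", "long")) {
      r <- records[records$subject_id == s & records$condition == cond, ]
      if (!nrow(r)) next
      row <- data.frame(subject_id = s, compartment = "Whole-muscle",
                        condition = cond)
      for (m in ARCH_METRICS) {
        row[[m]] <- if (m %in% SUM_METRICS) sum(r[[m]]) else mean(r[[m]])
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Table-2-shaped compartment summary
#'
#' Aggregates per-subject compartment records into the published table
#' layout: per compartment and condition, the mean and SD across subjects;
#' change rows are computed within subject (long minus short) before
#' averaging; the whole-muscle rows sum volume and PCSA and average the
#' other metrics over compartments within subject before averaging across
#' subjects.
#'
#' @param records data frame with columns `subject_id`, `compartment`,
#'   `condition` (`"short"`/`"long"`) and the five metric columns
#'   `volume_cm3`, `pcsa_cm2`, `fascicle_length_mm`, `pennation_deg`,
#'   `curvature_per_m`
#' @return long-format data frame: `compartment`, `condition`
#'   (Short/Long/Change), `metric`, `mean`, `sd`, `n_subjects`
#' @export
compartment_table <- function(records) {
  records <- validate_records(records)
  if (!nrow(records)) stop("no complete subject/compartment pairs")
  wm <- whole_muscle_records(records)
  all_rec <- rbind(records[, names(wm)], wm)
  comps <- c(setdiff(unique(records$compartment), "Whole-muscle"),
             "Whole-muscle")
  out <- list()
  for (comp in comps) {
    r <- all_rec[all_rec$compartment == comp, ]
    subj <- unique(r$subject_id)
    for (m in ARCH_METRICS) {
      short <- vapply(subj, function(s) {
        r[[m]][r$subject_id == s & r$condition == "short"]
      }, numeric(1))
      long <- vapply(subj, function(s) {
        r[[m]][r$subject_id == s & r$condition == "long"]
      }, numeric(1))
      chg <- long - short
      for (cond in c("Short", "Long", "Change")) {
        v <- switch(cond, Short = short, Long = long, Change = chg)
        out[[length(out) + 1]] <- data.frame(
          compartment = comp, condition = cond, metric = m,
          mean = mean(v), sd = stats::sd(v), n_subjects = length(v)
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Format a compartment summary as a printed report table
#'
#' Rounds half away from zero to one decimal and lays the summary out as
#' `mean +/- sd` cells, one row per compartment x condition.
#'
#' @param summary result of [compartment_table()]
#' @return wide data frame of character cells
#' @export
format_table2 <- function(summary) {
  cell <- function(m, s) {
    sprintf("%.1f ± %.1f", round_half_up(m, 1), round_half_up(s, 1))
  }
  combos <- unique(summary[, c("compartment", "condition")])
  out <- combos
  for (met in unique(summary$metric)) {
    out[[met]] <- vapply(seq_len(nrow(combos)), function(i) {
      r <- summary[summary$compartment == combos$compartment[i] &
                     summary$condition == combos$condition[i] &
                     summary$metric == met, ]
      cell(r$mean, r$sd)
    }, character(1))
  }
  out
}

#' Posterior volume fraction
#'
#' Per subject, each compartment volume is the mean of its short- and
#' long-length measurements; the fraction is the posterior share of the
#' total, in percent, averaged across subjects.
#'
#' @param records as in [compartment_table()]
#' @param posterior,anterior compartment names (all four must be present)
#' @return list with `mean_pct`, `sd_pct` and `per_subject`
#' @export
posterior_fraction <- function(records, posterior = c("MP", "LP"),
                               anterior = c("MA", "LA")) {
  records <- validate_records(records)
  need <- c(posterior, anterior)
  if (!all(need %in% records$compartment)) {
    stop("missing compartment(s): ",
         paste(setdiff(need, unique(records$compartment)), collapse = ", "))
  }
  subj <- unique(records$subject_id)
  fr <- vapply(subj, function(s) {
    v <- vapply(need, function(comp) {
      mean(records$volume_cm3[records$subject_id == s &
                                records$compartment == comp])
    }, numeric(1))
    100 * sum(v[posterior]) / sum(v)
  }, numeric(1))
  list(mean_pct = mean(fr), sd_pct = stats::sd(fr),
       per_subject = stats::setNames(fr, subj))
}

#' Architecture change per centimetre of muscle-tendon lengthening
#'
#' Within each subject, the long-minus-short change in each metric divided
#' by that subject's muscle-tendon unit (MTU) length change in cm, then
#' summarised (mean and SD) across subjects, per compartment and for the
#' whole muscle. Subjects with zero MTU change are excluded with a
#' warning.
#'
#' @param records as in [compartment_table()]
#' @param mtu data frame with columns `subject_id` and `delta_mtu_mm`
#'   (long minus short)
#' @return long-format data frame: `compartment`, `metric`,
#'   `mean_per_cm`, `sd_per_cm`, `n_subjects`; per-subject values in
#'   attribute `per_subject`
#' @export
per_cm_change <- function(records, mtu) {
  records <- validate_records(records)
  stopifnot(all(c("subject_id", "delta_mtu_mm") %in% names(mtu)))
  bad <- mtu$subject_id[mtu$delta_mtu_mm == 0 | !is.finite(mtu$delta_mtu_mm)]
  if (length(bad)) {
    warning("subject(s) excluded for zero/non-finite MTU change: ",
            paste(bad, collapse = ", "))
    records <- records[!(records$subject_id %in% bad), ]
    mtu <- mtu[!(mtu$subject_id %in% bad), ]
  }
  wm <- whole_muscle_records(records)
  all_rec <- rbind(records[, names(wm)], wm)
  comps <- c(setdiff(unique(records$compartment), "Whole-muscle"),
             "Whole-muscle")
  per_subject <- list()
  out <- list()
  for (comp in comps) {
    r <- all_rec[all_rec$compartment == comp, ]
    subj <- intersect(unique(r$subject_id), mtu$subject_id)
    for (m in ARCH_METRICS) {
      v <- vapply(subj, function(s) {
        chg <- r[[m]][r$subject_id == s & r$condition == "long"] -
          r[[m]][r$subject_id == s & r$condition == "short"]
        chg / (mtu$delta_mtu_mm[mtu$subject_id == s] / 10)
      }, numeric(1))
      per_subject[[paste(comp, m, sep = ".")]] <- stats::setNames(v, subj)
      out[[length(out) + 1]] <- data.frame(
        compartment = comp, metric = m,
        mean_per_cm = mean(v), sd_per_cm = stats::sd(v),
        n_subjects = length(v)
      )
    }
  }
  res <- do.call(rbind, out)
  attr(res, "per_subject") <- per_subject
  res
}

# ---- linear mixed models ------------------------------------------------

lmm_result <- function(fit, contrasts) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  subj_var <- vc$vcov[vc$grp == "subject_id"]
  res_var <- vc$vcov[vc$grp == "Residual"]
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  structure(list(
    fixed = data.frame(
      term = names(est), estimate = unname(est), se = unname(se),
      z = unname(z), p = unname(2 * stats::pnorm(-abs(z)))
    ),
    varcomp = c(subject_intercept = subj_var, residual = res_var),
    singular = lme4::isSingular(fit),
    contrasts = contrasts,
    fit = fit
  ), class = "myo_lmm_result")
}

#' @export
print.myo_lmm_result <- function(x, ...) {
  cat("<myo_lmm_result>", if (x$singular) "(singular fit)" else "", "\n")
  print(x$fixed, row.names = FALSE, digits = 4)
  cat("variance components: subject", format(x$varcomp[1], digits = 4),
      ", residual", format(x$varcomp[2], digits = 4), "\n")
  invisible(x)
}

# Wald tests for linear combinations of fixed effects; Holm column is an
# addition beyond the unadjusted presentation and is labelled as such.
wald_contrasts <- function(fit, L) {
  est <- as.vector(L %*% lme4::fixef(fit))
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(L %*% V %*% t(L)))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    contrast = rownames(L), estimate = est, se = se, z = z, p = p,
    p_holm = stats::p.adjust(p, "holm")
  )
}

#' Mixed model for between-compartment differences
#'
#' REML fit of `metric ~ 0 + compartment + (1 | subject_id)` on
#' short-length records (cell-means coding, so fixed effects are the
#' compartment means), with unadjusted pairwise Wald contrasts between
#' compartments and a clearly labelled Holm-adjusted column. A singular
#' fit (zero subject variance) is retained and flagged.
#'
#' @param records short-length records: `subject_id`, `compartment` and
#'   the metric column
#' @param metric metric column name
#' @return a `myo_lmm_result`
#' @export
lmm_compartment <- function(records, metric = "pennation_deg") {
  stopifnot(metric %in% names(records))
  df <- data.frame(
    subject_id = factor(records$subject_id),
    compartment = factor(records$compartment),
    value = records[[metric]]
  )
  if (nlevels(df$subject_id) < 2 || nlevels(df$compartment) < 2) {
    stop("need at least 2 subjects and 2 compartments")
  }
  fit <- suppressMessages(lme4::lmer(
    value ~ 0 + compartment + (1 | subject_id), data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  lev <- levels(df$compartment)
  pairs <- utils::combn(seq_along(lev), 2)
  L <- matrix(0, ncol(pairs), length(lev))
  rn <- character(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    L[i, pairs[1, i]] <- 1
    L[i, pairs[2, i]] <- -1
    rn[i] <- paste(lev[pairs[1, i]], "-", lev[pairs[2, i]])
  }
  rownames(L) <- rn
  lmm_result(fit, wald_contrasts(fit, L))
}

#' Mixed model for change with passive lengthening
#'
#' REML fit of `metric ~ compartment * condition + (1 | subject_id)` with
#' `short` as the reference condition. The reported contrasts are the
#' within-compartment long-minus-short changes and the between-compartment
#' differences in change (the interactions).
#'
#' @param records both-condition records as in [compartment_table()]
#' @param metric metric column name
#' @return a `myo_lmm_result`
#' @export
lmm_lengthening <- function(records, metric = "pennation_deg") {
  stopifnot(metric %in% names(records))
  df <- data.frame(
    subject_id = factor(records$subject_id),
    compartment = factor(records$compartment),
    condition = factor(records$condition, levels = c("short", "long")),
    value = records[[metric]]
  )
  single_comp <- nlevels(df$compartment) < 2
  form <- if (single_comp) {
    value ~ condition + (1 | subject_id)
  } else {
    value ~ compartment * condition + (1 | subject_id)
  }
  fit <- suppressMessages(lme4::lmer(
    form, data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  fe <- lme4::fixef(fit)
  lev <- levels(df$compartment)
  if (single_comp) {
    L <- matrix(0, 1, length(fe),
                dimnames = list("change", names(fe)))
    L[1, "conditionlong"] <- 1
  } else {
    # change within each compartment, then pairwise differences in change
    nmain <- length(fe)
    terms <- names(fe)
    rows <- list()
    for (k in seq_along(lev)) {
      l <- stats::setNames(numeric(nmain), terms)
      l["conditionlong"] <- 1
      inter <- paste0("compartment", lev[k], ":conditionlong")
      if (inter %in% terms) l[inter] <- 1
      rows[[paste0("change:", lev[k])]] <- l
    }
    pairs <- utils::combn(seq_along(lev), 2)
    for (i in seq_len(ncol(pairs))) {
      a <- rows[[paste0("change:", lev[pairs[1, i]])]]
      b <- rows[[paste0("change:", lev[pairs[2, i]])]]
      rows[[paste("dchange:", lev[pairs[1, i]], "-", lev[pairs[2, i]])]] <- a - b
    }
    L <- do.call(rbind, rows)
  }
  lmm_result(fit, wald_contrasts(fit, L))
}
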