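# compartment aggregation, derived quantities and mixed models

published_cells <- function() {
  t2 <- soleus_table2()
  t2[t2$compartment != "Whole-muscle", ]
}

test_that("whole-muscle cells derivable from compartment cells reproduce print", {
  wm <- whole_muscle_from_cells(published_cells())
  t2 <- soleus_table2()
  printed <- t2[t2$compartment == "Whole-muscle", ]
  get <- function(cond, m) printed[printed$condition == cond, m]
  # 11 of 15 cells are exactly derivable from the rounded compartment cells
  expect_equal(wm$volume_cm3, c(362.2, 349.1, -13.1))
  expect_equal(wm$fascicle_length_mm[1], get("Short", "fascicle_length_mm"))
  expect_equal(wm$fascicle_length_mm[2], get("Long", "fascicle_length_mm"))
  expect_equal(wm$fascicle_length_mm[3], get("Change", "fascicle_length_mm"))
  expect_equal(wm$pcsa_cm2[1], get("Short", "pcsa_cm2"))
  expect_equal(wm$pennation_deg[1], get("Short", "pennation_deg"))
  expect_equal(wm$curvature_per_m[1], get("Short", "curvature_per_m"))
  expect_equal(wm$curvature_per_m[3], get("Change", "curvature_per_m"))
  # the remaining cells (PCSA long/change, pennation long, curvature long)
  # cannot be reproduced exactly because the printed
  # compartment cells are themselves rounded to 0.1 (the published table
  # aggregated unrounded per-subject data); rounding propagation is at
  # most one printed ulp
  for (m in c("pcsa_cm2", "pennation_deg", "curvature_per_m")) {
    for (i in 1:3) {
      expect_lt(abs(wm[[m]][i] - get(wm$condition[i], m)), 0.1 + 1e-9)
    }
  }
})

test_that("abstract-level derived quantities match the published values", {
  q <- derive_abstract_quantities(published_cells())
  expect_equal(round(q$posterior_fraction_pct), 80)
  expect_equal(round(q$total_volume_cm3), 356)
  expect_equal(round(q$pennation_posterior_minus_anterior_deg), 12)
})

test_that("posterior fraction handles the degenerate volume splits", {
  rec <- expand.grid(subject_id = "S1", compartment = c("MA", "LA", "MP", "LP"),
                     condition = c("short", "long"),
                     stringsAsFactors = FALSE)
  for (m in c("volume_cm3", "pcsa_cm2", "fascicle_length_mm",
              "pennation_deg", "curvature_per_m")) {
    rec[[m]] <- 10
  }
  expect_equal(posterior_fraction(rec)$mean_pct, 50)
  rec2 <- rec
  rec2$volume_cm3[rec2$compartment %in% c("MA", "LA")] <- 0
  expect_equal(posterior_fraction(rec2)$mean_pct, 100)
  expect_error(posterior_fraction(rec[rec$compartment != "LP", ]),
               "missing compartment")
})

make_records <- function(n_subjects = 3, comps = c("MA", "LA", "MP", "LP"),
                         seed = 1) {
  set.seed(seed)
  rec <- expand.grid(subject_id = paste0("S", seq_len(n_subjects)),
                     compartment = comps,
                     condition = c("short", "long"),
                     stringsAsFactors = FALSE)
  rec$volume_cm3 <- stats::runif(nrow(rec), 30, 150)
  rec$pcsa_cm2 <- stats::runif(nrow(rec), 8, 45)
  rec$fascicle_length_mm <- stats::runif(nrow(rec), 30, 55)
  rec$pennation_deg <- stats::runif(nrow(rec), 15, 40)
  rec$curvature_per_m <- stats::runif(nrow(rec), 5, 25)
  rec
}

test_that("compartment_table computes change within subject and whole-muscle sums", {
  rec <- make_records()
  tab <- compartment_table(rec)
  # change = mean over subjects of within-subject long - short
  for (comp in c("MA", "LP")) {
    chg <- sapply(unique(rec$subject_id), function(s) {
      rec$pennation_deg[rec$subject_id == s & rec$compartment == comp &
                          rec$condition == "long"] -
        rec$pennation_deg[rec$subject_id == s & rec$compartment == comp &
                            rec$condition == "short"]
    })
    row <- tab[tab$compartment == comp & tab$condition == "Change" &
                 tab$metric == "pennation_deg", ]
    expect_equal(row$mean, mean(chg))
    expect_equal(row$sd, stats::sd(chg))
  }
  # whole muscle: volume summed, length averaged, per subject first
  wm_vol <- sapply(unique(rec$subject_id), function(s) {
    sum(rec$volume_cm3[rec$subject_id == s & rec$condition == "short"])
  })
  row <- tab[tab$compartment == "Whole-muscle" & tab$condition == "Short" &
               tab$metric == "volume_cm3", ]
  expect_equal(row$mean, mean(wm_vol))
  wm_len <- sapply(unique(rec$subject_id), function(s) {
    mean(rec$fascicle_length_mm[rec$subject_id == s & rec$condition == "short"])
  })
  row2 <- tab[tab$compartment == "Whole-muscle" & tab$condition == "Short" &
                tab$metric == "fascicle_length_mm", ]
  expect_equal(row2$mean, mean(wm_len))
})

test_that("single subject, single compartment: whole muscle equals the compartment", {
  rec <- make_records(n_subjects = 1, comps = "MA")
  tab <- suppressWarnings(compartment_table(rec))
  for (m in unique(tab$metric)) {
    a <- tab[tab$compartment == "MA" & tab$metric == m, "mean"]
    b <- tab[tab$compartment == "Whole-muscle" & tab$metric == m, "mean"]
    expect_equal(a, b)
  }
})

test_that("incomplete subject/compartment pairs are excluded with a warning", {
  rec <- make_records()
  rec <- rec[!(rec$subject_id == "S1" & rec$compartment == "MA" &
                 rec$condition == "long"), ]
  expect_warning(tab <- compartment_table(rec), "excluded")
  row <- tab[tab$compartment == "MA" & tab$metric == "volume_cm3" &
               tab$condition == "Short", ]
  expect_equal(row$n_subjects, 2)
})

test_that("per-cm change scales correctly and excludes zero MTU changes", {
  rec <- make_records(n_subjects = 2, comps = c("MA", "LA"))
  # force a known change: +10 mm fascicle length for S1
  rec$fascicle_length_mm <- 40
  rec$fascicle_length_mm[rec$subject_id == "S1" & rec$condition == "long"] <- 50
  mtu <- data.frame(subject_id = c("S1", "S2"), delta_mtu_mm = c(20, 30))
  pcc <- per_cm_change(rec, mtu)
  r <- pcc[pcc$compartment == "MA" & pcc$metric == "fascicle_length_mm", ]
  # S1: 10 mm over 2 cm = 5; S2: 0
  expect_equal(r$mean_per_cm, 2.5)

  # scale consistency: doubling the change doubles the estimate
  rec2 <- rec
  rec2$fascicle_length_mm[rec2$subject_id == "S1" & rec2$condition == "long"] <- 60
  pcc2 <- per_cm_change(rec2, mtu)
  r2 <- pcc2[pcc2$compartment == "MA" & pcc2$metric == "fascicle_length_mm", ]
  expect_equal(r2$mean_per_cm, 5)

  mtu0 <- data.frame(subject_id = c("S1", "S2"), delta_mtu_mm = c(20, 0))
  expect_warning(pcc0 <- per_cm_change(rec, mtu0), "excluded")
  r0 <- pcc0[pcc0$compartment == "MA" & pcc0$metric == "fascicle_length_mm", ]
  expect_equal(r0$n_subjects, 1)
})

test_that("zero-variance balanced data: fixed effects equal group means and OLS", {
  comps <- c("MA", "LA", "MP", "LP")
  mu <- c(MA = 22, LA = 27, MP = 38, LP = 35)
  rec <- expand.grid(subject_id = paste0("S", 1:4), compartment = comps,
                     stringsAsFactors = FALSE)
  rec$pennation_deg <- mu[rec$compartment]
  # tiny jitter: keeps lmer defined while variance ~ 0
  set.seed(5)
  rec$pennation_deg <- rec$pennation_deg + stats::rnorm(nrow(rec), 0, 1e-4)
  fit <- lmm_compartment(rec, "pennation_deg")
  means <- tapply(rec$pennation_deg, rec$compartment, mean)
  est <- fit$fixed$estimate
  names(est) <- sub("compartment", "", fit$fixed$term)
  expect_equal(unname(est[names(means)]), unname(c(means)), tolerance = 1e-6)
  ols <- stats::lm(pennation_deg ~ 0 + compartment, data = rec)
  expect_equal(unname(est[names(means)]),
               unname(stats::coef(ols)[paste0("compartment", names(means))]),
               tolerance = 1e-6)
  expect_true(fit$singular)
  expect_true(all(fit$varcomp >= 0))
})

test_that("a simulated posterior-vs-anterior pennation difference is recovered", {
  set.seed(31)
  beta <- c(MA = 22, LA = 25, MP = 36, LP = 35)   # posterior ~ 12 deg larger
  rec <- simulate_cohort(6, beta, sigma_subject = 1, sigma_e = 0.5)
  names(rec)[names(rec) == "value"] <- "pennation_deg"
  fit <- lmm_compartment(rec, "pennation_deg")
  cpa <- 0.5 * (fit$fixed$estimate[fit$fixed$term == "compartmentMP"] +
                  fit$fixed$estimate[fit$fixed$term == "compartmentLP"]) -
    0.5 * (fit$fixed$estimate[fit$fixed$term == "compartmentMA"] +
             fit$fixed$estimate[fit$fixed$term == "compartmentLA"])
  expect_equal(cpa, 12, tolerance = 0.15)
  # pairwise contrasts carry unadjusted and Holm-adjusted p-values
  expect_true(all(c("p", "p_holm") %in% names(fit$contrasts)))
  expect_true(all(fit$contrasts$p_holm >= fit$contrasts$p - 1e-12))
})

test_that("lengthening model recovers null interactions and collapses to paired", {
  set.seed(17)
  beta <- c(MA = 20, LA = 22, MP = 30, LP = 28)
  chg <- c(MA = 8, LA = 8, MP = 8, LP = 8)        # identical change: no interaction
  rec <- simulate_cohort(6, beta, 1, 0.4, conditions = c("short", "long"),
                         beta_long = chg)
  names(rec)[names(rec) == "value"] <- "fascicle_length_mm"
  fit <- lmm_lengthening(rec, "fascicle_length_mm")
  dch <- fit$contrasts[grepl("^dchange", fit$contrasts$contrast), ]
  expect_true(all(abs(dch$estimate) < 2.58 * dch$se + 1e-9))
  ch <- fit$contrasts[grepl("^change:", fit$contrasts$contrast), ]
  expect_equal(ch$estimate, rep(8, 4), tolerance = 0.25)

  # single compartment reduces to the paired-condition model
  rec1 <- rec[rec$compartment == "MA", ]
  fit1 <- lmm_lengthening(rec1, "fascicle_length_mm")
  expect_equal(fit1$contrasts$estimate[1], 8, tolerance = 0.5)
})

test_that("rounding for report tables is half away from zero", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(21.15, 1), 21.2)
  expect_equal(round_half_up(2.345, 2), 2.35)
  tab <- compartment_table(make_records())
  ft <- format_table2(tab)
  expect_true(all(grepl("±", ft$volume_cm3)))
})
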