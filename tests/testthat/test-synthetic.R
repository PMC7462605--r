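test_that("identical config and seed give byte-identical output tables", {
  cfg <- quick_config(seed = 42)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in c("relocations.csv", "individuals.csv", "scans.csv",
              "hunts.csv", "truth.json")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "sim_c")
  write_dataset(simulate_dataset(quick_config(seed = 43)), d3)
  expect_false(tools::md5sum(file.path(d1, "hunts.csv")) ==
                 tools::md5sum(file.path(d3, "hunts.csv")))
})

test_that("individuals respect group structure and presence windows", {
  cfg <- quick_config(seed = 2)
  ind <- generate_individuals(cfg)
  expect_equal(nrow(ind), 10 + 16)
  expect_equal(sum(ind$sex == "M" & ind$group_id == "Ekalakala"), 4)
  expect_true(all(ind$present_from <= ind$present_to))
  expect_true(all(ind$present_from >= cfg$start_date))
  expect_true(all(ind$present_to <= cfg$start_date + cfg$n_days - 1))
  # some turnover is simulated
  expect_gt(length(unique(ind$present_from)), 1)
})

test_that("intergroup-day probability controls mixed scans", {
  ind_groups <- function(scans, ind) {
    grp <- setNames(ind$group_id, ind$individual_id)
    vapply(split(grp[as.character(scans$individual_id)], scans$scan_id),
           function(g) length(unique(g)), integer(1))
  }
  cfg0 <- quick_config(seed = 8, p_intergroup_day = 0)
  ind <- generate_individuals(cfg0)
  sc0 <- generate_party_scans(cfg0, ind)
  expect_true(all(ind_groups(sc0, ind) == 1))
  # 1000 days: mixed-day fraction within 99% binomial bounds of 0.31
  cfg <- sim_config(seed = 9, n_days = 1000, scans_per_day = 4,
                    p_intergroup_day = 0.31)
  ind <- generate_individuals(cfg)
  sc <- generate_party_scans(cfg, ind)
  mixed_scan <- ind_groups(sc, ind) >= 2
  scan_day <- vapply(strsplit(names(mixed_scan), "_"), function(p)
    p[[length(p) - 1]], character(1))
  frac <- mean(vapply(split(mixed_scan, scan_day), any, TRUE))
  se <- sqrt(0.31 * 0.69 / 1000)
  expect_lt(abs(frac - 0.31), 2.576 * se)
})

test_that("full cohesion yields complete scans and unit within-group SRI", {
  cfg <- quick_config(seed = 3, cohesion = c(1, 1), p_intergroup_day = 0)
  ind <- generate_individuals(cfg)
  sc <- generate_party_scans(cfg, ind)
  # every group scan contains every group member present that day
  always <- ind[ind$present_from == cfg$start_date &
                  ind$present_to == cfg$start_date + cfg$n_days - 1, ]
  year <- format(cfg$start_date, "%Y")
  sri <- compute_sri(sc, year, ind)
  for (g in unique(always$group_id)) {
    ids <- always$individual_id[always$group_id == g]
    vals <- sri$values[ids, ids][upper.tri(diag(length(ids)))]
    expect_true(all(vals == 1), label = paste("SRI within", g))
  }
})

test_that("prey frequencies follow the softmax of the true coefficients", {
  # ~3000 hunts, all coefficients zero: categories near-uniform
  tc0 <- default_true_coefficients()
  tc0[] <- 0
  cfg <- sim_config(seed = 14, n_days = 120, scans_per_day = 4,
                    relocations_per_day = 10, hunt_rate_per_day = 12.5,
                    true_coefficients = tc0, cell_size = 0.2)
  sim <- suppressMessages(simulate_dataset(cfg))
  n <- nrow(sim$hunts)
  expect_gt(n, 2500)
  freq <- table(factor(sim$hunts$prey, levels = PREY_LEVELS)) / n
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))

  # default coefficients: group-B frequencies match the closed-form softmax
  cfg2 <- sim_config(seed = 15, n_days = 120, scans_per_day = 4,
                     relocations_per_day = 10, hunt_rate_per_day = 12.5,
                     cell_size = 0.2)
  sim2 <- suppressMessages(simulate_dataset(cfg2))
  hB <- sim2$hunts[sim2$hunts$catcher_group == "Kokoalongo", ]
  eta <- c(0, -3.25 + 4.5, -3.3 + 5.0)
  pB <- exp(eta) / sum(exp(eta))
  freqB <- table(factor(hB$prey, levels = PREY_LEVELS)) / nrow(hB)
  seB <- sqrt(pB * (1 - pB) / nrow(hB))
  expect_true(all(abs(freqB - pB) < 4 * seB))
  # group A: anomalure is modal under the negative intercepts
  hA <- sim2$hunts[sim2$hunts$catcher_group == "Ekalakala", ]
  expect_equal(names(which.max(table(hA$prey))), "anomalure")
})

test_that("overlap calibration hits the target and handles the endpoints", {
  # disjoint ranges: target 0 is met exactly
  cfg0 <- sim_config(seed = 5, n_days = 80,
                     range_centers = rbind(c(0, 0), c(100, 0)),
                     overlap_target = 0)
  w0 <- calibrate_mixture_weight(cfg0)
  expect_equal(w0, 0)
  cfg0$mixture_weight <- 0
  rel <- generate_relocations(cfg0)
  uds <- fit_kde_groups(rel, cell_size = 0.5)
  ov0 <- overlap_fraction(uds[[1]], uds[[2]], 95)
  expect_equal(ov0$fraction_a_in_b, 0)
  expect_equal(ov0$fraction_b_in_a, 0)
  expect_equal(ov0$shared_area_km2, 0)
  # identical ranging distributions: overlap far above 0.9
  cfgi <- sim_config(seed = 6, n_days = 80,
                     range_centers = rbind(c(0, 0), c(0, 0)),
                     mixture_weight = 0)
  reli <- generate_relocations(cfgi)
  udsi <- fit_kde_groups(reli, cell_size = 0.2)
  ovi <- overlap_fraction(udsi[[1]], udsi[[2]], 95)
  expect_gt(min(ovi$fraction_a_in_b, ovi$fraction_b_in_a), 0.9)
  # default geometry: realized overlap within 0.10 of the 0.65 target
  cfgd <- sim_config(seed = 7, n_days = 200)
  reld <- generate_relocations(cfgd)
  udsd <- fit_kde_groups(reld, cell_size = 0.1)
  ovd <- overlap_fraction(udsd[[1]], udsd[[2]], 95)
  expect_lt(abs(mean(c(ovd$fraction_a_in_b, ovd$fraction_b_in_a)) - 0.65),
            0.10)
})

test_that("generated covariates are non-degenerate and hunts well-formed", {
  cfg <- quick_config(seed = 21)
  sim <- suppressMessages(simulate_dataset(cfg))
  cov <- attr(sim$hunts, "covariates")
  expect_true(all(sim$hunts$prey %in% PREY_LEVELS))
  expect_true(all(sim$hunts$success == 1))
  for (col in c("n_available_males", "n_available_females",
                "mean_association", "usage_difference", "sin_date",
                "cos_date")) {
    expect_true(all(is.finite(cov[[col]])), label = paste(col, "finite"))
    expect_gt(sd(cov[[col]]), 0, label = paste(col, "sd"))
  }
  # standardized design used for generation has unit scale
  consts <- attr(sim$hunts, "standardization_constants")
  expect_true(all(consts$sd > 0))
})
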