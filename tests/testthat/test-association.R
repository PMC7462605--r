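test_that("SRI reproduces hand-computed identities", {
  # A and B always together
  sc <- make_scans(rep(list(c("A", "B")), 6))
  sri <- compute_sri(sc, 2019)
  expect_equal(sri$values["A", "B"], 1)
  # never together (C present so scans stay nonempty)
  sc <- make_scans(list(c("A", "C"), c("B", "C"), c("A", "C"), c("B", "C")))
  expect_equal(compute_sri(sc, 2019)$values["A", "B"], 0)
  # P_A = 10, P_B = 8, P_AB = 4  ->  4 / 14
  members <- c(rep(list(c("A", "B")), 4), rep(list(c("A", "C")), 6),
               rep(list(c("B", "C")), 4), rep(list("C"), 3))
  sri <- compute_sri(make_scans(members), 2019)
  expect_equal(sri$p_a[["A"]], 10)
  expect_equal(sri$p_a[["B"]], 8)
  expect_equal(sri$p_ab["A", "B"], 4)
  expect_equal(sri$values["A", "B"], 4 / 14)
})

test_that("SRI matches a brute-force double loop on random small instances", {
  ids <- LETTERS[1:6]
  for (s in 1:5) {
    set.seed(400 + s)
    n_scans <- sample(5:20, 1)
    members <- lapply(seq_len(n_scans), function(i) {
      m <- ids[runif(6) < 0.5]
      if (length(m) == 0) m <- sample(ids, 1)
      m
    })
    sc <- make_scans(members)
    sri <- compute_sri(sc, 2019)
    expect_true(isSymmetric(sri$values))
    expect_true(all(sri$values >= 0 & sri$values <= 1, na.rm = TRUE))
    seen <- sort(unique(unlist(members)))
    for (a in seen) for (b in setdiff(seen, a)) {
      expect_equal(sri$values[a, b], bruteforce_sri(members, a, b),
                   label = sprintf("seed %d dyad %s-%s", s, a, b))
    }
    # permuting scan order leaves the matrix unchanged
    sc_perm <- sc[sample(nrow(sc)), ]
    expect_equal(compute_sri(sc_perm, 2019)$values, sri$values)
  }
})

test_that("dyads with no sightings are undefined, not zero", {
  sc <- make_scans(list(c("A", "B"), c("A", "B")))
  ind <- data.frame(individual_id = c("A", "B", "Z"),
                    group_id = "G1", sex = "F")
  sri <- compute_sri(sc, 2019, ind)
  expect_true(is.na(sri$values["A", "Z"]))
  expect_true(is.na(sri$values["Z", "B"]))
  expect_equal(sri$values["A", "B"], 1)
  expect_error(compute_sri(sc, 2031), "no scans in year")
})

test_that("encounter classification follows the hunt-scan rule", {
  ind <- data.frame(individual_id = c("E1", "E2", "K1", "K2"),
                    group_id = c("Eka", "Eka", "Koko", "Koko"),
                    sex = c("M", "F", "M", "F"))
  t0 <- as.POSIXct("2019-03-01 10:00:00", tz = "UTC")
  one_group <- data.frame(scan_id = "s1", timestamp = t0,
                          individual_id = c("E1", "E2"))
  mixed <- data.frame(scan_id = "s1", timestamp = t0,
                      individual_id = c("E1", "E2", "K1"))
  expect_false(classify_encounter(t0 + 900, one_group, ind))
  expect_true(classify_encounter(t0 + 900, mixed, ind))
  # no scan within the window, and scans after the hunt never count
  expect_true(is.na(classify_encounter(t0 + 2 * 3600, mixed, ind)))
  expect_true(is.na(classify_encounter(t0 - 60, mixed, ind)))
  # simultaneous one-party scans: the hunting party's own scan is used
  both <- rbind(one_group,
                data.frame(scan_id = "s2", timestamp = t0,
                           individual_id = c("K1", "K2")))
  expect_false(classify_encounter(t0 + 900, both, ind, group = "Eka"))
})

test_that("seasonal terms map day-of-year onto the unit circle", {
  jan1 <- seasonal_terms(as.Date("2019-01-01"))
  expect_equal(jan1$sin_date, 0)
  expect_equal(jan1$cos_date, 1)
  # dates one full period apart are identical
  st <- seasonal_terms(as.Date(c("2019-01-03", "2019-01-13")),
                       period_days = 10)
  expect_equal(st$sin_date[1], st$sin_date[2], tolerance = 1e-9)
  expect_equal(st$cos_date[1], st$cos_date[2], tolerance = 1e-9)
  # frozen direct evaluation: day-of-year 92, default period
  theta <- 2 * pi * 91 / 365.25
  st92 <- seasonal_terms(as.Date("2019-04-02"))  # yday + 1 == 92
  expect_equal(st92$sin_date, sin(theta), tolerance = 1e-12)
  expect_equal(st92$cos_date, cos(theta), tolerance = 1e-12)
  expect_equal(st92$sin_date, 0.999985550650719, tolerance = 1e-12)
  expect_equal(st92$cos_date, 0.005375731557584, tolerance = 1e-9)
})

test_that("hunt-party covariates aggregate scan, SRI and usage information", {
  ind <- data.frame(individual_id = c("A", "B", "C", "F1", "F2", "F3",
                                      "F4", "F5"),
                    group_id = c(rep("Eka", 3), rep("Koko", 5)),
                    sex = c("M", "M", "F", rep("F", 5)))
  t0 <- as.POSIXct("2019-06-10 09:00:00", tz = "UTC")
  scans <- rbind(
    data.frame(scan_id = "s1", timestamp = t0, individual_id = c("A", "B", "C")),
    data.frame(scan_id = "s2", timestamp = t0 + 1800,
               individual_id = paste0("F", 1:5)))
  sri <- structure(list(
    year = 2019, ids = c("A", "B", "C"),
    values = matrix(c(NA, 0.2, 0.4, 0.2, NA, 0.6, 0.4, 0.6, NA), 3, 3,
                    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
    p_a = c(A = 5, B = 5, C = 5),
    p_ab = matrix(1, 3, 3)), class = "sri_matrix")
  hunts <- data.frame(hunt_id = c("h1", "h2"),
                      timestamp = c(t0 + 600, t0 + 2400),
                      catcher_group = c("Eka", "Koko"),
                      prey = c("duiker", "anomalure"))
  usage <- data.frame(hunt_id = c("h1", "h2"),
                      usage_difference = c(12.5, -3))
  cov <- hunt_party_covariates(hunts, scans, ind, list("2019" = sri), usage)
  expect_equal(cov$mean_association[1], mean(c(0.2, 0.4, 0.6)))
  expect_equal(cov$n_available_males[1], 2)
  expect_equal(cov$n_available_females[1], 1)
  expect_equal(cov$usage_difference, c(12.5, -3))
  expect_false(cov$is_intergroup[1])
  # hunt 2: single-sex party of five females, none in the SRI matrix
  expect_equal(cov$n_available_males[2], 0)
  expect_equal(cov$n_available_females[2], 5)
  expect_true(is.na(cov$mean_association[2]))
  expect_equal(attr(cov, "n_flagged"), 1)
})
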