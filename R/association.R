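#' Dyadic simple-ratio association index (SRI) for one year
#'
#' SRI = P_AB / (P_A + P_B - P_AB), where P_A and P_B count the scans in
#' which A or B was present and P_AB the scans with both. Computed from the
#' party-composition scans of one calendar year. Dyads whose denominator is
#' zero (neither individual ever scanned that year) are undefined and
#' returned as `NA`, never as 0.
#'
#' @param scans data.frame with `scan_id`, `timestamp`, `individual_id`.
#' @param year calendar year to subset on.
#' @param individuals optional data.frame with `individual_id`; individuals
#'   listed there but never scanned still get (all-`NA`) rows/columns.
#' @return object of class `sri_matrix`: `year`, `ids`, symmetric `values`
#'   matrix in \[0, 1\] with `NA` diagonal, and the retained counts `p_a`
#'   (per individual) and `p_ab` (per dyad).
#' @export
compute_sri <- function(scans, year, individuals = NULL) {
  ts <- as.POSIXct(scans$timestamp, tz = "UTC")
  sub <- scans[format(ts, "%Y") == as.character(year), , drop = FALSE]
  if (nrow(sub) == 0) stop("no scans in year ", year)
  ids <- sort(unique(as.character(sub$individual_id)))
  if (!is.null(individuals))
    ids <- sort(unique(c(ids, as.character(individuals$individual_id))))
  inc <- table(factor(sub$scan_id),
               factor(sub$individual_id, levels = ids)) > 0
  p_ab <- crossprod(inc)
  p_a <- diag(p_ab)
  denom <- outer(p_a, p_a, "+") - p_ab
  values <- ifelse(denom > 0, p_ab / denom, NA_real_)
  # dyads involving an individual never sighted that year are undefined
  values[p_a == 0, ] <- NA_real_
  values[, p_a == 0] <- NA_real_
  diag(values) <- NA_real_
  structure(list(year = year, ids = ids, values = values,
                 p_a = p_a, p_ab = p_ab),
            class = "sri_matrix")
}

#' Long-format view of an SRI matrix
#' @param sri an `sri_matrix`.
#' @return data.frame `id_a`, `id_b`, `p_a`, `p_b`, `p_ab`, `sri` (one row
#'   per unordered dyad).
#' @export
sri_long <- function(sri) {
  n <- length(sri$ids)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(id_a = sri$ids[pairs[, 1]], id_b = sri$ids[pairs[, 2]],
             p_a = as.numeric(sri$p_a[pairs[, 1]]),
             p_b = as.numeric(sri$p_a[pairs[, 2]]),
             p_ab = as.numeric(sri$p_ab[pairs]),
             sri = as.numeric(sri$values[pairs]))
}

# latest scan at or before `time` within `window_min` minutes; NA if none.
# When simultaneous scans from different parties exist, scans containing a
# member of `group` (the hunting party's scan) are preferred.
resolve_hunt_scan <- function(time, scan_times, window_min = 60,
                              group = NULL, scan_groups = NULL) {
  time <- as.POSIXct(time, tz = "UTC")
  ok <- scan_times <= time & scan_times > time - window_min * 60
  if (!any(ok)) return(NA_character_)
  cand <- scan_times[ok]
  if (!is.null(group) && !is.null(scan_groups)) {
    own <- vapply(names(cand), function(s) group %in% scan_groups[[s]], TRUE)
    if (any(own)) cand <- cand[own]
  }
  names(cand)[which.max(cand)]
}

# scan_id -> set of groups with a member in the scan
scan_group_index <- function(scans, individuals) {
  grp <- setNames(as.character(individuals$group_id),
                  individuals$individual_id)
  lapply(split(as.character(scans$individual_id), scans$scan_id),
         function(m) unique(grp[m]))
}

# named vector scan_id -> timestamp for the unique scans
scan_time_index <- function(scans) {
  u <- !duplicated(scans$scan_id)
  setNames(as.POSIXct(scans$timestamp[u], tz = "UTC"), scans$scan_id[u])
}

#' Classify a hunt as an intergroup encounter
#'
#' A hunt counts as occurring during an intergroup encounter when the party
#' scan at or immediately before the hunt contains members of both groups.
#' The rule keys on the scan, not the hunt itself, so a hunt can be flagged
#' even if only one group's members were at the capture — the mixed scan
#' indicates the other group is nearby.
#'
#' @param hunt_time hunt timestamp.
#' @param scans scans table (`scan_id`, `timestamp`, `individual_id`).
#' @param individuals data.frame with `individual_id`, `group_id`.
#' @param window_min how far back (minutes) a preceding scan may be; beyond
#'   it the hunt has no resolvable scan and `NA` is returned.
#' @param group optional hunting group id; when several parties were scanned
#'   at the same time, the hunting party's own scan is used.
#' @return `TRUE`, `FALSE`, or `NA` if no scan falls in the window.
#' @export
classify_encounter <- function(hunt_time, scans, individuals,
                               window_min = 60, group = NULL) {
  sid <- resolve_hunt_scan(hunt_time, scan_time_index(scans), window_min,
                           group, scan_group_index(scans, individuals))
  if (is.na(sid)) return(NA)
  members <- scans$individual_id[scans$scan_id == sid]
  grp <- individuals$group_id[match(members, individuals$individual_id)]
  length(unique(grp[!is.na(grp)])) >= 2
}

#' Seasonal circular covariates from dates
#'
#' Maps day-of-year onto the circle, theta = 2*pi*(doy - 1)/period, and
#' returns its sine and cosine, the standard pair of regressors for a smooth
#' annual cycle.
#'
#' @param dates `Date` (or coercible) vector.
#' @param period_days circle period; 365.25 absorbs leap years.
#' @return data.frame `sin_date`, `cos_date`.
#' @export
seasonal_terms <- function(dates, period_days = 365.25) {
  doy <- as.POSIXlt(as.Date(dates))$yday + 1
  theta <- 2 * pi * (doy - 1) / period_days
  data.frame(sin_date = sin(theta), cos_date = cos(theta))
}

#' Per-hunt covariates for the prey-type model
#'
#' For each hunt, resolves the hunt scan (the scan at or nearest before the
#' hunt within `window_min` minutes), counts available male and female adult
#' hunters in it, averages the dyadic SRI over all defined pairs of scan
#' members (cross-group dyads included at intergroup hunts), classifies the
#' encounter, attaches the usage-difference score and the seasonal terms.
#' Hunts without a resolvable scan, or whose scan has fewer than two
#' individuals, get `NA` covariates and are counted in the `n_flagged`
#' attribute.
#'
#' @param hunts data.frame `hunt_id`, `timestamp`, `catcher_group`, `prey`.
#' @param scans scans table.
#' @param individuals data.frame `individual_id`, `group_id`, `sex` (M/F;
#'   unknown sex is excluded from the sex counts).
#' @param sri_by_year named list of `sri_matrix` objects keyed by year.
#' @param usage_scores data.frame from [usage_difference()].
#' @param window_min scan-resolution window, minutes.
#' @param period_days seasonal period.
#' @param own_group_only if `TRUE`, party-size counts and mean association
#'   use only the catcher group's members of the hunt scan.
#' @return data.frame, one row per hunt: `hunt_id`, `group`,
#'   `n_available_males`, `n_available_females`, `mean_association`,
#'   `usage_difference`, `sin_date`, `cos_date`, `is_intergroup`, `prey`;
#'   attribute `n_flagged` counts hunts with missing covariates.
#' @export
hunt_party_covariates <- function(hunts, scans, individuals, sri_by_year,
                                  usage_scores, window_min = 60,
                                  period_days = 365.25,
                                  own_group_only = FALSE) {
  stimes <- scan_time_index(scans)
  members_by_scan <- split(as.character(scans$individual_id), scans$scan_id)
  sgroups <- scan_group_index(scans, individuals)
  sex <- setNames(as.character(individuals$sex), individuals$individual_id)
  grp <- setNames(as.character(individuals$group_id),
                  individuals$individual_id)
  n <- nrow(hunts)
  out <- data.frame(hunt_id = hunts$hunt_id,
                    group = as.character(hunts$catcher_group),
                    n_available_males = NA_real_,
                    n_available_females = NA_real_,
                    mean_association = NA_real_,
                    usage_difference = usage_scores$usage_difference[
                      match(hunts$hunt_id, usage_scores$hunt_id)],
                    sin_date = NA_real_, cos_date = NA_real_,
                    is_intergroup = NA, prey = as.character(hunts$prey))
  st <- seasonal_terms(as.Date(as.POSIXct(hunts$timestamp, tz = "UTC")),
                       period_days)
  out$sin_date <- st$sin_date
  out$cos_date <- st$cos_date
  flagged <- 0L
  for (k in seq_len(n)) {
    sid <- resolve_hunt_scan(hunts$timestamp[k], stimes, window_min,
                             out$group[k], sgroups)
    if (is.na(sid)) { flagged <- flagged + 1L; next }
    members <- unique(members_by_scan[[sid]])
    g <- grp[members]
    out$is_intergroup[k] <- length(unique(g[!is.na(g)])) >= 2
    if (own_group_only) members <- members[g %in% out$group[k]]
    s <- sex[members]
    out$n_available_males[k] <- sum(s == "M", na.rm = TRUE)
    out$n_available_females[k] <- sum(s == "F", na.rm = TRUE)
    if (length(members) < 2) { flagged <- flagged + 1L; next }
    yr <- format(as.POSIXct(hunts$timestamp[k], tz = "UTC"), "%Y")
    sri <- sri_by_year[[yr]]
    if (is.null(sri)) { flagged <- flagged + 1L; next }
    pos <- match(members, sri$ids)
    pos <- pos[!is.na(pos)]
    if (length(pos) < 2) { flagged <- flagged + 1L; next }
    vals <- sri$values[pos, pos][upper.tri(diag(length(pos)))]
    out$mean_association[k] <- mean(vals, na.rm = TRUE)
  }
  attr(out, "n_flagged") <- flagged
  out
}
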