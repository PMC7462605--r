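#' Tally successful hunts by group and prey type
#'
#' Counts of successful hunts per (group, prey) cell with row, column and
#' grand totals; hunt attempts (`success == 0`) are tallied separately.
#'
#' @param hunts data.frame with `catcher_group`, `prey`, `success` (0/1).
#' @return list of class `hunt_tally`: `successes` (group x prey matrix with
#'   margins), `attempts`, `total_successful`, `total_attempts`.
#' @export
tally_hunts <- function(hunts) {
  bad <- which(!hunts$prey %in% PREY_LEVELS)
  if (length(bad))
    stop("unknown prey label(s) ",
         paste(unique(hunts$prey[bad]), collapse = ", "), " at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  count <- function(sub) {
    groups <- sort(unique(hunts$catcher_group))
    m <- matrix(0L, length(groups), length(PREY_LEVELS),
                dimnames = list(groups, PREY_LEVELS))
    if (nrow(sub))
      m[] <- table(factor(sub$catcher_group, levels = groups),
                   factor(sub$prey, levels = PREY_LEVELS))
    m <- rbind(m, Total = colSums(m))
    cbind(m, Total = rowSums(m))
  }
  succ <- hunts[hunts$success == 1, , drop = FALSE]
  att <- hunts[hunts$success == 0, , drop = FALSE]
  structure(list(successes = count(succ), attempts = count(att),
                 total_successful = nrow(succ), total_attempts = nrow(att)),
            class = "hunt_tally")
}

#' @export
print.hunt_tally <- function(x, ...) {
  cat("Successful hunts by group and prey type\n")
  print(x$successes)
  if (x$total_attempts > 0) {
    cat("\nUnsuccessful attempts\n")
    print(x$attempts)
  }
  invisible(x)
}

stage_names <- c("simulate", "ranging", "covariates", "fit", "report")

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> ranging -> covariates -> fit -> report as one
#' reproducible run. In synthetic mode (`config` given) the first stage
#' generates the data; otherwise `input_dir` must hold `relocations.csv`,
#' `individuals.csv`, `scans.csv`, `hunts.csv` in the documented schemas.
#' Every stage writes its output files under `out_dir` and the run ends
#' with a JSON manifest recording the configuration, seeds, per-stage
#' timings, warnings, and an md5 content hash of every output file.
#'
#' @param config a [sim_config()] for synthetic mode, or `NULL`.
#' @param input_dir directory of input CSVs for real-data mode.
#' @param out_dir output directory.
#' @param spec a [model_spec()] for the fit stage; its seed defaults to the
#'   config seed in synthetic mode.
#' @param isopleths isopleth levels exported by the ranging stage.
#' @param stop_after optional stage name; later stages are skipped.
#' @return the manifest (list of class `run_manifest`), invisibly writes
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, input_dir = NULL, out_dir,
                         spec = NULL, isopleths = c(50, 95),
                         stop_after = NULL) {
  if (is.null(config) && is.null(input_dir))
    stop("either a simulation config or an input directory is required")
  if (!is.null(stop_after) && !stop_after %in% stage_names)
    stop("unknown stage: ", stop_after)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mode = if (is.null(config)) "real" else "synthetic",
                   seed = if (is.null(config)) NULL else config$seed,
                   stages = list(), warnings = character(0),
                   files = list())
  t_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(fun(), warning = function(w) {
      manifest$warnings <<- c(manifest$warnings,
                              paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3))
    res
  }
  done <- function(stage) !is.null(stop_after) && stage == stop_after

  # -- simulate / load ------------------------------------------------------
  dat <- t_stage("simulate", function() {
    if (!is.null(config)) {
      sim <- simulate_dataset(config)
      write_dataset(sim, out_dir)
      manifest$truth <<- file.path(out_dir, "truth.json")
      list(relocations = sim$relocations, individuals = sim$individuals,
           scans = sim$scans, hunts = sim$hunts, uds = sim$uds)
    } else {
      list(relocations = read_relocations(file.path(input_dir,
                                                    "relocations.csv")),
           individuals = read_individuals(file.path(input_dir,
                                                    "individuals.csv")),
           scans = read_scans(file.path(input_dir, "scans.csv")),
           hunts = read_hunts(file.path(input_dir, "hunts.csv")),
           uds = NULL)
    }
  })
  if (done("simulate")) return(finish_manifest(manifest, out_dir))

  # -- ranging --------------------------------------------------------------
  cell <- if (is.null(config)) 0.1 else config$cell_size
  ranging <- t_stage("ranging", function() {
    uds <- if (!is.null(dat$uds)) dat$uds
           else fit_kde_groups(dat$relocations, cell_size = cell)
    for (g in names(uds)) {
      write.csv(ud_to_table(uds[[g]]),
                file.path(out_dir, paste0("ud_", tolower(g), ".csv")),
                row.names = FALSE)
      write_isopleth_geojson(uds[[g]], isopleths,
                             file.path(out_dir,
                                       paste0("isopleths_", tolower(g),
                                              ".geojson")))
    }
    scores <- usage_difference(dat$hunts, uds)
    write.csv(scores, file.path(out_dir, "usage_scores.csv"),
              row.names = FALSE)
    ov <- overlap_fraction(uds[[1]], uds[[2]], 95)
    list(uds = uds, scores = scores, overlap = ov)
  })
  if (done("ranging")) return(finish_manifest(manifest, out_dir))

  # -- covariates -----------------------------------------------------------
  covs <- t_stage("covariates", function() {
    years <- sort(unique(format(dat$scans$timestamp, "%Y")))
    sri_by_year <- lapply(setNames(years, years), function(y)
      compute_sri(dat$scans, y, dat$individuals))
    for (y in years)
      write.csv(sri_long(sri_by_year[[y]]),
                file.path(out_dir, paste0("sri_", y, ".csv")),
                row.names = FALSE)
    cov <- hunt_party_covariates(dat$hunts, dat$scans, dat$individuals,
                                 sri_by_year, ranging$scores)
    write.csv(cov, file.path(out_dir, "hunt_covariates.csv"),
              row.names = FALSE)
    cov
  })
  if (done("covariates")) return(finish_manifest(manifest, out_dir))

  # -- fit ------------------------------------------------------------------
  if (is.null(spec))
    spec <- model_spec(seed = if (is.null(config)) 1L else config$seed,
                       reference_group = if (is.null(config))
                         sort(unique(covs$group))[1] else group_ids(config)[1])
  fit <- t_stage("fit", function() {
    fit <- fit_categorical(covs, covs$prey, spec)
    write.csv(fit$summary, file.path(out_dir, "fit_summary.csv"),
              row.names = FALSE)
    con <- gzfile(file.path(out_dir, "posterior_draws.csv.gz"), "w")
    write.csv(as.data.frame(fit$draws), con, row.names = FALSE)
    close(con)
    groups <- sort(unique(covs$group))
    pred <- do.call(rbind, lapply(groups, function(g)
      predict_category_probs(fit, g)))
    write.csv(pred, file.path(out_dir, "predicted_probs.csv"),
              row.names = FALSE)
    fit
  })
  manifest$max_rhat <- max(fit$rhat)
  manifest$convergence_warning <- fit$convergence_warning
  if (done("fit")) return(finish_manifest(manifest, out_dir))

  # -- report ---------------------------------------------------------------
  t_stage("report", function() {
    tal <- tally_hunts(dat$hunts)
    write.csv(as.data.frame(tal$successes),
              file.path(out_dir, "hunt_tally.csv"), row.names = FALSE)
    sink(file.path(out_dir, "report.txt"))
    print(tal)
    cat("\n")
    print(fit)
    sink()
    tal
  })
  finish_manifest(manifest, out_dir)
}

finish_manifest <- function(manifest, out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest$files <- as.list(setNames(unname(hashes), files))
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  manifest
}
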