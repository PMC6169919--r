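# Readers/writers for the pipeline's plain-text interchange formats and the
# end-to-end study runner.

#' Write a bend-test record to CSV
#'
#' The load trace goes to `record_csv` (columns time_s, load_N,
#' displacement_mm) and the crack-extension series to `frames_csv` (columns
#' frame_time_s, delta_a_mm).
#'
#' @param record A [bend_test_record()].
#' @param record_csv,frames_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_bend_record <- function(record, record_csv, frames_csv) {
  stopifnot(inherits(record, "bend_test_record"))
  utils::write.csv(
    data.frame(time_s = record$time, load_N = record$load,
               displacement_mm = record$displacement),
    record_csv, row.names = FALSE)
  utils::write.csv(
    data.frame(frame_time_s = record$frame_time, delta_a_mm = record$delta_a),
    frames_csv, row.names = FALSE)
  invisible(c(record_csv, frames_csv))
}

#' Read a bend-test record from CSV
#'
#' Rows are re-sorted by time; schema violations are reported per column. Span
#' and pixel size come from the geometry sidecar when given.
#'
#' @param record_csv CSV with columns time_s, load_N, displacement_mm.
#' @param frames_csv CSV with columns frame_time_s, delta_a_mm.
#' @param geometry Optional geometry list from [read_geometry()] supplying
#'   `span` (mm) and `pixel_size` (um/px).
#' @return A validated [bend_test_record()].
#' @export
read_bend_record <- function(record_csv, frames_csv, geometry = NULL) {
  tr <- utils::read.csv(record_csv)
  fr <- utils::read.csv(frames_csv)
  need_tr <- c("time_s", "load_N", "displacement_mm")
  need_fr <- c("frame_time_s", "delta_a_mm")
  miss <- c(setdiff(need_tr, names(tr)), setdiff(need_fr, names(fr)))
  if (length(miss) > 0) {
    stop("schema violation: missing column(s) ", paste(miss, collapse = ", "))
  }
  tr <- tr[order(tr$time_s), ]
  fr <- fr[order(fr$frame_time_s), ]
  span <- if (!is.null(geometry$span)) geometry$span else 8
  px <- if (!is.null(geometry$pixel_size)) geometry$pixel_size else 2.2
  bend_test_record(tr$time_s, tr$load_N, tr$displacement_mm,
                   fr$frame_time_s, fr$delta_a_mm,
                   span = span, pixel_size = px)
}

#' Read specimen geometry from a JSON sidecar
#'
#' Expects fields R_o_mm, R_i_mm, theta0_rad, and optionally notch_depth_mm,
#' span_mm (default 8) and pixel_size_um (default 2.2).
#'
#' @param path JSON file path.
#' @return List with `section` ([cross_section()]), `notch`
#'   ([notch_geometry()]), `span` and `pixel_size`.
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("R_o_mm", "R_i_mm", "theta0_rad")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0) {
    stop("schema violation: missing field(s) ", paste(miss, collapse = ", "))
  }
  list(
    section = cross_section(g$R_o_mm, g$R_i_mm),
    notch = notch_geometry(g$theta0_rad,
                           if (is.null(g$notch_depth_mm)) NA_real_ else g$notch_depth_mm),
    span = if (is.null(g$span_mm)) 8 else g$span_mm,
    pixel_size = if (is.null(g$pixel_size_um)) 2.2 else g$pixel_size_um
  )
}

#' Write specimen geometry to JSON
#'
#' @param section A [cross_section()].
#' @param notch A [notch_geometry()].
#' @param path Output path.
#' @param span Span in mm.
#' @param pixel_size Pixel size in um.
#' @return Invisibly, the path.
#' @export
write_geometry <- function(section, notch, path, span = 8, pixel_size = 2.2) {
  jsonlite::write_json(
    list(R_o_mm = section$R_o, R_i_mm = section$R_i,
         theta0_rad = notch$theta0, notch_depth_mm = notch$depth,
         span_mm = span, pixel_size_um = pixel_size),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a toughness result to JSON
#'
#' @param result A [toughness_triplet()] result.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_toughness <- function(result, path) {
  stopifnot(inherits(result, "toughness_result"))
  jsonlite::write_json(
    list(K_init = result$K_init, K_pl = result$K_pl, K_inst = result$K_inst,
         events = result$events, sigma_y_MPa = result$sigma_y),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full synthetic study end to end
#'
#' Generates the calibrated cohort, paired and ribosylation experiments, runs
#' the statistical battery on the main toughness outcome, processes one
#' forward-generated bend test through the toughness chain and one raster
#' section through morphometry, and writes everything (tidy CSVs, a JSON
#' statistics summary, and a log carrying the seed, package version and
#' calibration hash) to `out_dir`. Reruns with the same seed produce
#' identical tables.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving all generators.
#' @param calibration A [study_calibration()] (default: packaged calibration).
#' @param outcome Outcome for the statistics summary (default "K_inst").
#' @return Invisibly, a named list of the written paths.
#' @export
run_study <- function(out_dir, seed, calibration = study_calibration(),
                      outcome = "K_inst") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wr <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    paths[[name]] <<- p
  }

  cohort <- gen_cohort(calibration, seed)
  paired <- gen_paired_femurs(calibration, seed + 1L)
  ribose <- gen_ribosylation(calibration, seed + 2L)
  wr(cohort, "cohort.csv"); wr(paired, "paired.csv"); wr(ribose, "ribose.csv")

  tp <- timepoint_tests(cohort, outcome)
  wr(tp, "timepoint_tests.csv")
  an <- ancova(cohort, outcome)
  pt <- paired_tests(paired, outcome)
  rb <- ribose[ribose$outcome == outcome, ]
  lf <- linfit(rb$time, rb$value)
  stats_summary <- list(
    outcome = outcome,
    ancova = list(p_treatment = an$p_treatment, p_time = an$p_time,
                  p_interaction = an$p_interaction, r_squared = an$r_squared,
                  common_slope = an$common_slope),
    paired = pt[c("mean_diff", "pct_change", "p", "n")],
    ribosylation = lf[c("slope", "intercept", "r_squared", "p")]
  )
  p_json <- file.path(out_dir, "stats_summary.json")
  jsonlite::write_json(stats_summary, p_json, auto_unbox = TRUE, digits = NA)
  paths[["stats_summary.json"]] <- p_json

  section <- cross_section(0.9, 0.7)
  notch <- notch_geometry(0.55)
  rec <- gen_bend_test(section, notch)
  tough <- toughness_triplet(rec, notch, section)
  wr(tough$events, "toughness_events.csv")

  img <- gen_section_mask(R_o = 0.9, R_i = 0.7, seed = seed)
  wr(section_morphology(img), "morphology.csv")

  cal_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(calibration), cal_file)
  log_lines <- c(
    sprintf("femurtough %s", as.character(utils::packageVersion("femurtough"))),
    sprintf("seed: %d", seed),
    sprintf("calibration_md5: %s", unname(tools::md5sum(cal_file))),
    sprintf("generated: cohort (%d rows), paired (%d rows), ribose (%d rows)",
            nrow(cohort), nrow(paired), nrow(ribose)))
  unlink(cal_file)
  p_log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, p_log)
  paths[["run_log.txt"]] <- p_log
  invisible(paths)
}
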