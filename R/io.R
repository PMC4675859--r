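#' Read a tracking CSV
#'
#' Reads 10 Hz tracking records in the package's interchange schema:
#' columns `subject_id, group, genotype, treatment, phase, session, trial,
#' start_point, t_s, x_cm, y_cm`, coordinates pool-centered in cm, time in
#' seconds from trial start. Malformed rows and positions outside the pool
#' are rejected with their line numbers. Writing with [write_tracking()]
#' and reading back reproduces the trajectories exactly.
#'
#' @param path CSV file path.
#' @param geometry An [mwm_geometry()] used to validate coordinates.
#' @return A tracking tibble in the package's internal layout (`t`, `x`,
#'   `y` columns).
#' @export
read_tracking <- function(path, geometry = mwm_geometry()) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    genotype = readr::col_character(),
    treatment = readr::col_character(),
    phase = readr::col_character(),
    session = readr::col_integer(),
    trial = readr::col_integer(),
    start_point = readr::col_character(),
    t_s = readr::col_double(),
    x_cm = readr::col_double(),
    y_cm = readr::col_double()
  ), progress = FALSE)
  required <- c("subject_id", "group", "genotype", "treatment", "phase",
                "session", "trial", "start_point", "t_s", "x_cm", "y_cm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("Tracking file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(raw)
  bad <- which(!stats::complete.cases(raw[, c("t_s", "x_cm", "y_cm",
                                              "session", "trial")]))
  bad <- sort(unique(c(bad, if (nrow(probs)) probs$row)))
  if (length(bad)) {
    stop("Malformed tracking rows at line(s) ",
         paste(utils::head(bad + 1, 10), collapse = ", "),
         " (line 1 is the header).", call. = FALSE)
  }
  r2 <- raw$x_cm^2 + raw$y_cm^2
  out_of_pool <- which(r2 > geometry$pool_radius^2 * (1 + 1e-9))
  if (length(out_of_pool)) {
    stop("Position(s) outside the pool at line(s) ",
         paste(utils::head(out_of_pool + 1, 10), collapse = ", "),
         ".", call. = FALSE)
  }
  dplyr::rename(raw, t = "t_s", x = "x_cm", y = "y_cm")
}

#' Write tracking records to CSV
#'
#' @param tracking Tracking tibble (internal layout, as from
#'   [simulate_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(tracking, path) {
  tracking |>
    dplyr::select("subject_id", "group", "genotype", "treatment", "phase",
                  "session", "trial", "start_point",
                  t_s = "t", x_cm = "x", y_cm = "y") |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}
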