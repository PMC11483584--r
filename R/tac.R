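#' PET time-activity curve
#'
#' Regional PET radioactivity over the dynamic frames of a scan, with
#' the injected dose and body weight needed for SUV normalisation.
#'
#' @param frame_mid_times_min frame mid-times in minutes, strictly
#'   increasing.
#' @param activity_kbq_per_cc mean regional radioactivity per frame
#'   (kBq/cc), non-negative.
#' @param dose_kbq injected radioactivity (kBq), > 0.
#' @param body_weight_g body weight (g), > 0.
#' @param region optional region name (e.g. "hippocampus",
#'   "cerebellum").
#' @return An object of class `tac`.
#' @export
tac <- function(frame_mid_times_min, activity_kbq_per_cc, dose_kbq,
                body_weight_g, region = NA_character_) {
  t <- as.numeric(frame_mid_times_min)
  a <- as.numeric(activity_kbq_per_cc)
  if (length(t) != length(a)) stop("times and activities differ in length")
  if (any(diff(t) <= 0)) stop("frame mid-times must be strictly increasing")
  if (any(a < 0)) stop("activities must be >= 0")
  if (!is.finite(dose_kbq) || dose_kbq <= 0) stop("dose_kbq must be > 0")
  if (!is.finite(body_weight_g) || body_weight_g <= 0)
    stop("body_weight_g must be > 0")
  structure(list(frame_mid_times_min = t, activity_kbq_per_cc = a,
                 dose_kbq = dose_kbq, body_weight_g = body_weight_g,
                 region = region),
            class = "tac")
}

#' Read / write a time-activity curve as CSV
#'
#' CSV columns `frame_mid_time_min, activity_kbq_per_cc`; dose and body
#' weight are carried in `# dose_kbq:` / `# body_weight_g:` /
#' `# region:` comment lines at the top of the file.
#'
#' @param curve a [tac].
#' @param path CSV path.
#' @return `write_tac`: `path` invisibly; `read_tac`: a [tac].
#' @export
write_tac <- function(curve, path) {
  stopifnot(inherits(curve, "tac"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dose_kbq: %s", format(curve$dose_kbq, digits = 15)),
    sprintf("# body_weight_g: %s", format(curve$body_weight_g, digits = 15)),
    sprintf("# region: %s", curve$region)
  ), con)
  utils::write.table(
    data.frame(frame_mid_time_min = curve$frame_mid_times_min,
               activity_kbq_per_cc = curve$activity_kbq_per_cc),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# *", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("malformed TAC CSV: missing '# ", key, ":' line")
    trimws(sub(paste0("^# *", key, ": *"), "", ln[1]))
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)))
  if (!all(c("frame_mid_time_min", "activity_kbq_per_cc") %in% names(df)))
    stop("malformed TAC CSV: missing column(s)")
  tac(df$frame_mid_time_min, df$activity_kbq_per_cc,
      dose_kbq = as.numeric(get("dose_kbq")),
      body_weight_g = as.numeric(get("body_weight_g")),
      region = get("region"))
}
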