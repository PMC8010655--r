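#' Construct and validate an FSIGT time series
#'
#' An `fsigt_series` holds one subject's timed plasma glucose, insulin and
#' free fatty acid (FFA) measurements from an insulin-modified frequently
#' sampled intravenous glucose tolerance test (FSIGT).  Times are minutes
#' relative to the glucose bolus at t = 0; basal (fasting) samples have
#' negative times.  Canonical units are mmol/l (glucose), pmol/l (insulin)
#' and umol/l (FFA).
#'
#' @param subject_id character scalar identifying the subject.
#' @param times numeric vector of sampling times in minutes, strictly
#'   increasing, with at least one pre-bolus (t < 0) sample and at least
#'   five post-bolus (t >= 0) samples.
#' @param glucose plasma glucose, mmol/l.
#' @param insulin plasma insulin, pmol/l.
#' @param ffa plasma FFA, umol/l.
#' @param body_weight optional body weight in kg.
#' @return An object of class `fsigt_series`: a data frame with columns
#'   `time_min`, `glucose_mmol_l`, `insulin_pmol_l`, `ffa_umol_l` and
#'   attributes `subject_id` and `body_weight`.
#' @seealso [read_fsigt_csv()], [basal_state()]
#' @export
fsigt_series <- function(subject_id, times, glucose, insulin, ffa,
                         body_weight = NA_real_) {
  times <- as.numeric(times)
  glucose <- as.numeric(glucose)
  insulin <- as.numeric(insulin)
  ffa <- as.numeric(ffa)
  n <- length(times)
  if (length(glucose) != n || length(insulin) != n || length(ffa) != n)
    stop("times, glucose, insulin and ffa must have equal length", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("times must be finite", call. = FALSE)
  dup <- times[duplicated(times)]
  if (length(dup))
    stop("duplicate sampling time(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  for (nm in c("glucose", "insulin", "ffa")) {
    v <- get(nm)
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop("non-positive or non-finite ", nm, " at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!any(times < 0))
    stop("need at least one basal sample (time < 0)", call. = FALSE)
  if (sum(times >= 0) < 5)
    stop("need at least five post-bolus samples (time >= 0)", call. = FALSE)
  out <- data.frame(time_min = times, glucose_mmol_l = glucose,
                    insulin_pmol_l = insulin, ffa_umol_l = ffa)
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "body_weight") <- as.numeric(body_weight)
  class(out) <- c("fsigt_series", "data.frame")
  out
}

#' @export
print.fsigt_series <- function(x, ...) {
  cat("FSIGT series: subject ", attr(x, "subject_id"),
      " (", nrow(x), " samples, ", sum(x$time_min < 0), " basal)\n", sep = "")
  bw <- attr(x, "body_weight")
  if (!is.na(bw)) cat("Body weight:", bw, "kg\n")
  cat("Time range:", min(x$time_min), "to", max(x$time_min), "min\n")
  b <- basal_state(x)
  cat(sprintf("Basal: glucose %.2f mmol/l, insulin %.1f pmol/l, FFA %.0f umol/l\n",
              b$g_b, b$i_b, b$ffa_b))
  invisible(x)
}

# standard clinical conversion: 6.0 pmol/l per mU/l (= uU/ml) of insulin
.PMOL_PER_MU <- 6.0

# unit conversion factors to canonical units, per analyte
.unit_table <- list(
  glucose = c("mmol/l" = 1, "mg/dl" = 1 / 18.0),
  insulin = c("pmol/l" = 1, "mU/l" = 6.0, "uU/ml" = 6.0),
  ffa     = c("umol/l" = 1, "mmol/l" = 1000)
)

#' Convert glucose or insulin concentrations between clinical units
#'
#' Glucose converts between mg/dl and mmol/l with the standard factor
#' 18.0 mg/dl per mmol/l; insulin converts between mU/l (= uU/ml) and pmol/l
#' with the standard factor 6.0 pmol/l per mU/l.  Conversions are exact and
#' invertible.
#'
#' @param x numeric vector of concentrations.
#' @param quantity one of `"glucose"`, `"insulin"`, `"ffa"`.
#' @param from,to unit names; see Details for the supported set.
#' @return Numeric vector in the `to` units.
#' @examples
#' convert_units(90, "glucose", "mg/dl", "mmol/l")   # 5
#' convert_units(7.5, "insulin", "mU/l", "pmol/l")   # 45
#' @export
convert_units <- function(x, quantity = c("glucose", "insulin", "ffa"),
                          from, to) {
  quantity <- match.arg(quantity)
  tab <- .unit_table[[quantity]]
  for (u in c(from, to)) {
    if (!u %in% names(tab))
      stop("unknown ", quantity, " unit '", u, "'; supported: ",
           paste(names(tab), collapse = ", "), call. = FALSE)
  }
  x * tab[[from]] / tab[[to]]
}

#' Read one subject's FSIGT data from CSV
#'
#' Expects a comma-separated file with a header row and (by default) columns
#' `time_min`, `glucose`, `insulin`, `ffa`.  Values are converted to the
#' canonical units (mmol/l, pmol/l, umol/l) according to `units` and rows are
#' sorted by time before validation.
#'
#' @param path path to the CSV file.
#' @param units named character vector declaring the units of the glucose,
#'   insulin and ffa columns, e.g. `c(glucose = "mg/dl", insulin = "mU/l",
#'   ffa = "umol/l")`.
#' @param columns named character vector overriding column names, with names
#'   `time`, `glucose`, `insulin`, `ffa`.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param body_weight optional body weight, kg.
#' @return An [fsigt_series()].
#' @export
read_fsigt_csv <- function(path,
                           units = c(glucose = "mmol/l", insulin = "pmol/l",
                                     ffa = "umol/l"),
                           columns = c(time = "time_min", glucose = "glucose",
                                       insulin = "insulin", ffa = "ffa"),
                           subject_id = NULL, body_weight = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  def_cols <- c(time = "time_min", glucose = "glucose",
                insulin = "insulin", ffa = "ffa")
  def_cols[names(columns)] <- columns
  columns <- def_cols
  def_units <- c(glucose = "mmol/l", insulin = "pmol/l", ffa = "umol/l")
  def_units[names(units)] <- units
  units <- def_units
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns), names(d))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- d[order(d[[columns[["time"]]]]), , drop = FALSE]
  if (is.null(subject_id))
    subject_id <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  fsigt_series(
    subject_id = subject_id,
    times = d[[columns[["time"]]]],
    glucose = convert_units(d[[columns[["glucose"]]]], "glucose",
                            units[["glucose"]], "mmol/l"),
    insulin = convert_units(d[[columns[["insulin"]]]], "insulin",
                            units[["insulin"]], "pmol/l"),
    ffa = convert_units(d[[columns[["ffa"]]]], "ffa", units[["ffa"]], "umol/l"),
    body_weight = body_weight
  )
}

#' Write an FSIGT series to CSV in canonical units
#'
#' @param series an [fsigt_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fsigt_csv <- function(series, path) {
  stopifnot(inherits(series, "fsigt_series"))
  d <- data.frame(time_min = series$time_min, glucose = series$glucose_mmol_l,
                  insulin = series$insulin_pmol_l, ffa = series$ffa_umol_l)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Basal (fasting) state of an FSIGT series
#'
#' Basal glucose, insulin and FFA are the arithmetic means of all pre-bolus
#' (t < 0) samples of each analyte.
#'
#' @param series an [fsigt_series()], or any data frame with the canonical
#'   columns.
#' @return A `basal_state` list with elements `g_b` (mmol/l), `i_b` (pmol/l)
#'   and `ffa_b` (umol/l).
#' @export
basal_state <- function(series) {
  pre <- series$time_min < 0
  if (!any(pre)) stop("no basal samples (time < 0)", call. = FALSE)
  out <- list(g_b = mean(series$glucose_mmol_l[pre]),
              i_b = mean(series$insulin_pmol_l[pre]),
              ffa_b = mean(series$ffa_umol_l[pre]))
  class(out) <- "basal_state"
  out
}

#' @export
print.basal_state <- function(x, ...) {
  cat(sprintf("Basal state: glucose %.3f mmol/l, insulin %.2f pmol/l, FFA %.1f umol/l\n",
              x$g_b, x$i_b, x$ffa_b))
  invisible(x)
}

#' FSIGT sampling schedule
#'
#' The standard insulin-modified FSIGT schedule: basal samples at -15, -10,
#' -5 and -1 min; a 0.3 g/kg glucose bolus at t = 0; a 0.03 U/kg insulin
#' bolus at t = 20 min; and post-bolus samples from 2 to 180 min.
#'
#' @param basal_times numeric vector of basal sampling times (all < 0).
#' @param post_times numeric vector of post-bolus sampling times (all > 0).
#' @return A `sample_schedule` list with elements `basal_times` and
#'   `post_times`.
#' @export
sample_schedule <- function(basal_times = c(-15, -10, -5, -1),
                            post_times = c(2, 3, 4, 5, 6, 8, 10, 12, 14, 16,
                                           19, 22, 24, 25, 27, 30, 40, 50, 60,
                                           70, 80, 90, 100, 120, 140, 160, 180)) {
  basal_times <- as.numeric(basal_times)
  post_times <- as.numeric(post_times)
  if (any(basal_times >= 0)) stop("basal_times must all be < 0", call. = FALSE)
  if (any(post_times <= 0)) stop("post_times must all be > 0", call. = FALSE)
  if (is.unsorted(basal_times, strictly = TRUE) ||
      is.unsorted(post_times, strictly = TRUE))
    stop("schedule times must be strictly increasing", call. = FALSE)
  structure(list(basal_times = basal_times, post_times = post_times),
            class = "sample_schedule")
}

#' Read a cohort of FSIGT subjects via a manifest CSV
#'
#' The manifest has columns `subject_id`, `file` (path relative to the
#' manifest) and `body_weight_kg`.
#'
#' @param manifest path to the manifest CSV.
#' @param ... passed to [read_fsigt_csv()] (e.g. `units`).
#' @return A named list of [fsigt_series()] objects.
#' @export
read_fsigt_cohort <- function(manifest, ...) {
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "file", "body_weight_kg")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir <- dirname(manifest)
  out <- lapply(seq_len(nrow(m)), function(i) {
    read_fsigt_csv(file.path(dir, m$file[i]), subject_id = m$subject_id[i],
                   body_weight = m$body_weight_kg[i], ...)
  })
  names(out) <- m$subject_id
  out
}
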