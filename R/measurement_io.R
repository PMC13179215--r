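# Canonical CSV column order for cohort tables. Distances in cm, beta in
# degrees. Ratio columns are derived and therefore not part of the schema,
# but are tolerated (and cross-checked) on input.
COHORT_SCHEMA <- c(
  "specimen_id", "cadaver_id", "sex", "side",
  "aa_ol", "aa_leh", "ipa_ol", "ipb_leh",
  "ipa_ipb", "ipb_bpc", "beta"
)

REQUIRED_LENGTHS <- c("aa_ol", "aa_leh", "ipa_ol", "ipb_leh")
OPTIONAL_FIELDS <- c("ipa_ipb", "ipb_bpc", "beta")

#' Construct a validated cohort of specimen measurements
#'
#' A cohort is a data frame with one row per dissected limb, holding the
#' distances between the radial-nerve crossing points and the three bony
#' landmarks (Acromial Angle, Olecranon, Lateral Epicondyle of the
#' Humerus), plus the derived crossing fractions \code{r_a = ipa_ol/aa_ol}
#' and \code{r_b = ipb_leh/aa_leh}.
#'
#' All distances are in centimeters; \code{beta} is the angle (degrees)
#' between the IPB-LEH and IPB-BPC directions distal to the triangle.
#' The auxiliary fields \code{ipa_ipb}, \code{ipb_bpc} and \code{beta} may
#' be \code{NA}; analyses that need them drop incomplete rows.
#'
#' @param data data frame with the columns of the cohort CSV schema
#'   (\code{specimen_id, cadaver_id, sex, side, aa_ol, aa_leh, ipa_ol,
#'   ipb_leh, ipa_ipb, ipb_bpc, beta}). \code{r_a}/\code{r_b} columns, if
#'   present, are checked against the distance quotients (tolerance 0.005
#'   to absorb 0.1 cm rounding of the distances) and then replaced by the
#'   exact quotients.
#' @param label short cohort label carried through reports.
#' @return object of class \code{rn_cohort} (a data frame).
#' @export
cohort <- function(data, label = "cohort") {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  missing_cols <- setdiff(COHORT_SCHEMA, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  if (nrow(data) > 0L) {
    validate_cohort_rows(data)
    # canonical derived ratios: exact distance quotients
    r_a_new <- data$ipa_ol / data$aa_ol
    r_b_new <- data$ipb_leh / data$aa_leh
    for (nm in c("r_a", "r_b")) {
      if (nm %in% names(data)) {
        stored <- data[[nm]]
        recomputed <- if (nm == "r_a") r_a_new else r_b_new
        bad <- which(is.finite(stored) &
                       abs(stored - recomputed) > 0.005 + 1e-6)
        if (length(bad) > 0L) {
          stop("cohort validation error: ", nm, " inconsistent with ",
               "distance quotient at row ", bad[1L], call. = FALSE)
        }
      }
    }
    data$r_a <- r_a_new
    data$r_b <- r_b_new
  } else {
    data$r_a <- numeric(0)
    data$r_b <- numeric(0)
  }

  out <- data[, c(COHORT_SCHEMA, "r_a", "r_b")]
  rownames(out) <- NULL
  class(out) <- c("rn_cohort", "data.frame")
  attr(out, "label") <- label
  out
}

validate_cohort_rows <- function(data) {
  fail <- function(row, what) {
    stop("cohort validation error at row ", row, ": ", what, call. = FALSE)
  }
  sex <- as.character(data$sex)
  bad <- which(!sex %in% c("male", "female"))
  if (length(bad)) fail(bad[1L], "sex must be 'male' or 'female'")
  side <- as.character(data$side)
  bad <- which(!side %in% c("left", "right"))
  if (length(bad)) fail(bad[1L], "side must be 'left' or 'right'")

  for (nm in REQUIRED_LENGTHS) {
    v <- data[[nm]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) fail(bad[1L], paste0(nm, " must be a positive length"))
  }
  for (nm in c("ipa_ipb", "ipb_bpc")) {
    v <- data[[nm]]
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad)) fail(bad[1L], paste0(nm, " must be positive when present"))
  }
  b <- data$beta
  bad <- which(!is.na(b) & (!is.finite(b) | b < 0 | b >= 90))
  if (length(bad)) fail(bad[1L], "beta must satisfy 0 <= beta < 90 degrees")

  r_a <- data$ipa_ol / data$aa_ol
  bad <- which(r_a <= 0 | r_a >= 1)
  if (length(bad)) fail(bad[1L], "ipa_ol/aa_ol must lie strictly in (0, 1)")
  r_b <- data$ipb_leh / data$aa_leh
  bad <- which(r_b <= 0 | r_b >= 1)
  if (length(bad)) fail(bad[1L], "ipb_leh/aa_leh must lie strictly in (0, 1)")

  key <- paste(data$cadaver_id, data$side, sep = "\r")
  if (anyDuplicated(key)) {
    fail(which(duplicated(key))[1L], "(cadaver_id, side) must be unique")
  }
  if (anyDuplicated(data$specimen_id)) {
    fail(which(duplicated(data$specimen_id))[1L],
         "specimen_id must be unique")
  }
  invisible(TRUE)
}

#' @export
print.rn_cohort <- function(x, ...) {
  cat(sprintf("Radial-nerve measurement cohort '%s': %d specimens (%d cadavers)\n",
              attr(x, "label") %||% "cohort", nrow(x),
              length(unique(x$cadaver_id))))
  if (nrow(x) > 0L) {
    cat(sprintf("  sexes: %d male / %d female limbs; r_a mean %.3f, r_b mean %.3f\n",
                sum(x$sex == "male"), sum(x$sex == "female"),
                mean(x$r_a), mean(x$r_b)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort measurement table from CSV
#'
#' Reads a comma-separated, dot-decimal measurement table with one header
#' row following the cohort schema, validates every row (positivity,
#' crossing fractions in (0,1), unique (cadaver, side)), and recomputes
#' the crossing ratios from the distances.
#'
#' @param path path to an existing CSV file.
#' @param label cohort label; defaults to the file name.
#' @return validated \code{rn_cohort}.
#' @export
read_cohort_csv <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = NA, na.strings = c("", "NA"),
                         comment.char = "#")
  if (is.null(label)) {
    label <- tools::file_path_sans_ext(basename(path))
  }
  if (nrow(raw) == 0L) {
    missing_cols <- setdiff(COHORT_SCHEMA, names(raw))
    if (length(missing_cols) > 0L) {
      stop("cohort schema error: missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    warning("cohort file has no data rows: ", path, call. = FALSE)
  }
  for (nm in intersect(names(raw),
                       c(REQUIRED_LENGTHS, OPTIONAL_FIELDS, "r_a", "r_b"))) {
    raw[[nm]] <- as.numeric(raw[[nm]])
  }
  cohort(raw, label = label)
}

#' Write a cohort measurement table to CSV
#'
#' Writes the canonical schema columns (not the derived ratios) with
#' values rounded to 4 decimal places, so that
#' \code{read_cohort_csv(write_cohort_csv(x))} reproduces the cohort to
#' that precision.
#'
#' @param x an \code{rn_cohort}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "rn_cohort"))
  out <- as.data.frame(x)[, COHORT_SCHEMA, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) round(v, 4))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write cohort CSV to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Construct a set of duplicate measurements of one variable
#'
#' Holds the paired first/second readings of a single distance taken by
#' the same investigator, the input to the intraobserver precision
#' statistics.
#'
#' @param variable measured variable, e.g. \code{"AA-Ol"}.
#' @param side limb side the variable was measured on.
#' @param first,second numeric vectors of the two readings (cm), equal
#'   length, all positive.
#' @return object of class \code{rn_repeated}.
#' @export
repeated_measurements <- function(variable, side, first, second) {
  first <- as.numeric(first); second <- as.numeric(second)
  if (length(first) != length(second)) {
    stop("first and second readings must pair up", call. = FALSE)
  }
  if (length(first) < 1L) stop("at least one pair required", call. = FALSE)
  if (any(!is.finite(first)) || any(!is.finite(second)) ||
      any(first <= 0) || any(second <= 0)) {
    stop("all duplicate readings must be positive lengths", call. = FALSE)
  }
  structure(
    list(variable = variable, side = side,
         pairs = data.frame(first = first, second = second)),
    class = "rn_repeated"
  )
}

#' @export
print.rn_repeated <- function(x, ...) {
  cat(sprintf("Duplicate measurements: %s %s, %d pairs\n",
              x$side, x$variable, nrow(x$pairs)))
  invisible(x)
}

#' Embedded duplicate-measurement fixture
#'
#' The printed duplicate readings of the Acromial Angle-Olecranon and
#' Acromial Angle-Lateral Epicondyle distances: 12 extra upper limbs (six
#' cadavers, both sides), each distance measured twice by the same
#' investigator. Used to reproduce the published intraobserver precision
#' estimates without the raw study data.
#'
#' @return named list of four \code{rn_repeated} sets
#'   (left/right x AA-Ol/AA-LEH), six pairs each, ordered as printed
#'   (three female cadavers then three male).
#' @export
table1_fixture <- function() {
  list(
    left_aa_ol = repeated_measurements(
      "AA-Ol", "left",
      first  = c(27.5, 29.2, 28.2, 30.0, 31.2, 28.9),
      second = c(27.5, 29.4, 28.1, 30.1, 31.2, 29.0)),
    right_aa_ol = repeated_measurements(
      "AA-Ol", "right",
      first  = c(26.5, 30.0, 29.0, 30.1, 31.2, 29.5),
      second = c(26.5, 30.0, 29.0, 30.1, 31.2, 29.5)),
    left_aa_leh = repeated_measurements(
      "AA-LEH", "left",
      first  = c(26.8, 28.6, 27.9, 29.0, 30.5, 28.7),
      second = c(26.9, 28.6, 28.1, 29.1, 30.4, 28.8)),
    right_aa_leh = repeated_measurements(
      "AA-LEH", "right",
      first  = c(27.2, 28.7, 28.1, 29.6, 31.1, 29.0),
      second = c(27.1, 28.8, 28.2, 29.6, 31.0, 29.1))
  )
}

#' Read duplicate measurements from CSV
#'
#' Expects columns \code{variable,side,first,second}; one
#' \code{rn_repeated} set is built per (variable, side) combination.
#'
#' @param path CSV path.
#' @return named list of \code{rn_repeated}.
#' @export
read_repeated_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "side", "first", "second")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("duplicate-measurement schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keys <- unique(raw[, c("variable", "side")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- raw[raw$variable == keys$variable[i] & raw$side == keys$side[i], ]
    repeated_measurements(keys$variable[i], keys$side[i],
                          sub$first, sub$second)
  })
  names(out) <- tolower(paste(keys$side, gsub("[^A-Za-z]+", "_",
                                              keys$variable), sep = "_"))
  out
}
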