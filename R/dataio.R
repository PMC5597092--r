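#' Wide-format longitudinal dataset
#'
#' The central data container: one row per subject, one outcome column per
#' measurement wave, an explicit missingness mask (`NA` in the outcome
#' matrix), optional auxiliary covariates and an optional administrative
#' dropout-group label. Wave times are the slope loadings of the growth
#' model, in years since the first wave; they must start at 0 and be strictly
#' increasing. Subjects observed at no wave carry no information for any of
#' the estimators and are excluded (with the removed count recorded in
#' `$n_dropped`), mirroring standard practice in longitudinal panels.
#'
#' @param y numeric matrix (subjects x waves) of outcome scores, `NA` for
#'   missing.
#' @param wave_times numeric vector of slope loadings, one per wave; first
#'   must be 0, strictly increasing.
#' @param subject_id optional identifiers (default `1:n`).
#' @param aux optional data frame of per-subject auxiliary covariates.
#' @param dropout_group optional integer vector of administrative dropout
#'   labels (1 = least dropout).
#' @param drop_all_missing if `TRUE` (default) rows with no observed wave are
#'   removed and counted; if `FALSE` such rows are an error.
#' @return An object of class `wide_dataset`: a list with elements `y`,
#'   `wave_times`, `subject_id`, `aux`, `dropout_group`, `n_dropped`.
#' @export
wide_dataset <- function(y, wave_times, subject_id = NULL, aux = NULL,
                         dropout_group = NULL, drop_all_missing = TRUE) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  nt <- ncol(y)
  if (nt < 2L) stop("a longitudinal dataset needs at least two waves")
  wave_times <- as.numeric(wave_times)
  if (length(wave_times) != nt)
    stop("length(wave_times) must equal the number of wave columns")
  if (wave_times[1L] != 0)
    stop("the first wave time (slope loading) must be 0")
  if (any(diff(wave_times) <= 0))
    stop("wave_times must be strictly increasing")
  n <- nrow(y)
  if (is.null(subject_id)) subject_id <- seq_len(n)
  if (length(subject_id) != n) stop("subject_id has the wrong length")
  if (!is.null(aux)) {
    aux <- as.data.frame(aux)
    if (nrow(aux) != n) stop("aux must have one row per subject")
  }
  if (!is.null(dropout_group)) {
    dropout_group <- as.integer(dropout_group)
    if (length(dropout_group) != n) stop("dropout_group has the wrong length")
  }
  if (is.null(colnames(y))) colnames(y) <- paste0("wave", seq_len(nt))

  n_obs <- rowSums(!is.na(y))
  n_dropped <- 0L
  if (any(n_obs == 0L)) {
    if (!drop_all_missing)
      stop("subjects observed at no wave are present; ",
           "use drop_all_missing = TRUE to exclude them")
    keep <- n_obs > 0L
    n_dropped <- sum(!keep)
    y <- y[keep, , drop = FALSE]
    subject_id <- subject_id[keep]
    if (!is.null(aux)) aux <- aux[keep, , drop = FALSE]
    if (!is.null(dropout_group)) dropout_group <- dropout_group[keep]
    message(n_dropped, " subject(s) observed at no wave excluded")
  }

  structure(list(y = y, wave_times = wave_times, subject_id = subject_id,
                 aux = aux, dropout_group = dropout_group,
                 n_dropped = n_dropped),
            class = "wide_dataset")
}

#' @export
print.wide_dataset <- function(x, ...) {
  obs <- !is.na(x$y)
  cat("wide_dataset:", nrow(x$y), "subjects,", ncol(x$y), "waves",
      sprintf("(loadings %s)\n", paste(x$wave_times, collapse = ", ")))
  cat(sprintf("  observed cells: %.1f%%; complete cases: %d",
              100 * mean(obs), sum(rowSums(obs) == ncol(x$y))))
  if (x$n_dropped > 0L) cat(";", x$n_dropped, "all-missing subjects excluded")
  cat("\n")
  if (!is.null(x$aux))
    cat("  auxiliaries:", paste(names(x$aux), collapse = ", "), "\n")
  if (!is.null(x$dropout_group))
    cat("  dropout groups:",
        paste(names(table(x$dropout_group)), table(x$dropout_group),
              sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Read a wide-format longitudinal CSV
#'
#' Reads one row per subject. Both the empty string and `na_token` denote a
#' missing value; any other cell that does not parse as a number in a wave
#' column is a parse error naming the row and column.
#'
#' @param path CSV file path (comma-separated, header row required).
#' @param wave_columns names of the outcome columns, in wave order.
#' @param aux_columns optional names of auxiliary columns (numeric columns
#'   are parsed as numeric, anything else is kept as a factor).
#' @param group_column optional name of an integer dropout-group column.
#' @param id_column optional name of a subject-identifier column.
#' @param na_token text marking a missing value (in addition to empty cells).
#' @param wave_times slope loadings; defaults to `0:(T-1)`.
#' @param drop_all_missing passed to [wide_dataset()].
#' @return A [wide_dataset()].
#' @export
read_wide_csv <- function(path, wave_columns, aux_columns = NULL,
                          group_column = NULL, id_column = NULL,
                          na_token = "NA", wave_times = NULL,
                          drop_all_missing = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c(wave_columns, aux_columns, group_column, id_column)
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("column(s) not found in header: ", paste(absent, collapse = ", "))

  parse_num <- function(col, name) {
    miss <- is.na(col) | col == "" | col == na_token
    out <- rep(NA_real_, length(col))
    if (any(!miss)) {
      val <- suppressWarnings(as.numeric(col[!miss]))
      if (anyNA(val)) {
        bad <- which(!miss)[which(is.na(val))[1L]]
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     col[bad], name, bad))
      }
      out[!miss] <- val
    }
    out
  }

  y <- vapply(wave_columns, function(nm) parse_num(raw[[nm]], nm),
              numeric(nrow(raw)))
  if (nrow(raw) == 1L) y <- matrix(y, nrow = 1L,
                                   dimnames = list(NULL, wave_columns))
  aux <- NULL
  if (!is.null(aux_columns)) {
    aux <- as.data.frame(lapply(stats::setNames(aux_columns, aux_columns),
      function(nm) {
        col <- raw[[nm]]
        miss <- is.na(col) | col == "" | col == na_token
        num <- suppressWarnings(as.numeric(col[!miss]))
        if (!anyNA(num)) parse_num(col, nm)
        else factor(replace(col, miss, NA))
      }))
  }
  grp <- if (!is.null(group_column))
    as.integer(parse_num(raw[[group_column]], group_column))
  id <- if (!is.null(id_column)) raw[[id_column]] else NULL

  wide_dataset(y, wave_times %||% seq(0, length(wave_columns) - 1L),
               subject_id = id, aux = aux, dropout_group = grp,
               drop_all_missing = drop_all_missing)
}

#' Write a wide-format longitudinal CSV
#'
#' Writes the same dialect [read_wide_csv()] reads; numeric values are
#' written with 17 significant digits so a write/read round trip reproduces
#' values and mask exactly.
#'
#' @param ds a [wide_dataset()].
#' @param path output path.
#' @param na_token text written for missing values (default: empty cell).
#' @return `path`, invisibly.
#' @export
write_wide_csv <- function(ds, path, na_token = "") {
  df <- data.frame(subject_id = ds$subject_id, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(ds$wave_times)) {
    v <- ds$y[, j]
    df[[colnames(ds$y)[j]]] <- ifelse(is.na(v), na_token,
                                      sprintf("%.17g", v))
  }
  if (!is.null(ds$aux)) for (nm in names(ds$aux)) {
    v <- ds$aux[[nm]]
    df[[nm]] <- if (is.numeric(v))
      ifelse(is.na(v), na_token, sprintf("%.17g", v))
    else ifelse(is.na(v), na_token, as.character(v))
  }
  if (!is.null(ds$dropout_group))
    df$dropout_group <- ifelse(is.na(ds$dropout_group), na_token,
                               as.character(ds$dropout_group))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Missingness pattern table
#'
#' Tabulates the exhaustive, mutually exclusive observed/missing patterns
#' over waves, with the subject count and the number of observed waves per
#' pattern. These counts are the per-pattern inputs of Little's MCAR test.
#'
#' @param ds a [wide_dataset()].
#' @return An object of class `pattern_table`: a data frame with columns
#'   `pattern` (e.g. `"101"`, 1 = observed), `count`, `n_observed`.
#' @export
missingness_pattern_table <- function(ds) {
  obs <- !is.na(ds$y)
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(key)
  out <- data.frame(pattern = names(tab),
                    count = as.integer(tab),
                    n_observed = vapply(strsplit(names(tab), ""),
                                        function(s) sum(s == "1"),
                                        integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pattern), ]
  rownames(out) <- NULL
  class(out) <- c("pattern_table", "data.frame")
  out
}

#' @export
print.pattern_table <- function(x, ...) {
  cat("missingness patterns (1 = observed), N =", sum(x$count), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Per-wave response summary
#'
#' @param ds a [wide_dataset()].
#' @return An object of class `response_summary`: list with `wave` (observed
#'   count per wave), `complete` (fully observed subjects), `n` (retained
#'   subjects) and `n_excluded` (all-missing subjects removed on
#'   construction).
#' @export
response_summary <- function(ds) {
  obs <- !is.na(ds$y)
  structure(list(wave = colSums(obs),
                 complete = sum(rowSums(obs) == ncol(obs)),
                 n = nrow(obs),
                 n_excluded = ds$n_dropped),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat("observed per wave: ", paste(x$wave, collapse = ", "), "\n",
      "complete cases: ", x$complete, " of ", x$n,
      sprintf(" (%.1f%%)", 100 * x$complete / x$n), "\n", sep = "")
  if (x$n_excluded > 0)
    cat("all-missing subjects excluded on construction:", x$n_excluded, "\n")
  invisible(x)
}
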