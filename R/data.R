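#' Analysis-ready PK data
#'
#' A `pk_data` object is a list of subjects, each with `id`, `cov`
#' ([patient_covariates()]), `doses` (dose-event `data.frame`), `obs`
#' (`data.frame` with `time`, `value`) and an optional named numeric vector
#' `extra` of additional covariates.  It is the input to
#' [fit_population()], [external_validate()] and the dosing tools.
#'
#' @param x A rectangular dataset table (see [read_dataset()]) or a
#'   `pk_cohort`.
#' @param ... Method arguments.
#' @return A `pk_data` object.
#' @export
as_pk_data <- function(x, ...) UseMethod("as_pk_data")

#' @rdname as_pk_data
#' @param records For the `pk_cohort` method: a `data.frame` of simulated
#'   concentration records (e.g. from [simulate_cohort()]) with columns
#'   `subject_id`, `time`, `value`; attached as each subject's observations.
#' @export
as_pk_data.pk_cohort <- function(x, records = NULL, ...) {
  out <- lapply(x, function(s) {
    obs <- if (is.null(records)) {
      data.frame(time = numeric(), value = numeric())
    } else {
      r <- records[records$subject_id == s$id, , drop = FALSE]
      data.frame(time = r$time, value = r$value)
    }
    list(id = s$id, cov = s$cov, doses = s$doses, obs = obs,
         extra = s$extra)
  })
  structure(out, class = "pk_data")
}

#' @rdname as_pk_data
#' @export
as_pk_data.data.frame <- function(x, ...) {
  required <- c("ID", "TIME", "AMT", "DV", "MDV", "AGE", "SEX", "TBW", "SCR")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  known <- c(required, "RATE", "DUR")
  extra_cols <- setdiff(names(x), known)
  ids <- unique(x$ID)
  out <- lapply(ids, function(id) {
    rows <- x[x$ID == id, , drop = FALSE]
    if (is.unsorted(rows$TIME)) {
      stop("times are not non-decreasing within subject ", id, call. = FALSE)
    }
    sex_raw <- rows$SEX[1]
    sex <- if (is.character(sex_raw) || is.factor(sex_raw)) {
      as.character(sex_raw)
    } else if (as.numeric(sex_raw) == 1) "male" else "female"
    for (cc in c("AGE", "SEX", "TBW", "SCR")) {
      if (length(unique(rows[[cc]])) > 1) {
        stop("covariate ", cc, " is time-varying within subject ", id,
             "; this is not supported", call. = FALSE)
      }
    }
    cov <- patient_covariates(rows$AGE[1], sex, rows$TBW[1], rows$SCR[1])
    is_dose <- !is.na(rows$AMT) & rows$AMT > 0
    drows <- rows[is_dose, , drop = FALSE]
    dur <- if ("DUR" %in% names(drows) && any(!is.na(drows$DUR))) {
      drows$DUR
    } else if ("RATE" %in% names(drows) && any(!is.na(drows$RATE))) {
      drows$AMT / drows$RATE
    } else {
      default_infusion_duration(drows$AMT)
    }
    doses <- dose_events(drows$TIME, drows$AMT, dur)
    orows <- rows[!is_dose & !is.na(rows$DV) & rows$MDV == 0, , drop = FALSE]
    extra <- if (length(extra_cols)) {
      stats::setNames(as.numeric(rows[1, extra_cols]), extra_cols)
    } else {
      stats::setNames(numeric(0), character(0))
    }
    list(id = as.character(id), cov = cov, doses = doses,
         obs = data.frame(time = orows$TIME, value = orows$DV),
         extra = extra)
  })
  structure(out, class = "pk_data")
}

#' @export
print.pk_data <- function(x, ...) {
  nobs <- vapply(x, function(s) nrow(s$obs), numeric(1))
  cat(sprintf("PK dataset: %d subjects, %d observations (%.2f/subject)\n",
              length(x), sum(nobs), mean(nobs)))
  invisible(x)
}

#' Read a rectangular PK dataset
#'
#' Reads the package's NONMEM-style CSV layout: one row per dose or
#' observation event, columns `ID, TIME, AMT, RATE, DUR, DV, MDV, AGE, SEX,
#' TBW, SCR` (additional numeric columns are carried along as extra
#' subject-level covariates).  `"."` and empty fields are read as missing.
#' Each row must be either a dose row (`AMT` present, `MDV = 1`) or an
#' observation row (`DV` present, `AMT` absent).
#'
#' @param path CSV file path.
#' @param verbose Log row/column counts.
#' @return A validated `data.frame` (the dataset table).
#' @export
read_dataset <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, na.strings = c(".", "", "NA"),
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("dataset has 0 rows: ", path, call. = FALSE)
  required <- c("ID", "TIME", "AMT", "DV", "MDV", "AGE", "SEX", "TBW", "SCR")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- setdiff(names(df), "SEX")
  bad_lines <- integer(0)
  for (cc in numeric_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad_lines <- union(bad_lines,
                         which(!is.na(v) & is.na(coerced)) + 1L)
      df[[cc]] <- coerced
    }
  }
  bad_lines <- union(bad_lines, which(is.na(df$TIME) | df$TIME < 0) + 1L)
  both <- which(!is.na(df$AMT) & df$AMT > 0 & !is.na(df$DV) & df$MDV == 0)
  bad_lines <- union(bad_lines, both + 1L)
  if (length(bad_lines)) {
    stop("malformed dataset rows at line(s) ",
         paste(sort(bad_lines), collapse = ", "),
         " (non-numeric field, negative time, or dose and observation in ",
         "one row)", call. = FALSE)
  }
  vlog(verbose, "read %d rows x %d columns from %s (%d subjects)",
       nrow(df), ncol(df), path, length(unique(df$ID)))
  df
}

#' Write a rectangular PK dataset
#'
#' Inverse of [read_dataset()]; missing values are written as empty fields.
#'
#' @param df Dataset table.
#' @param path Output CSV path.
#' @export
write_dataset <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build a dataset table from a cohort and simulated records
#'
#' @param cohort A `pk_cohort`.
#' @param records Optional concentration records (`subject_id`, `time`,
#'   `value`) to include as observation rows.
#' @return A dataset table `data.frame` in the package's CSV layout.
#' @export
cohort_to_dataset <- function(cohort, records = NULL) {
  rows <- lapply(cohort, function(s) {
    base <- data.frame(
      AGE = s$cov$age, SEX = as.numeric(s$cov$sex == "male"),
      TBW = s$cov$tbw, SCR = s$cov$scr)
    d <- data.frame(ID = s$id, TIME = s$doses$time, AMT = s$doses$amount,
                    RATE = s$doses$rate, DUR = s$doses$duration,
                    DV = NA_real_, MDV = 1, base, row.names = NULL)
    o <- NULL
    if (!is.null(records)) {
      r <- records[records$subject_id == s$id, , drop = FALSE]
      if (nrow(r)) {
        o <- data.frame(ID = s$id, TIME = r$time, AMT = NA_real_,
                        RATE = NA_real_, DUR = NA_real_, DV = r$value,
                        MDV = 0, base, row.names = NULL)
      }
    }
    x <- rbind(d, o)
    if (length(s$extra)) for (nm in names(s$extra)) x[[nm]] <- s$extra[[nm]]
    x[order(x$TIME, x$MDV), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-parameter configuration
#'
#' Reads a YAML or JSON configuration whose keys mirror
#' [population_parameters()] arguments; any key may be overridden, all
#' others keep the published defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @param overrides Named list applied on top of the file (highest
#'   precedence, mirroring command-line flags).
#' @return A [population_parameters()] object.
#' @export
vanco_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(vals)) vals <- list()
  }
  vals <- utils::modifyList(as.list(vals), as.list(overrides))
  allowed <- names(formals(population_parameters))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(population_parameters, vals)
}
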