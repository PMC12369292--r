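#' Case-control dose-response datasets
#'
#' A `cc_dataset` holds one published case-control study as an ordered table
#' of exposure groups (the referent group first) plus the study metadata
#' needed for exposure adjustment.  Groups are stored as a data frame with
#' one row per exposure group and columns:
#'
#' \describe{
#'   \item{group_label}{the exposure range as printed, e.g. `"15.5-42.5"`}
#'   \item{dose_low, dose_high, dose_median}{interval bounds in ug/L; an
#'     `NA` bound marks an open-ended interval, `dose_median` an interval
#'     reported as a single point}
#'   \item{midpoint}{adjusted exposure midpoint in ug/L (filled by
#'     [adjust_dataset()])}
#'   \item{midpoint_printed}{a midpoint carried verbatim from the source
#'     table, used when `use_printed = TRUE`}
#'   \item{or, or_low, or_high}{adjusted odds ratio and its confidence
#'     bounds; the referent row has `or = 1` and `NA` bounds}
#'   \item{cases, noncases, n}{raw counts (`A_i^r`, `B_i^r`, `N_i^r`)}
#'   \item{eff_cases, eff_noncases, n_eff}{effective counts (`A_i^e`,
#'     `B_i^e`, `N_i^e`); real-valued in general}
#' }
#'
#' @param study_id short study identifier, e.g. `"Pu"`.
#' @param endpoint one of `"bladder"`, `"lung"`, `"other"`.
#' @param location free-text study location.
#' @param water_intake_rate study-population drinking-water intake in L/day.
#' @param baseline_intake_rate baseline intake in L/day the midpoints are
#'   scaled to; defaults to 2 L/day.
#' @param groups data frame of exposure groups as described above; missing
#'   optional columns are added as `NA`.
#' @param ci_level confidence level of the reported OR intervals.
#' @return an object of class `cc_dataset`.
#' @export
cc_dataset <- function(study_id, endpoint = c("bladder", "lung", "other"),
                       location = "", water_intake_rate,
                       baseline_intake_rate = 2, groups, ci_level = 0.95) {
  endpoint <- match.arg(endpoint)
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  needed <- c("group_label", "dose_low", "dose_high", "dose_median",
              "midpoint", "midpoint_printed", "or", "or_low", "or_high",
              "cases", "noncases", "n", "eff_cases", "eff_noncases", "n_eff")
  for (col in setdiff(needed, names(groups))) groups[[col]] <- NA_real_
  groups <- groups[, needed]
  ds <- structure(
    list(study_id = study_id, endpoint = endpoint, location = location,
         water_intake_rate = water_intake_rate,
         baseline_intake_rate = baseline_intake_rate,
         ci_level = ci_level, groups = groups),
    class = "cc_dataset")
  validate_cc_dataset(ds)
  ds
}

validate_cc_dataset <- function(ds) {
  g <- ds$groups
  if (nrow(g) < 2)
    stop("a case-control dataset needs at least 2 exposure groups ",
         "(referent + 1)", call. = FALSE)
  if (!is.numeric(ds$water_intake_rate) || ds$water_intake_rate <= 0)
    stop("water_intake_rate must be > 0", call. = FALSE)
  if (ds$baseline_intake_rate <= 0)
    stop("baseline_intake_rate must be > 0", call. = FALSE)
  no_interval <- is.na(g$dose_low) & is.na(g$dose_high) & is.na(g$dose_median)
  if (any(no_interval & is.na(g$midpoint_printed)))
    stop("every group needs at least one of dose_low, dose_high, dose_median",
         call. = FALSE)
  both <- !is.na(g$dose_low) & !is.na(g$dose_high)
  if (any(g$dose_low[both] > g$dose_high[both]))
    stop("dose_low > dose_high in some group", call. = FALSE)
  if (any(c(g$dose_low, g$dose_high, g$dose_median) < 0, na.rm = TRUE))
    stop("dose bounds must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(g$or[1], 1)))
    stop("first row must be the referent group with or = 1", call. = FALSE)
  if (!is.na(g$or_low[1]) || !is.na(g$or_high[1]))
    stop("the referent group must not carry a confidence interval",
         call. = FALSE)
  cnt <- !is.na(g$cases) & !is.na(g$noncases) & !is.na(g$n)
  if (any(abs(g$cases[cnt] + g$noncases[cnt] - g$n[cnt]) > 1e-8))
    stop("cases + noncases must equal n in every group", call. = FALSE)
  ok_or <- !is.na(g$or_low) & !is.na(g$or_high)
  if (any(g$or_low[ok_or] > g$or[ok_or] | g$or[ok_or] > g$or_high[ok_or]))
    stop("need or_low <= or <= or_high", call. = FALSE)
  invisible(ds)
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf("Case-control dataset: %s (%s), endpoint %s\n",
              x$study_id, x$location, x$endpoint))
  cat(sprintf("  water intake %.2f L/day (baseline %.2f), %d exposure groups\n",
              x$water_intake_rate, x$baseline_intake_rate, nrow(x$groups)))
  print(x$groups[, c("group_label", "midpoint", "or", "or_low", "or_high",
                     "cases", "noncases", "n", "eff_cases", "eff_noncases")],
        digits = 4)
  invisible(x)
}

#' Parse printed dose-interval strings
#'
#' Turns strings such as `"<26"`, `">=800"`, `"15.5-42.5"`, `"≤27.8"`
#' or a bare number into `(dose_low, dose_high, dose_median)` triplets.
#' `"<x"` and `"≤x"` parse identically (open below, upper bound x), as
#' do `">x"` and `"≥x"` (open above); midpoint formulas do not
#' distinguish strictness.  A bare number is taken as a reported median.
#'
#' @param x character vector of interval labels.
#' @return data frame with columns `dose_low`, `dose_high`, `dose_median`.
#' @export
parse_dose_interval <- function(x) {
  x <- trimws(as.character(x))
  # normalise unicode comparison signs and dashes
  x <- gsub("≤", "<=", x)
  x <- gsub("≥", ">=", x)
  x <- gsub("–|—|‒", "-", x)
  out <- data.frame(dose_low = NA_real_, dose_high = NA_real_,
                    dose_median = NA_real_)[rep(1, length(x)), , drop = FALSE]
  rownames(out) <- NULL
  num <- "([0-9]*\\.?[0-9]+)"
  for (i in seq_along(x)) {
    s <- x[i]
    if (grepl(paste0("^<=?", num, "$"), s)) {
      out$dose_high[i] <- as.numeric(sub(paste0("^<=?", num, "$"), "\\1", s))
    } else if (grepl(paste0("^>=?", num, "$"), s)) {
      out$dose_low[i] <- as.numeric(sub(paste0("^>=?", num, "$"), "\\1", s))
    } else if (grepl(paste0("^", num, "-", num, "$"), s)) {
      out$dose_low[i] <- as.numeric(sub(paste0("^", num, "-", num, "$"), "\\1", s))
      out$dose_high[i] <- as.numeric(sub(paste0("^", num, "-", num, "$"), "\\2", s))
    } else if (grepl(paste0("^", num, "$"), s)) {
      out$dose_median[i] <- as.numeric(s)
    } else {
      stop("cannot parse dose interval string: '", x[i], "'", call. = FALSE)
    }
  }
  out
}

#' Read a case-control dataset from a delimited table
#'
#' Reads a comma- or tab-separated table with one row per exposure group,
#' referent first.  Interval bounds are taken from `dose_low` / `dose_high`
#' / `dose_median` columns when present, otherwise parsed from
#' `group_label` via [parse_dose_interval()].
#'
#' @param table path to a delimited file, or a data frame.
#' @param meta named list of study metadata: `study_id`, `endpoint`,
#'   `location`, `water_intake_rate`, optionally `baseline_intake_rate`,
#'   `ci_level`.
#' @return a [cc_dataset()].
#' @export
read_dataset <- function(table, meta) {
  if (is.character(table)) {
    first <- readLines(table, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    table <- utils::read.csv(table, sep = sep, stringsAsFactors = FALSE,
                             check.names = FALSE)
  }
  g <- as.data.frame(table, stringsAsFactors = FALSE)
  has_bounds <- all(c("dose_low", "dose_high") %in% names(g)) &&
    !all(is.na(g$dose_low) & is.na(g$dose_high) &
         is.na(g[["dose_median"]] %||% NA))
  if (!has_bounds) {
    if (!"group_label" %in% names(g))
      stop("need dose_low/dose_high/dose_median columns or a group_label ",
           "column with parseable interval strings", call. = FALSE)
    g <- cbind(g[setdiff(names(g), c("dose_low", "dose_high", "dose_median"))],
               parse_dose_interval(g$group_label))
  }
  do.call(cc_dataset, c(meta, list(groups = g)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a case-control dataset back to a delimited file
#'
#' Emits the group table (all numeric fields at full precision) plus a
#' commented header block carrying the study metadata, so that
#' `read_dataset()` on the result round-trips every numeric field exactly.
#'
#' @param ds a [cc_dataset()].
#' @param path output file path; `".tsv"` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# study_id=%s endpoint=%s location=%s water_intake_rate=%.17g baseline_intake_rate=%.17g ci_level=%.17g",
                     ds$study_id, ds$endpoint, ds$location,
                     ds$water_intake_rate, ds$baseline_intake_rate,
                     ds$ci_level), con)
  utils::write.csv(ds$groups, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Re-read a dataset written by [write_dataset()]
#' @param path file written by [write_dataset()].
#' @return a [cc_dataset()].
#' @export
#' @rdname write_dataset
read_dataset_file <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- list()
  for (p in kv) {
    k <- sub("=.*", "", p); v <- sub("^[a-z_]+=", "", p)
    meta[[k]] <- if (k %in% c("study_id", "endpoint", "location")) v
                 else as.numeric(v)
  }
  g <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  do.call(cc_dataset, c(meta, list(groups = g)))
}

#' Packaged arsenic case-control fixtures
#'
#' Returns the bladder or lung cancer case-control tables (inorganic
#' arsenic in drinking water) shipped with the package: five studies per
#' endpoint, with raw counts, adjusted ORs and 95% CIs, printed adjusted
#' exposure midpoints, and printed effective counts all populated.  One
#' lung study (Mostafa, second group) prints an effective subject total
#' (576) different from its raw total (1879); the fixture stores both
#' verbatim.
#'
#' @param endpoint `"bladder"` or `"lung"`.
#' @return named list of five [cc_dataset()] objects.
#' @export
load_fixture <- function(endpoint = c("bladder", "lung")) {
  endpoint <- match.arg(endpoint)
  path <- system.file("extdata", paste0("arsenic_", endpoint, ".csv"),
                      package = "ccbmd", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(tab$study_id)) {
    rows <- tab[tab$study_id == id, ]
    out[[id]] <- cc_dataset(
      study_id = id, endpoint = endpoint, location = rows$location[1],
      water_intake_rate = rows$water_intake[1],
      groups = rows[, setdiff(names(rows),
                              c("study_id", "location", "water_intake"))])
  }
  out
}

#' Summary totals used by the Wang referent search
#'
#' Collapses a dataset to the quantities the referent-group effective-count
#' search needs: referent and total subject counts and the arithmetic means
#' of the adjusted ORs and their CI bounds over the non-referent groups.
#'
#' @param ds a [cc_dataset()].
#' @return list with `n_referent`, `n_total`, `mean_or`, `mean_or_low`,
#'   `mean_or_high`.
#' @export
totals_summary <- function(ds) {
  g <- ds$groups
  trt <- g[-1, ]
  if (any(is.na(trt$or) | is.na(trt$or_low) | is.na(trt$or_high)))
    stop("all non-referent groups need or, or_low, or_high", call. = FALSE)
  list(n_referent = g$n[1],
       n_total = sum(g$n),
       mean_or = mean(trt$or),
       mean_or_low = mean(trt$or_low),
       mean_or_high = mean(trt$or_high))
}
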