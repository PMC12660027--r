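#' Build a validated ratings table
#'
#' Validates a long-format rating data frame (one row per subject-by-rater
#' rating) and attaches the rating-scale metadata used throughout the
#' package. Labels are kept opaque; dense 1-based indices are stored
#' alongside so model code can use integer indexing while outputs keep the
#' original labels.
#'
#' @param data data frame with columns `subject`, `rater`, `rating`.
#'   `rating` is a real value on `[scale_low, scale_high]` for continuous
#'   tables, or an integer category in `1..n_categories` for ordinal ones.
#' @param scale_low,scale_high rating-scale bounds. Mandatory for continuous
#'   tables; never inferred from data.
#' @param n_categories number of ordered categories, or `NULL` (default) for
#'   continuous ratings.
#' @param .validate_scale internal: skip the scale-bound check (used by the
#'   synthetic generators, whose model is unbounded)
#' @return a tibble of class `ratings_tbl` with columns `subject`, `rater`,
#'   `rating`, `subject_idx`, `rater_idx` and attributes `scale_low`,
#'   `scale_high`, `n_categories`, `subjects`, `raters`.
#' @examples
#' df <- data.frame(subject = c("s1", "s1", "s2"),
#'                  rater = c("r1", "r2", "r1"),
#'                  rating = c(30, 35, 12))
#' ratings(df, scale_low = 1, scale_high = 50)
#' @export
ratings <- function(data, scale_low = NULL, scale_high = NULL,
                    n_categories = NULL, .validate_scale = TRUE) {
  stopifnot(is.data.frame(data))
  need <- c("subject", "rater", "rating")
  if (!all(need %in% names(data))) {
    stop("ratings data must have columns: ", paste(need, collapse = ", "))
  }
  data <- tibble::as_tibble(data[need])
  if (anyNA(data)) stop("ratings data contains missing values")
  ordinal <- !is.null(n_categories)
  if (ordinal) {
    n_categories <- as.integer(n_categories)
    if (n_categories < 2L) stop("n_categories must be >= 2")
    bad <- which(data$rating != round(data$rating) |
                   data$rating < 1 | data$rating > n_categories)
    if (length(bad)) {
      stop("row ", bad[1L], ": category ", data$rating[bad[1L]],
           " outside {1,...,", n_categories, "}")
    }
    data$rating <- as.integer(round(data$rating))
  } else {
    if (is.null(scale_low) || is.null(scale_high)) {
      stop("scale_low and scale_high are mandatory for continuous ratings")
    }
    stopifnot(scale_low < scale_high)
    bad <- if (.validate_scale) {
      which(data$rating < scale_low | data$rating > scale_high)
    } else integer(0)
    if (length(bad)) {
      stop("row ", bad[1L], ": rating ", data$rating[bad[1L]],
           " outside scale [", scale_low, ", ", scale_high, "]")
    }
  }
  key <- paste(data$subject, data$rater, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1L]
    stop("duplicate (subject, rater) pair at row ", dup, ": (",
         data$subject[dup], ", ", data$rater[dup], ")")
  }
  subjects <- unique(as.character(data$subject))
  raters <- unique(as.character(data$rater))
  data$subject_idx <- match(as.character(data$subject), subjects)
  data$rater_idx <- match(as.character(data$rater), raters)
  structure(data,
            class = c("ratings_tbl", class(data)),
            scale_low = scale_low, scale_high = scale_high,
            n_categories = if (ordinal) n_categories else NULL,
            subjects = subjects, raters = raters)
}

#' Read a ratings table from a delimited file
#'
#' Comma-separated text with header `subject,rater,rating`. The rating scale
#' (or category count) is given explicitly, never inferred.
#'
#' @inheritParams ratings
#' @param path path to a CSV file
#' @return a [ratings()] table
#' @export
read_ratings <- function(path, scale_low = NULL, scale_high = NULL,
                         n_categories = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ratings(df, scale_low = scale_low, scale_high = scale_high,
          n_categories = n_categories)
}

#' Write a ratings table to CSV
#'
#' @param x a [ratings()] table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ratings <- function(x, path) {
  stopifnot(inherits(x, "ratings_tbl"))
  utils::write.csv(as.data.frame(x)[c("subject", "rater", "rating")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a rating design
#'
#' Counts subjects, raters and records, and the distribution of ratings per
#' subject (panel size) and per rater (workload).
#'
#' @param data a [ratings()] table
#' @return a one-row tibble with columns `n_subjects`, `n_raters`,
#'   `n_records`, `per_subject_min/mean/max`, `per_rater_min/mean/max`
#' @export
summarize_design <- function(data) {
  stopifnot(inherits(data, "ratings_tbl"))
  ps <- tabulate(data$subject_idx)
  pr <- tabulate(data$rater_idx)
  tibble::tibble(
    n_subjects = length(attr(data, "subjects")),
    n_raters = length(attr(data, "raters")),
    n_records = nrow(data),
    per_subject_min = min(ps), per_subject_mean = mean(ps),
    per_subject_max = max(ps),
    per_rater_min = min(pr), per_rater_mean = mean(pr),
    per_rater_max = max(pr))
}

#' Coarsen continuous ratings into ordered categories
#'
#' Collapses each continuous rating into `1 + #(cutoffs strictly below it)`;
#' values exactly at a cutoff fall in the lower category, i.e. categories are
#' the right-closed intervals `(cut[c-1], cut[c]]`.
#'
#' @param data a continuous [ratings()] table
#' @param cutoffs strictly increasing cutoffs inside the rating scale
#' @return an ordinal [ratings()] table with `length(cutoffs) + 1` categories
#'   and attribute `cutoffs`
#' @export
coarsen <- function(data, cutoffs) {
  stopifnot(inherits(data, "ratings_tbl"),
            is.null(attr(data, "n_categories")))
  cutoffs <- as.numeric(cutoffs)
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be strictly increasing")
  }
  lo <- attr(data, "scale_low"); hi <- attr(data, "scale_high")
  if (any(cutoffs <= lo) || any(cutoffs >= hi)) {
    stop("cutoffs must lie strictly inside the rating scale")
  }
  cat <- 1L + as.integer(rowSums(outer(data$rating, cutoffs, ">")))
  out <- data.frame(subject = data$subject, rater = data$rater, rating = cat)
  out <- ratings(out, n_categories = length(cutoffs) + 1L)
  attr(out, "cutoffs") <- cutoffs
  out
}

#' @export
print.ratings_tbl <- function(x, ...) {
  nc <- attr(x, "n_categories")
  if (is.null(nc)) {
    cat(sprintf("# Continuous ratings on [%s, %s]\n",
                format(attr(x, "scale_low")), format(attr(x, "scale_high"))))
  } else {
    cat(sprintf("# Ordinal ratings with %d categories\n", nc))
  }
  NextMethod()
}
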