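# Bundled fixtures: the classical 72 guinea-pig survival times (days after
# injection with tubercle bacilli), the 36 first-failure minima obtained by
# randomly pairing them (k = 2, one published realisation), and the three
# progressively first-failure censored subsamples drawn from those minima
# under the schemes (18, 0*17), (1*18) and (0*17, 18) with m = 18.

.fixture_files <- c(
  guinea_complete = "guinea_complete.txt",
  guinea_ff36 = "guinea_ff36.txt",
  guinea_R1 = "guinea_R1.txt",
  guinea_R2 = "guinea_R2.txt",
  guinea_R3 = "guinea_R3.txt")

.fixture_schemes <- list(
  guinea_R1 = function() censoring_scheme(2, 36, c(18L, rep(0L, 17))),
  guinea_R2 = function() censoring_scheme(2, 36, rep(1L, 18)),
  guinea_R3 = function() censoring_scheme(2, 36, c(rep(0L, 17), 18L)))

#' Load a lifetime dataset
#'
#' Reads positive failure times from a plain-text file (one value per
#' line, or a single-column CSV with optional header; `#` comment lines
#' ignored), or returns one of the bundled fixtures by name:
#' `"guinea_complete"` (72 guinea-pig survival days),
#' `"guinea_ff36"` (the 36 first-failure group minima, k = 2),
#' `"guinea_R1"`, `"guinea_R2"`, `"guinea_R3"` (the three censored
#' subsamples, each with k = 2, n = 36, m = 18 and removal schemes
#' `(18, 0*17)`, `(1*18)`, `(0*17, 18)`).
#'
#' @param path file path or fixture name.
#' @return A list of class `"pff_dataset"` with `times`, `label`, and
#'   `censoring` (a [censoring_scheme] or `NULL` for complete data).
#' @examples
#' d <- load_dataset("guinea_complete")
#' length(d$times)
#' @export
load_dataset <- function(path) {
  if (path %in% names(.fixture_files)) {
    file <- system.file("extdata", .fixture_files[[path]],
                        package = "pffcens", mustWork = TRUE)
    label <- path
    sc <- if (path %in% names(.fixture_schemes)) {
      .fixture_schemes[[path]]()
    } else {
      NULL
    }
  } else {
    file <- path
    label <- basename(path)
    sc <- NULL
    if (!file.exists(file)) stop("file not found: ", file)
  }
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data in ", file)
  # tolerate a single header token that is not numeric
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1]) && length(lines) > 1L) {
    lines <- lines[-1]
    vals <- suppressWarnings(as.numeric(lines))
  }
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad)) {
    stop(sprintf("non-numeric or non-positive entry at data line %d of %s",
                 bad[1], file))
  }
  if (!is.null(sc) && length(vals) != sc$m) {
    stop("fixture length does not match its censoring scheme")
  }
  structure(list(times = vals, label = label, censoring = sc),
            class = "pff_dataset")
}

#' @export
print.pff_dataset <- function(x, ...) {
  cat(sprintf("Dataset '%s': %d times in [%g, %g]%s\n", x$label,
              length(x$times), min(x$times), max(x$times),
              if (is.null(x$censoring)) " (complete)" else " (censored)"))
  invisible(x)
}

#' Convert a censored dataset to a pff_sample
#'
#' @param data a `"pff_dataset"` whose `censoring` field is set.
#' @return A [pff_sample].
#' @export
as_pff_sample <- function(data) {
  stopifnot(inherits(data, "pff_dataset"))
  if (is.null(data$censoring)) {
    stop("dataset carries no censoring scheme; complete data can be ",
         "wrapped via censoring_scheme(1, n, rep(0, n))")
  }
  pff_sample(sort(data$times), data$censoring)
}

#' Random first-failure grouping of complete data
#'
#' Randomly partitions `N` complete lifetimes into `n = N / k` groups of
#' `k` and returns the sorted group minima — the first-failure censored
#' sample a grouped experiment would have produced.  `k = 1` returns the
#' sorted data unchanged; `k = N` returns the global minimum.
#'
#' @param data a `"pff_dataset"` (or bare numeric vector) of complete
#'   lifetimes.
#' @param k group size; must divide the number of observations.
#' @param seed optional integer seed for the random partition.
#' @return A `"pff_dataset"` of the `n` group minima.
#' @export
first_failure_grouping <- function(data, k, seed = NULL) {
  x <- if (inherits(data, "pff_dataset")) data$times else data
  .check_x_positive(x)
  N <- length(x)
  if (N %% k != 0) {
    stop(sprintf("group size k = %d does not divide N = %d", k, N))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  perm <- sample.int(N)
  groups <- matrix(x[perm], nrow = k)
  mins <- sort(apply(groups, 2, min))
  structure(list(times = mins,
                 label = sprintf("first-failure minima (k=%d)", k),
                 censoring = NULL),
            class = "pff_dataset")
}
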