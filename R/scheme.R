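#' Progressive first-failure censoring scheme
#'
#' Describes the experiment: `n` groups of `k` identical units are put on
#' test; at the `i`-th observed first failure the failing group plus `R[i]`
#' further surviving groups are withdrawn; the test stops at the `m`-th
#' failure.  The removal counts must account for every group:
#' `sum(R) == n - m`.
#'
#' Special cases: `k = 1` gives plain progressive Type-II censoring;
#' `R = (0, ..., 0)` gives first-failure censoring; `k = 1` with
#' `R = (0, ..., 0, n - m)` gives conventional Type-II censoring.
#'
#' @param k group size (positive integer).
#' @param n number of groups (positive integer).
#' @param R integer vector of removal counts, of length `m`; alternatively
#'   give `scheme`, a shorthand string (see [parse_scheme]).
#' @param scheme shorthand string such as `"(25, 0*24)"`; ignored when `R`
#'   is supplied.
#' @return An object of class `"pff_scheme"`: a list with elements `k`,
#'   `n`, `m`, `R` and the derived total `N = k * n`.
#' @examples
#' censoring_scheme(k = 2, n = 36, scheme = "(18, 0*17)")
#' @export
censoring_scheme <- function(k, n, R = NULL, scheme = NULL) {
  if (length(k) != 1L || k < 1 || k != round(k)) {
    stop("'k' must be a positive integer")
  }
  if (length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer")
  }
  if (is.null(R)) {
    if (is.null(scheme)) stop("supply 'R' or a 'scheme' shorthand string")
    R <- parse_scheme(scheme)
  }
  if (any(R < 0) || any(R != round(R))) {
    stop("removal counts 'R' must be non-negative integers")
  }
  m <- length(R)
  if (m < 1 || m > n) stop("'m' (= length(R)) must satisfy 1 <= m <= n")
  if (sum(R) != n - m) {
    stop(sprintf("inconsistent scheme: sum(R) = %d but n - m = %d",
                 sum(R), n - m))
  }
  structure(list(k = as.integer(k), n = as.integer(n), m = m,
                 R = as.integer(R), N = as.integer(k) * as.integer(n)),
            class = "pff_scheme")
}

#' @export
print.pff_scheme <- function(x, ...) {
  cat(sprintf(
    "Progressive first-failure censoring: k = %d, n = %d, m = %d (N = %d)\n",
    x$k, x$n, x$m, x$N))
  cat("R =", format_scheme(x$R), "\n")
  invisible(x)
}

#' Parse censoring-scheme shorthand
#'
#' Expands the star shorthand used for removal vectors: `"a*b"` repeats the
#' value `a` `b` times, `"(t1, t2, ...)*b"` repeats a tuple, and
#' comma-separated terms concatenate.  So `"(0*5)"` is `c(0,0,0,0,0)`,
#' `"((1,0)*2)"` is `c(1,0,1,0)` and `"(25, 0*24)"` is `c(25, 0, ..., 0)`.
#' A surrounding pair of parentheses is optional.
#'
#' @param text shorthand string.
#' @param k,n optional; when both are given the expanded vector is
#'   validated by constructing a [censoring_scheme], which is returned
#'   instead of the bare vector.
#' @return An integer vector of removal counts, or a `"pff_scheme"` when
#'   `k` and `n` are supplied.
#' @examples
#' parse_scheme("((1,0)*2)")
#' parse_scheme("(25, 0*24)", k = 1, n = 50)
#' @export
parse_scheme <- function(text, k = NULL, n = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("scheme shorthand must be a non-empty string")
  }
  s <- gsub("\\s", "", text)
  depth <- cumsum((strsplit(s, "")[[1]] == "(") -
                    (strsplit(s, "")[[1]] == ")"))
  if (length(depth) && (depth[length(depth)] != 0L || any(depth < 0L))) {
    stop("unbalanced parentheses in scheme shorthand")
  }
  R <- .parse_terms(s)
  if (!is.null(k) && !is.null(n)) {
    return(censoring_scheme(k = k, n = n, R = R))
  }
  R
}

# Recursive descent over comma-separated terms at the current depth.
# A term is: <int>, <int>*<count>, or (<terms>)[*<count>].
.parse_terms <- function(s) {
  if (grepl("^\\(.*\\)$", s) && .balanced_wrap(s)) {
    s <- substr(s, 2L, nchar(s) - 1L)
  }
  out <- integer(0)
  for (term in .split_top(s)) {
    if (grepl("^\\(", term)) {
      m <- regmatches(term, regexec("^(\\(.*\\))(\\*([0-9]+))?$", term))[[1]]
      if (length(m) == 0L || !.balanced_wrap(m[2])) {
        stop(sprintf("cannot parse scheme term '%s'", term))
      }
      inner <- .parse_terms(m[2])
      reps <- if (nzchar(m[4])) as.integer(m[4]) else 1L
      out <- c(out, rep(inner, reps))
    } else if (grepl("^[0-9]+\\*[0-9]+$", term)) {
      p <- as.integer(strsplit(term, "*", fixed = TRUE)[[1]])
      out <- c(out, rep(p[1], p[2]))
    } else if (grepl("^[0-9]+$", term)) {
      out <- c(out, as.integer(term))
    } else {
      stop(sprintf("cannot parse scheme term '%s'", term))
    }
  }
  if (length(out) == 0L) stop("scheme shorthand expands to an empty vector")
  out
}

# TRUE when the leading "(" matches the final ")".
.balanced_wrap <- function(s) {
  depth <- 0L
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth == 0L && i < length(chars)) return(FALSE)
    if (depth < 0L) stop("unbalanced parentheses in scheme shorthand")
  }
  if (depth != 0L) stop("unbalanced parentheses in scheme shorthand")
  TRUE
}

# Split on commas at parenthesis depth zero.
.split_top <- function(s) {
  depth <- 0L
  cuts <- integer(0)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, nchar(s))
  pieces <- substring(s, starts, ends)
  if (any(!nzchar(pieces))) stop("empty term in scheme shorthand")
  pieces
}

#' Compact shorthand for a removal vector
#'
#' Inverse of [parse_scheme] for run-length patterns: renders `R` using the
#' star notation, e.g. `c(25, 0, 0, ...)` becomes `"(25, 0*24)"`.
#'
#' @param R integer vector of removal counts.
#' @return A single string.
#' @export
format_scheme <- function(R) {
  rle_R <- rle(as.integer(R))
  parts <- ifelse(rle_R$lengths == 1L,
                  as.character(rle_R$values),
                  paste0(rle_R$values, "*", rle_R$lengths))
  paste0("(", paste(parts, collapse = ", "), ")")
}

#' Progressively first-failure censored sample
#'
#' Ties an ordered vector of observed failure times to its censoring
#' scheme.  Times must be positive and non-decreasing with exactly
#' `scheme$m` entries.  Tied times are accepted (real data are rounded).
#'
#' @param times numeric vector of the `m` ordered failure times.
#' @param scheme a [censoring_scheme].
#' @return An object of class `"pff_sample"`.
#' @export
pff_sample <- function(times, scheme) {
  if (!inherits(scheme, "pff_scheme")) stop("'scheme' must be a pff_scheme")
  if (!is.numeric(times) || any(!is.finite(times)) || any(times <= 0)) {
    stop("failure times must be positive and finite")
  }
  if (length(times) != scheme$m) {
    stop(sprintf("expected m = %d times, got %d", scheme$m, length(times)))
  }
  if (is.unsorted(times)) stop("failure times must be non-decreasing")
  structure(list(times = as.numeric(times), scheme = scheme),
            class = "pff_sample")
}

#' @export
print.pff_sample <- function(x, ...) {
  print(x$scheme)
  cat("times:", paste(signif(x$times, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pff_sample <- function(x, ...) {
  data.frame(index = seq_along(x$times), time = x$times)
}

#' Read and write censored samples as CSV
#'
#' The on-disk format is a plain CSV with columns `index,time`, preceded by
#' a comment header line `# pff k=<k> n=<n> m=<m> R=<shorthand>` that
#' encodes the censoring scheme, so a file round-trips to an identical
#' [pff_sample].
#'
#' @param x a `"pff_sample"`.
#' @param path file path.
#' @return `read_pff` returns a `"pff_sample"`; `write_pff` returns `path`
#'   invisibly.
#' @export
write_pff <- function(x, path) {
  stopifnot(inherits(x, "pff_sample"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pff k=%d n=%d m=%d R=%s", x$scheme$k, x$scheme$n,
                     x$scheme$m, gsub(" ", "", format_scheme(x$scheme$R))),
             con)
  writeLines("index,time", con)
  writeLines(sprintf("%d,%.17g", seq_along(x$times), x$times), con)
  invisible(path)
}

#' @rdname write_pff
#' @export
read_pff <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  mt <- regmatches(hdr, regexec(
    "^#\\s*pff\\s+k=([0-9]+)\\s+n=([0-9]+)\\s+m=([0-9]+)\\s+R=(\\S+)", hdr))[[1]]
  if (length(mt) == 0L) stop("not a pff sample file: header line missing")
  sc <- censoring_scheme(k = as.integer(mt[2]), n = as.integer(mt[3]),
                         R = parse_scheme(mt[5]))
  if (sc$m != as.integer(mt[4])) stop("header m does not match R vector")
  df <- read.table(text = lines[-1], header = TRUE, sep = ",")
  pff_sample(df$time, sc)
}
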