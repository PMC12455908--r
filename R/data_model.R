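#' One curve's censored observations
#'
#' Partitions a single subject's longitudinal record into fully observed
#' points `(t_obs, y_obs)` and value-censored points `t_cens` for which only
#' a bounding interval `(lower, upper)` on the latent response is known:
#' right-censoring at limit `L` is `(L, Inf)`, left-censoring is `(-Inf, L)`,
#' interval-censoring is a finite `(lower, upper)`.
#'
#' @param t_obs,y_obs Times and values of fully observed points (equal length).
#' @param t_cens Times of censored points.
#' @param lower,upper Bound vectors, one entry per censored point; `-Inf` /
#'   `Inf` allowed, and `lower < upper` element-wise.
#' @param subject_id Subject label.
#' @return An object of class `censored_series`.
#' @examples
#' censored_series(t_obs = c(0, 2), y_obs = c(0.3, -0.1),
#'                 t_cens = 1, lower = 0.75, upper = Inf)
#' @export
censored_series <- function(t_obs = numeric(), y_obs = numeric(),
                            t_cens = numeric(), lower = numeric(),
                            upper = numeric(), subject_id = "s1") {
  t_obs <- as.numeric(t_obs); y_obs <- as.numeric(y_obs)
  t_cens <- as.numeric(t_cens)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(t_obs) != length(y_obs))
    stop("t_obs and y_obs must have equal length", call. = FALSE)
  if (length(t_cens) != length(lower) || length(t_cens) != length(upper))
    stop("t_cens, lower, upper must have equal length", call. = FALSE)
  if (!all(is.finite(t_obs)) || !all(is.finite(y_obs)) || !all(is.finite(t_cens)))
    stop("times and observed values must be finite", call. = FALSE)
  if (any(is.na(lower)) || any(is.na(upper)) || any(lower >= upper))
    stop("censoring bounds must satisfy lower < upper", call. = FALSE)
  structure(list(t_obs = t_obs, y_obs = y_obs, t_cens = t_cens,
                 lower = lower, upper = upper,
                 subject_id = as.character(subject_id)),
            class = "censored_series")
}

#' @export
print.censored_series <- function(x, ...) {
  cat(sprintf("<censored_series> subject %s: %d observed, %d censored\n",
              x$subject_id, length(x$t_obs), length(x$t_cens)))
  invisible(x)
}

n_obs <- function(cs) length(cs$t_obs)
n_cens <- function(cs) length(cs$t_cens)

#' A collection of censored curves
#'
#' Ordered collection of [censored_series()] for the multi-level model. The
#' subject order is fixed and meaningful: the *last* subject's deviation
#' curve is the one reconstructed from the sum-to-zero constraint.
#'
#' @param series List of `censored_series` objects.
#' @return An object of class `multi_series` with elements `series` and `n`.
#' @export
multi_series <- function(series) {
  if (inherits(series, "censored_series")) series <- list(series)
  if (!is.list(series) || !all(vapply(series, inherits, TRUE, "censored_series")))
    stop("'series' must be a list of censored_series", call. = FALSE)
  structure(list(series = series, n = length(series)), class = "multi_series")
}

#' @export
print.multi_series <- function(x, ...) {
  cat(sprintf("<multi_series> %d curves, %d observed + %d censored points\n",
              x$n, sum(vapply(x$series, n_obs, 1L)),
              sum(vapply(x$series, n_cens, 1L))))
  invisible(x)
}

#' @rdname read_censored_csv
#' @export
as.data.frame.multi_series <- function(x, ...) {
  do.call(rbind, lapply(x$series, function(cs) {
    obs <- if (n_obs(cs) > 0)
      data.frame(subject = cs$subject_id, time = cs$t_obs, value = cs$y_obs,
                 status = "obs", lower = NA_real_, upper = NA_real_)
    cens <- if (n_cens(cs) > 0) {
      status <- ifelse(is.infinite(cs$upper), "right",
                       ifelse(is.infinite(cs$lower), "left", "interval"))
      value <- ifelse(status == "right", cs$lower,
                      ifelse(status == "left", cs$upper, NA_real_))
      data.frame(subject = cs$subject_id, time = cs$t_cens, value = value,
                 status = status,
                 lower = ifelse(status == "interval", cs$lower, NA_real_),
                 upper = ifelse(status == "interval", cs$upper, NA_real_))
    }
    rbind(obs, cens)
  }))
}

#' Read and write censored longitudinal data as CSV
#'
#' The on-disk format is a plain comma-separated file with a header row and
#' columns `subject`, `time`, `value`, `status`, `lower`, `upper`. `status`
#' is one of `obs` (the `value` column holds the observation), `right` /
#' `left` (the `value` column holds the censoring limit), or `interval`
#' (bounds in `lower` / `upper`). Infinite bounds are serialized as empty
#' fields. The reader never re-derives censoring from thresholds: a value
#' exactly at a limit is whatever its `status` says.
#'
#' The latent-function prior is zero-mean, so `center` optionally subtracts
#' a user-supplied constant from all values and finite bounds; it is recorded
#' in the `center` attribute of the result. Default off.
#'
#' @param path File path.
#' @param column_map Optional named character vector remapping the expected
#'   column names, e.g. `c(subject = "id", time = "day")`.
#' @param center Optional constant subtracted from values and finite bounds.
#' @param ms A `multi_series` object.
#' @param x A `multi_series` (for `as.data.frame`).
#' @param ... Unused.
#' @return `read_censored_csv` returns a [multi_series()]; subjects appear
#'   in order of first appearance, rows in file order within subject.
#' @export
read_censored_csv <- function(path, column_map = NULL, center = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  want <- c("subject", "time", "value", "status", "lower", "upper")
  names(df) <- tolower(names(df))
  if (!is.null(column_map))
    for (std in names(column_map)) names(df)[names(df) == tolower(column_map[[std]])] <- std
  for (opt in c("lower", "upper")) if (is.null(df[[opt]])) df[[opt]] <- ""
  miss <- setdiff(c("subject", "time", "value", "status"), names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- df[want]
  num <- function(s, row, what, allow_empty = FALSE) {
    s <- trimws(s)
    if (s == "" || is.na(s)) {
      if (allow_empty) return(NA_real_)
      stop(sprintf("row %d: missing %s", row, what), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop(sprintf("row %d: non-numeric %s '%s'", row, what, s),
                       call. = FALSE)
    v
  }
  subjects <- unique(df$subject)
  series <- lapply(subjects, function(id) {
    rows <- which(df$subject == id)
    to <- yo <- tc <- lo <- up <- numeric()
    for (r in rows) {
      tm <- num(df$time[r], r, "time")
      st <- trimws(df$status[r])
      if (st == "obs") {
        to <- c(to, tm); yo <- c(yo, num(df$value[r], r, "value"))
      } else if (st == "right") {
        tc <- c(tc, tm); lo <- c(lo, num(df$value[r], r, "value")); up <- c(up, Inf)
      } else if (st == "left") {
        tc <- c(tc, tm); lo <- c(lo, -Inf); up <- c(up, num(df$value[r], r, "value"))
      } else if (st == "interval") {
        l <- num(df$lower[r], r, "lower"); u <- num(df$upper[r], r, "upper")
        if (l >= u) stop(sprintf("row %d: interval lower >= upper", r), call. = FALSE)
        tc <- c(tc, tm); lo <- c(lo, l); up <- c(up, u)
      } else stop(sprintf("row %d: unknown status '%s'", r, st), call. = FALSE)
    }
    if (!is.null(center)) {
      yo <- yo - center
      lo <- ifelse(is.finite(lo), lo - center, lo)
      up <- ifelse(is.finite(up), up - center, up)
    }
    censored_series(to, yo, tc, lo, up, subject_id = id)
  })
  out <- multi_series(series)
  attr(out, "center") <- center
  out
}

#' @rdname read_censored_csv
#' @export
write_censored_csv <- function(ms, path) {
  stopifnot(inherits(ms, "multi_series"))
  df <- as.data.frame(ms)
  fmt <- function(v) ifelse(is.na(v) | is.infinite(v), "",
                            formatC(v, digits = 17, format = "g"))
  out <- data.frame(subject = df$subject, time = fmt(df$time),
                    value = fmt(df$value), status = df$status,
                    lower = fmt(df$lower), upper = fmt(df$upper))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
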