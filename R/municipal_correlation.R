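# Weekly municipal casualty series, their Pearson correlations, and
# permutation-null Z-scores.

#' Monday on-or-before a date
#'
#' All weekly binning in the package is anchored to the Monday on-or-before
#' the study window start (ISO weeks).
#'
#' @param date a `Date`.
#' @return the anchoring Monday as `Date`.
#' @export
week_anchor <- function(date) {
  date <- as.Date(date)
  # weekdays: Monday == 0 under this offset (1970-01-05 was a Monday)
  off <- as.integer(date - as.Date("1970-01-05")) %% 7L
  date - off
}

#' Week index of dates relative to an anchor Monday (0-based).
#' @param date Date vector.
#' @param anchor anchor Monday.
#' @return integer vector of 0-based week indices.
#' @export
week_index <- function(date, anchor) {
  as.integer(floor(as.numeric(as.Date(date) - as.Date(anchor)) / 7))
}

#' Aggregate mapped events into a weekly municipal count matrix
#'
#' Bins are consecutive 7-day intervals anchored at the Monday on-or-before
#' the window start. Each event adds its casualty count (default) or one
#' event (`measure = "events"`) to its municipality's bin. Municipalities
#' listed in `municipalities` but absent from the events get all-zero
#' vectors.
#'
#' @param events mapped event data.frame (needs `municipality`).
#' @param window length-2 `Date` vector (start, end), inclusive. Defaults to
#'   the event date range.
#' @param municipalities optional character vector fixing the municipality
#'   set (and its order).
#' @param measure `"casualties"` (default) or `"events"`.
#' @return `weekly_counts` object: a weeks x municipalities numeric matrix
#'   with attributes `week_start` (Date vector of bin Mondays) and `anchor`.
#' @export
weekly_aggregate <- function(events, window = NULL, municipalities = NULL,
                             measure = c("casualties", "events")) {
  measure <- match.arg(measure)
  if (is.null(events$municipality)) stop("events must be mapped (no 'municipality' column)")
  if (is.null(window)) {
    if (nrow(events) == 0) stop("cannot infer a window from an empty event table")
    window <- range(events$date)
  }
  window <- as.Date(window)
  if (window[2] < window[1]) stop("empty study window")
  anchor <- week_anchor(window[1])
  n_weeks <- week_index(window[2], anchor) + 1L

  keep <- events$date >= window[1] & events$date <= window[2]
  ev <- events[keep, , drop = FALSE]
  if (is.null(municipalities)) municipalities <- sort(unique(ev$municipality))

  m <- matrix(0, nrow = n_weeks, ncol = length(municipalities),
              dimnames = list(NULL, municipalities))
  if (nrow(ev) > 0) {
    wk <- week_index(ev$date, anchor) + 1L
    val <- if (measure == "casualties") ev$casualties else rep(1, nrow(ev))
    known <- ev$municipality %in% municipalities
    tab <- tapply(val[known], list(wk[known], ev$municipality[known]), sum)
    m[as.integer(rownames(tab)), colnames(tab)] <-
      ifelse(is.na(tab), 0, tab)
  }
  structure(
    m,
    week_start = anchor + 7 * (seq_len(n_weeks) - 1L),
    anchor = anchor,
    class = c("weekly_counts", "matrix", "array")
  )
}

#' Scale a weekly count matrix to rates per 100,000 inhabitants
#'
#' @param wc a `weekly_counts` matrix.
#' @param pops municipality/population data.frame.
#' @return `weekly_counts` matrix of rates (counts * 1e5 / P_m).
#' @export
rate_per_100k <- function(wc, pops) {
  idx <- match(colnames(wc), pops$municipality)
  if (anyNA(idx)) {
    stop("no population for municipality: ",
         paste(colnames(wc)[is.na(idx)], collapse = ", "))
  }
  out <- sweep(wc, 2, 1e5 / pops$population[idx], `*`)
  attributes(out)[c("week_start", "anchor", "class")] <-
    attributes(wc)[c("week_start", "anchor", "class")]
  out
}

#' Pairwise Pearson correlations of weekly municipal series
#'
#' One row per unordered municipality pair. Pairs involving a zero-variance
#' series are reported with `pcc = NA` (undefined, not zero).
#'
#' @param wc a `weekly_counts` matrix (>= 2 weeks, >= 2 municipalities).
#' @return data.frame (`municipality_1`, `municipality_2`, `pcc`) with the
#'   full correlation matrix in attribute `"matrix"`.
#' @export
pcc_matrix <- function(wc) {
  if (nrow(wc) < 2) stop("need at least 2 weeks")
  if (ncol(wc) < 2) stop("need at least 2 municipalities")
  sds <- apply(wc, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(unclass(wc)))
  cm[sds == 0, ] <- NA
  cm[, sds == 0] <- NA
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(
    municipality_1 = colnames(wc)[pairs[, 1]],
    municipality_2 = colnames(wc)[pairs[, 2]],
    pcc = cm[pairs],
    stringsAsFactors = FALSE
  )
  attr(out, "matrix") <- cm
  out
}

#' Permutation-null Z-scores for municipal correlations
#'
#' For each of `n_iter` iterations, every municipality's weekly vector is
#' independently reshuffled across weeks and the pairwise Pearson
#' correlations are recomputed, giving a per-pair null distribution. Each
#' observed PCC is then scored as `Z = (pcc - null mean) / null sd`, and
#' pairs with `Z > 3` are flagged significant.
#'
#' Note the null destroys both cross- and auto-correlation; with strongly
#' autocorrelated series its Z-scores are anti-conservative (see the package
#' vignette).
#'
#' @param wc a `weekly_counts` matrix.
#' @param n_iter number of reshuffling iterations (default 1000).
#' @param seed integer seed making the null reproducible.
#' @return data.frame (`municipality_1`, `municipality_2`, `pcc`,
#'   `null_mean`, `null_sd`, `z`, `significant`) sorted by `z` descending;
#'   pairs with undefined PCC or zero null spread have `z = NA`.
#' @export
null_zscores <- function(wc, n_iter = 1000, seed = 1) {
  if (n_iter < 2) stop("n_iter must be >= 2")
  obs <- pcc_matrix(wc)
  x <- unclass(wc)
  n_pair <- nrow(obs)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  pairs <- which(upper.tri(matrix(0, ncol(x), ncol(x))), arr.ind = TRUE)
  s <- numeric(n_pair)   # running sums of null correlations
  s2 <- numeric(n_pair)
  for (it in seq_len(n_iter)) {
    perm <- apply(x, 2, sample)
    cm <- suppressWarnings(stats::cor(perm))
    v <- cm[pairs]
    s <- s + v
    s2 <- s2 + v * v
  }
  null_mean <- s / n_iter
  null_sd <- sqrt(pmax(0, s2 / n_iter - null_mean^2) * n_iter / (n_iter - 1))

  out <- obs
  out$null_mean <- null_mean
  out$null_sd <- null_sd
  out$z <- ifelse(is.na(out$pcc) | null_sd == 0, NA_real_,
                  (out$pcc - null_mean) / null_sd)
  out$significant <- !is.na(out$z) & out$z > 3
  attr(out, "matrix") <- attr(obs, "matrix")
  out[order(-out$z, na.last = TRUE), , drop = FALSE]
}

#' Write a correlation table as CSV (Z-descending) plus a square matrix CSV
#'
#' @param ct output of [null_zscores()] (or [pcc_matrix()]).
#' @param path CSV path for the pair table.
#' @param matrix_path optional CSV path for the heatmap-ready square PCC
#'   matrix.
#' @export
write_correlation_csv <- function(ct, path, matrix_path = NULL) {
  df <- as.data.frame(ct)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(matrix_path)) {
    utils::write.csv(attr(ct, "matrix"), matrix_path, row.names = TRUE)
  }
  invisible(path)
}
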