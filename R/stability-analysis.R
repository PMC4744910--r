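#' Pair samples taken 24 h apart
#'
#' Finds every pair of samples with the same clock time and an absolute-hour
#' difference of exactly 24 h (tolerance 1e-6). For the standard 25-sample,
#' 2-hourly two-day design this yields 13 pairs (sample i with sample
#' i + 12); the start clock time, sampled three times, contributes two
#' pairs.
#'
#' @param schedule sampling schedule spanning at least 24 h.
#' @param tol tolerance on the 24-h gap, in hours.
#' @return data.frame with columns \code{clock_hour}, \code{sample_i},
#'   \code{sample_j} (day-1 and day-2 member of each pair).
#' @export
pair_days <- function(schedule, tol = 1e-6) {
  if (diff(range(schedule$abs_hour)) < 24)
    stop("schedule must span at least 24 h to pair days")
  gap <- outer(schedule$abs_hour, schedule$abs_hour, "-")
  hit <- which(abs(gap + 24) < tol, arr.ind = TRUE)  # j = i + 24 h
  if (nrow(hit) == 0) stop("no 24-h-apart sample pairs in schedule")
  pairs <- data.frame(clock_hour = schedule$clock_hour[hit[, 1]],
                      sample_i = schedule$sample_id[hit[, 1]],
                      sample_j = schedule$sample_id[hit[, 2]],
                      stringsAsFactors = FALSE)
  pairs[order(schedule$abs_hour[hit[, 1]]), , drop = FALSE] -> pairs
  rownames(pairs) <- NULL
  pairs
}

#' Day-to-day determination coefficient
#'
#' Squared Pearson correlation, across timetable genes, between the
#' normalized expression vectors of two samples taken at the same clock
#' time on consecutive days. High values at every clock hour indicate that
#' the time-indicating rhythms are stable from day to day.
#'
#' @param z normalized matrix (timetable genes only).
#' @param sample_i,sample_j the paired sample ids.
#' @return R-squared, or \code{NA} when either vector has zero variance.
#' @export
day_pair_r2 <- function(z, sample_i, sample_j) {
  for (s in c(sample_i, sample_j))
    if (!s %in% colnames(z)) stop("unknown sample: ", s)
  if (nrow(z) < 3) stop("need at least 3 genes")
  a <- z[, sample_i]
  b <- z[, sample_j]
  if (pop_sd(a) == 0 || pop_sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Day-to-day stability across the whole course
#'
#' Applies \code{\link{day_pair_r2}} to every 24-h-apart sample pair.
#'
#' @param z normalized matrix.
#' @param schedule the sampling schedule.
#' @return the \code{\link{pair_days}} table with an \code{r_squared}
#'   column appended.
#' @export
stability_table <- function(z, schedule) {
  pairs <- pair_days(schedule)
  pairs$r_squared <- vapply(seq_len(nrow(pairs)), function(k) {
    day_pair_r2(z, pairs$sample_i[k], pairs$sample_j[k])
  }, numeric(1))
  pairs
}

#' Export a peak-ordered heatmap matrix
#'
#' Writes the normalized expression rows in ascending molecular peak time
#' order as TSV; on rhythmic data the result shows the diagonal striped
#' pattern of phase-ordered oscillation.
#'
#' @param z normalized matrix.
#' @param results periodicity table covering the rows of \code{z}.
#' @param path output path.
#' @return the reordered matrix, invisibly.
#' @export
write_heatmap_matrix <- function(z, results, path) {
  ord <- peak_sorted_order(results, rownames(z))
  zo <- z[ord, , drop = FALSE]
  write_expression_table(expression_matrix(zo, units = "normalized"), path)
  invisible(zo)
}
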