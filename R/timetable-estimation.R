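#' Build a molecular timetable
#'
#' A molecular timetable is the ordered catalogue of time-indicating genes:
#' for each gene its molecular peak time and the mean and population SD of
#' its expression across the training samples. The stored constants let a
#' later single-snapshot sample be normalized and placed on the 24-h dial
#' without re-running the time course.
#'
#' @param m expression matrix the genes were trained on.
#' @param results periodicity table from \code{\link{analyze_matrix}}.
#' @param gene_ids time-indicating genes (e.g. from
#'   \code{\link{select_time_indicating}}); all must be valid with
#'   positive SD.
#' @return data.frame of class \code{molecular_timetable} with columns
#'   \code{gene_id}, \code{peak_time_h}, \code{mean}, \code{sd}, sorted by
#'   ascending peak time (ties by gene id).
#' @export
build_timetable <- function(m, results, gene_ids) {
  idx <- match(gene_ids, results$gene_id)
  if (anyNA(idx)) stop("genes missing from results: ",
                       paste(gene_ids[is.na(idx)], collapse = ", "))
  if (any(!results$valid[idx]))
    stop("invalid (flat or nonpositive-mean) gene requested: ",
         paste(gene_ids[!results$valid[idx]], collapse = ", "))
  midx <- match(gene_ids, rownames(m))
  if (anyNA(midx)) stop("genes missing from matrix: ",
                        paste(gene_ids[is.na(midx)], collapse = ", "))
  sub <- m[midx, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- sqrt(rowMeans((sub - mu)^2))
  if (any(sdv <= 0))
    stop("zero expression SD for gene: ",
         paste(gene_ids[sdv <= 0], collapse = ", "))
  tt <- data.frame(gene_id = gene_ids, peak_time_h = results$peak_time_h[idx],
                   mean = mu, sd = sdv, stringsAsFactors = FALSE)
  tt <- tt[order(tt$peak_time_h, tt$gene_id), ]
  rownames(tt) <- NULL
  class(tt) <- c("molecular_timetable", "data.frame")
  tt
}

#' Read / write a molecular timetable
#'
#' TSV with columns \code{gene_id}, \code{peak_time_h}, \code{mean},
#' \code{sd}.
#'
#' @param path file path.
#' @return \code{read_timetable}: a \code{molecular_timetable} data.frame.
#' @export
read_timetable <- function(path) {
  tt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "peak_time_h", "mean", "sd")
  if (!all(need %in% names(tt)))
    stop("timetable file must have columns: ", paste(need, collapse = ", "))
  if (any(tt$sd <= 0)) stop("timetable SDs must be positive")
  class(tt) <- c("molecular_timetable", "data.frame")
  tt
}

#' @rdname read_timetable
#' @param timetable a \code{molecular_timetable}.
#' @export
write_timetable <- function(timetable, path) {
  utils::write.table(timetable, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score expression against timetable constants
#'
#' For each timetable gene, normalized expression is the raw level minus the
#' stored mean, divided by the stored SD. Rows are restricted to the
#' timetable genes, in timetable (peak time) order.
#'
#' @param m expression matrix containing at least the timetable genes.
#' @param timetable a \code{\link{build_timetable}} result.
#' @return expression matrix with units \code{"normalized"}.
#' @export
normalize_expression <- function(m, timetable) {
  idx <- match(timetable$gene_id, rownames(m))
  if (anyNA(idx)) stop("genes missing from matrix: ",
                       paste(timetable$gene_id[is.na(idx)], collapse = ", "))
  z <- (m[idx, , drop = FALSE] - timetable$mean) / timetable$sd
  rownames(z) <- timetable$gene_id
  expression_matrix(z, units = "normalized")
}

#' Expression profile of one sample
#'
#' The expression profile plots, for a single sample, the normalized level
#' of every time-indicating gene against that gene's molecular peak time.
#' For a sample taken at internal time T the profile traces
#' \code{cos(2*pi*(phi - T)/24)}, so its crest marks the sample's position
#' on the clock.
#'
#' @param z normalized matrix from \code{\link{normalize_expression}}.
#' @param timetable the matching timetable.
#' @param sample_id which sample to profile.
#' @return data.frame of class \code{expression_profile} with columns
#'   \code{gene_id}, \code{peak_time_h}, \code{z}; the sample id is kept as
#'   an attribute.
#' @export
build_profile <- function(z, timetable, sample_id) {
  if (!sample_id %in% colnames(z)) stop("unknown sample: ", sample_id)
  idx <- match(timetable$gene_id, rownames(z))
  if (anyNA(idx)) stop("timetable genes missing from normalized matrix")
  prof <- data.frame(gene_id = timetable$gene_id,
                     peak_time_h = timetable$peak_time_h,
                     z = z[idx, sample_id], stringsAsFactors = FALSE)
  rownames(prof) <- NULL
  attr(prof, "sample_id") <- sample_id
  class(prof) <- c("expression_profile", "data.frame")
  prof
}

#' Estimate internal time from an expression profile
#'
#' Fits every cosine template in the bank to the profile (normalized level
#' z against molecular peak time phi, template
#' \code{cos(2*pi*(phi - p)/24)}), scoring by Pearson correlation; the peak
#' phase of the best-fitting template is the estimated internal time T.
#' Amplitude and offset are then fit by least squares at that phase, and the
#' measurement noise is 100 times the population SD of the residuals — on
#' z-scored data the unit-amplitude cosine is the 100% reference.
#'
#' @param profile an \code{\link{build_profile}} result with at least 3
#'   distinct peak times and non-constant z.
#' @param bank template bank.
#' @return list of class \code{internal_time_estimate}: \code{sample_id},
#'   \code{internal_time_h}, \code{fit_correlation}, \code{fitted_offset}
#'   (b0), \code{fitted_amplitude} (b1), \code{measurement_noise_pct}.
#' @export
estimate_internal_time <- function(profile, bank = make_template_bank()) {
  phi <- profile$peak_time_h
  zv <- profile$z
  if (length(unique(phi)) < 3)
    stop("internal-time estimation needs >= 3 distinct peak times")
  if (pop_sd(zv) == 0)
    stop("degenerate profile: all normalized levels equal")
  tm <- template_values(bank, phi)
  r <- as.vector(suppressWarnings(stats::cor(zv, tm)))
  r[!is.finite(r)] <- -Inf
  best <- which.max(r)
  if (!is.finite(r[best])) stop("degenerate profile: no template correlates")
  tt <- bank$peak_phases_h[best]
  x <- tm[, best]
  b1 <- stats::cov(zv, x) / stats::var(x)
  b0 <- mean(zv) - b1 * mean(x)
  resid <- zv - (b0 + b1 * x)
  structure(list(sample_id = attr(profile, "sample_id"),
                 internal_time_h = tt, fit_correlation = r[best],
                 fitted_offset = b0, fitted_amplitude = b1,
                 measurement_noise_pct = 100 * pop_sd(resid)),
            class = "internal_time_estimate")
}

#' @export
print.internal_time_estimate <- function(x, ...) {
  cat(sprintf("sample %s: internal time %.2f h (r = %.3f, noise %.1f%%)\n",
              x$sample_id %||% "?", x$internal_time_h, x$fit_correlation,
              x$measurement_noise_pct))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measurement noise of a fitted profile
#'
#' The SD of the differences between observed and cosine-estimated
#' normalized expression across time-indicating genes, as a percentage of
#' unit amplitude. Recomputed from the profile and the estimate's fitted
#' phase/amplitude/offset.
#'
#' @param profile the profile the estimate was fit to.
#' @param estimate an \code{\link{estimate_internal_time}} result.
#' @param period_h oscillation period in hours.
#' @return noise percentage (nonnegative scalar).
#' @export
measurement_noise <- function(profile, estimate, period_h = 24) {
  omega <- 2 * pi / period_h
  fitted <- estimate$fitted_offset + estimate$fitted_amplitude *
    cos(omega * (profile$peak_time_h - estimate$internal_time_h))
  100 * pop_sd(profile$z - fitted)
}

#' Internal-time estimates for every sample of a course
#'
#' Convenience wrapper: builds each sample's profile and estimates its
#' internal time.
#'
#' @param z normalized matrix.
#' @param timetable the matching timetable.
#' @param bank template bank.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{internal_time_h}, \code{fit_correlation}, \code{fitted_offset},
#'   \code{fitted_amplitude}, \code{measurement_noise_pct}.
#' @export
estimate_internal_times <- function(z, timetable, bank = make_template_bank()) {
  rows <- lapply(colnames(z), function(sid) {
    est <- estimate_internal_time(build_profile(z, timetable, sid), bank)
    data.frame(sample_id = sid, internal_time_h = est$internal_time_h,
               fit_correlation = est$fit_correlation,
               fitted_offset = est$fitted_offset,
               fitted_amplitude = est$fitted_amplitude,
               measurement_noise_pct = est$measurement_noise_pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Internal minus external time
#'
#' Signed circular difference between estimated internal time and the
#' schedule's clock time, mapped into (-12, 12]: a sample whose clock reads
#' 23:00 but whose transcriptome says 1:00 is +2 h, not -22 h.
#'
#' @param estimates data.frame from \code{\link{estimate_internal_times}}
#'   (or any with \code{sample_id} and \code{internal_time_h}).
#' @param schedule the sampling schedule.
#' @return data.frame with \code{sample_id}, \code{clock_hour},
#'   \code{internal_time_h}, \code{diff_h}.
#' @export
internal_external_difference <- function(estimates, schedule) {
  idx <- match(schedule$sample_id, estimates$sample_id)
  if (anyNA(idx)) stop("estimates missing for sample: ",
                       paste(schedule$sample_id[is.na(idx)], collapse = ", "))
  est <- estimates$internal_time_h[idx]
  data.frame(sample_id = schedule$sample_id, clock_hour = schedule$clock_hour,
             internal_time_h = est,
             diff_h = circular_diff(est, schedule$clock_hour),
             stringsAsFactors = FALSE)
}
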