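#' Bank of phase-shifted cosine templates
#'
#' The periodicity score of a gene is its best Pearson correlation against a
#' dense bank of cosine curves that differ only in peak phase. With the
#' defaults (24-h period, 1-min spacing) the bank holds 1440 templates; the
#' template with peak phase p evaluates at time t as
#' \code{cos(2*pi*(t - p)/period_h)}.
#'
#' @param period_h oscillation period in hours (default 24).
#' @param step_min phase spacing in minutes (default 1). \code{period_h * 60}
#'   must be divisible by \code{step_min}.
#' @return an object of class \code{template_bank} with fields
#'   \code{period_h}, \code{step_min}, \code{peak_phases_h}.
#' @export
make_template_bank <- function(period_h = 24, step_min = 1) {
  if (period_h <= 0 || step_min <= 0) stop("period_h and step_min must be positive")
  n <- period_h * 60 / step_min
  if (abs(n - round(n)) > 1e-9)
    stop("period_h * 60 must be divisible by step_min")
  n <- round(n)
  structure(list(period_h = period_h, step_min = step_min,
                 peak_phases_h = seq(0, by = step_min / 60, length.out = n)),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("template bank: %d cosine templates, period %g h, step %g min\n",
              length(x$peak_phases_h), x$period_h, x$step_min))
  invisible(x)
}

# Template values at the given times: a length(times) x n_phases matrix.
template_values <- function(bank, times) {
  omega <- 2 * pi / bank$period_h
  outer(omega * times, omega * bank$peak_phases_h, function(t, p) cos(t - p))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Signed circular difference a - b mapped into (-half, half].
circular_diff <- function(a, b, period = 24) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Relative oscillation amplitude
#'
#' The amplitude value a of a series is its population standard deviation
#' divided by its mean; for an ideal cosine \code{m*(1 + rho*cos)} sampled
#' uniformly over full periods, a equals \code{rho/sqrt(2)}.
#'
#' @param series numeric vector of expression values with positive mean.
#' @return a, or \code{NA} if the mean is not positive.
#' @export
amplitude_value <- function(series) {
  mu <- mean(series)
  if (!is.finite(mu) || mu <= 0) return(NA_real_)
  pop_sd(series) / mu
}

#' Molecular peak time of a single series
#'
#' Scores the series against every template in the bank, evaluated at the
#' schedule's clock hours, and reports the peak phase of the best-fitting
#' template (the molecular peak time) together with the Pearson correlation
#' r achieved there. Ties are broken toward the smallest phase. A
#' zero-variance series yields an invalid result rather than an error.
#'
#' @param series numeric vector, one value per schedule sample.
#' @param schedule schedule data.frame (see \code{\link{sample_schedule}}).
#' @param bank a \code{\link{make_template_bank}} object.
#' @return list with \code{peak_time_h}, \code{correlation}, \code{valid}.
#' @export
fit_molecular_peak_time <- function(series, schedule, bank) {
  if (length(series) != nrow(schedule))
    stop("series length must equal schedule length")
  if (length(series) < 3) stop("need at least 3 samples")
  if (pop_sd(series) == 0)
    return(list(peak_time_h = NA_real_, correlation = NA_real_, valid = FALSE))
  tm <- template_values(bank, schedule$clock_hour)
  r <- as.vector(suppressWarnings(stats::cor(series, tm)))
  r[!is.finite(r)] <- -Inf
  best <- which.max(r)
  list(peak_time_h = bank$peak_phases_h[best], correlation = r[best],
       valid = TRUE)
}

#' Continuous-phase harmonic regression
#'
#' Closed-form counterpart of the grid search: least-squares fit of
#' \code{series ~ c + alpha*cos(wt) + beta*sin(wt)} with
#' \code{w = 2*pi/period_h}. The fitted peak time is
#' \code{atan2(beta, alpha)/w mod period_h} and the reported correlation is
#' the Pearson correlation of the series with the fitted harmonic, which is
#' the supremum of the grid-search correlation over a continuous phase.
#' Used as an independent validation oracle for the template fit.
#'
#' @inheritParams fit_molecular_peak_time
#' @param period_h oscillation period in hours.
#' @return list with \code{peak_time_h}, \code{correlation}, \code{valid}.
#' @export
harmonic_regression_phase <- function(series, schedule, period_h = 24) {
  if (length(series) != nrow(schedule))
    stop("series length must equal schedule length")
  if (pop_sd(series) == 0)
    return(list(peak_time_h = NA_real_, correlation = NA_real_, valid = FALSE))
  omega <- 2 * pi / period_h
  co <- cos(omega * schedule$clock_hour)
  si <- sin(omega * schedule$clock_hour)
  fit <- stats::lm(series ~ co + si)
  alpha <- stats::coef(fit)[["co"]]
  beta <- stats::coef(fit)[["si"]]
  if (!is.finite(alpha) || !is.finite(beta) || (alpha == 0 && beta == 0))
    return(list(peak_time_h = NA_real_, correlation = NA_real_, valid = FALSE))
  peak <- (atan2(beta, alpha) / omega) %% period_h
  list(peak_time_h = peak,
       correlation = stats::cor(series, stats::fitted(fit)), valid = TRUE)
}

#' Periodicity analysis of a whole matrix
#'
#' Computes, for every gene, the molecular peak time, the best template
#' correlation r and the amplitude value a. Genes with zero variance or
#' nonpositive mean are flagged invalid (\code{valid == FALSE}, statistics
#' \code{NA}) instead of aborting the run.
#'
#' @param m expression matrix.
#' @param schedule paired schedule; \code{ncol(m)} must match.
#' @param bank template bank.
#' @return data.frame with columns \code{gene_id}, \code{peak_time_h},
#'   \code{r}, \code{a}, \code{valid}, one row per gene in input order.
#' @export
analyze_matrix <- function(m, schedule, bank = make_template_bank()) {
  if (ncol(m) != nrow(schedule))
    stop("matrix has ", ncol(m), " samples but schedule has ", nrow(schedule))
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))
  valid <- sdv > 0 & mu > 0
  res <- data.frame(gene_id = rownames(m), peak_time_h = NA_real_,
                    r = NA_real_, a = NA_real_, valid = valid,
                    stringsAsFactors = FALSE)
  if (any(valid)) {
    tm <- template_values(bank, schedule$clock_hour)
    rmat <- suppressWarnings(stats::cor(t(m[valid, , drop = FALSE]), tm))
    rmat[!is.finite(rmat)] <- -Inf
    best <- max.col(rmat, ties.method = "first")
    res$peak_time_h[valid] <- bank$peak_phases_h[best]
    res$r[valid] <- rmat[cbind(seq_len(nrow(rmat)), best)]
    res$a[valid] <- (sdv / mu)[valid]
  }
  rownames(res) <- NULL
  res
}

#' Cutoff presets for time-indicating gene selection
#'
#' Named (r, a) cutoff pairs: \code{"whole_genes"} (r = 0.915, a = 0.15,
#' the strict selection used for internal-time estimation),
#' \code{"heatmap"} (r = 0.80, a = 0.15, the looser set used for
#' peak-sorted heatmaps), and \code{"stress"} (r = 0.635, a = 0.15, for
#' weakly rhythmic stress-responsive genes).
#'
#' @param name preset name.
#' @return list with elements \code{r_cut} and \code{a_cut}.
#' @export
cutoff_preset <- function(name = c("whole_genes", "heatmap", "stress")) {
  name <- match.arg(name)
  switch(name,
         whole_genes = list(r_cut = 0.915, a_cut = 0.15),
         heatmap = list(r_cut = 0.80, a_cut = 0.15),
         stress = list(r_cut = 0.635, a_cut = 0.15))
}

#' Select time-indicating genes
#'
#' A gene qualifies when it is valid and both its template correlation and
#' its amplitude value meet the cutoffs. Raising either cutoff can only
#' shrink the selection.
#'
#' @param results periodicity table from \code{\link{analyze_matrix}}.
#' @param r_cut,a_cut lower bounds on r and a (inclusive); see
#'   \code{\link{cutoff_preset}} for the standard pairs.
#' @return character vector of gene ids in input order.
#' @export
select_time_indicating <- function(results, r_cut = 0.915, a_cut = 0.15) {
  keep <- results$valid & !is.na(results$r) & !is.na(results$a) &
    results$r >= r_cut & results$a >= a_cut
  results$gene_id[keep]
}

#' Day/night classification of peak times
#'
#' Classifies peak phases on the 24-h dial into day and night using a
#' half-open day window: day iff \code{peak in [day_start, day_end)}.
#' The default window 7:00-17:00 gives a 10-h day and a 14-h night,
#' matching a winter short-day photoperiod.
#'
#' @param peak_time_h numeric vector of peak phases in [0, 24).
#' @param day_start,day_end day window bounds on the 24-h dial; a window
#'   wrapping midnight (\code{day_start > day_end}) is handled.
#' @return character vector, \code{"day"} or \code{"night"} (\code{NA} for
#'   missing peaks).
#' @export
classify_day_night <- function(peak_time_h, day_start = 7, day_end = 17) {
  p <- peak_time_h %% 24
  inside <- if (day_start <= day_end) {
    p >= day_start & p < day_end
  } else {
    p >= day_start | p < day_end
  }
  out <- ifelse(inside, "day", "night")
  out[is.na(peak_time_h)] <- NA_character_
  out
}

#' Peak-sorted gene ordering
#'
#' Orders genes by ascending molecular peak time (ties by gene id) so that
#' exporting their normalized expression rows in this order produces the
#' diagonal-stripe heatmap structure characteristic of rhythmic data.
#'
#' @param results periodicity table from \code{\link{analyze_matrix}}.
#' @param gene_ids genes to order (default: all valid genes in
#'   \code{results}).
#' @return gene ids sorted by peak time.
#' @export
peak_sorted_order <- function(results, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- results$gene_id[results$valid]
  idx <- match(gene_ids, results$gene_id)
  if (anyNA(idx)) stop("gene ids missing from results: ",
                       paste(gene_ids[is.na(idx)], collapse = ", "))
  sub <- results[idx, ]
  sub$gene_id[order(sub$peak_time_h, sub$gene_id)]
}

#' Write a periodicity table
#'
#' TSV export with columns \code{gene_id}, \code{peak_time_h}, \code{r},
#' \code{a}, \code{valid}, \code{day_night}.
#'
#' @param results periodicity table.
#' @param path output path.
#' @param day_start,day_end day window for \code{\link{classify_day_night}}.
#' @return \code{path}, invisibly.
#' @export
write_periodicity_table <- function(results, path, day_start = 7, day_end = 17) {
  results$day_night <- classify_day_night(results$peak_time_h, day_start, day_end)
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
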