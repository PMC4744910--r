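#' Configuration for the synthetic diel time-course generator
#'
#' Defaults emulate the standard field design this package targets: leaves
#' sampled every 2 h for 2 days starting at 14:00 (25 samples), a 24-h
#' period, and a transcriptome mixing clearly rhythmic genes, arrhythmic
#' genes, and weakly rhythmic "stress-like" genes.
#'
#' @param n_rhythmic,n_arrhythmic,n_stresslike gene counts per class.
#' @param days,interval_h,start_clock sampling design (see
#'   \code{\link{make_schedule}}); \code{interval_h} must divide 24 so that
#'   days pair cleanly.
#' @param period_h oscillation period in hours.
#' @param baseline_range range for per-gene baseline expression m (RPKM
#'   scale); baselines are drawn log-uniformly.
#' @param rel_amplitude_range range in (0, 1] for the relative oscillation
#'   amplitude rho; stress-like genes draw from its lower third.
#' @param noise_rel additive noise SD as a fraction of each rhythmic gene's
#'   oscillation SD (\code{m * rho / sqrt(2)}); arrhythmic genes get noise
#'   SD \code{noise_rel * m * 0.1}, stress-like genes double the rhythmic
#'   noise.
#' @param phase_shift_h global internal-minus-external phase shift Delta in
#'   hours: every rhythmic gene's observed peak is delayed by Delta
#'   relative to its internal phase.
#' @param day2_damping amplitude multiplier applied on the second day to a
#'   fraction \code{day2_frac} of rhythmic/stress-like genes, emulating a
#'   dull (e.g. rainy) second day; 1 = off.
#' @param day2_frac fraction of genes subject to \code{day2_damping}.
#' @param seed RNG seed; the same config always generates the same data.
#' @return a validated config list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_rhythmic = 500, n_arrhythmic = 400,
                             n_stresslike = 100, days = 2, interval_h = 2,
                             start_clock = 14, period_h = 24,
                             baseline_range = c(5, 500),
                             rel_amplitude_range = c(0.2, 0.9),
                             noise_rel = 0.2, phase_shift_h = 0,
                             day2_damping = 1, day2_frac = 0,
                             seed = 1L) {
  cfg <- list(n_rhythmic = n_rhythmic, n_arrhythmic = n_arrhythmic,
              n_stresslike = n_stresslike, days = days,
              interval_h = interval_h, start_clock = start_clock,
              period_h = period_h, baseline_range = baseline_range,
              rel_amplitude_range = rel_amplitude_range,
              noise_rel = noise_rel, phase_shift_h = phase_shift_h,
              day2_damping = day2_damping, day2_frac = day2_frac,
              seed = as.integer(seed))
  if (any(c(n_rhythmic, n_arrhythmic, n_stresslike) < 0))
    stop("gene counts must be nonnegative")
  if (n_rhythmic + n_arrhythmic + n_stresslike == 0)
    stop("config generates no genes")
  if (abs(24 / interval_h - round(24 / interval_h)) > 1e-9)
    stop("interval_h must divide 24")
  if (period_h <= 0 || days <= 0) stop("days and period_h must be positive")
  if (baseline_range[1] <= 0 || diff(baseline_range) < 0)
    stop("baseline_range must be a positive increasing interval")
  if (rel_amplitude_range[1] <= 0 || rel_amplitude_range[2] > 1 ||
      diff(rel_amplitude_range) < 0)
    stop("rel_amplitude_range must lie in (0, 1]")
  if (noise_rel < 0) stop("noise_rel must be nonnegative")
  if (day2_frac < 0 || day2_frac > 1) stop("day2_frac must lie in [0, 1]")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic diel expression time course
#'
#' Each rhythmic gene g follows
#' \code{x = max(0, m_g * (1 + rho_g * cos(2*pi*(t - Delta - phi_g)/period)) + eps)}
#' at the schedule's clock-continuous times t, with additive Gaussian noise
#' \code{eps ~ N(0, (noise_rel * m_g * rho_g / sqrt(2))^2)} — i.e. noise SD
#' is \code{noise_rel} times the oscillation SD. Peak phases phi are drawn
#' from the 1-min phase grid so that noiseless courses are recovered
#' exactly by the template fit. Arrhythmic genes are flat baselines plus
#' mild noise; stress-like genes oscillate weakly (lower third of the
#' amplitude range) with doubled noise. Truncation at zero is rare (< 1%)
#' at the default parameters.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{matrix} (RPKM-scale expression matrix),
#'   \code{schedule}, and \code{truth} — a data.frame per gene with
#'   \code{gene_id}, \code{class}, \code{true_peak_h} (internal phase phi,
#'   \code{NA} for arrhythmic), \code{observed_peak_h}
#'   (\code{(phi + Delta) mod 24}), \code{baseline}, \code{rel_amplitude},
#'   \code{noise_sd}; the config is attached as an attribute.
#' @export
generate_timecourse <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sched <- make_schedule(config$days, config$interval_h, config$start_clock)
  tt <- config$start_clock + sched$abs_hour  # clock-continuous time
  omega <- 2 * pi / config$period_h

  n <- c(rhythmic = config$n_rhythmic, arrhythmic = config$n_arrhythmic,
         stresslike = config$n_stresslike)
  ntot <- sum(n)
  class_g <- rep(names(n), n)
  gene_id <- sprintf("G%05d", seq_len(ntot))

  m_g <- exp(stats::runif(ntot, log(config$baseline_range[1]),
                          log(config$baseline_range[2])))
  # phases on the 1-min grid so noiseless recovery is exact
  grid <- seq(0, config$period_h - 1 / 60, by = 1 / 60)
  phi_g <- sample(grid, ntot, replace = TRUE)
  phi_g[class_g == "arrhythmic"] <- NA_real_

  lo <- config$rel_amplitude_range[1]
  hi <- config$rel_amplitude_range[2]
  rho_g <- numeric(ntot)
  rho_g[class_g == "rhythmic"] <-
    stats::runif(n[["rhythmic"]], lo, hi)
  rho_g[class_g == "stresslike"] <-
    stats::runif(n[["stresslike"]], lo, lo + (hi - lo) / 3)

  osc_sd <- m_g * rho_g / sqrt(2)
  noise_sd <- config$noise_rel * osc_sd
  noise_sd[class_g == "arrhythmic"] <-
    config$noise_rel * m_g[class_g == "arrhythmic"] * 0.1
  noise_sd[class_g == "stresslike"] <- 2 * noise_sd[class_g == "stresslike"]

  damped <- rep(FALSE, ntot)
  if (config$day2_damping != 1 && config$day2_frac > 0) {
    cand <- which(class_g != "arrhythmic")
    damped[sample(cand, round(config$day2_frac * length(cand)))] <- TRUE
  }

  nt <- length(tt)
  x <- matrix(0, ntot, nt, dimnames = list(gene_id, sched$sample_id))
  day2 <- sched$abs_hour > 24
  for (g in seq_len(ntot)) {
    rho_t <- rep(rho_g[g], nt)
    if (damped[g]) rho_t[day2] <- rho_t[day2] * config$day2_damping
    signal <- if (class_g[g] == "arrhythmic") {
      rep(m_g[g], nt)
    } else {
      m_g[g] * (1 + rho_t * cos(omega * (tt - config$phase_shift_h - phi_g[g])))
    }
    x[g, ] <- pmax(0, signal + stats::rnorm(nt, 0, noise_sd[g]))
  }

  truth <- data.frame(gene_id = gene_id, class = class_g,
                      true_peak_h = phi_g,
                      observed_peak_h = (phi_g + config$phase_shift_h) %%
                        config$period_h,
                      baseline = m_g, rel_amplitude = rho_g,
                      noise_sd = noise_sd, stringsAsFactors = FALSE)
  attr(truth, "config") <- config
  list(matrix = expression_matrix(x, units = "rpkm"), schedule = sched,
       truth = truth)
}

#' Write a ground-truth table
#' @param truth truth data.frame from \code{\link{generate_timecourse}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score results against simulation ground truth
#'
#' For a periodicity table, compares detected molecular peak times with the
#' true observed peaks (circular absolute error) and, when cutoffs are
#' given, tabulates class-by-selection confusion. For an internal-time
#' estimates table plus schedule, compares estimated internal time with the
#' true internal time (\code{clock - Delta}).
#'
#' @param x periodicity table (gene-level, with \code{peak_time_h}) or
#'   internal-time estimates table (sample-level, with
#'   \code{internal_time_h}).
#' @param truth truth data.frame from \code{\link{generate_timecourse}}.
#' @param schedule required for estimates tables.
#' @param r_cut,a_cut optional selection cutoffs for the confusion table.
#' @return list with \code{errors} (per gene/sample circular absolute
#'   error, hours), \code{median}, \code{mean}, \code{max}, and optionally
#'   \code{confusion} (class x selected table).
#' @export
truth_evaluation <- function(x, truth, schedule = NULL, r_cut = NULL,
                             a_cut = NULL) {
  cfg <- attr(truth, "config")
  period <- if (is.null(cfg)) 24 else cfg$period_h
  if ("peak_time_h" %in% names(x)) {
    idx <- match(x$gene_id, truth$gene_id)
    if (anyNA(idx)) stop("gene ids missing from truth: ",
                         paste(x$gene_id[is.na(idx)], collapse = ", "))
    tr <- truth[idx, ]
    osc <- tr$class != "arrhythmic"
    err <- abs(circular_diff(x$peak_time_h[osc], tr$observed_peak_h[osc],
                             period))
    names(err) <- x$gene_id[osc]
    out <- list(errors = err, median = stats::median(err, na.rm = TRUE),
                mean = mean(err, na.rm = TRUE), max = max(err, na.rm = TRUE))
    if (!is.null(r_cut) && !is.null(a_cut)) {
      sel <- x$gene_id %in% select_time_indicating(x, r_cut, a_cut)
      out$confusion <- table(class = tr$class, selected = sel)
    }
    out
  } else if ("internal_time_h" %in% names(x)) {
    if (is.null(schedule)) stop("schedule required to evaluate estimates")
    idx <- match(x$sample_id, schedule$sample_id)
    if (anyNA(idx)) stop("sample ids missing from schedule: ",
                         paste(x$sample_id[is.na(idx)], collapse = ", "))
    shift <- if (is.null(cfg)) 0 else cfg$phase_shift_h
    true_internal <- (schedule$clock_hour[idx] - shift) %% period
    err <- abs(circular_diff(x$internal_time_h, true_internal, period))
    names(err) <- x$sample_id
    list(errors = err, median = stats::median(err), mean = mean(err),
         max = max(err))
  } else {
    stop("x must carry peak_time_h (per gene) or internal_time_h (per sample)")
  }
}
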