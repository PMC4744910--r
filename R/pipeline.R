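#' Run the molecular timetable pipeline end to end
#'
#' Drives the full analysis: load (or simulate) an expression matrix and
#' schedule, normalize counts to RPKM if needed, drop weakly expressed
#' genes, fit the cosine template bank per gene, select time-indicating
#' genes, build the timetable, z-score expression, estimate internal time
#' for every sample, and quantify day-to-day stability. All outputs are
#' TSV/JSON files in \code{outdir}; given the same inputs and seed the run
#' is deterministic.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Recognized fields:
#'   \describe{
#'     \item{input}{either \code{list(rpkm = path)},
#'       \code{list(counts = path, gene_lengths = path, library_sizes =
#'       path)}, or \code{list(simulate = list(...))} with
#'       \code{\link{synthetic_config}} arguments.}
#'     \item{schedule}{path to a schedule TSV (not needed when
#'       simulating).}
#'     \item{outdir}{output directory (created if missing).}
#'     \item{fraction}{low-expression cutoff fraction (default 0.05).}
#'     \item{period_h, step_min}{template bank (defaults 24, 1).}
#'     \item{preset}{cutoff preset name (see \code{\link{cutoff_preset}});
#'       overridden by explicit \code{r_cut}/\code{a_cut}.}
#'     \item{r_cut, a_cut}{selection cutoffs (defaults 0.915, 0.15).}
#'     \item{day_window}{\code{c(start, end)} day window (default 7, 17).}
#'     \item{seed}{RNG seed (default 1).}
#'   }
#' @return invisibly, a list with the in-memory results: \code{results},
#'   \code{timetable}, \code{estimates}, \code{differences},
#'   \code{stability}, \code{summary}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(field) {
    if (is.null(config[[field]])) stop("config is missing field: ", field)
    config[[field]]
  }
  get_or <- function(field, default) config[[field]] %||% default

  outdir <- need("outdir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- get_or("seed", 1L)
  fraction <- get_or("fraction", 0.05)
  period_h <- get_or("period_h", 24)
  step_min <- get_or("step_min", 1)
  cuts <- if (!is.null(config$preset)) cutoff_preset(config$preset)
          else list(r_cut = 0.915, a_cut = 0.15)
  r_cut <- get_or("r_cut", cuts$r_cut)
  a_cut <- get_or("a_cut", cuts$a_cut)
  day_window <- get_or("day_window", c(7, 17))

  input <- need("input")
  if (is.null(input$simulate) && is.null(input$rpkm) && is.null(input$counts))
    stop("config is missing field: input$rpkm or input$counts or input$simulate")
  if (!is.null(input$simulate)) {
    sim_args <- input$simulate
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(synthetic_config, sim_args)
    sim <- generate_timecourse(cfg)
    m <- sim$matrix
    schedule <- sim$schedule
    write_truth_table(sim$truth, file.path(outdir, "truth.tsv"))
  } else {
    schedule <- read_schedule(need("schedule"))
    if (!is.null(input$rpkm)) {
      m <- read_expression_table(input$rpkm, units = "rpkm")
    } else if (!is.null(input$counts)) {
      counts <- read_expression_table(input$counts, units = "counts")
      lens <- read_gene_lengths(need_input(input, "gene_lengths"))
      libs <- read_library_sizes(need_input(input, "library_sizes"))
      m <- compute_rpkm(counts, lens, libs)
    } else {
      stop("config is missing field: input$rpkm or input$counts")
    }
  }

  filt <- filter_low_expression(m, fraction)
  bank <- make_template_bank(period_h, step_min)
  results <- analyze_matrix(filt$matrix, schedule, bank)
  write_periodicity_table(results, file.path(outdir, "periodicity.tsv"),
                          day_window[1], day_window[2])

  selected <- select_time_indicating(results, r_cut, a_cut)
  if (length(selected) < 3)
    stop("fewer than 3 time-indicating genes at r >= ", r_cut,
         ", a >= ", a_cut, "; nothing to estimate from")
  timetable <- build_timetable(filt$matrix, results, selected)
  write_timetable(timetable, file.path(outdir, "timetable.tsv"))

  z <- normalize_expression(filt$matrix, timetable)
  write_heatmap_matrix(z, results, file.path(outdir, "heatmap_matrix.tsv"))

  estimates <- estimate_internal_times(z, timetable, bank)
  diffs <- internal_external_difference(estimates, schedule)
  est_out <- data.frame(sample_id = diffs$sample_id,
                        clock_hour = diffs$clock_hour,
                        internal_time_h = diffs$internal_time_h,
                        diff_h = diffs$diff_h,
                        fit_r = estimates$fit_correlation,
                        noise_pct = estimates$measurement_noise_pct,
                        stringsAsFactors = FALSE)
  utils::write.table(est_out, file.path(outdir, "internal_times.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stability <- stability_table(z, schedule)
  utils::write.table(stability, file.path(outdir, "stability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    package_version = as.character(utils::packageVersion("dieltime")),
    parameters = list(fraction = fraction, period_h = period_h,
                      step_min = step_min, r_cut = r_cut, a_cut = a_cut,
                      day_window = day_window, seed = seed),
    n_genes_input = nrow(m), n_genes_filtered = nrow(filt$matrix),
    n_removed = length(filt$removed), n_selected = length(selected),
    median_abs_diff_h = stats::median(abs(diffs$diff_h)),
    max_noise_pct = max(est_out$noise_pct),
    min_day_pair_r2 = min(stability$r_squared, na.rm = TRUE))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(results = results, timetable = timetable,
                 estimates = est_out, differences = diffs,
                 stability = stability, summary = summary))
}

need_input <- function(input, field) {
  if (is.null(input[[field]])) stop("config is missing field: input$", field)
  input[[field]]
}
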