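# Shared fixture builders; all data is generated in code.

# Expression profile from explicit peak phases and normalized levels.
make_profile <- function(peak_time_h, z, sample_id = "S1") {
  prof <- data.frame(gene_id = sprintf("g%04d", seq_along(peak_time_h)),
                     peak_time_h = peak_time_h, z = z,
                     stringsAsFactors = FALSE)
  attr(prof, "sample_id") <- sample_id
  class(prof) <- c("expression_profile", "data.frame")
  prof
}

# Tiny expression matrix with named genes/samples.
make_matrix <- function(values, units = "rpkm",
                        genes = sprintf("g%d", seq_len(nrow(values))),
                        samples = sprintf("S%02d", seq_len(ncol(values)))) {
  expression_matrix(values, units = units, gene_ids = genes,
                    sample_ids = samples)
}

# A periodicity table built from ground truth, bypassing fitting, so the
# timetable can carry known phases.
results_from_truth <- function(truth) {
  data.frame(gene_id = truth$gene_id, peak_time_h = truth$true_peak_h,
             r = 1, a = 1, valid = !is.na(truth$true_peak_h),
             stringsAsFactors = FALSE)
}

# Circular absolute distance on the 24-h dial.
circ_abs <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
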