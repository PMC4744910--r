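#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns, both named) carrying a \code{units} attribute that records what
#' the values are: raw \code{"counts"}, \code{"rpkm"}, or z-scored
#' \code{"normalized"} expression.
#'
#' @param values numeric matrix, genes x samples; non-normalized units must
#'   be nonnegative.
#' @param units one of \code{"counts"}, \code{"rpkm"}, \code{"normalized"}.
#' @param gene_ids,sample_ids optional dimnames; taken from \code{values} if
#'   already present. Must be duplicate-free.
#' @return the validated matrix with dimnames and a \code{units} attribute.
#' @export
expression_matrix <- function(values, units = c("counts", "rpkm", "normalized"),
                              gene_ids = NULL, sample_ids = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("expression matrix needs gene (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (units != "normalized" && nrow(values) > 0 && any(values < 0))
    stop("negative expression value in '", units, "' matrix")
  attr(values, "units") <- units
  values
}

#' Units of an expression matrix
#' @param m an expression matrix built by \code{\link{expression_matrix}}.
#' @return the units string, or \code{NA} if untagged.
#' @export
expr_units <- function(m) {
  u <- attr(m, "units")
  if (is.null(u)) NA_character_ else u
}

#' Read an expression table
#'
#' Reads a TSV/CSV with a header row of sample ids and gene ids in the first
#' column into an expression matrix.
#'
#' @param path file path.
#' @param units units tag to attach (the file format does not carry one).
#' @param sep field separator, tab by default.
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression_table <- function(path, units = c("rpkm", "counts", "normalized"),
                                  sep = "\t") {
  units <- match.arg(units)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 1) stop("empty expression table: ", path)
  gene_ids <- df[[1]]
  body <- df[-1]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), ncol = ncol(body),
                 dimnames = list(gene_ids, colnames(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or empty cell at gene '%s', sample '%s'",
                 gene_ids[bad[1]], colnames(body)[bad[2]]))
  }
  expression_matrix(vals, units = units)
}

#' Write an expression table
#'
#' Writes the matrix as TSV (\code{gene_id} first column, sample ids as
#' header). Values are printed with 6 significant digits so that
#' write/read round-trips are exact at that precision and byte-stable.
#'
#' @param m expression matrix.
#' @param path output path.
#' @param digits significant digits for the fixed float format.
#' @return \code{path}, invisibly.
#' @export
write_expression_table <- function(m, path, digits = 6) {
  txt <- matrix(sprintf(paste0("%.", digits, "g"), m), nrow = nrow(m),
                ncol = ncol(m), dimnames = dimnames(m))
  df <- data.frame(gene_id = rownames(m) %||% character(0), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a sampling schedule
#'
#' A schedule maps each sample to its absolute hour since the first sample
#' and its clock time on the 24-h dial.
#'
#' @param sample_ids ordered sample identifiers.
#' @param abs_hour hours since the first sample, strictly increasing.
#' @param start_clock clock time of the first sample in [0, 24).
#' @return data.frame with columns \code{sample_id}, \code{abs_hour},
#'   \code{clock_hour}; \code{start_clock} kept as an attribute.
#' @export
sample_schedule <- function(sample_ids, abs_hour, start_clock = 0) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample id in schedule")
  if (length(abs_hour) != length(sample_ids))
    stop("sample_ids and abs_hour lengths differ")
  if (any(diff(abs_hour) <= 0)) stop("abs_hour must be strictly increasing")
  if (start_clock < 0 || start_clock >= 24) stop("start_clock must lie in [0, 24)")
  sched <- data.frame(sample_id = sample_ids, abs_hour = as.numeric(abs_hour),
                      clock_hour = (start_clock + abs_hour) %% 24,
                      stringsAsFactors = FALSE)
  attr(sched, "start_clock") <- start_clock
  sched
}

#' Regular diel sampling schedule
#'
#' Convenience constructor for the standard design: sampling every
#' \code{interval_h} hours for \code{days} days (inclusive of both ends, so
#' 2 days at 2 h gives 25 samples), starting at \code{start_clock}.
#'
#' @param days number of days covered.
#' @param interval_h sampling interval in hours.
#' @param start_clock clock time of the first sample.
#' @param prefix sample id prefix.
#' @return a schedule data.frame (see \code{\link{sample_schedule}}).
#' @export
make_schedule <- function(days = 2, interval_h = 2, start_clock = 14,
                          prefix = "S") {
  abs_hour <- seq(0, days * 24, by = interval_h)
  ids <- sprintf("%s%02d", prefix, seq_along(abs_hour))
  sample_schedule(ids, abs_hour, start_clock)
}

#' Read / write a sampling schedule
#'
#' Schedules are stored as TSV with columns \code{sample_id},
#' \code{abs_hour}, \code{clock_hour}.
#'
#' @param path file path.
#' @return \code{read_schedule}: a schedule data.frame.
#' @export
read_schedule <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "abs_hour", "clock_hour")
  if (!all(need %in% names(df)))
    stop("schedule file must have columns: ", paste(need, collapse = ", "))
  start_clock <- (df$clock_hour[1] - df$abs_hour[1]) %% 24
  sched <- sample_schedule(df$sample_id, df$abs_hour, start_clock)
  if (any(abs(sched$clock_hour - df$clock_hour) > 1e-6))
    stop("clock_hour column inconsistent with abs_hour and start clock")
  sched
}

#' @rdname read_schedule
#' @param schedule schedule data.frame.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule[c("sample_id", "abs_hour", "clock_hour")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' RPKM normalization
#'
#' Converts raw read counts to reads per kilobase of transcript per million
#' mapped reads: \code{count * 1e9 / (gene_length_bp * total_mapped_reads)}.
#'
#' @param counts expression matrix with units \code{"counts"}.
#' @param gene_length_bp named vector of transcript lengths (bp), covering
#'   every gene in \code{counts}.
#' @param total_mapped_reads named vector of per-sample library sizes,
#'   covering every sample.
#' @return an expression matrix with units \code{"rpkm"}.
#' @export
compute_rpkm <- function(counts, gene_length_bp, total_mapped_reads) {
  if (expr_units(counts) != "counts") stop("input units must be 'counts'")
  missing_g <- setdiff(rownames(counts), names(gene_length_bp))
  if (length(missing_g)) stop("no gene length for: ", paste(missing_g, collapse = ", "))
  missing_s <- setdiff(colnames(counts), names(total_mapped_reads))
  if (length(missing_s)) stop("no library size for: ", paste(missing_s, collapse = ", "))
  len <- gene_length_bp[rownames(counts)]
  tot <- total_mapped_reads[colnames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  if (any(tot <= 0)) stop("library sizes must be positive")
  rpkm <- counts * 1e9 / outer(len, tot)
  expression_matrix(rpkm, units = "rpkm")
}

#' Drop weakly expressed genes
#'
#' Removes genes whose mean expression across samples falls below
#' \code{fraction} of the grand mean (the mean over genes of per-gene
#' means), both computed once on the input. Survivors keep their order.
#'
#' @param m expression matrix.
#' @param fraction cutoff as a fraction of the grand mean, in (0, 1);
#'   default 0.05.
#' @return list with elements \code{matrix} (the filtered expression
#'   matrix) and \code{removed} (character vector of dropped gene ids).
#' @export
filter_low_expression <- function(m, fraction = 0.05) {
  if (nrow(m) == 0) stop("empty expression matrix")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  gene_means <- rowMeans(m)
  cutoff <- fraction * mean(gene_means)
  drop <- gene_means < cutoff
  kept <- expression_matrix(m[!drop, , drop = FALSE], units = expr_units(m))
  list(matrix = kept, removed = rownames(m)[drop])
}

#' Two-column TSV readers for gene lengths and library sizes
#'
#' \code{read_gene_lengths} expects columns \code{gene_id},
#' \code{length_bp}; \code{read_library_sizes} expects \code{sample_id},
#' \code{total_mapped_reads}. Both return named numeric vectors suitable
#' for \code{\link{compute_rpkm}}.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_gene_lengths
#' @export
read_library_sizes <- read_gene_lengths
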