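#' Read a clinical table
#'
#' Reads a tab-delimited clinical table with one row per patient. Required
#' columns are \code{patient_id}, \code{survival_years} (time in years from
#' diagnosis to death or censoring) and \code{event} (1 = death observed,
#' 0 = censored). Optional columns \code{metastasis_at_diagnosis}, \code{race},
#' \code{gender} and \code{age_years} are carried through when present and
#' reported as absent otherwise; they are never imputed.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame of class \code{clinical_table} with one row per
#'   patient. Attribute \code{optional_present} lists which optional
#'   covariates the file supplied.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "survival_years", "event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "))
  }
  df$survival_years <- as.numeric(df$survival_years)
  bad_time <- which(!is.finite(df$survival_years) | df$survival_years <= 0)
  if (length(bad_time) > 0) {
    stop("nonpositive or non-numeric survival_years for patient(s): ",
         paste(df$patient_id[bad_time], collapse = ", "))
  }
  if (!all(df$event %in% c(0L, 1L))) {
    bad <- df$patient_id[!df$event %in% c(0L, 1L)]
    stop("event must be 0 or 1; offending patient(s): ",
         paste(bad, collapse = ", "))
  }
  df$event <- as.integer(df$event)
  optional <- c("metastasis_at_diagnosis", "race", "gender", "age_years")
  present <- intersect(optional, names(df))
  if ("metastasis_at_diagnosis" %in% present &&
      !all(df$metastasis_at_diagnosis %in% c(0L, 1L, NA))) {
    stop("metastasis_at_diagnosis must be 0/1")
  }
  attr(df, "optional_present") <- present
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table
#'
#' @param clinical A data.frame as returned by [read_clinical()].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample matrix
#'
#' Reads a TSV whose first column holds gene symbols and whose remaining
#' columns hold per-sample values: normalized log-scale expression
#' (\code{kind = "expression"}), continuous copy number on the linear scale
#' with diploid near 2 (\code{"copy_number_continuous"}), or three-state
#' copy-number calls in \{-1, 0, +1\} (\code{"copy_number_categorical"}).
#'
#' @param path Path to a TSV file; header row of sample ids, first column
#'   named \code{gene}.
#' @param kind One of \code{"expression"}, \code{"copy_number_continuous"},
#'   \code{"copy_number_categorical"}.
#' @return A numeric matrix (genes x samples) with \code{kind} stored as an
#'   attribute.
#' @export
read_matrix <- function(path,
                        kind = c("expression", "copy_number_continuous",
                                 "copy_number_categorical")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol: ", genes[duplicated(genes)][1])
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1])
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "numeric")
  if (any(!is.finite(vals))) {
    idx <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or non-finite value at (%s, %s)",
                 genes[idx[1]], samples[idx[2]]))
  }
  dimnames(vals) <- list(genes, samples)
  if (kind == "copy_number_categorical" && !all(vals %in% c(-1, 0, 1))) {
    bad <- matrix(!(vals %in% c(-1, 0, 1)), nrow(vals))
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("categorical copy number outside {-1,0,+1} at (%s, %s)",
                 genes[idx[1]], samples[idx[2]]))
  }
  if (kind == "copy_number_continuous" && any(vals <= 0)) {
    idx <- which(vals <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive copy number at (%s, %s)",
                 genes[idx[1]], samples[idx[2]]))
  }
  attr(vals, "kind") <- kind
  vals
}

#' Write a gene-by-sample matrix
#'
#' Inverse of [read_matrix()]: \code{read_matrix(write_matrix(m, path))}
#' restores values and labels exactly (up to decimal text representation).
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from a BED4 file
#'
#' Intervals are 0-based half-open, the BED convention, and are kept that way
#' internally; marker positions elsewhere in the package are 1-based as
#' printed in array annotations, with conversions made explicit at use sites.
#'
#' @param path 4-column BED file: chrom, start, end, symbol. No header.
#' @return A data.frame (class \code{gene_annotation}) with columns
#'   \code{symbol}, \code{chromosome}, \code{start}, \code{end}, sorted by
#'   (chromosome, start).
#' @export
read_annotation_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("annotation BED needs 4 columns: chrom start end symbol")
  ann <- data.frame(symbol = as.character(df[[4]]),
                    chromosome = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  bad <- which(ann$start >= ann$end)
  if (length(bad) > 0) {
    stop("start >= end for symbol(s): ", paste(ann$symbol[bad], collapse = ", "))
  }
  dup <- ann$symbol[duplicated(ann$symbol)]
  if (length(dup) > 0) {
    stop("duplicate symbol: ", paste(unique(dup), collapse = ", "))
  }
  ann <- ann[order(ann$chromosome, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write gene annotations as BED4
#'
#' @param annotation A \code{gene_annotation} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  utils::write.table(
    data.frame(annotation$chromosome, annotation$start, annotation$end,
               annotation$symbol),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a marker-level copy-number track
#'
#' @param path TSV with columns sample, chromosome, position (1-based),
#'   copy_number (linear scale, diploid near 2).
#' @return A data.frame of class \code{marker_track}.
#' @export
read_marker_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chromosome", "position", "copy_number")
  if (!all(need %in% names(df))) {
    stop("marker track needs columns: ", paste(need, collapse = ", "))
  }
  as_marker_track(df)
}

#' Validate and class a marker-track data.frame
#'
#' @param df data.frame with sample, chromosome, position, copy_number.
#' @return The validated data.frame, classed \code{marker_track}.
#' @export
as_marker_track <- function(df) {
  if (any(df$copy_number <= 0)) stop("copy_number must be > 0")
  split_idx <- split(seq_len(nrow(df)), list(df$sample, df$chromosome),
                     drop = TRUE)
  for (idx in split_idx) {
    pos <- df$position[idx]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("positions must be strictly increasing within a chromosome")
    }
  }
  class(df) <- c("marker_track", "data.frame")
  df
}

#' Write a marker track
#' @param track A \code{marker_track} data.frame.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_marker_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a checkerboard dose-response CSV
#'
#' First row and first column carry the dose grids in micromolar for the two
#' agents; the top-left cell is ignored. Interior cells are fraction-affected
#' values (growth inhibition relative to vehicle) in [0, 1]. Row doses belong
#' to drug A, column doses to drug B. Replicate plates are separate files.
#'
#' @param path CSV path.
#' @param drug_a,drug_b Names of the two agents.
#' @return A list of class \code{dose_response_matrix} with \code{doses_a},
#'   \code{doses_b}, \code{effects} (|doses_a| x |doses_b| matrix), and names.
#' @export
read_dose_matrix <- function(path, drug_a = "drug_a", drug_b = "drug_b") {
  raw <- as.matrix(utils::read.csv(path, header = FALSE))
  suppressWarnings(storage.mode(raw) <- "numeric")
  doses_b <- raw[1, -1]
  doses_a <- raw[-1, 1]
  effects <- raw[-1, -1, drop = FALSE]
  dose_response_matrix(doses_a, doses_b, effects, drug_a, drug_b)
}

#' Construct a dose-response matrix object
#'
#' @param doses_a,doses_b Strictly increasing positive dose grids (uM).
#' @param effects |doses_a| x |doses_b| matrix of fraction affected in [0,1],
#'   or a 3-d array with replicates in the third dimension.
#' @param drug_a,drug_b Agent names.
#' @return A \code{dose_response_matrix} list.
#' @export
dose_response_matrix <- function(doses_a, doses_b, effects,
                                 drug_a = "drug_a", drug_b = "drug_b") {
  if (any(doses_a <= 0) || any(doses_b <= 0)) stop("doses must be positive")
  if (is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE)) {
    stop("dose grids must be strictly increasing")
  }
  d <- dim(effects)
  if (d[1] != length(doses_a) || d[2] != length(doses_b)) {
    stop("effects dimensions do not match dose grids")
  }
  if (any(effects < 0 | effects > 1, na.rm = TRUE)) {
    stop("effects must lie in [0, 1]")
  }
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 doses_a = as.numeric(doses_a), doses_b = as.numeric(doses_b),
                 effects = effects),
            class = "dose_response_matrix")
}
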