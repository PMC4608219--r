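#' Write a data.frame as TSV
#'
#' Tab-separated, header row, no quoting of numerics; the format used for
#' every tabular artifact the pipeline writes.
#'
#' @param df data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE),
                stringsAsFactors = FALSE)
}

#' Write a probe x sample matrix as TSV (probe ids in the first column)
#' @param m numeric matrix with rownames (probe ids) and colnames (samples).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.table::data.table(probe_id = rownames(m))
  df <- cbind(df, data.table::as.data.table(m))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a probe x sample matrix written by [write_matrix_tsv()]
#' @param path file path.
#' @return numeric matrix with probe rownames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write one cohort's study files
#'
#' Writes `<cohort>_intensities.tsv`, `<cohort>_detection.tsv` (probe x
#' sample matrices) and `<cohort>_covariates.tsv` (sample per row, includes
#' `bmi`).
#'
#' @param study an `expression_study`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- study$cohort_id
  paths <- file.path(dir, paste0(id, c("_intensities.tsv", "_detection.tsv",
                                       "_covariates.tsv")))
  write_matrix_tsv(study$intensities, paths[1])
  write_matrix_tsv(study$detection_p, paths[2])
  write_tsv(study$covariates, paths[3])
  invisible(paths)
}

#' Read one cohort's study files written by [write_study()]
#' @param dir directory containing the files.
#' @param cohort_id cohort label / file prefix.
#' @param annotation probe annotation data.frame (`probe_id`, `gene`).
#' @return an `expression_study`.
#' @export
read_study <- function(dir, cohort_id, annotation) {
  expression_study(
    intensities = read_matrix_tsv(file.path(dir, paste0(cohort_id, "_intensities.tsv"))),
    detection_p = read_matrix_tsv(file.path(dir, paste0(cohort_id, "_detection.tsv"))),
    covariates = read_tsv(file.path(dir, paste0(cohort_id, "_covariates.tsv"))),
    cohort_id = cohort_id,
    annotation = annotation)
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, then tab-separated gene symbols.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to "na").
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated genes).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}
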