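#' Define an ordered stage sequence
#'
#' The biological progression of cell stages (e.g. hESC -> EB -> Rosette ->
#' hNPC -> Neuron). Consecutive pairs of stages are the transitions that the
#' pair-wise PCA / network overlay analyses operate on.
#'
#' @param stages character vector of at least two unique stage names, in
#'   biological order.
#' @return An object of class `StageSequence` with elements `stages` and
#'   `transitions` (a list of length `length(stages) - 1`, each a character
#'   pair `c(from, to)`).
#' @examples
#' stage_sequence(c("hESC", "EB", "Rosette", "hNPC", "Neuron"))
#' @export
stage_sequence <- function(stages) {
  stages <- as.character(stages)
  if (length(stages) < 2L) stop("a stage sequence needs at least 2 stages")
  if (anyDuplicated(stages)) stop("stage names must be unique")
  transitions <- lapply(seq_len(length(stages) - 1L), function(i) {
    c(stages[i], stages[i + 1L])
  })
  structure(list(stages = stages, transitions = transitions),
            class = "StageSequence")
}

#' @export
print.StageSequence <- function(x, ...) {
  cat("StageSequence:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' Construct a concentration matrix
#'
#' The pipeline's sole primary input: a samples x metabolites table of
#' (non-negative) concentrations with a stage label and replicate id per
#' sample.
#'
#' @param values numeric matrix, rows = samples, columns = metabolites.
#' @param stage_labels character, one stage per row of `values`.
#' @param replicate_ids per-sample replicate tags (coerced to character).
#' @param sample_ids unique sample labels; defaults to rownames of `values`
#'   or `sample_1 ...`.
#' @param metabolite_names unique metabolite labels; defaults to colnames.
#' @param stages optional [stage_sequence()]; when supplied, every stage
#'   label must belong to it.
#' @return An object of class `ConcentrationMatrix`.
#' @export
concentration_matrix <- function(values, stage_labels, replicate_ids = NULL,
                                 sample_ids = NULL, metabolite_names = NULL,
                                 stages = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  }
  if (is.null(metabolite_names)) {
    metabolite_names <- colnames(values)
    if (is.null(metabolite_names)) metabolite_names <- paste0("met_", seq_len(p))
  }
  sample_ids <- as.character(sample_ids)
  metabolite_names <- as.character(metabolite_names)
  stage_labels <- as.character(stage_labels)
  if (is.null(replicate_ids)) replicate_ids <- as.character(seq_len(n))
  replicate_ids <- as.character(replicate_ids)
  if (length(sample_ids) != n) stop("sample_ids length must match nrow(values)")
  if (length(stage_labels) != n) stop("stage_labels length must match nrow(values)")
  if (length(replicate_ids) != n) stop("replicate_ids length must match nrow(values)")
  if (length(metabolite_names) != p) stop("metabolite_names length must match ncol(values)")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(metabolite_names)) {
    stop("duplicate metabolite names: ",
         paste(unique(metabolite_names[duplicated(metabolite_names)]), collapse = ", "))
  }
  if (anyNA(values)) stop("values contain missing entries; load via ",
                          "read_concentration_table() with an imputation policy ",
                          "or supply a complete matrix")
  if (!is.null(stages)) {
    bad <- setdiff(unique(stage_labels), stages$stages)
    if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, metabolite_names)
  structure(list(values = values,
                 sample_ids = sample_ids,
                 stage_labels = stage_labels,
                 replicate_ids = replicate_ids,
                 metabolite_names = metabolite_names),
            class = "ConcentrationMatrix")
}

#' @export
print.ConcentrationMatrix <- function(x, ...) {
  cat("ConcentrationMatrix:", nrow(x$values), "samples x",
      ncol(x$values), "metabolites\n")
  tab <- table(x$stage_labels)
  cat("stages:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  invisible(x)
}

.delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a concentration table from delimited text
#'
#' Expects a header row; the first column holds sample ids, one column holds
#' the stage label and (optionally) one the replicate id; every remaining
#' column is a metabolite. Numeric parsing is locale-independent (decimal
#' point).
#'
#' @param path CSV (`,`) or TSV (`.tsv`/`.txt`, tab) file.
#' @param stage_column,replicate_column names of the metadata columns
#'   (defaults `"stage"`, `"replicate"`). A missing replicate column is
#'   tolerated; replicates are then numbered within stage.
#' @param stages optional [stage_sequence()] used to validate stage labels.
#' @param missing policy for missing cells: `"reject"` (default) errors
#'   naming the offending cells; `"impute_half_min"` replaces each missing
#'   value by half the smallest observed positive value of that metabolite.
#' @return A [concentration_matrix()].
#' @export
read_concentration_table <- function(path, stage_column = "stage",
                                     replicate_column = "replicate",
                                     stages = NULL,
                                     missing = c("reject", "impute_half_min")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  if (ncol(df) < 3L) stop("expected at least sample id, stage and one metabolite column")
  sample_ids <- df[[1L]]
  meta_cols <- names(df)[1L]
  if (!stage_column %in% names(df)) stop("stage column '", stage_column, "' not found")
  stage_labels <- df[[stage_column]]
  meta_cols <- c(meta_cols, stage_column)
  if (replicate_column %in% names(df)) {
    replicate_ids <- df[[replicate_column]]
    meta_cols <- c(meta_cols, replicate_column)
  } else {
    replicate_ids <- as.character(stats::ave(seq_along(stage_labels), stage_labels,
                                             FUN = seq_along))
  }
  met_cols <- names(df)[!names(df) %in% meta_cols]
  if (!length(met_cols)) stop("no metabolite columns found")
  dup <- unique(met_cols[duplicated(met_cols)])
  if (length(dup)) stop("duplicate metabolite column(s): ", paste(dup, collapse = ", "))

  raw <- df[met_cols]
  values <- matrix(NA_real_, nrow(raw), length(met_cols),
                   dimnames = list(sample_ids, met_cols))
  for (j in seq_along(met_cols)) {
    cell <- raw[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", cell[bad[1L]], "' at row ", bad[1L],
           " (sample '", sample_ids[bad[1L]], "'), column '", met_cols[j], "'")
    }
    values[, j] <- num
  }

  if (anyNA(values)) {
    miss <- which(is.na(values), arr.ind = TRUE)
    if (missing == "reject") {
      first <- miss[1L, ]
      stop("missing value at row ", first[1L], " (sample '",
           sample_ids[first[1L]], "'), column '", met_cols[first[2L]],
           "'; ", nrow(miss), " missing cell(s) total. Use ",
           "missing = 'impute_half_min' to impute.")
    }
    for (j in unique(miss[, 2L])) {
      pos <- values[, j][!is.na(values[, j]) & values[, j] > 0]
      if (!length(pos)) stop("cannot impute metabolite '", met_cols[j],
                             "': no positive observed value")
      values[is.na(values[, j]), j] <- min(pos) / 2
    }
  }

  concentration_matrix(values, stage_labels, replicate_ids,
                       sample_ids = sample_ids, metabolite_names = met_cols,
                       stages = stages)
}

#' Write a concentration table to delimited text
#'
#' Values are written with up to 12 significant digits so that a write/read
#' round trip reproduces them exactly.
#'
#' @param data a [concentration_matrix()].
#' @param path output file; `,`-delimited unless the extension is
#'   `.tsv`/`.txt`.
#' @param stage_column,replicate_column header names for the metadata columns.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(data, path, stage_column = "stage",
                                      replicate_column = "replicate") {
  stopifnot(inherits(data, "ConcentrationMatrix"))
  vals <- apply(data$values, 2L, function(x) formatC(x, digits = 12, format = "g"))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(data$values))
  df <- data.frame(sample = data$sample_ids, stage = data$stage_labels,
                   replicate = data$replicate_ids, vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample", stage_column, replicate_column, data$metabolite_names)
  write.table(df, path, sep = .delim_for(path), row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a metabolite annotation table
#'
#' Two-column delimited text mapping metabolite name to compound class
#' (e.g. amino acid, bioenergetics, peptide, carbohydrate). Metabolites that
#' are absent from the table are treated downstream as class `"unknown"`.
#'
#' @param path two-column CSV/TSV with a header row.
#' @return An `AnnotationTable`: a data.frame with columns `metabolite` and
#'   `class`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(annotation_table(character(), character()))
  }
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(annotation_table(character(), character()))
  if (ncol(df) < 2L) stop("annotation table needs two columns (metabolite, class)")
  annotation_table(as.character(df[[1L]]), as.character(df[[2L]]))
}

#' Construct an annotation table in memory
#'
#' @param metabolite,class character vectors of equal length. Duplicate
#'   metabolite rows are allowed only when they agree on the class.
#' @return An `AnnotationTable` data.frame.
#' @export
annotation_table <- function(metabolite, class) {
  metabolite <- as.character(metabolite)
  class <- as.character(class)
  stopifnot(length(metabolite) == length(class))
  df <- unique(data.frame(metabolite = metabolite, class = class,
                          stringsAsFactors = FALSE))
  dup <- unique(df$metabolite[duplicated(df$metabolite)])
  if (length(dup)) {
    stop("conflicting class annotations for: ", paste(dup, collapse = ", "))
  }
  structure(df, class = c("AnnotationTable", "data.frame"))
}

#' Class composition of a metabolite set
#'
#' Counts and percentages per compound class over a given metabolite list
#' (e.g. "amino acids represent 25% of the metabolites"). Metabolites without
#' an annotation fall into class `"unknown"`.
#'
#' @param annot an [annotation_table()].
#' @param names non-empty character vector of metabolite names to tally.
#' @param drop_unknown if `TRUE`, unannotated metabolites are excluded from
#'   the denominator (percentages are then over annotated metabolites only).
#' @return data.frame with columns `class`, `count`, `percentage`
#'   (one-decimal rounding; sums to 100 within rounding), ordered by
#'   decreasing count.
#' @export
class_composition <- function(annot, names, drop_unknown = FALSE) {
  if (!length(names)) stop("'names' must be non-empty")
  cls <- annot$class[match(names, annot$metabolite)]
  cls[is.na(cls)] <- "unknown"
  if (drop_unknown) {
    cls <- cls[cls != "unknown"]
    if (!length(cls)) stop("all metabolites unannotated")
  }
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(class = names(tab),
             count = as.integer(tab),
             percentage = round(100 * as.integer(tab) / length(cls), 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}
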