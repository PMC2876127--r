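# ---- internal helpers -------------------------------------------------------

#' Stop with a classed condition
#' @noRd
cgh_stop <- function(msg, class) {
  stop(structure(class = c(class, "crosscgh_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Check that a data frame has the required columns, error naming the missing one
#' @noRd
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    cgh_stop(sprintf("%s: missing required column(s): %s",
                     what, paste(missing, collapse = ", ")),
             "crosscgh_format_error")
  }
  invisible(df)
}

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) {
    cgh_stop(sprintf("%s: file not found: %s", what, path),
             "crosscgh_format_error")
  }
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

as_logical01 <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

# ---- feature annotation -----------------------------------------------------

#' Read a feature annotation table
#'
#' Reads the per-feature annotation of an array platform: chromosome and
#' position of each probe's source locus, X linkage, membership in the two
#' conserved-gene normalization subsets, probe length and GC fraction.
#'
#' The file is tab-separated with header columns \code{feature_id},
#' \code{chromosome}, \code{position_bp}, \code{is_x}, \code{conserved_1000},
#' \code{conserved_100}, \code{length_bp}, \code{gc_fraction}.
#'
#' Validation enforces: unique \code{feature_id}; \code{is_x} consistent with
#' \code{chromosome == x_chrom}; the ~100-gene conserved set nested inside the
#' ~1000-gene set; \code{position_bp >= 0}, \code{length_bp > 0} and
#' \code{gc_fraction} in [0, 1].
#'
#' @param path Path to the TSV file.
#' @param x_chrom Name of the X chromosome in the platform genome.
#' @return A \code{data.frame} with the columns above, logical flags coerced
#'   to \code{logical}.
#' @export
read_feature_annotation <- function(path, x_chrom = "X") {
  df <- read_tsv_checked(path, "feature annotation")
  check_columns(df, c("feature_id", "chromosome", "position_bp", "is_x",
                      "conserved_1000", "conserved_100", "length_bp",
                      "gc_fraction"),
                "feature annotation")
  df$feature_id <- as.character(df$feature_id)
  df$chromosome <- as.character(df$chromosome)
  df$position_bp <- as.integer(df$position_bp)
  df$is_x <- as_logical01(df$is_x)
  df$conserved_1000 <- as_logical01(df$conserved_1000)
  df$conserved_100 <- as_logical01(df$conserved_100)
  df$length_bp <- as.integer(df$length_bp)
  df$gc_fraction <- as.numeric(df$gc_fraction)
  validate_feature_annotation(df, x_chrom = x_chrom)
}

#' Validate a feature annotation table against its invariants
#'
#' @param df A data frame shaped like the output of
#'   \code{\link{read_feature_annotation}}.
#' @param x_chrom Name of the X chromosome.
#' @return The validated data frame, invisibly classed.
#' @export
validate_feature_annotation <- function(df, x_chrom = "X") {
  dup <- unique(df$feature_id[duplicated(df$feature_id)])
  if (length(dup) > 0L) {
    cgh_stop(sprintf("feature annotation: duplicate feature_id: %s",
                     paste(utils::head(dup, 10L), collapse = ", ")),
             "crosscgh_validation_error")
  }
  if (nrow(df) > 0L) {
    if (!identical(df$is_x, df$chromosome == x_chrom)) {
      cgh_stop(sprintf(
        "feature annotation: is_x inconsistent with chromosome == '%s'",
        x_chrom), "crosscgh_validation_error")
    }
    bad <- df$conserved_100 & !df$conserved_1000
    if (any(bad)) {
      cgh_stop(sprintf(
        "feature annotation: conserved_100 not nested in conserved_1000 for: %s",
        paste(utils::head(df$feature_id[bad], 10L), collapse = ", ")),
        "crosscgh_validation_error")
    }
    if (any(df$position_bp < 0L) || any(df$length_bp <= 0L) ||
        any(df$gc_fraction < 0 | df$gc_fraction > 1)) {
      cgh_stop("feature annotation: position_bp/length_bp/gc_fraction out of range",
               "crosscgh_validation_error")
    }
  }
  df
}

#' Write a feature annotation table
#' @param df Annotation data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_annotation <- function(df, path) {
  out <- df
  for (col in c("is_x", "conserved_1000", "conserved_100")) {
    out[[col]] <- as.integer(out[[col]])
  }
  write_tsv(out, path)
}

# ---- genome metadata --------------------------------------------------------

#' Read genome metadata
#'
#' Per-chromosome (or scaffold) metadata of a genome assembly: length, X
#' linkage and whether the sequence is annotated as heterochromatic. Needed by
#' the divergence-profile rules (X versus autosome hits, hits to
#' heterochromatin, hits within 25 kb of a chromosome end).
#'
#' @param path TSV with header \code{chromosome}, \code{length_bp},
#'   \code{is_x}, \code{is_heterochromatin}.
#' @param genome Label attached to the table (e.g. species name).
#' @return A data frame with attribute \code{genome}.
#' @export
read_genome_meta <- function(path, genome = NA_character_) {
  df <- read_tsv_checked(path, "genome metadata")
  check_columns(df, c("chromosome", "length_bp", "is_x", "is_heterochromatin"),
                "genome metadata")
  df$chromosome <- as.character(df$chromosome)
  df$length_bp <- as.numeric(df$length_bp)
  df$is_x <- as_logical01(df$is_x)
  df$is_heterochromatin <- as_logical01(df$is_heterochromatin)
  if (any(df$length_bp <= 0)) {
    cgh_stop("genome metadata: chromosome lengths must be > 0",
             "crosscgh_validation_error")
  }
  attr(df, "genome") <- genome
  df
}

#' Write genome metadata
#' @param df Genome metadata data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome_meta <- function(df, path) {
  out <- df[c("chromosome", "length_bp", "is_x", "is_heterochromatin")]
  out$is_x <- as.integer(out$is_x)
  out$is_heterochromatin <- as.integer(out$is_heterochromatin)
  write_tsv(out, path)
}

# ---- scan tables ------------------------------------------------------------

#' Read a scan table
#'
#' Per-array, per-feature two-channel fluorescence readings in a minimal
#' GenePix-like dialect: foreground and background medians plus background
#' standard deviation for each channel, and a QC flag in
#' \{\code{ok}, \code{low_signal}, \code{technical_error}\}.
#'
#' @param path TSV with header \code{array_id}, \code{feature_id}, \code{fg1},
#'   \code{bg1}, \code{bg1_sd}, \code{fg2}, \code{bg2}, \code{bg2_sd},
#'   \code{qc_flag}.
#' @return A data frame, one row per (array, feature).
#' @export
read_scan_table <- function(path) {
  df <- read_tsv_checked(path, "scan table")
  check_columns(df, c("array_id", "feature_id", "fg1", "bg1", "bg1_sd",
                      "fg2", "bg2", "bg2_sd", "qc_flag"), "scan table")
  df$array_id <- as.character(df$array_id)
  df$feature_id <- as.character(df$feature_id)
  for (col in c("fg1", "bg1", "bg1_sd", "fg2", "bg2", "bg2_sd")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]])) || any(df[[col]] < 0)) {
      cgh_stop(sprintf("scan table: column %s must be finite and >= 0", col),
               "crosscgh_validation_error")
    }
  }
  df$qc_flag <- as.character(df$qc_flag)
  bad <- !df$qc_flag %in% c("ok", "low_signal", "technical_error")
  if (any(bad)) {
    cgh_stop(sprintf("scan table: unknown qc_flag value(s): %s",
                     paste(unique(df$qc_flag[bad]), collapse = ", ")),
             "crosscgh_validation_error")
  }
  key <- paste(df$array_id, df$feature_id)
  if (anyDuplicated(key)) {
    cgh_stop("scan table: duplicate (array_id, feature_id) rows",
             "crosscgh_validation_error")
  }
  df
}

#' Write a scan table
#' @param df Scan table data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scan_table <- function(df, path) {
  write_tsv(df[c("array_id", "feature_id", "fg1", "bg1", "bg1_sd",
                 "fg2", "bg2", "bg2_sd", "qc_flag")], path)
}

# ---- hybridization design ---------------------------------------------------

#' Read a hybridization design table
#'
#' @param path TSV with header \code{array_id}, \code{test_sample},
#'   \code{reference_sample}, \code{dye_orientation} (+1 means the test sample
#'   is in channel 1).
#' @return A data frame.
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path, "design")
  check_columns(df, c("array_id", "test_sample", "reference_sample",
                      "dye_orientation"), "design")
  df$array_id <- as.character(df$array_id)
  df$test_sample <- as.character(df$test_sample)
  df$reference_sample <- as.character(df$reference_sample)
  df$dye_orientation <- as.integer(df$dye_orientation)
  validate_design(df)
}

#' Validate a hybridization design
#' @param df Design data frame.
#' @return The validated data frame.
#' @export
validate_design <- function(df) {
  if (!all(df$dye_orientation %in% c(-1L, 1L))) {
    cgh_stop("design: dye_orientation must be +1 or -1",
             "crosscgh_validation_error")
  }
  if (anyDuplicated(df$array_id)) {
    cgh_stop("design: duplicate array_id", "crosscgh_validation_error")
  }
  if (length(unique(df$reference_sample)) > 1L) {
    cgh_stop("design: reference_sample must be identical across arrays",
             "crosscgh_validation_error")
  }
  for (sp in unique(df$test_sample)) {
    ori <- df$dye_orientation[df$test_sample == sp]
    if (!all(c(-1L, 1L) %in% ori)) {
      cgh_stop(sprintf(
        "design: test sample '%s' lacks an array of each dye orientation", sp),
        "crosscgh_validation_error")
    }
  }
  df
}

#' Write a hybridization design table
#' @param df Design data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_design <- function(df, path) {
  write_tsv(df[c("array_id", "test_sample", "reference_sample",
                 "dye_orientation")], path)
}

# ---- BLAST-style hit tables -------------------------------------------------

hit_table_cols <- c("query_id", "subject_chromosome", "percent_identity",
                    "align_length", "mismatches", "gaps", "q_start", "q_end",
                    "subject_start", "subject_end", "e_value", "bitscore")

#' Read a BLAST tabular hit table
#'
#' Parses 12-column tab-separated output (the standard tabular format:
#' query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score). The subject field
#' is the chromosome or scaffold name of the searched genome. Subject
#' coordinates are order-normalized so that \code{subject_start <=
#' subject_end}; strand is irrelevant to every downstream rule and is
#' discarded.
#'
#' @param path Path to the tabular file (no header).
#' @param subject_genome Label of the genome the hits point into.
#' @return A data frame of hit records with attribute \code{subject_genome}.
#' @export
read_hit_table <- function(path, subject_genome = NA_character_) {
  if (!file.exists(path)) {
    cgh_stop(sprintf("hit table: file not found: %s", path),
             "crosscgh_format_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), 2L), hit_table_cols[1:2]),
      stringsAsFactors = FALSE)
    for (col in hit_table_cols[3:12]) df[[col]] <- numeric(0)
    return(normalize_hit_table(df, subject_genome))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    cgh_stop(sprintf("hit table: line %d has %d fields, expected 12",
                     which(nf != 12L)[1L], nf[nf != 12L][1L]),
             "crosscgh_format_error")
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  df <- data.frame(query_id = m[, 1L], subject_chromosome = m[, 2L],
                   stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) & !is.na(m[, j]))
    if (length(bad) > 0L) {
      cgh_stop(sprintf("hit table: non-numeric value '%s' in column %d, line %d",
                       m[bad[1L], j], j, bad[1L]),
               "crosscgh_format_error")
    }
    df[[hit_table_cols[j]]] <- v
  }
  normalize_hit_table(df, subject_genome)
}

#' @noRd
normalize_hit_table <- function(df, subject_genome) {
  s <- pmin(df$subject_start, df$subject_end)
  e <- pmax(df$subject_start, df$subject_end)
  df$subject_start <- s
  df$subject_end <- e
  if (any(df$e_value < 0, na.rm = TRUE)) {
    cgh_stop("hit table: negative E-value", "crosscgh_validation_error")
  }
  if (any(df$percent_identity < 0 | df$percent_identity > 100, na.rm = TRUE)) {
    cgh_stop("hit table: percent_identity outside [0, 100]",
             "crosscgh_validation_error")
  }
  attr(df, "subject_genome") <- subject_genome
  df
}

#' Write a hit table in BLAST tabular format
#' @param df Hit table data frame (columns as in \code{\link{read_hit_table}}).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hit_table <- function(df, path) {
  out <- df[hit_table_cols]
  # format() would pad; write raw fields so values round-trip exactly
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(out) > 0L) {
    fields <- vapply(seq_len(nrow(out)), function(i) {
      paste(vapply(out[i, ], function(x) {
        if (is.numeric(x)) format(x, digits = 17, scientific = NA) else as.character(x)
      }, character(1)), collapse = "\t")
    }, character(1))
    writeLines(fields, con)
  }
  invisible(path)
}
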