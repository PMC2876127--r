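# Small fixtures built in code; all files go to tempdir().

tiny_annotation <- function() {
  data.frame(
    feature_id = c("fx1", "fx2", "fa1", "fa2", "fa3", "fh1"),
    chromosome = c("X", "X", "2L", "2R", "3R", "2L"),
    position_bp = c(1000L, 50000L, 2000L, 3000L, 4000L, 5000L),
    is_x = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    conserved_1000 = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    conserved_100 = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    length_bp = c(500L, 480L, 520L, 500L, 450L, 500L),
    gc_fraction = c(0.45, 0.5, 0.4, 0.55, 0.42, 0.48),
    stringsAsFactors = FALSE)
}

tiny_meta <- function(genome = "test") {
  df <- data.frame(
    chromosome = c("X", "2L", "2R", "3R", "Het1"),
    length_bp = c(1e6, 2e6, 1.5e6, 1.8e6, 2e5),
    is_x = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    is_heterochromatin = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  attr(df, "genome") <- genome
  df
}

# one BLAST-tabular hit record with sensible defaults
hit_row <- function(query, chrom, pid = 95, evalue = 1e-50, bitscore = 800,
                    sstart = 10000, send = 10499) {
  data.frame(query_id = query, subject_chromosome = chrom,
             percent_identity = pid, align_length = 500, mismatches = 10,
             gaps = 0, q_start = 1, q_end = 500,
             subject_start = sstart, subject_end = send,
             e_value = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

hit_table <- function(..., genome = "het") {
  rows <- list(...)
  df <- if (length(rows) == 0L) hit_row("none", "X")[0, ] else do.call(rbind, rows)
  attr(df, "subject_genome") <- genome
  df
}

write_hits_raw <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# scan table with given per-channel values, one array
scan_row <- function(feature_id, fg1, bg1, fg2, bg2, bg1_sd = 10, bg2_sd = 10,
                     qc_flag = "ok", array_id = "a1") {
  data.frame(array_id = array_id, feature_id = feature_id,
             fg1 = fg1, bg1 = bg1, bg1_sd = bg1_sd,
             fg2 = fg2, bg2 = bg2, bg2_sd = bg2_sd,
             qc_flag = qc_flag, stringsAsFactors = FALSE)
}

# a noise-free simulation config for exactness tests
noiseless_config <- function(n_features = 600, species = "platform", ...) {
  args <- list(...)
  defaults <- list(n_features = n_features, species = species,
                   sigma_feature = 0, sigma_array = 0, dye_amplitude = 0,
                   bg_sd = 0,
                   confounder_probs = list(paralog_family = 0, move_off_x = 0,
                                           move_onto_x = 0, deletion = 0,
                                           heterochromatic = 0))
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}
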