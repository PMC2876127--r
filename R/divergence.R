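# Per-feature divergence and confounder profiles from sequence-similarity hits.
#
# The rules mirror the sequence-analysis side of the assessment: the top hit
# to the heterologous genome (E < 1e-14) gives each feature its percent
# identity; hit counts at the looser E < 1e-10 threshold give the
# heterologous/platform hit-count ratio; chromosome-class rules flag possible
# movement on/off the X and hits to heterochromatin or telomeric windows
# (25 kb from a chromosome end).

#' Derive per-feature divergence and confounder profiles
#'
#' Combines hit tables against the heterologous and platform (reference)
#' genomes with the feature annotation and genome metadata into one row per
#' feature:
#' \describe{
#'   \item{top_hit_pid}{Percent identity of the top heterologous hit among
#'     hits with \code{e_value < e_top}; the top hit is the lowest E-value,
#'     ties broken by highest bit score, then lowest subject start. \code{NA}
#'     when no hit qualifies.}
#'   \item{n_hits_het, n_hits_ref}{Hit counts at \code{e_value < e_count}.}
#'   \item{hit_ratio}{\code{n_hits_het / n_hits_ref}; \code{NA} when
#'     \code{n_hits_ref == 0}.}
#'   \item{no_hit}{No heterologous hit at \code{e_value < e_top}.}
#'   \item{ref_not_found}{No hit to the platform genome at
#'     \code{e_value < e_top}.}
#'   \item{autosomal_only}{X-linked feature whose heterologous hits (at
#'     \code{e_count}) all fall on non-X chromosomes.}
#'   \item{het_x_hit}{Autosomal feature with at least one heterologous hit on
#'     an X chromosome.}
#'   \item{tel_or_het}{Any hit (either genome, at \code{e_count}) on a
#'     heterochromatic sequence or overlapping the \code{telomere_bp} window
#'     at either end of its chromosome.}
#' }
#'
#' @param hits_het Hit table against the heterologous genome
#'   (\code{\link{read_hit_table}}).
#' @param hits_ref Hit table against the platform genome.
#' @param annotation Feature annotation
#'   (\code{\link{read_feature_annotation}}); must cover every query id.
#' @param meta_het,meta_ref Genome metadata (\code{\link{read_genome_meta}})
#'   covering every subject chromosome.
#' @param e_top E-value threshold for top-hit identity and presence flags.
#' @param e_count E-value threshold for hit counting and chromosome-class
#'   flags.
#' @param telomere_bp Width of the telomeric window at each chromosome end.
#' @return A data frame, one row per annotated feature.
#' @export
derive_divergence_profile <- function(hits_het, hits_ref, annotation,
                                      meta_het, meta_ref,
                                      e_top = 1e-14, e_count = 1e-10,
                                      telomere_bp = 25000) {
  check_hits_known(hits_het, meta_het, "heterologous")
  check_hits_known(hits_ref, meta_ref, "reference")
  unknown_q <- setdiff(unique(c(hits_het$query_id, hits_ref$query_id)),
                       annotation$feature_id)
  if (length(unknown_q) > 0L) {
    cgh_stop(sprintf("divergence profile: hits for unannotated feature(s): %s",
                     paste(utils::head(unknown_q, 10L), collapse = ", ")),
             "crosscgh_validation_error")
  }

  ids <- annotation$feature_id
  n <- length(ids)
  idx_het <- match(hits_het$query_id, ids)
  idx_ref <- match(hits_ref$query_id, ids)

  # top heterologous hit at e_top
  top_pid <- rep(NA_real_, n)
  qual <- which(hits_het$e_value < e_top)
  if (length(qual) > 0L) {
    h <- hits_het[qual, ]
    hi <- idx_het[qual]
    ord <- order(hi, h$e_value, -h$bitscore, h$subject_start)
    first <- ord[!duplicated(hi[ord])]
    top_pid[hi[first]] <- h$percent_identity[first]
  }
  no_hit <- !ids %in% hits_het$query_id[hits_het$e_value < e_top]
  ref_not_found <- !ids %in% hits_ref$query_id[hits_ref$e_value < e_top]

  # hit counts at e_count
  n_het <- tabulate(idx_het[hits_het$e_value < e_count], nbins = n)
  n_ref <- tabulate(idx_ref[hits_ref$e_value < e_count], nbins = n)
  hit_ratio <- ifelse(n_ref >= 1L, n_het / n_ref, NA_real_)

  # chromosome-class flags at e_count
  het_x <- meta_het$chromosome[meta_het$is_x]
  sel <- hits_het$e_value < e_count
  hits_on_x <- tabulate(idx_het[sel & hits_het$subject_chromosome %in% het_x],
                        nbins = n) > 0L
  any_het_hit <- n_het > 0L
  autosomal_only <- annotation$is_x & any_het_hit & !hits_on_x
  het_x_hit <- !annotation$is_x & hits_on_x

  tel_or_het <- tel_het_flag(hits_het, idx_het, meta_het, e_count,
                             telomere_bp, n) |
    tel_het_flag(hits_ref, idx_ref, meta_ref, e_count, telomere_bp, n)

  data.frame(feature_id = ids,
             top_hit_pid = top_pid,
             n_hits_het = n_het,
             n_hits_ref = n_ref,
             hit_ratio = hit_ratio,
             no_hit = no_hit,
             autosomal_only = autosomal_only,
             het_x_hit = het_x_hit,
             tel_or_het = tel_or_het,
             ref_not_found = ref_not_found,
             stringsAsFactors = FALSE)
}

#' @noRd
check_hits_known <- function(hits, meta, label) {
  unknown <- setdiff(unique(hits$subject_chromosome), meta$chromosome)
  if (length(unknown) > 0L) {
    cgh_stop(sprintf(
      "divergence profile: %s hits reference unknown chromosome(s): %s",
      label, paste(utils::head(unknown, 10L), collapse = ", ")),
      "crosscgh_validation_error")
  }
  invisible(hits)
}

#' @noRd
tel_het_flag <- function(hits, idx, meta, e_count, telomere_bp, n) {
  if (nrow(hits) == 0L) return(logical(n))
  sel <- hits$e_value < e_count
  if (!any(sel)) return(logical(n))
  mi <- match(hits$subject_chromosome, meta$chromosome)
  chrom_len <- meta$length_bp[mi]
  in_het <- meta$is_heterochromatin[mi]
  # overlap of [start, end] with [1, telomere_bp] or [len - telomere_bp + 1, len]
  near_start <- hits$subject_start <= telomere_bp
  near_end <- hits$subject_end >= chrom_len - telomere_bp + 1
  flag <- sel & (in_het | near_start | near_end)
  tabulate(idx[flag], nbins = n) > 0L
}

#' Write / read a divergence profile table
#' @param df Divergence profile data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_divergence_profile <- function(df, path) {
  out <- df
  for (col in c("no_hit", "autosomal_only", "het_x_hit", "tel_or_het",
                "ref_not_found")) {
    out[[col]] <- as.integer(out[[col]])
  }
  write_tsv(out, path)
}

#' @rdname write_divergence_profile
#' @export
read_divergence_profile <- function(path) {
  df <- read_tsv_checked(path, "divergence profile")
  check_columns(df, c("feature_id", "top_hit_pid", "n_hits_het", "n_hits_ref",
                      "hit_ratio", "no_hit", "autosomal_only", "het_x_hit",
                      "tel_or_het", "ref_not_found"), "divergence profile")
  df$feature_id <- as.character(df$feature_id)
  for (col in c("no_hit", "autosomal_only", "het_x_hit", "tel_or_het",
                "ref_not_found")) {
    df[[col]] <- as_logical01(df[[col]])
  }
  df
}
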