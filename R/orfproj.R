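# Reference-projected ORF prediction: align an isotig to its best-mapped
# reference transcript, carry the reference CDS through the alignment,
# translate, and locate premature termination codons.

#' Semi-global pairwise alignment of an isotig against a reference transcript
#'
#' Global in the isotig, with free end gaps on the isotig side (the
#' reference may extend beyond the isotig unpenalized), affine gap
#' penalties.  Default scores: match +2, mismatch -3, gap open 12, gap
#' extend 2.  A column map (isotig position, reference position per
#' alignment column) is attached for coordinate projection.
#'
#' @param isotig_seq,transcript_seq nucleotide strings (nonempty).
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @param type alignment mode passed to the aligner; the default
#'   \code{"global-local"} is the semi-global mode above, \code{"local"}
#'   is used by the novel-region intron filter.
#' @return list of class \code{pair_alignment}: gapped \code{pattern} and
#'   \code{subject} strings, \code{score}, 0-based \code{q_pos} /
#'   \code{t_pos} per column (NA at gaps), and \code{nmatch}.
#' @export
align_pair <- function(isotig_seq, transcript_seq, match = 2, mismatch = -3,
                       gap_open = 12, gap_ext = 2, type = "global-local") {
  if (!nzchar(isotig_seq) || !nzchar(transcript_seq))
    stop("align_pair: both sequences must be nonempty", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(isotig_seq),
    subject = Biostrings::DNAString(transcript_seq),
    type = type, substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  p0 <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
  q_pos <- ifelse(pc == "-", NA_integer_, p0 + cumsum(pc != "-") - 1L)
  t_pos <- ifelse(sc == "-", NA_integer_, s0 + cumsum(sc != "-") - 1L)
  structure(list(pattern = p, subject = s, score = Biostrings::score(aln),
                 q_pos = q_pos, t_pos = t_pos,
                 nmatch = sum(pc == sc & pc != "-")),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment> %d columns, score %.1f, %d matches\n",
              length(x$q_pos), x$score, x$nmatch))
  invisible(x)
}

#' Project a reference CDS interval onto the isotig
#'
#' Maps the reference CDS columns through the alignment: the projected
#' isotig interval runs from the first to the last isotig base aligned to
#' a CDS column; the reading frame is set so that codon 1 of the reference
#' maps to frame 0; \code{aligned_cds_fraction} is the fraction of CDS
#' positions aligned to an isotig base (not a gap).
#'
#' @param alignment an [align_pair()] result.
#' @param cds length-2 vector: reference CDS in transcript coordinates
#'   (0-based half-open).
#' @return list of class \code{cds_projection} (\code{orf_start},
#'   \code{orf_end}, \code{frame}, \code{aligned_cds_fraction},
#'   \code{ref_stop_q}, \code{frameshift}), or \code{NULL} when no CDS
#'   position is aligned.
#' @export
project_cds <- function(alignment, cds) {
  t_pos <- alignment$t_pos; q_pos <- alignment$q_pos
  in_cds <- !is.na(t_pos) & t_pos >= cds[1] & t_pos < cds[2]
  aligned <- in_cds & !is.na(q_pos)
  cds_len <- cds[2] - cds[1]
  if (!any(aligned)) return(NULL)
  fraction <- sum(aligned) / cds_len
  orf_start <- min(q_pos[aligned])
  orf_end <- max(q_pos[aligned]) + 1L
  first <- which(aligned)[1]
  d <- t_pos[first] - cds[1]
  frame <- (3L - d %% 3L) %% 3L
  # isotig position aligned to the reference stop codon (first base)
  stop_cols <- which(!is.na(t_pos) & t_pos >= cds[2] - 3L & !is.na(q_pos))
  ref_stop_q <- if (length(stop_cols)) q_pos[stop_cols[1]] else Inf
  # indels within the CDS region whose length is not a multiple of 3
  region <- which(in_cds | (!is.na(q_pos) & q_pos >= orf_start & q_pos < orf_end))
  gaps <- rle(is.na(q_pos[region]) | is.na(t_pos[region]))
  frameshift <- any(gaps$lengths[gaps$values] %% 3L != 0L)
  structure(list(orf_start = orf_start, orf_end = orf_end, frame = frame,
                 aligned_cds_fraction = fraction, ref_stop_q = ref_stop_q,
                 frameshift = frameshift, cds = cds),
            class = "cds_projection")
}

#' Predict the isotig protein from a CDS projection
#'
#' Translates the isotig from the projected start, in the projected frame,
#' to the first stop codon or the end of the sequence.  A premature
#' termination codon (PTC) is flagged when a stop occurs strictly before
#' the isotig position aligned to the reference stop codon; the
#' \code{complete75} flag marks projections covering more than 75% of the
#' reference CDS.
#'
#' @param isotig_seq the isotig sequence.
#' @param projection a [project_cds()] result.
#' @param isotig_id,transcript_id identifiers carried through to the
#'   result.
#' @param complete_threshold CDS-coverage fraction for \code{complete75}.
#' @return list of class \code{orf_projection}: the protein string, the
#'   in-frame \code{orf_interval}, \code{frame}, PTC flag with codon index
#'   and isotig position, \code{complete75}, \code{uninterrupted} and a
#'   \code{frameshift} warning flag.
#' @export
predict_protein <- function(isotig_seq, projection, isotig_id = NA_character_,
                            transcript_id = NA_character_,
                            complete_threshold = 0.75) {
  if (is.null(projection))
    stop("predict_protein: no projection", call. = FALSE)
  start <- projection$orf_start + projection$frame
  if (nchar(isotig_seq) - start < 3L)
    stop("predict_protein: projected interval shorter than one codon",
         call. = FALSE)
  aa_full <- translate_dna(substr0(isotig_seq, start, nchar(isotig_seq)))
  aa_chars <- strsplit(aa_full, "", fixed = TRUE)[[1]]
  stop_idx <- which(aa_chars == "*")
  first_stop <- if (length(stop_idx)) stop_idx[1] else NA_integer_
  protein <- if (is.na(first_stop)) aa_full else
    paste(aa_chars[seq_len(first_stop - 1L)], collapse = "")
  stop_q <- if (is.na(first_stop)) NA_integer_ else start + 3L * (first_stop - 1L)
  ptc <- !is.na(first_stop) && stop_q < projection$ref_stop_q
  span <- projection$orf_end - start
  orf_interval <- c(start, start + 3L * (span %/% 3L))
  structure(list(isotig_id = isotig_id, transcript_id = transcript_id,
                 aligned_cds_fraction = projection$aligned_cds_fraction,
                 orf_interval = orf_interval, frame = projection$frame,
                 protein = protein, ptc = ptc,
                 ptc_codon = if (ptc) first_stop else NA_integer_,
                 ptc_pos = if (ptc) stop_q else NA_integer_,
                 complete75 = projection$aligned_cds_fraction > complete_threshold,
                 uninterrupted = !ptc,
                 frameshift = projection$frameshift),
            class = "orf_projection")
}

#' @export
print.orf_projection <- function(x, ...) {
  cat(sprintf(
    "<orf_projection> %s vs %s: %.0f%% CDS aligned, ORF [%d,%d) frame %d, %d aa%s%s\n",
    x$isotig_id, x$transcript_id, 100 * x$aligned_cds_fraction,
    x$orf_interval[1], x$orf_interval[2], x$frame, nchar(x$protein),
    if (x$ptc) sprintf(", PTC at codon %d", x$ptc_codon) else "",
    if (x$complete75) ", complete75" else ""))
  invisible(x)
}

#' Project a reference model onto an isotig in one step
#'
#' Convenience wrapper: [align_pair()], [project_cds()] with the model's
#' CDS, then [predict_protein()].
#'
#' @param isotig_seq isotig sequence.
#' @param model the reference [gene_model()].
#' @param isotig_id identifier carried to the result.
#' @param ... scoring parameters forwarded to [align_pair()].
#' @return an \code{orf_projection}, or \code{NULL} when the CDS is
#'   entirely unaligned.
#' @export
project_orf <- function(isotig_seq, model, isotig_id = NA_character_, ...) {
  aln <- align_pair(isotig_seq, model$transcript_seq, ...)
  prj <- project_cds(aln, model$cds)
  if (is.null(prj)) return(NULL)
  predict_protein(isotig_seq, prj, isotig_id = isotig_id,
                  transcript_id = model$transcript_id)
}
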