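# Detection of non-conserved (novel) transcribed regions: isotig segments
# with no homology to the references, flanked on both sides by conserved
# chained alignments, surviving a realignment against the intervening
# target intron.

#' Find novel-region candidates in a chained hit
#'
#' Every gap between consecutive chained HSPs on the query is a candidate,
#' bounded by the two HSPs as conserved flanks.  Uncovered isotig termini
#' are never candidates (no flank on one side).  Gaps of \code{min_len} bp
#' or less are emitted with status \code{rejected-short} ("more than 50
#' bp" is strict).
#'
#' @param chain a [chain_hsps()] result with at least two members.
#' @param isotig_len isotig length (bp).
#' @param min_len minimum candidate length, exclusive (default 50).
#' @return list of \code{novel_candidate} objects: interval, length, the
#'   flanking HSP rows and an initial status (\code{candidate} or
#'   \code{rejected-short}).
#' @export
find_candidates <- function(chain, isotig_len, min_len = 50L) {
  mem <- chain$members
  if (nrow(mem) < 2) return(list())
  out <- list()
  for (i in seq_len(nrow(mem) - 1L)) {
    gs <- mem$q_end[i]; ge <- mem$q_start[i + 1L]
    len <- ge - gs
    if (len < 1) next
    out[[length(out) + 1L]] <- structure(list(
      isotig_id = chain$query_id, start = gs, end = ge, length = len,
      left_flank = mem[i, , drop = FALSE],
      right_flank = mem[i + 1L, , drop = FALSE],
      status = if (len <= min_len) "rejected-short" else "candidate",
      class = NA_character_, intron_identity = NA_real_,
      orf_status = "untested"), class = "novel_candidate")
  }
  out
}

#' @export
print.novel_candidate <- function(x, ...) {
  cat(sprintf("<novel_candidate> %s [%d,%d) %d bp: %s%s\n",
              x$isotig_id, x$start, x$end, x$length, x$status,
              if (is.na(x$class)) "" else paste0(" (", x$class, ")")))
  invisible(x)
}

#' Realign a candidate against the intervening target sequence
#'
#' The candidate plus up to \code{flank_bp} of each conserved flank is
#' aligned semi-globally to the target span between the flanks' genomic
#' positions (extended by \code{flank_bp} on each side), with the gap-open
#' penalty multiplied by \code{gap_open_multiplier} to keep exons from
#' fragmenting into multiple blocks.  The flanks must anchor (align at
#' \code{anchor_identity} or better); the candidate itself is then locally
#' aligned to the span, and the region is \code{rejected-intronic} when
#' its best local identity reaches \code{identity_reject} percent over at
#' least \code{min_cover} of its length; otherwise \code{novel}.
#'
#' @param cand a [find_candidates()] candidate.
#' @param isotig_seq the isotig sequence.
#' @param target_span_seq target genomic span between (and including
#'   \code{flank_bp} of) the flank positions.
#' @param gap_open_multiplier anchor-alignment gap-open multiplier
#'   (default 3).
#' @param identity_reject percent identity at or above which the
#'   candidate is called intronic (default 70).
#' @param min_cover minimum aligned fraction of the candidate for a
#'   rejection (default 0.8).
#' @param anchor_identity minimum flank identity for the anchor check
#'   (default 0.75).
#' @param flank_bp flank context taken on each side (default 50).
#' @param gap_open,gap_ext,match,mismatch base scoring (as [align_pair()]).
#' @return the candidate with \code{status} set to \code{novel},
#'   \code{rejected-intronic} or \code{unresolved}, and
#'   \code{intron_identity} / \code{intron_cover} filled in.
#' @export
intron_filter <- function(cand, isotig_seq, target_span_seq,
                          gap_open_multiplier = 3.0, identity_reject = 70,
                          min_cover = 0.8, anchor_identity = 0.75,
                          flank_bp = 50L, gap_open = 12, gap_ext = 2,
                          match = 2, mismatch = -3) {
  if (cand$status == "rejected-short") return(cand)
  L <- nchar(isotig_seq)
  # flank context never extends beyond the flanking HSP itself, so it is
  # guaranteed contiguous with the extracted target span
  qL <- substr0(isotig_seq,
                max(0L, cand$start - flank_bp, cand$left_flank$q_start),
                cand$start)
  qR <- substr0(isotig_seq, cand$end,
                min(L, cand$end + flank_bp, cand$right_flank$q_end))
  cand_seq <- substr0(isotig_seq, cand$start, cand$end)
  if (!nzchar(qL) || !nzchar(qR)) { cand$status <- "unresolved"; return(cand) }
  span_len <- nchar(target_span_seq)
  go <- gap_open * gap_open_multiplier

  # each flank must locally align near its own end of the span
  anchor_ok <- function(flank, at_start) {
    a <- align_pair(flank, target_span_seq, match = match, mismatch = mismatch,
                    gap_open = go, gap_ext = gap_ext, type = "local")
    t_hit <- range(a$t_pos[!is.na(a$t_pos)])
    near <- if (at_start) t_hit[1] <= 2L * flank_bp
            else t_hit[2] >= span_len - 2L * flank_bp
    near && a$nmatch >= anchor_identity * nchar(flank)
  }
  anchored <- tryCatch(anchor_ok(qL, TRUE) && anchor_ok(qR, FALSE),
                       error = function(e) FALSE)
  if (!anchored) { cand$status <- "unresolved"; return(cand) }

  loc <- align_pair(cand_seq, target_span_seq, match = match,
                    mismatch = mismatch, gap_open = go, gap_ext = gap_ext,
                    type = "local")
  aligned_cols <- sum(!is.na(loc$q_pos) & !is.na(loc$t_pos))
  aligned_q <- sum(!is.na(loc$q_pos))
  pid_local <- if (aligned_cols > 0) 100 * loc$nmatch / aligned_cols else 0
  cover <- aligned_q / cand$length
  cand$intron_identity <- 100 * loc$nmatch / cand$length
  cand$intron_cover <- cover
  cand$status <- if (pid_local >= identity_reject && cover >= min_cover)
    "rejected-intronic" else "novel"
  cand
}

#' Classify a surviving novel region
#'
#' When the flanking alignments are adjacent on the target genome (gap of
#' at most \code{adjacency_bp}), the region is an insertion inside a
#' conserved exon; when they map across an annotated intron, it is a
#' novel exon.
#'
#' @param cand a candidate with both flanks.
#' @param model the target [gene_model()] (projects flank transcript
#'   coordinates to the genome).
#' @param adjacency_bp maximum target gap still called
#'   insertion-in-exon (default 10).
#' @return the candidate with \code{class} set.
#' @export
classify_region <- function(cand, model, adjacency_bp = 10L) {
  lg <- transcript_to_genomic(model, cand$left_flank$t_start,
                              cand$left_flank$t_end)
  rg <- transcript_to_genomic(model, cand$right_flank$t_start,
                              cand$right_flank$t_end)
  left_end <- max(lg$g_end); right_start <- min(rg$g_start)
  gap <- max(0L, right_start - left_end)
  cand$class <- if (gap <= adjacency_bp) "insertion-in-exon" else "novel-exon"
  cand$target_gap <- gap
  cand
}

#' ORF status of a novel region
#'
#' Within a projected reading frame: \code{ORF} when the region lies
#' inside the projected CDS, has length divisible by 3 and introduces no
#' stop codon in frame; \code{PTC+} when a stop is introduced;
#' \code{untested} when no projection covers it.
#'
#' @param cand the candidate.
#' @param isotig_seq the isotig sequence.
#' @param projection an [predict_protein()] result for the isotig (or
#'   NULL).
#' @return the candidate with \code{orf_status} set.
#' @export
orf_status <- function(cand, isotig_seq, projection) {
  if (is.null(projection)) { cand$orf_status <- "untested"; return(cand) }
  orf <- projection$orf_interval
  if (cand$start < orf[1] || cand$end > orf[2]) {
    cand$orf_status <- "untested"
    return(cand)
  }
  origin <- orf[1]                      # codon-aligned by construction
  first_codon <- origin + 3L * ((cand$start - origin) %/% 3L)
  last_codon_end <- min(orf[2], origin + 3L * (((cand$end - 1L - origin) %/% 3L) + 1L))
  aa <- translate_dna(substr0(isotig_seq, first_codon, last_codon_end))
  has_stop <- grepl("*", aa, fixed = TRUE)
  cand$orf_status <- if (has_stop) "PTC+"
    else if (cand$length %% 3L == 0L) "ORF" else "PTC+"
  cand
}

#' Detect novel regions of one isotig across all reference species
#'
#' Extracts candidates from the chain against the focal reference,
#' realigns each against the intervening genomic span of every species
#' carrying the gene, and rejects a candidate when ANY species rejects it
#' (conservative multi-species rule).  Surviving regions are classified
#' and ORF-tested.
#'
#' @param chain the focal-species [chain_hsps()] result (gene-resolved).
#' @param isotig_seq the isotig sequence.
#' @param models named list of [gene_model()] objects (all species).
#' @param genomes list: species -> named vector of contig sequences.
#' @param homologs character vector of transcript ids homologous to the
#'   chain target (one per species, including the target itself).
#' @param projection optional [predict_protein()] result for ORF status.
#' @param min_len,flank_bp,gap_open_multiplier,identity_reject,min_cover
#'   filter parameters (see [find_candidates()] and [intron_filter()]).
#' @return list of finished \code{novel_candidate} objects.
#' @export
detect_novel_regions <- function(chain, isotig_seq, models, genomes,
                                 homologs, projection = NULL, min_len = 50L,
                                 flank_bp = 50L, gap_open_multiplier = 3.0,
                                 identity_reject = 70, min_cover = 0.8) {
  cands <- find_candidates(chain, nchar(isotig_seq), min_len)
  focal_model <- models[[chain$target_id]]
  lapply(cands, function(cand) {
    if (cand$status == "rejected-short") return(cand)
    statuses <- character(0); ids <- numeric(0)
    for (tid in homologs) {
      m <- models[[tid]]
      if (is.null(m)) next
      span <- extract_target_span(cand, m, genomes[[m$species]], flank_bp)
      if (is.null(span)) next
      res <- intron_filter(cand, isotig_seq, span,
                           gap_open_multiplier = gap_open_multiplier,
                           identity_reject = identity_reject,
                           min_cover = min_cover, flank_bp = flank_bp)
      statuses <- c(statuses, res$status)
      if (!is.na(res$intron_identity)) ids <- c(ids, res$intron_identity)
    }
    cand$intron_identity <- if (length(ids)) max(ids) else NA_real_
    cand$status <- if (length(statuses) == 0) "unresolved"
      else if (any(statuses == "rejected-intronic")) "rejected-intronic"
      else if (all(statuses == "unresolved")) "unresolved"
      else "novel"
    cand <- classify_region(cand, focal_model)
    orf_status(cand, isotig_seq, projection)
  })
}

#' Genomic span between a candidate's flanks on one species' genome
#'
#' Extracts the target sequence between the flanking alignments' genomic
#' projections, extended by \code{flank_bp} of exonic context on each
#' side; \code{NULL} when the flanks project nowhere.
#'
#' @param cand a [find_candidates()] candidate.
#' @param model the species' [gene_model()].
#' @param genome named vector of that species' contig sequences.
#' @param flank_bp context taken on each side (default 50).
#' @return the span string, or NULL.
#' @export
extract_target_span <- function(cand, model, genome, flank_bp = 50L) {
  lg <- transcript_to_genomic(model, cand$left_flank$t_start, cand$left_flank$t_end)
  rg <- transcript_to_genomic(model, cand$right_flank$t_start, cand$right_flank$t_end)
  if (nrow(lg) == 0 || nrow(rg) == 0) return(NULL)
  gseq <- genome[[model$chrom]]
  if (is.null(gseq)) return(NULL)
  lo <- max(0L, max(lg$g_end) - flank_bp)
  hi <- min(nchar(gseq), min(rg$g_start) + flank_bp)
  if (hi <= lo) return(NULL)
  substr0(gseq, lo, hi)
}

#' Plain-text block alignment report for a novel region
#'
#' Renders the candidate-plus-flanks versus target-span alignment as
#' wrapped text blocks, flank context in lower case.
#'
#' @param cand the candidate (after filtering).
#' @param isotig_seq the isotig sequence.
#' @param target_span_seq the target span it was tested against.
#' @param width characters per block line.
#' @return character vector of report lines.
#' @export
format_novel_alignment <- function(cand, isotig_seq, target_span_seq,
                                   width = 60L) {
  qL <- substr0(isotig_seq, max(0L, cand$start - 50L), cand$start)
  qR <- substr0(isotig_seq, cand$end, min(nchar(isotig_seq), cand$end + 50L))
  query <- paste0(tolower(qL), substr0(isotig_seq, cand$start, cand$end),
                  tolower(qR))
  aln <- align_pair(toupper(query), target_span_seq, gap_open = 36,
                    type = "global-local")
  pc <- strsplit(aln$pattern, "", fixed = TRUE)[[1]]
  sc <- strsplit(aln$subject, "", fixed = TRUE)[[1]]
  marks <- ifelse(pc == sc & pc != "-", "|", " ")
  lines <- character(0)
  for (s in seq(1, length(pc), by = width)) {
    e <- min(s + width - 1L, length(pc))
    lines <- c(lines,
               paste0("isotig  ", paste(pc[s:e], collapse = "")),
               paste0("        ", paste(marks[s:e], collapse = "")),
               paste0("target  ", paste(sc[s:e], collapse = "")), "")
  }
  c(sprintf("%s [%d,%d) %d bp  status=%s class=%s identity=%s",
            cand$isotig_id, cand$start, cand$end, cand$length, cand$status,
            cand$class %||% NA,
            format(cand$intron_identity)), "", lines)
}
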