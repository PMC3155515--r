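# Pileup-based SNP calling from assembly read stacks: depth and
# minor-allele-fraction thresholds, flanking-ambiguity filter, one isotig
# kept per gene, substitution classification and summary.

PILEUP_BASES <- c("A", "C", "G", "T", "N")

#' Build the pileup of an assembled isotig
#'
#' Counts A/C/G/T/N over the reads covering each consensus column.
#' Minus-strand reads are reverse-complemented before counting, so all
#' counts are in consensus orientation.
#'
#' @param assembly an [isotig_assembly()].
#' @return list of class \code{pileup_stack}: the 5 x L count matrix,
#'   per-column total depth, and the consensus.
#' @export
pileup <- function(assembly) {
  L <- nchar(assembly$consensus)
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(PILEUP_BASES, NULL))
  rd <- assembly$reads
  for (j in seq_len(nrow(rd))) {
    s <- if (rd$strand[j] == "-") revcomp(rd$seq[j]) else rd$seq[j]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    cols <- rd$offset[j] + seq_along(chars)
    bi <- match(chars, PILEUP_BASES)
    idx <- cbind(bi, cols)
    counts[idx] <- counts[idx] + 1L
  }
  structure(list(isotig_id = assembly$isotig_id, counts = counts,
                 depth = colSums(counts), consensus = assembly$consensus),
            class = "pileup_stack")
}

#' @export
print.pileup_stack <- function(x, ...) {
  cat(sprintf("<pileup_stack> %s: %d columns, median depth %d\n",
              x$isotig_id, ncol(x$counts), as.integer(stats::median(x$depth))))
  invisible(x)
}

#' Call candidate biallelic sites from a pileup
#'
#' A column is a candidate when its total read depth is at least
#' \code{min_depth} and the second-most-frequent non-N base reaches
#' \code{min_fraction} of the non-N depth.  N never counts as an allele;
#' ties between bases are broken alphabetically.  Columns whose third base
#' also reaches the fraction threshold are flagged multi-allelic and not
#' called.
#'
#' @param pile a [pileup()] result.
#' @param min_depth minimum total depth at the column (default 6).
#' @param min_fraction minimum minor-allele fraction of the non-N depth
#'   (default 0.30).
#' @return data frame of calls: \code{isotig_id, position} (0-based),
#'   \code{major_allele, minor_allele, depth, minor_fraction,
#'   substitution_class, is_transition, high_depth}; multi-allelic columns
#'   are reported in the \code{multiallelic} attribute.
#' @export
call_candidates <- function(pile, min_depth = 6L, min_fraction = 0.30) {
  counts <- pile$counts
  acgt <- counts[1:4, , drop = FALSE]
  non_n <- colSums(acgt)
  depth <- pile$depth
  calls <- list(); multi <- integer(0)
  cand_cols <- which(depth >= min_depth & non_n > 0)
  for (p in cand_cols) {
    cnt <- acgt[, p]
    ord <- order(-cnt, DNA_BASES4)            # count desc, base alphabetical
    major <- DNA_BASES4[ord[1]]; minor <- DNA_BASES4[ord[2]]
    f2 <- cnt[ord[2]] / non_n[p]
    if (f2 < min_fraction) next
    f3 <- cnt[ord[3]] / non_n[p]
    if (f3 >= min_fraction) { multi <- c(multi, p - 1L); next }
    calls[[length(calls) + 1L]] <- data.frame(
      isotig_id = pile$isotig_id, position = p - 1L,
      major_allele = major, minor_allele = minor,
      depth = depth[p], minor_fraction = f2, stringsAsFactors = FALSE)
  }
  out <- rbind_or_empty(calls, c("isotig_id", "position", "major_allele",
                                 "minor_allele", "depth", "minor_fraction"))
  if (nrow(out)) {
    out$substitution_class <- classify_substitution(out$major_allele,
                                                    out$minor_allele)
    out$is_transition <- out$substitution_class == "AG_CT"
    out$high_depth <- out$depth >= 31L
  } else {
    out$substitution_class <- character(0)
    out$is_transition <- logical(0)
    out$high_depth <- logical(0)
  }
  attr(out, "multiallelic") <- multi
  out
}

#' Remove candidate calls with ambiguous flanking columns
#'
#' A call is dropped when, at either immediately adjacent consensus
#' position, the consensus base is N, no read covers the position, or more
#' than \code{max_n_fraction} of the covering reads carry N.  Calls at the
#' consensus ends are judged on the existing flank only.
#'
#' @param calls data frame from [call_candidates()].
#' @param pile the same [pileup()] result.
#' @param max_n_fraction tolerated fraction of N among covering reads at a
#'   flank (default 0.2; "more than" is strict).
#' @return the filtered call data frame.
#' @export
filter_flanking <- function(calls, pile, max_n_fraction = 0.2) {
  if (nrow(calls) == 0) return(calls)
  L <- ncol(pile$counts)
  cons <- strsplit(pile$consensus, "", fixed = TRUE)[[1]]
  flank_ok <- function(p) {          # p: 0-based flank position
    if (p < 0 || p >= L) return(TRUE)     # no flank on this side
    if (cons[p + 1L] == "N") return(FALSE)
    cov <- pile$depth[p + 1L]
    if (cov == 0) return(FALSE)
    pile$counts["N", p + 1L] / cov <= max_n_fraction
  }
  keep <- vapply(calls$position, function(p) flank_ok(p - 1L) && flank_ok(p + 1L),
                 logical(1))
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep one isotig's calls per gene
#'
#' For all isotigs mapped to a single gene (splice variants of the same
#' gene), only the isotig with the largest number of surviving calls is
#' kept (ties: larger chained coverage, then lexicographic isotig id).
#' Isotigs with no gene mapping are kept as their own units.
#'
#' @param calls data frame of calls across isotigs.
#' @param annotation data frame mapping isotigs to genes: columns
#'   \code{isotig_id, gene_id, coverage} (as written by the annotation
#'   stage; only unique mappings should be supplied).
#' @return the deduplicated call data frame, with a \code{gene_id} column
#'   (NA for unmapped isotigs).
#' @export
dedupe_per_gene <- function(calls, annotation) {
  if (nrow(calls) == 0) { calls$gene_id <- character(0); return(calls) }
  ann <- annotation[!duplicated(annotation$isotig_id), , drop = FALSE]
  idx <- match(calls$isotig_id, ann$isotig_id)
  calls$gene_id <- ann$gene_id[idx]
  per_iso <- stats::aggregate(list(n_calls = calls$position),
                              by = list(isotig_id = calls$isotig_id), FUN = length)
  per_iso$gene_id <- ann$gene_id[match(per_iso$isotig_id, ann$isotig_id)]
  per_iso$coverage <- ann$coverage[match(per_iso$isotig_id, ann$isotig_id)]
  per_iso$coverage[is.na(per_iso$coverage)] <- 0
  mapped <- per_iso[!is.na(per_iso$gene_id), , drop = FALSE]
  winners <- vapply(split(seq_len(nrow(mapped)), mapped$gene_id), function(rows) {
    sub <- mapped[rows, , drop = FALSE]
    sub$isotig_id[order(-sub$n_calls, -sub$coverage, sub$isotig_id)[1]]
  }, character(1))
  keep <- is.na(calls$gene_id) | calls$isotig_id %in% winners
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a substitution by its unordered allele pair
#'
#' \code{\{A,G\}} and \code{\{C,T\}} are transitions (\code{AG_CT});
#' \code{\{A,C\}}/\code{\{G,T\}} (\code{AC_GT}), \code{\{A,T\}}
#' (\code{AT}) and \code{\{C,G\}} (\code{GC}) are transversions.
#'
#' @param major,minor character vectors of bases.
#' @return character vector of class labels.
#' @export
classify_substitution <- function(major, minor) {
  a <- pmin(major, minor); b <- pmax(major, minor)
  key <- paste0(a, b)
  map <- c(AG = "AG_CT", CT = "AG_CT", AC = "AC_GT", GT = "AC_GT",
           AT = "AT", CG = "GC")
  cls <- unname(map[key])
  if (anyNA(cls)) stop("classify_substitution: invalid allele pair", call. = FALSE)
  cls
}

#' Summarize a SNP call set
#'
#' Reports the total number of calls, genes hit, per-class counts, the
#' transition percentage (rounded to the nearest integer), and the same
#' figures for the high-depth subset (depth >= \code{high_depth},
#' inclusive).
#'
#' @param calls data frame of calls (with \code{substitution_class} and
#'   \code{depth}; \code{gene_id} optional).
#' @param high_depth depth bound of the high-confidence subset (default 31).
#' @return list of class \code{snp_summary}.
#' @export
summarize_snps <- function(calls, high_depth = 31L) {
  tally <- function(df) {
    classes <- c("AG_CT", "AC_GT", "AT", "GC")
    cc <- table(factor(df$substitution_class, levels = classes))
    total <- nrow(df)
    list(total = total,
         genes = if ("gene_id" %in% names(df))
           length(unique(df$gene_id[!is.na(df$gene_id)])) else NA_integer_,
         class_counts = setNames(as.integer(cc), classes),
         transition_pct = if (total > 0)
           as.integer(round(100 * cc[["AG_CT"]] / total)) else NA_integer_)
  }
  structure(list(all = tally(calls),
                 high_depth = tally(calls[calls$depth >= high_depth, , drop = FALSE]),
                 high_depth_threshold = high_depth),
            class = "snp_summary")
}

#' @export
print.snp_summary <- function(x, ...) {
  fmt <- function(t, label) {
    cat(sprintf("%s: %d SNPs", label, t$total))
    if (!is.na(t$genes)) cat(sprintf(" in %d genes", t$genes))
    cat(sprintf(" | %s | transitions %s%%\n",
                paste(sprintf("%s=%d", names(t$class_counts), t$class_counts),
                      collapse = " "),
                format(t$transition_pct)))
  }
  fmt(x$all, "all")
  fmt(x$high_depth, sprintf("depth>=%d", x$high_depth_threshold))
  invisible(x)
}

#' Run the full SNP-calling pipeline over assemblies
#'
#' Pileup, candidate calling, flanking filter and per-gene deduplication
#' in their fixed order.
#'
#' @param assemblies list of [isotig_assembly()] objects.
#' @param annotation isotig-to-gene map for [dedupe_per_gene()], or NULL
#'   to skip deduplication.
#' @param min_depth,min_fraction,max_n_fraction,high_depth thresholds.
#' @return list: \code{calls} (deduplicated data frame) and
#'   \code{summary} ([summarize_snps()]).
#' @export
call_snps <- function(assemblies, annotation = NULL, min_depth = 6L,
                      min_fraction = 0.30, max_n_fraction = 0.2,
                      high_depth = 31L) {
  per <- lapply(assemblies, function(a) {
    pile <- pileup(a)
    filter_flanking(call_candidates(pile, min_depth, min_fraction),
                    pile, max_n_fraction)
  })
  calls <- do.call(rbind, per)
  if (is.null(calls) || nrow(calls) == 0) {
    calls <- call_candidates(pileup(isotig_assembly("empty", "ACGT",
                                                    empty_read_frame())))
  }
  rownames(calls) <- NULL
  if (!is.null(annotation)) calls <- dedupe_per_gene(calls, annotation)
  list(calls = calls, summary = summarize_snps(calls, high_depth))
}
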