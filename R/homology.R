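# Homology-based isotig annotation: chain HSPs into syntenic hits, screen
# unique gene-level mappings, cluster by gene and assign cross-species
# orthology-consistency categories.

#' Chain HSPs of one query-target pair into the best syntenic subset
#'
#' Among all colinear (order-consistent along both query and target),
#' pairwise non-overlapping subsets of the given HSPs, returns the one with
#' the largest total query coverage.  Computed by weighted dynamic
#' programming over HSPs sorted by query start.  Ties are broken by larger
#' total bit-score, then fewer members, then lexicographically smallest
#' member order.
#'
#' @param hsps data frame of HSPs (as from [read_blast_tabular()]) sharing
#'   one \code{query_id}, \code{target_id} and \code{strand}.
#' @return An object of class \code{chained_hit}: members (the chained HSP
#'   rows in chain order), \code{coverage} (total query bp), and
#'   \code{total_bits}.
#' @export
chain_hsps <- function(hsps) {
  if (is.null(hsps) || nrow(hsps) == 0)
    stop("chain_hsps: empty HSP set", call. = FALSE)
  if (length(unique(hsps$strand)) != 1)
    stop("chain_hsps: mixed strands; split by strand first", call. = FALSE)
  if (length(unique(hsps$query_id)) != 1 || length(unique(hsps$target_id)) != 1)
    stop("chain_hsps: HSPs must share one query-target pair", call. = FALSE)
  strand <- hsps$strand[1]
  ord <- order(hsps$q_start, hsps$q_end, hsps$t_start, hsps$t_end)
  h <- hsps[ord, , drop = FALSE]
  n <- nrow(h)
  qlen <- h$q_end - h$q_start

  compatible <- function(i, j) {
    if (h$q_end[i] > h$q_start[j]) return(FALSE)
    if (strand == "+") h$t_end[i] <= h$t_start[j] else h$t_start[i] >= h$t_end[j]
  }
  # TRUE if chain a (index vector into h) beats chain b
  better <- function(a, cov_a, bits_a, b, cov_b, bits_b) {
    if (cov_a != cov_b) return(cov_a > cov_b)
    if (bits_a != bits_b) return(bits_a > bits_b)
    if (length(a) != length(b)) return(length(a) < length(b))
    d <- which(a != b)
    if (length(d) == 0) return(FALSE)
    a[d[1]] < b[d[1]]
  }

  chains <- vector("list", n)
  cov <- numeric(n); bits <- numeric(n)
  for (j in seq_len(n)) {
    chains[[j]] <- j; cov[j] <- qlen[j]; bits[j] <- h$bit_score[j]
    if (j > 1) for (i in seq_len(j - 1L)) {
      if (!compatible(i, j)) next
      c_cov <- cov[i] + qlen[j]
      c_bits <- bits[i] + h$bit_score[j]
      cand <- c(chains[[i]], j)
      if (better(cand, c_cov, c_bits, chains[[j]], cov[j], bits[j])) {
        chains[[j]] <- cand; cov[j] <- c_cov; bits[j] <- c_bits
      }
    }
  }
  best <- 1L
  for (j in seq_len(n)) {
    if (better(chains[[j]], cov[j], bits[j], chains[[best]], cov[best], bits[best]))
      best <- j
  }
  members <- h[chains[[best]], , drop = FALSE]
  rownames(members) <- NULL
  structure(list(query_id = h$query_id[1], target_id = h$target_id[1],
                 strand = strand, members = members,
                 coverage = sum(members$q_end - members$q_start),
                 total_bits = sum(members$bit_score),
                 gene_id = NA_character_, coding_bp = NA_real_,
                 utr_bp = NA_real_),
            class = "chained_hit")
}

#' @export
print.chained_hit <- function(x, ...) {
  cat(sprintf("<chained_hit> %s -> %s (%s): %d HSPs, %d bp coverage, %.1f bits\n",
              x$query_id, x$target_id,
              if (is.na(x$gene_id)) x$strand else x$gene_id,
              nrow(x$members), x$coverage, x$total_bits))
  invisible(x)
}

#' Resolve the gene and coding/UTR split of a chained hit
#'
#' Attaches the target transcript's gene id and partitions the chain's
#' query coverage into bases aligned to the reference CDS versus the UTRs
#' (intersection of member target intervals with the CDS interval in
#' transcript coordinates).
#'
#' @param chain a [chain_hsps()] result whose target is a known transcript.
#' @param models named list of [gene_model()] objects (by transcript id).
#' @return The chain with \code{gene_id}, \code{coding_bp} and
#'   \code{utr_bp} filled in.
#' @export
resolve_gene <- function(chain, models) {
  m <- models[[chain$target_id]]
  if (is.null(m))
    stop(sprintf("resolve_gene: unknown transcript '%s'", chain$target_id),
         call. = FALSE)
  mem <- chain$members
  coding <- sum(vapply(seq_len(nrow(mem)), function(i) {
    interval_overlap(mem$t_start[i], mem$t_end[i], m$cds[1], m$cds[2])
  }, numeric(1)))
  chain$gene_id <- m$gene_id
  chain$coding_bp <- coding
  chain$utr_bp <- chain$coverage - coding
  chain
}

#' Classify an isotig's hits within one species as unique or ambiguous
#'
#' Chains hitting the same gene are first merged (the per-gene coverage and
#' bit-score are the maxima over its chains), so transcripts of one gene
#' never compete with each other.  The best gene (largest coverage, ties by
#' bits) is called \code{unique} if its coverage AND bit-score are each at
#' least \code{ratio} times those of every other gene; a lone gene is
#' unique; an empty input is a \code{no-hit}.
#'
#' @param chains list of gene-resolved [chain_hsps()] results for one query
#'   within one species.
#' @param ratio dominance ratio (default 2).
#' @return An object of class \code{unique_call} with \code{status} in
#'   \code{unique/ambiguous/no-hit}, the best and runner-up chains, and the
#'   coverage and bit-score ratios.
#' @export
classify_unique <- function(chains, ratio = 2.0) {
  if (length(chains) == 0) {
    return(structure(list(query_id = NA_character_, status = "no-hit",
                          best = NULL, runner_up = NULL,
                          size_ratio = NA_real_, bits_ratio = NA_real_),
                     class = "unique_call"))
  }
  genes <- vapply(chains, function(c) c$gene_id, character(1))
  if (anyNA(genes))
    stop("classify_unique: chains must be gene-resolved", call. = FALSE)
  per_gene <- lapply(split(seq_along(chains), genes), function(idx) {
    covs <- vapply(chains[idx], `[[`, numeric(1), "coverage")
    bits <- vapply(chains[idx], `[[`, numeric(1), "total_bits")
    rep_i <- idx[order(-covs, -bits)[1]]
    list(coverage = max(covs), bits = max(bits), chain = chains[[rep_i]])
  })
  covs <- vapply(per_gene, `[[`, numeric(1), "coverage")
  bits <- vapply(per_gene, `[[`, numeric(1), "bits")
  ord <- order(-covs, -bits, names(per_gene))
  best <- per_gene[[ord[1]]]
  if (length(per_gene) == 1) {
    return(structure(list(query_id = best$chain$query_id, status = "unique",
                          best = best$chain, runner_up = NULL,
                          size_ratio = Inf, bits_ratio = Inf),
                     class = "unique_call"))
  }
  others <- per_gene[ord[-1]]
  size_ratio <- best$coverage / max(vapply(others, `[[`, numeric(1), "coverage"))
  bits_ratio <- best$bits / max(vapply(others, `[[`, numeric(1), "bits"))
  status <- if (size_ratio >= ratio && bits_ratio >= ratio) "unique" else "ambiguous"
  structure(list(query_id = best$chain$query_id, status = status,
                 best = best$chain, runner_up = others[[1]]$chain,
                 size_ratio = size_ratio, bits_ratio = bits_ratio),
            class = "unique_call")
}

#' @export
print.unique_call <- function(x, ...) {
  cat(sprintf("<unique_call> %s: %s (size ratio %.2f, bits ratio %.2f)\n",
              x$query_id %||% "?", x$status, x$size_ratio, x$bits_ratio))
  invisible(x)
}

# Genomic footprint of a unique call: union of member target intervals
# projected onto the genome through the transcript's exon map.
call_footprint <- function(call, models) {
  m <- models[[call$best$target_id]]
  mem <- call$best$members
  pieces <- do.call(rbind, lapply(seq_len(nrow(mem)), function(i) {
    transcript_to_genomic(m, mem$t_start[i], mem$t_end[i])
  }))
  ir <- IRanges::reduce(IRanges::IRanges(pieces$g_start + 1L, pieces$g_end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

footprints_overlap <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (interval_overlap(a$start[i], a$end[i], b$start[j], b$end[j]) > 0)
      return(TRUE)
  }
  FALSE
}

#' Cluster unique isotigs by reference gene
#'
#' Groups unique calls of one species by their gene, picks the
#' largest-coverage isotig as the cluster representative, and greedily
#' selects a set of isotigs whose genomic footprints on the gene are
#' pairwise disjoint (largest coverage first), i.e. isotigs mapped to
#' different regions of the same gene.
#'
#' @param calls list of \code{unique_call} objects with status
#'   \code{unique}, all from one species.
#' @param models named list of [gene_model()] objects of that species.
#' @param species species label recorded on the clusters.
#' @return list of \code{gene_cluster} objects: \code{gene_id},
#'   \code{member_isotigs}, \code{representative}, \code{non_overlapping}.
#' @export
cluster_by_gene <- function(calls, models, species = "ref") {
  calls <- Filter(function(c) c$status == "unique", calls)
  if (length(calls) == 0) return(list())
  genes <- vapply(calls, function(c) c$best$gene_id, character(1))
  lapply(split(seq_along(calls), genes), function(idx) {
    cs <- calls[idx]
    covs <- vapply(cs, function(c) c$best$coverage, numeric(1))
    bits <- vapply(cs, function(c) c$best$total_bits, numeric(1))
    ids <- vapply(cs, function(c) c$query_id, character(1))
    ord <- order(-covs, -bits, ids)
    accepted <- integer(0)
    fps <- lapply(cs, call_footprint, models = models)
    for (k in ord) {
      clash <- any(vapply(accepted, function(a) footprints_overlap(fps[[k]], fps[[a]]),
                          logical(1)))
      if (!clash) accepted <- c(accepted, k)
    }
    structure(list(species = species, gene_id = cs[[1]]$best$gene_id,
                   member_isotigs = ids[ord], representative = ids[ord[1]],
                   non_overlapping = ids[accepted]),
              class = "gene_cluster")
  })
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("<gene_cluster> %s (%s): %d isotigs, representative %s, %d non-overlapping\n",
              x$gene_id, x$species, length(x$member_isotigs),
              x$representative, length(x$non_overlapping)))
  invisible(x)
}

#' Assign the orthology-consistency category of an isotig
#'
#' Given the isotig's unique gene hit in each of three reference species
#' (\code{NA} where the call was ambiguous or no-hit), looks the genes up
#' in the orthology table and classifies: category 3 when all three genes
#' share one ortholog group, category 2 when exactly one species pair
#' shares a group, category 1 otherwise.  Missing species and genes with
#' no ortholog group never match.
#'
#' @param isotig_id query identifier.
#' @param gene_by_species named character vector (species -> gene id, NA
#'   for no unique hit); at least one non-NA entry required.
#' @param orthology orthology data frame as from [read_orthology()].
#' @param coding_bp,utr_bp coding/UTR split of the reference-species chain,
#'   used to derive \code{coding_portion} and \code{aligned_total}.
#' @return list of class \code{category_call}: \code{category} in 1..3,
#'   the per-species genes and groups, \code{coding_portion} and
#'   \code{aligned_total}.
#' @export
assign_category <- function(isotig_id, gene_by_species, orthology,
                            coding_bp = NA_real_, utr_bp = NA_real_) {
  if (all(is.na(gene_by_species)))
    stop("assign_category: no species with a unique call", call. = FALSE)
  groups <- vapply(names(gene_by_species), function(sp) {
    g <- gene_by_species[[sp]]
    if (is.na(g)) return(NA_character_)
    hit <- orthology$ortholog_group[orthology$species == sp &
                                    orthology$gene_id == g]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  ok <- !is.na(groups)
  category <- 1L
  if (sum(ok) >= 3 && length(unique(groups[ok])) == 1 && sum(ok) == length(groups)) {
    category <- 3L
  } else {
    # any pair sharing a group -> category 2
    tab <- table(groups[ok])
    if (any(tab >= 2)) category <- 2L
  }
  portion <- if (!is.na(coding_bp) && (coding_bp + utr_bp) > 0)
    coding_bp / (coding_bp + utr_bp) else NA_real_
  structure(list(isotig_id = isotig_id, gene_by_species = gene_by_species,
                 group_by_species = groups, category = category,
                 coding_portion = portion,
                 aligned_total = if (is.na(coding_bp)) NA_real_ else coding_bp + utr_bp),
            class = "category_call")
}

#' @export
print.category_call <- function(x, ...) {
  cat(sprintf("<category_call> %s: category %d (portion %.2f, %s bp aligned)\n",
              x$isotig_id, x$category, x$coding_portion,
              format(x$aligned_total)))
  invisible(x)
}

#' Per-category profiles of coding portion and aligned size
#'
#' Tabulates, per orthology category, the coding portion
#' (\code{coding_bp / (coding_bp + utr_bp)}) in quarter bins and the total
#' aligned size in the bins <400, 400-800, 800-1600, >=1600 bp.
#'
#' @param calls list of [assign_category()] results.
#' @return list with two category x bin contingency tables,
#'   \code{portion} and \code{size}.
#' @export
utr_profile <- function(calls) {
  cat_f <- factor(vapply(calls, `[[`, integer(1), "category"), levels = 1:3)
  portion <- vapply(calls, `[[`, numeric(1), "coding_portion")
  total <- vapply(calls, `[[`, numeric(1), "aligned_total")
  pbin <- cut(portion, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
              labels = c("<0.25", "0.25-0.5", "0.5-0.75", ">=0.75"),
              right = FALSE)
  sbin <- cut(total, breaks = c(-Inf, 400, 800, 1600, Inf),
              labels = c("<400", "400-800", "800-1600", ">=1600"),
              right = FALSE)
  list(portion = table(category = cat_f, portion = pbin),
       size = table(category = cat_f, size = sbin))
}
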