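# Independent oracles used by the test suite.  These re-derive expected
# results by brute force (exhaustive enumeration, independent DP), never by
# calling the code paths they check.

# ---- brute-force chain search -------------------------------------------
# Enumerate every subset of HSPs, keep the colinear, query- and
# target-disjoint ones, and pick the best under the same tie-break order as
# the chainer: coverage desc, bits desc, fewer members, lexicographic
# member indices (in canonical q_start order).
brute_force_chain <- function(hsps) {
  ord <- order(hsps$q_start, hsps$q_end, hsps$t_start, hsps$t_end)
  h <- hsps[ord, , drop = FALSE]
  n <- nrow(h)
  strand <- h$strand[1]
  valid <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    for (a in seq_len(length(idx) - 1L)) {
      i <- idx[a]; j <- idx[a + 1L]
      if (h$q_end[i] > h$q_start[j]) return(FALSE)
      ok <- if (strand == "+") h$t_end[i] <= h$t_start[j]
            else h$t_start[i] >= h$t_end[j]
      if (!ok) return(FALSE)
    }
    TRUE
  }
  best <- NULL; best_cov <- -1; best_bits <- -1
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) == 0 || !valid(idx)) next
    cov <- sum(h$q_end[idx] - h$q_start[idx])
    bits <- sum(h$bit_score[idx])
    replace <- is.null(best) || cov > best_cov ||
      (cov == best_cov && bits > best_bits) ||
      (cov == best_cov && bits == best_bits && length(idx) < length(best)) ||
      (cov == best_cov && bits == best_bits && length(idx) == length(best) &&
         lex_less(idx, best))
    if (replace) { best <- idx; best_cov <- cov; best_bits <- bits }
  }
  list(members = h[best, , drop = FALSE], coverage = best_cov,
       total_bits = best_bits)
}

lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

# Random HSP instance; small coordinate universe and quantized scores
# provoke ties so the tie-break order is exercised too.
random_hsp_set <- function(n, strand = "+") {
  q_start <- sample(0:200, n, replace = TRUE)
  q_len <- sample(c(20L, 40L, 60L, 80L), n, replace = TRUE)
  t_start <- sample(0:400, n, replace = TRUE)
  data.frame(query_id = "q", target_id = "t",
             q_start = q_start, q_end = q_start + q_len,
             t_start = t_start, t_end = t_start + q_len,
             strand = strand, pct_identity = 95,
             bit_score = q_len * sample(c(1, 2), n, replace = TRUE),
             e_value = 1e-10, stringsAsFactors = FALSE)
}

# ---- independent affine-gap alignment DP --------------------------------
# Gap of length k costs open + k * ext (the aligner's convention).  Global
# alignment of a vs b by a three-state DP written independently of the
# package's aligner.
affine_global_score <- function(a, b, match = 2, mismatch = -3,
                                open = 12, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Iy[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Best semi-global score: pattern global, subject consumed locally
# (maximum over all subject substrings).
semi_global_oracle <- function(pattern, subject, ...) {
  m <- nchar(subject)
  best <- -Inf
  for (i in seq_len(m)) for (j in (i - 1L):m) {
    sub <- if (j < i) "" else substr(subject, i, j)
    if (!nzchar(sub)) next
    best <- max(best, affine_global_score(pattern, sub, ...))
  }
  best
}

# Reference-protein oracle: translate a CDS nucleotide string directly and
# cut at the first stop (independent of the projection machinery).
translate_protein_oracle <- function(cds_seq) {
  n <- 3L * (nchar(cds_seq) %/% 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds_seq, 1, n)), if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}

# In-frame stop-free insert, built directly from a fixed codon pool.
orf_preserving_insert_oracle <- function(len) {
  stopifnot(len %% 3 == 0)
  pool <- c("GCT", "TGC", "GAT", "GAA", "TTC", "GGA", "CAT", "ATA", "AAA",
            "CTG", "ATG", "AAC", "CCG", "CAA", "CGT", "AGC", "ACT", "GTA")
  paste(sample(pool, len / 3, replace = TRUE), collapse = "")
}

# ---- shared tiny fixtures ------------------------------------------------
make_hsp <- function(qs, qe, ts, te, bits = (qe - qs) * 2, strand = "+",
                     query = "q", target = "t") {
  data.frame(query_id = query, target_id = target, q_start = qs, q_end = qe,
             t_start = ts, t_end = te, strand = strand, pct_identity = 98,
             bit_score = bits, e_value = 1e-30, stringsAsFactors = FALSE)
}

# Minimal single-exon gene model on its own contig.
make_model <- function(tid = "t", gid = "g", species = "mouse", seq = NULL,
                       len = 600L, cds = c(100L, 400L)) {
  if (is.null(seq)) seq <- paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                 collapse = "")
  gene_model(tid, gid, species, chrom = paste0(species, "_ctg_", gid),
             exons = data.frame(g_start = 0L, g_end = nchar(seq),
                                t_start = 0L, t_end = nchar(seq)),
             cds = cds, transcript_seq = seq)
}

# A chained hit made directly from HSP rows (bypasses the chainer; for
# modules downstream of chaining).
make_chain <- function(hsps, gene_id = NA_character_) {
  structure(list(query_id = hsps$query_id[1], target_id = hsps$target_id[1],
                 strand = hsps$strand[1], members = hsps,
                 coverage = sum(hsps$q_end - hsps$q_start),
                 total_bits = sum(hsps$bit_score), gene_id = gene_id,
                 coding_bp = NA_real_, utr_bp = NA_real_),
            class = "chained_hit")
}

# Hand-built read stack: reads tile [0, len) at the given depth with no
# planted variation; columns can then be edited by the caller.
uniform_stack <- function(consensus, depth, read_len = 20L,
                          library = "C.1") {
  L <- nchar(consensus)
  rl <- min(read_len, L)
  rows <- list()
  for (i in seq_len(depth)) {
    o <- floor((i - 1L) * rl / depth)
    for (s in seq(o - rl, L - 1L, by = rl)) {
      s0 <- max(s, 0L); e0 <- min(s + rl, L)
      if (e0 <= s0) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("r%03d_%03d", i, s0), offset = s0, strand = "+",
        library = library, seq = substr(consensus, s0 + 1L, e0),
        stringsAsFactors = FALSE)
    }
  }
  isotig_assembly("iso_test", consensus, do.call(rbind, rows))
}

# Put base `b` into `k` of the reads covering column `pos` (0-based).
plant_allele <- function(assembly, pos, b, k) {
  rd <- assembly$reads
  cov <- which(rd$offset <= pos & pos < rd$offset + nchar(rd$seq))
  stopifnot(length(cov) >= k)
  for (j in cov[seq_len(k)]) {
    off <- pos - rd$offset[j]
    substr(rd$seq[j], off + 1L, off + 1L) <- b
  }
  assembly$reads <- rd
  assembly
}
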