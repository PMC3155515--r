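# Readers and writers for the external formats the pipeline touches.
#
# Internal convention: all coordinates are 0-based half-open.  Conversion to
# the 1-based inclusive conventions of BLAST tabular and GFF3 happens only
# here, at the file boundary.

# ---------------------------------------------------------------------------
# BLAST tabular (12-column outfmt-6)

#' Read a BLAST tabular hit file
#'
#' Parses 12-column tab-separated local-alignment hits (the classic
#' \code{outfmt 6} dialect: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore).  Coordinates are converted to
#' 0-based half-open; hits with \code{sstart > send} become minus-strand
#' hits with ascending target coordinates.
#'
#' @param path file path.
#' @return A data frame of HSPs with columns \code{query_id, target_id,
#'   q_start, q_end, t_start, t_end, strand, pct_identity, bit_score,
#'   e_value}.
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  out <- empty_hsp_frame()
  if (!any(keep)) return(out)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop_parse(path, idx[bad], sprintf("expected 12 columns, found %d", nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, c(7:10, 3, 11, 12), drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 7L)
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1]
    stop_parse(path, idx[bad], "non-numeric coordinate or score field")
  }
  qs <- num[, 1]; qe <- num[, 2]; ss <- num[, 3]; se <- num[, 4]
  minus <- ss > se
  data.frame(
    query_id = m[, 1], target_id = m[, 2],
    q_start = as.integer(qs - 1), q_end = as.integer(qe),
    t_start = as.integer(ifelse(minus, se, ss) - 1),
    t_end = as.integer(ifelse(minus, ss, se)),
    strand = ifelse(minus, "-", "+"),
    pct_identity = num[, 5], bit_score = num[, 7], e_value = num[, 6],
    stringsAsFactors = FALSE
  )
}

empty_hsp_frame <- function() {
  data.frame(query_id = character(), target_id = character(),
             q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(), strand = character(),
             pct_identity = numeric(), bit_score = numeric(),
             e_value = numeric(), stringsAsFactors = FALSE)
}

#' Write HSPs as BLAST tabular
#'
#' Inverse of [read_blast_tabular()]: 0-based half-open internal coordinates
#' are emitted 1-based inclusive, minus-strand hits with swapped target ends.
#'
#' @param hsps HSP data frame.
#' @param path output path.
#' @export
write_blast_tabular <- function(hsps, path) {
  minus <- hsps$strand == "-"
  qlen <- hsps$q_end - hsps$q_start
  mism <- as.integer(round(qlen * (1 - hsps$pct_identity / 100)))
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2g\t%.1f",
                   hsps$query_id, hsps$target_id, hsps$pct_identity,
                   qlen, mism, 0L,
                   hsps$q_start + 1L, hsps$q_end,
                   ifelse(minus, hsps$t_end, hsps$t_start + 1L),
                   ifelse(minus, hsps$t_start + 1L, hsps$t_end),
                   hsps$e_value, hsps$bit_score)
  atomic_writelines(lines, path)
}

# ---------------------------------------------------------------------------
# ACE assemblies

#' Assembly container for one isotig
#'
#' Holds the consensus sequence and the placed reads of one assembled
#' isotig: the substrate of the pileup-based SNP caller.
#'
#' @param isotig_id consensus identifier.
#' @param consensus consensus nucleotide string (A/C/G/T/N).
#' @param reads data frame with columns \code{read_id}, \code{offset}
#'   (0-based start on the consensus), \code{strand} (\code{"+"} or
#'   \code{"-"}), \code{library} (\code{C.1}\dots\code{C.4}) and \code{seq}
#'   (read sequence in sequencing orientation).
#' @return An object of class \code{isotig_assembly}.
#' @export
isotig_assembly <- function(isotig_id, consensus, reads) {
  if (nrow(reads) > 0) {
    if (any(grepl("[^ACGTN]", c(consensus, reads$seq))))
      stop("only A/C/G/T/N are accepted in consensus and reads", call. = FALSE)
    if (any(reads$offset < 0L | reads$offset + nchar(reads$seq) > nchar(consensus)))
      stop("read extends past consensus bounds", call. = FALSE)
    if (!all(reads$library %in% paste0("C.", 1:4)))
      stop("library tag must be one of C.1-C.4", call. = FALSE)
  }
  structure(list(isotig_id = isotig_id, consensus = consensus, reads = reads),
            class = "isotig_assembly")
}

#' @export
print.isotig_assembly <- function(x, ...) {
  cat(sprintf("<isotig_assembly> %s: %d bp consensus, %d reads\n",
              x$isotig_id, nchar(x$consensus), nrow(x$reads)))
  invisible(x)
}

empty_read_frame <- function() {
  data.frame(read_id = character(), offset = integer(), strand = character(),
             library = character(), seq = character(), stringsAsFactors = FALSE)
}

#' Read assemblies from an ACE file
#'
#' Auto-detects the dialect from the first record: either the package's
#' minimal dialect (\code{CO id len nreads} followed by the consensus, then
#' \code{RD id offset strand library} lines each followed by the read
#' sequence) or classic assembler ACE (\code{AS}/\code{CO}/\code{AF}/
#' \code{RD} records with pad characters \code{*}).  Pads are stripped and
#' offsets adjusted, so all returned coordinates are unpadded.
#'
#' @param path file path.
#' @return A list of [isotig_assembly()] objects.
#' @export
read_ace <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | TRUE]  # keep blanks: record separators
  first <- ""
  for (l in lines) {
    if (nzchar(trimws(l))) { first <- strsplit(trimws(l), "\\s+")[[1]][1]; break }
  }
  if (first == "AS") return(read_ace_classic(lines, path))
  if (first == "CO") {
    tok <- strsplit(trimws(lines[which(nzchar(trimws(lines)))[1]]), "\\s+")[[1]]
    if (length(tok) >= 6) return(read_ace_classic(lines, path))
    return(read_ace_minimal(lines, path))
  }
  stop_parse(path, 1L, "not an ACE file (expected AS or CO record)")
}

read_ace_minimal <- function(lines, path) {
  out <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    l <- trimws(lines[i])
    if (!nzchar(l)) { i <- i + 1L; next }
    tok <- strsplit(l, "\\s+")[[1]]
    if (tok[1] != "CO") stop_parse(path, i, "expected CO record")
    if (length(tok) != 4L) stop_parse(path, i, "CO line needs: CO id len nreads")
    iso_id <- tok[2]; clen <- as.integer(tok[3]); nreads <- as.integer(tok[4])
    i <- i + 1L
    cons <- ""
    while (i <= n && nchar(cons) < clen) {
      if (grepl("^(CO|RD)\\b", lines[i])) stop_parse(path, i, "consensus shorter than declared")
      cons <- paste0(cons, trimws(lines[i])); i <- i + 1L
    }
    if (nchar(cons) != clen) stop_parse(path, i, "consensus length mismatch")
    reads <- vector("list", nreads)
    for (r in seq_len(nreads)) {
      while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (tok[1] != "RD" || length(tok) != 5L)
        stop_parse(path, i, "RD line needs: RD id offset strand library")
      i <- i + 1L
      seq <- ""
      while (i <= n && nzchar(trimws(lines[i])) && !grepl("^(CO|RD)\\b", lines[i])) {
        seq <- paste0(seq, trimws(lines[i])); i <- i + 1L
      }
      reads[[r]] <- data.frame(read_id = tok[2], offset = as.integer(tok[3]),
                               strand = tok[4], library = tok[5], seq = seq,
                               stringsAsFactors = FALSE)
    }
    reads <- if (nreads > 0) do.call(rbind, reads) else empty_read_frame()
    out[[iso_id]] <- isotig_assembly(iso_id, cons, reads)
  }
  out
}

# Classic ACE: AS / CO <name> <len> <nreads> <nsegs> <U|C>, padded consensus,
# AF <read> <U|C> <padded 1-based offset>, RD <read> <len> ... + padded seq.
read_ace_classic <- function(lines, path) {
  out <- list()
  i <- 1L; n <- length(lines)
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    # strip consensus pads, shifting read offsets left past removed columns
    padpos <- which(strsplit(cur$cons, "", fixed = TRUE)[[1]] == "*")
    unpadded <- gsub("*", "", cur$cons, fixed = TRUE)
    af <- cur$af
    rd <- cur$rd
    reads <- lapply(names(rd), function(id) {
      if (is.null(af[[id]])) stop(sprintf("%s: read %s has RD but no AF", path, id), call. = FALSE)
      off1 <- af[[id]]$offset                      # 1-based, padded
      off0 <- off1 - 1L - sum(padpos < off1)       # 0-based, unpadded
      seq <- gsub("*", "", rd[[id]], fixed = TRUE)
      # classic ACE stores complemented reads in assembly orientation;
      # internally reads are kept in sequencing orientation
      if (af[[id]]$comp) seq <- revcomp(seq)
      data.frame(read_id = id, offset = off0,
                 strand = if (af[[id]]$comp) "-" else "+",
                 library = af[[id]]$library, seq = seq, stringsAsFactors = FALSE)
    })
    reads <- if (length(reads)) do.call(rbind, reads) else empty_read_frame()
    isotig_assembly(cur$id, unpadded, reads)
  }
  while (i <= n) {
    l <- trimws(lines[i])
    if (!nzchar(l)) { i <- i + 1L; next }
    tok <- strsplit(l, "\\s+")[[1]]
    if (tok[1] == "AS") { i <- i + 1L; next }
    if (tok[1] == "CO") {
      a <- flush(cur); if (!is.null(a)) out[[a$isotig_id]] <- a
      clen <- as.integer(tok[3])
      i <- i + 1L
      cons <- ""
      while (i <= n && nchar(cons) < clen && nzchar(trimws(lines[i]))) {
        cons <- paste0(cons, trimws(lines[i])); i <- i + 1L
      }
      if (nchar(cons) != clen) stop_parse(path, i, "padded consensus length mismatch")
      cur <- list(id = tok[2], cons = cons, af = list(), rd = list())
      next
    }
    if (tok[1] == "BQ") {  # skip quality block
      i <- i + 1L
      while (i <= n && !grepl("^(AF|RD|CO|BS)\\b", lines[i])) i <- i + 1L
      next
    }
    if (tok[1] == "BS") { i <- i + 1L; next }
    if (tok[1] == "AF") {
      lib <- if (length(tok) >= 5) tok[5] else "C.1"  # library tag: extension field
      cur$af[[tok[2]]] <- list(comp = tok[3] == "C", offset = as.integer(tok[4]),
                               library = lib)
      i <- i + 1L; next
    }
    if (tok[1] == "RD") {
      rlen <- as.integer(tok[3])
      i <- i + 1L
      seq <- ""
      while (i <= n && nchar(seq) < rlen && nzchar(trimws(lines[i]))) {
        seq <- paste0(seq, trimws(lines[i])); i <- i + 1L
      }
      if (nchar(seq) != rlen) stop_parse(path, i, "padded read length mismatch")
      cur$rd[[tok[2]]] <- seq
      next
    }
    i <- i + 1L  # QA, DS, WA... ignored
  }
  a <- flush(cur); if (!is.null(a)) out[[a$isotig_id]] <- a
  out
}

#' Write assemblies in the minimal ACE dialect
#'
#' @param assemblies list of [isotig_assembly()] objects.
#' @param path output path.
#' @export
write_ace <- function(assemblies, path) {
  blocks <- vapply(assemblies, function(a) {
    hdr <- sprintf("CO %s %d %d", a$isotig_id, nchar(a$consensus), nrow(a$reads))
    body <- wrap_seq(a$consensus)
    rd <- character(0)
    if (nrow(a$reads) > 0) {
      rd <- unlist(lapply(seq_len(nrow(a$reads)), function(j) {
        r <- a$reads[j, ]
        c(sprintf("RD %s %d %s %s", r$read_id, r$offset, r$strand, r$library),
          wrap_seq(r$seq))
      }))
    }
    paste(c(hdr, body, rd), collapse = "\n")
  }, character(1))
  atomic_writelines(blocks, path)
}

wrap_seq <- function(seq, width = 60L) {
  starts <- seq(1L, nchar(seq), by = width)
  substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
}

# ---------------------------------------------------------------------------
# Gene models (GFF3 + transcript FASTA)

#' Reference gene model
#'
#' One transcript of one species: genomic exon layout, the CDS interval in
#' transcript coordinates, the transcript sequence, and an ortholog-group
#' label.  All coordinates 0-based half-open; only plus-strand models are
#' supported (the generator emits one contig per gene).
#'
#' @param transcript_id,gene_id,species identifiers.
#' @param chrom contig the exons live on.
#' @param exons data frame with genomic \code{g_start,g_end} and transcript
#'   \code{t_start,t_end} columns, one row per exon in transcript order.
#' @param cds length-2 integer vector: CDS interval in transcript
#'   coordinates.
#' @param transcript_seq transcript nucleotide string.
#' @param ortholog_group group label or \code{NA}.
#' @return An object of class \code{gene_model}.
#' @export
gene_model <- function(transcript_id, gene_id, species, chrom, exons, cds,
                       transcript_seq, ortholog_group = NA_character_) {
  tlen <- nchar(transcript_seq)
  if (sum(exons$g_end - exons$g_start) != tlen)
    stop(sprintf("%s: exon lengths do not sum to transcript length", transcript_id),
         call. = FALSE)
  if (cds[1] < 0 || cds[2] > tlen || cds[1] >= cds[2])
    stop(sprintf("%s: CDS outside transcript", transcript_id), call. = FALSE)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 species = species, chrom = chrom, exons = exons, cds = cds,
                 transcript_seq = transcript_seq,
                 ortholog_group = ortholog_group),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s): %d exons, %d bp, CDS [%d,%d)\n",
              x$transcript_id, x$gene_id, x$species, nrow(x$exons),
              nchar(x$transcript_seq), x$cds[1], x$cds[2]))
  invisible(x)
}

# Map a transcript-coordinate interval to genomic intervals via the exon map.
transcript_to_genomic <- function(model, t_start, t_end) {
  ex <- model$exons
  pieces <- lapply(seq_len(nrow(ex)), function(i) {
    ov <- interval_overlap(t_start, t_end, ex$t_start[i], ex$t_end[i])
    if (ov == 0) return(NULL)
    s <- max(t_start, ex$t_start[i]); e <- min(t_end, ex$t_end[i])
    data.frame(g_start = ex$g_start[i] + (s - ex$t_start[i]),
               g_end = ex$g_start[i] + (e - ex$t_start[i]))
  })
  do.call(rbind, c(pieces, list(data.frame(g_start = integer(), g_end = integer()))))
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS features, 1-based inclusive, one file for one
#' species panel.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gff3_models <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    ex <- m$exons
    gspan <- c(min(ex$g_start), max(ex$g_end))
    attr_gene <- sprintf("ID=%s", m$gene_id)
    if (!is.na(m$ortholog_group))
      attr_gene <- paste0(attr_gene, ";ortholog_group=", m$ortholog_group)
    lines <- c(lines,
      sprintf("%s\tisotigr\tgene\t%d\t%d\t.\t+\t.\t%s",
              m$chrom, gspan[1] + 1L, gspan[2], attr_gene),
      sprintf("%s\tisotigr\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
              m$chrom, gspan[1] + 1L, gspan[2], m$transcript_id, m$gene_id),
      sprintf("%s\tisotigr\texon\t%d\t%d\t.\t+\t.\tParent=%s",
              m$chrom, ex$g_start + 1L, ex$g_end, m$transcript_id))
    cdsg <- transcript_to_genomic(m, m$cds[1], m$cds[2])
    phase <- cumsum(c(0L, cdsg$g_end - cdsg$g_start))
    lines <- c(lines,
      sprintf("%s\tisotigr\tCDS\t%d\t%d\t.\t+\t%d\tParent=%s",
              m$chrom, cdsg$g_start + 1L, cdsg$g_end,
              (3L - utils::head(phase, -1L) %% 3L) %% 3L, m$transcript_id))
  }
  atomic_writelines(lines, path)
}

#' Read gene models from GFF3 plus a transcript FASTA
#'
#' @param gff_path GFF3 with gene/mRNA/exon/CDS features.
#' @param fasta_path transcript FASTA named by transcript id.
#' @param species species label attached to the models.
#' @param orthology optional orthology table used to fill in ortholog
#'   groups; groups in GFF3 \code{ortholog_group} attributes win.
#' @return named list of [gene_model()] objects (by transcript id).
#' @export
read_gff3_models <- function(gff_path, fasta_path, species = "ref",
                             orthology = NULL) {
  gr <- rtracklayer::import(gff_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  df <- as.data.frame(gr)
  df$Parent <- vapply(as.list(df$Parent %||% list()), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  mrna <- df[df$type == "mRNA", ]
  if (anyDuplicated(mrna$ID))
    stop(sprintf("%s: duplicate transcript ids", gff_path), call. = FALSE)
  genes <- df[df$type == "gene", ]
  models <- list()
  for (i in seq_len(nrow(mrna))) {
    tid <- mrna$ID[i]; gid <- mrna$Parent[i]
    ex <- df[df$type == "exon" & df$Parent == tid, ]
    ex <- ex[order(ex$start), ]
    if (any(ex$strand == "-"))
      stop(sprintf("%s: minus-strand gene models are not supported", gff_path),
           call. = FALSE)
    g_start <- ex$start - 1L; g_end <- ex$end
    t_end <- cumsum(g_end - g_start)
    t_start <- c(0L, utils::head(t_end, -1L))
    exons <- data.frame(g_start = g_start, g_end = g_end,
                        t_start = t_start, t_end = t_end)
    cds <- df[df$type == "CDS" & df$Parent == tid, ]
    cds <- cds[order(cds$start), ]
    # genomic CDS back to transcript coordinates through the exon map
    g2t <- function(g) {
      j <- which(exons$g_start <= g & g <= exons$g_end)[1]
      exons$t_start[j] + (g - exons$g_start[j])
    }
    cds_t <- c(g2t(min(cds$start) - 1L), g2t(max(cds$end)))
    if (!tid %in% names(seqs))
      stop(sprintf("%s: transcript %s missing from FASTA", fasta_path, tid),
           call. = FALSE)
    og <- NA_character_
    gi <- which(genes$ID == gid)
    if (length(gi) && "ortholog_group" %in% names(genes) &&
        !is.na(genes$ortholog_group[gi[1]]))
      og <- genes$ortholog_group[gi[1]]
    if (is.na(og) && !is.null(orthology)) {
      hit <- orthology$ortholog_group[orthology$species == species &
                                      orthology$gene_id == gid]
      if (length(hit)) og <- hit[1]
    }
    models[[tid]] <- gene_model(tid, gid, species, chrom = as.character(ex$seqnames[1]),
                                exons = exons, cds = cds_t,
                                transcript_seq = as.character(seqs[[tid]]),
                                ortholog_group = og)
  }
  models
}

# ---------------------------------------------------------------------------
# Orthology, counts, GMT, FASTA, TSV

#' Read an orthology table
#'
#' Three tab-separated columns with a header: \code{gene_id}, \code{species},
#' \code{ortholog_group}.  A gene may map to at most one group per species.
#'
#' @param path file path.
#' @export
read_orthology <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "ortholog_group")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: orthology table needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  key <- paste(tab$species, tab$gene_id)
  if (anyDuplicated(key)) {
    groups_per_key <- tapply(tab$ortholog_group, key, function(g) length(unique(g)))
    if (any(groups_per_key > 1))
      stop(sprintf("%s: conflicting ortholog groups for a (species, gene) pair", path),
           call. = FALSE)
    tab <- tab[!duplicated(key), ]
    rownames(tab) <- NULL
  }
  tab[, need]
}

#' Write an orthology table
#' @param tab orthology data frame.
#' @param path output path.
#' @export
write_orthology <- function(tab, path) {
  atomic_write_table(tab[, c("gene_id", "species", "ortholog_group")], path)
}

#' Read a per-gene read-count table
#'
#' Tab-separated with header \code{gene_id n1 n2 n3 n4} and a second row
#' \code{__totals__} carrying the per-library read totals N1..N4.
#'
#' @param path file path.
#' @return data frame of per-gene counts with a numeric \code{totals}
#'   attribute of length 4.
#' @export
read_counts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), c("gene_id", "n1", "n2", "n3", "n4")))
    stop(sprintf("%s: count table needs columns gene_id n1 n2 n3 n4", path),
         call. = FALSE)
  ti <- which(tab$gene_id == "__totals__")
  if (length(ti) != 1)
    stop(sprintf("%s: missing __totals__ row", path), call. = FALSE)
  totals <- as.numeric(tab[ti, -1])
  tab <- tab[-ti, , drop = FALSE]
  rownames(tab) <- NULL
  if (any(colSums(tab[, -1]) > totals))
    stop(sprintf("%s: library totals smaller than column sums", path), call. = FALSE)
  attr(tab, "totals") <- totals
  tab
}

#' Write a per-gene read-count table
#' @param counts count data frame with a \code{totals} attribute.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  totals <- attr(counts, "totals")
  if (is.null(totals)) totals <- colSums(counts[, c("n1", "n2", "n3", "n4")])
  top <- data.frame(gene_id = "__totals__", n1 = totals[1], n2 = totals[2],
                    n3 = totals[3], n4 = totals[4])
  atomic_write_table(rbind(top, counts[, c("gene_id", "n1", "n2", "n3", "n4")]),
                     path)
}

#' Read a GMT gene-set file
#'
#' @param path file path (term, description, member genes per line).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read / write FASTA
#'
#' Thin wrappers with 60-column wrapping and name truncation at whitespace.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  tmp <- paste0(path, ".tmp")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), tmp, width = 60L)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a tab-separated table (atomically)
#'
#' Partial output is written to a temporary path and renamed only on
#' success, so a crash never leaves a truncated result file.
#'
#' @param records data frame.
#' @param path output path.
#' @export
write_tsv <- function(records, path) {
  atomic_write_table(records, path)
}

atomic_write_table <- function(tab, path) {
  tmp <- paste0(path, ".tmp")
  write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

atomic_writelines <- function(lines, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}
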