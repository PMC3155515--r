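# Synthetic-data generator: reference panels, isotigs, read stacks, hit
# tables and count tables with planted, recorded ground truth.  Every
# downstream stage of the pipeline is testable against the truth set,
# without any external download or aligner run.
#
# Modelling choices: novel inserts are uniform-random sequence (50% GC), so
# they have no homology to the references by construction; reads are
# error-free except planted alleles and injected Ns, isolating the SNP
# filter logic from base-error modelling; species copies of a transcript
# are diverged by independent per-site substitution, half the nominal
# divergence per species, so that any two homologous copies differ at about
# the nominal rate.

SPECIES_DEFAULT <- c("mouse", "rat", "human")  # pseudo-species labels

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Configuration of the synthetic-data generator
#'
#' All coordinates and lengths in bp, all fractions in \code{[0,1]}.
#' Defaults emulate the scale of a normalized four-library transcriptome
#' study: transcripts averaging around 1.6 kb, per-column read depths in
#' the 8-40 range, planted biallelic sites at 2 per kb with minor-allele
#' fractions 0.3-0.5, and non-conserved inserts of at least 60 bp.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_genes number of genes in the panel.
#' @param n_species number of pseudo-species (<= 3; labelled
#'   pseudo-mouse/rat/human).
#' @param exon_len_range,n_exons_range,intron_len_range gene structure.
#' @param utr5_len,utr3_len UTR lengths on the transcript.
#' @param substitution_divergence expected per-site difference between two
#'   homologous transcript copies.
#' @param snp_rate planted biallelic sites per kb of isotig.
#' @param ti_fraction probability that a planted substitution is a
#'   transition (A<->G / C<->T); transcriptome variation is strongly
#'   transition-biased, so the default plants about three transitions per
#'   transversion.
#' @param minor_allele_frac_range planted minor-allele fraction interval.
#' @param depth_range per-isotig read depth interval (reads per column).
#' @param read_len simulated read length.
#' @param n_rate per-base probability of an injected ambiguous 'N' in a
#'   read (never at a planted site or its immediate flanks).
#' @param novel_insert_len_range planted insert length interval (min >= 50).
#' @param frac_novel_isotigs fraction of isotigs receiving one planted
#'   non-conserved insert.
#' @param frac_intron_retention among planted junction inserts, the
#'   fraction copied from the focal species' intervening intron instead of
#'   random sequence (intron-contamination controls; the realignment
#'   filter must reject them).
#' @param frac_splice_variants fraction of multi-exon genes emitting a
#'   second isotig with one internal exon skipped.
#' @param frac_partial fraction of isotigs copying only part of their
#'   source transcript.
#' @param frac_withheld fraction of genes withheld from one non-focal
#'   species (no transcript, no orthology row).
#' @param frac_reassigned fraction of genes whose ortholog group in one
#'   non-focal species is replaced by a fresh group.
#' @param library_weights four nonnegative sampling weights for libraries
#'   C.1-C.4.
#' @param mean_gene_count expected total read count of a gene across the
#'   four libraries.
#' @param frac_de,de_lfc,de_contrast planted differential expression:
#'   fraction of genes, log2 fold factor, and the (a, b) library pair of
#'   the contrast (the factor multiplies library a's weight).
#' @param decoy_ratio if not \code{NA}, each isotig's hit table gains a
#'   decoy paralog hit whose coverage and bit-score are this ratio of the
#'   true hit's.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 30L,
                       n_species = 3L,
                       exon_len_range = c(150L, 450L),
                       n_exons_range = c(3L, 8L),
                       intron_len_range = c(200L, 600L),
                       utr5_len = 90L,
                       utr3_len = 240L,
                       substitution_divergence = 0.05,
                       snp_rate = 2,
                       ti_fraction = 0.73,
                       minor_allele_frac_range = c(0.3, 0.5),
                       depth_range = c(8L, 40L),
                       read_len = 100L,
                       n_rate = 0,
                       novel_insert_len_range = c(60L, 300L),
                       frac_novel_isotigs = 0.2,
                       frac_intron_retention = 0,
                       frac_splice_variants = 0.2,
                       frac_partial = 0.1,
                       frac_withheld = 0.1,
                       frac_reassigned = 0.1,
                       library_weights = c(1, 1, 1, 1),
                       mean_gene_count = 100,
                       frac_de = 0.1,
                       de_lfc = 2,
                       de_contrast = c(1L, 3L),
                       decoy_ratio = NA_real_) {
  cfg <- as.list(environment())
  fr <- c(frac_novel_isotigs, frac_splice_variants, frac_partial,
          frac_withheld, frac_reassigned, frac_de, n_rate, ti_fraction,
          frac_intron_retention, minor_allele_frac_range)
  if (any(fr < 0 | fr > 1))
    stop("sim_config: all fractions must lie in [0,1]", call. = FALSE)
  if (n_genes < 1) stop("sim_config: n_genes must be positive", call. = FALSE)
  if (n_species < 1 || n_species > length(SPECIES_DEFAULT))
    stop("sim_config: n_species must be 1-3", call. = FALSE)
  if (novel_insert_len_range[1] < 50)
    stop("sim_config: novel insert length minimum is 50 bp", call. = FALSE)
  if (sum(library_weights) <= 0 || any(library_weights < 0))
    stop("sim_config: library_weights must be nonnegative with positive sum",
         call. = FALSE)
  if (depth_range[1] < 1) stop("sim_config: depth must be positive", call. = FALSE)
  cfg$species <- SPECIES_DEFAULT[seq_len(n_species)]
  structure(cfg, class = "sim_config")
}

sample_range <- function(r, n = 1L) {
  if (r[1] == r[2]) rep(as.integer(r[1]), n) else
    sample(seq.int(r[1], r[2]), n, replace = TRUE)
}

# Random stop-free coding sequence of n_codons codons, starting with ATG.
random_cds <- function(n_codons) {
  codons <- apply(expand.grid(DNA_BASES4, DNA_BASES4, DNA_BASES4), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(codons, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}

#' Generate a multi-species reference panel
#'
#' Builds \code{n_genes} genes, each with one transcript per pseudo-species
#' sharing exon/CDS structure; species copies diverge by independent
#' substitution.  A configurable fraction of genes is withheld from one
#' species or reassigned to a fresh ortholog group, so downstream
#' orthology-consistency categories 1 and 2 are exercised.
#'
#' @param cfg a [sim_config()].
#' @return list of class \code{ref_panel}: per-transcript [gene_model()]s
#'   (\code{models}, keyed by transcript id), per-species transcript and
#'   genome sequence sets, the orthology table and a per-gene truth table.
#' @export
generate_reference_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "panel"))
  sp <- cfg$species
  n_withheld <- floor(cfg$frac_withheld * cfg$n_genes)
  n_reassigned <- floor(cfg$frac_reassigned * cfg$n_genes)
  special <- if (length(sp) > 1) sample(cfg$n_genes, min(cfg$n_genes, n_withheld + n_reassigned))
             else integer(0)
  withheld <- utils::head(special, n_withheld)
  reassigned <- utils::tail(special, length(special) - n_withheld)

  models <- list()
  transcripts <- setNames(vector("list", length(sp)), sp)
  genomes <- setNames(vector("list", length(sp)), sp)
  ortho <- list()
  genes <- list()
  fresh_group <- 0L
  for (g in seq_len(cfg$n_genes)) {
    core <- sprintf("g%03d", g)
    og <- sprintf("OG%03d", g)
    n_ex <- sample_range(cfg$n_exons_range)
    ex_len <- sample_range(cfg$exon_len_range, n_ex)
    # guarantee room for UTRs plus at least 30 coding codons
    need <- cfg$utr5_len + cfg$utr3_len + 90L
    if (sum(ex_len) < need) ex_len[n_ex] <- ex_len[n_ex] + need - sum(ex_len)
    tlen <- sum(ex_len)
    cds_len <- tlen - cfg$utr5_len - cfg$utr3_len
    cds_len <- cds_len - cds_len %% 3L
    cds <- c(cfg$utr5_len, cfg$utr5_len + cds_len)
    anc <- paste0(paste(sample(DNA_BASES4, cfg$utr5_len, TRUE), collapse = ""),
                  random_cds(cds_len %/% 3L),
                  paste(sample(DNA_BASES4, tlen - cds[2], TRUE), collapse = ""))
    introns <- if (n_ex > 1) random_dna(n_ex - 1L, sample_range(cfg$intron_len_range))
               else character(0)
    t_end <- cumsum(ex_len); t_start <- c(0L, utils::head(t_end, -1L))
    wh_sp <- if (g %in% withheld) sample(sp[-1], 1) else NA_character_
    # reassignment of one non-focal species yields category 2 downstream;
    # reassigning both yields category 1
    re_sps <- if (g %in% reassigned) {
      if (length(sp) > 2 && runif(1) < 0.5) sp[-1] else sample(sp[-1], 1)
    } else character(0)
    for (s in sp) {
      if (identical(s, wh_sp)) next
      rate <- cfg$substitution_divergence / 2
      tseq <- sanitize_cds(mutate_seq(anc, rate), cds, anc)
      iseq <- vapply(introns, mutate_seq, character(1), rate = rate,
                     USE.NAMES = FALSE)
      chrom <- sprintf("%s_ctg_%s", s, core)
      gpieces <- character(2 * n_ex - 1)
      gpieces[seq(1, 2 * n_ex - 1, by = 2)] <-
        substring(tseq, t_start + 1L, t_end)
      if (n_ex > 1) gpieces[seq(2, 2 * n_ex - 2, by = 2)] <- iseq
      gseq <- paste(gpieces, collapse = "")
      ilen <- c(0L, cumsum(nchar(iseq)))
      g_start <- t_start + ilen[seq_len(n_ex)]
      g_end <- t_end + ilen[seq_len(n_ex)]
      gid <- sprintf("%s_%s", s, core)
      tid <- sprintf("%s_%s_t1", s, core)
      grp <- if (s %in% re_sps) {
        fresh_group <- fresh_group + 1L
        sprintf("OGX%03d", fresh_group)
      } else og
      models[[tid]] <- gene_model(tid, gid, s, chrom,
        exons = data.frame(g_start = g_start, g_end = g_end,
                           t_start = t_start, t_end = t_end),
        cds = cds, transcript_seq = tseq, ortholog_group = grp)
      transcripts[[s]][[tid]] <- tseq
      genomes[[s]][[chrom]] <- gseq
      ortho[[length(ortho) + 1L]] <- data.frame(gene_id = gid, species = s,
                                                ortholog_group = grp)
    }
    genes[[g]] <- data.frame(core_id = core, ortholog_group = og,
                             withheld_species = wh_sp,
                             reassigned_species = if (length(re_sps))
                               paste(re_sps, collapse = ",") else NA_character_,
                             cds_start = cds[1], cds_end = cds[2], n_exons = n_ex)
  }
  structure(list(cfg = cfg,
                 species = sp,
                 genes = do.call(rbind, genes),
                 models = models,
                 transcripts = lapply(transcripts, unlist),
                 genomes = lapply(genomes, unlist),
                 orthology = do.call(rbind, ortho)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d genes x %d species (%s), %d transcripts\n",
              nrow(x$genes), length(x$species),
              paste(x$species, collapse = "/"), length(x$models)))
  invisible(x)
}

# Substitution divergence must not break a species copy's reading frame:
# internal codons mutated into stops, or a lost terminal stop, revert to
# the ancestral codon.
sanitize_cds <- function(seq, cds, anc) {
  stops <- c("TAA", "TAG", "TGA")
  for (p in seq.int(cds[1], cds[2] - 6L, by = 3L)) {
    if (substr0(seq, p, p + 3L) %in% stops)
      substr(seq, p + 1L, p + 3L) <- substr0(anc, p, p + 3L)
  }
  last <- cds[2] - 3L
  if (!substr0(seq, last, last + 3L) %in% stops)
    substr(seq, last + 1L, last + 3L) <- substr0(anc, last, last + 3L)
  seq
}

# choose an in-frame, stop-free insert of length len starting at codon
# phase 0; len is forced to a multiple of 3.
orf_preserving_insert <- function(len) {
  len <- max(51L, 3L * (len %/% 3L))
  codons <- apply(expand.grid(DNA_BASES4, DNA_BASES4, DNA_BASES4), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, len %/% 3L, replace = TRUE), collapse = "")
}

#' Generate isotigs from a reference panel
#'
#' Isotigs copy the focal (first) species' transcripts, fully or partially.
#' A fraction of multi-exon genes emits a second, exon-skipping splice
#' variant; a fraction of isotigs receives one planted random-sequence
#' insert, either inside an exon copy (insertion-in-exon) or between two
#' exon copies (novel-exon); biallelic sites are planted at
#' \code{snp_rate} per kb with recorded target minor-allele fractions.
#' Everything planted is recorded in the returned truth set, together with
#' the isotig-to-transcript segment map the hit-table generator uses.
#'
#' @param panel a [generate_reference_panel()] result.
#' @param cfg the same [sim_config()].
#' @return list of class \code{isotig_set}: \code{seqs} (named character
#'   vector), \code{truth} (class \code{truth_set}) and \code{segments}
#'   (per-isotig copy/insert map).
#' @export
generate_isotigs <- function(panel, cfg) {
  stopifnot(inherits(panel, "ref_panel"))
  set.seed(derive_seed(cfg$seed, "isotigs"))
  focal <- panel$species[1]
  seqs <- character(0)
  segments <- list()
  snps <- list(); novel <- list(); vmap <- list()
  counter <- 0L

  emit <- function(core, tid, exon_keep) {
    model <- panel$models[[tid]]
    ex <- model$exons
    keep <- sort(exon_keep)
    counter <<- counter + 1L
    iso <- sprintf("iso%04d", counter)
    # copied transcript segments, one per kept exon
    seg <- data.frame(t_start = ex$t_start[keep], t_end = ex$t_end[keep])
    # optional partial truncation of the first/last segment
    if (runif(1) < cfg$frac_partial && nrow(seg) >= 1) {
      cut <- sample_range(c(30L, 120L))
      if (runif(1) < 0.5) {
        seg$t_start[1] <- min(seg$t_start[1] + cut, seg$t_end[1] - 30L)
      } else {
        n <- nrow(seg)
        seg$t_end[n] <- max(seg$t_end[n] - cut, seg$t_start[n] + 30L)
      }
    }
    pieces <- substring(model$transcript_seq, seg$t_start + 1L, seg$t_end)
    q_end <- cumsum(nchar(pieces)); q_start <- c(0L, utils::head(q_end, -1L))
    segmap <- data.frame(q_start = q_start, q_end = q_end,
                         t_start = seg$t_start, t_end = seg$t_end,
                         type = "copy", stringsAsFactors = FALSE)
    iso_seq <- paste(pieces, collapse = "")

    # one planted non-conserved insert on a fraction of isotigs
    if (runif(1) < cfg$frac_novel_isotigs) {
      ins_len <- sample_range(cfg$novel_insert_len_range)
      as_exon <- nrow(segmap) >= 2 && runif(1) < 0.5
      if (as_exon) {
        j <- sample(nrow(segmap) - 1L, 1)       # junction after segment j
        at <- segmap$q_end[j]
      } else {
        j <- which.max(segmap$q_end - segmap$q_start)
        margin <- 30L
        lo <- segmap$q_start[j] + margin; hi <- segmap$q_end[j] - margin
        at <- if (hi > lo) sample(seq.int(lo, hi), 1) else segmap$q_start[j] + 1L
      }
      # intron-retention control: copy the focal intervening intron
      retention <- as_exon && runif(1) < cfg$frac_intron_retention &&
        j < nrow(segmap) && keep[j + 1L] == keep[j] + 1L
      ins_seq <- NULL
      if (retention) {
        oj <- keep[j]
        gseq <- panel$genomes[[model$species]][[model$chrom]]
        intron <- substr0(gseq, model$exons$g_end[oj],
                          model$exons$g_start[oj + 1L])
        if (nchar(intron) > 50) {
          ins_len <- min(ins_len, nchar(intron))
          off <- sample.int(nchar(intron) - ins_len + 1L, 1) - 1L
          ins_seq <- substr0(intron, off, off + ins_len)
        } else retention <- FALSE
      }
      # ORF preservation only meaningful inside the copied CDS
      cds_q <- map_t_to_q(segmap, model$cds)
      in_cds <- !is.null(cds_q) && at > cds_q[1] && at < cds_q[2]
      preserve <- !retention && in_cds && runif(1) < 0.5
      if (preserve && !as_exon) {
        phase <- (at - cds_q[1]) %% 3L
        at <- at - phase                        # snap to codon boundary
      }
      if (preserve && as_exon && (at - cds_q[1]) %% 3L != 0L)
        preserve <- FALSE                       # junction position is fixed
      if (preserve) {
        ins_seq <- orf_preserving_insert(ins_len)
        ins_len <- nchar(ins_seq)
      } else if (is.null(ins_seq)) {
        ins_seq <- random_dna(1, ins_len)
      }
      iso_seq <- paste0(substr0(iso_seq, 0, at), ins_seq,
                        substr0(iso_seq, at, nchar(iso_seq)))
      segmap <- insert_into_segmap(segmap, at, ins_len)
      novel[[length(novel) + 1L]] <<- data.frame(
        isotig_id = iso, start = at, end = at + ins_len,
        class = if (as_exon) "novel-exon" else "insertion-in-exon",
        origin = if (retention) "intron" else "random",
        orf_preserving = preserve, stringsAsFactors = FALSE)
    }

    # planted biallelic sites on copied (non-insert) positions
    L <- nchar(iso_seq)
    n_snp <- rpois(1, cfg$snp_rate * L / 1000)
    if (n_snp > 0) {
      copies <- segmap[segmap$type == "copy", ]
      eligible <- unlist(lapply(seq_len(nrow(copies)), function(i)
        seq.int(copies$q_start[i] + 2L, copies$q_end[i] - 3L)))
      pos <- sort(sample(eligible, min(n_snp, length(eligible))))
      pos <- pos[c(TRUE, diff(pos) >= 3L)]      # keep flanks independent
      for (p in pos) {
        ref <- substr0(iso_seq, p, p + 1L)
        alt <- if (runif(1) < cfg$ti_fraction) TRANSITION_PARTNER[[ref]]
               else sample(setdiff(DNA_BASES4, c(ref, TRANSITION_PARTNER[[ref]])), 1)
        frac <- runif(1, cfg$minor_allele_frac_range[1],
                      cfg$minor_allele_frac_range[2])
        snps[[length(snps) + 1L]] <<- data.frame(
          isotig_id = iso, position = p, ref_allele = ref, alt_allele = alt,
          target_frac = frac, true_depth = NA_integer_,
          true_alt_fraction = NA_real_, stringsAsFactors = FALSE)
      }
    }
    seqs[iso] <<- iso_seq
    segments[[iso]] <<- segmap
    vmap[[length(vmap) + 1L]] <<- data.frame(
      isotig_id = iso, core_id = core, source_transcript = tid,
      gene_id = model$gene_id, stringsAsFactors = FALSE)
  }

  for (g in seq_len(nrow(panel$genes))) {
    core <- panel$genes$core_id[g]
    tid <- sprintf("%s_%s_t1", focal, core)
    if (is.null(panel$models[[tid]])) next     # withheld from focal species
    n_ex <- panel$genes$n_exons[g]
    emit(core, tid, seq_len(n_ex))
    if (n_ex >= 3 && runif(1) < cfg$frac_splice_variants) {
      skip <- sample(seq.int(2L, n_ex - 1L), 1)
      emit(core, tid, setdiff(seq_len(n_ex), skip))
    }
  }
  truth <- structure(list(
    planted_snps = rbind_or_empty(snps, c("isotig_id", "position", "ref_allele",
      "alt_allele", "target_frac", "true_depth", "true_alt_fraction")),
    planted_novel_regions = rbind_or_empty(novel, c("isotig_id", "start", "end",
      "class", "origin", "orf_preserving")),
    planted_de_genes = data.frame(gene_id = character(), contrast = character(),
                                  log2_fold = numeric()),
    variant_map = do.call(rbind, vmap)), class = "truth_set")
  validate_truth(truth, seqs)
  structure(list(seqs = seqs, truth = truth, segments = segments),
            class = "isotig_set")
}

# Project a transcript interval through the copy segments onto the isotig;
# NULL when the interval misses every copied segment.
map_t_to_q <- function(segmap, t_int) {
  copies <- segmap[segmap$type == "copy", ]
  hit_q <- unlist(lapply(seq_len(nrow(copies)), function(i) {
    s <- max(t_int[1], copies$t_start[i]); e <- min(t_int[2], copies$t_end[i])
    if (s >= e) return(NULL)
    c(copies$q_start[i] + (s - copies$t_start[i]),
      copies$q_start[i] + (e - copies$t_start[i]))
  }))
  if (is.null(hit_q)) NULL else c(min(hit_q), max(hit_q))
}

insert_into_segmap <- function(segmap, at, len) {
  out <- list()
  for (i in seq_len(nrow(segmap))) {
    row <- segmap[i, ]
    if (row$q_end <= at) { out[[length(out) + 1L]] <- row; next }
    if (row$q_start >= at) {
      row$q_start <- row$q_start + len; row$q_end <- row$q_end + len
      out[[length(out) + 1L]] <- row; next
    }
    left <- row; left$q_end <- at; left$t_end <- row$t_start + (at - row$q_start)
    right <- row
    right$q_start <- at + len; right$q_end <- row$q_end + len
    right$t_start <- left$t_end
    out[[length(out) + 1L]] <- left
    out[[length(out) + 1L]] <- right
  }
  ins <- data.frame(q_start = at, q_end = at + len, t_start = NA_integer_,
                    t_end = NA_integer_, type = "insert")
  res <- rbind(do.call(rbind, out), ins)
  res <- res[order(res$q_start), ]
  rownames(res) <- NULL
  res
}

rbind_or_empty <- function(lst, cols) {
  if (length(lst)) {
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  } else {
    as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  }
}

validate_truth <- function(truth, seqs) {
  s <- truth$planted_snps
  if (nrow(s) > 0 && any(s$position < 0 | s$position >= nchar(seqs[s$isotig_id])))
    stop("planted SNP outside its isotig", call. = FALSE)
  nv <- truth$planted_novel_regions
  if (nrow(nv) > 0) {
    if (any(nv$end - nv$start < 50))
      stop("planted novel region shorter than 50 bp", call. = FALSE)
    if (any(nv$start < 0 | nv$end > nchar(seqs[nv$isotig_id])))
      stop("planted novel region outside its isotig", call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate the read stack of one isotig
#'
#' Reads of length \code{read_len} tile the isotig in staggered layers so
#' that every column has exactly the drawn per-isotig depth.  At each
#' planted site, the alt allele is written into \code{round(fraction *
#' depth)} of the covering reads; each read carries a random library tag
#' C.1-C.4 (weights from the config) and a random strand.  Minus-strand
#' reads are stored reverse-complemented (sequencing orientation).
#'
#' @param iso_seq isotig consensus sequence.
#' @param isotig_id consensus identifier.
#' @param snps data frame of planted sites for this isotig (may be empty):
#'   columns \code{position}, \code{alt_allele}, \code{target_frac}.
#' @param cfg a [sim_config()].
#' @param depth per-column depth; drawn from \code{cfg$depth_range} when
#'   \code{NULL}.
#' @return list: the [isotig_assembly()] and the realized per-site
#'   \code{true_depth} / \code{true_alt_fraction} table.
#' @export
generate_assembly <- function(iso_seq, isotig_id, snps, cfg, depth = NULL) {
  if (!is.null(depth) && depth < 1) stop("depth must be positive", call. = FALSE)
  if (is.null(depth)) depth <- sample_range(cfg$depth_range)
  L <- nchar(iso_seq)
  rl <- min(cfg$read_len, L)
  starts <- unlist(lapply(seq_len(depth), function(i) {
    o <- floor((i - 1L) * rl / depth)
    seq.int(o - rl, L - 1L, by = rl)
  }))
  s0 <- pmax(starts, 0L); e0 <- pmin(starts + rl, L)
  keep <- e0 > s0
  s0 <- s0[keep]; e0 <- e0[keep]
  ord <- order(s0, e0)
  s0 <- s0[ord]; e0 <- e0[ord]
  n <- length(s0)
  segs <- substring(iso_seq, s0 + 1L, e0)

  realized <- snps
  if (nrow(snps) > 0) {
    realized$true_depth <- NA_integer_; realized$true_alt_fraction <- NA_real_
    for (k in seq_len(nrow(snps))) {
      p <- snps$position[k]
      cov <- which(s0 <= p & p < e0)
      nalt <- round(snps$target_frac[k] * length(cov))
      pick <- if (nalt > 0) sample(cov, nalt) else integer(0)
      for (j in pick) {
        off <- p - s0[j]
        substr(segs[j], off + 1L, off + 1L) <- snps$alt_allele[k]
      }
      realized$true_depth[k] <- length(cov)
      realized$true_alt_fraction[k] <- if (length(cov)) nalt / length(cov) else NA_real_
    }
  }
  if (cfg$n_rate > 0) {
    protected <- if (nrow(snps)) sort(unique(c(snps$position - 1L, snps$position,
                                               snps$position + 1L))) else integer(0)
    for (j in seq_len(n)) {
      hits <- which(runif(e0[j] - s0[j]) < cfg$n_rate)
      hits <- hits[!((s0[j] + hits - 1L) %in% protected)]
      for (h in hits) substr(segs[j], h, h) <- "N"
    }
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  segs[strand == "-"] <- revcomp(segs[strand == "-"])
  lib <- paste0("C.", sample(4L, n, replace = TRUE,
                             prob = cfg$library_weights / sum(cfg$library_weights)))
  reads <- data.frame(read_id = sprintf("%s_r%04d", isotig_id, seq_len(n)),
                      offset = s0, strand = strand, library = lib, seq = segs,
                      stringsAsFactors = FALSE)
  list(assembly = isotig_assembly(isotig_id, iso_seq, reads),
       realized_snps = realized, depth = depth)
}

#' Simulate read stacks for a whole isotig set
#'
#' @param iso a [generate_isotigs()] result.
#' @param cfg the [sim_config()].
#' @return list: \code{assemblies} (list of [isotig_assembly()]) and the
#'   truth set with realized depths and alt fractions filled in.
#' @export
generate_assemblies <- function(iso, cfg) {
  set.seed(derive_seed(cfg$seed, "assembly"))
  truth <- iso$truth
  snp_rows <- list()
  assemblies <- lapply(names(iso$seqs), function(id) {
    snps <- truth$planted_snps[truth$planted_snps$isotig_id == id, , drop = FALSE]
    res <- generate_assembly(iso$seqs[[id]], id, snps, cfg)
    if (nrow(res$realized_snps)) snp_rows[[id]] <<- res$realized_snps
    res$assembly
  })
  names(assemblies) <- names(iso$seqs)
  if (length(snp_rows)) {
    upd <- do.call(rbind, snp_rows); rownames(upd) <- NULL
    truth$planted_snps <- upd
  }
  list(assemblies = assemblies, truth = truth)
}

#' Generate a hit table with known expected chains
#'
#' For every isotig and every species carrying its gene, one HSP is
#' emitted per conserved exon block of the copied transcript (correct
#' coordinates; identity computed from the actual sequences; bit-score
#' proportional to length times identity).  Planted inserts produce no
#' HSP.  When \code{decoy_ratio} is set, each isotig additionally hits a
#' paralog decoy gene with coverage and bit-score at that ratio of the
#' true hit's, which exercises the 2x unique rule at and around threshold.
#'
#' @param iso a [generate_isotigs()] result.
#' @param panel the [generate_reference_panel()] result.
#' @param cfg the [sim_config()].
#' @param decoy_ratio overrides \code{cfg$decoy_ratio}.
#' @return list: \code{hits} (HSP data frame in the internal convention)
#'   and \code{expected} (per isotig x species: true target, HSP count,
#'   chained coverage, decoy target or NA).
#' @export
generate_hit_table <- function(iso, panel, cfg, decoy_ratio = cfg$decoy_ratio) {
  set.seed(derive_seed(cfg$seed, "hits"))
  hits <- list(); expected <- list()
  vmap <- iso$truth$variant_map
  cores <- setNames(vmap$core_id, vmap$isotig_id)
  for (id in names(iso$seqs)) {
    core <- cores[[id]]
    segmap <- iso$segments[[id]]
    copies <- segmap[segmap$type == "copy", , drop = FALSE]
    for (s in panel$species) {
      tid <- sprintf("%s_%s_t1", s, core)
      model <- panel$models[[tid]]
      if (is.null(model)) next                 # withheld species
      tseq <- model$transcript_seq
      rows <- list()
      for (i in seq_len(nrow(copies))) {
        for (e in seq_len(nrow(model$exons))) {
          ts <- max(copies$t_start[i], model$exons$t_start[e])
          te <- min(copies$t_end[i], model$exons$t_end[e])
          if (ts >= te) next
          qs <- copies$q_start[i] + (ts - copies$t_start[i])
          qe <- qs + (te - ts)
          a <- strsplit(substr0(iso$seqs[[id]], qs, qe), "")[[1]]
          b <- strsplit(substr0(tseq, ts, te), "")[[1]]
          pid <- 100 * mean(a == b)
          len <- te - ts
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = id, target_id = tid, q_start = qs, q_end = qe,
            t_start = ts, t_end = te, strand = "+",
            pct_identity = round(pid, 2),
            bit_score = round(2 * len * pid / 100, 1),
            e_value = signif(2^(-pmin(2 * len * pid / 100, 500)), 3),
            stringsAsFactors = FALSE)
        }
      }
      block <- do.call(rbind, rows)
      hits[[length(hits) + 1L]] <- block
      decoy_tid <- NA_character_
      if (!is.na(decoy_ratio)) {
        cov <- sum(block$q_end - block$q_start)
        bits <- sum(block$bit_score)
        cands <- setdiff(names(panel$models), tid)
        cands <- cands[vapply(cands, function(t) {
          m <- panel$models[[t]]
          m$species == s && nchar(m$transcript_seq) >= ceiling(decoy_ratio * cov)
        }, logical(1))]
        if (length(cands)) {
          decoy_tid <- sample(cands, 1)
          dlen <- max(1L, as.integer(round(decoy_ratio * cov)))
          hits[[length(hits) + 1L]] <- data.frame(
            query_id = id, target_id = decoy_tid, q_start = 0L, q_end = dlen,
            t_start = 0L, t_end = dlen, strand = "+", pct_identity = 85,
            bit_score = round(decoy_ratio * bits, 4),
            e_value = 1e-10, stringsAsFactors = FALSE)
        }
      }
      expected[[length(expected) + 1L]] <- data.frame(
        isotig_id = id, species = s, target_id = tid, n_hsps = nrow(block),
        coverage = sum(block$q_end - block$q_start),
        decoy_target = decoy_tid, stringsAsFactors = FALSE)
    }
  }
  list(hits = do.call(rbind, hits), expected = do.call(rbind, expected))
}

#' Generate a per-gene read-count table with planted differential expression
#'
#' Per-gene totals are Poisson with mean \code{mean_gene_count}; counts are
#' split multinomially across the four libraries with the configured
#' weights.  Planted genes have library \code{de_contrast[1]}'s weight
#' multiplied by \code{2^de_lfc}.
#'
#' @param panel a [generate_reference_panel()] result (supplies gene ids of
#'   the focal species), or a plain character vector of gene ids when only
#'   counts are needed.
#' @param cfg the [sim_config()].
#' @param de_genes optional data frame \code{gene_id, contrast, log2_fold}
#'   overriding the config-driven planting.
#' @return list: \code{counts} (data frame with a \code{totals} attribute)
#'   and \code{de_truth}.
#' @export
generate_counts <- function(panel, cfg, de_genes = NULL) {
  set.seed(derive_seed(cfg$seed, "counts"))
  gid <- if (is.character(panel)) panel
         else sprintf("%s_%s", panel$species[1], panel$genes$core_id)
  if (is.null(de_genes)) {
    n_de <- floor(cfg$frac_de * length(gid))
    picked <- if (n_de > 0) sample(gid, n_de) else character(0)
    de_genes <- data.frame(gene_id = picked,
      contrast = rep(sprintf("C.%d_vs_C.%d", cfg$de_contrast[1], cfg$de_contrast[2]),
                     length(picked)),
      log2_fold = rep(cfg$de_lfc, length(picked)), stringsAsFactors = FALSE)
  }
  w0 <- cfg$library_weights
  counts <- t(vapply(gid, function(g) {
    w <- w0
    j <- match(g, de_genes$gene_id)
    if (!is.na(j)) {
      a <- cfg$de_contrast[1]
      w[a] <- w[a] * 2^de_genes$log2_fold[j]
    }
    tot <- rpois(1, cfg$mean_gene_count)
    as.numeric(rmultinom(1, tot, w))
  }, numeric(4)))
  tab <- data.frame(gene_id = gid, n1 = counts[, 1], n2 = counts[, 2],
                    n3 = counts[, 3], n4 = counts[, 4], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "totals") <- colSums(counts)
  list(counts = tab, de_truth = de_genes)
}
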