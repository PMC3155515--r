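test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(novel_insert_len_range = c(40, 100)), "50")
  expect_error(sim_config(library_weights = c(0, 0, 0, 0)), "weights")
  expect_error(sim_config(frac_de = 1.2), "fractions")
})

test_that("zero divergence produces identical transcripts across species", {
  cfg <- sim_config(seed = 5, n_genes = 1, substitution_divergence = 0,
                    frac_withheld = 0, frac_reassigned = 0)
  panel <- generate_reference_panel(cfg)
  seqs <- vapply(panel$models, `[[`, character(1), "transcript_seq")
  expect_length(seqs, 3)
  expect_equal(length(unique(seqs)), 1)
  groups <- vapply(panel$models, `[[`, character(1), "ortholog_group")
  expect_equal(length(unique(groups)), 1)
})

test_that("panel regeneration with one seed is byte-identical on disk", {
  cfg <- sim_config(seed = 42, n_genes = 5)
  render <- function() {
    dir <- withr::local_tempdir()
    pc <- pipeline_config(dir, seed = 42, sim = cfg)
    run_simulate(pc)
    files <- sort(list.files(dir, recursive = TRUE))
    vapply(file.path(dir, files), function(f) unname(tools::md5sum(f)),
           character(1), USE.NAMES = FALSE)
  }
  expect_identical(render(), render())
})

test_that("pairwise identity of homologous transcripts matches the nominal divergence", {
  cfg <- sim_config(seed = 8, n_genes = 100, substitution_divergence = 0.05,
                    frac_withheld = 0, frac_reassigned = 0)
  panel <- generate_reference_panel(cfg)
  # direct mismatch count over all species pairs of each gene
  idents <- unlist(lapply(panel$genes$core_id, function(core) {
    seqs <- lapply(panel$species, function(s)
      strsplit(panel$models[[sprintf("%s_%s_t1", s, core)]]$transcript_seq,
               "")[[1]])
    combn(3, 2, function(p) mean(seqs[[p[1]]] == seqs[[p[2]]]))
  }))
  expect_gt(mean(idents), 0.94)
  expect_lt(mean(idents), 0.96)
})

test_that("exon and CDS coordinates are mutually consistent", {
  cfg <- sim_config(seed = 13, n_genes = 10)
  panel <- generate_reference_panel(cfg)
  for (m in panel$models) {
    expect_equal(sum(m$exons$g_end - m$exons$g_start),
                 nchar(m$transcript_seq))
    expect_true(m$cds[1] >= 0 && m$cds[2] <= nchar(m$transcript_seq))
    expect_equal((m$cds[2] - m$cds[1]) %% 3, 0)
    # exons tile the transcript and sit inside the genome contig
    expect_equal(m$exons$t_start,
                 c(0L, utils::head(m$exons$t_end, -1L)))
    gseq <- panel$genomes[[m$species]][[m$chrom]]
    expect_true(max(m$exons$g_end) <= nchar(gseq))
    # the spliced genomic exons reproduce the transcript
    spliced <- paste(substring(gseq, m$exons$g_start + 1, m$exons$g_end),
                     collapse = "")
    expect_equal(spliced, m$transcript_seq)
  }
})

test_that("withheld and reassigned genes are reflected in the orthology table", {
  cfg <- sim_config(seed = 21, n_genes = 30, frac_withheld = 0.2,
                    frac_reassigned = 0.2)
  panel <- generate_reference_panel(cfg)
  wh <- panel$genes[!is.na(panel$genes$withheld_species), ]
  expect_gt(nrow(wh), 0)
  for (i in seq_len(nrow(wh))) {
    tid <- sprintf("%s_%s_t1", wh$withheld_species[i], wh$core_id[i])
    expect_null(panel$models[[tid]])
  }
  re <- panel$genes[!is.na(panel$genes$reassigned_species), ]
  expect_gt(nrow(re), 0)
  for (i in seq_len(nrow(re))) {
    for (s in strsplit(re$reassigned_species[i], ",")[[1]]) {
      grp <- panel$orthology$ortholog_group[
        panel$orthology$species == s &
        panel$orthology$gene_id == sprintf("%s_%s", s, re$core_id[i])]
      expect_false(grp == re$ortholog_group[i])
    }
  }
})

test_that("no planted novel regions when the fraction is zero", {
  cfg <- sim_config(seed = 2, n_genes = 5, frac_novel_isotigs = 0)
  iso <- generate_isotigs(generate_reference_panel(cfg), cfg)
  expect_equal(nrow(iso$truth$planted_novel_regions), 0)
})

test_that("planted SNP totals follow the configured rate", {
  cfg <- sim_config(seed = 17, n_genes = 50, snp_rate = 2,
                    frac_novel_isotigs = 0, frac_splice_variants = 0,
                    frac_partial = 0, frac_withheld = 0)
  iso <- generate_isotigs(generate_reference_panel(cfg), cfg)
  expected <- sum(nchar(iso$seqs)) * 2 / 1000
  observed <- nrow(iso$truth$planted_snps)
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("planted features verify against the emitted sequences", {
  cfg <- sim_config(seed = 23, n_genes = 20, frac_novel_isotigs = 0.5)
  panel <- generate_reference_panel(cfg)
  iso <- generate_isotigs(panel, cfg)
  tr <- iso$truth
  # every planted coordinate lies inside its isotig
  expect_true(all(tr$planted_snps$position >= 0 &
                  tr$planted_snps$position <
                    nchar(iso$seqs[tr$planted_snps$isotig_id])))
  expect_true(all(tr$planted_novel_regions$end - tr$planted_novel_regions$start >= 50))
  # random inserts have no counterpart in any reference transcript
  nv <- tr$planted_novel_regions
  nv <- nv[nv$origin == "random", , drop = FALSE]
  for (i in seq_len(nrow(nv))) {
    ins <- substr(iso$seqs[[nv$isotig_id[i]]], nv$start[i] + 1, nv$end[i])
    probe <- substr(ins, 1, 30)
    hits <- vapply(panel$transcripts, function(tx)
      any(grepl(probe, tx, fixed = TRUE)), logical(1))
    expect_false(any(hits))
  }
})

test_that("read stacks honor depth, alt fractions and determinism", {
  cfg <- sim_config(seed = 31, n_genes = 2, frac_novel_isotigs = 0)
  panel <- generate_reference_panel(cfg)
  iso <- generate_isotigs(panel, cfg)
  id <- names(iso$seqs)[1]
  ref <- substr(iso$seqs[[id]], 51, 51)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  snps <- data.frame(isotig_id = id, position = 50L, ref_allele = ref,
                     alt_allele = alt, target_frac = 0.4,
                     true_depth = NA, true_alt_fraction = NA)
  set.seed(99)
  res <- generate_assembly(iso$seqs[[id]], id, snps, cfg, depth = 10)
  # alt allele in exactly round(0.4 * 10) = 4 of 10 covering reads
  expect_equal(res$realized_snps$true_depth, 10L)
  expect_equal(res$realized_snps$true_alt_fraction, 0.4)
  p <- pileup(res$assembly)
  expect_equal(unname(p$depth[51]), 10L)
  alt_count <- p$counts[alt, 51]
  expect_equal(unname(alt_count), 4L)
  expect_error(generate_assembly(iso$seqs[[id]], id, snps, cfg, depth = 0),
               "positive")
  # no injected N at the default rate
  expect_false(any(grepl("N", res$assembly$reads$seq, fixed = TRUE)))
  # seeded ACE output is identical across runs
  render <- function() {
    f <- withr::local_tempfile()
    asm <- generate_assemblies(iso, cfg)
    write_ace(asm$assemblies, f)
    unname(tools::md5sum(f))
  }
  expect_identical(render(), render())
})

test_that("hit tables cover conserved blocks only and plant decoys at ratio", {
  cfg <- sim_config(seed = 37, n_genes = 6, frac_novel_isotigs = 1,
                    frac_splice_variants = 0, frac_partial = 0,
                    frac_withheld = 0, frac_reassigned = 0)
  panel <- generate_reference_panel(cfg)
  iso <- generate_isotigs(panel, cfg)
  ht <- generate_hit_table(iso, panel, cfg)
  nv <- iso$truth$planted_novel_regions
  for (i in seq_len(nrow(nv))) {
    h <- ht$hits[ht$hits$query_id == nv$isotig_id[i], ]
    overlaps <- pmax(0, pmin(h$q_end, nv$end[i]) - pmax(h$q_start, nv$start[i]))
    expect_equal(sum(overlaps), 0)    # planted inserts produce no HSP
  }
  # single-exon full-copy isotig produces one HSP covering everything
  cfg1 <- sim_config(seed = 38, n_genes = 1, n_exons_range = c(1, 1),
                     frac_novel_isotigs = 0, frac_splice_variants = 0,
                     frac_partial = 0, frac_withheld = 0,
                     substitution_divergence = 0)
  p1 <- generate_reference_panel(cfg1)
  i1 <- generate_isotigs(p1, cfg1)
  h1 <- generate_hit_table(i1, p1, cfg1)
  hm <- h1$hits[grepl("^mouse", h1$hits$target_id), ]
  expect_equal(nrow(hm), 1)
  expect_equal(hm$q_end - hm$q_start, nchar(i1$seqs[[1]]))
  expect_equal(hm$pct_identity, 100)
  # decoys carry the requested coverage and bit-score ratio
  htd <- generate_hit_table(iso, panel, cfg, decoy_ratio = 0.49)
  ex <- htd$expected[!is.na(htd$expected$decoy_target), ][1, ]
  d <- htd$hits[htd$hits$query_id == ex$isotig_id &
                htd$hits$target_id == ex$decoy_target, ]
  expect_equal(d$q_end - d$q_start, round(0.49 * ex$coverage))
})

test_that("count tables split genes by library weights and record totals", {
  cfg <- sim_config(seed = 41, n_genes = 400, frac_de = 0,
                    library_weights = c(1, 1, 1, 1), mean_gene_count = 100)
  gid <- sprintf("mouse_g%03d", 1:400)   # gene ids suffice for counting
  cnt <- generate_counts(gid, cfg)
  tab <- cnt$counts
  expect_equal(attr(tab, "totals"),
               unname(colSums(tab[, c("n1", "n2", "n3", "n4")])))
  props <- colSums(tab[, c("n1", "n2", "n3", "n4")]) / sum(attr(tab, "totals"))
  expect_true(all(abs(props - 0.25) < 0.05))
  # planted genes shift weight into the contrast library
  cfg_de <- sim_config(seed = 43, n_genes = 4, frac_de = 0.5, de_lfc = 2,
                       de_contrast = c(1L, 3L), mean_gene_count = 4000)
  cnt2 <- generate_counts(gid[1:4], cfg_de)
  de_gene <- cnt2$de_truth$gene_id[1]
  row <- cnt2$counts[cnt2$counts$gene_id == de_gene, ]
  expect_gt(row$n1 / max(row$n3, 1), 2.5)     # 4-fold planted, some noise
  # seeded regeneration is identical
  cnt3 <- generate_counts(gid[1:4], cfg_de)
  expect_identical(cnt2$counts, cnt3$counts)
})
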