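test_that("pileup counts reads in consensus orientation", {
  mk <- function(reads) isotig_assembly("i", "ACGTACGT", reads)
  one <- mk(data.frame(read_id = "r1", offset = 0L, strand = "+",
                       library = "C.1", seq = "ACGT", stringsAsFactors = FALSE))
  p <- pileup(one)
  expect_equal(unname(p$depth[1:4]), rep(1L, 4))
  expect_equal(unname(p$counts["A", 1]), 1L)
  expect_equal(unname(p$counts["T", 4]), 1L)
  # two identical reads double every count
  two <- mk(data.frame(read_id = c("r1", "r2"), offset = c(0L, 0L),
                       strand = c("+", "+"), library = c("C.1", "C.1"),
                       seq = c("ACGT", "ACGT"), stringsAsFactors = FALSE))
  expect_equal(unname(pileup(two)$depth[1:4]), rep(2L, 4))
  # a minus-strand read contributes its reverse complement
  minus <- mk(data.frame(read_id = "r1", offset = 0L, strand = "-",
                         library = "C.1", seq = "ACGT", stringsAsFactors = FALSE))
  pm <- pileup(minus)
  expect_equal(unname(pm$counts["A", 1]), 1L)   # revcomp(ACGT) = ACGT
  minus2 <- mk(data.frame(read_id = "r1", offset = 0L, strand = "-",
                          library = "C.1", seq = "TTTT", stringsAsFactors = FALSE))
  expect_equal(unname(pileup(minus2)$counts["A", 1]), 1L)
})

test_that("candidate calling enforces depth and minor-fraction thresholds", {
  stack <- function(counts_a, counts_g, len = 3L) {
    # column 2 carries the polymorphic site; flanks are clean
    cons <- "AAA"
    reads <- do.call(rbind, lapply(seq_len(counts_a + counts_g), function(j) {
      s <- if (j <= counts_a) "AAA" else "AGA"
      data.frame(read_id = sprintf("r%02d", j), offset = 0L, strand = "+",
                 library = "C.1", seq = s, stringsAsFactors = FALSE)
    }))
    pileup(isotig_assembly("i", cons, reads))
  }
  # depth 10, A:6 G:4 -> candidate with minor G at 0.40
  calls <- call_candidates(stack(6, 4))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 1L)
  expect_equal(calls$major_allele, "A")
  expect_equal(calls$minor_allele, "G")
  expect_equal(calls$minor_fraction, 0.4)
  # depth 5 fails the threshold (5 < 6)
  expect_equal(nrow(call_candidates(stack(3, 2))), 0)
  # fraction 0.20 < 0.30 fails
  expect_equal(nrow(call_candidates(stack(8, 2))), 0)
  # exact tie 5/5: major and minor break alphabetically
  tie <- call_candidates(stack(5, 5))
  expect_equal(tie$major_allele, "A")
  expect_equal(tie$minor_allele, "G")
})

test_that("N never counts as an allele and fractions use non-N depth", {
  reads <- do.call(rbind, lapply(1:10, function(j) {
    s <- if (j <= 5) "AAA" else if (j <= 8) "AGA" else "ANA"
    data.frame(read_id = sprintf("r%02d", j), offset = 0L, strand = "+",
               library = "C.1", seq = s, stringsAsFactors = FALSE)
  }))
  p <- pileup(isotig_assembly("i", "AAA", reads))
  calls <- call_candidates(p)
  # non-N depth 8, minor G 3/8 = 0.375
  expect_equal(nrow(calls), 1)
  expect_equal(calls$minor_fraction, 3 / 8)
  expect_equal(calls$depth, 10)
})

test_that("a third allele at threshold invalidates the column", {
  reads <- do.call(rbind, lapply(1:10, function(j) {
    s <- if (j <= 4) "AAA" else if (j <= 7) "AGA" else "ATA"
    data.frame(read_id = sprintf("r%02d", j), offset = 0L, strand = "+",
               library = "C.1", seq = s, stringsAsFactors = FALSE)
  }))
  calls <- call_candidates(pileup(isotig_assembly("i", "AAA", reads)))
  expect_equal(nrow(calls), 0)
  expect_equal(attr(calls, "multiallelic"), 1L)
})

test_that("the flanking filter drops calls beside ambiguous columns", {
  set.seed(5)
  cons <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  base <- uniform_stack(cons, depth = 10)
  planted <- plant_allele(base, 30L, "G", 4L)
  p <- pileup(planted)
  calls <- call_candidates(p)
  expect_true(30L %in% calls$position)
  # clean flanks: retained
  expect_true(30L %in% filter_flanking(calls, p)$position)
  # consensus N at position + 1: removed
  consN <- planted
  substr(consN$consensus, 32, 32) <- "N"
  # (read bases unchanged; consensus alone decides this clause)
  pN <- pileup(consN)
  expect_false(30L %in% filter_flanking(call_candidates(pN), pN)$position)
  # 3 of 10 flanking reads carry N: 30% > 20% -> removed
  readN <- plant_allele(planted, 31L, "N", 3L)
  pr <- pileup(readN)
  expect_false(30L %in% filter_flanking(call_candidates(pr), pr)$position)
  # exactly 2 of 10 (20%, not more) is tolerated
  read2 <- plant_allele(planted, 31L, "N", 2L)
  p2 <- pileup(read2)
  expect_true(30L %in% filter_flanking(call_candidates(p2), p2)$position)
})

test_that("calls at consensus ends are judged on the existing flank only", {
  cons <- strrep("A", 20)
  a <- plant_allele(uniform_stack(cons, depth = 10), 0L, "G", 4L)
  p <- pileup(a)
  calls <- call_candidates(p)
  expect_true(0L %in% filter_flanking(calls, p)$position)
})

test_that("per-gene deduplication keeps the isotig with most calls", {
  calls <- data.frame(
    isotig_id = c(rep("i1", 5), rep("i2", 3), rep("i3", 2)),
    position = c(1:5, 1:3, 1:2) * 10L,
    major_allele = "A", minor_allele = "G", depth = 12L,
    minor_fraction = 0.4, substitution_class = "AG_CT",
    is_transition = TRUE, high_depth = FALSE, stringsAsFactors = FALSE)
  ann <- data.frame(isotig_id = c("i1", "i2"), gene_id = c("gX", "gX"),
                    coverage = c(900, 700), stringsAsFactors = FALSE)
  out <- dedupe_per_gene(calls, ann)
  expect_setequal(unique(out$isotig_id), c("i1", "i3"))  # i2 dropped, i3 unmapped
  expect_equal(sum(out$isotig_id == "i1"), 5)
  # tie on call count: larger coverage wins
  calls2 <- calls[calls$isotig_id != "i3", ]
  calls2 <- calls2[c(1:3, 6:8), ]                        # 3 calls each
  out2 <- dedupe_per_gene(calls2, ann)
  expect_equal(unique(out2$isotig_id), "i1")
})

test_that("substitution classes partition the allele pairs", {
  expect_equal(classify_substitution("A", "G"), "AG_CT")
  expect_equal(classify_substitution("G", "A"), "AG_CT")  # symmetric
  expect_equal(classify_substitution("C", "T"), "AG_CT")
  expect_equal(classify_substitution("A", "C"), "AC_GT")
  expect_equal(classify_substitution("T", "G"), "AC_GT")
  expect_equal(classify_substitution("A", "T"), "AT")
  expect_equal(classify_substitution("C", "G"), "GC")
  expect_error(classify_substitution("A", "N"), "invalid")
})

test_that("summaries report class counts and rounded transition percentage", {
  mk_calls <- function(n_by_class, depth = 12L) {
    classes <- rep(names(n_by_class), n_by_class)
    data.frame(isotig_id = "i", position = seq_along(classes),
               major_allele = "A", minor_allele = "G", depth = depth,
               minor_fraction = 0.4, substitution_class = classes,
               is_transition = classes == "AG_CT",
               high_depth = depth >= 31, stringsAsFactors = FALSE)
  }
  s <- summarize_snps(mk_calls(c(AG_CT = 73, AC_GT = 17, AT = 6, GC = 4)))
  expect_equal(s$all$total, 100)
  expect_equal(s$all$transition_pct, 73L)
  # empty input: zeros with an undefined percentage
  empty <- summarize_snps(mk_calls(c(AG_CT = 1))[0, ])
  expect_equal(empty$all$total, 0)
  expect_true(is.na(empty$all$transition_pct))
  # the depth bound is inclusive: depth 31 calls land in the subset
  s31 <- summarize_snps(mk_calls(c(AG_CT = 10, AC_GT = 2), depth = 31L))
  expect_equal(s31$high_depth$total, s31$all$total)
})

test_that("call order is invariant to read order", {
  set.seed(9)
  cons <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  a <- plant_allele(uniform_stack(cons, depth = 12), 40L, "T", 5L)
  p1 <- pileup(a)
  shuffled <- a
  shuffled$reads <- shuffled$reads[sample(nrow(shuffled$reads)), ]
  p2 <- pileup(shuffled)
  c1 <- filter_flanking(call_candidates(p1), p1)
  c2 <- filter_flanking(call_candidates(p2), p2)
  expect_equal(c1, c2, ignore_attr = TRUE)
})

test_that("planted sites are recovered exactly on an error-free fixture", {
  # (generator-level recovery; per-stack mechanics are covered above)
  cfg <- sim_config(seed = 77, n_genes = 15, frac_novel_isotigs = 0,
                    depth_range = c(6L, 40L))
  panel <- generate_reference_panel(cfg)
  iso <- generate_isotigs(panel, cfg)
  asm <- generate_assemblies(iso, cfg)
  tr <- asm$truth$planted_snps
  eligible <- tr[tr$true_depth >= 6 & tr$true_alt_fraction >= 0.30, ]
  calls <- do.call(rbind, lapply(asm$assemblies, function(a) {
    p <- pileup(a)
    filter_flanking(call_candidates(p), p)
  }))
  key <- function(d) paste(d$isotig_id, d$position)
  expect_gt(nrow(eligible), 10)
  expect_true(all(key(eligible) %in% key(calls)))        # recall 100%
  expect_true(all(key(calls) %in% key(tr)))              # precision 100%
  # reported minor alleles and fractions match the plant
  m <- merge(calls, tr, by.x = c("isotig_id", "position"),
             by.y = c("isotig_id", "position"))
  expect_true(all(m$minor_allele == m$alt_allele |
                  m$minor_fraction == 0.5))  # at 0.5 the tie-break may flip
})
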