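test_that("a single HSP chains to itself", {
  ch <- chain_hsps(make_hsp(0, 100, 500, 600))
  expect_equal(ch$coverage, 100)
  expect_equal(nrow(ch$members), 1)
})

test_that("order-breaking HSPs are excluded from the chain", {
  # three colinear 100 bp HSPs plus one crossing the target order
  h <- rbind(make_hsp(0, 100, 0, 100),
             make_hsp(120, 220, 150, 250),
             make_hsp(240, 340, 300, 400),
             make_hsp(150, 250, 600, 700))   # crosses members 2-3 on target
  ch <- chain_hsps(h)
  bf <- brute_force_chain(h)
  expect_equal(ch$coverage, 300)
  expect_equal(ch$coverage, bf$coverage)
  expect_equal(ch$members[, c("q_start", "t_start")],
               bf$members[, c("q_start", "t_start")], ignore_attr = TRUE)
})

test_that("query-overlapping HSPs cannot co-chain; higher bits wins ties", {
  h <- rbind(make_hsp(0, 100, 0, 100, bits = 180),
             make_hsp(90, 190, 150, 250, bits = 200))  # 10 bp query overlap
  ch <- chain_hsps(h)
  bf <- brute_force_chain(h)
  expect_equal(ch$coverage, 100)
  expect_equal(ch$total_bits, 200)
  expect_equal(ch$total_bits, bf$total_bits)
})

test_that("chaining equals exhaustive best-subset search on random instances", {
  set.seed(1234)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    strand <- sample(c("+", "-"), 1)
    h <- random_hsp_set(n, strand)
    ch <- chain_hsps(h)
    bf <- brute_force_chain(h)
    expect_equal(ch$coverage, bf$coverage, info = sprintf("rep %d", rep))
    expect_equal(ch$total_bits, bf$total_bits, info = sprintf("rep %d", rep))
    expect_equal(ch$members[, c("q_start", "q_end", "t_start", "t_end")],
                 bf$members[, c("q_start", "q_end", "t_start", "t_end")],
                 ignore_attr = TRUE, info = sprintf("rep %d", rep))
  }
})

test_that("chaining rejects empty and mixed-strand input", {
  expect_error(chain_hsps(make_hsp(0, 10, 0, 10)[0, ]), "empty")
  expect_error(chain_hsps(rbind(make_hsp(0, 10, 0, 10),
                                make_hsp(20, 30, 20, 30, strand = "-"))),
               "strand")
})

test_that("gene resolution splits coverage into coding and UTR", {
  model <- make_model(cds = c(100L, 400L))
  models <- list(t = model)
  # chain entirely inside the 3' UTR
  utr <- resolve_gene(make_chain(make_hsp(0, 150, 420, 570)), models)
  expect_equal(utr$coding_bp, 0)
  expect_equal(utr$utr_bp, 150)
  # chain exactly spanning the CDS
  cds <- resolve_gene(make_chain(make_hsp(0, 300, 100, 400)), models)
  expect_equal(cds$coding_bp, 300)
  expect_equal(cds$utr_bp, 0)
  # half in: CDS 100-400, chain target 250-550 -> 150 coding
  half <- resolve_gene(make_chain(make_hsp(0, 300, 250, 550)), models)
  expect_equal(half$coding_bp, 150)
  expect_equal(half$utr_bp, 150)
  expect_error(resolve_gene(make_chain(make_hsp(0, 10, 0, 10,
                                                target = "nope")), models),
               "unknown transcript")
})

test_that("the 2x unique rule is conjunctive on coverage and bit-score", {
  mk <- function(cov, bits, gene, target = gene) {
    make_chain(make_hsp(0, cov, 0, cov, bits = bits, target = target),
               gene_id = gene)
  }
  expect_equal(classify_unique(list(mk(500, 450, "gA")))$status, "unique")
  both <- classify_unique(list(mk(1000, 900, "gA"), mk(400, 420, "gB")))
  expect_equal(both$status, "unique")
  expect_equal(both$size_ratio, 2.5)
  expect_equal(both$bits_ratio, 900 / 420, tolerance = 1e-12)
  bits_short <- classify_unique(list(mk(1000, 900, "gA"), mk(400, 460, "gB")))
  expect_equal(bits_short$status, "ambiguous")   # bits ratio 1.96 < 2
  expect_equal(classify_unique(list())$status, "no-hit")
})

test_that("transcripts of one gene are exempt from the dominance rule", {
  mk <- function(cov, bits, gene, target) {
    make_chain(make_hsp(0, cov, 0, cov, bits = bits, target = target),
               gene_id = gene)
  }
  # two same-gene transcripts with similar scores: naive rule would say
  # ambiguous, the same-gene grouping says unique
  same <- classify_unique(list(mk(800, 700, "gA", "tA1"),
                               mk(760, 690, "gA", "tA2")))
  expect_equal(same$status, "unique")
  # with a weak third gene the merged best still dominates
  mixed <- classify_unique(list(mk(800, 700, "gA", "tA1"),
                                mk(760, 690, "gA", "tA2"),
                                mk(300, 200, "gB", "tB")))
  expect_equal(mixed$status, "unique")
})

test_that("unique classification is order- and duplication-invariant", {
  mk <- function(cov, bits, gene) {
    make_chain(make_hsp(0, cov, 0, cov, bits = bits, target = gene),
               gene_id = gene)
  }
  chains <- list(mk(900, 800, "gA"), mk(400, 350, "gB"), mk(100, 90, "gC"))
  base <- classify_unique(chains)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    r <- classify_unique(chains[perm])
    expect_equal(r$status, base$status)
    expect_equal(r$size_ratio, base$size_ratio)
  }
  dup <- classify_unique(c(chains, chains[1]))
  expect_equal(dup$status, base$status)
  expect_equal(dup$size_ratio, base$size_ratio)
})

test_that("gene clustering picks representatives and disjoint footprints", {
  model <- make_model(tid = "t", gid = "g", len = 900L, cds = c(100L, 700L))
  models <- list(t = model)
  mkcall <- function(iso, qs, qe, ts, te, bits = (qe - qs) * 2) {
    ch <- make_chain(make_hsp(qs, qe, ts, te, bits = bits, query = iso),
                     gene_id = "g")
    structure(list(query_id = iso, status = "unique", best = ch,
                   runner_up = NULL, size_ratio = Inf, bits_ratio = Inf),
              class = "unique_call")
  }
  # three isotigs covering disjoint thirds -> all selected
  calls <- list(mkcall("i1", 0, 300, 0, 300), mkcall("i2", 0, 300, 300, 600),
                mkcall("i3", 0, 300, 600, 900))
  cl <- cluster_by_gene(calls, models, "mouse")[[1]]
  expect_setequal(cl$member_isotigs, c("i1", "i2", "i3"))
  expect_setequal(cl$non_overlapping, c("i1", "i2", "i3"))
  # nested footprints -> only the larger
  calls2 <- list(mkcall("big", 0, 600, 100, 700), mkcall("small", 0, 200, 300, 500))
  cl2 <- cluster_by_gene(calls2, models, "mouse")[[1]]
  expect_equal(cl2$representative, "big")
  expect_equal(cl2$non_overlapping, "big")
})

test_that("greedy non-overlapping selection matches brute force on a mixed fixture", {
  model <- make_model(tid = "t", gid = "g", len = 1200L, cds = c(0L, 1200L))
  models <- list(t = model)
  spans <- list(a = c(0, 500), b = c(450, 700), c = c(700, 1200),
                d = c(480, 950), e = c(1000, 1100))
  calls <- lapply(names(spans), function(nm) {
    s <- spans[[nm]]
    ch <- make_chain(make_hsp(0, s[2] - s[1], s[1], s[2], query = nm),
                     gene_id = "g")
    structure(list(query_id = nm, status = "unique", best = ch,
                   runner_up = NULL, size_ratio = Inf, bits_ratio = Inf),
              class = "unique_call")
  })
  cl <- cluster_by_gene(calls, models, "mouse")[[1]]
  # exhaustive search over disjoint subsets, greedy-compatible fixture
  best <- NULL; best_cov <- -1
  nm <- names(spans)
  for (mask in seq_len(2^5) - 1L) {
    idx <- which(bitwAnd(mask, 2^(0:4)) > 0)
    ok <- TRUE
    if (length(idx) > 1) {
      for (i in idx) for (j in idx) if (i < j) {
        if (max(spans[[i]][1], spans[[j]][1]) < min(spans[[i]][2], spans[[j]][2]))
          ok <- FALSE
      }
    }
    if (!ok) next
    cov <- sum(vapply(idx, function(i) spans[[i]][2] - spans[[i]][1], 1))
    if (cov > best_cov) { best_cov <- cov; best <- nm[idx] }
  }
  expect_setequal(cl$non_overlapping, best)
})

test_that("orthology categories follow shared-group counts", {
  ortho <- data.frame(
    gene_id = c("m1", "r1", "h1", "m2", "r2", "h2", "m3", "r3", "h3"),
    species = rep(c("mouse", "rat", "human"), 3),
    ortholog_group = c("OG1", "OG1", "OG1", "OG2", "OG2", "OGX", "OGa",
                       "OGb", "OGc"))
  g3 <- assign_category("i", c(mouse = "m1", rat = "r1", human = "h1"), ortho)
  expect_equal(g3$category, 3L)
  g2 <- assign_category("i", c(mouse = "m2", rat = "r2", human = "h2"), ortho)
  expect_equal(g2$category, 2L)
  g1 <- assign_category("i", c(mouse = "m3", rat = "r3", human = "h3"), ortho)
  expect_equal(g1$category, 1L)
  # missing species never matches: best a pair can do is category 2
  miss <- assign_category("i", c(mouse = "m1", rat = "r1", human = NA), ortho)
  expect_equal(miss$category, 2L)
  solo <- assign_category("i", c(mouse = "m1", rat = NA, human = NA), ortho)
  expect_equal(solo$category, 1L)
  expect_error(assign_category("i", c(mouse = NA, rat = NA, human = NA), ortho),
               "no species")
})

test_that("category recovery matches the planted panel structure", {
  cfg <- sim_config(seed = 51, n_genes = 40, frac_withheld = 0.15,
                    frac_reassigned = 0.2, frac_novel_isotigs = 0,
                    frac_splice_variants = 0, frac_partial = 0)
  pc <- pipeline_config(withr::local_tempdir(), seed = 51, sim = cfg)
  b <- run_simulate(pc)
  ann <- run_annotate(pc)
  panel <- b$panel
  vmap <- b$isotigs$truth$variant_map
  for (q in names(ann$categories)) {
    core <- vmap$core_id[vmap$isotig_id == q]
    g <- panel$genes[panel$genes$core_id == core, ]
    expected <- if (!is.na(g$withheld_species)) 2L
      else if (is.na(g$reassigned_species)) 3L
      else if (grepl(",", g$reassigned_species)) 1L else 2L
    expect_equal(ann$categories[[q]]$category, expected,
                 info = sprintf("isotig %s (gene %s)", q, core))
  }
})

test_that("coding-portion and size profiles land in the documented bins", {
  mk <- function(cat, coding, utr) {
    structure(list(isotig_id = "i", gene_by_species = NULL,
                   group_by_species = NULL, category = cat,
                   coding_portion = coding / (coding + utr),
                   aligned_total = coding + utr), class = "category_call")
  }
  calls <- list(mk(1L, 0, 300), mk(1L, 50, 250), mk(3L, 600, 600),
                mk(3L, 1700, 0))
  prof <- utr_profile(calls)
  expect_equal(unname(prof$portion["1", "<0.25"]), 2)
  expect_equal(unname(prof$portion["3", "0.5-0.75"]), 1)
  expect_equal(unname(prof$size["1", "<400"]), 2)
  expect_equal(unname(prof$size["3", ">=1600"]), 1)
})
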