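# End-to-end pipeline driver: simulate -> annotate -> {orf, snps, novel}
# -> de, with every stage reading and writing the plain-text formats of
# io_formats.  Stages are stateless: each reads its inputs from the output
# directory, so they can be re-run individually.

#' Pipeline configuration
#'
#' Collects every path and threshold of the pipeline.  The single master
#' seed governs all stochastic stages (per-stage sub-seeds are derived
#' deterministically from it).
#'
#' @param out_dir directory all stage outputs are written to.
#' @param seed master seed.
#' @param sim a [sim_config()] for the simulate stage (its seed is
#'   overridden by \code{seed}).
#' @param min_depth,min_fraction,high_depth SNP thresholds.
#' @param unique_ratio dominance ratio of the unique-hit rule.
#' @param orf_complete CDS-coverage fraction of the completeness flag.
#' @param novel_min_len,identity_reject,gap_open_multiplier novel-region
#'   thresholds.
#' @param alpha significance level used for selections and the summary.
#' @param gmt_path optional GMT file for term enrichment.
#' @param contrasts list of library index pairs tested by the DE stage.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(),
                            min_depth = 6L, min_fraction = 0.30,
                            high_depth = 31L, unique_ratio = 2.0,
                            orf_complete = 0.75, novel_min_len = 50L,
                            identity_reject = 70, gap_open_multiplier = 3.0,
                            alpha = 0.05, gmt_path = NULL,
                            contrasts = list(c(1L, 3L), c(2L, 4L),
                                             c(1L, 2L), c(3L, 4L))) {
  stopifnot(min_depth >= 1, min_fraction >= 0, min_fraction <= 1,
            high_depth >= min_depth, unique_ratio >= 1,
            orf_complete > 0, orf_complete < 1, novel_min_len >= 1,
            identity_reject > 0, identity_reject <= 100,
            gap_open_multiplier >= 1, alpha > 0, alpha < 1)
  sim$seed <- seed
  structure(list(out_dir = out_dir, seed = seed, sim = sim,
                 min_depth = min_depth, min_fraction = min_fraction,
                 high_depth = high_depth, unique_ratio = unique_ratio,
                 orf_complete = orf_complete, novel_min_len = novel_min_len,
                 identity_reject = identity_reject,
                 gap_open_multiplier = gap_open_multiplier, alpha = alpha,
                 gmt_path = gmt_path, contrasts = contrasts),
            class = "pipeline_config")
}

pc_path <- function(pc, ...) file.path(pc$out_dir, paste0(...))

require_stage <- function(pc, file, stage) {
  p <- pc_path(pc, file)
  if (!file.exists(p))
    stop(sprintf("missing %s: run %s first", p, stage), call. = FALSE)
  p
}

#' Run the simulate stage
#'
#' Generates the reference panel, isotigs, read stacks, hit table and
#' count table, and writes them (plus the planted truth) under the output
#' directory.
#'
#' @param pc a [pipeline_config()].
#' @return (invisibly) the in-memory bundle of generated objects.
#' @export
run_simulate <- function(pc) {
  cfg <- pc$sim
  dir.create(pc$out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- generate_reference_panel(cfg)
  iso <- generate_isotigs(panel, cfg)
  asm <- generate_assemblies(iso, cfg)
  iso$truth <- asm$truth
  ht <- generate_hit_table(iso, panel, cfg)
  cnt <- generate_counts(panel, cfg)
  iso$truth$planted_de_genes <- cnt$de_truth

  for (s in panel$species) {
    write_fasta(panel$transcripts[[s]], pc_path(pc, "ref_", s, "_transcripts.fa"))
    write_fasta(panel$genomes[[s]], pc_path(pc, "ref_", s, "_genome.fa"))
    sp_models <- Filter(function(m) m$species == s, panel$models)
    write_gff3_models(sp_models, pc_path(pc, "ref_", s, ".gff3"))
  }
  write_orthology(panel$orthology, pc_path(pc, "orthology.tsv"))
  write_fasta(iso$seqs, pc_path(pc, "isotigs.fa"))
  write_ace(asm$assemblies, pc_path(pc, "assembly.ace"))
  write_blast_tabular(ht$hits, pc_path(pc, "hits.tsv"))
  write_counts(cnt$counts, pc_path(pc, "counts.tsv"))
  write_tsv(iso$truth$planted_snps, pc_path(pc, "truth_snps.tsv"))
  write_tsv(iso$truth$planted_novel_regions, pc_path(pc, "truth_novel.tsv"))
  write_tsv(iso$truth$planted_de_genes, pc_path(pc, "truth_de.tsv"))
  write_tsv(iso$truth$variant_map, pc_path(pc, "variant_map.tsv"))
  write_tsv(ht$expected, pc_path(pc, "expected_chains.tsv"))
  invisible(list(panel = panel, isotigs = iso, assemblies = asm$assemblies,
                 hits = ht, counts = cnt))
}

load_models <- function(pc) {
  ortho <- read_orthology(require_stage(pc, "orthology.tsv", "run_simulate"))
  models <- list()
  for (s in pc$sim$species) {
    gff <- pc_path(pc, "ref_", s, ".gff3")
    if (!file.exists(gff)) next
    models <- c(models, read_gff3_models(gff,
      pc_path(pc, "ref_", s, "_transcripts.fa"), species = s,
      orthology = ortho))
  }
  list(models = models, orthology = ortho)
}

# Chain all HSPs of one query-target pair: split by strand, keep the
# better strand's chain.
chain_query_target <- function(hsps) {
  chains <- lapply(split(hsps, hsps$strand), chain_hsps)
  covs <- vapply(chains, `[[`, numeric(1), "coverage")
  bits <- vapply(chains, `[[`, numeric(1), "total_bits")
  chains[[order(-covs, -bits)[1]]]
}

#' Run the annotation stage
#'
#' Chains the hit table per isotig and target, resolves genes, screens
#' unique gene-level hits per species, clusters unique isotigs by gene,
#' and assigns orthology-consistency categories.  Writes
#' \code{annotation.tsv}, \code{clusters.tsv} and \code{categories.tsv}.
#'
#' @param pc a [pipeline_config()].
#' @return (invisibly) list with the per-species unique calls, clusters
#'   and category calls.
#' @export
run_annotate <- function(pc) {
  hsps <- read_blast_tabular(require_stage(pc, "hits.tsv", "run_simulate"))
  md <- load_models(pc)
  models <- md$models
  species_of <- vapply(models, `[[`, character(1), "species")

  calls <- list()   # calls[[species]][[query]]
  ann_rows <- list()
  for (q in unique(hsps$query_id)) {
    hq <- hsps[hsps$query_id == q, , drop = FALSE]
    chains <- lapply(split(hq, hq$target_id), chain_query_target)
    chains <- lapply(chains, resolve_gene, models = models)
    sp_of_chain <- vapply(chains, function(c) species_of[[c$target_id]],
                          character(1))
    for (s in unique(sp_of_chain)) {
      uc <- classify_unique(chains[sp_of_chain == s], ratio = pc$unique_ratio)
      uc$query_id <- q
      calls[[s]][[q]] <- uc
      b <- uc$best
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        isotig_id = q, species = s, status = uc$status,
        gene_id = if (is.null(b)) NA_character_ else b$gene_id,
        target_id = if (is.null(b)) NA_character_ else b$target_id,
        coverage = if (is.null(b)) 0 else b$coverage,
        bits = if (is.null(b)) 0 else b$total_bits,
        coding_bp = if (is.null(b)) NA_real_ else b$coding_bp,
        utr_bp = if (is.null(b)) NA_real_ else b$utr_bp,
        size_ratio = uc$size_ratio, bits_ratio = uc$bits_ratio,
        stringsAsFactors = FALSE)
    }
  }
  annotation <- do.call(rbind, ann_rows)
  annotation <- annotation[order(annotation$isotig_id, annotation$species), ]
  rownames(annotation) <- NULL
  write_tsv(annotation, pc_path(pc, "annotation.tsv"))

  cluster_rows <- list(); clusters <- list()
  for (s in names(calls)) {
    cl <- cluster_by_gene(calls[[s]], models, species = s)
    clusters[[s]] <- cl
    for (c in cl) cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
      species = s, gene_id = c$gene_id,
      n_members = length(c$member_isotigs),
      members = paste(c$member_isotigs, collapse = ","),
      representative = c$representative,
      non_overlapping = paste(c$non_overlapping, collapse = ","),
      stringsAsFactors = FALSE)
  }
  cl_tab <- rbind_or_empty(cluster_rows, c("species", "gene_id", "n_members",
                                           "members", "representative",
                                           "non_overlapping"))
  cl_tab <- cl_tab[order(cl_tab$species, cl_tab$gene_id), , drop = FALSE]
  rownames(cl_tab) <- NULL
  write_tsv(cl_tab, pc_path(pc, "clusters.tsv"))

  focal <- pc$sim$species[1]
  cat_rows <- list(); cats <- list()
  for (q in sort(unique(annotation$isotig_id))) {
    gene_by_sp <- vapply(pc$sim$species, function(s) {
      uc <- calls[[s]][[q]]
      if (!is.null(uc) && uc$status == "unique") uc$best$gene_id else NA_character_
    }, character(1))
    if (all(is.na(gene_by_sp))) next
    src <- calls[[focal]][[q]]
    if (is.null(src) || src$status != "unique") {
      s_ok <- pc$sim$species[which(!is.na(gene_by_sp))[1]]
      src <- calls[[s_ok]][[q]]
    }
    cc <- assign_category(q, gene_by_sp, md$orthology,
                          coding_bp = src$best$coding_bp,
                          utr_bp = src$best$utr_bp)
    cats[[q]] <- cc
    cat_rows[[length(cat_rows) + 1L]] <- data.frame(
      isotig_id = q, category = cc$category,
      genes = paste(ifelse(is.na(gene_by_sp), ".", gene_by_sp), collapse = ","),
      coding_portion = cc$coding_portion, aligned_total = cc$aligned_total,
      stringsAsFactors = FALSE)
  }
  cat_tab <- rbind_or_empty(cat_rows, c("isotig_id", "category", "genes",
                                        "coding_portion", "aligned_total"))
  write_tsv(cat_tab, pc_path(pc, "categories.tsv"))
  invisible(list(annotation = annotation, calls = calls, clusters = clusters,
                 categories = cats))
}

focal_unique <- function(pc, annotation) {
  focal <- pc$sim$species[1]
  annotation[annotation$species == focal & annotation$status == "unique", ,
             drop = FALSE]
}

#' Run the ORF-projection stage
#'
#' Projects each uniquely annotated isotig's reference CDS (focal
#' species) onto the isotig and predicts the protein.  Writes
#' \code{orf.tsv} and \code{proteins.fa}.
#'
#' @param pc a [pipeline_config()].
#' @return (invisibly) the named list of \code{orf_projection} objects.
#' @export
run_orf <- function(pc) {
  ann <- read.delim(require_stage(pc, "annotation.tsv", "run_annotate"),
                    stringsAsFactors = FALSE)
  isotigs <- read_fasta(require_stage(pc, "isotigs.fa", "run_simulate"))
  models <- load_models(pc)$models
  rows <- list(); projections <- list(); proteins <- character(0)
  fu <- focal_unique(pc, ann)
  for (i in seq_len(nrow(fu))) {
    q <- fu$isotig_id[i]; tid <- fu$target_id[i]
    prj <- project_orf(isotigs[[q]], models[[tid]], isotig_id = q)
    if (is.null(prj)) {
      rows[[length(rows) + 1L]] <- data.frame(
        isotig_id = q, reference = tid, aligned_cds_fraction = 0,
        orf_start = NA_integer_, orf_end = NA_integer_, frame = NA_integer_,
        ptc = NA, ptc_codon = NA_integer_, complete75 = FALSE,
        uninterrupted = NA, frameshift = NA, stringsAsFactors = FALSE)
      next
    }
    projections[[q]] <- prj
    proteins[q] <- prj$protein
    rows[[length(rows) + 1L]] <- data.frame(
      isotig_id = q, reference = tid,
      aligned_cds_fraction = prj$aligned_cds_fraction,
      orf_start = prj$orf_interval[1], orf_end = prj$orf_interval[2],
      frame = prj$frame, ptc = prj$ptc, ptc_codon = prj$ptc_codon,
      complete75 = prj$aligned_cds_fraction > pc$orf_complete,
      uninterrupted = prj$uninterrupted, frameshift = prj$frameshift,
      stringsAsFactors = FALSE)
  }
  tab <- rbind_or_empty(rows, c("isotig_id", "reference",
                                "aligned_cds_fraction", "orf_start", "orf_end",
                                "frame", "ptc", "ptc_codon", "complete75",
                                "uninterrupted", "frameshift"))
  write_tsv(tab, pc_path(pc, "orf.tsv"))
  if (length(proteins)) {
    tmp <- pc_path(pc, "proteins.fa.tmp")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), tmp,
                                width = 60L)
    file.rename(tmp, pc_path(pc, "proteins.fa"))
  }
  invisible(projections)
}

#' Run the SNP-calling stage
#'
#' Pileup, candidate filters and per-gene deduplication over the ACE
#' assemblies, using the annotation's unique isotig-to-gene map.  Writes
#' \code{snps.tsv} and \code{snp_summary.tsv}.
#'
#' @param pc a [pipeline_config()].
#' @return (invisibly) the [call_snps()] result.
#' @export
run_snps <- function(pc) {
  ann <- read.delim(require_stage(pc, "annotation.tsv", "run_annotate"),
                    stringsAsFactors = FALSE)
  assemblies <- read_ace(require_stage(pc, "assembly.ace", "run_simulate"))
  res <- call_snps(assemblies, annotation = focal_unique(pc, ann),
                   min_depth = pc$min_depth, min_fraction = pc$min_fraction,
                   high_depth = pc$high_depth)
  write_tsv(res$calls, pc_path(pc, "snps.tsv"))
  s <- res$summary
  srow <- function(t, label) data.frame(
    subset = label, total = t$total, genes = t$genes,
    AG_CT = t$class_counts[["AG_CT"]], AC_GT = t$class_counts[["AC_GT"]],
    AT = t$class_counts[["AT"]], GC = t$class_counts[["GC"]],
    transition_pct = t$transition_pct, stringsAsFactors = FALSE)
  write_tsv(rbind(srow(s$all, "all"),
                  srow(s$high_depth, sprintf("depth>=%d", s$high_depth_threshold))),
            pc_path(pc, "snp_summary.tsv"))
  invisible(res)
}

#' Run the novel-region stage
#'
#' Extracts alignment gaps of each uniquely annotated isotig as novel
#' candidates, realigns them against the intervening genomic spans of
#' every species, classifies survivors and tests their reading frames.
#' Writes \code{novel_regions.tsv} and \code{novel_alignments.txt}.
#'
#' @param pc a [pipeline_config()].
#' @return (invisibly) the list of finished candidates.
#' @export
run_novel <- function(pc) {
  ann <- read.delim(require_stage(pc, "annotation.tsv", "run_annotate"),
                    stringsAsFactors = FALSE)
  hsps <- read_blast_tabular(require_stage(pc, "hits.tsv", "run_simulate"))
  isotigs <- read_fasta(require_stage(pc, "isotigs.fa", "run_simulate"))
  models <- load_models(pc)$models
  genomes <- lapply(setNames(nm = pc$sim$species), function(s) {
    p <- pc_path(pc, "ref_", s, "_genome.fa")
    if (file.exists(p)) read_fasta(p) else character(0)
  })
  fu <- focal_unique(pc, ann)
  all_regions <- list(); report <- character(0)
  for (i in seq_len(nrow(fu))) {
    q <- fu$isotig_id[i]; tid <- fu$target_id[i]
    hq <- hsps[hsps$query_id == q & hsps$target_id == tid, , drop = FALSE]
    if (nrow(hq) < 2) next
    chain <- resolve_gene(chain_query_target(hq), models)
    core <- sub("^[^_]+_", "", chain$gene_id)
    homologs <- sprintf("%s_%s_t1", pc$sim$species, core)
    prj <- project_orf(isotigs[[q]], models[[tid]], isotig_id = q)
    regions <- detect_novel_regions(chain, isotigs[[q]], models, genomes,
                                    homologs, projection = prj,
                                    min_len = pc$novel_min_len,
                                    gap_open_multiplier = pc$gap_open_multiplier,
                                    identity_reject = pc$identity_reject)
    for (r in regions) {
      all_regions[[length(all_regions) + 1L]] <- r
      if (identical(r$status, "novel")) {
        m <- models[[tid]]
        span <- extract_target_span(r, m, genomes[[m$species]])
        if (!is.null(span))
          report <- c(report, format_novel_alignment(r, isotigs[[q]], span), "")
      }
    }
  }
  tab <- rbind_or_empty(lapply(all_regions, function(r) data.frame(
    isotig_id = r$isotig_id, start = r$start, end = r$end, length = r$length,
    class = r$class %||% NA_character_, status = r$status,
    intron_identity = r$intron_identity, orf_status = r$orf_status,
    stringsAsFactors = FALSE)),
    c("isotig_id", "start", "end", "length", "class", "status",
      "intron_identity", "orf_status"))
  write_tsv(tab, pc_path(pc, "novel_regions.tsv"))
  atomic_writelines(report, pc_path(pc, "novel_alignments.txt"))
  invisible(all_regions)
}

#' Run the differential-expression stage
#'
#' Tests every gene in every configured library contrast with the exact
#' conditional binomial test plus the four-library chi-squared test, and
#' adjusts with Benjamini-Hochberg and Storey.  With a GMT file
#' configured, term enrichment of the significantly up-regulated genes is
#' tested per contrast.  Writes \code{de.tsv} (and \code{enrichment.tsv}).
#'
#' @param pc a [pipeline_config()].
#' @return (invisibly) the combined DE table.
#' @export
run_de <- function(pc) {
  counts <- read_counts(require_stage(pc, "counts.tsv", "run_simulate"))
  de <- do.call(rbind, lapply(pc$contrasts, function(ct) de_table(counts, ct)))
  write_tsv(de, pc_path(pc, "de.tsv"))
  if (!is.null(pc$gmt_path)) {
    gmt <- read_gmt(pc$gmt_path)
    enr <- list()
    for (ct in unique(de$contrast)) {
      d <- de[de$contrast == ct, , drop = FALSE]
      d <- d[d$testable, , drop = FALSE]
      background <- d$gene_id
      for (dir in c("up", "down")) {
        sel <- d$gene_id[d$p_value < pc$alpha &
                         (if (dir == "up") d$M > 0 else d$M < 0)]
        if (length(sel) == 0) next
        e <- enrich(sel, background, gmt)
        if (nrow(e)) {
          e$contrast <- ct; e$direction <- dir
          enr[[length(enr) + 1L]] <- e
        }
      }
    }
    write_tsv(do.call(rbind, enr) %||%
                data.frame(term = character(), count = integer()),
              pc_path(pc, "enrichment.tsv"))
  }
  invisible(de)
}

#' Run the full pipeline
#'
#' All stages in dependency order, then a one-file summary of the
#' headline tallies: isotigs annotated, unique fractions, clusters,
#' category counts, SNP classes and transition percentage, novel regions
#' by class, and significant genes per contrast.
#'
#' @param pc a [pipeline_config()].
#' @return (invisibly) the summary as a named list.
#' @export
run_all <- function(pc) {
  run_simulate(pc)
  run_annotate(pc)
  run_orf(pc)
  snps <- run_snps(pc)
  run_novel(pc)
  de <- run_de(pc)

  isotigs <- read_fasta(pc_path(pc, "isotigs.fa"))
  ann <- read.delim(pc_path(pc, "annotation.tsv"), stringsAsFactors = FALSE)
  cl <- read.delim(pc_path(pc, "clusters.tsv"), stringsAsFactors = FALSE)
  cats <- read.delim(pc_path(pc, "categories.tsv"), stringsAsFactors = FALSE)
  nv <- read.delim(pc_path(pc, "novel_regions.tsv"), stringsAsFactors = FALSE)
  focal <- pc$sim$species[1]
  s <- snps$summary
  de_sig <- vapply(split(de$q_bh < pc$alpha & de$testable, de$contrast), sum,
                   numeric(1))
  summary <- c(list(
    n_isotigs = length(isotigs),
    mean_isotig_len = round(mean(nchar(isotigs)), 1),
    n_annotated = length(unique(ann$isotig_id)),
    unique_fraction_focal = round(mean(ann$status[ann$species == focal] == "unique"), 4),
    n_clusters_focal = sum(cl$species == focal),
    category_1 = sum(cats$category == 1),
    category_2 = sum(cats$category == 2),
    category_3 = sum(cats$category == 3),
    snps_total = s$all$total,
    snps_AG_CT = s$all$class_counts[["AG_CT"]],
    snps_AC_GT = s$all$class_counts[["AC_GT"]],
    snps_AT = s$all$class_counts[["AT"]],
    snps_GC = s$all$class_counts[["GC"]],
    transition_pct = s$all$transition_pct,
    snps_high_depth = s$high_depth$total,
    transition_pct_high_depth = s$high_depth$transition_pct,
    novel_regions = sum(nv$status == "novel"),
    novel_exon = sum(nv$status == "novel" & nv$class == "novel-exon"),
    insertion_in_exon = sum(nv$status == "novel" & nv$class == "insertion-in-exon"),
    rejected_intronic = sum(nv$status == "rejected-intronic")),
    as.list(setNames(de_sig, paste0("de_sig_", names(de_sig)))))
  write_tsv(data.frame(metric = names(summary),
                       value = unlist(lapply(summary, format), use.names = FALSE)),
            pc_path(pc, "summary.tsv"))
  invisible(summary)
}
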