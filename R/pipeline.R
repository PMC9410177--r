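# End-to-end orchestration: write simulated inputs to disk, run every stage
# from files under one configuration, and emit a report bundle.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write gene models as GFF3
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`, `strand`
#' @param path output GFF3 path
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$source <- "lignanscreen"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(NULL)
}

#' Write a simulated study to disk
#'
#' Serializes every pipeline input produced by the generator in the standard
#' text formats the pipeline consumes: GFF3 gene models, FASTA genome,
#' HMMER3 domtblout hit tables (one per family), PfamScan-style domain scan
#' TSV, similarity-edge TSV, anchor TSVs, paralog-pair TSV, cis-element and
#' TF-binding TSVs, expression matrix + sample sheet TSVs, kinetic profile
#' TSV, and the planted truth as JSON. Output bytes are a pure function of
#' the simulation object, so a fixed `rng_seed` gives bit-identical files.
#'
#' @param pangenome a [simulate_pangenome()] result
#' @param dir output directory (created if needed)
#' @param expression optional [simulate_expression()] result
#' @param profile optional [simulate_pinoresinol_profile()] result
#' @return invisibly, the named vector of written paths
#' @export
write_simulation <- function(pangenome, dir, expression = NULL, profile = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  hit_cols <- c("gene_id", "profile_id", "full_evalue", "dom_ievalue",
                "ali_start", "ali_end", "bit_score")
  write_domtblout(pangenome$hits[pangenome$hits$family == "POD", hit_cols],
                  p("pod_hits.domtblout"))
  write_domtblout(pangenome$hits[pangenome$hits$family == "LAC", hit_cols],
                  p("lac_hits.domtblout"))
  write_tsv(pangenome$scan_table, p("scan.tsv"))
  write_tsv(pangenome$edges, p("edges.tsv"))
  gv <- data.frame(gene_id = pangenome$hits$gene_id,
                   variety = sub("(POD|LAC|DECT|DECS|FILL|ACT).*$", "",
                                 pangenome$hits$gene_id),
                   stringsAsFactors = FALSE)
  write_tsv(gv, p("gene_varieties.tsv"))
  write_gene_models(pangenome$ref_genes, p("reference.gff3"))
  write_gene_models(pangenome$ath_genes, p("outgroup.gff3"))
  write_tsv(pangenome$intra_anchors, p("anchors_intra.tsv"))
  write_tsv(pangenome$cross_anchors, p("anchors_cross.tsv"))
  write_tsv(pangenome$truth$duplication_calls[, c("gene_a", "gene_b")],
            p("paralog_pairs.tsv"))
  Biostrings::writeXStringSet(pangenome$genome, p("genome.fa"))
  write_tsv(pangenome$elements, p("elements.tsv"))
  write_tsv(pangenome$binding_map, p("binding_map.tsv"))
  truth <- pangenome$truth
  truth$per_variety_counts <- as.list(truth$per_variety_counts)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(expression)) {
    write_expression_set(expression, p("expression.tsv"), p("samples.tsv"))
  }
  if (!is.null(profile)) {
    write_tsv(data.frame(stage = profile$stage, content = profile$content),
              p("profile.tsv"))
  }
  invisible(list.files(dir, full.names = TRUE))
}

#' Read a kinetic profile TSV (stage, content)
#' @param path TSV path
#' @return a `kinetic_profile`
#' @export
read_kinetic_profile <- function(path) {
  df <- read.delim(path)
  structure(list(stage = df$stage, content = df$content), class = "kinetic_profile")
}

#' Default pipeline parameters
#' @return named list of stage parameters
#' @export
default_pipeline_params <- function() {
  list(e_full = 1e-5, e_dom = 1e-5, min_score = 50,
       max_gap = 25, min_anchors = 5, tandem_max_rank_gap = 1,
       promoter_length = 2000, white_variety = "white",
       reference_gene = NULL, calibrator_sample = NULL,
       screen = list())
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates census -> synteny -> candidate screen -> promoter/TF
#' analysis -> (optional) qPCR validation from files on disk, then writes
#' every stage output plus a human-readable report. All referenced input
#' paths are validated up front; nothing is written if any is missing.
#'
#' @param config a YAML file path or a list with elements `inputs` (named
#'   input paths as written by [write_simulation()]), optional `params`
#'   (overrides of [default_pipeline_params()]) and `output_dir`
#' @return invisibly, the results bundle (also written to `output_dir`)
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  required <- c("pod_hits", "lac_hits", "scan", "edges", "gene_varieties",
                "gff", "gff_outgroup", "anchors_intra", "anchors_cross",
                "paralog_pairs", "expression", "samples", "profile",
                "genome", "elements", "binding_map")
  miss <- setdiff(required, names(inputs))
  if (length(miss)) stopf("pipeline config missing input(s): %s", paste(miss, collapse = ", "))
  for (nm in names(inputs)) {
    if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]])) {
      stopf("input '%s' does not exist: %s", nm, inputs[[nm]])
    }
  }
  params <- utils::modifyList(default_pipeline_params(), config$params %||% list())
  cfg <- do.call(screen_config, params$screen)

  ## census
  hits <- rbind(read_domtblout(inputs$pod_hits), read_domtblout(inputs$lac_hits))
  assignments <- call_family_members(hits, e_full = params$e_full, e_dom = params$e_dom)
  scan <- read.delim(inputs$scan, stringsAsFactors = FALSE)
  assignments <- verify_domains(assignments, scan)
  accepted <- assignments[assignments$status == "accepted", , drop = FALSE]
  gv <- read.delim(inputs$gene_varieties, stringsAsFactors = FALSE)
  gene_variety <- setNames(gv$variety, gv$gene_id)[accepted$gene_id]
  edges <- read.delim(inputs$edges, stringsAsFactors = FALSE)
  edges <- edges[edges$gene_a %in% accepted$gene_id &
                   edges$gene_b %in% accepted$gene_id, , drop = FALSE]
  groups <- cluster_orthogroups(edges, gene_variety, min_score = params$min_score)
  varieties <- sort(unique(unname(gene_variety)))
  classified <- classify_orthogroups(groups, varieties)
  fam_of <- setNames(accepted$family, accepted$gene_id)
  per_var <- table(factor(unname(gene_variety), levels = varieties))
  census <- summarize_counts(as.integer(per_var))
  names(census$per_variety_counts) <- varieties

  ## synteny
  ref_genes <- assign_ranks(read_gene_models(inputs$gff))
  out_genes <- assign_ranks(read_gene_models(inputs$gff_outgroup))
  anchors_intra <- read.delim(inputs$anchors_intra, stringsAsFactors = FALSE)
  anchors_cross <- read.delim(inputs$anchors_cross, stringsAsFactors = FALSE)
  blocks_intra <- chain_collinear_blocks(anchors_intra, ref_genes,
                                         max_gap = params$max_gap,
                                         min_anchors = params$min_anchors)
  blocks_cross <- chain_collinear_blocks(anchors_cross, ref_genes, out_genes,
                                         max_gap = params$max_gap,
                                         min_anchors = params$min_anchors)
  pairs <- read.delim(inputs$paralog_pairs, stringsAsFactors = FALSE)
  calls <- classify_duplicates(pairs, blocks_intra, ref_genes,
                               tandem_max_rank_gap = params$tandem_max_rank_gap)
  ref_fam <- intersect(ref_genes$gene_id, accepted$gene_id)
  synteny_frac <- lapply(split(ref_fam, fam_of[ref_fam]), function(g) {
    interspecies_synteny_fraction(g, blocks_cross)
  })

  ## candidate screen
  expr <- read_expression_set(inputs$expression, inputs$samples)
  profile <- read_kinetic_profile(inputs$profile)
  screen <- run_screen(expr, profile, classified, cfg,
                       white_variety = params$white_variety)

  ## promoters and TF enrichment of the final candidates
  genome <- Biostrings::readDNAStringSet(inputs$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  elements <- read.delim(inputs$elements, stringsAsFactors = FALSE)
  candidates <- screen$candidates
  promoter_stage <- if (length(candidates)) {
    proms <- extract_promoters(ref_genes[match(candidates, ref_genes$gene_id), ],
                               genome, length = params$promoter_length)
    occ <- scan_motifs(proms, elements)
    list(promoters = proms, occurrences = occ,
         categories = categorize_elements(occ, elements, genes = candidates))
  } else list(promoters = NULL, occurrences = NULL, categories = NULL)
  binding <- read.delim(inputs$binding_map, stringsAsFactors = FALSE)
  enrichment <- if (length(candidates)) {
    tf_enrichment(candidates, binding, background_genes = ref_fam)
  } else NULL

  ## qPCR validation (optional)
  qpcr <- NULL
  if (!is.null(inputs$ct)) {
    ct <- read.delim(inputs$ct, stringsAsFactors = FALSE)
    rel <- ddct(ct, params$reference_gene, params$calibrator_sample)
    fpkm_long <- data.frame(gene = rep(rownames(expr$fpkm), ncol(expr$fpkm)),
                            sample = rep(colnames(expr$fpkm), each = nrow(expr$fpkm)),
                            fpkm = as.vector(expr$fpkm), stringsAsFactors = FALSE)
    qpcr <- list(relative_expression = rel,
                 concordance = concordance(rel, fpkm_long))
  }

  results <- list(
    params = params, screen_config = cfg,
    assignments = assignments[, c("gene_id", "family", "status")],
    orthogroups = classified, census = census,
    blocks_intra = blocks_intra, blocks_cross = blocks_cross,
    duplication_calls = calls, synteny_fraction = synteny_frac,
    screen = screen, promoter = promoter_stage, enrichment = enrichment,
    qpcr = qpcr
  )
  if (!is.null(config$output_dir)) write_report(results, config$output_dir)
  invisible(results)
}

blocks_to_df <- function(blocks) {
  if (!length(blocks)) {
    return(data.frame(block_id = character(), chrom_a = character(),
                      chrom_b = character(), orientation = character(),
                      gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(block_id = sprintf("B%03d", i), chrom_a = b$chrom_a,
               chrom_b = b$chrom_b, orientation = b$orientation,
               gene_a = b$anchors$gene_a, gene_b = b$anchors$gene_b,
               stringsAsFactors = FALSE)
  }))
}

#' Write the pipeline report bundle
#'
#' Writes each stage output as TSV, a machine-readable `summary.json`, and a
#' human-readable `report.md` whose header echoes every threshold used.
#'
#' @param results bundle from [run_full_pipeline()]
#' @param dir output directory
#' @return invisibly, the summary list
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv(results$assignments, p("family_assignments.tsv"))
  write_tsv(results$orthogroups$groups, p("orthogroups.tsv"))
  write_tsv(blocks_to_df(results$blocks_intra), p("blocks_intra.tsv"))
  write_tsv(blocks_to_df(results$blocks_cross), p("blocks_cross.tsv"))
  write_tsv(results$duplication_calls, p("duplication_calls.tsv"))
  write_tsv(results$screen$report, p("candidate_report.tsv"))
  if (!is.null(results$promoter$occurrences)) {
    write_tsv(results$promoter$occurrences, p("motif_occurrences.tsv"))
    write_tsv(results$promoter$categories, p("element_categories.tsv"))
  }
  if (!is.null(results$enrichment)) write_tsv(results$enrichment, p("tf_enrichment.tsv"))
  if (!is.null(results$qpcr)) {
    write_tsv(results$qpcr$relative_expression, p("qpcr_relative_expression.tsv"))
  }

  cls_tab <- table(vapply(split(results$orthogroups$groups$cls,
                                results$orthogroups$groups$og_id), `[`, "", 1))
  dup_tab <- table(results$duplication_calls$cls)
  summary <- list(
    thresholds = results$params[c("e_full", "e_dom", "min_score", "max_gap",
                                  "min_anchors", "tandem_max_rank_gap")],
    screen_thresholds = unclass(results$screen_config),
    per_variety_counts = as.list(results$census$per_variety_counts),
    count_mean = results$census$mean, count_sd = results$census$sd,
    orthogroup_classes = as.list(cls_tab),
    duplication_classes = as.list(dup_tab),
    synteny_fraction = results$synteny_fraction,
    final_candidates = results$screen$candidates,
    top_tf_families = if (!is.null(results$enrichment)) {
      utils::head(results$enrichment$family, 3)
    } else character(),
    qpcr_r_squared = if (!is.null(results$qpcr)) results$qpcr$concordance$r_squared
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  lines <- c(
    "# Pan-genome oxidase census and candidate screen report", "",
    sprintf("Thresholds: E-value <= %g / domain E-value <= %g; orthogroup min score %g; block chaining max_gap %d, min_anchors %d; tandem rank gap <= %d.",
            results$params$e_full, results$params$e_dom, results$params$min_score,
            results$params$max_gap, results$params$min_anchors,
            results$params$tandem_max_rank_gap),
    sprintf("Screen thresholds: min_expr %g FPKM, seed fold %g, decline ratio %g from %g DAA, flat CV %g.",
            results$screen_config$min_expr, results$screen_config$seed_fold,
            results$screen_config$decline_ratio, results$screen_config$decline_stage,
            results$screen_config$flat_cv),
    "",
    "## Census",
    sprintf("Per-variety counts: %s.",
            paste(sprintf("%s = %d", names(results$census$per_variety_counts),
                          results$census$per_variety_counts), collapse = ", ")),
    sprintf("Mean +/- sd: %d +/- %d genes per variety.",
            round_half_up(results$census$mean), round_half_up(results$census$sd)),
    sprintf("Orthogroups: %s.",
            paste(sprintf("%d %s", as.integer(cls_tab), names(cls_tab)),
                  collapse = ", ")),
    "",
    "## Duplication and synteny",
    sprintf("Duplication calls: %s.",
            paste(sprintf("%d %s", as.integer(dup_tab), names(dup_tab)),
                  collapse = ", ")),
    paste(vapply(names(results$synteny_fraction), function(f) {
      s <- results$synteny_fraction[[f]]
      sprintf("%s: %d genes (%d%%) syntenic with the outgroup.", f, s$count, s$percent)
    }, ""), collapse = " "),
    "",
    "## Candidate screen",
    if (length(results$screen$candidates)) {
      sprintf("Final candidates (%d): %s.", length(results$screen$candidates),
              paste(results$screen$candidates, collapse = ", "))
    } else "No gene passed all screening criteria.",
    "",
    "## Regulation",
    if (!is.null(results$enrichment)) {
      sprintf("Top TF families by enrichment q-value: %s.",
              paste(utils::head(results$enrichment$family, 3), collapse = ", "))
    } else "TF enrichment not run (no candidates).",
    if (!is.null(results$qpcr)) {
      sprintf("qPCR vs RNA-seq concordance R^2 = %.4f over %d points.",
              results$qpcr$concordance$r_squared, results$qpcr$concordance$n)
    } else "qPCR validation not run (no Ct table provided)."
  )
  writeLines(lines, p("report.md"))
  invisible(summary)
}
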