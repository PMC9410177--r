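# Shared fixtures built in code.

# A small, fast simulation configuration for unit tests (the full-size
# defaults are exercised by the acceptance tests).
small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(family_sizes = c(POD = 18, LAC = 12), n_planted_candidates = 2,
         n_segmental_pairs = 3, n_tandem_pairs = 1, n_dispersed_pairs = 1,
         n_decoy_threshold = 2, n_decoy_spurious = 1,
         n_cross_blocks = 1, cross_block_size = 5, rng_seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Gene models laid out on one chromosome at the given rank order.
genes_at_ranks <- function(ids, chrom = "c1", spacing = 100) {
  data.frame(gene_id = ids, chrom = chrom,
             start = spacing * seq_along(ids), end = spacing * seq_along(ids) + 50,
             strand = "+", stringsAsFactors = FALSE)
}

# Random chaining instance: two chromosomes with n_a/n_b genes and m anchors.
random_anchor_instance <- function(n_a = 12, n_b = 12, m = 10) {
  ga <- genes_at_ranks(sprintf("a%02d", seq_len(n_a)), "cA")
  gb <- genes_at_ranks(sprintf("b%02d", seq_len(n_b)), "cB")
  grid <- expand.grid(a = seq_len(n_a), b = seq_len(n_b))
  pick <- grid[sample(nrow(grid), m), ]
  anchors <- data.frame(gene_a = ga$gene_id[pick$a], gene_b = gb$gene_id[pick$b],
                        score = 1, stringsAsFactors = FALSE)
  list(genes_a = ga, genes_b = gb, anchors = anchors,
       ra = pick$a, rb = pick$b)
}

# Minimal expression set: one organ panel sample per tissue plus seed time
# series for the oil and color panels, built from a per-gene profile spec.
make_expression <- function(fpkm, samples) expression_set(as.matrix(fpkm), samples)

organ_samples <- function(tissues = c("seed", "root", "leaf", "stem", "capsule"),
                          variety = "ref") {
  data.frame(sample_id = paste0("organ.", tissues), dataset = "organ",
             variety = variety, tissue = tissues, stage = 30, replicate = 1,
             stringsAsFactors = FALSE)
}

series_samples <- function(dataset, varieties, stages) {
  g <- expand.grid(variety = varieties, stage = stages, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s.%s.%d", dataset, g$variety, g$stage),
             dataset = dataset, variety = g$variety, tissue = "seed",
             stage = g$stage, replicate = 1, stringsAsFactors = FALSE)
}

run_recovery <- function(seed, noise_sd = NULL) {
  cfg <- if (is.null(noise_sd)) sim_config(rng_seed = seed) else
    sim_config(rng_seed = seed, noise_sd = noise_sd)
  st <- simulate_study(cfg)
  pg <- st$pangenome
  members <- pg$truth$orthogroup_members
  gv <- setNames(members$variety, members$gene_id)
  groups <- cluster_orthogroups(pg$edges, gv, min_score = 50)
  classified <- classify_orthogroups(groups, pg$varieties)
  screen <- run_screen(st$expression, st$profile, classified)
  list(study = st, screen = screen, classified = classified)
}
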