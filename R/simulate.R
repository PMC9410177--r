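# Synthetic pan-genome and expression generator with known ground truth.
# Every pipeline input (domain hits incl. decoys, similarity edges, gene
# coordinates, genome and promoter sequences, expression panels, Ct tables)
# can be generated so that the downstream stages have an exactly known
# correct answer.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package emulates: a six-variety
#' pan-genome with two oxidase families (class III peroxidases, POD, and
#' laccases, LAC), a multi-organ expression atlas, an oil-content seed time
#' series (10-30 DAA) and a white/black seed-color time series (5-30 DAA),
#' with four planted pinoresinol-synthase-like candidates and one flat
#' seed-preferential confounder.
#'
#' @param n_varieties number of pan-genome varieties (default 6)
#' @param family_sizes named counts of orthogroups per family
#'   (default `c(POD = 60, LAC = 40)`), the per-variety target gene counts
#' @param core_fraction proportion of orthogroups present in all varieties
#'   (default 0.65)
#' @param n_planted_candidates planted true candidates, drawn from core
#'   orthogroups of the reference variety (default 4)
#' @param stages list with DAA sampling points for the `oil` and `color`
#'   panels; each must be strictly increasing
#' @param tissues organ labels of the multi-organ panel
#' @param noise_sd lognormal sigma of multiplicative FPKM noise
#'   (default 0.15)
#' @param decoy_evalue_range interval, strictly above the 1e-5 acceptance
#'   threshold, from which decoy-hit E-values are drawn
#' @param n_segmental_pairs,n_tandem_pairs,n_dispersed_pairs planted paralog
#'   pairs by duplication mode (defaults 18, 1, 2)
#' @param n_decoy_threshold,n_decoy_spurious per-variety decoy genes removed
#'   by the E-value filter and by domain verification, respectively
#' @param n_cross_blocks,cross_block_size planted cross-species collinear
#'   blocks and family anchors per block (defaults 2 and 6)
#' @param candidate_base peak seed FPKM of planted candidates (default 30)
#' @param candidate_fold seed/other-organ fold of planted candidates
#'   (default 8)
#' @param rng_seed integer seed; a fixed seed makes all outputs bit-identical
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_varieties = 6,
                       family_sizes = c(POD = 60, LAC = 40),
                       core_fraction = 0.65,
                       n_planted_candidates = 4,
                       stages = list(oil = c(10, 20, 25, 30),
                                     color = c(5, 8, 11, 14, 17, 20, 23, 26, 30)),
                       tissues = c("seed", "root", "leaf", "stem", "capsule"),
                       noise_sd = 0.15,
                       decoy_evalue_range = c(1e-4, 1e-2),
                       n_segmental_pairs = 18,
                       n_tandem_pairs = 1,
                       n_dispersed_pairs = 2,
                       n_decoy_threshold = 5,
                       n_decoy_spurious = 3,
                       n_cross_blocks = 2,
                       cross_block_size = 6,
                       candidate_base = 30,
                       candidate_fold = 8,
                       rng_seed = 1) {
  if (!is_count1(n_varieties) || n_varieties < 2) {
    stopf("sim_config: 'n_varieties' must be an integer >= 2")
  }
  if (is.null(names(family_sizes)) || !all(family_sizes >= 1)) {
    stopf("sim_config: 'family_sizes' must be a named vector of positive counts")
  }
  if (!is_prob1(core_fraction)) stopf("sim_config: 'core_fraction' must be in [0, 1]")
  if (!is_count1(n_planted_candidates)) {
    stopf("sim_config: 'n_planted_candidates' must be a nonnegative integer")
  }
  for (panel in names(stages)) {
    s <- stages[[panel]]
    if (!length(s) || any(diff(s) <= 0)) {
      stopf("sim_config: 'stages' (%s) must be strictly increasing", panel)
    }
  }
  if (!"seed" %in% tissues) stopf("sim_config: 'tissues' must include 'seed'")
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("sim_config: 'noise_sd' must be >= 0")
  if (length(decoy_evalue_range) != 2 || decoy_evalue_range[1] <= 1e-5 ||
      diff(decoy_evalue_range) <= 0) {
    stopf("sim_config: 'decoy_evalue_range' must be an increasing interval strictly above 1e-5")
  }
  if (!is_count1(rng_seed %% 2^31)) stopf("sim_config: 'rng_seed' must be an integer")
  structure(list(
    n_varieties = n_varieties, family_sizes = family_sizes,
    core_fraction = core_fraction, n_planted_candidates = n_planted_candidates,
    stages = stages, tissues = tissues, noise_sd = noise_sd,
    decoy_evalue_range = decoy_evalue_range,
    n_segmental_pairs = n_segmental_pairs, n_tandem_pairs = n_tandem_pairs,
    n_dispersed_pairs = n_dispersed_pairs,
    n_decoy_threshold = n_decoy_threshold, n_decoy_spurious = n_decoy_spurious,
    n_cross_blocks = n_cross_blocks, cross_block_size = cross_block_size,
    candidate_base = candidate_base, candidate_fold = candidate_fold,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Bundled toy cis-element table
#'
#' A small set of well-known plant promoter elements with IUPAC consensus
#' strings and functional categories, standing in for a versioned remote
#' element database so that scanning is reproducible offline.
#' @return data.frame `name`, `consensus`, `category`
#' @export
default_cis_elements <- function() {
  data.frame(
    name = c("ABRE", "TGACG-motif", "G-box", "GT1-motif", "MBS", "LTR",
             "W-box", "ARE", "RY-element", "Skn-1-motif", "CAAT-box"),
    consensus = c("ACGTGGC", "TGACG", "CACGTG", "GGTTAA", "CAACTG", "CCGAAA",
                  "TTGACY", "AAACCA", "CATGCA", "GTCAT", "CCAAT"),
    category = c("hormonal", "hormonal", "light", "light", "stress", "stress",
                 "stress", "stress", "development", "development", "other"),
    stringsAsFactors = FALSE
  )
}

# IUPAC nucleotide sets shared by the generator and the motif scanner.
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

realize_iupac <- function(consensus) {
  letters <- strsplit(consensus, "")[[1]]
  paste(vapply(letters, function(l) {
    s <- iupac_sets[[l]]
    if (is.null(s)) stopf("invalid IUPAC letter '%s' in consensus '%s'", l, consensus)
    if (length(s) == 1L) s else sample(s, 1L)
  }, ""), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Genome layout constants: gene spacing/length chosen so that 2-kb promoter
# windows of neighbouring genes can never overlap each other or gene bodies.
.GENE_SPACING <- 5500L
.GENE_LEN <- 1000L
.FIRST_START <- 2500L
.PROM_LEN <- 2000L

chrom_coords <- function(pos) {
  start <- .FIRST_START + (pos - 1L) * .GENE_SPACING
  cbind(start = start, end = start + .GENE_LEN - 1L)
}

#' Simulate a pan-genome with planted ground truth
#'
#' Generates the full input bundle for the census, synteny and promoter
#' stages: per-variety family genes organized into orthogroups with a known
#' core/shared/specific structure, HMMER-style domain hits including decoys
#' that the E-value filter must remove and spurious genes that domain
#' verification must remove, a similarity edge table whose connected
#' components are the true orthogroups, reference-genome gene coordinates
#' with planted tandem/segmental/dispersed paralog pairs inside generated
#' collinear blocks, a cross-species anchor set, a reference genome sequence
#' with motifs planted in candidate promoters, and a TF-binding map in which
#' MYB binds all planted candidates.
#'
#' @param cfg a [sim_config()]
#' @return object of class `pangenome_sim`; element `truth` carries all
#'   planted labels
#' @export
simulate_pangenome <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(cfg$rng_seed)
  varieties <- paste0("var", seq_len(cfg$n_varieties))
  ref <- varieties[1]

  ## ---- orthogroup skeleton ----
  fam_of_og <- rep(names(cfg$family_sizes), cfg$family_sizes)
  n_og <- length(fam_of_og)
  n_core <- round(cfg$core_fraction * n_og)
  n_rest <- n_og - n_core
  n_spec <- floor(n_rest / 2)
  cls <- sample(c(rep("core", n_core), rep("specific", n_spec),
                  rep("shared", n_rest - n_spec)))
  og_id <- sprintf("TOG%03d", seq_len(n_og))
  present <- vector("list", n_og)
  for (i in seq_len(n_og)) {
    present[[i]] <- switch(cls[i],
      core = varieties,
      specific = varieties[(i - 1L) %% cfg$n_varieties + 1L],
      shared = sort(sample(varieties, sample(2:(cfg$n_varieties - 1L), 1L)))
    )
  }

  members <- do.call(rbind, lapply(seq_len(n_og), function(i) {
    data.frame(og_id = og_id[i], family = fam_of_og[i],
               gene_id = sprintf("%s%s%03d", present[[i]], fam_of_og[i], i),
               variety = present[[i]], stringsAsFactors = FALSE)
  }))

  ## ---- planted candidates and flat confounder (core, reference) ----
  core_ref <- members[members$variety == ref &
                        members$og_id %in% og_id[cls == "core"], , drop = FALSE]
  if (cfg$n_planted_candidates > nrow(core_ref) - 1L) {
    stopf("sim_config: 'n_planted_candidates' exceeds available core reference genes")
  }
  picks <- if (cfg$n_planted_candidates > 0) {
    sample(nrow(core_ref), cfg$n_planted_candidates + 1L)
  } else sample(nrow(core_ref), 1L)
  candidate_genes <- if (cfg$n_planted_candidates > 0) {
    sort(core_ref$gene_id[picks[seq_len(cfg$n_planted_candidates)]])
  } else character()
  flat_confounder <- core_ref$gene_id[picks[length(picks)]]

  ## ---- reference genome layout with planted duplications ----
  ref_members <- members[members$variety == ref, , drop = FALSE]
  chroms <- paste0("chr", 1:4)
  chrom_of <- chroms[(seq_len(nrow(ref_members)) - 1L) %% 4L + 1L]
  fam_lists <- split(ref_members$gene_id, chrom_of)[chroms]  # immutable source pool
  chrom_lists <- fam_lists                                   # working gene order

  extra_genes <- list() # gene_id -> og_id/family for paralog partners
  add_member <- function(src, suffix) {
    i <- match(src, members$gene_id)
    id <- paste0(src, suffix)
    extra_genes[[id]] <<- list(og_id = members$og_id[i], family = members$family[i])
    id
  }

  duplication_calls <- data.frame(gene_a = character(), gene_b = character(),
                                  cls = character(), stringsAsFactors = FALSE)
  nxt <- c(chr1 = 1L, chr2 = 1L, chr3 = 1L, chr4 = 1L) # next unused family gene
  draw_sources <- function(chrom, k) {
    idx <- seq.int(nxt[chrom], length.out = k)
    if (max(idx) > length(fam_lists[[chrom]])) {
      stopf("sim_config: 'family_sizes' too small for the planted duplication/synteny layout")
    }
    nxt[chrom] <<- nxt[chrom] + k
    fam_lists[[chrom]][idx]
  }

  # tandem pairs: partner inserted immediately after its source on chr1
  for (t in seq_len(cfg$n_tandem_pairs)) {
    src <- draw_sources("chr1", 1L)
    partner <- add_member(src, "_td")
    pos <- match(src, chrom_lists$chr1)
    chrom_lists$chr1 <- append(chrom_lists$chr1, partner, after = pos)
    duplication_calls <- rbind(duplication_calls,
      data.frame(gene_a = src, gene_b = partner, cls = "tandem"))
  }

  # segmental pairs inside planted collinear blocks: each block pairs three
  # family genes (plus four filler anchors) on a source chromosome with new
  # partner genes appended to chr4; one block is inverted.
  n_blocks <- ceiling(cfg$n_segmental_pairs / 3)
  intra_anchors <- data.frame(gene_a = character(), gene_b = character(),
                              score = numeric(), stringsAsFactors = FALSE)
  filler_i <- 0L
  seg_left <- cfg$n_segmental_pairs
  for (b in seq_len(n_blocks)) {
    chrA <- chroms[(b - 1L) %% 3L + 1L]
    take <- min(3L, seg_left)
    seg_left <- seg_left - take
    srcs <- draw_sources(chrA, take)
    partners <- vapply(srcs, add_member, "", suffix = "_sd")
    fillers <- sprintf("%sFILL%03d", ref, filler_i + seq_len(take + 1L))
    filler_i <- filler_i + take + 1L
    # interleave fillers F1 s1 F2 s2 ... sK F(K+1) on chrA
    a_order <- character(2L * take + 1L)
    a_order[seq(1L, by = 2L, length.out = take + 1L)] <- fillers
    a_order[seq(2L, by = 2L, length.out = take)] <- srcs
    pos <- match(srcs[1], chrom_lists[[chrA]])
    chrom_lists[[chrA]] <- append(
      setdiff(chrom_lists[[chrA]], srcs),
      a_order, after = pos - 1L
    )
    b_partner <- paste0(a_order, "_p")
    b_partner[a_order %in% srcs] <- partners
    filler_partners <- setdiff(b_partner, partners)
    for (fp in filler_partners) extra_genes[[fp]] <- list(og_id = NA, family = NA)
    inverted <- b == 3L
    chrom_lists$chr4 <- c(chrom_lists$chr4, if (inverted) rev(b_partner) else b_partner)
    intra_anchors <- rbind(intra_anchors,
      data.frame(gene_a = a_order, gene_b = b_partner,
                 score = round(runif(length(a_order), 200, 900), 1)))
    duplication_calls <- rbind(duplication_calls,
      data.frame(gene_a = srcs, gene_b = partners, cls = "segmental"))
  }

  # dispersed pairs: partners appended far away, never anchored in a block
  disp_srcs <- draw_sources("chr4", cfg$n_dispersed_pairs)
  for (k in seq_len(cfg$n_dispersed_pairs)) {
    partner <- add_member(disp_srcs[k], "_dd")
    home <- c("chr2", "chr3")[(k - 1L) %% 2L + 1L]
    chrom_lists[[home]] <- c(chrom_lists[[home]], partner)
    duplication_calls <- rbind(duplication_calls,
      data.frame(gene_a = disp_srcs[k], gene_b = partner, cls = "dispersed"))
  }

  # decoy anchors on chr1 x chr2 in scrambled order: too few and too
  # disordered to ever reach the minimum block size
  decoy_a <- sprintf("%sFILL%03d", ref, filler_i + 1:4); filler_i <- filler_i + 4L
  decoy_b <- sprintf("%sFILL%03d", ref, filler_i + 1:4); filler_i <- filler_i + 4L
  for (g in c(decoy_a, decoy_b)) extra_genes[[g]] <- list(og_id = NA, family = NA)
  chrom_lists$chr1 <- c(chrom_lists$chr1, decoy_a)
  chrom_lists$chr2 <- c(chrom_lists$chr2, decoy_b)
  intra_anchors <- rbind(intra_anchors,
    data.frame(gene_a = decoy_a, gene_b = decoy_b[c(3, 1, 4, 2)],
               score = round(runif(4, 200, 900), 1)))

  ## ---- cross-species synteny (reference vs outgroup genome) ----
  cross_anchors <- data.frame(gene_a = character(), gene_b = character(),
                              score = numeric(), stringsAsFactors = FALSE)
  ath_list <- sprintf("athBG%02d", 1:3) # leading background genes
  syntenic_genes <- character()
  for (b in seq_len(cfg$n_cross_blocks)) {
    chrA <- c("chr2", "chr3", "chr4", "chr1")[(b - 1L) %% 4L + 1L]
    k <- cfg$cross_block_size
    srcs <- draw_sources(chrA, k)
    partners <- sprintf("athG%03d", (b - 1L) * k + seq_len(k))
    ath_list <- c(ath_list, partners)
    cross_anchors <- rbind(cross_anchors,
      data.frame(gene_a = srcs, gene_b = partners,
                 score = round(runif(k, 200, 900), 1)))
    syntenic_genes <- c(syntenic_genes, srcs)
  }
  # only family genes count toward the synteny fraction truth
  fam_univ <- c(members$gene_id,
                names(extra_genes)[!vapply(extra_genes, function(e) is.na(e$family[1]), TRUE)])
  syntenic_genes <- sort(intersect(syntenic_genes, fam_univ))

  ## ---- gene model tables ----
  ref_genes <- do.call(rbind, lapply(chroms, function(ch) {
    ids <- chrom_lists[[ch]]
    co <- chrom_coords(seq_along(ids))
    data.frame(gene_id = ids, chrom = ch, start = co[, "start"], end = co[, "end"],
               strand = rep_len(c("+", "-"), length(ids)), stringsAsFactors = FALSE)
  }))
  co <- chrom_coords(seq_along(ath_list))
  ath_genes <- data.frame(gene_id = ath_list, chrom = "athChr1",
                          start = co[, "start"], end = co[, "end"],
                          strand = rep_len(c("+", "-"), length(ath_list)),
                          stringsAsFactors = FALSE)

  ## ---- extend orthogroup membership with reference paralogs ----
  paralogs <- names(extra_genes)[!vapply(extra_genes, function(e) is.na(e$og_id[1]), TRUE)]
  if (length(paralogs)) {
    members <- rbind(members, do.call(rbind, lapply(paralogs, function(g) {
      data.frame(og_id = extra_genes[[g]]$og_id, family = extra_genes[[g]]$family,
                 gene_id = g, variety = ref, stringsAsFactors = FALSE)
    })))
  }
  members <- members[order(members$og_id, members$gene_id), , drop = FALSE]
  rownames(members) <- NULL

  ## ---- domain hits, decoys, scan table ----
  profiles <- c(POD = "PF00141.26", LAC = "TIGR03390.1")
  domains <- default_family_domains()
  n_mem <- nrow(members)
  hits <- data.frame(
    gene_id = members$gene_id,
    profile_id = unname(profiles[members$family]),
    full_evalue = 10^-runif(n_mem, 6, 40),
    dom_ievalue = 10^-runif(n_mem, 6, 40),
    ali_start = sample(1:20, n_mem, replace = TRUE),
    ali_end = sample(220:300, n_mem, replace = TRUE),
    bit_score = round(runif(n_mem, 100, 600), 1),
    family = members$family,
    truth_status = "accepted",
    stringsAsFactors = FALSE
  )
  lo <- log10(cfg$decoy_evalue_range[1]); hi <- log10(cfg$decoy_evalue_range[2])
  mk_decoys <- function(kind, n_per_var, status) {
    if (n_per_var == 0) return(NULL)
    ids <- as.vector(outer(sprintf("%s%s", varieties, kind), seq_len(n_per_var),
                           function(v, i) sprintf("%s%02d", v, i)))
    fam <- rep_len(names(cfg$family_sizes), length(ids))
    above <- status == "rejected_threshold"
    data.frame(
      gene_id = ids, profile_id = unname(profiles[fam]),
      full_evalue = if (above) 10^runif(length(ids), lo, hi) else 10^-runif(length(ids), 6, 40),
      dom_ievalue = if (above) 10^runif(length(ids), lo, hi) else 10^-runif(length(ids), 6, 40),
      ali_start = sample(1:20, length(ids), replace = TRUE),
      ali_end = sample(220:300, length(ids), replace = TRUE),
      bit_score = round(runif(length(ids), if (above) 10 else 100, if (above) 40 else 600), 1),
      family = fam, truth_status = status, stringsAsFactors = FALSE
    )
  }
  hits <- rbind(hits,
                mk_decoys("DECT", cfg$n_decoy_threshold, "rejected_threshold"),
                mk_decoys("DECS", cfg$n_decoy_spurious, "rejected_spurious"))
  scan_table <- data.frame(
    gene_id = hits$gene_id,
    domain = ifelse(hits$truth_status == "rejected_spurious", "ABC_membrane",
                    unname(domains[hits$family])),
    stringsAsFactors = FALSE
  )

  ## ---- similarity edges: chains within orthogroups, weak decoy edges ----
  edges <- do.call(rbind, lapply(split(members$gene_id, members$og_id), function(g) {
    g <- sort(g)
    if (length(g) < 2L) return(NULL)
    data.frame(gene_a = g[-length(g)], gene_b = g[-1],
               score = round(runif(length(g) - 1L, 80, 100), 2),
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  og_of <- setNames(members$og_id, members$gene_id)
  decoy_pairs <- matrix(sample(members$gene_id, 20L), ncol = 2)
  keep <- og_of[decoy_pairs[, 1]] != og_of[decoy_pairs[, 2]]
  if (any(keep)) {
    edges <- rbind(edges, data.frame(
      gene_a = decoy_pairs[keep, 1], gene_b = decoy_pairs[keep, 2],
      score = round(runif(sum(keep), 5, 40), 2), stringsAsFactors = FALSE))
  }

  ## ---- genome sequence with planted promoter motifs ----
  elements <- default_cis_elements()
  chrom_len <- vapply(chrom_lists, function(g)
    .FIRST_START + length(g) * .GENE_SPACING + 3500L, 0L)
  genome <- lapply(chrom_len, random_dna)
  plant_in <- unique(c(candidate_genes, flat_confounder,
                       sample(setdiff(ref_genes$gene_id, c(candidate_genes, flat_confounder)), 2L)))
  planted_motifs <- list()
  promoters_truth <- character()
  plant_set <- c("RY-element", "ABRE", "MBS", "G-box")
  for (g in plant_in) {
    prom <- random_dna(.PROM_LEN)
    mot <- data.frame(element = character(), start = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    starts <- sort(sample(seq(10L, .PROM_LEN - 60L, by = 60L),
                          length(plant_set)))
    for (j in seq_along(plant_set)) {
      el <- elements[elements$name == plant_set[j], ]
      inst <- realize_iupac(el$consensus)
      strand <- sample(c("+", "-"), 1L)
      put <- if (strand == "-") revcomp_chr(inst) else inst
      substr(prom, starts[j], starts[j] + nchar(put) - 1L) <- put
      mot <- rbind(mot, data.frame(element = el$name, start = starts[j],
                                   strand = strand, stringsAsFactors = FALSE))
    }
    gi <- ref_genes[ref_genes$gene_id == g, ]
    if (gi$strand == "+") {
      substr(genome[[gi$chrom]], gi$start - .PROM_LEN, gi$start - 1L) <- prom
    } else {
      substr(genome[[gi$chrom]], gi$end + 1L, gi$end + .PROM_LEN) <- revcomp_chr(prom)
    }
    planted_motifs[[g]] <- mot
    promoters_truth[g] <- prom
  }
  genome <- Biostrings::DNAStringSet(unlist(genome))
  names(genome) <- chroms

  ## ---- TF binding map: MYB binds every planted candidate ----
  families <- c("MYB", "NAC", "bZIP", "HSF", "HD-ZIP", "MIKC_MADS", "WRKY", "AP2")
  ref_fam_genes <- sort(intersect(ref_genes$gene_id, fam_univ))
  non_cand <- setdiff(ref_fam_genes, candidate_genes)
  binding <- list(MYB = sort(c(candidate_genes,
                               sample(non_cand, round(0.25 * length(non_cand))))))
  for (f in families[-1]) {
    binding[[f]] <- sort(sample(non_cand, round(runif(1, 0.08, 0.2) * length(non_cand))))
  }
  binding_map <- do.call(rbind, lapply(names(binding), function(f) {
    data.frame(family = f, gene_id = binding[[f]], stringsAsFactors = FALSE)
  }))

  truth <- list(
    candidate_genes = candidate_genes,
    flat_confounder = flat_confounder,
    orthogroup_classes = setNames(cls, og_id),
    orthogroup_members = members,
    member_status = setNames(hits$truth_status, hits$gene_id),
    duplication_calls = duplication_calls,
    planted_motifs = planted_motifs,
    promoters = promoters_truth,
    syntenic_genes = syntenic_genes,
    per_variety_counts = table(members$variety)[varieties]
  )
  structure(list(
    cfg = cfg, varieties = varieties, reference = ref,
    ref_genes = ref_genes, ath_genes = ath_genes,
    hits = hits, scan_table = scan_table, edges = edges,
    intra_anchors = intra_anchors, cross_anchors = cross_anchors,
    genome = genome, elements = elements, binding_map = binding_map,
    truth = truth
  ), class = "pangenome_sim")
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat(sprintf("pangenome_sim: %d varieties, %d orthogroups, %d reference genes\n",
              length(x$varieties), length(x$truth$orthogroup_classes),
              nrow(x$ref_genes)))
  cat(sprintf("  planted: %d candidates, %d duplication pairs, motifs in %d promoters\n",
              length(x$truth$candidate_genes), nrow(x$truth$duplication_calls),
              length(x$truth$planted_motifs)))
  invisible(x)
}

# Planted mean trajectory of a rise-fall (candidate) gene: linear rise from
# `early_level` at 5 DAA to the peak at 20 DAA, then exponential decay with
# a 3-day time constant (decline ratio past 23 DAA ~ 0.18 of the peak).
candidate_shape <- function(stage, early_level = 0.3, peak = 20, tau = 3) {
  ifelse(stage <= peak,
         pmax(early_level, early_level + (1 - early_level) * (stage - 5) / (peak - 5)),
         exp(-(stage - peak) / tau))
}

late_shape <- function(stage) exp(-(30 - stage) / 4)

# Planted mean FPKM for one gene in one sample.
planted_mean <- function(archetype, dataset, tissue, stage, base, fold) {
  other <- base / fold
  switch(archetype,
    candidate = if (dataset == "organ") {
      if (tissue == "seed") base else other
    } else base * candidate_shape(stage),
    flat_seed = if (dataset == "organ") {
      if (tissue == "seed") 0.8 * base else 0.8 * other
    } else 0.8 * base,
    other_tissue = if (dataset == "organ") {
      if (tissue == "seed") 2 else base
    } else 5,
    late_peak = if (dataset == "organ") {
      if (tissue == "seed") 20 else 2
    } else 25 * late_shape(stage),
    low = if (dataset == "organ") { if (tissue == "seed") 0.4 else 0.2 } else 0.3,
    flat_low = 0.5,
    housekeeping = 50
  )
}

#' Simulate the three expression panels
#'
#' Builds the multi-organ atlas (reference variety, five organs), the
#' oil-content seed time series (one high-oil and two low-oil varieties) and
#' the white/black seed-color time series, with planted per-gene mean
#' trajectories: planted candidates rise from 5 DAA, peak at 20 DAA and
#' decline steeply after 23 DAA while being seed-preferential and expressed
#' early in every variety; the flat confounder is seed-preferential and
#' expressed early but constant across stages; remaining genes are
#' other-organ-dominant, late-peaking, or weakly/flatly expressed.
#' Multiplicative lognormal noise with sigma `cfg$noise_sd` is applied, so
#' log-FPKM is Gaussian around the log of the planted mean.
#'
#' @param cfg a [sim_config()]
#' @param truth the `truth` element of a [simulate_pangenome()] result (or
#'   the result itself)
#' @return an [expression_set()] over the reference-variety family genes and
#'   a constitutive housekeeping gene (`<ref>ACT1`)
#' @export
simulate_expression <- function(cfg, truth) {
  if (inherits(truth, "pangenome_sim")) truth <- truth$truth
  if (is.null(truth$orthogroup_members)) {
    stopf("truth must come from simulate_pangenome()")
  }
  set.seed(derive_seed(cfg$rng_seed, 101L))
  ref <- "var1"
  genes <- sort(unique(truth$orthogroup_members$gene_id[
    truth$orthogroup_members$variety == ref]))
  arch <- setNames(rep_len(c("other_tissue", "late_peak", "low", "flat_low"),
                           length(genes)), sample(genes))
  arch[truth$candidate_genes] <- "candidate"
  arch[truth$flat_confounder] <- "flat_seed"
  hk <- paste0(ref, "ACT1")
  genes <- c(genes, hk)
  arch[hk] <- "housekeeping"
  arch <- arch[genes]

  samples <- rbind(
    data.frame(dataset = "organ", variety = ref, tissue = cfg$tissues,
               stage = 30, replicate = 1, stringsAsFactors = FALSE),
    expand.grid(dataset = "oil", variety = c("oilHigh1", "oilLow1", "oilLow2"),
                tissue = "seed", stage = cfg$stages$oil, replicate = 1,
                stringsAsFactors = FALSE),
    expand.grid(dataset = "color", variety = c("white", "black"),
                tissue = "seed", stage = cfg$stages$color, replicate = 1,
                stringsAsFactors = FALSE)
  )
  samples$sample_id <- sprintf("%s.%s.%s.%d.r%d", samples$dataset, samples$variety,
                               samples$tissue, samples$stage, samples$replicate)
  samples <- samples[, c("sample_id", "dataset", "variety", "tissue", "stage", "replicate")]

  mu <- matrix(0, nrow = length(genes), ncol = nrow(samples),
               dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu[, j] <- vapply(genes, function(g) {
      planted_mean(arch[[g]], samples$dataset[j], samples$tissue[j],
                   samples$stage[j], cfg$candidate_base, cfg$candidate_fold)
    }, 0)
  }
  noise <- matrix(exp(rnorm(length(mu), 0, cfg$noise_sd)), nrow = nrow(mu))
  fpkm <- mu * noise
  expr <- expression_set(fpkm, samples)
  attr(expr, "archetypes") <- arch
  attr(expr, "planted_means") <- mu
  expr
}

#' Parametric pinoresinol accumulation profile
#'
#' A unimodal rise-fall curve of relative (+)-pinoresinol content across
#' seed development, peaking at 20 DAA. The published profile is
#' figure-derived from an external metabolite study; this parametric
#' stand-in reproduces its qualitative shape (see the methods vignette).
#'
#' @param stages numeric vector of DAA sampling points (increasing)
#' @return object of class `kinetic_profile`: list with `stage` and
#'   nonnegative `content`
#' @export
simulate_pinoresinol_profile <- function(stages) {
  if (!length(stages)) stopf("stages must be nonempty")
  if (any(diff(stages) <= 0)) stopf("stages must be strictly increasing")
  content <- 10 * exp(-((stages - 20)^2) / 50)
  structure(list(stage = stages, content = content), class = "kinetic_profile")
}

#' @export
print.kinetic_profile <- function(x, ...) {
  cat("kinetic_profile over", length(x$stage), "stages; peak at",
      x$stage[which.max(x$content)], "DAA\n")
  invisible(x)
}

#' Simulate qPCR Ct values from expression
#'
#' Back-computes cycle-threshold values from FPKM under the standard
#' exponential-amplification model, `Ct = intercept - log2(FPKM + 1)`, with
#' Gaussian technical noise of standard deviation `ct_sd` and three
#' replicates per gene x sample.
#'
#' @param expr an [expression_set()]
#' @param genes target genes (must be rows of `expr`)
#' @param reference_gene housekeeping gene id (must be a row of `expr`)
#' @param ct_sd Gaussian noise sd in cycles
#' @param seed RNG seed
#' @param intercept Ct of a transcript at FPKM 0 (default 35 cycles)
#' @param n_replicates replicates per gene x sample (default 3)
#' @return data.frame `gene`, `sample`, `replicate`, `ct`
#' @export
simulate_ct <- function(expr, genes, reference_gene, ct_sd = 0.2, seed = 1,
                        intercept = 35, n_replicates = 3) {
  if (!reference_gene %in% rownames(expr$fpkm)) {
    stopf("reference gene '%s' absent from expression data", reference_gene)
  }
  miss <- setdiff(genes, rownames(expr$fpkm))
  if (length(miss)) stopf("unknown target gene(s): %s", paste(miss, collapse = ", "))
  set.seed(seed)
  all_genes <- unique(c(genes, reference_gene))
  grid <- expand.grid(gene = all_genes, sample = colnames(expr$fpkm),
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  base_ct <- intercept - log2(expr$fpkm[cbind(grid$gene, grid$sample)] + 1)
  grid$ct <- base_ct + rnorm(nrow(grid), 0, ct_sd)
  grid[order(grid$gene, grid$sample, grid$replicate), , drop = FALSE]
}

#' One-call study simulation
#'
#' Convenience wrapper: pan-genome, expression panels and metabolite profile
#' under one configuration.
#' @param cfg a [sim_config()]
#' @return list with `pangenome`, `expression`, `profile`
#' @export
simulate_study <- function(cfg = sim_config()) {
  pg <- simulate_pangenome(cfg)
  expr <- simulate_expression(cfg, pg$truth)
  profile <- simulate_pinoresinol_profile(cfg$stages$color)
  list(pangenome = pg, expression = expr, profile = profile)
}
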