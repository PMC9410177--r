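# Multi-stage candidate screen: seed preference -> early expression in the
# oil panel -> early presence in the white-seed panel -> kinetic concordance
# with the pinoresinol accumulation curve -> pan-genome core membership.

#' Screen configuration
#'
#' Thresholds for the candidate screen. The source studies state the
#' criteria qualitatively ("preferentially expressed in seed", "expressed
#' early"); the quantitative defaults here are deliberate, documented
#' choices (see the methods vignette) and are echoed in screen output.
#'
#' @param min_expr FPKM floor for calling a gene expressed (default 1.0)
#' @param seed_fold required fold of mean seed FPKM over the maximum mean
#'   FPKM of any other organ (default 2.0)
#' @param early_stages optional DAA stage set to use as "early"; by default
#'   each dataset's earliest sampled stage is used
#' @param decline_ratio late-stage mean FPKM must be at most this fraction
#'   of the peak for the kinetic criterion (default 0.7)
#' @param decline_stage DAA from which expression must decline (default 23)
#' @param flat_cv minimum coefficient of variation across stages; flatter
#'   trajectories are excluded as not matching the lignan kinetic
#'   (default 0.3)
#' @param color_early_max latest DAA still counted as "early" in the
#'   seed-color panel (default 8)
#' @param pseudocount pseudocount for log2 transformation (default 1.0)
#' @return object of class `screen_config`
#' @export
screen_config <- function(min_expr = 1.0, seed_fold = 2.0, early_stages = NULL,
                          decline_ratio = 0.7, decline_stage = 23,
                          flat_cv = 0.3, color_early_max = 8,
                          pseudocount = 1.0) {
  for (nm in c("min_expr", "seed_fold", "decline_ratio", "decline_stage",
               "flat_cv", "color_early_max", "pseudocount")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stopf("screen_config: '%s' must be a positive number", nm)
    }
  }
  if (decline_ratio >= 1) stopf("screen_config: 'decline_ratio' must be < 1")
  structure(list(min_expr = min_expr, seed_fold = seed_fold,
                 early_stages = early_stages, decline_ratio = decline_ratio,
                 decline_stage = decline_stage, flat_cv = flat_cv,
                 color_early_max = color_early_max, pseudocount = pseudocount),
            class = "screen_config")
}

#' Log2 transform FPKM with a pseudocount
#'
#' @param x numeric matrix/vector of FPKM values (nonnegative)
#' @param pseudocount positive offset added before log2 (default 1)
#' @return log2(x + pseudocount), same shape as `x`
#' @export
log_transform <- function(x, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) stopf("pseudocount must be > 0")
  v <- if (inherits(x, "expression_set")) x$fpkm else x
  if (any(v < 0)) stopf("FPKM values must be nonnegative")
  log2(v + pseudocount)
}

#' Seed-preference filter (multi-organ panel)
#'
#' A gene passes when its mean seed FPKM is at least `seed_fold` times the
#' maximum mean FPKM over every other organ (root, leaf, stem, capsule) and
#' at least `min_expr`. Replicates are averaged first; comparisons are
#' inclusive. The fold value is `Inf` when the gene is silent outside the
#' seed.
#'
#' @param expr `expression_set` restricted to the multi-organ panel
#' @param cfg a [screen_config()]
#' @return data.frame `gene_id`, `fold`, `pass`
#' @export
seed_preference_filter <- function(expr, cfg = screen_config()) {
  tissues <- unique(expr$samples$tissue)
  if (!"seed" %in% tissues) stopf("seed tissue missing from the multi-organ panel")
  others <- setdiff(tissues, "seed")
  if (!length(others)) stopf("multi-organ panel needs at least one non-seed tissue")
  seed_mean <- mean_fpkm(expr, expr$samples$tissue == "seed")
  other_means <- vapply(others, function(t) mean_fpkm(expr, expr$samples$tissue == t),
                        numeric(nrow(expr$fpkm)))
  if (is.null(dim(other_means))) other_means <- matrix(other_means, ncol = length(others))
  max_other <- apply(other_means, 1L, max)
  fold <- ifelse(max_other == 0, Inf, seed_mean / max_other)
  pass <- seed_mean >= cfg$seed_fold * max_other & seed_mean >= cfg$min_expr
  data.frame(gene_id = rownames(expr$fpkm), fold = fold, pass = pass,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Per-variety early stages: the configured set if given, else the earliest
# sampled stage; errors if a variety lacks the early stage(s).
early_stages_by_variety <- function(samples, early_stages) {
  vars <- unique(samples$variety)
  setNames(lapply(vars, function(v) {
    st <- sort(unique(samples$stage[samples$variety == v]))
    if (is.null(early_stages)) return(st[1L])
    use <- intersect(early_stages, st)
    if (!length(use)) {
      stopf("variety '%s' has no sample at the configured early stage(s) %s",
            v, paste(early_stages, collapse = ", "))
    }
    use
  }), vars)
}

#' Early-expression filter (oil-content seed panel)
#'
#' A gene passes when its mean FPKM at the earliest sampled stage (10 DAA in
#' the oil panel) is at least `min_expr` in every variety of the panel.
#'
#' @param expr `expression_set` restricted to the oil-content seed panel
#' @param genes genes to evaluate (default: all genes in `expr`)
#' @param cfg a [screen_config()]
#' @return data.frame `gene_id`, `pass`
#' @export
early_expression_filter <- function(expr, genes = rownames(expr$fpkm),
                                    cfg = screen_config()) {
  stages <- early_stages_by_variety(expr$samples, cfg$early_stages)
  pass <- rep(TRUE, length(genes))
  for (v in names(stages)) {
    sel <- expr$samples$variety == v & expr$samples$stage %in% stages[[v]]
    if (!any(sel)) stopf("variety '%s' missing its earliest stage", v)
    m <- mean_fpkm(expr, sel)[genes]
    pass <- pass & m >= cfg$min_expr
  }
  data.frame(gene_id = genes, pass = pass, row.names = NULL, stringsAsFactors = FALSE)
}

#' Early-presence filter (seed-color panel)
#'
#' A gene passes when it is expressed (mean FPKM >= `min_expr`) at every
#' early stage (<= `color_early_max` DAA, i.e. 5 and 8 DAA in the
#' white/black panel) of the white-seeded variety. Presence, not dominance
#' over the black variety, is required: a gene higher in black seed early
#' on but present in white seed still passes and is left to the kinetic
#' criterion.
#'
#' @param expr `expression_set` restricted to the seed-color panel
#' @param genes genes to evaluate
#' @param white_variety label of the white-seeded variety
#' @param cfg a [screen_config()]
#' @return data.frame `gene_id`, `pass`
#' @export
seedcolor_filter <- function(expr, genes = rownames(expr$fpkm),
                             white_variety = "white", cfg = screen_config()) {
  if (!white_variety %in% expr$samples$variety) {
    stopf("white variety '%s' absent from the seed-color panel", white_variety)
  }
  st <- sort(unique(expr$samples$stage[expr$samples$variety == white_variety]))
  early <- st[st <= cfg$color_early_max]
  if (!length(early)) {
    stopf("white variety '%s' has no stage <= %s DAA", white_variety, cfg$color_early_max)
  }
  pass <- rep(TRUE, length(genes))
  for (s in early) {
    sel <- expr$samples$variety == white_variety & expr$samples$stage == s
    pass <- pass & mean_fpkm(expr, sel)[genes] >= cfg$min_expr
  }
  data.frame(gene_id = genes, pass = pass, row.names = NULL, stringsAsFactors = FALSE)
}

#' Kinetic concordance of a seed trajectory with the pinoresinol curve
#'
#' Tests whether a stage trajectory matches the lignan biosynthesis kinetic:
#' (a) the expression peak falls strictly before the last sampled stage;
#' (b) mean FPKM over stages at or after `decline_stage` (23 DAA) is at most
#' `decline_ratio` times the peak FPKM; and (c) the coefficient of variation
#' across stages is at least `flat_cv`, excluding constitutively expressed
#' genes. The Pearson correlation between the trajectory and the metabolite
#' profile over shared stages is reported but not thresholded.
#'
#' @param trajectory named numeric vector, names = DAA stages, values = FPKM
#' @param profile a [kinetic_profile()] or named numeric vector of relative
#'   pinoresinol content by stage
#' @param cfg a [screen_config()]
#' @return list `pass`, `peak_stage`, `decline_ratio_observed`, `cv`, `corr`
#' @export
kinetic_concordance <- function(trajectory, profile, cfg = screen_config()) {
  stages <- as.numeric(names(trajectory))
  if (length(stages) < 4L || anyNA(stages)) {
    stopf("kinetic concordance needs a trajectory over >= 4 named stages")
  }
  o <- order(stages)
  stages <- stages[o]
  traj <- as.numeric(trajectory)[o]
  peak_i <- which.max(traj)
  peak_stage <- stages[peak_i]
  cond_a <- peak_stage < stages[length(stages)]
  late <- stages >= cfg$decline_stage
  decline_obs <- if (any(late) && traj[peak_i] > 0) {
    mean(traj[late]) / traj[peak_i]
  } else NA_real_
  cond_b <- !is.na(decline_obs) && decline_obs <= cfg$decline_ratio
  cv <- if (mean(traj) > 0) sd(traj) / mean(traj) else 0
  cond_c <- cv >= cfg$flat_cv
  prof <- if (inherits(profile, "kinetic_profile")) {
    setNames(profile$content, profile$stage)
  } else profile
  shared <- intersect(names(trajectory), names(prof))
  corr <- if (length(shared) >= 3L &&
              sd(trajectory[shared]) > 0 && sd(prof[shared]) > 0) {
    cor(as.numeric(trajectory[shared]), as.numeric(prof[shared]))
  } else NA_real_
  list(pass = cond_a && cond_b && cond_c, peak_stage = peak_stage,
       decline_ratio_observed = decline_obs, cv = cv, corr = corr)
}

#' Retain genes belonging to core orthogroups
#'
#' @param genes gene ids to filter
#' @param orthogroups classified orthogroup table (with `cls`) as produced
#'   by [classify_orthogroups()]
#' @return character vector of genes whose orthogroup is `core`; genes not
#'   found in any orthogroup are treated as non-core with a warning
#' @export
core_membership_filter <- function(genes, orthogroups) {
  groups <- if (is.list(orthogroups) && !is.data.frame(orthogroups)) {
    orthogroups$groups
  } else orthogroups
  m <- match(genes, groups$gene_id)
  if (anyNA(m)) {
    warnf("gene(s) absent from all orthogroups treated as non-core: %s",
          paste(genes[is.na(m)], collapse = ", "))
  }
  genes[!is.na(m) & groups$cls[m] == "core"]
}

#' Run the full candidate screen
#'
#' Applies, in order: seed-preference (multi-organ panel), early expression
#' (oil-content panel), early presence in white seed (seed-color panel),
#' kinetic concordance of the white-variety trajectory with the pinoresinol
#' accumulation profile, and pan-genome core membership. Each stage is
#' evaluated on the survivors of the previous one; the report keeps every
#' input gene with its per-stage outcome (`NA` for stages it was not
#' evaluated at). The final candidate set passes all five criteria.
#'
#' @param expr an [expression_set()] containing the three panels
#' @param profile a [kinetic_profile()]
#' @param orthogroups classified orthogroups from [classify_orthogroups()]
#' @param cfg a [screen_config()]
#' @param datasets named character vector mapping panel roles (`organ`,
#'   `oil`, `color`) to dataset labels in the sample sheet
#' @param white_variety label of the white-seeded variety in the color panel
#' @return object of class `candidate_screen` with elements `report`
#'   (per-gene audit trail), `candidates` and `config`
#' @export
run_screen <- function(expr, profile, orthogroups, cfg = screen_config(),
                       datasets = c(organ = "organ", oil = "oil", color = "color"),
                       white_variety = "white") {
  genes <- sort(rownames(expr$fpkm))
  n <- length(genes)
  report <- data.frame(
    gene_id = genes,
    stage1_seed_pref = rep(NA, n), seed_fold_value = rep(NA_real_, n),
    stage2_early_oil = rep(NA, n), stage3_color = rep(NA, n),
    kinetic_pass = rep(NA, n), peak_stage = rep(NA_real_, n),
    decline_ratio_observed = rep(NA_real_, n), trajectory_cv = rep(NA_real_, n),
    kinetic_corr = rep(NA_real_, n), core_member = rep(NA, n),
    final = rep(FALSE, n),
    row.names = genes, stringsAsFactors = FALSE
  )
  if (!length(genes)) {
    return(structure(list(report = report[, , drop = FALSE],
                          candidates = character(), config = cfg),
                     class = "candidate_screen"))
  }
  for (role in c("organ", "oil", "color")) {
    if (!datasets[[role]] %in% expr$samples$dataset) {
      stopf("expression data is missing the '%s' panel (dataset label '%s')",
            role, datasets[[role]])
    }
  }
  organ <- subset_expression(expr, dataset = datasets[["organ"]])
  oil <- subset_expression(expr, dataset = datasets[["oil"]])
  color <- subset_expression(expr, dataset = datasets[["color"]])

  s1 <- seed_preference_filter(organ, cfg)
  report[s1$gene_id, "stage1_seed_pref"] <- s1$pass
  report[s1$gene_id, "seed_fold_value"] <- s1$fold
  surv <- s1$gene_id[s1$pass]

  if (length(surv)) {
    s2 <- early_expression_filter(oil, genes = surv, cfg = cfg)
    report[s2$gene_id, "stage2_early_oil"] <- s2$pass
    surv <- s2$gene_id[s2$pass]
  }
  if (length(surv)) {
    s3 <- seedcolor_filter(color, genes = surv, white_variety = white_variety,
                           cfg = cfg)
    report[s3$gene_id, "stage3_color"] <- s3$pass
    surv <- s3$gene_id[s3$pass]
  }
  if (length(surv)) {
    white <- subset_expression(color, variety = white_variety)
    stages <- sort(unique(white$samples$stage))
    traj_mat <- vapply(stages, function(s) {
      mean_fpkm(white, white$samples$stage == s)[surv]
    }, numeric(length(surv)))
    if (is.null(dim(traj_mat))) traj_mat <- matrix(traj_mat, nrow = length(surv))
    for (i in seq_along(surv)) {
      kin <- kinetic_concordance(setNames(traj_mat[i, ], stages), profile, cfg)
      report[surv[i], "kinetic_pass"] <- kin$pass
      report[surv[i], "peak_stage"] <- kin$peak_stage
      report[surv[i], "decline_ratio_observed"] <- kin$decline_ratio_observed
      report[surv[i], "trajectory_cv"] <- kin$cv
      report[surv[i], "kinetic_corr"] <- kin$corr
    }
    surv <- surv[report[surv, "kinetic_pass"]]
  }
  if (length(surv)) {
    core <- core_membership_filter(surv, orthogroups)
    report[surv, "core_member"] <- surv %in% core
    surv <- core
  }
  report$final <- rownames(report) %in% surv
  structure(list(report = report, candidates = sort(surv), config = cfg),
            class = "candidate_screen")
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat("Candidate screen:", nrow(x$report), "genes evaluated\n")
  cat(sprintf("  thresholds: min_expr=%g seed_fold=%g decline_ratio=%g (from %g DAA) flat_cv=%g\n",
              x$config$min_expr, x$config$seed_fold, x$config$decline_ratio,
              x$config$decline_stage, x$config$flat_cv))
  if (length(x$candidates)) {
    cat("  final candidates:", paste(x$candidates, collapse = ", "), "\n")
  } else {
    cat("  final candidates: none\n")
  }
  invisible(x)
}

#' @method summary candidate_screen
#' @export
summary.candidate_screen <- function(object, ...) {
  r <- object$report
  counts <- c(
    evaluated = nrow(r),
    seed_preferential = sum(r$stage1_seed_pref, na.rm = TRUE),
    early_in_oil_panel = sum(r$stage2_early_oil, na.rm = TRUE),
    early_in_white_seed = sum(r$stage3_color, na.rm = TRUE),
    kinetic_concordant = sum(r$kinetic_pass, na.rm = TRUE),
    core_members = sum(r$core_member, na.rm = TRUE),
    final = sum(r$final)
  )
  structure(list(counts = counts, candidates = object$candidates,
                 config = object$config),
            class = "summary.candidate_screen")
}

#' @export
print.summary.candidate_screen <- function(x, ...) {
  cat("Candidate screen funnel:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  cat("Candidates:", if (length(x$candidates)) paste(x$candidates, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
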