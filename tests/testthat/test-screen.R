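# Candidate screen: individual filters, kinetic concordance, full funnel.

test_that("log transform is exact at the pseudocount and order-preserving", {
  expect_identical(log_transform(0, 1), 0)
  expect_identical(log_transform(1, 1), 1)
  expect_error(log_transform(-1), "nonnegative")
  expect_error(log_transform(1, 0), "pseudocount")
  set.seed(5)
  x <- matrix(rexp(60), 10)
  y <- log_transform(x, 0.5)
  expect_true(all((order(x) == order(y))))
})

test_that("seed preference requires fold dominance and the expression floor", {
  organ <- organ_samples()
  fpkm <- rbind(
    silent_elsewhere = c(10, 0, 0, 0, 0),
    root_gene = c(0, 5, 0, 0, 0),
    boundary = c(4, 2, 1, 1, 1),
    below_floor = c(0.6, 0.1, 0.1, 0.1, 0.1)
  )
  colnames(fpkm) <- organ$sample_id
  res <- seed_preference_filter(make_expression(fpkm, organ))
  got <- setNames(res$pass, res$gene_id)
  expect_true(got[["silent_elsewhere"]])
  expect_identical(res$fold[res$gene_id == "silent_elsewhere"], Inf)
  expect_false(got[["root_gene"]])
  expect_true(got[["boundary"]]) # seed exactly seed_fold x max(other): inclusive
  expect_false(got[["below_floor"]])
  no_seed <- organ[organ$tissue != "seed", ]
  expect_error(seed_preference_filter(
    make_expression(fpkm[, no_seed$sample_id], no_seed)), "seed tissue missing")
})

test_that("early-oil filter needs the floor at every variety's earliest stage", {
  oil <- series_samples("oil", c("h1", "l1", "l2"), c(10, 20, 25, 30))
  fpkm <- matrix(5, nrow = 2, ncol = nrow(oil),
                 dimnames = list(c("ok", "late"), oil$sample_id))
  fpkm["late", oil$stage == 10 & oil$variety == "l2"] <- 0
  res <- early_expression_filter(make_expression(fpkm, oil))
  expect_identical(setNames(res$pass, res$gene_id), c(ok = TRUE, late = FALSE))
  cfg_bad <- screen_config(early_stages = 7)
  expect_error(early_expression_filter(make_expression(fpkm, oil), cfg = cfg_bad),
               "early stage")
})

test_that("seed-color filter requires presence, not dominance, in white seed", {
  color <- series_samples("color", c("white", "black"), c(5, 8, 14, 20, 23, 26, 30))
  fpkm <- matrix(0.2, nrow = 3, ncol = nrow(color),
                 dimnames = list(c("white_early", "black_higher", "white_absent"),
                                 color$sample_id))
  early_white <- color$variety == "white" & color$stage <= 8
  fpkm["white_early", early_white] <- 4
  fpkm["black_higher", early_white] <- 2
  fpkm["black_higher", color$variety == "black" & color$stage <= 8] <- 20
  res <- seedcolor_filter(make_expression(fpkm, color))
  got <- setNames(res$pass, res$gene_id)
  expect_true(got[["white_early"]])
  expect_true(got[["black_higher"]]) # higher in black, but present in white
  expect_false(got[["white_absent"]])
  expect_error(seedcolor_filter(make_expression(fpkm, color), white_variety = "cream"),
               "white variety")
})

test_that("kinetic concordance excludes rising, flat and late-peaking trajectories", {
  stages <- c(5, 8, 11, 14, 17, 20, 23, 26, 30)
  prof <- simulate_pinoresinol_profile(stages)
  rising <- setNames(seq(1, 40, length.out = 9), stages)
  expect_false(kinetic_concordance(rising, prof)$pass)
  flat <- setNames(rep(24, 9), stages)
  kin_flat <- kinetic_concordance(flat, prof)
  expect_false(kin_flat$pass)
  expect_equal(kin_flat$cv, 0)
  rise_fall <- setNames(30 * c(.3, .44, .58, .72, .86, 1, .37, .14, .04), stages)
  kin <- kinetic_concordance(rise_fall, prof)
  expect_true(kin$pass)
  expect_identical(kin$peak_stage, 20)
  expect_equal(kin$decline_ratio_observed, mean(c(.37, .14, .04)), tolerance = 1e-12)
  expect_equal(kin$corr,
               oracle_cor(unname(rise_fall), prof$content), tolerance = 1e-12)
  expect_error(kinetic_concordance(setNames(c(1, 2, 3), c(5, 8, 11)), prof),
               ">= 4")
})

test_that("core membership keeps only genes in core orthogroups", {
  groups <- data.frame(og_id = c("OG1", "OG1", "OG2"),
                       gene_id = c("a", "b", "c"),
                       variety = c("v1", "v2", "v1"),
                       cls = c("core", "core", "specific"),
                       stringsAsFactors = FALSE)
  expect_identical(core_membership_filter(c("a", "c"), groups), "a")
  expect_warning(out <- core_membership_filter(c("a", "zz"), groups), "non-core")
  expect_identical(out, "a")
})

test_that("the full screen recovers exactly the planted candidates", {
  rec <- run_recovery(seed = 17)
  expect_identical(rec$screen$candidates,
                   rec$study$pangenome$truth$candidate_genes)
  rep <- rec$screen$report
  # audit completeness: every gene has a defined stage-1 record, and every
  # evaluated stage has a defined boolean
  expect_true(all(!is.na(rep$stage1_seed_pref)))
  expect_true(all(!is.na(rep$stage2_early_oil[rep$stage1_seed_pref])))
  expect_true(all(rep$final == (rep$stage1_seed_pref & !is.na(rep$core_member) &
                                  rep$core_member)))
  # the flat confounder survives the three expression filters but fails the
  # kinetic criterion
  conf <- rec$study$pangenome$truth$flat_confounder
  expect_true(rep[conf, "stage3_color"])
  expect_false(rep[conf, "kinetic_pass"])
})

test_that("screen output is invariant to gene and sample permutations", {
  st <- simulate_study(small_cfg(seed = 23))
  members <- st$pangenome$truth$orthogroup_members
  cl <- classify_orthogroups(
    cluster_orthogroups(st$pangenome$edges,
                        setNames(members$variety, members$gene_id), 50),
    st$pangenome$varieties)
  base <- run_screen(st$expression, st$profile, cl)
  set.seed(1)
  perm <- st$expression
  gi <- sample(nrow(perm$fpkm)); si <- sample(ncol(perm$fpkm))
  perm <- expression_set(perm$fpkm[gi, si], perm$samples[si, ])
  shuffled <- run_screen(perm, st$profile, cl)
  expect_identical(shuffled$report, base$report)
  expect_identical(shuffled$candidates, base$candidates)
})

test_that("degenerate screens behave: empty matrix and unreachable floor", {
  st <- simulate_study(small_cfg(seed = 29))
  members <- st$pangenome$truth$orthogroup_members
  cl <- classify_orthogroups(
    cluster_orthogroups(st$pangenome$edges,
                        setNames(members$variety, members$gene_id), 50),
    st$pangenome$varieties)
  empty <- expression_set(st$expression$fpkm[0, , drop = FALSE], st$expression$samples)
  scr0 <- run_screen(empty, st$profile, cl)
  expect_identical(nrow(scr0$report), 0L)
  expect_length(scr0$candidates, 0)
  high <- run_screen(st$expression, st$profile, cl,
                     cfg = screen_config(min_expr = 1e6))
  expect_length(high$candidates, 0)
  expect_true(all(!high$report$stage1_seed_pref)) # audit shows stage-1 failures
})
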