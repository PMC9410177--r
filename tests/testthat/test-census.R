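# Family census: domtblout parsing, E-value filtering, domain verification,
# orthogrouping and count summaries.

test_that("domtblout files round-trip through write and read", {
  pg <- simulate_pangenome(small_cfg())
  hits <- pg$hits[, c("gene_id", "profile_id", "full_evalue", "dom_ievalue",
                      "ali_start", "ali_end", "bit_score")]
  path <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout(hits, path)
  back <- read_domtblout(path)
  expect_identical(back$gene_id, hits$gene_id)
  expect_identical(back$profile_id, hits$profile_id)
  expect_equal(back$full_evalue, hits$full_evalue, tolerance = 1e-2)
  expect_identical(back$ali_start, as.integer(hits$ali_start))
  expect_identical(back$ali_end, as.integer(hits$ali_end))
})

test_that("domtblout parsing skips comments and reports malformed rows by line", {
  path <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# comment", "#", "# another"), path)
  expect_identical(nrow(read_domtblout(path)), 0L)
  expect_error(read_domtblout(file.path(tempdir(), "nope.domtblout")), "no such file")

  row <- function(ev, st, en) {
    paste("g1 - 500 PF00141.26 - 300", ev, "100 0.0 1 1 1e-9 1e-9 100 0.0 1 300",
          st, en, st, en, "0.9 -")
  }
  writeLines(c("# c", row("abc", 1, 10)), path)
  expect_error(read_domtblout(path), "line 2.*non-numeric")
  writeLines(c(row("1e-9", 50, 10)), path)
  expect_error(read_domtblout(path), "line 1.*start 50 > end 10")
})

test_that("E-value filtering is inclusive on both thresholds and monotone", {
  hits <- data.frame(gene_id = c("a", "b", "c", "d"),
                     profile_id = "PF00141.26",
                     full_evalue = c(1e-6, 1e-4, 1e-5, 1e-6),
                     dom_ievalue = c(1e-7, 1e-7, 1e-5, 1e-3),
                     ali_start = 1L, ali_end = 10L, bit_score = 50,
                     stringsAsFactors = FALSE)
  kept <- filter_hits(hits)
  expect_setequal(kept$gene_id, c("a", "c")) # boundary 1e-5/1e-5 is kept
  expect_error(filter_hits(hits, e_full = 0), "positive")
  # relaxing either threshold never shrinks the accepted set
  set.seed(1)
  rnd <- data.frame(gene_id = paste0("g", 1:50), profile_id = "PF00141.26",
                    full_evalue = 10^runif(50, -9, -2),
                    dom_ievalue = 10^runif(50, -9, -2),
                    ali_start = 1L, ali_end = 10L, bit_score = 1,
                    stringsAsFactors = FALSE)
  for (i in 1:10) {
    e1 <- 10^runif(1, -8, -3); e2 <- e1 * 10^runif(1, 0, 2)
    expect_true(all(filter_hits(rnd, e1, e1)$gene_id %in%
                      filter_hits(rnd, e2, e2)$gene_id))
  }
})

test_that("family calling merges duplicate rows and domain scan removes spurious genes", {
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    profile_id = c("PF00141.26", "PF00141.26", "TIGR03390.1", "PF00141.26"),
    full_evalue = c(1e-8, 1e-3, 1e-9, 1e-10),
    dom_ievalue = c(1e-8, 1e-3, 1e-9, 1e-10),
    ali_start = 1L, ali_end = 100L, bit_score = 80, stringsAsFactors = FALSE)
  asg <- call_family_members(hits)
  expect_identical(nrow(asg), 3L) # g1's two rows merged, all evidence kept
  expect_identical(nrow(asg$evidence[[match("g1", asg$gene_id)]]), 2L)
  expect_identical(asg$status[match("g1", asg$gene_id)], "accepted")
  scan <- data.frame(gene_id = c("g1", "g2"), domain = c("peroxidase", "laccase"))
  ver <- verify_domains(asg, scan)
  expect_identical(ver$status[match("g3", ver$gene_id)], "rejected_spurious")
  expect_identical(ver$status[match("g1", ver$gene_id)], "accepted")
})

test_that("planted members, threshold decoys and spurious decoys are all resolved", {
  pg <- simulate_pangenome(small_cfg(seed = 4))
  asg <- verify_domains(call_family_members(pg$hits[, 1:7]), pg$scan_table)
  got <- setNames(asg$status, asg$gene_id)
  expect_identical(got[names(pg$truth$member_status)], pg$truth$member_status)
})

test_that("orthogroup clustering is single-linkage over the score threshold", {
  gv <- c(a = "v1", b = "v2", c = "v1")
  edges <- data.frame(gene_a = "a", gene_b = "b", score = 80)
  groups <- cluster_orthogroups(edges, gv, min_score = 50)
  expect_identical(sort(groups$gene_id[groups$og_id == groups$og_id[1]]), c("a", "b"))
  expect_identical(sum(groups$og_id == groups$og_id[groups$gene_id == "c"]), 1L)
  # below-threshold edge leaves singletons
  weak <- cluster_orthogroups(data.frame(gene_a = "a", gene_b = "b", score = 10),
                              gv, min_score = 50)
  expect_identical(length(unique(weak$og_id)), 3L)
  expect_error(cluster_orthogroups(data.frame(gene_a = "a", gene_b = "z", score = 99),
                                   gv, 50), "unknown gene.*z")
})

test_that("clustering equals brute-force transitive closure on random graphs", {
  for (i in 1:20) {
    set.seed(100 + i)
    n <- sample(4:15, 1)
    genes <- sprintf("g%02d", seq_len(n))
    gv <- setNames(rep("v1", n), genes)
    m <- sample(0:(2 * n), 1)
    edges <- data.frame(gene_a = sample(genes, m, replace = TRUE),
                        gene_b = sample(genes, m, replace = TRUE),
                        score = runif(m, 0, 100), stringsAsFactors = FALSE)
    groups <- cluster_orthogroups(edges, gv, min_score = 50)
    got <- sort(vapply(split(groups$gene_id, groups$og_id),
                       function(g) paste(sort(g), collapse = ","), ""))
    expect_identical(unname(got), oracle_components(edges, genes, 50))
  }
})

test_that("orthogroup classification and intersection counts partition the groups", {
  pg <- simulate_pangenome(small_cfg(seed = 6))
  members <- pg$truth$orthogroup_members
  gv <- setNames(members$variety, members$gene_id)
  groups <- cluster_orthogroups(pg$edges, gv, 50)
  cl <- classify_orthogroups(groups, pg$varieties)
  n_groups <- length(unique(cl$groups$og_id))
  expect_identical(sum(cl$intersection_counts), n_groups)
  tab <- table(vapply(split(cl$groups$cls, cl$groups$og_id), `[`, "", 1))
  expect_identical(sum(tab), n_groups) # core + shared + specific partition
  # every accepted gene sits in exactly one orthogroup
  expect_identical(anyDuplicated(cl$groups$gene_id), 0L)
  # recovered classes match the planted ones
  tru_key <- vapply(split(members$gene_id, members$og_id),
                    function(g) paste(sort(g), collapse = ","), "")
  cls_by_key <- setNames(unname(pg$truth$orthogroup_classes[names(tru_key)]), tru_key)
  got_key <- vapply(split(cl$groups$gene_id, cl$groups$og_id),
                    function(g) paste(sort(g), collapse = ","), "")
  got_cls <- vapply(split(cl$groups$cls, cl$groups$og_id), `[`, "", 1)
  expect_identical(unname(got_cls), unname(cls_by_key[got_key]))
  expect_error(classify_orthogroups(groups, c("v1", "v2")), "unlisted variety")
})

test_that("count summaries match an independent two-pass formula", {
  expect_error(summarize_counts(numeric()), "nonempty")
  expect_identical(summarize_counts(c(5, 5, 5))$sd, 0)
  expect_identical(summarize_counts(7)$sd, 0)
  set.seed(2)
  for (i in 1:10) {
    x <- sample(20:90, sample(2:8, 1), replace = TRUE)
    s <- summarize_counts(x)
    expect_equal(s$mean, sum(x) / length(x), tolerance = 1e-12)
    expect_equal(s$sd, oracle_sd(x), tolerance = 1e-12)
  }
})
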