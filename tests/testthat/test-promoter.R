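# Promoter extraction, IUPAC scanning, categorization, TF enrichment.

test_that("promoter extraction honors strand and truncates at chromosome edges", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste(rep("ACGT", 100), collapse = "")))
  plus <- data.frame(gene_id = "gp", chrom = "c1", start = 100, end = 150,
                     strand = "+", stringsAsFactors = FALSE)
  p <- extract_promoters(plus, genome, length = 2000)
  expect_identical(unname(Biostrings::width(p)), 99L) # truncated at position 1
  expect_identical(as.character(p[[1]]),
                   substr(as.character(genome[[1]]), 1, 99))
  minus <- data.frame(gene_id = "gm", chrom = "c1", start = 100, end = 150,
                      strand = "-", stringsAsFactors = FALSE)
  m <- extract_promoters(minus, genome, length = 30)
  expect_identical(as.character(m[[1]]),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::subseq(genome[[1]], 151, 180))))
  edge <- data.frame(gene_id = "ge", chrom = "c1", start = 1, end = 10,
                     strand = "+", stringsAsFactors = FALSE)
  expect_warning(e <- extract_promoters(edge, genome), "empty promoter")
  expect_identical(unname(Biostrings::width(e)), 0L)
  bad <- data.frame(gene_id = "gb", chrom = "c9", start = 5, end = 10,
                    strand = "+", stringsAsFactors = FALSE)
  expect_error(extract_promoters(bad, genome), "chromosome")
})

test_that("generator promoters round-trip through extraction", {
  pg <- simulate_pangenome(small_cfg(seed = 31))
  genes <- names(pg$truth$promoters)
  proms <- extract_promoters(pg$ref_genes[match(genes, pg$ref_genes$gene_id), ],
                             pg$genome)
  expect_identical(unname(as.character(proms)), unname(pg$truth$promoters))
  # planted motifs are all recovered at their planted position and strand
  occ <- scan_motifs(proms, pg$elements)
  for (g in genes) {
    tm <- pg$truth$planted_motifs[[g]]
    og <- occ[occ$promoter_id == g, ]
    for (r in seq_len(nrow(tm))) {
      expect_true(any(og$element == tm$element[r] & og$start == tm$start[r] &
                        og$strand == tm$strand[r]),
                  label = sprintf("%s %s@%d%s", g, tm$element[r], tm$start[r],
                                  tm$strand[r]))
    }
  }
})

test_that("IUPAC scanning matches on both strands and N matches nothing", {
  el <- data.frame(name = "e", consensus = "TGACGT", category = "hormonal")
  occ <- scan_motifs(c(p1 = "TGACGTAA"), el)
  expect_identical(occ[, c("start", "strand")],
                   data.frame(start = 1L, strand = "+"))
  occ2 <- scan_motifs(c(p1 = "TTACGTCA"), el)
  expect_identical(occ2[, c("start", "strand")],
                   data.frame(start = 3L, strand = "-"))
  expect_identical(nrow(scan_motifs(c(p1 = "TGANGTAA"), el)), 0L)
  deg <- data.frame(name = "w", consensus = "TTGACY", category = "stress")
  expect_identical(nrow(scan_motifs(c(p1 = "TTGACCTTGACT"), deg)), 2L)
  bad <- data.frame(name = "x", consensus = "ACGJ", category = "other")
  expect_error(scan_motifs(c(p1 = "ACGT"), bad), "IUPAC")
  expect_error(scan_motifs(c(p1 = "ACGU"), el), "outside")
})

test_that("scanning equals the regex oracle and obeys strand symmetry", {
  set.seed(77)
  elements <- default_cis_elements()
  seqs <- vapply(1:2, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 2000, replace = TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = ""), "")
  names(seqs) <- c("p1", "p2")
  occ <- scan_motifs(seqs, elements)
  for (p in names(seqs)) {
    for (e in seq_len(nrow(elements))) {
      got <- occ[occ$promoter_id == p & occ$element == elements$name[e],
                 c("start", "strand")]
      want <- oracle_scan(seqs[[p]], elements$consensus[e])
      if (is.null(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        want <- want[order(want$start, want$strand), ]
        got <- got[order(got$start, got$strand), ]
        expect_identical(unname(as.matrix(got)), unname(as.matrix(want)))
      }
    }
    # position-count bound per element
    for (e in seq_len(nrow(elements))) {
      L <- nchar(seqs[[p]]); k <- nchar(elements$consensus[e])
      expect_lte(sum(occ$promoter_id == p & occ$element == elements$name[e]),
                 2 * (L - k + 1))
    }
  }
  # strand symmetry: reverse-complementing a promoter flips strands and
  # reflects starts (start' = L - start - len + 2)
  rc <- vapply(seqs, function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  occ_rc <- scan_motifs(rc, elements)
  len_of <- setNames(nchar(elements$consensus), elements$name)
  expected <- occ
  expected$start <- nchar(seqs[expected$promoter_id]) - expected$start -
    len_of[expected$element] + 2L
  expected$strand <- ifelse(expected$strand == "+", "-", "+")
  key <- function(d) sort(paste(d$promoter_id, d$element, d$start, d$strand))
  expect_identical(key(occ_rc), key(expected))
})

test_that("element categorization zero-fills and conserves totals", {
  elements <- default_cis_elements()
  empty <- categorize_elements(
    data.frame(promoter_id = character(), element = character(),
               start = integer(), strand = character()),
    elements, genes = c("g1", "g2"))
  expect_identical(nrow(empty), 2L)
  expect_true(all(empty[, -1] == 0))
  occ <- data.frame(promoter_id = c("g1", "g1", "g1", "g1"),
                    element = c("ABRE", "TGACG-motif", "ABRE", "G-box"),
                    start = 1:4, strand = "+", stringsAsFactors = FALSE)
  tab <- categorize_elements(occ, elements, genes = c("g1", "g2"))
  expect_identical(tab$hormonal[tab$gene_id == "g1"], 3L)
  expect_identical(tab$light[tab$gene_id == "g1"], 1L)
  expect_identical(sum(as.matrix(tab[, -1])), nrow(occ))
  expect_error(categorize_elements(
    data.frame(promoter_id = "g1", element = "nope", start = 1, strand = "+"),
    elements), "unknown element")
})

test_that("TF enrichment matches the closed form and brute-force enumeration", {
  bg <- sprintf("g%02d", 1:20)
  bound <- bg[1:5]
  res <- tf_enrichment(bound, list(TF = bound), bg)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # target = background makes every family's p exactly 1
  res2 <- tf_enrichment(bg, list(A = bg[1:4], B = bg[2:9]), bg)
  expect_true(all(res2$p == 1))
  expect_error(tf_enrichment(c("zz"), list(A = bg), bg), "not in background")
  # random small instances against the combinatorial oracle
  set.seed(13)
  for (i in 1:40) {
    N <- sample(5:30, 1)
    bg <- sprintf("x%02d", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    fam <- sample(bg, K); tgt <- sample(bg, n)
    res <- tf_enrichment(tgt, list(F1 = fam), bg)
    k <- length(intersect(fam, tgt))
    expect_lt(abs(res$p - oracle_hyper_upper(k, K, n, N)), 1e-10)
  }
  # BH q-values are nondecreasing in the p-sorted order
  set.seed(14)
  bg <- sprintf("y%02d", 1:30)
  fams <- lapply(1:8, function(i) sample(bg, sample(3:20, 1)))
  names(fams) <- paste0("TF", 1:8)
  res3 <- tf_enrichment(sample(bg, 10), fams, bg)
  o <- order(res3$p)
  expect_true(all(diff(res3$q[o]) >= -1e-15))
})

test_that("MYB tops the enrichment ranking on generator data", {
  pg <- simulate_pangenome(sim_config(rng_seed = 19))
  members <- pg$truth$orthogroup_members
  ref_fam <- members$gene_id[members$variety == "var1"]
  res <- tf_enrichment(pg$truth$candidate_genes, pg$binding_map, ref_fam)
  expect_identical(res$family[1], "MYB")
})
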