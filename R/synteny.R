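# Chromosome gene ordering, MCScanX-style collinear block chaining, and
# tandem/segmental/dispersed duplicate classification.

#' Read gene models from a GFF3 file
#'
#' Imports `type == "gene"` records and returns the 1-based closed
#' coordinates used throughout the synteny module.
#'
#' @param path GFF3 file path
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("cannot read GFF3 file '%s': no such file", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Assign per-chromosome gene order ranks
#'
#' Within each chromosome genes are sorted by `start` (ties broken by `end`,
#' then `gene_id`) and numbered 1..n. Ranks are the only positional
#' coordinate the collinearity chaining uses.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#' @return `genes` with an added integer `rank` column
#' @export
assign_ranks <- function(genes) {
  if (anyDuplicated(genes$gene_id)) {
    stopf("duplicate gene_id(s): %s",
          paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (any(genes$start > genes$end)) stopf("gene with start > end")
  genes$rank <- NA_integer_
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    o <- order(genes$start[i], genes$end[i], genes$gene_id[i])
    genes$rank[i[o]] <- seq_along(i)
  }
  genes
}

# Annotate anchors with (chrom, rank) on both sides; errors on unknown genes.
resolve_anchors <- function(anchors, ranked_a, ranked_b) {
  look <- function(ranked, ids, side) {
    m <- match(ids, ranked$gene_id)
    if (anyNA(m)) {
      stopf("anchor references unknown gene(s) on side %s: %s", side,
            paste(unique(ids[is.na(m)]), collapse = ", "))
    }
    m
  }
  ia <- look(ranked_a, anchors$gene_a, "A")
  ib <- look(ranked_b, anchors$gene_b, "B")
  anchors$chrom_a <- ranked_a$chrom[ia]
  anchors$rank_a <- ranked_a$rank[ia]
  anchors$chrom_b <- ranked_b$chrom[ib]
  anchors$rank_b <- ranked_b$rank[ib]
  anchors
}

# Longest valid chain among anchors sorted by (rank_a, rank_b).
# Returns indices (into the sorted table) of the lexicographically smallest
# maximum-length chain, or integer(0). Orientation "same" requires rank_b
# strictly increasing, "inverted" strictly decreasing; consecutive rank gaps
# on both sides must be <= max_gap.
best_chain_oriented <- function(ra, rb, max_gap, inverted) {
  m <- length(ra)
  if (!m) return(integer())
  compat <- function(i, j) {
    da <- ra[j] - ra[i]
    db <- if (inverted) rb[i] - rb[j] else rb[j] - rb[i]
    da > 0 && da <= max_gap && db > 0 && db <= max_gap
  }
  f <- integer(m) # longest chain starting at i
  for (i in m:1) {
    best <- 0L
    j <- i + 1L
    while (j <= m) {
      if (f[j] > best && compat(i, j)) best <- f[j]
      j <- j + 1L
    }
    f[i] <- 1L + best
  }
  len <- max(f)
  chain <- integer(len)
  chain[1L] <- which(f == len)[1L]
  k <- 1L
  while (k < len) {
    cur <- chain[k]
    nxt <- 0L
    for (j in (cur + 1L):m) {
      if (f[j] == len - k && compat(cur, j)) { nxt <- j; break }
    }
    chain[k + 1L] <- nxt
    k <- k + 1L
  }
  chain
}

#' Chain anchors into collinear blocks
#'
#' For each chromosome pair, repeatedly extracts the maximum-length chain of
#' anchor pairs whose ranks increase strictly on side A and increase
#' (orientation `same`) or decrease (orientation `inverted`) strictly on
#' side B, with consecutive-anchor rank gaps at most `max_gap` on both
#' sides; used anchors are removed and chaining repeats until no chain of at
#' least `min_anchors` anchors remains. Chains are scored by anchor count;
#' ties prefer orientation `same`, then the lexicographically smallest
#' anchor sequence (anchors ordered by side-A then side-B rank), so the
#' output order is deterministic.
#'
#' @param anchors data.frame with columns `gene_a`, `gene_b` and optionally
#'   `score`
#' @param genes_a,genes_b gene model data.frames (ranks are computed with
#'   [assign_ranks()] if absent); pass the same table twice for
#'   intragenomic chaining
#' @param max_gap maximum rank gap between consecutive anchors (default 25)
#' @param min_anchors minimum anchors per reported block (default 5)
#' @return list of blocks, each a list with `chrom_a`, `chrom_b`,
#'   `orientation` and an `anchors` data.frame
#' @export
chain_collinear_blocks <- function(anchors, genes_a, genes_b = genes_a,
                                   max_gap = 25, min_anchors = 5) {
  ranked_a <- if ("rank" %in% names(genes_a)) genes_a else assign_ranks(genes_a)
  ranked_b <- if ("rank" %in% names(genes_b)) genes_b else assign_ranks(genes_b)
  if (!nrow(anchors)) return(list())
  ann <- resolve_anchors(anchors, ranked_a, ranked_b)
  blocks <- list()
  pair_key <- paste(ann$chrom_a, ann$chrom_b, sep = "\r")
  for (key in sort(unique(pair_key))) {
    sub <- ann[pair_key == key, , drop = FALSE]
    sub <- sub[order(sub$rank_a, sub$rank_b), , drop = FALSE]
    repeat {
      if (nrow(sub) < min_anchors) break
      same <- best_chain_oriented(sub$rank_a, sub$rank_b, max_gap, inverted = FALSE)
      inv <- best_chain_oriented(sub$rank_a, sub$rank_b, max_gap, inverted = TRUE)
      use_inv <- length(inv) > length(same)
      chain <- if (use_inv) inv else same
      if (length(chain) < min_anchors) break
      blocks[[length(blocks) + 1L]] <- list(
        chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
        orientation = if (use_inv) "inverted" else "same",
        anchors = sub[chain, c("gene_a", "gene_b", "rank_a", "rank_b",
                               intersect("score", names(sub))), drop = FALSE]
      )
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  blocks
}

#' Classify paralog pairs as tandem, segmental or dispersed
#'
#' A pair is `tandem` when both genes lie on the same chromosome within
#' `tandem_max_rank_gap` positions of each other in gene order; otherwise it
#' is `segmental` when the pair (in either orientation) is an anchor inside
#' any intragenomic collinear block; all remaining pairs are `dispersed`.
#'
#' @param paralog_pairs data.frame with columns `gene_a`, `gene_b`
#' @param blocks intragenomic blocks from [chain_collinear_blocks()]
#' @param ranked_genes gene models with a `rank` column
#' @param tandem_max_rank_gap maximum gene-order gap for tandem calls
#'   (default 1, i.e. adjacent genes)
#' @return data.frame `gene_a`, `gene_b`, `cls`
#' @export
classify_duplicates <- function(paralog_pairs, blocks, ranked_genes,
                                tandem_max_rank_gap = 1) {
  m_a <- match(paralog_pairs$gene_a, ranked_genes$gene_id)
  m_b <- match(paralog_pairs$gene_b, ranked_genes$gene_id)
  if (anyNA(m_a) || anyNA(m_b)) {
    bad <- c(paralog_pairs$gene_a[is.na(m_a)], paralog_pairs$gene_b[is.na(m_b)])
    stopf("paralog pair references unknown gene(s): %s", paste(unique(bad), collapse = ", "))
  }
  anchor_keys <- unlist(lapply(blocks, function(b) {
    c(paste(b$anchors$gene_a, b$anchors$gene_b, sep = "\r"),
      paste(b$anchors$gene_b, b$anchors$gene_a, sep = "\r"))
  }))
  same_chrom <- ranked_genes$chrom[m_a] == ranked_genes$chrom[m_b]
  gap <- abs(ranked_genes$rank[m_a] - ranked_genes$rank[m_b])
  in_block <- paste(paralog_pairs$gene_a, paralog_pairs$gene_b, sep = "\r") %in% anchor_keys
  cls <- ifelse(same_chrom & gap <= tandem_max_rank_gap, "tandem",
                ifelse(in_block, "segmental", "dispersed"))
  data.frame(gene_a = paralog_pairs$gene_a, gene_b = paralog_pairs$gene_b,
             cls = cls, stringsAsFactors = FALSE)
}

#' Fraction of family genes in cross-species collinear blocks
#'
#' Counts the family genes that appear as a side-A anchor in at least one
#' cross-species block and reports the percentage of the family, rounded to
#' the nearest integer as printed in census summaries (e.g. 31 of 83 POD
#' genes -> 37%).
#'
#' @param family_genes character vector of family gene ids (side A genome)
#' @param blocks cross-species blocks from [chain_collinear_blocks()]
#' @return list with `count` and `percent`
#' @export
interspecies_synteny_fraction <- function(family_genes, blocks) {
  if (!length(family_genes)) stopf("family gene set must be nonempty")
  anchored <- unique(unlist(lapply(blocks, function(b) b$anchors$gene_a)))
  count <- sum(family_genes %in% anchored)
  list(count = count,
       percent = round_half_up(100 * count / length(family_genes)))
}
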