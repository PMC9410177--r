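# Promoter extraction, IUPAC cis-element scanning, element categorization
# and hypergeometric TF-family enrichment.

#' Extract promoter sequences upstream of gene starts
#'
#' For a `+` strand gene the promoter is the `length` bases immediately
#' upstream of the annotated gene start (1-based closed coordinates),
#' truncated at position 1; for a `-` strand gene it is the `length` bases
#' downstream of the annotated end in assembly coordinates,
#' reverse-complemented. Output is therefore always 5'->3' relative to the
#' gene. The promoter is anchored at the annotated gene start (transcription
#' and translation starts are not distinguished).
#'
#' @param genes gene model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`)
#' @param genome a [Biostrings::DNAStringSet] of chromosome sequences
#' @param length promoter length in bp (default 2000)
#' @return named [Biostrings::DNAStringSet] of promoters
#' @export
extract_promoters <- function(genes, genome, length = 2000) {
  miss <- setdiff(unique(genes$chrom), names(genome))
  if (base::length(miss)) {
    stopf("chromosome(s) missing from genome: %s", paste(miss, collapse = ", "))
  }
  seqs <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    chrom <- genome[[g$chrom]]
    L <- Biostrings::nchar(chrom)
    if (g$strand == "+") {
      if (g$start <= 1L) {
        warnf("gene '%s' starts at position 1 on + strand: empty promoter", g$gene_id)
        return("")
      }
      from <- max(1L, g$start - length)
      as.character(Biostrings::subseq(chrom, from, g$start - 1L))
    } else {
      if (g$end >= L) {
        warnf("gene '%s' ends at the chromosome end on - strand: empty promoter", g$gene_id)
        return("")
      }
      to <- min(L, g$end + length)
      revcomp_chr(as.character(Biostrings::subseq(chrom, g$end + 1L, to)))
    }
  }, "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genes$gene_id
  out
}

# Bit codes: a sequence base matches an IUPAC pattern letter iff their bit
# sets intersect; N in the *sequence* is coded outside every pattern mask so
# it matches nothing (conservative).
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)

iupac_mask <- function(consensus) {
  letters <- strsplit(consensus, "")[[1]]
  vapply(letters, function(l) {
    s <- iupac_sets[[l]]
    if (is.null(s)) stopf("invalid IUPAC letter '%s' in consensus '%s'", l, consensus)
    sum(.base_bits[s])
  }, 0L)
}

scan_one <- function(codes, mask) {
  L <- length(codes)
  k <- length(mask)
  if (k > L) return(integer())
  ok <- rep(TRUE, L - k + 1L)
  for (i in seq_len(k)) {
    ok <- ok & bitwAnd(codes[i:(L - k + i)], mask[i]) != 0L
  }
  which(ok)
}

#' Scan promoters for cis-element consensus occurrences
#'
#' Exact IUPAC-degenerate matching on both strands: every position where
#' the consensus matches is reported. An `N` in the promoter sequence
#' matches nothing. A minus-strand occurrence is a match of the
#' reverse-complemented consensus on the given string, reported with strand
#' `-` and the 1-based start of the match on the given string.
#'
#' @param promoters named character vector or [Biostrings::DNAStringSet]
#'   over the alphabet `{A, C, G, T, N}`
#' @param elements data.frame `name`, `consensus`, `category` (see
#'   [default_cis_elements()])
#' @return data.frame `promoter_id`, `element`, `start`, `strand`
#' @export
scan_motifs <- function(promoters, elements) {
  if (methods::is(promoters, "DNAStringSet")) {
    promoters <- setNames(as.character(promoters), names(promoters))
  }
  masks_f <- lapply(elements$consensus, iupac_mask)
  masks_r <- lapply(elements$consensus, function(cns) iupac_mask(revcomp_chr(cns)))
  out <- list()
  for (p in names(promoters)) {
    chars <- strsplit(promoters[[p]], "")[[1]]
    codes <- unname(.base_bits[chars])
    if (anyNA(codes)) {
      stopf("promoter '%s' contains letters outside {A,C,G,T,N}", p)
    }
    for (e in seq_len(nrow(elements))) {
      for (str in c("+", "-")) {
        hits <- scan_one(codes, if (str == "+") masks_f[[e]] else masks_r[[e]])
        if (length(hits)) {
          out[[length(out) + 1L]] <- data.frame(
            promoter_id = p, element = elements$name[e],
            start = hits, strand = str, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(promoter_id = character(), element = character(),
                      start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$promoter_id, res$element, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count element occurrences per gene and functional category
#'
#' @param occurrences data.frame from [scan_motifs()]
#' @param elements element table defining the name -> category map
#' @param genes gene (promoter) ids forming the rows; defaults to the ids
#'   present in `occurrences`
#' @return data.frame, one row per gene, one zero-filled count column per
#'   category (hormonal, light, stress, development, other)
#' @export
categorize_elements <- function(occurrences, elements,
                                genes = unique(occurrences$promoter_id)) {
  unknown <- setdiff(unique(occurrences$element), elements$name)
  if (length(unknown)) {
    stopf("unknown element name(s): %s", paste(unknown, collapse = ", "))
  }
  categories <- c("hormonal", "light", "stress", "development", "other")
  cat_of <- setNames(elements$category, elements$name)
  tab <- matrix(0L, nrow = length(genes), ncol = length(categories),
                dimnames = list(genes, categories))
  if (nrow(occurrences)) {
    cc <- table(factor(occurrences$promoter_id, levels = genes),
                factor(cat_of[occurrences$element], levels = categories))
    tab[rownames(cc), colnames(cc)] <- as.integer(cc)
  }
  data.frame(gene_id = genes, tab, row.names = NULL, stringsAsFactors = FALSE)
}

#' Transcription-factor family enrichment in a target gene set
#'
#' Upper-tail hypergeometric test of over-representation of each TF
#' family's bound genes among the targets, against a background universe,
#' with Benjamini-Hochberg adjustment across families. For a family binding
#' `K` of the `N` background genes, with `k` of the `n` targets bound,
#' `p = P[X >= k]`, `X ~ Hypergeometric(N, K, n)`.
#'
#' @param target_genes candidate gene set (must be contained in the
#'   background)
#' @param binding_map data.frame `family`, `gene_id` (TF family -> bound
#'   genes), or a named list of gene-id vectors
#' @param background_genes background gene universe
#' @return data.frame `family`, `k`, `K`, `n`, `N`, `p`, `q`, sorted by `q`
#'   then `p`
#' @export
tf_enrichment <- function(target_genes, binding_map, background_genes) {
  extra <- setdiff(target_genes, background_genes)
  if (length(extra)) {
    stopf("target gene(s) not in background: %s", paste(extra, collapse = ", "))
  }
  if (is.data.frame(binding_map)) {
    binding_map <- split(binding_map$gene_id, binding_map$family)
  }
  N <- length(unique(background_genes))
  n <- length(unique(target_genes))
  res <- do.call(rbind, lapply(names(binding_map), function(f) {
    bound <- intersect(binding_map[[f]], background_genes)
    K <- length(bound)
    k <- length(intersect(bound, target_genes))
    data.frame(family = f, k = k, K = K, n = n, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  res <- res[order(res$q, res$p, res$family), , drop = FALSE]
  rownames(res) <- NULL
  res
}
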