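# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Connected components by boolean transitive closure of the adjacency matrix.
oracle_components <- function(edges, genes, min_score) {
  n <- length(genes)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(genes, genes)
  keep <- edges[edges$score >= min_score, , drop = FALSE]
  for (i in seq_len(nrow(keep))) {
    adj[keep$gene_a[i], keep$gene_b[i]] <- TRUE
    adj[keep$gene_b[i], keep$gene_a[i]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(apply(adj, 1, function(r) paste(sort(genes[r]), collapse = ",")))
  sort(comps)
}

# Exhaustive chain enumeration mirroring the chaining tie-breaks: longest
# chain, preferring orientation "same", then the lexicographically smallest
# anchor-index sequence (anchors sorted by (rank_a, rank_b)); extraction
# repeats greedily until no chain reaches min_anchors.
oracle_chains <- function(ra, rb, max_gap, min_anchors) {
  best_for <- function(ra, rb, inverted) {
    m <- length(ra)
    best <- integer()
    recurse <- function(chain, last) {
      if (length(chain) > length(best)) best <<- chain
      from <- if (is.null(last)) 1L else last + 1L
      if (from > m) return()
      for (j in from:m) {
        if (is.null(last)) { recurse(j, j); next }
        da <- ra[j] - ra[last]
        db <- if (inverted) rb[last] - rb[j] else rb[j] - rb[last]
        if (da > 0 && da <= max_gap && db > 0 && db <= max_gap) {
          recurse(c(chain, j), j)
        }
      }
    }
    recurse(integer(), NULL)
    best
  }
  blocks <- list()
  idx <- order(ra, rb)
  ra <- ra[idx]; rb <- rb[idx]
  live <- seq_along(ra)
  repeat {
    if (length(live) < min_anchors) break
    same <- best_for(ra[live], rb[live], FALSE)
    inv <- best_for(ra[live], rb[live], TRUE)
    use_inv <- length(inv) > length(same)
    chain <- if (use_inv) inv else same
    if (length(chain) < min_anchors) break
    blocks[[length(blocks) + 1L]] <- list(
      orientation = if (use_inv) "inverted" else "same",
      idx = idx[live[chain]])
    live <- live[-chain]
  }
  blocks
}

# Exact hypergeometric upper tail from binomial coefficients.
oracle_hyper_upper <- function(k, K, n, N) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# IUPAC consensus scan via regular expressions with overlap-permitting
# lookahead, both strands.
oracle_scan <- function(seq, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
               H = "ACT", V = "ACG", N = "ACGT")
  to_regex <- function(cns) {
    paste0("(?=", paste(vapply(strsplit(cns, "")[[1]], function(l) {
      paste0("[", sets[[l]], "]")
    }, ""), collapse = ""), ")")
  }
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
              N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  find <- function(pattern) {
    m <- gregexpr(to_regex(pattern), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m)
  }
  rbind(
    if (length(f <- find(consensus))) data.frame(start = f, strand = "+"),
    if (length(r <- find(rc(consensus)))) data.frame(start = r, strand = "-")
  )
}

# Two-pass sample standard deviation.
oracle_sd <- function(x) {
  if (length(x) == 1L) return(0)
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1L))
}

# Pearson correlation from first principles.
oracle_cor <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
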