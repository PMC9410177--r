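# Gene-family census: HMM domain-hit filtering, domain verification,
# similarity-graph orthogrouping and core/shared/specific classification.

#' Default HMM profile to family map
#'
#' Maps the class III peroxidase Pfam profile and the laccase TIGRFAM profile
#' to the two family labels. Profile accession versions (e.g. "PF00141.26")
#' are stripped before lookup.
#' @export
default_profile_families <- function() {
  c(PF00141 = "POD", TIGR03390 = "LAC")
}

#' Domain names that verify family membership
#' @export
default_family_domains <- function() {
  c(POD = "peroxidase", LAC = "laccase")
}

#' Read a HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-delimited per-domain output of `hmmsearch --domtblout`.
#' Comment lines starting with `#` are skipped. One row per domain hit is
#' returned with the full-sequence E-value (column 7), the per-domain
#' independent E-value (column 13) and the alignment coordinates on the
#' protein (columns 18-19, 1-based inclusive).
#'
#' @param path path to a domtblout text file
#' @return data.frame with columns `gene_id`, `profile_id`, `full_evalue`,
#'   `dom_ievalue`, `ali_start`, `ali_end`, `bit_score`
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stopf("cannot read domtblout file '%s': no such file", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(
      gene_id = character(), profile_id = character(),
      full_evalue = numeric(), dom_ievalue = numeric(),
      ali_start = integer(), ali_end = integer(), bit_score = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "[[:space:]]+")
  parse_row <- function(f, lineno) {
    if (length(f) < 19L) {
      stopf("domtblout parse error at line %d: expected >= 19 columns, got %d",
            lineno, length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(7, 13, 14, 18, 19)]))
    if (any(is.na(num))) {
      stopf("domtblout parse error at line %d: non-numeric value in E-value/score/coordinate columns",
            lineno)
    }
    if (num[1] <= 0 || num[2] <= 0) {
      stopf("domtblout parse error at line %d: E-values must be > 0", lineno)
    }
    if (num[4] > num[5]) {
      stopf("domtblout parse error at line %d: alignment start %d > end %d",
            lineno, num[4], num[5])
    }
    list(gene_id = f[1], profile_id = f[4], full_evalue = num[1],
         dom_ievalue = num[2], bit_score = num[3],
         ali_start = as.integer(num[4]), ali_end = as.integer(num[5]))
  }
  rows <- Map(parse_row, fields, idx)
  data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    profile_id = vapply(rows, `[[`, "", "profile_id"),
    full_evalue = vapply(rows, `[[`, 0, "full_evalue"),
    dom_ievalue = vapply(rows, `[[`, 0, "dom_ievalue"),
    ali_start = vapply(rows, `[[`, 0L, "ali_start"),
    ali_end = vapply(rows, `[[`, 0L, "ali_end"),
    bit_score = vapply(rows, `[[`, 0, "bit_score"),
    stringsAsFactors = FALSE
  )
}

#' Write domain hits in HMMER3 domtblout format
#'
#' Inverse of [read_domtblout()]; used by the synthetic-data generator.
#' Emits the standard 23-column layout with placeholder values for columns
#' the census does not consume.
#'
#' @param hits data.frame as returned by [read_domtblout()]
#' @param path output path
#' @export
write_domtblout <- function(hits, path) {
  header <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  fmt_row <- function(i) {
    h <- hits[i, ]
    paste(
      h$gene_id, "-", 500L, h$profile_id, "-", 300L,
      format(h$full_evalue, scientific = TRUE, digits = 3),
      format(h$bit_score, nsmall = 1), "0.0",
      1L, 1L,
      format(h$dom_ievalue, scientific = TRUE, digits = 3),
      format(h$dom_ievalue, scientific = TRUE, digits = 3),
      format(h$bit_score, nsmall = 1), "0.0",
      1L, 300L, h$ali_start, h$ali_end, h$ali_start, h$ali_end,
      "0.95", "-",
      sep = " "
    )
  }
  body <- if (nrow(hits)) vapply(seq_len(nrow(hits)), fmt_row, "") else character()
  writeLines(c(header, body, "#"), path)
}

#' Filter domain hits on full-sequence and per-domain E-values
#'
#' Keeps hits with `full_evalue <= e_full` and `dom_ievalue <= e_dom`; both
#' comparisons are inclusive, matching hmmsearch `-E`/`--domE` reporting
#' semantics. Defaults are the 1e-5 thresholds used for the family search.
#'
#' @param hits data.frame of domain hits
#' @param e_full full-sequence E-value threshold (> 0)
#' @param e_dom per-domain independent E-value threshold (> 0)
#' @return the accepted subset of `hits`
#' @export
filter_hits <- function(hits, e_full = 1e-5, e_dom = 1e-5) {
  if (!is.numeric(e_full) || e_full <= 0 || !is.numeric(e_dom) || e_dom <= 0) {
    stopf("E-value thresholds must be positive")
  }
  hits[hits$full_evalue <= e_full & hits$dom_ievalue <= e_dom, , drop = FALSE]
}

#' Call family members from domain hits
#'
#' Assigns each gene with at least one hit to a family via its HMM profile,
#' with status `accepted` if any of its hits passes both E-value thresholds
#' and `rejected_threshold` otherwise. Duplicate domain rows for one gene are
#' merged into a single assignment keeping all hits as evidence. Genes with
#' passing hits against profiles of both families are flagged with a warning
#' and reported once per family.
#'
#' @param hits data.frame of domain hits
#' @param profile_families named character vector mapping profile accession
#'   (version stripped) to family label
#' @inheritParams filter_hits
#' @return data.frame with columns `gene_id`, `family`, `status` and a
#'   list-column `evidence` of per-gene hit tables
#' @export
call_family_members <- function(hits, profile_families = default_profile_families(),
                                e_full = 1e-5, e_dom = 1e-5) {
  acc <- sub("\\..*$", "", hits$profile_id)
  fam <- unname(profile_families[acc])
  if (anyNA(fam) && nrow(hits)) {
    bad <- unique(hits$profile_id[is.na(fam)])
    stopf("unknown HMM profile(s): %s", paste(bad, collapse = ", "))
  }
  hits$family <- fam
  hits$pass <- hits$full_evalue <= e_full & hits$dom_ievalue <= e_dom
  key <- paste(hits$gene_id, hits$family, sep = "\r")
  split_hits <- split(hits, key)
  out <- do.call(rbind, lapply(split_hits, function(h) {
    data.frame(gene_id = h$gene_id[1], family = h$family[1],
               status = if (any(h$pass)) "accepted" else "rejected_threshold",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$gene_id, out$family), , drop = FALSE]
  out$evidence <- lapply(seq_len(nrow(out)), function(i) {
    h <- split_hits[[paste(out$gene_id[i], out$family[i], sep = "\r")]]
    h[, c("gene_id", "profile_id", "full_evalue", "dom_ievalue",
          "ali_start", "ali_end", "bit_score"), drop = FALSE]
  })
  dup <- out$gene_id[out$status == "accepted"]
  dup <- unique(dup[duplicated(dup)])
  if (length(dup)) {
    warnf("gene(s) with accepted evidence for both families (reported in both): %s",
          paste(dup, collapse = ", "))
  }
  out
}

#' Verify family domains against an independent domain scan
#'
#' Spurious-gene filter: an accepted candidate whose PfamScan-style domain
#' set lacks its family's named domain is demoted to `rejected_spurious`.
#' Genes missing from `scan_table` are treated as having an empty domain set.
#'
#' @param assignments data.frame from [call_family_members()]
#' @param scan_table named list mapping gene_id to a character vector of
#'   domain names, or a data.frame with columns `gene_id`, `domain`
#' @param family_domains named character vector mapping family to the domain
#'   name that verifies it
#' @return `assignments` with updated `status`
#' @export
verify_domains <- function(assignments, scan_table,
                           family_domains = default_family_domains()) {
  if (is.data.frame(scan_table)) {
    scan_table <- split(as.character(scan_table$domain), scan_table$gene_id)
  }
  ok <- vapply(seq_len(nrow(assignments)), function(i) {
    need <- family_domains[[assignments$family[i]]]
    need %in% (scan_table[[assignments$gene_id[i]]] %||% character())
  }, TRUE)
  demote <- assignments$status == "accepted" & !ok
  assignments$status[demote] <- "rejected_spurious"
  assignments
}

#' Cluster genes into orthogroups by single-linkage on a similarity graph
#'
#' Orthogroups are the connected components of the graph whose edges are
#' similarity pairs with `score >= min_score`; genes without any retained
#' edge form singleton groups. This is a deliberate, documented
#' simplification of OrthoFinder-style orthogrouping (see the methods
#' vignette): the downstream census only needs the presence/absence pattern
#' of each group across varieties. Group ids are assigned in the
#' lexicographic order of each group's smallest member gene id.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `score`
#' @param gene_variety named character vector mapping every known gene_id to
#'   its variety; defines the gene universe (singletons included)
#' @param min_score similarity threshold for keeping an edge
#' @return data.frame with columns `og_id`, `gene_id`, `variety`
#' @export
cluster_orthogroups <- function(edges, gene_variety, min_score) {
  genes <- names(gene_variety)
  if (is.null(genes) || anyNA(genes)) stopf("gene_variety must be a named vector")
  if (nrow(edges)) {
    unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), genes)
    if (length(unknown)) {
      stopf("similarity edge references unknown gene(s): %s",
            paste(unknown, collapse = ", "))
    }
  }
  keep <- edges[edges$score >= min_score, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    keep[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  smallest <- vapply(groups, function(m) min(m), "")
  groups <- groups[order(smallest)]
  do.call(rbind, lapply(seq_along(groups), function(i) {
    members <- sort(groups[[i]])
    data.frame(og_id = sprintf("OG%04d", i), gene_id = members,
               variety = unname(gene_variety[members]),
               stringsAsFactors = FALSE)
  }))
}

#' Classify orthogroups as core, shared or variety-specific
#'
#' `core` = members in every variety; `specific` = members in exactly one;
#' `shared` otherwise. Also tabulates, UpSet-style, how many orthogroups
#' show each exact present-variety subset.
#'
#' @param groups data.frame from [cluster_orthogroups()]
#' @param varieties character vector of all varieties in the pan-genome
#' @return list with `groups` (input plus a `cls` column) and
#'   `intersection_counts` (named integer vector keyed by the sorted
#'   present-variety subset joined with `+`)
#' @export
classify_orthogroups <- function(groups, varieties) {
  if (!length(varieties)) stopf("varieties must be nonempty")
  unknown <- setdiff(unique(groups$variety), varieties)
  if (length(unknown)) {
    stopf("orthogroup member from unlisted variety: %s", paste(unknown, collapse = ", "))
  }
  present <- lapply(split(groups$variety, groups$og_id), function(v) sort(unique(v)))
  cls_of <- vapply(present, function(p) {
    if (length(p) == length(varieties)) "core"
    else if (length(p) == 1L) "specific"
    else "shared"
  }, "")
  groups$cls <- unname(cls_of[groups$og_id])
  subset_key <- vapply(present, paste, "", collapse = "+")
  counts <- table(subset_key)
  list(groups = groups,
       intersection_counts = setNames(as.integer(counts), names(counts)))
}

#' Mean and standard deviation of per-variety family counts
#'
#' Arithmetic mean and sample (n - 1) standard deviation of the per-variety
#' gene counts; `sd` is 0 for a single variety. The reporting layer rounds
#' both to integers, reproducing summaries of the form "44 +/- 7".
#'
#' @param per_variety_counts numeric vector of per-variety counts
#' @return list with `mean`, `sd` and the input counts
#' @export
summarize_counts <- function(per_variety_counts) {
  if (!length(per_variety_counts)) stopf("per-variety counts must be nonempty")
  m <- mean(per_variety_counts)
  s <- if (length(per_variety_counts) == 1L) 0 else sd(per_variety_counts)
  list(mean = m, sd = s, per_variety_counts = per_variety_counts)
}
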