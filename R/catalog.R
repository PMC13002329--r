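# Gene-family catalog construction: homology-hit filtering, subfamily
# assignment by best reference similarity, copy-number tabulation, and
# ranking of alignment columns that separate the two subfamilies.

#' Filter homology-search hits into a candidate gene set
#'
#' Applies the screening rule used for large-scale family identification:
#' a gene survives if it has at least one hit at `evalue <= evalue_max`
#' from either evidence source (domain scan or similarity search; set
#' `require_both = TRUE` for the intersection rule) and its protein length
#' falls inside the closed interval `[len_min, len_max]`. The length window
#' guards against annotation artefacts: overlong proteins suggest fused
#' tandem copies, short ones risk domain loss.
#'
#' @param hits data.frame with columns `query_id`, `source`
#'   ("domain_scan" or "similarity"), `evalue` (and optionally `bitscore`,
#'   `subject_id`).
#' @param lengths named numeric vector of protein lengths (aa) per gene.
#' @param evalue_max inclusive E-value ceiling.
#' @param len_min,len_max inclusive protein-length bounds in aa.
#' @param require_both if `TRUE`, demand a passing hit from both evidence
#'   sources instead of either.
#' @return sorted character vector of surviving gene ids. Genes with hits
#'   but no length entry are dropped with a warning.
#' @examples
#' hits <- data.frame(query_id = c("g1", "g2"), source = "similarity",
#'                    evalue = c(1e-8, 1e-3))
#' filter_candidates(hits, c(g1 = 350, g2 = 350))
#' @export
filter_candidates <- function(hits, lengths, evalue_max = 1e-5,
                              len_min = 200, len_max = 600,
                              require_both = FALSE) {
  stopifnot(is.data.frame(hits),
            all(c("query_id", "source", "evalue") %in% names(hits)))
  if (any(hits$evalue < 0)) stop("E-values must be nonnegative")
  bad_src <- setdiff(unique(hits$source), c("domain_scan", "similarity"))
  if (length(bad_src)) {
    stop("unknown evidence source(s): ", paste(bad_src, collapse = ", "))
  }
  pass <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (require_both) {
    srcs <- tapply(pass$source, pass$query_id,
                   function(s) length(unique(s)))
    genes <- names(srcs)[srcs == 2L]
  } else {
    genes <- unique(pass$query_id)
  }
  missing <- genes[!(genes %in% names(lengths))]
  if (length(missing)) {
    warning("no length entry for gene(s): ",
            paste(missing, collapse = ", "), "; excluded")
    genes <- setdiff(genes, missing)
  }
  len <- lengths[genes]
  sort(genes[len >= len_min & len <= len_max])
}

#' @noRd
.align_stats <- function(query, ref) {
  aln <- Biostrings::pairwiseAlignment(
    query, ref, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5
  )
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ident <- sum(p == s & p != "-")
  list(score = Biostrings::score(aln),
       identity = ident / length(p),               # identical / aligned columns
       aligned_rr = sum(p != "-" & s != "-"))      # residue-residue columns
}

#' Assign candidate proteins to the ASMT or COMT subfamily
#'
#' Labels each candidate with the subfamily of its best-scoring reference
#' under a global BLOSUM62 alignment (affine gaps, opening 10 / extension
#' 0.5). Score ties are broken by higher percent identity, then by the
#' lexicographically smaller reference id, making the assignment invariant
#' to reference input order.
#'
#' @param candidates named character vector or [Biostrings::AAStringSet] of
#'   query proteins.
#' @param references named character vector or [Biostrings::AAStringSet] of
#'   reference proteins.
#' @param ref_labels named character vector giving "ASMT"/"COMT" per
#'   reference id.
#' @return data.frame with `gene_id`, `subfamily`, `best_ref`, `score`,
#'   `identity`.
#' @export
assign_subfamily <- function(candidates, references, ref_labels) {
  candidates <- Biostrings::AAStringSet(candidates)
  references <- Biostrings::AAStringSet(references)
  if (length(references) == 0) stop("reference set is empty")
  if (is.null(names(references)) || is.null(names(candidates))) {
    stop("candidates and references must be named")
  }
  if (!all(names(references) %in% names(ref_labels))) {
    stop("every reference needs a subfamily label")
  }
  if (length(unique(ref_labels[names(references)])) < 2) {
    stop("references must cover both subfamilies")
  }
  ref_order <- order(names(references))  # lexicographic tie-break built in
  references <- references[ref_order]
  res <- lapply(seq_along(candidates), function(i) {
    stats_list <- lapply(seq_along(references),
                         function(j) .align_stats(candidates[[i]],
                                                  references[[j]]))
    score <- vapply(stats_list, `[[`, 0, "score")
    ident <- vapply(stats_list, `[[`, 0, "identity")
    # best score; ties by identity; remaining ties by smaller reference id
    # (references already in lexicographic order, so which.max suffices)
    best <- which(score == max(score))
    best <- best[which.max(ident[best])]
    data.frame(
      gene_id = names(candidates)[i],
      subfamily = unname(ref_labels[names(references)[best]]),
      best_ref = names(references)[best],
      score = score[best],
      identity = ident[best],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Tabulate per-species subfamily copy numbers
#'
#' Counts ASMT and COMT members per species from a labelled gene catalog.
#' Species listed in `roster` but absent from the catalog appear with
#' all-zero rows, so genome sets without family members are not silently
#' dropped.
#'
#' @param genes data.frame with columns `gene_id`, `species_id`,
#'   `subfamily` ("ASMT"/"COMT"/"unassigned").
#' @param receptor_genes optional data.frame (`gene_id`, `species_id`) of
#'   receptor-family members to count alongside.
#' @param roster optional character vector of species ids to guarantee rows
#'   for.
#' @param allow_unassigned if `FALSE` (default), any "unassigned" subfamily
#'   is an error; if `TRUE`, such genes count toward the total only.
#' @return data.frame with `species`, `asmt`, `comt`, `total` (and
#'   `receptor` when supplied).
#' @export
tabulate_copy_numbers <- function(genes, receptor_genes = NULL,
                                  roster = NULL, allow_unassigned = FALSE) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) > 0) {
    stopifnot(all(c("gene_id", "species_id", "subfamily") %in% names(genes)))
    unass <- genes$subfamily == "unassigned"
    if (any(unass) && !allow_unassigned) {
      stop(sum(unass), " gene(s) have unassigned subfamily; ",
           "set allow_unassigned = TRUE to count them in totals only")
    }
  }
  species <- sort(unique(c(as.character(roster),
                           if (nrow(genes)) genes$species_id,
                           if (!is.null(receptor_genes))
                             receptor_genes$species_id)))
  count_of <- function(sub) {
    if (nrow(genes) == 0) return(stats::setNames(rep(0L, length(species)),
                                                 species))
    t0 <- table(factor(genes$species_id[genes$subfamily == sub],
                       levels = species))
    stats::setNames(as.integer(t0), species)
  }
  asmt <- count_of("ASMT")
  comt <- count_of("COMT")
  total <- if (nrow(genes)) {
    t0 <- table(factor(genes$species_id, levels = species))
    stats::setNames(as.integer(t0), species)
  } else asmt
  tab <- data.frame(species = species, asmt = unname(asmt),
                    comt = unname(comt), total = unname(total),
                    stringsAsFactors = FALSE)
  if (!is.null(receptor_genes)) {
    tr <- table(factor(receptor_genes$species_id, levels = species))
    tab$receptor <- as.integer(tr)
  }
  tab
}

#' @noRd
.entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' @noRd
.column_mi <- function(col, labels) {
  # plug-in mutual information in bits; gaps are a 21st symbol
  tab <- table(col, labels)
  n <- sum(tab)
  h_col <- .entropy_bits(rowSums(tab))
  h_lab <- .entropy_bits(colSums(tab))
  h_joint <- .entropy_bits(as.vector(tab))
  max(h_col + h_lab - h_joint, 0)
}

#' Rank alignment columns by subfamily divergence
#'
#' Scores every column of a labelled protein alignment by the mutual
#' information (in bits) between residue identity — with the gap character
#' treated as a 21st symbol — and the subfamily label, and attaches a
#' permutation p-value from label shuffles. This is the statistic used to
#' locate candidate residues separating ASMT from COMT, such as the
#' tryptophan/phenylalanine switch in the substrate-binding pocket.
#'
#' @param msa character matrix (rows = sequences) or
#'   [Biostrings::AAStringSet] of equal-length aligned sequences.
#' @param labels factor/character of two class labels, one per sequence.
#' @param n_permutations label shuffles for the null.
#' @param top_k number of top-ranked columns to flag (13 mirrors the number
#'   of candidate diagnostic residues in the reference analysis).
#' @param seed integer seed for the permutations.
#' @return data.frame sorted by rank with columns `column`, `mi`, `null_p`,
#'   `rank`, `top_k` (logical flag for the leading `top_k` columns). MI is
#'   bounded by the label entropy; ties rank by smaller column index.
#' @export
rank_divergence_columns <- function(msa, labels, n_permutations = 200,
                                    top_k = 13, seed = 1L) {
  if (methods::is(msa, "XStringSet")) {
    msa <- do.call(rbind, strsplit(as.character(msa), ""))
  }
  stopifnot(is.matrix(msa))
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two class labels are required")
  if (any(table(labels) < 2)) stop("need at least 2 sequences per label")
  if (nrow(msa) != length(labels)) stop("labels must match alignment rows")

  mi <- apply(msa, 2, .column_mi, labels = labels)
  set.seed(as.integer(seed))
  exceed <- integer(ncol(msa))
  for (b in seq_len(n_permutations)) {
    perm <- sample(labels)
    mi_b <- apply(msa, 2, .column_mi, labels = perm)
    exceed <- exceed + (mi_b >= mi)
  }
  null_p <- (exceed + 1) / (n_permutations + 1)
  ord <- order(-mi, seq_along(mi))
  out <- data.frame(column = ord, mi = mi[ord], null_p = null_p[ord],
                    rank = seq_along(ord))
  out$top_k <- out$rank <= top_k
  rownames(out) <- NULL
  out
}
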