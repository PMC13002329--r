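# Collinearity analysis: dynamic-programming chaining of homologous anchor
# pairs into synteny blocks, duplication-origin classification, and
# cross-genome synteny networks with connected-component communities.

#' @noRd
.best_chain <- function(ra, rb, max_gap) {
  # longest chain with both ranks strictly increasing and per-step gaps
  # bounded by max_gap; returns indices in chain order
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]
  rb <- rb[ord]
  dp <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[j] < ra[i] && rb[j] < rb[i] &&
          ra[i] - ra[j] <= max_gap && rb[i] - rb[j] <= max_gap &&
          dp[j] + 1L > dp[i]) {
        dp[i] <- dp[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(dp)
  chain <- integer(0)
  while (end > 0L) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  ord[chain]
}

#' Chain collinear anchors into synteny blocks
#'
#' Within each chromosome pair, repeatedly extracts the highest-scoring
#' chain (score = anchor count) of anchors whose gene-order ranks are
#' strictly monotone in both genomes — increasing for same-orientation
#' blocks, decreasing in the second genome for inverted blocks — with
#' consecutive-anchor rank gaps bounded by `max_gap`. Extracted anchors are
#' removed before the next chain is sought, so each anchor belongs to at
#' most one (its best) block. Chains shorter than `min_size` are discarded.
#'
#' @param anchors data.frame with columns `geneA`, `geneB`, `chrA`, `chrB`,
#'   `rankA`, `rankB` (gene-order indices per chromosome).
#' @param min_size minimum anchors per reported block.
#' @param max_gap maximum rank gap between consecutive anchors, in either
#'   genome.
#' @return list of class `synteny_blocks`; each element is a block
#'   data.frame (anchors in chain order) with attribute `"orientation"`
#'   (`"same"` or `"inverted"`). Empty input gives an empty list.
#' @export
chain_collinear_blocks <- function(anchors, min_size = 5, max_gap = 25) {
  blocks <- list()
  if (!is.null(anchors) && nrow(anchors) > 0) {
    stopifnot(all(c("geneA", "geneB", "chrA", "chrB", "rankA", "rankB") %in%
                    names(anchors)))
    key <- paste(anchors$chrA, anchors$chrB, sep = "\r")
    for (grp in split(seq_len(nrow(anchors)), key)) {
      remaining <- grp
      repeat {
        if (length(remaining) == 0) break
        ra <- anchors$rankA[remaining]
        rb <- anchors$rankB[remaining]
        fwd <- .best_chain(ra, rb, max_gap)
        rev_ <- .best_chain(ra, -rb, max_gap)
        use_fwd <- length(fwd) >= length(rev_)
        chain <- if (use_fwd) fwd else rev_
        if (length(chain) < min_size) break
        blk <- anchors[remaining[chain], , drop = FALSE]
        attr(blk, "orientation") <- if (use_fwd) "same" else "inverted"
        blocks[[length(blocks) + 1L]] <- blk
        remaining <- remaining[-chain]
      }
    }
  }
  structure(blocks, class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  if (length(x) == 0) {
    cat("No synteny blocks\n")
    return(invisible(x))
  }
  sizes <- vapply(x, nrow, 0L)
  ori <- vapply(x, attr, "", "orientation")
  cat(sprintf("%d synteny block(s): %d anchors total (%d inverted block(s))\n",
              length(x), sum(sizes), sum(ori == "inverted")))
  invisible(x)
}

#' Classify duplicate origins of family genes
#'
#' Assigns each family gene exactly one duplication class, evaluated in
#' priority order: `wgd_segmental` if the gene anchors any synteny block;
#' else `tandem` if another family member sits at an adjacent rank (gap 0)
#' on the same chromosome; else `proximal` if one lies within
#' `proximal_max` ranks; else `dispersed` if the family has any other
#' member; else `singleton`.
#'
#' @param family_genes character vector of family gene ids (or a data.frame
#'   with a `gene_id` column).
#' @param blocks `synteny_blocks` from [chain_collinear_blocks()] (may be
#'   empty).
#' @param gene_order data.frame with columns `gene_id`, `chrom`, `rank`
#'   covering all family genes.
#' @param proximal_max rank window for the proximal class.
#' @return list with `classes` (data.frame `gene_id`, `class`) and `shares`
#'   (named proportions over the five classes, summing to 1).
#' @export
classify_duplicates <- function(family_genes, blocks, gene_order,
                                proximal_max = 10) {
  if (is.data.frame(family_genes)) family_genes <- family_genes$gene_id
  stopifnot(all(c("gene_id", "chrom", "rank") %in% names(gene_order)))
  missing <- setdiff(family_genes, gene_order$gene_id)
  if (length(missing)) {
    stop("gene(s) missing from gene order: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  idx <- match(family_genes, gene_order$gene_id)
  chrom <- gene_order$chrom[idx]
  rank <- gene_order$rank[idx]
  anchored <- unique(unlist(lapply(blocks, function(b) c(b$geneA, b$geneB))))

  levels_ <- c("wgd_segmental", "tandem", "proximal", "dispersed",
               "singleton")
  cls <- character(length(family_genes))
  for (i in seq_along(family_genes)) {
    others <- setdiff(seq_along(family_genes), i)
    same_chr <- others[chrom[others] == chrom[i]]
    gaps <- abs(rank[same_chr] - rank[i])
    cls[i] <- if (family_genes[i] %in% anchored) {
      "wgd_segmental"
    } else if (any(gaps == 1)) {
      "tandem"
    } else if (any(gaps <= proximal_max)) {
      "proximal"
    } else if (length(others) > 0) {
      "dispersed"
    } else {
      "singleton"
    }
  }
  classes <- data.frame(gene_id = family_genes,
                        class = factor(cls, levels = levels_),
                        stringsAsFactors = FALSE)
  shares <- table(classes$class) / length(family_genes)
  list(classes = classes, shares = c(shares))
}

#' Build a cross-genome synteny network of family genes
#'
#' Nodes are family genes; an edge joins two genes appearing together as a
#' block anchor pair. The graph is simple (no multi-edges), and communities
#' are its connected components — a deterministic stand-in for modularity
#' clustering that needs no resolution parameter.
#'
#' @param blocks `synteny_blocks` (anchors across genome pairs).
#' @param family_genes character vector restricting the network to family
#'   members; anchors touching non-family genes are ignored.
#' @return list with `graph` (igraph), `membership` (component id per
#'   node), `sizes` (component sizes), `n_nodes`, `n_edges`.
#' @export
build_synteny_network <- function(blocks, family_genes) {
  edges <- do.call(rbind, lapply(blocks, function(b) {
    keep <- b$geneA %in% family_genes & b$geneB %in% family_genes
    b[keep, c("geneA", "geneB"), drop = FALSE]
  }))
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(list(graph = g, membership = integer(0), sizes = integer(0),
                n_nodes = 0L, n_edges = 0L))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  list(graph = g, membership = comp$membership,
       sizes = unname(comp$csize),
       n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g))
}
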