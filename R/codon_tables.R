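# Shared codon machinery for the NG86 estimator and the codon-pair simulator.
# Tables are built once per session from the standard genetic code.

.codon_env <- new.env(parent = emptyenv())

.NUCS <- c("A", "C", "G", "T")

#' @noRd
.codon_tables <- function() {
  if (!is.null(.codon_env$tables)) {
    return(.codon_env$tables)
  }
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  sense <- codons[gc_map != "*"]

  # Single-base neighbours of each sense codon, classified as synonymous,
  # nonsynonymous or stop-creating.
  neighbours <- lapply(sense, function(cdn) {
    bases <- strsplit(cdn, "")[[1]]
    aa0 <- gc_map[[cdn]]
    out <- list(pos = integer(), to = character(), type = character())
    for (pos in 1:3) {
      for (nt in setdiff(.NUCS, bases[pos])) {
        nb <- bases
        nb[pos] <- nt
        nbc <- paste(nb, collapse = "")
        aa1 <- gc_map[[nbc]]
        type <- if (aa1 == "*") "stop" else if (aa1 == aa0) "syn" else "nonsyn"
        out$pos <- c(out$pos, pos)
        out$to <- c(out$to, nbc)
        out$type <- c(out$type, type)
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  names(neighbours) <- sense

  # NG86 site counts: fraction of the 3 possible changes per position that is
  # synonymous; stop-creating changes count as nonsynonymous so S + N = 3.
  syn_sites <- vapply(neighbours, function(nb) sum(nb$type == "syn") / 3, 0)

  .codon_env$tables <- list(
    code = gc_map,
    sense = sense,
    neighbours = neighbours,
    syn_sites = syn_sites
  )
  .codon_env$tables
}

#' @noRd
.split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length must be a multiple of 3, got ", n)
  }
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' @noRd
.translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}
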