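# Pairwise molecular-evolution statistics: codon-alignment projection from a
# protein alignment, the Nei-Gojobori (1986) Ka/Ks estimator with
# Jukes-Cantor correction, and Ks-to-time conversion.

#' Project a protein alignment onto the underlying codon sequences
#'
#' Maps each aligned residue back to its codon, turning protein gaps into
#' 3-base codon gaps. Each CDS must translate exactly to its ungapped
#' protein (a trailing stop codon is tolerated and trimmed).
#'
#' @param protein_alignment character vector of two gapped, equal-length
#'   aligned protein strings.
#' @param cds1,cds2 ungapped coding sequences for the first and second
#'   protein.
#' @return object of class `codon_alignment`: list with gapped `cds1`,
#'   `cds2` and `n_complete_codon_pairs`.
#' @export
project_codon_alignment <- function(protein_alignment, cds1, cds2) {
  stopifnot(length(protein_alignment) == 2,
            nchar(protein_alignment[1]) == nchar(protein_alignment[2]))
  cds <- c(cds1, cds2)
  gapped <- character(2)
  for (i in 1:2) {
    prot <- gsub("-", "", protein_alignment[i])
    codons <- .split_codons(cds[i])
    # tolerate a trailing stop codon
    if (length(codons) == nchar(prot) + 1L &&
        .codon_tables()$code[[codons[length(codons)]]] == "*") {
      codons <- codons[-length(codons)]
    }
    if (length(codons) != nchar(prot)) {
      stop("CDS ", i, " has ", length(codons), " codons but the protein has ",
           nchar(prot), " residues")
    }
    trans <- .translate_cds(paste(codons, collapse = ""))
    if (trans != prot) {
      stop("CDS ", i, " does not translate to its aligned protein")
    }
    cols <- strsplit(protein_alignment[i], "")[[1]]
    out <- character(length(cols))
    k <- 0L
    for (j in seq_along(cols)) {
      if (cols[j] == "-") {
        out[j] <- "---"
      } else {
        k <- k + 1L
        out[j] <- codons[k]
      }
    }
    gapped[i] <- paste(out, collapse = "")
  }
  p1 <- .split_codons(gapped[1])
  p2 <- .split_codons(gapped[2])
  complete <- !grepl("-", p1) & !grepl("-", p2)
  structure(list(cds1 = gapped[1], cds2 = gapped[2],
                 n_complete_codon_pairs = sum(complete)),
            class = "codon_alignment")
}

# Average synonymous/nonsynonymous differences between two codons over all
# substitution orderings; pathways passing through a stop codon are dropped
# (if every pathway is blocked, all pathways are used with stop-passing
# steps counted as nonsynonymous). Memoised per codon pair.
#' @noRd
.codon_pair_diffs <- function(c1, c2) {
  key <- paste(c1, c2, sep = "|")
  cached <- .codon_env$paircache[[key]]
  if (!is.null(cached)) return(cached)
  gc_map <- .codon_tables()$code
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(b1 != b2)
  nd <- length(diff_pos)
  res <- if (nd == 0L) {
    c(sd = 0, nd = 0)
  } else {
    perms <- if (nd == 1L) list(diff_pos) else {
      # all orderings of the differing positions
      idx <- seq_len(nd)
      all_perms <- function(v) {
        if (length(v) == 1L) return(list(v))
        out <- list()
        for (i in seq_along(v)) {
          for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
        }
        out
      }
      lapply(all_perms(idx), function(o) diff_pos[o])
    }
    score_path <- function(order_pos, allow_stop) {
      cur <- b1
      sd <- 0; ndc <- 0
      for (pos in order_pos) {
        aa_from <- gc_map[[paste(cur, collapse = "")]]
        cur[pos] <- b2[pos]
        to_codon <- paste(cur, collapse = "")
        aa_to <- gc_map[[to_codon]]
        if (aa_to == "*" && !allow_stop) return(NULL)
        if (aa_to == aa_from && aa_to != "*") sd <- sd + 1 else ndc <- ndc + 1
      }
      c(sd = sd, nd = ndc)
    }
    scored <- Filter(Negate(is.null),
                     lapply(perms, score_path, allow_stop = FALSE))
    if (length(scored) == 0) {
      scored <- lapply(perms, score_path, allow_stop = TRUE)
    }
    colMeans(do.call(rbind, scored))
  }
  if (is.null(.codon_env$paircache)) {
    .codon_env$paircache <- new.env(parent = emptyenv())
  }
  assign(key, res, envir = .codon_env$paircache)
  res
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Synonymous and nonsynonymous site counts are averaged over both
#' sequences, with stop-creating single-base changes counted as
#' nonsynonymous so that S + N equals three times the number of complete
#' codon pairs. Codon pairs differing at multiple positions are averaged
#' over all substitution orderings with equal weight, excluding pathways
#' through stop codons. Proportions are corrected by the Jukes-Cantor
#' formula d = -(3/4) log(1 - 4p/3); a proportion at or beyond the 3/4
#' ceiling flags the estimate as saturated rather than raising an error.
#' Codon pairs containing a gap, an ambiguous base or a stop codon are
#' skipped.
#'
#' @param x a `codon_alignment` from [project_codon_alignment()], or a
#'   gapped/ungapped CDS string (then `y` supplies the second).
#' @param y second CDS string when `x` is a string.
#' @return object of class `kaks_result`: list with `ka`, `ks`, `ratio`,
#'   `coverage` (complete codon pairs over codons of the shorter ungapped
#'   CDS), site/difference counts `S`, `N`, `Sd`, `Nd`,
#'   `n_codon_pairs`, and `reason` (`NA`, `"saturation"`, or `"ks_zero"`
#'   when the ratio is undefined).
#' @examples
#' pair <- simulate_codon_pair(300, target_ka = 0.05, target_ks = 0.2,
#'                             seed = 42)
#' ng86_kaks(pair$cds1, pair$cds2)
#' @export
ng86_kaks <- function(x, y = NULL) {
  if (inherits(x, "codon_alignment")) {
    s1 <- x$cds1
    s2 <- x$cds2
  } else {
    stopifnot(is.character(x), is.character(y))
    s1 <- x
    s2 <- y
  }
  if (nchar(s1) != nchar(s2)) stop("aligned CDS lengths differ")
  tabs <- .codon_tables()
  p1 <- .split_codons(s1)
  p2 <- .split_codons(s2)
  ok <- !grepl("[^ACGT]", p1) & !grepl("[^ACGT]", p2) &
    p1 %in% tabs$sense & p2 %in% tabs$sense
  if (sum(ok) < 1) stop("no complete codon pairs to compare")
  p1 <- p1[ok]
  p2 <- p2[ok]

  s_sites <- (tabs$syn_sites[p1] + tabs$syn_sites[p2]) / 2
  S <- sum(s_sites)
  N <- 3 * length(p1) - S
  diffs <- mapply(function(a, b) .codon_pair_diffs(a, b), p1, p2)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])

  len1 <- nchar(gsub("-", "", s1)) / 3
  len2 <- nchar(gsub("-", "", s2)) / 3
  coverage <- length(p1) / min(len1, len2)

  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(Sd / S)
  ka <- jc(Nd / N)
  reason <- NA_character_
  ratio <- NA_real_
  if (is.na(ka) || is.na(ks)) {
    reason <- "saturation"
  } else if (ks == 0) {
    reason <- "ks_zero"
  } else {
    ratio <- ka / ks
  }
  structure(list(ka = ka, ks = ks, ratio = ratio, coverage = coverage,
                 S = S, N = N, Sd = Sd, Nd = Nd,
                 n_codon_pairs = length(p1), reason = reason),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86 Ka/Ks over %d codon pairs (coverage %.1f%%)\n",
              x$n_codon_pairs, 100 * x$coverage))
  cat(sprintf("  Ka = %.4f  Ks = %.4f  Ka/Ks = %s\n",
              x$ka, x$ks,
              if (is.na(x$ratio)) paste0("undefined (", x$reason, ")")
              else sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Convert Ks to divergence time
#'
#' T = Ks / (2 * rate) * 1e-6 million years, with the default rate of
#' 6.5e-9 substitutions per synonymous site per year commonly applied to
#' grasses. Time is linear in Ks.
#'
#' @param ks synonymous distance(s), substitutions per synonymous site.
#' @param rate substitution rate per site per year.
#' @return divergence time(s) in million years.
#' @examples
#' divergence_time(0.338)  # ~26 Myr
#' @export
divergence_time <- function(ks, rate = 6.5e-9) {
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be nonnegative")
  stopifnot(rate > 0)
  ks / (2 * rate) * 1e-6
}
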