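# Independent oracles used across tests. These deliberately re-derive
# results by brute force (exhaustive enumeration, direct recounting) and
# stay independent of the package's own algorithms.

# --- NG86 oracle: recursive enumeration over intermediate codons ----------

.oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  as.list(gc)
})

.oracle_sense <- names(.oracle_code)[unlist(.oracle_code) != "*"]

# Synonymous-site count of one codon: per position, the fraction of the
# three alternative bases giving a synonymous codon (stops count as
# nonsynonymous).
oracle_syn_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  aa0 <- .oracle_code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      nb <- b
      nb[pos] <- nt
      aa <- .oracle_code[[paste(nb, collapse = "")]]
      if (!is.null(aa) && aa != "*" && aa == aa0) s <- s + 1 / 3
    }
  }
  s
}

# All syn/nonsyn step counts over stop-free substitution paths from c1 to
# c2, found by depth-first search over intermediate codons (a different
# formulation than the package's permutation averaging).
oracle_pair_diffs <- function(c1, c2) {
  paths <- list()
  walk <- function(cur, sd, nd) {
    if (cur == c2) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd)
      return(invisible())
    }
    bc <- strsplit(cur, "")[[1]]
    bt <- strsplit(c2, "")[[1]]
    for (pos in which(bc != bt)) {
      nb <- bc
      nb[pos] <- bt[pos]
      nxt <- paste(nb, collapse = "")
      aa_from <- .oracle_code[[cur]]
      aa_to <- .oracle_code[[nxt]]
      if (aa_to == "*" && nxt != c2) next       # stop intermediate blocked
      if (aa_to == "*") next                    # stop endpoint impossible here
      walk(nxt, sd + (aa_to == aa_from), nd + (aa_to != aa_from))
    }
  }
  walk(c1, 0, 0)
  if (length(paths) == 0) {
    # every path blocked: allow stop-passing steps, counted nonsynonymous
    walk2 <- function(cur, sd, nd) {
      if (cur == c2) {
        paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd)
        return(invisible())
      }
      bc <- strsplit(cur, "")[[1]]
      bt <- strsplit(c2, "")[[1]]
      for (pos in which(bc != bt)) {
        nb <- bc
        nb[pos] <- bt[pos]
        nxt <- paste(nb, collapse = "")
        aa_from <- .oracle_code[[cur]]
        aa_to <- .oracle_code[[nxt]]
        syn <- !is.null(aa_from) && aa_to != "*" && aa_from != "*" &&
          aa_to == aa_from
        walk2(nxt, sd + syn, nd + !syn)
      }
    }
    walk2(c1, 0, 0)
  }
  colMeans(do.call(rbind, paths))
}

# Full NG86 oracle on two equal-length stop-free CDS strings.
oracle_ng86 <- function(cds1, cds2) {
  n <- nchar(cds1) / 3
  p1 <- substring(cds1, 3 * seq_len(n) - 2, 3 * seq_len(n))
  p2 <- substring(cds2, 3 * seq_len(n) - 2, 3 * seq_len(n))
  S <- sum((vapply(p1, oracle_syn_sites, 0) +
              vapply(p2, oracle_syn_sites, 0)) / 2)
  N <- 3 * n - S
  d <- vapply(seq_len(n), function(i) oracle_pair_diffs(p1[i], p2[i]),
              c(sd = 0, nd = 0))
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sum(d["sd", ]), Nd = sum(d["nd", ]),
       ks = jc(sum(d["sd", ]) / S), ka = jc(sum(d["nd", ]) / N))
}

random_sense_cds <- function(n_codons) {
  paste(sample(.oracle_sense, n_codons, replace = TRUE), collapse = "")
}

# --- chaining oracle: exhaustive search over anchor subsets ---------------

# Longest valid chain (either orientation) among <= ~12 anchors, by testing
# every subset for the monotonicity and gap constraints.
oracle_best_chain_size <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0L
  valid <- function(idx, dir) {
    o <- order(ra[idx])
    a <- ra[idx][o]
    b <- rb[idx][o] * dir
    if (any(diff(a) <= 0) || any(diff(b) <= 0)) return(FALSE)
    all(diff(a) <= max_gap) && all(diff(b * 1) <= max_gap)
  }
  for (m in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    if (valid(idx, 1) || valid(idx, -1)) best <- length(idx)
  }
  max(best, 1L * (n > 0))
}

# --- openness oracle: exact average over all variety permutations ---------

oracle_openness_exact <- function(pav) {
  nv <- ncol(pav)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  all_p <- perms(seq_len(nv))
  acc <- numeric(nv)
  for (p in all_p) {
    seen <- rep(FALSE, nrow(pav))
    for (step in seq_len(nv)) {
      new_here <- pav[, p[step]] & !seen
      acc[step] <- acc[step] + sum(new_here)
      seen <- seen | new_here
    }
  }
  acc / length(all_p)
}

# --- tiny fixture builders ------------------------------------------------

random_protein_string <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}
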