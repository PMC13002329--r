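# Synthetic-data generators. Every generator is a pure function of its
# arguments plus a seed, and returns recorded ground truth alongside the data
# so downstream recovery tests never need to re-derive it.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a per-species ASMT/COMT copy-number table
#'
#' Emulates a multi-species copy-number survey of a two-subfamily gene family.
#' Each species draws a total copy number uniformly from `total_range`; the
#' ASMT count is Binomial(total, `asmt_share`) and COMT takes the remainder,
#' so `asmt + comt == total` holds exactly for every row. The binomial
#' allocation makes the two subfamily-on-total regression slopes sum to one,
#' the identity the dosage regressions exploit.
#'
#' Optionally a melatonin-receptor (CAND2-like) copy count is added through a
#' Gaussian copula with latent correlation `receptor_rho` to the total,
#' mapped to a Poisson(2) margin (receptors sit around two copies in most
#' species). The population Spearman correlation implied by the copula is
#' (6/pi) * asin(receptor_rho / 2) before discreteness attenuation.
#'
#' @param n_species number of species rows.
#' @param asmt_share probability in (0,1) that a family member is ASMT.
#' @param total_range inclusive integer range for total copy number.
#' @param receptor_rho optional latent copula correlation for a receptor
#'   column; `NULL` omits the column.
#' @param seed integer seed.
#' @return data.frame with columns `species`, `asmt`, `comt`, `total` (and
#'   `receptor` if requested); the generating parameters are attached as
#'   attribute `"truth"`.
#' @examples
#' tab <- simulate_copy_number_table(50, asmt_share = 0.6, seed = 1)
#' stopifnot(all(tab$asmt + tab$comt == tab$total))
#' @export
simulate_copy_number_table <- function(n_species, asmt_share,
                                       total_range = c(2L, 120L),
                                       receptor_rho = NULL, seed = 1L) {
  stopifnot(n_species >= 1)
  if (!is.numeric(asmt_share) || asmt_share <= 0 || asmt_share >= 1) {
    stop("asmt_share must lie strictly inside (0, 1)")
  }
  total_range <- as.integer(round(total_range))
  if (length(total_range) != 2L || total_range[1] > total_range[2] ||
      total_range[1] < 1L) {
    stop("total_range must be a nonempty inclusive range of positive totals")
  }
  set.seed(as.integer(seed))
  vals <- seq.int(total_range[1], total_range[2])
  total <- if (length(vals) == 1L) rep(vals, n_species) else
    sample(vals, n_species, replace = TRUE)
  asmt <- stats::rbinom(n_species, total, asmt_share)
  tab <- data.frame(
    species = sprintf("sp%04d", seq_len(n_species)),
    asmt = asmt,
    comt = total - asmt,
    total = total,
    stringsAsFactors = FALSE
  )
  if (!is.null(receptor_rho)) {
    stopifnot(abs(receptor_rho) < 1)
    # Gaussian copula against the total's latent normal score
    z_tot <- stats::qnorm(stats::punif(total, total_range[1] - 1,
                                       total_range[2]))
    z_tot[!is.finite(z_tot)] <- 0
    z_rec <- receptor_rho * z_tot +
      sqrt(1 - receptor_rho^2) * stats::rnorm(n_species)
    tab$receptor <- stats::qpois(stats::pnorm(z_rec), lambda = 2)
  }
  attr(tab, "truth") <- list(asmt_share = asmt_share,
                             total_range = total_range,
                             receptor_rho = receptor_rho,
                             seed = as.integer(seed))
  tab
}

#' Simulate a pair of coding sequences with target Ka and Ks
#'
#' Draws an ancestral CDS uniformly over sense codons, then scatters Poisson
#' numbers of synonymous and nonsynonymous single-base substitution events
#' (expected counts `target_ks * S` and `target_ka * N`, with S and N the
#' NG86 site counts of the ancestor) across the two descendant lineages.
#' Events are placed uniformly over the eligible single-base changes of the
#' current sequence; stop-creating changes are never proposed, so no internal
#' stop codon can arise. The expected NG86 estimates of the resulting pair
#' match the targets up to multiple-hit noise.
#'
#' @param n_codons number of codons (>= 10).
#' @param target_ka,target_ks expected substitutions per nonsynonymous /
#'   synonymous site. Targets of 3 or more are refused: the expected
#'   p-distance then approaches the 3/4 ceiling where the Jukes-Cantor
#'   correction is undefined.
#' @param seed integer seed.
#' @return list with CDS strings `cds1`, `cds2` and the generating targets
#'   in attribute `"truth"`.
#' @export
simulate_codon_pair <- function(n_codons, target_ka, target_ks, seed = 1L) {
  if (n_codons < 10) stop("n_codons must be at least 10")
  stopifnot(target_ka >= 0, target_ks >= 0)
  if (target_ka >= 3 || target_ks >= 3) {
    stop("target divergence >= 3 substitutions/site is refused: expected ",
         "p-distance approaches 3/4, where the Jukes-Cantor correction ",
         "is undefined")
  }
  tabs <- .codon_tables()
  set.seed(as.integer(seed))
  anc <- sample(tabs$sense, n_codons, replace = TRUE)

  syn_count <- vapply(tabs$neighbours, function(nb) sum(nb$type == "syn"), 0L)
  non_count <- vapply(tabs$neighbours, function(nb) sum(nb$type == "nonsyn"), 0L)

  S0 <- sum(tabs$syn_sites[anc])
  N0 <- 3 * n_codons - S0
  n_syn <- stats::rpois(1L, target_ks * S0)
  n_non <- stats::rpois(1L, target_ka * N0)

  lineages <- list(anc, anc)
  events <- sample(c(rep("syn", n_syn), rep("nonsyn", n_non)))
  who <- sample(1:2, length(events), replace = TRUE)
  for (i in seq_along(events)) {
    seqc <- lineages[[who[i]]]
    counts <- if (events[i] == "syn") syn_count[seqc] else non_count[seqc]
    if (sum(counts) == 0) next
    at <- sample.int(n_codons, 1L, prob = counts)
    nb <- tabs$neighbours[[seqc[at]]]
    opts <- nb$to[nb$type == events[i]]
    seqc[at] <- opts[sample.int(length(opts), 1L)]
    lineages[[who[i]]] <- seqc
  }
  out <- list(cds1 = paste(lineages[[1]], collapse = ""),
              cds2 = paste(lineages[[2]], collapse = ""))
  attr(out, "truth") <- list(target_ka = target_ka, target_ks = target_ks,
                             n_codons = n_codons, seed = as.integer(seed))
  out
}

#' @noRd
.random_protein <- function(len) {
  sample(.AA20, len, replace = TRUE)
}

# Substitute a fixed fraction of positions (rounded count) so realized
# identity to the input sits at the target rather than fluctuating around
# it -- clustering-recovery tests rely on the planted identities holding.
#' @noRd
.mutate_protein <- function(chars, d) {
  k <- round(length(chars) * d)
  if (k > 0) {
    idx <- sample.int(length(chars), k)
    chars[idx] <- vapply(chars[idx],
                         function(a) sample(setdiff(.AA20, a), 1L), "")
  }
  chars
}

#' Simulate a multi-variety pan-genome protein set with planted OGGs
#'
#' One ancestral protein is generated per orthologous gene group (OGG);
#' ancestors descend from a common root mutated so that inter-OGG identity
#' sits near `between_identity`. Each variety carrying an OGG receives a copy
#' mutated at half of `1 - within_identity` from the ancestor, so two copies
#' of the same OGG share roughly `within_identity` identity — above the
#' downstream clustering threshold — while copies of different OGGs stay
#' well below it.
#'
#' Core OGGs are present in every variety by construction; each dispensable
#' OGG is present in each variety independently with probability
#' `occupancy`. Dispensable OGGs absent from every variety do not exist
#' observationally and are dropped from the emitted sequences and truth PAV
#' matrix, but the full presence-draw matrix (including all-absent rows) is
#' kept in the truth record so occupancy-recovery tests can score the raw
#' Bernoulli draws.
#'
#' @param n_varieties number of varieties.
#' @param n_core,n_dispensable counts of always-present and variably present
#'   OGGs.
#' @param occupancy presence probability for dispensable OGGs; scalar or a
#'   vector of length `n_dispensable`.
#' @param within_identity target identity between two variety copies of one
#'   OGG; must exceed `between_identity`.
#' @param between_identity approximate identity between different OGG
#'   ancestors.
#' @param seq_length protein length in residues.
#' @param seed integer seed.
#' @return list with `sequences` (an [Biostrings::AAStringSet] named
#'   `<gene>`), `mapping` (data.frame gene/variety/ogg) and `truth`
#'   (planted PAV matrix, full presence draws, parameters).
#' @export
simulate_pangenome <- function(n_varieties, n_core, n_dispensable,
                               occupancy = 0.5,
                               within_identity = 0.98,
                               between_identity = 0.60,
                               seq_length = 120L, seed = 1L) {
  stopifnot(n_varieties >= 1, n_core >= 0, n_dispensable >= 0,
            n_core + n_dispensable >= 1)
  if (!(within_identity > between_identity)) {
    stop("within_identity must exceed between_identity")
  }
  if (any(occupancy <= 0) || any(occupancy >= 1)) {
    stop("occupancy probabilities must lie strictly inside (0, 1)")
  }
  occupancy <- rep_len(occupancy, n_dispensable)
  set.seed(as.integer(seed))

  n_ogg <- n_core + n_dispensable
  varieties <- sprintf("v%02d", seq_len(n_varieties))
  ogg_ids <- sprintf("ogg%03d", seq_len(n_ogg))

  root <- .random_protein(seq_length)
  d_anc <- 1 - sqrt(between_identity)  # two lineages at depth d: identity ~ (1-d)^2
  ancestors <- lapply(seq_len(n_ogg), function(i) .mutate_protein(root, d_anc))

  draws <- matrix(TRUE, n_ogg, n_varieties,
                  dimnames = list(ogg_ids, varieties))
  if (n_dispensable > 0) {
    for (j in seq_len(n_dispensable)) {
      draws[n_core + j, ] <- stats::runif(n_varieties) < occupancy[j]
    }
  }
  keep <- rowSums(draws) > 0
  pav <- draws[keep, , drop = FALSE]

  d_copy <- (1 - within_identity) / 2
  genes <- character(0); gene_var <- character(0); gene_ogg <- character(0)
  seqs <- character(0)
  for (i in which(keep)) {
    for (v in which(draws[i, ])) {
      g <- sprintf("%s_%s", ogg_ids[i], varieties[v])
      genes <- c(genes, g)
      gene_var <- c(gene_var, varieties[v])
      gene_ogg <- c(gene_ogg, ogg_ids[i])
      seqs <- c(seqs, paste(.mutate_protein(ancestors[[i]], d_copy),
                            collapse = ""))
    }
  }
  sequences <- Biostrings::AAStringSet(stats::setNames(seqs, genes))
  list(
    sequences = sequences,
    mapping = data.frame(gene = genes, variety = gene_var, ogg = gene_ogg,
                         stringsAsFactors = FALSE),
    truth = list(pav = pav, presence_draws = draws,
                 n_core = n_core, n_dispensable = n_dispensable,
                 occupancy = occupancy,
                 within_identity = within_identity,
                 between_identity = between_identity,
                 seed = as.integer(seed))
  )
}

#' Simulate Ks values from a Gaussian mixture
#'
#' Draws i.i.d. values from a mixture of normals after renormalizing the
#' component weights to sum to one. Sampling is untruncated: negative draws
#' are kept so that component-mean recovery by a refit stays unbiased.
#'
#' @param components data.frame (or matrix) with columns `mean`, `sd`,
#'   `weight`, one row per component.
#' @param n_draws number of values.
#' @param seed integer seed.
#' @return numeric vector of Ks draws with the renormalized components in
#'   attribute `"truth"`.
#' @seealso [poaceae_ks_components()] for the grass-family three-component
#'   reference mixture.
#' @export
simulate_ks_mixture <- function(components, n_draws, seed = 1L) {
  components <- as.data.frame(components)
  stopifnot(nrow(components) >= 1,
            all(c("mean", "sd", "weight") %in% names(components)))
  if (any(components$sd <= 0)) stop("component sds must be positive")
  if (any(components$weight <= 0)) stop("component weights must be positive")
  w <- components$weight / sum(components$weight)
  set.seed(as.integer(seed))
  comp <- sample.int(nrow(components), n_draws, replace = TRUE, prob = w)
  x <- stats::rnorm(n_draws, components$mean[comp], components$sd[comp])
  attr(x, "truth") <- data.frame(mean = components$mean, sd = components$sd,
                                 weight = w)
  x
}

#' Three-component grass-family Ks mixture
#'
#' The reference Gaussian-mixture decomposition of the ASMT/COMT Ks
#' distribution across grasses: component means 0.339, 0.730 and 1.131 with
#' standard deviations 0.139, 0.162, 0.204 and weights 0.542, 0.238, 0.169
#' (renormalized to sum to one when sampled).
#'
#' @return data.frame with columns `mean`, `sd`, `weight`.
#' @export
poaceae_ks_components <- function() {
  data.frame(
    mean = c(0.339, 0.730, 1.131),
    sd = c(0.139, 0.162, 0.204),
    weight = c(0.542, 0.238, 0.169)
  )
}

#' Simulate a labelled protein alignment with planted diagnostic columns
#'
#' Produces a gapless alignment of two sequence classes (ASMT-like and
#' COMT-like). Non-diagnostic columns share one residue distribution across
#' classes: each column has a consensus residue that every sequence carries
#' with probability 0.8, otherwise a random residue — so their expected
#' mutual information with the class label is zero. Diagnostic columns carry
#' a class-specific residue pair (e.g. W in one class, F in the other);
#' with probability `leakage` a sequence swaps to the other class's residue.
#'
#' @param n_per_class sequences per class (>= 2).
#' @param length alignment columns.
#' @param diagnostic_columns integer set of planted column indices (1-based).
#' @param leakage per-cell probability of carrying the wrong class residue.
#' @param seed integer seed.
#' @return list with `msa` (character matrix, rows = sequences) and `labels`
#'   (factor); planted columns recorded in attribute `"truth"`.
#' @export
simulate_labeled_alignment <- function(n_per_class, length,
                                       diagnostic_columns = integer(0),
                                       leakage = 0, seed = 1L) {
  if (n_per_class < 2) stop("n_per_class must be at least 2")
  stopifnot(length >= 1, leakage >= 0, leakage < 1)
  diagnostic_columns <- as.integer(diagnostic_columns)
  if (any(diagnostic_columns < 1L | diagnostic_columns > length)) {
    stop("diagnostic_columns must lie within 1..length")
  }
  set.seed(as.integer(seed))
  n <- 2L * n_per_class
  labels <- factor(rep(c("ASMT", "COMT"), each = n_per_class))
  msa <- matrix("", n, length)
  consensus <- sample(.AA20, length, replace = TRUE)
  for (j in seq_len(length)) {
    hit <- stats::runif(n) < 0.8
    col <- ifelse(hit, consensus[j], sample(.AA20, n, replace = TRUE))
    msa[, j] <- col
  }
  pairs <- list()
  for (j in diagnostic_columns) {
    res <- sample(.AA20, 2L)
    pairs[[as.character(j)]] <- res
    want <- ifelse(labels == "ASMT", res[1], res[2])
    flip <- stats::runif(n) < leakage
    msa[, j] <- ifelse(flip, ifelse(labels == "ASMT", res[2], res[1]), want)
  }
  rownames(msa) <- sprintf("%s_%03d", as.character(labels),
                           stats::ave(seq_len(n), labels, FUN = seq_along))
  out <- list(msa = msa, labels = labels)
  attr(out, "truth") <- list(diagnostic_columns = diagnostic_columns,
                             residue_pairs = pairs, leakage = leakage,
                             seed = as.integer(seed))
  out
}

#' Simulate an FPKM expression matrix with a subfamily shift
#'
#' FPKM values are log-normal: log2(FPKM) is normal with a gene-family
#' baseline, and every COMT row is shifted upward by `comt_shift` log2-fold
#' units. Values are strictly positive by construction.
#'
#' @param n_asmt,n_comt gene counts per subfamily (>= 1).
#' @param n_samples expression samples (columns).
#' @param comt_shift log2 fold-change added to COMT rows.
#' @param base_log2,sd_log2 baseline mean and sd of log2(FPKM).
#' @param seed integer seed.
#' @return list with `fpkm` (genes x samples matrix) and `subfamily`
#'   (named character vector of row labels).
#' @export
simulate_expression_matrix <- function(n_asmt, n_comt, n_samples,
                                       comt_shift = 0, base_log2 = 3,
                                       sd_log2 = 1, seed = 1L) {
  stopifnot(n_asmt >= 1, n_comt >= 1, n_samples >= 1)
  set.seed(as.integer(seed))
  n <- n_asmt + n_comt
  subfam <- c(rep("ASMT", n_asmt), rep("COMT", n_comt))
  genes <- sprintf("%s_%03d", subfam,
                   c(seq_len(n_asmt), seq_len(n_comt)))
  mu <- ifelse(subfam == "COMT", base_log2 + comt_shift, base_log2)
  fpkm <- matrix(2^(stats::rnorm(n * n_samples, rep(mu, n_samples), sd_log2)),
                 nrow = n, ncol = n_samples,
                 dimnames = list(genes, sprintf("sample%02d",
                                                seq_len(n_samples))))
  list(fpkm = fpkm, subfamily = stats::setNames(subfam, genes))
}
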