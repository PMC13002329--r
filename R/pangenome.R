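# Orthologous-gene-group construction and pan-genome openness analysis:
# greedy incremental clustering in the CD-HIT style (identity >= 95%,
# coverage >= 90%, longest sequence as representative), presence/absence
# matrices, Core/Shell/SoftCore/Cloud occupancy classes, new-OGG discovery
# curves and the n = k * N^-a openness power law.

#' Greedy incremental protein clustering into orthologous gene groups
#'
#' Sequences are visited in order of decreasing length (ties by
#' lexicographically smaller id). Each sequence either joins the first
#' existing cluster whose representative it matches at
#' `identity >= identity_min` with `coverage >= coverage_min`
#' (CD-HIT's greedy first-match semantics; `best_match = TRUE` joins the
#' best-identity match instead), or seeds a new cluster and becomes its
#' representative. Identity is identical positions over aligned columns of a
#' global BLOSUM62 alignment (affine gaps, opening 10 / extension 0.5);
#' coverage is residue-residue aligned columns over the length of, by
#' default, the shorter sequence.
#'
#' @param sequences named character vector or [Biostrings::AAStringSet];
#'   ids must be unique and sequences nonempty.
#' @param identity_min,coverage_min inclusive thresholds.
#' @param coverage_mode denominator for coverage: `"shorter"` (default),
#'   `"longer"`, or `"query"` (the incoming sequence).
#' @param best_match join the best matching cluster rather than the first.
#' @return an object of class `ogg_set`: a list of clusters, each with
#'   `ogg_id`, `representative_id`, `members`.
#' @export
greedy_cluster <- function(sequences, identity_min = 0.95,
                           coverage_min = 0.90,
                           coverage_mode = c("shorter", "longer", "query"),
                           best_match = FALSE) {
  coverage_mode <- match.arg(coverage_mode)
  sequences <- Biostrings::AAStringSet(sequences)
  if (length(sequences) == 0) stop("no input sequences")
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequence ids must be present and unique")
  }
  lens <- Biostrings::width(sequences)
  if (any(lens == 0)) stop("empty sequences are not allowed")

  ord <- order(-lens, ids)
  sequences <- sequences[ord]
  ids <- ids[ord]
  lens <- lens[ord]

  reps <- integer(0)     # index (into sorted input) of each representative
  members <- list()
  for (i in seq_along(sequences)) {
    assigned <- 0L
    best_ident <- -1
    for (ci in seq_along(reps)) {
      st <- .align_stats(sequences[[i]], sequences[[reps[ci]]])
      denom <- switch(coverage_mode,
                      shorter = min(lens[i], lens[reps[ci]]),
                      longer = max(lens[i], lens[reps[ci]]),
                      query = lens[i])
      cov <- st$aligned_rr / denom
      if (st$identity >= identity_min && cov >= coverage_min) {
        if (!best_match) {
          assigned <- ci
          break
        } else if (st$identity > best_ident) {
          best_ident <- st$identity
          assigned <- ci
        }
      }
    }
    if (assigned > 0L) {
      members[[assigned]] <- c(members[[assigned]], ids[i])
    } else {
      reps <- c(reps, i)
      members[[length(reps)]] <- ids[i]
    }
  }
  clusters <- lapply(seq_along(reps), function(ci) {
    list(ogg_id = sprintf("OGG%04d", ci),
         representative_id = ids[reps[ci]],
         members = members[[ci]])
  })
  structure(clusters, class = "ogg_set")
}

#' @export
print.ogg_set <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$members), 0L)
  cat("Orthologous gene groups:", length(x), "clusters,",
      sum(sizes), "sequences\n")
  cat("Cluster sizes:", paste(utils::head(sizes, 10), collapse = " "),
      if (length(sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Build a presence/absence matrix from clustered OGGs
#'
#' @param oggs an `ogg_set` from [greedy_cluster()].
#' @param variety_of_gene named character vector mapping every member gene
#'   id to its variety.
#' @return logical matrix, rows = OGGs (named by representative cluster id),
#'   columns = varieties; presence means the cluster holds at least one
#'   member from that variety.
#' @export
build_pav_matrix <- function(oggs, variety_of_gene) {
  stopifnot(inherits(oggs, "ogg_set"))
  all_members <- unlist(lapply(oggs, `[[`, "members"))
  unmapped <- setdiff(all_members, names(variety_of_gene))
  if (length(unmapped)) {
    stop("unmapped member gene(s): ", paste(utils::head(unmapped, 5),
                                            collapse = ", "))
  }
  varieties <- sort(unique(unname(variety_of_gene[all_members])))
  pav <- matrix(FALSE, length(oggs), length(varieties),
                dimnames = list(vapply(oggs, `[[`, "", "ogg_id"), varieties))
  for (i in seq_along(oggs)) {
    pav[i, unique(unname(variety_of_gene[oggs[[i]]$members]))] <- TRUE
  }
  pav
}

#' Classify OGG occupancy into Core / Shell / SoftCore / Cloud
#'
#' Occupancy is the fraction of varieties containing the OGG. Classes:
#' Core = 100%; Shell = \[90%, 100%); SoftCore = \[10%, 90%); Cloud < 10%.
#' Everything not Core is flagged dispensable (absent from at least one
#' variety).
#'
#' @param pav logical presence/absence matrix (OGG x variety).
#' @return data.frame with `ogg`, `occupancy`, `class` (ordered factor) and
#'   `dispensable`.
#' @export
classify_occupancy <- function(pav) {
  stopifnot(is.matrix(pav), ncol(pav) >= 1)
  occ <- rowMeans(pav)
  if (any(occ == 0)) stop("all-absent OGG rows are not allowed")
  cls <- ifelse(occ == 1, "Core",
                ifelse(occ >= 0.9, "Shell",
                       ifelse(occ >= 0.1, "SoftCore", "Cloud")))
  data.frame(
    ogg = if (is.null(rownames(pav))) as.character(seq_len(nrow(pav)))
          else rownames(pav),
    occupancy = unname(occ),
    class = factor(cls, levels = c("Core", "Shell", "SoftCore", "Cloud")),
    dispensable = unname(occ < 1),
    stringsAsFactors = FALSE
  )
}

#' Pan-genome openness curve (new-OGG discovery)
#'
#' For each of `n_iter` uniformly random orderings of the varieties
#' (sampling without replacement), counts the OGGs first observed in the
#' N-th added variety, and averages over iterations. The cumulative sum of
#' any single ordering's counts equals the total OGG count.
#'
#' @param pav logical presence/absence matrix (OGG x variety).
#' @param n_iter number of random orderings.
#' @param seed integer seed.
#' @return data.frame with `N` (sample size) and `new_mean` (mean new OGGs).
#' @export
openness_curve <- function(pav, n_iter = 100, seed = 1L) {
  stopifnot(is.matrix(pav), ncol(pav) >= 2, n_iter >= 1)
  set.seed(as.integer(seed))
  nv <- ncol(pav)
  acc <- numeric(nv)
  for (it in seq_len(n_iter)) {
    perm <- sample.int(nv)
    seen <- rep(FALSE, nrow(pav))
    for (step in seq_len(nv)) {
      new_here <- pav[, perm[step]] & !seen
      acc[step] <- acc[step] + sum(new_here)
      seen <- seen | new_here
    }
  }
  data.frame(N = seq_len(nv), new_mean = acc / n_iter)
}

#' Fit the openness power law n = k * N^-a
#'
#' Nonlinear least squares on the original scale, initialized from the
#' log-log linear regression. Points with nonpositive `n` are excluded with
#' a warning (the log-log start is undefined there). The quality of fit is
#' the pseudo-R-squared 1 - SSres/SStot computed on the original scale.
#'
#' @param N sample sizes (number of varieties added).
#' @param n mean new-OGG counts at each N.
#' @param min_n drop points with N below this (the full curve, `min_n = 1`,
#'   is the default).
#' @return object of class `power_law_fit` with elements `k`, `a`, `r2`,
#'   `fitted`, `data`; has `print`, `coef` and `predict` methods.
#' @export
fit_power_law <- function(N, n, min_n = 1) {
  if (is.data.frame(N)) {
    n <- N[[2]]
    N <- N[[1]]
  }
  stopifnot(length(N) == length(n))
  keep <- N >= min_n
  if (any(n[keep] <= 0)) {
    warning(sum(n[keep] <= 0), " point(s) with nonpositive n excluded")
    keep <- keep & n > 0
  }
  N <- N[keep]
  n <- n[keep]
  if (length(N) < 3) stop("need at least 3 usable points to fit")
  start_fit <- stats::lm(log(n) ~ log(N))
  start <- list(k = exp(unname(stats::coef(start_fit)[1])),
                a = -unname(stats::coef(start_fit)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(n ~ k * N^(-a), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    k <- unname(stats::coef(fit)["k"])
    a <- unname(stats::coef(fit)["a"])
  } else {
    # degenerate curves (e.g. exactly flat) make the LM gradient singular;
    # fall back to direct SSE minimization from the same start
    o <- stats::optim(c(start$k, start$a),
                      function(p) sum((n - p[1] * N^(-p[2]))^2),
                      control = list(reltol = 1e-14, maxit = 5000))
    k <- o$par[1]
    a <- o$par[2]
  }
  pred <- k * N^(-a)
  r2 <- 1 - sum((n - pred)^2) / sum((n - mean(n))^2)
  structure(list(k = k, a = a, r2 = r2, fitted = pred,
                 data = data.frame(N = N, n = n)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Pan-genome openness power law: n = %.4g * N^-%.4g\n",
              x$k, x$a))
  cat(sprintf("  pseudo-R2 (original scale): %.4f on %d points\n",
              x$r2, nrow(x$data)))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(k = object$k, a = object$a)
}

#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  N <- if (is.null(newdata)) object$data$N else
    if (is.data.frame(newdata)) newdata$N else newdata
  object$k * N^(-object$a)
}
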