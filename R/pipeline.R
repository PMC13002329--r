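# Workflow orchestration: the two end-to-end analyses (multi-species CNV /
# dosage statistics, and pan-genome clustering / openness / Ks dating /
# ploidy contrast) driven by a single config list with one root seed.
# Stage seeds are derived as root_seed + 1000 * stage_offset so a stage
# rerun in isolation reproduces its in-workflow result.

.STAGE_OFFSETS <- c(simulate = 0L, catalog = 1L, cluster = 2L,
                    openness = 3L, kaks = 4L, ksmix = 5L, dosage = 6L)

#' @noRd
.stage_seed <- function(root_seed, stage) {
  offset <- .STAGE_OFFSETS[[stage]]
  as.integer((as.integer(root_seed) + 1000L * offset) %% .Machine$integer.max)
}

#' @noRd
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @noRd
.run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' @noRd
.htest_brief <- function(ht) {
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Run the multi-species copy-number-variation workflow
#'
#' Generates (or accepts) a per-species copy-number table, then computes
#' the dosage-balance statistics: subfamily regression with slope ratio,
#' the k-means high/low copy split with group tests on the COMT share
#' (configurable to the ASMT share), and — when a receptor column exists —
#' the receptor-total Spearman correlation. Emits a single JSON-able
#' report embedding the config and its hash.
#'
#' @param config list with elements `seed` (root seed) and either
#'   `copy_table` (a ready copy-number data.frame) or `synthetic`
#'   (arguments for [simulate_copy_number_table()]: `n_species`,
#'   `asmt_share`, optional `total_range`, `receptor_rho`); optional
#'   `share` ("comt" default, or "asmt") selects the proportion compared
#'   between copy groups; optional `out_dir` writes `cnv_report.json` and
#'   `copy_table.tsv` there.
#' @return report list (invisibly JSON-written when `out_dir` is set) with
#'   elements `config`, `config_hash`, `regression`, `group_split`,
#'   `receptor`.
#' @export
run_cnv_workflow <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed))
  share <- match.arg(config$share %||% "comt", c("comt", "asmt"))

  tab <- .run_stage("family_catalog", {
    if (!is.null(config$copy_table)) {
      ct <- config$copy_table
      stopifnot(is.data.frame(ct), nrow(ct) >= 1)
      ct
    } else if (!is.null(config$synthetic)) {
      sy <- config$synthetic
      simulate_copy_number_table(
        n_species = sy$n_species, asmt_share = sy$asmt_share,
        total_range = sy$total_range %||% c(2L, 120L),
        receptor_rho = sy$receptor_rho,
        seed = .stage_seed(config$seed, "simulate"))
    } else {
      stop("config must supply copy_table or synthetic")
    }
  })

  res <- .run_stage("dosage_stats", {
    reg <- subfamily_regression(tab)
    prop <- if (share == "comt") tab$comt / tab$total else tab$asmt / tab$total
    split <- split_high_low(tab$total, statistic = prop)
    rec <- if ("receptor" %in% names(tab)) receptor_correlation(tab) else NULL
    list(reg = reg, split = split, rec = rec)
  })

  cfg_embed <- config[setdiff(names(config), c("copy_table", "out_dir"))]
  report <- list(
    workflow = "cnv",
    config = cfg_embed,
    config_hash = .config_hash(cfg_embed),
    n_species = nrow(tab),
    regression = res$reg[c("slope_asmt", "slope_comt", "slope_ratio",
                           "pearson_r", "pearson_p", "spearman_rho",
                           "spearman_p")],
    group_split = list(
      n = as.list(res$split$n),
      boundary = as.list(res$split$boundary),
      share_compared = share,
      t_test = .htest_brief(res$split$t_test),
      mann_whitney = .htest_brief(res$split$mann_whitney)
    ),
    receptor = if (!is.null(res$rec)) res$rec[c("rho", "p", "n")]
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "cnv_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(tab, file.path(config$out_dir, "copy_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

#' Run the pan-genome workflow
#'
#' Simulates (or accepts) a multi-variety protein set, clusters it into
#' OGGs at the 95% identity / 90% coverage thresholds, classifies
#' occupancy, computes the openness curve and fits the n = k N^-a power
#' law; then decomposes a Ks sample into a BIC-selected Gaussian mixture,
#' dates its dominant peak, and contrasts two ploidy groups' copy-number
#' tables.
#'
#' @param config list with `seed` plus optional blocks:
#'   `pangenome` (arguments for [simulate_pangenome()]), `openness`
#'   (`n_iter`), `ks` (either `values` or `components` + `n_draws` for
#'   [simulate_ks_mixture()], and `rate`), and `ploidy` (two synthetic
#'   table specs `a` and `b`, each with `n_species`, `asmt_share`,
#'   `total_range`); optional `out_dir` writes `pangenome_report.json`.
#' @return report list with OGG/occupancy counts, power-law fit, mixture
#'   components, peak dating and ploidy contrast.
#' @export
run_pangenome_workflow <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed))
  cfg_embed <- config[setdiff(names(config), "out_dir")]
  report <- list(workflow = "pangenome",
                 config = cfg_embed,
                 config_hash = .config_hash(cfg_embed))

  if (!is.null(config$pangenome)) {
    pg <- config$pangenome
    sim <- .run_stage("synthetic_data", simulate_pangenome(
      n_varieties = pg$n_varieties, n_core = pg$n_core,
      n_dispensable = pg$n_dispensable,
      occupancy = pg$occupancy %||% 0.5,
      within_identity = pg$within_identity %||% 0.98,
      between_identity = pg$between_identity %||% 0.60,
      seq_length = pg$seq_length %||% 120L,
      seed = .stage_seed(config$seed, "simulate")))
    oggs <- .run_stage("ogg_pangenome", greedy_cluster(sim$sequences))
    pav <- .run_stage("ogg_pangenome", build_pav_matrix(
      oggs, stats::setNames(sim$mapping$variety, sim$mapping$gene)))
    occ <- classify_occupancy(pav)
    curve <- .run_stage("openness_curve", openness_curve(
      pav, n_iter = config$openness$n_iter %||% 100,
      seed = .stage_seed(config$seed, "openness")))
    # a fully closed pan-genome has no positive tail to fit
    plfit <- tryCatch(suppressWarnings(fit_power_law(curve)),
                      error = function(e) NULL)
    report$pangenome <- list(
      n_ogg = length(oggs),
      n_planted = nrow(sim$truth$pav),
      occupancy_classes = as.list(table(occ$class)),
      n_dispensable = sum(occ$dispensable),
      openness_curve = curve,
      power_law = if (!is.null(plfit))
        list(k = plfit$k, a = plfit$a, r2 = plfit$r2)
    )
  }

  if (!is.null(config$ks)) {
    ksc <- config$ks
    ks_values <- .run_stage("molecular_evolution", {
      if (!is.null(ksc$values)) ksc$values
      else simulate_ks_mixture(as.data.frame(ksc$components),
                               n_draws = ksc$n_draws %||% 10000L,
                               seed = .stage_seed(config$seed, "ksmix"))
    })
    fit <- .run_stage("molecular_evolution", filter_and_fit_ks(
      ks_values, seed = .stage_seed(config$seed, "ksmix")))
    dom <- which.max(fit$components$weight)
    rate <- ksc$rate %||% 6.5e-9
    report$ks <- list(
      selected_k = fit$selected_k,
      components = fit$components,
      global_peak = fit$global_peak,
      dominant_mean = fit$components$mean[dom],
      dominant_age_myr = divergence_time(max(fit$components$mean[dom], 0),
                                         rate = rate),
      peak_age_myr = divergence_time(max(fit$global_peak, 0), rate = rate)
    )
  }

  if (!is.null(config$ploidy)) {
    mk <- function(grp, off) simulate_copy_number_table(
      n_species = grp$n_species, asmt_share = grp$asmt_share,
      total_range = grp$total_range %||% c(2L, 120L),
      seed = .stage_seed(config$seed, "dosage") + off)
    cmp <- .run_stage("dosage_stats", ploidy_comparison(
      mk(config$ploidy$a, 0L), mk(config$ploidy$b, 1L)))
    report$ploidy <- list(
      mean_total = as.list(cmp$mean_total),
      fold_change = cmp$fold_change,
      total_t = .htest_brief(cmp$total_t),
      total_mw = .htest_brief(cmp$total_mw),
      share_t = .htest_brief(cmp$share_t),
      share_mw = .htest_brief(cmp$share_mw)
    )
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "pangenome_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
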