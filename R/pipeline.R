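#' Published summary statistics for 46 empirical food webs
#'
#' The per-web summary table shipped with the package: name, species count
#' `N`, basal count `B`, link count `L`, trophic incoherence `q`, the
#' model temperature `T` calibrated to that `q`, habitat `type`, and the
#' coherence-rank `id` (webs numbered by increasing `q`). These are the
#' published per-web statistics for a standard collection of 46 marine,
#' freshwater and terrestrial webs; the full edge lists are not
#' redistributed here.
#'
#' @return a data frame with 46 rows
#' @export
food_web_summaries <- function() {
  path <- system.file("extdata", "food_web_summaries.tsv",
                      package = "trophicmotifs", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Compute triad significance profiles for a corpus of webs
#'
#' Reads every edge-list file, checks trophic validity, computes the
#' incoherence parameter and the triad significance profile of each web, and
#' returns a record table plus the profile objects. Webs that fail to parse
#' or are trophic-invalid are skipped with a logged message, not fatal.
#'
#' Results can be cached: with `cache_dir` set, each web's result is stored
#' keyed by the MD5 of the file content together with all null-model
#' settings, so reruns with identical inputs are hits and bit-identical.
#' Each web's null ensemble is seeded from the master seed combined with the
#' content hash, making results independent of corpus ordering.
#'
#' @param paths character vector of edge-list files, or a single directory
#'   (all regular files inside are taken)
#' @param ensemble_size,swaps_per_link,mode null-model settings, see
#'   [triad_significance()]
#' @param seed integer master seed
#' @param cache_dir optional directory for cached per-web results
#' @return a list of class `tsp_batch`: `records` (data frame with `id`,
#'   `N`, `B`, `L`, `q`, `z_s2`, `zhat_s2`), `tsps` (named list of
#'   `triad_significance` objects) and `skipped` (named character vector of
#'   error messages)
#' @export
run_tsp_batch <- function(paths, ensemble_size = 200, swaps_per_link = 10,
                          mode = c("plain", "mutual"), seed = 1,
                          cache_dir = NULL) {
  mode <- match.arg(mode)
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, full.names = TRUE)
  if (length(paths) < 1) stop("no input files")
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  ids <- tools::file_path_sans_ext(basename(paths))
  records <- list(); tsps <- list(); skipped <- character(0)
  for (i in seq_along(paths)) {
    res <- tryCatch(
      .tsp_one(paths[i], ensemble_size, swaps_per_link, mode, seed, cache_dir),
      error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", ids[i], ": ", conditionMessage(res))
      skipped[ids[i]] <- conditionMessage(res)
      next
    }
    records[[ids[i]]] <- res$record
    tsps[[ids[i]]] <- res$tsp
  }
  if (length(records) == 0) stop("no parseable, trophic-valid web in corpus")
  rec <- do.call(rbind, records)
  rec <- data.frame(id = names(records), rec, row.names = NULL)
  structure(list(records = rec, tsps = tsps, skipped = skipped,
                 settings = list(ensemble_size = ensemble_size,
                                 swaps_per_link = swaps_per_link,
                                 mode = mode, seed = seed)),
            class = "tsp_batch")
}

.tsp_one <- function(path, ensemble_size, swaps_per_link, mode, seed,
                     cache_dir) {
  hash <- unname(tools::md5sum(path))
  key <- paste(hash, ensemble_size, swaps_per_link, mode, seed, sep = "_")
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir, paste0(key, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  web <- read_edge_list(path)
  v <- validate_trophic(web)
  if (!v$valid) stop("not trophic-valid: ", v$reason)
  prof <- trophic_incoherence(web)
  web_seed <- (seed + strtoi(substr(hash, 1, 7), 16L)) %% 2147483647L
  ts <- triad_significance(web, ensemble_size = ensemble_size,
                           swaps_per_link = swaps_per_link, mode = mode,
                           seed = web_seed)
  out <- list(record = data.frame(N = n_species(web),
                                  B = length(basal_species(web)),
                                  L = n_links(web), q = prof$q,
                                  z_s2 = ts$z["S2"],
                                  zhat_s2 = ts$z_hat["S2"]),
              tsp = ts)
  if (!is.null(cache_dir)) saveRDS(out, cache_file)
  out
}

#' Regress incoherence on the basal-species ratio
#'
#' Ordinary least squares of `q` on `B/N` across a set of webs: the linear
#' model `q = a (B/N) + b`. A strongly negative slope reflects the
#' empirical anti-correlation between incoherence and the proportion of
#' basal species. The slope p-value is the usual two-sided t-test on `n - 2`
#' degrees of freedom.
#'
#' @param records a data frame with columns `q`, `B` and `N` (e.g. from
#'   [run_tsp_batch()] or [food_web_summaries()])
#' @return a list of class `qbn_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, and the underlying [stats::lm] fit
#' @export
regress_q_on_basal_ratio <- function(records) {
  stopifnot(all(c("q", "B", "N") %in% names(records)))
  if (nrow(records) < 3) stop("need at least 3 webs")
  ratio <- records$B / records$N
  if (stats::var(ratio) == 0) stop("basal ratio is constant across webs")
  fit <- stats::lm(q ~ ratio, data = data.frame(q = records$q, ratio = ratio))
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_value = unname(s$coefficients[2, 4]),
                 n = nrow(records), fit = fit),
            class = "qbn_regression")
}

#' @export
print.qbn_regression <- function(x, ...) {
  cat(sprintf("q = %.3f (B/N) + %.3f   [n = %d, R^2 = %.3f, p = %.3g]\n",
              x$slope, x$intercept, x$n, x$r_squared, x$p_value))
  invisible(x)
}

#' Assign webs to motif families
#'
#' Clusters the webs of a batch by UPGMA on the profile distance
#' `d = sqrt(2(1 - r))` and cuts the dendrogram at `d_c`. Family numbers are
#' renumbered so that family 1 is the cluster containing the web with the
#' lowest incoherence `q` (labels are then stable across runs).
#'
#' @param batch a `tsp_batch` from [run_tsp_batch()], or a named list of
#'   profiles plus a `records` data frame with matching `id` and `q`
#' @param d_c threshold distance (default 1.1)
#' @param records required when `batch` is a plain list of profiles
#' @return a list of class `family_classification`: `records` (with a
#'   `family` column), `similarity` (`tsp_similarity`), `tree`
#'   ([stats::hclust]) and `d_c`
#' @export
classify_families <- function(batch, d_c = 1.1, records = NULL) {
  if (inherits(batch, "tsp_batch")) {
    tsps <- batch$tsps
    records <- batch$records
  } else {
    tsps <- batch
    if (is.null(records)) stop("`records` is required with a plain profile list")
  }
  if (length(tsps) < 2) stop("need at least 2 profiles to cluster")
  sim <- tsp_similarity_matrix(tsps)
  tree <- tsp_upgma(sim)
  fam <- tsp_families(tree, d_c)
  anchor <- records$id[which.min(records$q)]
  anchor_fam <- fam[[anchor]]
  relabel <- c(anchor_fam, setdiff(sort(unique(fam)), anchor_fam))
  fam <- match(fam, relabel)
  names(fam) <- tree$labels
  records$family <- fam[records$id]
  structure(list(records = records, similarity = sim, tree = tree, d_c = d_c),
            class = "family_classification")
}

#' Fit the coherence model to each web and compare profiles
#'
#' For every record (requiring `N`, `B`, `L`, `q`), calibrates the model
#' temperature to the web's incoherence with [gppm_fit()], generates an
#' ensemble of model webs at the fitted temperature, scores each model web's
#' triad significance profile, and computes the Pearson coefficient between
#' the empirical z-score vector and the ensemble-mean model z-score vector
#' ([model_vs_empirical_r()]). Records whose `q` is infeasible for the model
#' are flagged (`T_fit = NA`) rather than fatal.
#'
#' @param batch a `tsp_batch` from [run_tsp_batch()] (supplies both records
#'   and empirical profiles)
#' @param tol tolerance on mean q for the temperature fit
#' @param seed integer master seed
#' @param model_ensemble model webs per record (1000 matches common
#'   practice; reduce for desk-scale runs)
#' @param null_ensemble,swaps_per_link null-model settings for the model
#'   webs' profiles
#' @param fit_draws draws per Monte-Carlo evaluation inside [gppm_fit()]
#' @return the records data frame with columns `T_fit`, `model_q` and
#'   `model_r` appended
#' @export
fit_models_batch <- function(batch, tol = 0.01, seed = 1,
                             model_ensemble = 1000, null_ensemble = 200,
                             swaps_per_link = 10, fit_draws = 200) {
  stopifnot(inherits(batch, "tsp_batch"))
  rec <- batch$records
  rec$T_fit <- rec$model_q <- rec$model_r <- NA_real_
  set.seed(seed)
  for (i in seq_len(nrow(rec))) {
    id <- rec$id[i]
    fit <- tryCatch(
      gppm_fit(rec$B[i], rec$N[i], rec$L[i], target_q = rec$q[i], tol = tol,
               n_coarse = fit_draws, n_fine = max(fit_draws, 500)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      message("flagging ", id, ": ", conditionMessage(fit))
      next
    }
    rec$T_fit[i] <- fit$T_fit
    rec$model_q[i] <- fit$mean_q
    tsps <- vector("list", model_ensemble)
    for (m in seq_len(model_ensemble)) {
      d <- gppm_generate(rec$B[i], rec$N[i], rec$L[i], fit$T_fit)
      tsps[[m]] <- triad_significance(d$web, ensemble_size = null_ensemble,
                                      swaps_per_link = swaps_per_link)
    }
    rec$model_r[i] <- model_vs_empirical_r(batch$tsps[[id]], tsps)
  }
  rec
}
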